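# Divergence Index: shared-bin histograms, the total-variation statistic,
# threshold classification, bootstrap and reduction metrics.

test_that("groups are binned on shared pooled edges with fair proportions", {
  h <- binSizes(list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4)), bins = 2)
  expect_equal(binEdges(h$a), binEdges(h$b))
  expect_equal(binProportions(h$a), c(0.5, 0.5))
  expect_equal(binProportions(h$b), c(0.5, 0.5))

  # all values in one class
  h1 <- binSizes(list(g = rep(7, 20)), bins = 5)
  expect_equal(sum(binProportions(h1$g) == 1), 1)
  expect_equal(sum(binProportions(h1$g)), 1)

  # unequal n still yields proportions
  h2 <- binSizes(list(a = 1:10, b = 1:100), bins = 10)
  expect_equal(sum(binProportions(h2$a)), 1)
  expect_equal(sampleSize(h2$b), 100L)
})

test_that("explicit edges must cover the data; empty/non-finite groups error", {
  expect_error(binSizes(list(a = 1:10), bins = c(0, 2, 5)),
               "do not cover")
  expect_error(binSizes(list(a = numeric())), "empty")
  expect_error(binSizes(list(bad = c(1, NA, 3))), "bad")
  expect_error(binSizes(list(bad = c(1, Inf))), "bad")
})

test_that("the DI is the normalized sum of class-frequency differences", {
  p <- histFromProps(c(0.5, 0.5))
  q <- histFromProps(c(0.8, 0.2))
  expect_equal(diValue(divergenceIndex(p, q)), 0.3)

  expect_equal(diValue(divergenceIndex(p, p)), 0)
  expect_equal(diCategory(divergenceIndex(p, p)), "moderate")

  disj <- divergenceIndex(histFromProps(c(1, 0)), histFromProps(c(0, 1)))
  expect_equal(diValue(disj), 1)
  expect_equal(diCategory(disj), "substantial")

  # symmetry
  expect_equal(diValue(divergenceIndex(p, q)),
               diValue(divergenceIndex(q, p)))
})

test_that("mismatched bin edges are an error, never silently rebinned", {
  p <- histFromProps(c(0.5, 0.5))
  q <- new("SizeHistogram", edges = c(0, 2, 4), proportions = c(0.5, 0.5),
           n = 10L, groupId = "q")
  expect_error(divergenceIndex(p, q), "different bin edges")
})

test_that("threshold classification matches the reported condition labels", {
  expect_equal(classifyDivergence(0.3), "moderate")
  expect_equal(classifyDivergence(0.6), "substantial")
  expect_equal(classifyDivergence(0.4), "moderate")  # tie -> moderate
  expect_error(classifyDivergence(1.2), "0, 1")
  expect_error(classifyDivergence(-0.1), "0, 1")
})

test_that("DI is a metric: triangle inequality and bounds on random triples", {
  set.seed(101)
  for (i in 1:200) {
    k <- sample(3:12, 1)
    p <- randomProportions(k); q <- randomProportions(k)
    r <- randomProportions(k)
    dpq <- diValue(divergenceIndex(histFromProps(p), histFromProps(q)))
    dqr <- diValue(divergenceIndex(histFromProps(q), histFromProps(r)))
    dpr <- diValue(divergenceIndex(histFromProps(p), histFromProps(r)))
    expect_gte(dpq, 0); expect_lte(dpq, 1)
    expect_lte(dpr, dpq + dqr + 1e-12)
  }
})

test_that("splitting a bin never decreases the DI", {
  set.seed(55)
  for (i in 1:20) {
    a <- rlnorm(300, log(500), 0.5)
    b <- rlnorm(300, log(350), 0.5)
    lo <- min(c(a, b)); hi <- max(c(a, b))
    coarse <- seq(lo, hi, length.out = 6)       # 5 bins
    fine <- seq(lo, hi, length.out = 11)        # each bin split in two
    hc <- binSizes(list(a = a, b = b), bins = coarse)
    hf <- binSizes(list(a = a, b = b), bins = fine)
    expect_gte(diValue(divergenceIndex(hf$a, hf$b)) + 1e-12,
               diValue(divergenceIndex(hc$a, hc$b)))
  }
})

test_that("bootstrap DI is seeded, ordered and detects real shifts", {
  set.seed(7)
  a <- rlnorm(300, log(700), 0.4)
  b <- rlnorm(300, log(420), 0.4)
  r1 <- bootstrapDI(a, b, nBoot = 300, seed = 42)
  r2 <- bootstrapDI(a, b, nBoot = 300, seed = 42)
  expect_identical(diCI(r1), diCI(r2))
  ci <- diCI(r1)
  expect_lte(ci[["low"]], ci[["high"]])
  expect_gt(ci[["low"]], 0)  # a 0.6 median shift is detectable at n=300

  # identical samples: point DI exactly 0, lower bound non-negative
  same <- bootstrapDI(a, a, nBoot = 300, seed = 1)
  expect_equal(diValue(same), 0)
  expect_gte(diCI(same)[["low"]], 0)

  expect_error(bootstrapDI(a, b, nBoot = 50), ">= 100")
  expect_error(bootstrapDI(numeric(), b, nBoot = 200), "non-empty")
})

test_that("same-law DI shrinks with sample size (finite-sample bias floor)", {
  set.seed(31)
  meanDI <- function(n, reps = 60) {
    mean(vapply(seq_len(reps), function(i) {
      a <- rlnorm(n, log(500), 0.4); b <- rlnorm(n, log(500), 0.4)
      h <- binSizes(list(a = a, b = b), bins = 10)
      diValue(divergenceIndex(h$a, h$b))
    }, numeric(1)))
  }
  expect_lt(meanDI(500), meanDI(50))
})

test_that("percent reduction reproduces the reported arithmetic", {
  r <- percentReduction(0.61, 0.29)
  expect_equal(r@percentReduction, 100 * (0.61 - 0.29) / 0.61)
  expect_equal(r@percentReduction, 52.46, tolerance = 1e-3)
  expect_false(r@worsened)

  expect_equal(percentReduction(0.5, 0.25)@percentReduction, 50)
  expect_equal(percentReduction(0.4, 0.4)@percentReduction, 0)
  expect_true(percentReduction(0.3, 0.6)@worsened)
  expect_error(percentReduction(0, 0.2), "undefined")
  expect_error(percentReduction(1.4, 0.2), "0, 1")
})

test_that("DI against an implementation-independent TV computation", {
  set.seed(77)
  a <- rlnorm(400, log(600), 0.5)
  b <- rlnorm(400, log(400), 0.5)
  h <- binSizes(list(a = a, b = b), bins = 12)
  expect_equal(diValue(divergenceIndex(h$a, h$b)),
               bruteTV(a, b, binEdges(h$a)))
})
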