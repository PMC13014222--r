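# Scaffold physics: exact formula evaluation and generate-and-recover for
# every fitted quantity.

test_that("swelling evaluates its formula and rejects non-physical input", {
  expect_equal(swelling(1, 1)@swelling, 0)
  expect_equal(swelling(2, 1)@swelling, 100)
  expect_equal(swelling(1.79, 1.00)@swelling, 79)
  expect_equal(swelling(c(1.79, 1.89), 1)@swelling, c(79, 89))
  expect_error(swelling(0.9, 1), "non-physical")
  expect_error(swelling(1, 0), "positive")
  # strictly increasing in hydrated weight at fixed dry weight
  s <- swelling(c(1.1, 1.5, 2.2), 1)@swelling
  expect_true(all(diff(s) > 0))
})

test_that("Darcy fit recovers a noiseless permeability to 1e-6 relative", {
  kTrue <- 3.7e-12
  df <- simulateSignal(signalConfig("pressure_flow",
    trueParams = list(k = kTrue, viscosity = 0.015, length = 5e-3,
                      area = 1e-4)))
  fit <- fitDarcy(df$pressure_Pa, df$time_s, area = 1e-4, length = 5e-3)
  expect_lt(abs(permeability(fit) / kTrue - 1), 1e-6)
  expect_gt(fit@rSquared, 1 - 1e-9)
})

test_that("Darcy fit is invariant to trial order and unit-consistent rescaling", {
  df <- simulateSignal(signalConfig("pressure_flow", noiseSd = 0.01,
    trueParams = list(k = 1e-12, area = 1e-4, length = 5e-3), seed = 3))
  f1 <- fitDarcy(df$pressure_Pa, df$time_s, area = 1e-4, length = 5e-3)
  ord <- c(4, 1, 5, 2, 3)
  f2 <- fitDarcy(df$pressure_Pa[ord], df$time_s[ord], area = 1e-4,
                 length = 5e-3)
  expect_equal(permeability(f1), permeability(f2))
  # rescaling pressures and viscosity consistently leaves k unchanged
  f3 <- fitDarcy(df$pressure_Pa * 1000, df$time_s, area = 1e-4,
                 length = 5e-3, viscosity = 0.015 * 1000)
  expect_equal(permeability(f1), permeability(f3), tolerance = 1e-12)
  expect_equal(f3@slope, f1@slope * 1000, tolerance = 1e-12)
})

test_that("Darcy fit rejects degenerate designs", {
  expect_error(fitDarcy(c(3000, 3000), c(10, 10), area = 1e-4,
                        length = 5e-3), "distinct")
  expect_error(fitDarcy(c(3000, 5000), c(-1, 10), area = 1e-4,
                        length = 5e-3), "positive")
})

test_that("amide II deconvolution recovers noiseless component areas", {
  sp <- simulateSignal(signalConfig("amide2_spectrum", nPoints = 201,
    trueParams = list(betaArea = 2, alphaArea = 1)))
  fit <- fitAmideII(sp)
  expect_equal(betaFraction(fit), 2 / 3, tolerance = 1e-3)
  expect_equal(fit@betaCenter, 1515, tolerance = 0.1)
  expect_equal(fit@alphaCenter, 1545, tolerance = 0.1)
  expect_equal(fit@betaFraction + fit@alphaFraction, 1)
})

test_that("crystallinity index is the interpolated 1515/1545 ratio", {
  # symmetric band around 1530: identical absorbance at the two markers
  wn <- seq(1480, 1580, by = 0.5)
  ab <- exp(-(wn - 1530)^2 / (2 * 15^2))
  fit <- tryCatch(fitAmideII(wn, ab), error = function(e) NULL)
  ratio <- approx(wn, ab, 1515)$y / approx(wn, ab, 1545)$y
  expect_equal(ratio, 1)
  if (!is.null(fit)) expect_equal(ciRatio(fit), 1, tolerance = 1e-9)
})

test_that("amide II fit errors on flat bands and insufficient coverage", {
  wn <- seq(1480, 1580, by = 1)
  expect_error(fitAmideII(wn, rep(0.3, length(wn))), "flat")
  expect_error(fitAmideII(seq(1480, 1580, by = 20),
                          rnorm(6) + 1), "20 points")
})

test_that("Thioflavin-T relative content is the plain intensity ratio", {
  expect_equal(thtRelativeBeta(5, 5), 1)
  expect_equal(thtRelativeBeta(10, 5), 2)
  expect_error(thtRelativeBeta(-1, 5), "positive")

  # region table: background-subtracted per-replicate means, ratio mean/SD
  set.seed(2)
  mkTable <- function(level) data.frame(
    replicate = rep(1:3, each = 10),
    intensity = level + rnorm(30, 0, 1),
    background = 5)
  s <- mkTable(45); r <- mkTable(25)
  out <- thtSummary(s, r)
  expect_length(out$ratios, 3)
  expect_equal(out$mean, 2, tolerance = 0.1)
  byHand <- tapply(s$intensity - 5, s$replicate, mean) /
            tapply(r$intensity - 5, r$replicate, mean)
  expect_equal(out$ratios, as.numeric(byHand))
})

test_that("Lorentzian peak value matches its closed form at the center", {
  y0 <- 1.5; A <- 40; w <- 20; xc <- 100
  yAt <- y0 + (2 * A / pi) * w / (4 * (xc - xc)^2 + w^2)
  expect_equal(yAt, y0 + 2 * A / (pi * w))
})

test_that("modulus distribution fit recovers a truncated-Lorentzian peak", {
  x <- simulateSignal(signalConfig("modulus_samples", nPoints = 4096,
    trueParams = list(xc = 230, w = 40), seed = 9))
  fit <- fitModulusDistribution(x)
  expect_lt(abs(peakModulus(fit) / 230 - 1), 0.05)
  expect_equal(averageModulus(fit), mean(x))
  # symmetric distribution: peak near the sample median (within bin width)
  expect_lt(abs(peakModulus(fit) - median(x)),
            diff(range(x)) / 10)
  # the Gaussian alternative fits the same data with a similar center
  g <- fitModulusDistribution(x, model = "gaussian")
  expect_lt(abs(peakModulus(g) / 230 - 1), 0.1)
})

test_that("modulus fit rejects degenerate inputs", {
  expect_error(fitModulusDistribution(rep(100, 60)), "degenerate")
  expect_error(fitModulusDistribution(1:10), "at least 50")
})

test_that("sweep analysis finds the constructed -10% crossing", {
  sw <- simulateSignal(signalConfig("amplitude_sweep", nPoints = 50,
    trueParams = list(plateau = 800, gamma0 = 0.02, gammaStar = 0.12)))
  an <- analyzeSweep(sw)
  expect_true(an@hasUltimate)
  expect_equal(ultimateStrain(an), 0.12, tolerance = 0.01)
  expect_equal(plateauModulus(an), 800, tolerance = 1e-9)
})

test_that("a flat G' sweep has no ultimate strain (flagged, not an error)", {
  strain <- exp(seq(log(0.002), log(0.3), length.out = 20))
  an <- analyzeSweep(strain, rep(1000, 20), rep(150, 20))
  expect_false(an@hasUltimate)
  expect_true(is.na(ultimateStrain(an)))
})

test_that("tan delta is pointwise G''/G' and equals 1 where they cross", {
  strain <- exp(seq(log(0.002), log(0.3), length.out = 10))
  gp <- rep(500, 10); gpp <- c(rep(100, 9), 500)
  an <- analyzeSweep(strain, gp, gpp)
  expect_equal(tanDelta(an), gpp / gp)
  expect_equal(tanDelta(an)[10], 1)
})

test_that("ultimate strain grows with the allowed G' deviation", {
  sw <- simulateSignal(signalConfig("amplitude_sweep", nPoints = 60,
    trueParams = list(plateau = 1000, gamma0 = 0.02, gammaStar = 0.05)))
  us <- vapply(c(0.05, 0.10, 0.20), function(dv)
    ultimateStrain(analyzeSweep(sw, deviation = dv)), numeric(1))
  expect_true(all(diff(us) >= 0))  # larger allowed drop -> larger strain
})

test_that("shape factor is the Rg/Rh ratio", {
  expect_equal(shapeFactor(10, 10)@shapeFactor, 1)
  expect_equal(shapeFactor(18, 24)@shapeFactor, 0.75)
  expect_equal(shapeFactor(26, 20)@shapeFactor, 1.3)
  expect_error(shapeFactor(-1, 2), "positive")
})
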