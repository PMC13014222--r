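#' Bin per-group cell sizes into shared-edge frequency histograms
#'
#' All groups are binned over one common set of edges so their class-wise
#' frequencies are directly comparable (the precondition of the Divergence
#' Index). When a binning rule is used the edges are computed on the pooled
#' values; explicit edges must cover every pooled value (values outside are
#' an error, never silently dropped). Frequencies are per-group
#' proportions, class count / group n, so unequal sample sizes compare
#' fairly.
#'
#' @param x either a named list of numeric size vectors or a data.frame
#'   with columns \code{group} and \code{size}.
#' @param bins a single integer K (default 10) for K equal-width classes
#'   over the pooled min-max; \code{"fd"} for Freedman-Diaconis class
#'   widths on the pooled data; or a numeric vector (length >= 2) of
#'   explicit ascending edges.
#' @return A named list of \linkS4class{SizeHistogram} objects, one per
#'   group, all sharing identical edges.
#' @examples
#' h <- binSizes(list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4)), bins = 2)
#' binProportions(h$a)
#' @export
binSizes <- function(x, bins = 10) {
  if (is.data.frame(x)) {
    if (!all(c("group", "size") %in% names(x)))
      stop("data.frame input needs columns 'group' and 'size'")
    x <- split(x$size, x$group)
  }
  if (!is.list(x) || !length(x)) stop("need at least one group of sizes")
  if (is.null(names(x)) || any(!nzchar(names(x))))
    names(x) <- paste0("group", seq_along(x))
  for (g in names(x)) {
    if (!length(x[[g]])) stop("group '", g, "' is empty")
    if (any(!is.finite(x[[g]])))
      stop("group '", g, "' contains non-finite values")
  }
  pooled <- unlist(x, use.names = FALSE)
  if (is.numeric(bins) && length(bins) > 1L) {
    edges <- as.numeric(bins)
    if (any(diff(edges) <= 0)) stop("explicit edges must be ascending")
    if (min(pooled) < edges[1] || max(pooled) > edges[length(edges)])
      stop("explicit edges do not cover the pooled values [",
           signif(min(pooled), 6), ", ", signif(max(pooled), 6), "]")
  } else if (identical(bins, "fd")) {
    k <- max(1L, grDevices::nclass.FD(pooled))
    edges <- .pooledEdges(pooled, k)
  } else if (is.numeric(bins) && length(bins) == 1L && bins >= 1) {
    edges <- .pooledEdges(pooled, as.integer(bins))
  } else stop("'bins' must be a count, \"fd\", or a vector of edges")
  lapply(setNames(names(x), names(x)), function(g)
    .histFromValues(x[[g]], edges, g))
}

.pooledEdges <- function(pooled, k) {
  rng <- range(pooled)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)  # degenerate: widen
  seq(rng[1], rng[2], length.out = k + 1L)
}

# Classes are [e_i, e_{i+1}) with the last class closed on the right.
.histFromValues <- function(values, edges, groupId) {
  cls <- findInterval(values, edges, rightmost.closed = TRUE)
  counts <- tabulate(cls, length(edges) - 1L)
  new("SizeHistogram", edges = as.numeric(edges),
      proportions = counts / length(values),
      n = length(values), groupId = as.character(groupId))
}

#' Divergence Index between two shared-bin size distributions
#'
#' DI = sum_i |p_i - q_i| / 2: the sum of absolute differences in
#' class-wise frequencies, normalized by its theoretical maximum of 2 (the
#' largest the raw sum can be for two probability vectors), so DI lies in
#' [0, 1] with 0 for identical distributions and 1 for disjoint supports.
#' This is the total-variation distance on the binned distributions:
#' symmetric and satisfying the triangle inequality. Histograms with
#' different edges are an error - never silently rebinned.
#'
#' @param p,q \linkS4class{SizeHistogram} objects with identical edges.
#' @param threshold moderate/substantial boundary (default 0.4).
#' @return A \linkS4class{DivergenceResult} (no confidence interval; see
#'   \code{\link{bootstrapDI}}).
#' @examples
#' h <- binSizes(list(a = 1:100, b = (1:100) * 0.6), bins = 10)
#' divergenceIndex(h$a, h$b)
#' @export
divergenceIndex <- function(p, q, threshold = 0.4) {
  stopifnot(is(p, "SizeHistogram"), is(q, "SizeHistogram"))
  if (length(p@edges) != length(q@edges) || any(p@edges != q@edges))
    stop("histograms have different bin edges; rebin both on shared edges")
  di <- min(max(sum(abs(p@proportions - q@proportions)) / 2, 0), 1)
  new("DivergenceResult", di = di, threshold = threshold,
      category = classifyDivergence(di, threshold))
}

#' Classify a Divergence Index value against the threshold
#'
#' Divergence strictly above the threshold (default 0.4) is
#' "substantial"; at or below it, "moderate" (the tie is assigned to
#' moderate).
#'
#' @param di DI value(s) in [0, 1].
#' @param threshold boundary value (default 0.4).
#' @return Character vector: "moderate" or "substantial".
#' @examples
#' classifyDivergence(c(0.3, 0.6))
#' @export
classifyDivergence <- function(di, threshold = 0.4) {
  if (any(!is.finite(di)) || any(di < 0) || any(di > 1))
    stop("'di' must lie in [0, 1]")
  ifelse(di > threshold, "substantial", "moderate")
}

#' Bootstrap confidence interval for the Divergence Index
#'
#' Percentile CI from resampling both size samples with replacement. Bin
#' edges are computed once on the pooled original data and frozen, so every
#' resample is binned on the same classes. The point estimate is the DI of
#' the original samples. Note the DI of two finite samples from the same
#' law is positive (a finite-sample bias floor that shrinks with n), so
#' the CI of a null comparison sits above zero. This uncertainty interval
#' is a package extension beyond the point statistic.
#'
#' @param valuesA,valuesB numeric size samples (non-empty).
#' @param bins binning rule or edges, as in \code{\link{binSizes}}.
#' @param nBoot number of resamples (>= 100; fewer makes the percentile CI
#'   unstable and is an error).
#' @param seed RNG seed for reproducibility.
#' @param conf confidence level (default 0.95).
#' @param threshold classification threshold (default 0.4).
#' @return A \linkS4class{DivergenceResult} with \code{ciLow}/\code{ciHigh}
#'   filled in.
#' @examples
#' a <- rlnorm(200, log(500), 0.5); b <- rlnorm(200, log(300), 0.5)
#' bootstrapDI(a, b, nBoot = 200, seed = 1)
#' @export
bootstrapDI <- function(valuesA, valuesB, bins = 10, nBoot = 1000,
                        seed = NA_integer_, conf = 0.95, threshold = 0.4) {
  if (!length(valuesA) || !length(valuesB))
    stop("both samples must be non-empty")
  if (nBoot < 100) stop("nBoot must be >= 100 for a stable percentile CI")
  h <- binSizes(list(A = valuesA, B = valuesB), bins = bins)
  edges <- h$A@edges
  point <- divergenceIndex(h$A, h$B, threshold)
  nA <- length(valuesA); nB <- length(valuesB)
  tv <- function(a, b) {
    pa <- tabulate(findInterval(a, edges, rightmost.closed = TRUE),
                   length(edges) - 1L) / length(a)
    pb <- tabulate(findInterval(b, edges, rightmost.closed = TRUE),
                   length(edges) - 1L) / length(b)
    sum(abs(pa - pb)) / 2
  }
  dis <- .withSeed(seed, vapply(seq_len(nBoot), function(i) {
    tv(valuesA[sample.int(nA, nA, replace = TRUE)],
       valuesB[sample.int(nB, nB, replace = TRUE)])
  }, numeric(1)))
  ci <- quantile(dis, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  new("DivergenceResult", di = point@di, threshold = threshold,
      category = point@category, ciLow = ci[1], ciHigh = ci[2],
      nBoot = as.integer(nBoot), seed = as.integer(seed))
}

#' Treatment-response reduction of the Divergence Index
#'
#' Relative change of the deviation from the reference (healthy)
#' distribution: 100 * (diPre - diPost) / diPre. Negative values (a DI
#' that worsened under treatment) are allowed and flagged; a pre-treatment
#' DI of zero leaves the relative change undefined and is an error.
#'
#' @param diPre DI before treatment (> 0); a
#'   \linkS4class{DivergenceResult} is also accepted.
#' @param diPost DI after treatment; DivergenceResult accepted.
#' @return A \linkS4class{ReductionResult}.
#' @examples
#' percentReduction(0.61, 0.29)  # ~52.5% reduction
#' @export
percentReduction <- function(diPre, diPost) {
  if (is(diPre, "DivergenceResult")) diPre <- diValue(diPre)
  if (is(diPost, "DivergenceResult")) diPost <- diValue(diPost)
  if (!is.finite(diPre) || diPre < 0 || diPre > 1 ||
      !is.finite(diPost) || diPost < 0 || diPost > 1)
    stop("DI values must lie in [0, 1]")
  if (diPre == 0)
    stop("diPre is 0: relative reduction is undefined")
  pct <- 100 * (diPre - diPost) / diPre
  new("ReductionResult", diPre = diPre, diPost = diPost,
      absoluteReduction = diPre - diPost, percentReduction = pct,
      worsened = pct < 0)
}
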