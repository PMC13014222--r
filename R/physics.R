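#' Scaffold swelling (water absorption)
#'
#' Swelling(%) = 100 * (Wh - Wd) / Wd from hydrated and dry specimen
#' weights. A hydrated weight below the dry weight is non-physical and an
#' error. Vectorized over specimens.
#'
#' @param wHydrated hydrated weight(s), g.
#' @param wDry dry weight(s), g (> 0).
#' @return A \linkS4class{SwellingRecord}.
#' @examples
#' swelling(1.79, 1.00)  # 79%
#' @export
swelling <- function(wHydrated, wDry) {
  .assertPositive(wDry, "wDry")
  if (any(!is.finite(wHydrated)) || any(wHydrated < wDry))
    stop("hydrated weight below dry weight is non-physical")
  new("SwellingRecord", wHydrated = as.numeric(wHydrated),
      wDry = as.numeric(wDry),
      swelling = 100 * (wHydrated - wDry) / wDry)
}

#' Darcy permeability from pressure/perfusion-time trials
#'
#' Each trial perfuses a fixed fluid volume through the scaffold under a
#' constant pressure difference; the flow rate is Q = volume / time and the
#' superficial velocity v = Q / A. Darcy's law Q = k A dp / (mu L) makes
#' dp linear in v through the origin (no flow without a pressure drop), so
#' the slope of the through-origin least-squares fit of dp against v gives
#' k = mu L / slope. The default viscosity 0.015 Pa s corresponds to a
#' 66 wt% aqueous glycerol solution near room temperature (about 25 C) and
#' should be overridden if the perfusion fluid or temperature differ.
#'
#' @param deltaP applied pressure differences, Pa (>= 2 distinct values).
#' @param time time to perfuse \code{volume}, s (> 0).
#' @param area scaffold cross-sectional area, m^2.
#' @param length scaffold height along the flow, m.
#' @param viscosity fluid dynamic viscosity, Pa s.
#' @param volume perfused fluid volume per trial, m^3 (default 2 mL).
#' @return A \linkS4class{PermeabilityResult}; the uncentered R^2 of the
#'   through-origin fit is reported as goodness of fit.
#' @examples
#' df <- simulateSignal(signalConfig("pressure_flow",
#'   trueParams = list(k = 2e-12, area = 1e-4, length = 5e-3)))
#' fitDarcy(df$pressure_Pa, df$time_s, area = 1e-4, length = 5e-3)
#' @export
fitDarcy <- function(deltaP, time, area, length, viscosity = 0.015,
                     volume = 2e-6) {
  if (base::length(deltaP) != base::length(time))
    stop("'deltaP' and 'time' must have equal length")
  if (base::length(unique(deltaP)) < 2L)
    stop("need at least 2 distinct pressures")
  .assertPositive(deltaP, "deltaP")
  .assertPositive(time, "time")
  .assertScalarPositive(area, "area")
  .assertScalarPositive(length, "length")
  .assertScalarPositive(viscosity, "viscosity")
  .assertScalarPositive(volume, "volume")
  v <- (volume / time) / area
  fit <- lm(deltaP ~ v + 0)
  slope <- unname(coef(fit)[1])
  if (!is.finite(slope) || slope <= 0)
    stop("non-positive fitted slope: permeability is undefined")
  r2 <- 1 - sum(resid(fit)^2) / sum(deltaP^2)  # uncentered (no intercept)
  new("PermeabilityResult", k = viscosity * length / slope, slope = slope,
      rSquared = min(max(r2, 0), 1), nPoints = base::length(deltaP),
      viscosity = viscosity, length = length, area = area)
}

.gauss <- function(x, h, c, s) h * exp(-(x - c)^2 / (2 * s^2))

#' Two-Gaussian deconvolution of the amide II band
#'
#' Restricts the spectrum to the amide II window (default 1480-1580
#' cm^-1), subtracts a linear baseline anchored at the window endpoints,
#' and fits the band with two Gaussian components whose centers are
#' bounded to the beta-sheet (1510-1520 cm^-1) and alpha-helix
#' (1540-1550 cm^-1) positions. Component fractions are analytic Gaussian
#' areas divided by the total fitted band area. The crystallinity index is
#' also reported as the interpolated 1515/1545 cm^-1 absorbance ratio of
#' the input spectrum.
#'
#' @param wavenumber ascending wavenumbers, cm^-1 (or a data.frame with
#'   columns \code{wavenumber}, \code{absorbance}).
#' @param absorbance absorbance values (omit for data.frame input).
#' @param window fitted band limits, cm^-1.
#' @param betaBounds,alphaBounds allowed center ranges, cm^-1.
#' @return An \linkS4class{AmideFit}. A flat band or a fit that fails to
#'   converge is an error carrying the optimizer diagnostics.
#' @examples
#' sp <- simulateSignal(signalConfig("amide2_spectrum", nPoints = 201))
#' fitAmideII(sp)
#' @export
fitAmideII <- function(wavenumber, absorbance = NULL,
                       window = c(1480, 1580),
                       betaBounds = c(1510, 1520),
                       alphaBounds = c(1540, 1550)) {
  if (is.data.frame(wavenumber)) {
    absorbance <- wavenumber$absorbance
    wavenumber <- wavenumber$wavenumber
  }
  if (any(!is.finite(absorbance))) stop("absorbance must be finite")
  if (is.unsorted(wavenumber))
    stop("wavenumber must be ascending (see readSpectrum for auto-reversal)")
  sel <- wavenumber >= window[1] & wavenumber <= window[2]
  if (sum(sel) < 20L)
    stop("spectrum must cover the window with at least 20 points")
  x <- wavenumber[sel]
  yRaw <- absorbance[sel]
  # linear baseline through the window endpoints
  n <- length(x)
  base <- yRaw[1] + (yRaw[n] - yRaw[1]) * (x - x[1]) / (x[n] - x[1])
  y <- yRaw - base
  if (max(abs(y)) <= .Machine$double.eps * 100 || sd(y) == 0)
    stop("flat or zero amide II band: nothing to fit")
  h0 <- max(y)
  start <- list(h1 = max(approx(x, y, 1515)$y, h0 / 4), c1 = 1515, s1 = 10,
                h2 = max(approx(x, y, 1545)$y, h0 / 4), c2 = 1545, s2 = 10)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ .gauss(x, h1, c1, s1) + .gauss(x, h2, c2, s2),
      start = start,
      lower = c(h1 = 0, c1 = betaBounds[1], s1 = 1,
                h2 = 0, c2 = alphaBounds[1], s2 = 1),
      upper = c(h1 = Inf, c1 = betaBounds[2], s1 = 60,
                h2 = Inf, c2 = alphaBounds[2], s2 = 60),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("amide II fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  p <- coef(fit)
  areaB <- p["h1"] * p["s1"] * sqrt(2 * pi)
  areaA <- p["h2"] * p["s2"] * sqrt(2 * pi)
  if (areaB <= 0 || areaA <= 0)
    stop("amide II fit collapsed a component to zero area")
  ciR <- approx(wavenumber, absorbance, 1515)$y /
         approx(wavenumber, absorbance, 1545)$y
  new("AmideFit",
      betaCenter = unname(p["c1"]), betaWidth = unname(p["s1"]),
      betaArea = unname(areaB),
      alphaCenter = unname(p["c2"]), alphaWidth = unname(p["s2"]),
      alphaArea = unname(areaA),
      betaFraction = unname(areaB / (areaB + areaA)),
      alphaFraction = unname(areaA / (areaB + areaA)),
      ciRatio = ciR, rmse = sqrt(mean(resid(fit)^2)),
      window = as.numeric(window))
}

#' Thioflavin-T relative beta-sheet content
#'
#' Ratio of sample to reference fluorescence intensity at the emission
#' peak (480 nm): the relative beta-sheet content of the sample with
#' respect to the reference preparation.
#'
#' @param intensitySample,intensityReference positive intensities (a.u.),
#'   vectorized.
#' @return Numeric ratio(s).
#' @examples
#' thtRelativeBeta(2, 1)
#' @export
thtRelativeBeta <- function(intensitySample, intensityReference) {
  .assertPositive(intensitySample, "intensitySample")
  .assertPositive(intensityReference, "intensityReference")
  intensitySample / intensityReference
}

#' Summarize Thioflavin-T region intensities into a relative content
#'
#' For imaging-based measurements: each replicate contributes the
#' background-subtracted mean intensity over its measured regions
#' (typically 10 regions of 50 um^2); the relative beta-sheet content is
#' the per-replicate sample/reference ratio, summarized as mean and SD.
#'
#' @param sampleTable,referenceTable data.frames with columns
#'   \code{replicate}, \code{intensity} and optionally \code{background}
#'   (default 0), one row per region.
#' @return list with \code{ratios} (per replicate), \code{mean}, \code{sd}.
#' @export
thtSummary <- function(sampleTable, referenceTable) {
  perRep <- function(df, what) {
    if (!all(c("replicate", "intensity") %in% names(df)))
      stop(what, " table needs columns 'replicate' and 'intensity'")
    bg <- if ("background" %in% names(df)) df$background else 0
    m <- tapply(df$intensity - bg, df$replicate, mean)
    if (any(m <= 0))
      stop("non-positive background-subtracted intensity in ", what)
    m
  }
  s <- perRep(sampleTable, "sample")
  r <- perRep(referenceTable, "reference")
  if (length(s) != length(r))
    stop("sample and reference must have the same replicates")
  ratios <- as.numeric(s) / as.numeric(r)
  list(ratios = ratios, mean = mean(ratios), sd = sd(ratios))
}

#' Peak fit of a Young's-modulus surface distribution
#'
#' Histograms the per-pixel moduli (Freedman-Diaconis classes) and fits the
#' occurrence curve with
#' \deqn{y = y_0 + \frac{2A}{\pi}\,\frac{w}{4 (x - x_c)^2 + w^2}}
#' a Cauchy/Lorentzian peak in which \eqn{x_c} is the peak (most probable)
#' modulus and \eqn{w} the full width at half maximum. The arithmetic mean
#' of the raw values is reported separately as the average modulus; for a
#' heavy-tailed surface distribution the two differ. A Gaussian peak of the
#' same area parametrization is available via \code{model = "gaussian"}
#' (see the package vignette for why both forms are offered).
#'
#' @param values raw modulus values, kPa (>= 50; all-equal values are a
#'   degenerate error).
#' @param model "lorentzian" (default) or "gaussian".
#' @param bins number of histogram classes, or "fd" (default) for
#'   Freedman-Diaconis.
#' @return A \linkS4class{LorentzFit}.
#' @examples
#' x <- simulateSignal(signalConfig("modulus_samples", nPoints = 1000,
#'                                  seed = 1))
#' fitModulusDistribution(x)
#' @export
fitModulusDistribution <- function(values,
                                   model = c("lorentzian", "gaussian"),
                                   bins = "fd") {
  model <- match.arg(model)
  values <- as.numeric(values)
  if (length(values) < 50L) stop("need at least 50 modulus values")
  if (any(!is.finite(values))) stop("modulus values must be finite")
  if (diff(range(values)) == 0)
    stop("degenerate input: all modulus values are equal")
  k <- if (identical(bins, "fd"))
    max(10L, grDevices::nclass.FD(values)) else as.integer(bins)
  breaks <- seq(min(values), max(values), length.out = k + 1L)
  cls <- findInterval(values, breaks, rightmost.closed = TRUE)
  counts <- tabulate(cls, k)
  mids <- (breaks[-1] + breaks[-(k + 1L)]) / 2
  bw <- diff(breaks[1:2])
  x <- mids; y <- counts
  startW <- max(2 * bw, stats::IQR(values) / 2)
  start <- list(y0 = 0, A = length(values) * bw,
                xc = mids[which.max(counts)], w = startW)
  form <- if (model == "lorentzian")
    y ~ y0 + (2 * A / pi) * w / (4 * (x - xc)^2 + w^2)
  else
    y ~ y0 + A / (w / 2.354820045 * sqrt(2 * pi)) *
      exp(-(x - xc)^2 / (2 * (w / 2.354820045)^2))  # w is FWHM in both
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = data.frame(x = x, y = y), start = start,
                      lower = c(y0 = -Inf, A = 0, xc = min(values),
                                w = bw / 10),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) stop("modulus distribution fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  p <- coef(fit)
  new("LorentzFit", xc = unname(p["xc"]), w = unname(p["w"]),
      A = unname(p["A"]), y0 = unname(p["y0"]),
      peakModulus = unname(p["xc"]), averageModulus = mean(values),
      model = model, rmse = sqrt(mean(resid(fit)^2)))
}

#' Strain-sweep analysis: plateau, ultimate strain and tan(delta)
#'
#' The plateau storage modulus is the mean G' over the first
#' \code{plateauPoints} points of the sweep (the low-strain linear
#' viscoelastic region). The ultimate strain - the LVR limit - is the first
#' strain at which G' falls \code{deviation} (default 10%) below the
#' plateau, linearly interpolated in log10-strain between the bracketing
#' points. If G' never drops below the threshold the ultimate strain is
#' absent (NA, flagged), which is a valid outcome, not an error. The loss
#' tangent G''/G' is computed pointwise.
#'
#' @param strain ascending oscillation strains (%), >= 5 points (or a
#'   data.frame with columns \code{strain}, \code{Gp}, \code{Gpp}).
#' @param gPrime,gDoublePrime storage and loss moduli, Pa.
#' @param deviation relative G' drop defining the LVR limit.
#' @param plateauPoints number of initial points averaged for the plateau.
#' @return A \linkS4class{SweepAnalysis}.
#' @examples
#' sw <- simulateSignal(signalConfig("amplitude_sweep", nPoints = 40))
#' ultimateStrain(analyzeSweep(sw))
#' @export
analyzeSweep <- function(strain, gPrime = NULL, gDoublePrime = NULL,
                         deviation = 0.10, plateauPoints = 5) {
  if (is.data.frame(strain)) {
    gPrime <- strain$Gp
    gDoublePrime <- strain$Gpp
    strain <- strain$strain
  }
  n <- length(strain)
  if (n < 5L) stop("need at least 5 sweep points")
  if (is.unsorted(strain, strictly = TRUE))
    stop("strains must be strictly ascending")
  .assertPositive(gPrime, "gPrime")
  .assertPositive(gDoublePrime, "gDoublePrime")
  if (deviation <= 0 || deviation >= 1)
    stop("'deviation' must lie in (0, 1)")
  m <- min(plateauPoints, n)
  plateau <- mean(gPrime[seq_len(m)])
  thr <- (1 - deviation) * plateau
  below <- which(gPrime < thr)
  if (length(below)) {
    i <- below[1]
    if (i == 1L) us <- strain[1]
    else {
      lg <- log10(strain)
      f <- (thr - gPrime[i - 1]) / (gPrime[i] - gPrime[i - 1])
      us <- 10^(lg[i - 1] + f * (lg[i] - lg[i - 1]))
    }
    hasU <- TRUE
  } else {
    us <- NA_real_
    hasU <- FALSE
  }
  new("SweepAnalysis", strain = strain, gPrime = gPrime,
      gDoublePrime = gDoublePrime, tanDelta = gDoublePrime / gPrime,
      plateauG = plateau, ultimateStrain = us, hasUltimate = hasU,
      deviation = deviation)
}

#' Shape factor Rg/Rh of a polymer in solution
#'
#' The ratio of the radius of gyration to the hydrodynamic radius
#' discriminates chain conformations: about 0.66-0.8 for compact globular
#' chains, above 1 for extended or unfolded chains.
#'
#' @param rg radius of gyration, nm (> 0), vectorized.
#' @param rh hydrodynamic radius, nm (> 0).
#' @return A \linkS4class{HydroDims}.
#' @examples
#' shapeFactor(18, 24)  # compact: 0.75
#' @export
shapeFactor <- function(rg, rh) {
  .assertPositive(rg, "rg")
  .assertPositive(rh, "rh")
  new("HydroDims", rg = as.numeric(rg), rh = as.numeric(rh),
      shapeFactor = rg / rh)
}
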