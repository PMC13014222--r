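#' VoxelVolume: a 3D labeled or binary voxel grid with physical spacing
#'
#' Container for 3D image data on a regular grid. The voxel array is stored
#' in \code{(z, y, x)} axis order with integer values: 0 is background (or
#' void), positive integers are cell labels (or 1 for the material phase of
#' a binary volume). Spacing is micrometres per voxel along each axis.
#'
#' @slot voxels 3D integer array, dim = (z, y, x).
#' @slot spacing numeric length-3, micrometres per voxel along (z, y, x).
#' @export
setClass("VoxelVolume",
  representation(voxels = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@voxels)) != 3L)
      msg <- c(msg, "voxels must be a 3D array")
    if (!is.integer(object@voxels))
      msg <- c(msg, "voxels must be integer-valued")
    else if (length(object@voxels) && min(object@voxels) < 0L)
      msg <- c(msg, "labels must be non-negative")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive finite values (z, y, x)")
    if (length(msg)) msg else TRUE
  })

#' SizeHistogram: a binned cell-size frequency distribution
#'
#' Frequencies of a per-cell scalar size (projected area, volume, ...) over
#' shared bin edges; the operand of the Divergence Index. Proportions are
#' per-group class frequencies (class count / group n) and sum to 1.
#'
#' @slot edges strictly increasing numeric bin boundaries.
#' @slot proportions per-class frequencies, length = length(edges) - 1.
#' @slot n integer sample size.
#' @slot groupId character group identifier.
#' @export
setClass("SizeHistogram",
  representation(edges = "numeric", proportions = "numeric",
                 n = "integer", groupId = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@edges) < 2L || any(diff(object@edges) <= 0))
      msg <- c(msg, "edges must be strictly increasing, length >= 2")
    if (length(object@proportions) != length(object@edges) - 1L)
      msg <- c(msg, "length(proportions) must equal length(edges) - 1")
    if (any(object@proportions < 0))
      msg <- c(msg, "proportions must be non-negative")
    if (abs(sum(object@proportions) - 1) > 1e-12)
      msg <- c(msg, "proportions must sum to 1 (within 1e-12)")
    if (length(object@n) != 1L || is.na(object@n) || object@n < 1L)
      msg <- c(msg, "n must be a positive integer")
    if (length(msg)) msg else TRUE
  })

#' DivergenceResult: a Divergence Index value with classification
#'
#' The Divergence Index (DI) between two shared-bin size distributions:
#' half the sum of absolute class-wise frequency differences, i.e. the
#' total-variation distance, in [0, 1]. Category is "substantial" iff
#' DI strictly exceeds the threshold (default 0.4), "moderate" otherwise.
#' Bootstrap percentile confidence bounds are optional (NA when absent).
#'
#' @slot di DI value in [0, 1].
#' @slot threshold classification threshold (default 0.4).
#' @slot category "moderate" or "substantial".
#' @slot ciLow,ciHigh bootstrap percentile CI bounds, NA if not computed.
#' @slot nBoot number of bootstrap resamples (0 if none).
#' @slot seed RNG seed used for the bootstrap (NA if none).
#' @export
setClass("DivergenceResult",
  representation(di = "numeric", threshold = "numeric", category = "character",
                 ciLow = "numeric", ciHigh = "numeric", nBoot = "integer",
                 seed = "integer"),
  prototype(ciLow = NA_real_, ciHigh = NA_real_, nBoot = 0L,
            seed = NA_integer_),
  validity = function(object) {
    msg <- character()
    if (object@di < -1e-12 || object@di > 1 + 1e-12)
      msg <- c(msg, "di must lie in [0, 1]")
    if (!object@category %in% c("moderate", "substantial"))
      msg <- c(msg, "category must be 'moderate' or 'substantial'")
    if (!is.na(object@ciLow) && !is.na(object@ciHigh)) {
      if (object@ciLow > object@ciHigh)
        msg <- c(msg, "ciLow must not exceed ciHigh")
    }
    if (length(msg)) msg else TRUE
  })

#' ReductionResult: treatment-response change in Divergence Index
#'
#' Absolute and relative reduction of the DI between a pre-treatment and a
#' post-treatment comparison against the same reference distribution.
#' Negative percent reduction indicates worsening and is flagged.
#'
#' @slot diPre,diPost DI before and after treatment.
#' @slot absoluteReduction diPre - diPost.
#' @slot percentReduction 100 * (diPre - diPost) / diPre.
#' @slot worsened TRUE when the DI increased.
#' @export
setClass("ReductionResult",
  representation(diPre = "numeric", diPost = "numeric",
                 absoluteReduction = "numeric", percentReduction = "numeric",
                 worsened = "logical"))

#' PorosityReport: porosity and local thickness/separation distributions
#'
#' Porosity (void fraction) of a binary volume together with histograms of
#' the local wall thickness (material phase) and local separation (void
#' phase), both computed with the largest-inscribed-sphere local thickness
#' method. Histogram densities are voxel proportions summing to 1; empty
#' distributions (degenerate all-void/all-material volumes) have length 0.
#'
#' @slot porosity void-voxel fraction in [0, 1].
#' @slot thicknessBreaks,thicknessDensity wall-thickness histogram (um).
#' @slot separationBreaks,separationDensity pore-separation histogram (um).
#' @slot meanThickness,meanSeparation mean local thickness per phase (um).
#' @export
setClass("PorosityReport",
  representation(porosity = "numeric",
                 thicknessBreaks = "numeric", thicknessDensity = "numeric",
                 separationBreaks = "numeric", separationDensity = "numeric",
                 meanThickness = "numeric", meanSeparation = "numeric"),
  validity = function(object) {
    if (object@porosity < 0 || object@porosity > 1)
      return("porosity must lie in [0, 1]")
    TRUE
  })

#' SwellingRecord: scaffold water-uptake measurement
#'
#' Swelling percentage 100 * (Wh - Wd) / Wd from hydrated and dry weights.
#' Slots are parallel vectors (one element per specimen).
#'
#' @slot wHydrated,wDry hydrated and dry weights (g).
#' @slot swelling swelling percentage.
#' @export
setClass("SwellingRecord",
  representation(wHydrated = "numeric", wDry = "numeric",
                 swelling = "numeric"))

#' PermeabilityResult: Darcy permeability from pressure-perfusion data
#'
#' Through-origin least-squares fit of pressure drop against superficial
#' fluid velocity; the Darcy coefficient is k = mu * L / slope.
#'
#' @slot k permeability (m^2).
#' @slot slope fitted slope d(Delta p)/d(v) (Pa s / m).
#' @slot rSquared uncentered R^2 of the through-origin fit.
#' @slot nPoints number of trials fitted.
#' @slot viscosity,length,area the fluid/geometry constants used (SI).
#' @export
setClass("PermeabilityResult",
  representation(k = "numeric", slope = "numeric", rSquared = "numeric",
                 nPoints = "integer", viscosity = "numeric",
                 length = "numeric", area = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@k <= 0) msg <- c(msg, "k must be positive")
    if (object@rSquared < 0 || object@rSquared > 1)
      msg <- c(msg, "rSquared must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' AmideFit: two-Gaussian deconvolution of the amide II band
#'
#' Components: beta-sheet (center bounded to 1510-1520 cm^-1) and
#' alpha-helix (1540-1550 cm^-1). Fractions are component areas divided by
#' the total fitted band area; the crystallinity index is the interpolated
#' 1515/1545 cm^-1 absorbance ratio.
#'
#' @slot betaCenter,betaWidth,betaArea beta component (cm^-1, cm^-1, a.u.).
#' @slot alphaCenter,alphaWidth,alphaArea alpha component.
#' @slot betaFraction,alphaFraction component area fractions in (0, 1).
#' @slot ciRatio 1515/1545 cm^-1 absorbance ratio.
#' @slot rmse root-mean-square fit residual (a.u.).
#' @slot window fitted wavenumber window (cm^-1).
#' @export
setClass("AmideFit",
  representation(betaCenter = "numeric", betaWidth = "numeric",
                 betaArea = "numeric", alphaCenter = "numeric",
                 alphaWidth = "numeric", alphaArea = "numeric",
                 betaFraction = "numeric", alphaFraction = "numeric",
                 ciRatio = "numeric", rmse = "numeric", window = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@betaArea <= 0 || object@alphaArea <= 0)
      msg <- c(msg, "component areas must be positive")
    if (object@betaFraction <= 0 || object@betaFraction >= 1)
      msg <- c(msg, "betaFraction must lie in (0, 1)")
    if (length(msg)) msg else TRUE
  })

#' LorentzFit: peak fit of a Young's-modulus surface distribution
#'
#' Histogrammed nanoindentation moduli fitted with
#' y = y0 + (2A/pi) * w / (4 (x - xc)^2 + w^2) (Cauchy/Lorentzian form;
#' w is the full width at half maximum and xc the peak, i.e. most probable,
#' modulus). A Gaussian alternative of equal area/width parametrization is
#' available via \code{model = "gaussian"}. The arithmetic mean of the raw
#' values is reported separately as the average modulus.
#'
#' @slot xc peak (most probable) modulus (kPa).
#' @slot w full width at half maximum (kPa).
#' @slot A fitted peak area.
#' @slot y0 constant offset.
#' @slot peakModulus alias of xc (kPa).
#' @slot averageModulus arithmetic mean of the input values (kPa).
#' @slot model "lorentzian" or "gaussian".
#' @slot rmse root-mean-square residual of the histogram fit.
#' @export
setClass("LorentzFit",
  representation(xc = "numeric", w = "numeric", A = "numeric", y0 = "numeric",
                 peakModulus = "numeric", averageModulus = "numeric",
                 model = "character", rmse = "numeric"),
  validity = function(object) {
    if (object@w <= 0) return("width w must be positive")
    TRUE
  })

#' SweepAnalysis: strain-sweep rheology with LVR limit
#'
#' Storage/loss moduli versus oscillation strain, enriched with the
#' pointwise loss tangent, the plateau storage modulus (mean over the
#' initial linear viscoelastic region window) and the ultimate strain: the
#' first strain at which G' falls a given fraction (default 10%) below the
#' plateau, linearly interpolated in log-strain. When G' never drops below
#' the threshold the ultimate strain is absent (NA) and flagged.
#'
#' @slot strain ascending strain values (%).
#' @slot gPrime,gDoublePrime storage and loss moduli (Pa).
#' @slot tanDelta pointwise G''/G'.
#' @slot plateauG plateau storage modulus (Pa).
#' @slot ultimateStrain LVR limit (%), NA when not reached.
#' @slot hasUltimate TRUE when the threshold crossing exists.
#' @slot deviation relative G' drop defining the limit (default 0.10).
#' @export
setClass("SweepAnalysis",
  representation(strain = "numeric", gPrime = "numeric",
                 gDoublePrime = "numeric", tanDelta = "numeric",
                 plateauG = "numeric", ultimateStrain = "numeric",
                 hasUltimate = "logical", deviation = "numeric"))

#' HydroDims: solution conformation from Rg and Rh
#'
#' The shape factor Rg/Rh: about 0.66-0.8 for compact globular chains,
#' above 1 for extended or unfolded conformations.
#'
#' @slot rg radius of gyration (nm).
#' @slot rh hydrodynamic radius (nm).
#' @slot shapeFactor Rg/Rh.
#' @export
setClass("HydroDims",
  representation(rg = "numeric", rh = "numeric", shapeFactor = "numeric"),
  validity = function(object) {
    if (any(object@rg <= 0) || any(object@rh <= 0))
      return("radii must be positive")
    TRUE
  })
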