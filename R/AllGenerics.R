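#' @name accessors
#' @title Accessor generics for nichemetrics result objects
#' @description Accessors for the core S4 containers: the voxel grid and its
#'   spacing, histogram components, Divergence Index results and fit outputs.
#' @param object an S4 object from this package.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("binEdges", function(object) standardGeneric("binEdges"))
#' @rdname accessors
#' @export
setGeneric("binProportions", function(object) standardGeneric("binProportions"))
#' @rdname accessors
#' @export
setGeneric("groupId", function(object) standardGeneric("groupId"))
#' @rdname accessors
#' @export
setGeneric("sampleSize", function(object) standardGeneric("sampleSize"))
#' @rdname accessors
#' @export
setGeneric("diValue", function(object) standardGeneric("diValue"))
#' @rdname accessors
#' @export
setGeneric("diCategory", function(object) standardGeneric("diCategory"))
#' @rdname accessors
#' @export
setGeneric("diCI", function(object) standardGeneric("diCI"))
#' @rdname accessors
#' @export
setGeneric("porosity", function(object) standardGeneric("porosity"))
#' @rdname accessors
#' @export
setGeneric("permeability", function(object) standardGeneric("permeability"))
#' @rdname accessors
#' @export
setGeneric("betaFraction", function(object) standardGeneric("betaFraction"))
#' @rdname accessors
#' @export
setGeneric("ciRatio", function(object) standardGeneric("ciRatio"))
#' @rdname accessors
#' @export
setGeneric("peakModulus", function(object) standardGeneric("peakModulus"))
#' @rdname accessors
#' @export
setGeneric("averageModulus", function(object) standardGeneric("averageModulus"))
#' @rdname accessors
#' @export
setGeneric("plateauModulus", function(object) standardGeneric("plateauModulus"))
#' @rdname accessors
#' @export
setGeneric("ultimateStrain", function(object) standardGeneric("ultimateStrain"))
#' @rdname accessors
#' @export
setGeneric("tanDelta", function(object) standardGeneric("tanDelta"))

#' @rdname accessors
#' @export
setMethod("voxels", "VoxelVolume", function(object) object@voxels)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "VoxelVolume", function(object) object@spacing)
#' @rdname accessors
#' @export
setMethod("binEdges", "SizeHistogram", function(object) object@edges)
#' @rdname accessors
#' @export
setMethod("binProportions", "SizeHistogram", function(object) object@proportions)
#' @rdname accessors
#' @export
setMethod("groupId", "SizeHistogram", function(object) object@groupId)
#' @rdname accessors
#' @export
setMethod("sampleSize", "SizeHistogram", function(object) object@n)
#' @rdname accessors
#' @export
setMethod("diValue", "DivergenceResult", function(object) object@di)
#' @rdname accessors
#' @export
setMethod("diCategory", "DivergenceResult", function(object) object@category)
#' @rdname accessors
#' @export
setMethod("diCI", "DivergenceResult",
          function(object) c(low = object@ciLow, high = object@ciHigh))
#' @rdname accessors
#' @export
setMethod("porosity", "PorosityReport", function(object) object@porosity)
#' @rdname accessors
#' @export
setMethod("permeability", "PermeabilityResult", function(object) object@k)
#' @rdname accessors
#' @export
setMethod("betaFraction", "AmideFit", function(object) object@betaFraction)
#' @rdname accessors
#' @export
setMethod("ciRatio", "AmideFit", function(object) object@ciRatio)
#' @rdname accessors
#' @export
setMethod("peakModulus", "LorentzFit", function(object) object@peakModulus)
#' @rdname accessors
#' @export
setMethod("averageModulus", "LorentzFit", function(object) object@averageModulus)
#' @rdname accessors
#' @export
setMethod("plateauModulus", "SweepAnalysis", function(object) object@plateauG)
#' @rdname accessors
#' @export
setMethod("ultimateStrain", "SweepAnalysis",
          function(object) object@ultimateStrain)
#' @rdname accessors
#' @export
setMethod("tanDelta", "SweepAnalysis", function(object) object@tanDelta)

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@voxels)
  labs <- unique(object@voxels[object@voxels != 0L])
  cat(sprintf("VoxelVolume: %d x %d x %d voxels (z, y, x), spacing %s um\n",
              d[1], d[2], d[3],
              paste(signif(object@spacing, 3), collapse = " x ")))
  cat(sprintf("  %d labeled object(s), %.1f%% occupied\n", length(labs),
              100 * mean(object@voxels != 0L)))
})

setMethod("show", "SizeHistogram", function(object) {
  cat(sprintf("SizeHistogram '%s': %d classes over [%.3g, %.3g], n = %d\n",
              object@groupId, length(object@proportions),
              min(object@edges), max(object@edges), object@n))
})

setMethod("show", "DivergenceResult", function(object) {
  cat(sprintf("Divergence Index: %.4f (%s; threshold %.2f)\n",
              object@di, object@category, object@threshold))
  if (!is.na(object@ciLow))
    cat(sprintf("  bootstrap %d resamples, CI [%.4f, %.4f]\n",
                object@nBoot, object@ciLow, object@ciHigh))
})

setMethod("show", "ReductionResult", function(object) {
  cat(sprintf("DI reduction: %.3f -> %.3f (absolute %.3f, %.1f%%)%s\n",
              object@diPre, object@diPost, object@absoluteReduction,
              object@percentReduction,
              if (object@worsened) " [worsened]" else ""))
})

setMethod("show", "PorosityReport", function(object) {
  cat(sprintf("PorosityReport: porosity %.3f\n", object@porosity))
  if (length(object@thicknessDensity))
    cat(sprintf("  mean wall thickness %.2f um (%d classes)\n",
                object@meanThickness, length(object@thicknessDensity)))
  if (length(object@separationDensity))
    cat(sprintf("  mean separation %.2f um (%d classes)\n",
                object@meanSeparation, length(object@separationDensity)))
})

setMethod("show", "SwellingRecord", function(object) {
  cat(sprintf("Swelling: %s%%\n",
              paste(signif(object@swelling, 4), collapse = ", ")))
})

setMethod("show", "PermeabilityResult", function(object) {
  cat(sprintf("Darcy permeability k = %.4g m^2 (slope %.4g Pa s/m, R^2 %.4f, n = %d)\n",
              object@k, object@slope, object@rSquared, object@nPoints))
})

setMethod("show", "AmideFit", function(object) {
  cat(sprintf("Amide II fit (window %g-%g cm^-1):\n",
              object@window[1], object@window[2]))
  cat(sprintf("  beta : center %.1f, FWHM-equiv width %.1f, area %.3g (fraction %.3f)\n",
              object@betaCenter, object@betaWidth, object@betaArea,
              object@betaFraction))
  cat(sprintf("  alpha: center %.1f, width %.1f, area %.3g (fraction %.3f)\n",
              object@alphaCenter, object@alphaWidth, object@alphaArea,
              object@alphaFraction))
  cat(sprintf("  crystallinity index (1515/1545) %.3f, rmse %.3g\n",
              object@ciRatio, object@rmse))
})

setMethod("show", "LorentzFit", function(object) {
  cat(sprintf("%s modulus fit: peak %.4g kPa, width %.3g, average %.4g kPa\n",
              object@model, object@peakModulus, object@w,
              object@averageModulus))
})

setMethod("show", "SweepAnalysis", function(object) {
  cat(sprintf("Strain sweep: plateau G' = %.4g Pa; ", object@plateauG))
  if (object@hasUltimate)
    cat(sprintf("ultimate strain %.4g%% (%.0f%% G' drop)\n",
                object@ultimateStrain, 100 * object@deviation))
  else
    cat(sprintf("G' never drops %.0f%% below plateau (no ultimate strain)\n",
                100 * object@deviation))
})

setMethod("show", "HydroDims", function(object) {
  cat(sprintf("Rg = %s nm, Rh = %s nm, shape factor Rg/Rh = %s\n",
              paste(signif(object@rg, 3), collapse = ", "),
              paste(signif(object@rh, 3), collapse = ", "),
              paste(signif(object@shapeFactor, 3), collapse = ", ")))
})
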