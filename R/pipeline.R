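#' Run a config-driven end-to-end analysis pipeline
#'
#' Executes an ordered subset of the stages \code{simulate}, \code{morpho},
#' \code{di} and \code{physics}, wiring each stage's input to the previous
#' stage's output (or to files named in the config), and writes a
#' machine-readable JSON manifest recording inputs, outputs, seeds,
#' package version and MD5 checksums of every written file. The manifest
#' contains no timestamps, so identical config + seed reproduce identical
#' manifests for deterministic stages. The single run seed is fanned out
#' to each stochastic stage through a documented hash of the stage name,
#' so stages draw from unrelated RNG substreams.
#'
#' Config layout (YAML file or equivalent nested list):
#' \preformatted{
#' seed: 7
#' output_dir: out
#' stages: [simulate, morpho, di]
#' simulate:
#'   mode: volumes            # or "sizes" (size samples only, no raster)
#'   groups:
#'     healthy:  {regime: healthy,  nCells: 30}
#'     fibrotic: {regime: fibrotic, nCells: 30}
#' morpho:
#'   sizeMetric: projected_area   # or "volume"
#' di:
#'   reference: healthy
#'   bins: 10
#'   boot: 0                  # > 0 adds bootstrap CIs
#' physics:
#'   darcy:    {file: darcy.csv, area: 1.0e-4, length: 5.0e-3}
#'   spectrum: {file: spectrum.csv}
#'   sweep:    {file: sweep.csv}
#'   moduli:   {file: moduli.csv}
#' }
#' Schema violations are reported before any stage runs; a failing stage
#' leaves a partial manifest (written to the output directory) with the
#' failed stage's diagnostics.
#'
#' @param config path to a YAML run config, or the equivalent list.
#' @param outputDir overrides the config's \code{output_dir}.
#' @return The manifest, invisibly (also written to
#'   \code{output_dir/manifest.json}).
#' @examples
#' cfg <- list(seed = 1, stages = list("simulate", "di"),
#'             simulate = list(mode = "sizes", groups = list(
#'               healthy = list(regime = "healthy", nCells = 100),
#'               fibrotic = list(regime = "fibrotic", nCells = 100))),
#'             di = list(reference = "healthy"),
#'             output_dir = tempfile("run"))
#' mf <- runPipeline(cfg)
#' mf$stages$di$pairs
#' @export
runPipeline <- function(config, outputDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .validateRunConfig(config)
  outDir <- if (!is.null(outputDir)) outputDir
            else if (!is.null(config$output_dir)) config$output_dir
            else stop("config must name an output_dir")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) NA_integer_ else as.integer(config$seed)
  stages <- unlist(config$stages)
  manifest <- list(package = "nichemetrics",
                   version = as.character(packageVersion("nichemetrics")),
                   seed = seed, stages = list(), outputs = list())
  ctx <- new.env(parent = emptyenv())

  writeManifest <- function() {
    path <- file.path(outDir, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null")
    path
  }
  if (!length(stages)) {
    writeManifest()
    return(invisible(manifest))
  }
  for (stage in stages) {
    res <- tryCatch(
      switch(stage,
             simulate = .stageSimulate(config, ctx, outDir, seed),
             morpho   = .stageMorpho(config, ctx, outDir),
             di       = .stageDI(config, ctx, outDir, seed),
             physics  = .stagePhysics(config, ctx, outDir)),
      error = function(e) structure(list(error = conditionMessage(e)),
                                    class = "stageFailure"))
    if (inherits(res, "stageFailure")) {
      manifest$stages[[stage]] <- list(status = "failed",
                                       error = res$error)
      writeManifest()
      stop("pipeline stage '", stage, "' failed: ", res$error)
    }
    manifest$stages[[stage]] <- res
  }
  files <- list.files(outDir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(outDir, "manifest.json"))
  sums <- tools::md5sum(files)
  manifest$outputs <- as.list(setNames(unname(sums),
                                       basename(names(sums))))
  writeManifest()
  invisible(manifest)
}

.validateRunConfig <- function(config) {
  if (!is.list(config)) stop("run config must be a list")
  known <- c("simulate", "morpho", "di", "physics")
  stages <- unlist(config$stages)
  bad <- setdiff(stages, known)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(stages)) stop("stages must not repeat")
  if (!is.null(config$seed) &&
      (length(config$seed) != 1L || is.na(suppressWarnings(
        as.integer(config$seed)))))
    stop("seed must be a single integer")
  # stage input resolvability
  if ("morpho" %in% stages) {
    before <- stages[seq_len(match("morpho", stages) - 1L)]
    if (!"simulate" %in% before && is.null(config$morpho$file))
      stop("stage 'morpho' needs a prior 'simulate' stage or morpho$file")
  }
  if ("di" %in% stages) {
    before <- stages[seq_len(match("di", stages) - 1L)]
    if (!any(c("simulate", "morpho") %in% before) &&
        is.null(config$di$file))
      stop("stage 'di' needs a prior simulate/morpho stage or di$file")
  }
  if ("simulate" %in% stages &&
      (is.null(config$simulate$groups) || !length(config$simulate$groups)))
    stop("stage 'simulate' needs simulate$groups")
  invisible(TRUE)
}

.stageSimulate <- function(config, ctx, outDir, seed) {
  sc <- config$simulate
  mode <- if (is.null(sc$mode)) "volumes" else sc$mode
  groups <- sc$groups
  info <- list(mode = mode, groups = list())
  if (mode == "sizes") {
    cfgs <- lapply(names(groups), function(g) {
      args <- groups[[g]]
      args$seed <- .stageSeed(seed, paste0("simulate:", g))
      do.call(nicheConfig, args)
    })
    names(cfgs) <- names(groups)
    sizes <- simulateSizeSamples(cfgs)
    path <- file.path(outDir, "sizes.csv")
    write.csv(sizes, path, row.names = FALSE)
    ctx$sizes <- sizes
    for (g in names(groups))
      info$groups[[g]] <- list(seed = cfgs[[g]]$seed,
                               n = cfgs[[g]]$nCells)
    info$output <- "sizes.csv"
  } else {
    ctx$volumes <- list()
    for (g in names(groups)) {
      args <- groups[[g]]
      args$seed <- .stageSeed(seed, paste0("simulate:", g))
      cfg <- do.call(nicheConfig, args)
      sim <- simulateNicheVolume(cfg)
      vPath <- file.path(outDir, paste0(g, "_labels.tif"))
      tPath <- file.path(outDir, paste0(g, "_truth.csv"))
      writeVoxelVolume(sim$volume, vPath)
      write.csv(sim$truth, tPath, row.names = FALSE)
      ctx$volumes[[g]] <- sim$volume
      info$groups[[g]] <- list(seed = cfg$seed, n = cfg$nCells,
                               outputs = basename(c(vPath, tPath)))
    }
  }
  info
}

.stageMorpho <- function(config, ctx, outDir) {
  mc <- config$morpho
  metric <- if (is.null(mc$sizeMetric)) "projected_area" else mc$sizeMetric
  if (!metric %in% c("projected_area", "volume"))
    stop("morpho$sizeMetric must be 'projected_area' or 'volume'")
  vols <- ctx$volumes
  if (is.null(vols)) {
    if (is.null(mc$file)) stop("no volumes available for morpho stage")
    vols <- list(input = readVoxelVolume(
      mc$file, if (is.null(mc$spacing)) 1 else unlist(mc$spacing)))
  }
  sizes <- NULL
  info <- list(sizeMetric = metric, groups = list())
  for (g in names(vols)) {
    cells <- measureCells(vols[[g]])
    path <- file.path(outDir, paste0(g, "_cells.csv"))
    write.csv(cells, path, row.names = FALSE)
    col <- if (metric == "projected_area") "projected_area_um2"
           else "volume_um3"
    if (nrow(cells))
      sizes <- rbind(sizes, data.frame(group = g, size = cells[[col]]))
    info$groups[[g]] <- list(cells = nrow(cells),
                             output = basename(path))
  }
  ctx$sizes <- sizes
  info
}

.stageDI <- function(config, ctx, outDir, seed) {
  dc <- config$di
  sizes <- ctx$sizes
  if (is.null(sizes)) {
    if (is.null(dc$file)) stop("no size table available for di stage")
    sizes <- readSizeTable(dc$file)
  }
  bins <- if (is.null(dc$bins)) 10 else
    if (length(dc$bins) > 1L) unlist(dc$bins) else dc$bins
  boot <- if (is.null(dc$boot)) 0L else as.integer(dc$boot)
  threshold <- if (is.null(dc$threshold)) 0.4 else dc$threshold
  hists <- binSizes(sizes, bins = bins)
  groups <- names(hists)
  ref <- if (is.null(dc$reference)) groups[1] else dc$reference
  if (!ref %in% groups) stop("di reference group '", ref, "' not found")
  valuesOf <- function(g) sizes$size[sizes$group == g]
  pairs <- list()
  for (a in seq_along(groups)) for (b in seq_along(groups)) {
    if (a >= b) next
    g1 <- groups[a]; g2 <- groups[b]
    d <- divergenceIndex(hists[[g1]], hists[[g2]], threshold)
    entry <- list(di = diValue(d), category = diCategory(d))
    if (boot > 0) {
      bd <- bootstrapDI(valuesOf(g1), valuesOf(g2), bins = bins,
                        nBoot = boot, threshold = threshold,
                        seed = .stageSeed(seed, paste0("di:", g1, ":", g2)))
      entry$ciLow <- bd@ciLow
      entry$ciHigh <- bd@ciHigh
      entry$nBoot <- boot
    }
    pairs[[paste(g1, g2, sep = "|")]] <- entry
  }
  report <- list(reference = ref, threshold = threshold,
                 edges = binEdges(hists[[1]]),
                 proportions = lapply(hists, binProportions),
                 n = lapply(hists, sampleSize),
                 pairs = pairs)
  # treatment-response reduction when the config names a pre/post pair
  if (!is.null(dc$pre) && !is.null(dc$post)) {
    key <- function(g) paste(sort(c(ref, g))[1], sort(c(ref, g))[2],
                             sep = "|")
    diPre <- pairs[[key(dc$pre)]]$di
    diPost <- pairs[[key(dc$post)]]$di
    red <- percentReduction(diPre, diPost)
    report$reduction <- list(pre = dc$pre, post = dc$post,
                             diPre = red@diPre, diPost = red@diPost,
                             absolute = red@absoluteReduction,
                             percent = red@percentReduction)
  }
  path <- file.path(outDir, "di_report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(report["pairs"], list(output = basename(path)))
}

.stagePhysics <- function(config, ctx, outDir) {
  pc <- config$physics
  if (is.null(pc) || !length(pc)) stop("physics stage has no tasks")
  report <- list()
  if (!is.null(pc$darcy)) {
    d <- pc$darcy
    df <- read.csv(d$file)
    if (!all(c("pressure_Pa", "time_s") %in% names(df)))
      stop("darcy CSV needs columns pressure_Pa, time_s")
    fit <- fitDarcy(df$pressure_Pa, df$time_s, area = d$area,
                    length = d$length,
                    viscosity = if (is.null(d$viscosity)) 0.015
                                else d$viscosity,
                    volume = if (is.null(d$volume)) 2e-6 else d$volume)
    report$darcy <- list(k_m2 = fit@k, slope = fit@slope,
                         r_squared = fit@rSquared, n = fit@nPoints)
  }
  if (!is.null(pc$spectrum)) {
    sp <- readSpectrum(pc$spectrum$file)
    fit <- fitAmideII(sp)
    report$amide2 <- list(beta_fraction = fit@betaFraction,
                          alpha_fraction = fit@alphaFraction,
                          beta_center = fit@betaCenter,
                          alpha_center = fit@alphaCenter,
                          ci_ratio = fit@ciRatio, rmse = fit@rmse)
  }
  if (!is.null(pc$sweep)) {
    df <- read.csv(pc$sweep$file)
    if (!all(c("strain", "Gp", "Gpp") %in% names(df)))
      stop("sweep CSV needs columns strain, Gp, Gpp")
    an <- analyzeSweep(df)
    report$sweep <- list(plateau_G = an@plateauG,
                         ultimate_strain = an@ultimateStrain,
                         has_ultimate = an@hasUltimate)
  }
  if (!is.null(pc$moduli)) {
    df <- read.csv(pc$moduli$file)
    fit <- fitModulusDistribution(df[[1]],
      model = if (is.null(pc$moduli$model)) "lorentzian"
              else pc$moduli$model)
    report$moduli <- list(peak_kPa = fit@peakModulus,
                          average_kPa = fit@averageModulus,
                          width = fit@w, model = fit@model)
  }
  path <- file.path(outDir, "physics_report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(report, list(output = basename(path)))
}

#' Validate an input file against an expected format
#'
#' Format-specific structural checks with precise diagnostics:
#' \describe{
#'   \item{tiff}{readable multi-page TIFF, integer pixel type, >= 2D.}
#'   \item{cells}{CSV with the per-cell morphometry columns.}
#'   \item{sizes}{CSV with columns group, size; finite sizes.}
#'   \item{spectrum}{CSV with wavenumber, absorbance; a descending
#'     wavenumber axis is reported as auto-reversible (the readers reverse
#'     it with a warning).}
#'   \item{sweep}{CSV with strain, Gp, Gpp; ascending strain.}
#'   \item{darcy}{CSV with pressure_Pa, time_s; positive values.}
#'   \item{moduli}{single-column numeric CSV.}
#' }
#' An unreadable file is reported distinctly from readable-but-invalid
#' content.
#'
#' @param path file to check.
#' @param expectedFormat one of the formats above.
#' @return list with \code{ok} (logical), \code{format}, and a character
#'   vector \code{issues} (empty when the file passes).
#' @export
validateInputs <- function(path, expectedFormat = c("tiff", "cells",
                           "sizes", "spectrum", "sweep", "darcy",
                           "moduli")) {
  expectedFormat <- match.arg(expectedFormat)
  if (!file.exists(path)) stop("file not found (unreadable): ", path)
  issues <- character()
  note <- character()
  if (expectedFormat == "tiff") {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                      error = function(e)
                        stop("unreadable TIFF: ", conditionMessage(e),
                             call. = FALSE))
    if (!is.list(pages)) pages <- list(pages)
    if (length(dim(pages[[1]])) < 2L)
      issues <- c(issues, "pages must be at least 2D")
    vals <- unlist(lapply(pages, function(p) p[seq_len(min(100, length(p)))]))
    if (any(abs(vals - round(vals)) > 0))
      issues <- c(issues, "pixel values are not integers (not a label image)")
  } else {
    df <- tryCatch(read.csv(path),
                   error = function(e)
                     stop("unreadable CSV: ", conditionMessage(e),
                          call. = FALSE))
    needCols <- switch(expectedFormat,
      cells = c("label", "volume_um3", "surface_um2", "sphericity",
                "projected_area_um2", "eq_diameter_um"),
      sizes = c("group", "size"),
      spectrum = c("wavenumber", "absorbance"),
      sweep = c("strain", "Gp", "Gpp"),
      darcy = c("pressure_Pa", "time_s"),
      moduli = NULL)
    missing <- setdiff(needCols, names(df))
    if (length(missing))
      issues <- c(issues, paste0("missing column(s): ",
                                 paste(missing, collapse = ", ")))
    else switch(expectedFormat,
      sizes = {
        bad <- which(!is.finite(df$size))
        if (length(bad))
          issues <- c(issues, paste0("non-finite size at row(s) ",
                                     paste(head(bad, 5), collapse = ", ")))
      },
      spectrum = {
        if (is.unsorted(df$wavenumber)) {
          if (!is.unsorted(rev(df$wavenumber)))
            note <- c(note,
              "descending wavenumber axis: will be auto-reversed on read")
          else issues <- c(issues, "wavenumber axis is not monotone")
        }
      },
      sweep = {
        if (is.unsorted(df$strain, strictly = TRUE))
          issues <- c(issues, "strain must be strictly ascending")
      },
      darcy = {
        if (any(df$pressure_Pa <= 0) || any(df$time_s <= 0))
          issues <- c(issues, "pressures and times must be positive")
      },
      moduli = {
        if (!is.numeric(df[[1]]))
          issues <- c(issues, "first column must be numeric moduli")
      },
      NULL)
  }
  list(ok = length(issues) == 0L, format = expectedFormat,
       issues = issues, notes = note)
}
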