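#' Configuration for the synthetic niche-volume generator
#'
#' Describes a population of megakaryocyte-like cells to rasterize into a
#' labeled voxel volume: spheres with lognormal diameters, optionally
#' carrying a cylindrical proplatelet-like protrusion (which lowers
#' sphericity, as maturing megakaryocytes do). The \code{regime} models the
#' niche condition: \code{"fibrotic"} shifts the diameter median by a
#' multiplicative factor (default 0.6, i.e. smaller cells), and
#' \code{"treated"} moves that shift a configurable fraction (default 0.5)
#' back toward the healthy median, mimicking partial pharmacological
#' restoration of maturation.
#'
#' Defaults (healthy diameter median 30 um, sigma-log 0.35) are generator
#' configuration, not measured values.
#'
#' @param nCells number of cells to place (>= 0).
#' @param volumeShape voxel grid dimensions (z, y, x).
#' @param voxelSpacing micrometres per voxel (z, y, x); scalar recycled.
#' @param diameterMedian healthy-regime median cell diameter (um).
#' @param diameterSdLog lognormal sigma of the diameter law (>= 0).
#' @param protrusionRate probability that a cell carries a protrusion.
#' @param protrusionLengthMedian,protrusionLengthSdLog lognormal law of
#'   protrusion length (um).
#' @param protrusionRadiusFraction protrusion radius as a fraction of the
#'   cell radius (must be < 1 so the protrusion stays thinner than the
#'   cell).
#' @param regime niche condition: "healthy", "fibrotic" or "treated".
#' @param regimeShift multiplicative factor on the diameter median; when
#'   NULL it is derived from the regime (healthy 1, fibrotic
#'   \code{fibroticShift}, treated
#'   \code{1 - treatedRecovery * (1 - fibroticShift)}).
#' @param fibroticShift diameter-median factor of the fibrotic regime.
#' @param treatedRecovery fraction of the fibrotic shift recovered under
#'   treatment.
#' @param maxRetries placement retries per cell before an "overcrowded"
#'   error.
#' @param seed RNG seed (NA = use the current stream).
#' @return A validated configuration list of class \code{"nicheConfig"}.
#' @examples
#' cfg <- nicheConfig(nCells = 3, volumeShape = c(80, 160, 160), seed = 1)
#' sim <- simulateNicheVolume(cfg)
#' sim$truth
#' @export
nicheConfig <- function(nCells = 50,
                        volumeShape = c(64, 256, 256),
                        voxelSpacing = c(1, 1, 1),
                        diameterMedian = 30,
                        diameterSdLog = 0.35,
                        protrusionRate = 0.3,
                        protrusionLengthMedian = 15,
                        protrusionLengthSdLog = 0.3,
                        protrusionRadiusFraction = 0.25,
                        regime = c("healthy", "fibrotic", "treated"),
                        regimeShift = NULL,
                        fibroticShift = 0.6,
                        treatedRecovery = 0.5,
                        maxRetries = 1000,
                        seed = NA_integer_) {
  regime <- match.arg(regime)
  if (length(nCells) != 1L || is.na(nCells) || nCells < 0)
    stop("'nCells' must be a single non-negative count")
  if (any(volumeShape < 1)) stop("'volumeShape' must be positive (z, y, x)")
  if (length(voxelSpacing) == 1L) voxelSpacing <- rep(voxelSpacing, 3L)
  .assertPositive(voxelSpacing, "voxelSpacing")
  .assertScalarPositive(diameterMedian, "diameterMedian")
  if (diameterSdLog < 0) stop("'diameterSdLog' must be >= 0")
  if (protrusionRate < 0 || protrusionRate > 1)
    stop("'protrusionRate' must lie in [0, 1]")
  .assertScalarPositive(protrusionLengthMedian, "protrusionLengthMedian")
  if (protrusionLengthSdLog < 0) stop("'protrusionLengthSdLog' must be >= 0")
  if (protrusionRadiusFraction <= 0 || protrusionRadiusFraction >= 1)
    stop("'protrusionRadiusFraction' must lie in (0, 1)")
  if (is.null(regimeShift))
    regimeShift <- switch(regime,
                          healthy  = 1,
                          fibrotic = fibroticShift,
                          treated  = 1 - treatedRecovery * (1 - fibroticShift))
  .assertScalarPositive(regimeShift, "regimeShift")
  structure(list(nCells = as.integer(nCells),
                 volumeShape = as.integer(volumeShape),
                 voxelSpacing = as.numeric(voxelSpacing),
                 diameterMedian = diameterMedian,
                 diameterSdLog = diameterSdLog,
                 protrusionRate = protrusionRate,
                 protrusionLengthMedian = protrusionLengthMedian,
                 protrusionLengthSdLog = protrusionLengthSdLog,
                 protrusionRadiusFraction = protrusionRadiusFraction,
                 regime = regime, regimeShift = regimeShift,
                 maxRetries = as.integer(maxRetries),
                 seed = as.integer(seed)),
            class = "nicheConfig")
}

# Exact volume of the generating solid: ball(r) union a cylinder of radius
# rp running from the center to r + L along an axis through the center. The
# added volume is the cylinder part outside the sphere, integrated in
# closed form.
.solidVolume <- function(r, hasProtrusion, L, rp) {
  v <- 4 / 3 * pi * r^3
  i <- which(hasProtrusion)
  if (length(i)) {
    a <- sqrt(r[i]^2 - rp[i]^2)
    seg <- pi * rp[i]^2 * (r[i] - a) -
      pi * (r[i]^2 * (r[i] - a) - (r[i]^3 - a^3) / 3)
    v[i] <- v[i] + pi * rp[i]^2 * L[i] + seg
  }
  v
}

#' Generate a labeled niche volume with known ground truth
#'
#' Places \code{nCells} non-overlapping cells (spheres, optionally with one
#' cylindrical protrusion) uniformly in the volume by center rejection
#' sampling, then rasterizes them into an integer label image (label i =
#' cell i, background 0). The returned ground truth carries the analytic
#' volume of each generating solid, the oracle for morphometry tests.
#'
#' Deterministic for a fixed seed. Placement keeps every cell (including
#' its protrusion) at least one voxel away from other cells and from the
#' volume faces, so labels are unambiguous; if a placement cannot be found
#' within \code{maxRetries} draws the generator stops with an
#' "overcrowded" error.
#'
#' @param config a \code{\link{nicheConfig}}.
#' @return A list with elements \code{volume} (a
#'   \linkS4class{VoxelVolume}) and \code{truth} (data.frame: label,
#'   centerZ/Y/X um, trueDiameter um, trueVolume um^3, hasProtrusion,
#'   protrusionLength um).
#' @export
simulateNicheVolume <- function(config) {
  stopifnot(inherits(config, "nicheConfig"))
  shape <- config$volumeShape
  sp <- config$voxelSpacing
  if (any(shape < 1) || prod(shape) == 0) stop("zero-sized volume")
  arr <- array(0L, dim = shape)
  truth <- data.frame(label = integer(), centerZ = numeric(),
                      centerY = numeric(), centerX = numeric(),
                      trueDiameter = numeric(), trueVolume = numeric(),
                      hasProtrusion = logical(),
                      protrusionLength = numeric())
  if (config$nCells == 0L)
    return(list(volume = VoxelVolume(arr, sp), truth = truth))

  .withSeed(config$seed, {
    n <- config$nCells
    extent <- shape * sp
    d <- rlnorm(n, meanlog = log(config$diameterMedian * config$regimeShift),
                sdlog = config$diameterSdLog)
    r <- d / 2
    hasP <- runif(n) < config$protrusionRate
    L <- ifelse(hasP,
                rlnorm(n, log(config$protrusionLengthMedian),
                       config$protrusionLengthSdLog),
                0)
    rp <- config$protrusionRadiusFraction * r
    # reach: radius of the smallest ball around the center containing the
    # whole solid, plus one voxel of clearance
    reach <- ifelse(hasP, sqrt((r + L)^2 + rp^2), r) + max(sp)
    centers <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      lo <- reach[i]
      hi <- extent - reach[i]
      if (any(hi <= lo))
        stop("volume too small to contain cell ", i,
             " (diameter ", signif(d[i], 3), " um)")
      ok <- FALSE
      for (try in seq_len(config$maxRetries)) {
        cand <- lo + runif(3) * (hi - lo)
        if (i == 1L) { ok <- TRUE }
        else {
          prev <- centers[seq_len(i - 1L), , drop = FALSE]
          dist <- sqrt(rowSums((prev - matrix(cand, i - 1L, 3,
                                              byrow = TRUE))^2))
          ok <- all(dist > reach[i] + reach[seq_len(i - 1L)])
        }
        if (ok) { centers[i, ] <- cand; break }
      }
      if (!ok)
        stop("overcrowded: could not place cell ", i, " after ",
             config$maxRetries, " retries")
    }
    # random protrusion directions (uniform on the sphere)
    u <- matrix(rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2))

    for (i in seq_len(n)) {
      arr <- .rasterizeCell(arr, sp, i, centers[i, ], r[i], hasP[i],
                            L[i], rp[i], u[i, ])
    }
    truth <- data.frame(label = seq_len(n),
                        centerZ = centers[, 1], centerY = centers[, 2],
                        centerX = centers[, 3],
                        trueDiameter = d,
                        trueVolume = .solidVolume(r, hasP, L, rp),
                        hasProtrusion = hasP, protrusionLength = L)
  })
  list(volume = VoxelVolume(arr, sp), truth = truth)
}

# Rasterize one cell into the label array: voxel centers at
# (index - 0.5) * spacing; a voxel belongs to the cell if it is inside the
# sphere or within the protrusion cylinder (distance-to-segment <= rp).
.rasterizeCell <- function(arr, sp, label, center, r, hasP, L, rp, u) {
  shape <- dim(arr)
  reach <- if (hasP) sqrt((r + L)^2 + rp^2) else r
  lo <- pmax(1L, ceiling((center - reach) / sp + 0.5))
  hi <- pmin(shape, floor((center + reach) / sp + 0.5))
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  dz <- (zi - 0.5) * sp[1] - center[1]
  dy <- (yi - 0.5) * sp[2] - center[2]
  dx <- (xi - 0.5) * sp[3] - center[3]
  nz <- length(dz); ny <- length(dy); nx <- length(dx)
  Z <- array(dz, c(nz, ny, nx))
  Y <- array(rep(dy, each = nz), c(nz, ny, nx))
  X <- array(rep(dx, each = nz * ny), c(nz, ny, nx))
  inside <- Z^2 + Y^2 + X^2 <= r^2
  if (hasP && L > 0) {
    # distance from voxel to the segment 0 -> (r + L) u from the center
    t <- Z * u[1] + Y * u[2] + X * u[3]
    tc <- pmin(pmax(t, 0), r + L)
    d2 <- (Z - tc * u[1])^2 + (Y - tc * u[2])^2 + (X - tc * u[3])^2
    inside <- inside | (d2 <= rp^2)
  }
  sub <- arr[zi, yi, xi, drop = FALSE]
  sub[inside] <- as.integer(label)
  arr[zi, yi, xi] <- sub
  arr
}

#' Draw per-group cell-size samples from niche configurations
#'
#' For each configuration, draws \code{nCells} scalar sizes from the
#' regime's diameter law: the size is the area of the generating sphere's
#' equatorial section, pi (d/2)^2, emulating the per-cell area measurements
#' that feed size-distribution comparisons. No volume is rasterized, so
#' large samples are cheap.
#'
#' @param configs a list of \code{\link{nicheConfig}} objects; list names
#'   (or, failing that, regimes) become group labels.
#' @return data.frame with columns \code{group}, \code{size} (um^2).
#' @examples
#' sizes <- simulateSizeSamples(list(
#'   healthy  = nicheConfig(nCells = 200, regime = "healthy", seed = 1),
#'   fibrotic = nicheConfig(nCells = 200, regime = "fibrotic", seed = 2)))
#' tapply(sizes$size, sizes$group, median)
#' @export
simulateSizeSamples <- function(configs) {
  if (inherits(configs, "nicheConfig")) configs <- list(configs)
  if (!length(configs)) stop("need at least one group configuration")
  nm <- names(configs)
  if (is.null(nm)) nm <- rep("", length(configs))
  out <- vector("list", length(configs))
  for (g in seq_along(configs)) {
    cfg <- configs[[g]]
    stopifnot(inherits(cfg, "nicheConfig"))
    if (cfg$nCells < 1L) stop("each group needs nCells >= 1")
    gid <- if (nzchar(nm[g])) nm[g] else cfg$regime
    sizes <- .withSeed(cfg$seed, {
      dia <- rlnorm(cfg$nCells,
                    meanlog = log(cfg$diameterMedian * cfg$regimeShift),
                    sdlog = cfg$diameterSdLog)
      pi * (dia / 2)^2
    })
    out[[g]] <- data.frame(group = gid, size = sizes)
  }
  do.call(rbind, out)
}

#' Configuration for instrument-like signal generators
#'
#' @param kind one of \code{"pressure_flow"}, \code{"amide2_spectrum"},
#'   \code{"modulus_samples"}, \code{"amplitude_sweep"},
#'   \code{"porous_volume"}.
#' @param trueParams named list of kind-specific ground-truth parameters
#'   (see \code{\link{simulateSignal}} for defaults).
#' @param noiseSd relative noise standard deviation (>= 0).
#' @param nPoints number of points / samples (>= 2).
#' @param seed RNG seed (NA = current stream).
#' @return A validated configuration list of class \code{"signalConfig"}.
#' @export
signalConfig <- function(kind, trueParams = list(), noiseSd = 0,
                         nPoints = 50, seed = NA_integer_) {
  kinds <- c("pressure_flow", "amide2_spectrum", "modulus_samples",
             "amplitude_sweep", "porous_volume")
  if (length(kind) != 1L || !kind %in% kinds)
    stop("unknown signal kind '", paste(kind, collapse = ","),
         "'; must be one of: ", paste(kinds, collapse = ", "))
  if (noiseSd < 0) stop("'noiseSd' must be >= 0")
  if (nPoints < 2) stop("'nPoints' must be >= 2")
  structure(list(kind = kind, trueParams = trueParams, noiseSd = noiseSd,
                 nPoints = as.integer(nPoints), seed = as.integer(seed)),
            class = "signalConfig")
}

#' Generate an instrument-like signal with known ground truth
#'
#' Seeded generators for the fixtures behind every scaffold-physics fit:
#' \describe{
#'   \item{pressure_flow}{Pressure/perfusion-time trials obeying Darcy's
#'     law at permeability \code{k} (m^2), with relative noise on the
#'     times. Params: \code{k} (1e-12), \code{viscosity} (0.015 Pa s),
#'     \code{length} (5e-3 m), \code{area} (1e-4 m^2), \code{volume}
#'     (2e-6 m^3), \code{pressures} (Pa; default
#'     \code{c(3, 5, 6, 7, 8) * 1e3}). Returns data.frame(pressure_Pa,
#'     time_s).}
#'   \item{amide2_spectrum}{Sum of two Gaussian components over
#'     1480-1580 cm^-1. Params: \code{betaCenter} (1515), \code{betaSd}
#'     (8), \code{betaArea} (2), \code{alphaCenter} (1545),
#'     \code{alphaSd} (10), \code{alphaArea} (1). Additive noise of sd
#'     \code{noiseSd * max(absorbance)}. Returns data.frame(wavenumber,
#'     absorbance).}
#'   \item{modulus_samples}{\code{nPoints} draws from a positive-truncated
#'     Lorentzian. Params: \code{xc} (230 kPa), \code{w} (FWHM, 40 kPa).
#'     Returns a numeric vector.}
#'   \item{amplitude_sweep}{Log-spaced strain sweep with constant plateau
#'     G' up to \code{gamma0} then a linear-in-log10 decay crossing the
#'     -10% line exactly at \code{gammaStar}. Params: \code{plateau}
#'     (1000 Pa), \code{gamma0} (0.02 %), \code{gammaStar} (0.1 %),
#'     \code{tanDelta} (0.2), \code{gammaMin} (0.0021 %), \code{gammaMax}
#'     (0.3 %). Multiplicative noise. Returns data.frame(strain, Gp, Gpp).}
#'   \item{porous_volume}{Binary volume of known wall thickness. Params:
#'     \code{type} ("slab" or "spheres"), \code{shape} (c(40, 40, 40)),
#'     \code{thickness} (11 voxels, slab), \code{radius} (6 voxels,
#'     spheres), \code{nSpheres} (5). Returns a \linkS4class{VoxelVolume}.}
#' }
#' Each return value carries the ground-truth parameters in
#' \code{attr(, "truth")}.
#'
#' @param config a \code{\link{signalConfig}}.
#' @return Kind-specific dataset (see Details).
#' @examples
#' df <- simulateSignal(signalConfig("pressure_flow", nPoints = 5))
#' df
#' @export
simulateSignal <- function(config) {
  stopifnot(inherits(config, "signalConfig"))
  p <- config$trueParams
  dflt <- function(name, value) if (is.null(p[[name]])) value else p[[name]]
  .withSeed(config$seed, switch(config$kind,
    pressure_flow = {
      k <- .assertScalarPositive(dflt("k", 1e-12), "k")
      mu <- dflt("viscosity", 0.015)
      len <- dflt("length", 5e-3)
      area <- dflt("area", 1e-4)
      vol <- dflt("volume", 2e-6)
      dp <- dflt("pressures", c(3, 5, 6, 7, 8) * 1e3)
      v <- k * dp / (mu * len)
      t <- vol / (area * v)
      tObs <- t * (1 + rnorm(length(t), 0, config$noiseSd))
      out <- data.frame(pressure_Pa = dp, time_s = tObs)
      attr(out, "truth") <- list(k = k, viscosity = mu, length = len,
                                 area = area, volume = vol)
      out
    },
    amide2_spectrum = {
      bc <- dflt("betaCenter", 1515); bs <- dflt("betaSd", 8)
      ba <- dflt("betaArea", 2)
      ac <- dflt("alphaCenter", 1545); as_ <- dflt("alphaSd", 10)
      aa <- dflt("alphaArea", 1)
      .assertPositive(c(bs, as_, ba, aa), "component widths/areas")
      wn <- seq(1480, 1580, length.out = max(config$nPoints, 21))
      ab <- ba / (bs * sqrt(2 * pi)) * exp(-(wn - bc)^2 / (2 * bs^2)) +
            aa / (as_ * sqrt(2 * pi)) * exp(-(wn - ac)^2 / (2 * as_^2))
      if (config$noiseSd > 0)  # relative (multiplicative) noise
        ab <- ab * (1 + rnorm(length(ab), 0, config$noiseSd))
      out <- data.frame(wavenumber = wn, absorbance = ab)
      attr(out, "truth") <- list(betaCenter = bc, betaSd = bs, betaArea = ba,
                                 alphaCenter = ac, alphaSd = as_,
                                 alphaArea = aa)
      out
    },
    modulus_samples = {
      xc <- .assertScalarPositive(dflt("xc", 230), "xc")
      w <- .assertScalarPositive(dflt("w", 40), "w")
      out <- numeric(0)
      while (length(out) < config$nPoints) {
        draw <- rcauchy(config$nPoints, location = xc, scale = w / 2)
        out <- c(out, draw[draw > 0])
      }
      out <- out[seq_len(config$nPoints)]
      attr(out, "truth") <- list(xc = xc, w = w)
      out
    },
    amplitude_sweep = {
      g0 <- dflt("plateau", 1000)
      gamma0 <- dflt("gamma0", 0.02)
      gammaStar <- dflt("gammaStar", 0.1)
      td <- dflt("tanDelta", 0.2)
      gmin <- dflt("gammaMin", 0.0021)
      gmax <- dflt("gammaMax", 0.3)
      if (gammaStar <= gamma0) stop("gammaStar must exceed gamma0")
      strain <- exp(seq(log(gmin), log(gmax), length.out = config$nPoints))
      # slope chosen so G' = 0.9 * plateau exactly at gammaStar
      slope <- 0.1 / log10(gammaStar / gamma0)
      gp <- ifelse(strain <= gamma0, g0,
                   g0 * (1 - slope * log10(strain / gamma0)))
      gpp <- td * g0 + numeric(length(strain))
      if (config$noiseSd > 0) {
        gp <- gp * (1 + rnorm(length(gp), 0, config$noiseSd))
        gpp <- gpp * (1 + rnorm(length(gpp), 0, config$noiseSd))
      }
      out <- data.frame(strain = strain, Gp = gp, Gpp = gpp)
      attr(out, "truth") <- list(plateau = g0, gamma0 = gamma0,
                                 gammaStar = gammaStar, tanDelta = td)
      out
    },
    porous_volume = {
      type <- dflt("type", "slab")
      shape <- dflt("shape", c(40, 40, 40))
      arr <- array(0L, dim = shape)
      truth <- list(type = type)
      if (type == "slab") {
        th <- dflt("thickness", 11)
        if (th >= shape[1]) stop("slab thickness must be below the z extent")
        z0 <- floor((shape[1] - th) / 2) + 1L
        arr[z0:(z0 + th - 1L), , ] <- 1L
        truth$thickness <- th
      } else if (type == "spheres") {
        rad <- dflt("radius", 6)
        ns <- dflt("nSpheres", 5)
        centers <- matrix(NA_real_, 0, 3)
        tries <- 0
        while (nrow(centers) < ns && tries < 1000 * ns) {
          tries <- tries + 1
          cand <- rad + 1 + runif(3) * (shape - 2 * rad - 2)
          if (!nrow(centers) ||
              all(sqrt(rowSums((centers - matrix(cand, nrow(centers), 3,
                                                 byrow = TRUE))^2)) >
                  2 * rad + 2))
            centers <- rbind(centers, cand)
        }
        if (nrow(centers) < ns) stop("overcrowded: cannot place spheres")
        for (i in seq_len(ns)) {
          arr <- .rasterizeCell(arr, c(1, 1, 1), 1L, centers[i, ], rad,
                                FALSE, 0, 0, c(0, 0, 1))
        }
        truth$radius <- rad
        truth$centers <- centers
      } else stop("unknown porous_volume type '", type, "'")
      out <- VoxelVolume(arr, dflt("spacing", c(1, 1, 1)))
      attr(out, "truth") <- truth
      out
    }))
}
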