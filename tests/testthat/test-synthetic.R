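# Synthetic-data generators: seeded determinism, analytic ground truth,
# and agreement of noiseless signals with their generating laws.

test_that("niche volume generator handles the empty case and is seeded", {
  cfg0 <- nicheConfig(nCells = 0, volumeShape = c(8, 8, 8))
  sim0 <- simulateNicheVolume(cfg0)
  expect_equal(sum(voxels(sim0$volume)), 0)
  expect_equal(nrow(sim0$truth), 0)

  cfg <- nicheConfig(nCells = 3, volumeShape = c(80, 160, 160), seed = 11)
  s1 <- simulateNicheVolume(cfg)
  s2 <- simulateNicheVolume(cfg)
  expect_identical(voxels(s1$volume), voxels(s2$volume))
  expect_identical(s1$truth, s2$truth)
})

test_that("a rasterized 20 um sphere matches the analytic ball volume", {
  cfg <- nicheConfig(nCells = 1, volumeShape = c(40, 40, 40),
                     diameterMedian = 20, diameterSdLog = 0,
                     protrusionRate = 0, seed = 3)
  sim <- simulateNicheVolume(cfg)
  expect_equal(sim$truth$trueVolume, 4 / 3 * pi * 10^3)
  measured <- sum(voxels(sim$volume) == 1L)  # spacing 1 => um^3
  expect_lt(abs(measured / (4 / 3 * pi * 10^3) - 1), 0.03)
})

test_that("labels are unique, non-overlapping and 26-connected", {
  cfg <- nicheConfig(nCells = 5, volumeShape = c(110, 260, 260),
                     diameterMedian = 24, diameterSdLog = 0.25,
                     protrusionRate = 1, protrusionLengthMedian = 10,
                     seed = 21)
  sim <- simulateNicheVolume(cfg)
  v <- voxels(sim$volume)
  expect_setequal(unique(as.integer(v[v != 0])), sim$truth$label)
  for (lab in sim$truth$label)
    expect_equal(countComponents(sim$volume, lab), 1)
})

test_that("placement failure in a crowded volume raises an explicit error", {
  cfg <- nicheConfig(nCells = 40, volumeShape = c(40, 40, 40),
                     diameterMedian = 18, diameterSdLog = 0,
                     protrusionRate = 0, maxRetries = 50, seed = 1)
  expect_error(simulateNicheVolume(cfg), "overcrowded|too small")
})

test_that("size samples follow the configured lognormal law", {
  # degenerate law: all sizes identical
  one <- simulateSizeSamples(list(g = nicheConfig(
    nCells = 10, diameterSdLog = 0, seed = 1)))
  expect_equal(length(unique(one$size)), 1)
  expect_equal(unique(one$size), pi * 15^2)

  # identical configs + seeds => identical samples
  cfgA <- nicheConfig(nCells = 50, seed = 9)
  twice <- simulateSizeSamples(list(a = cfgA, b = cfgA))
  expect_identical(twice$size[twice$group == "a"],
                   twice$size[twice$group == "b"])

  # fibrotic shift 0.6 moves the sample median down
  sh <- simulateSizeSamples(list(
    healthy = nicheConfig(nCells = 500, regime = "healthy", seed = 5),
    fibrotic = nicheConfig(nCells = 500, regime = "fibrotic", seed = 6)))
  med <- tapply(sh$size, sh$group, median)
  expect_lt(med[["fibrotic"]], med[["healthy"]])

  # moment recovery: log-mean of areas within 3 SE of its analytic value;
  # area = pi (d/2)^2 so log(area) ~ Normal(log(pi m^2/4), (2 sigma)^2)
  big <- simulateSizeSamples(list(g = nicheConfig(
    nCells = 10000, diameterMedian = 30, diameterSdLog = 0.35, seed = 7)))
  se <- 2 * 0.35 / sqrt(10000)
  expect_lt(abs(mean(log(big$size)) - log(pi * 15^2)), 3 * se)
})

test_that("noiseless pressure-flow data are collinear through the origin", {
  df <- simulateSignal(signalConfig("pressure_flow",
    trueParams = list(k = 1e-12, viscosity = 0.015, length = 5e-3,
                      area = 1e-4, volume = 2e-6)))
  truth <- attr(df, "truth")
  v <- (truth$volume / df$time_s) / truth$area
  # dp = (mu L / k) v exactly
  expect_equal(df$pressure_Pa, truth$viscosity * truth$length / truth$k * v,
               tolerance = 1e-12)
})

test_that("noiseless amide II spectrum integrates to the configured 2:1 area ratio", {
  sp <- simulateSignal(signalConfig("amide2_spectrum", nPoints = 2001,
    trueParams = list(betaArea = 2, alphaArea = 1)))
  truth <- attr(sp, "truth")
  g <- function(c, s, a) a / (s * sqrt(2 * pi)) *
    exp(-(sp$wavenumber - c)^2 / (2 * s^2))
  beta <- g(truth$betaCenter, truth$betaSd, truth$betaArea)
  alpha <- sp$absorbance - beta
  dx <- diff(sp$wavenumber[1:2])
  expect_equal(sum(beta) * dx / (sum(alpha) * dx), 2, tolerance = 1e-3)
})

test_that("modulus samples are positive and seed-reproducible", {
  x1 <- simulateSignal(signalConfig("modulus_samples", nPoints = 200,
                                    seed = 4))
  x2 <- simulateSignal(signalConfig("modulus_samples", nPoints = 200,
                                    seed = 4))
  expect_identical(as.numeric(x1), as.numeric(x2))
  expect_true(all(x1 > 0))
})

test_that("noiseless amplitude sweep crosses -10% exactly at gammaStar", {
  sw <- simulateSignal(signalConfig("amplitude_sweep", nPoints = 60,
    trueParams = list(plateau = 1000, gamma0 = 0.02, gammaStar = 0.1)))
  gp <- approx(log10(sw$strain), sw$Gp, log10(0.1))$y
  expect_equal(gp, 900, tolerance = 1e-6)
  expect_true(all(sw$Gp[sw$strain <= 0.02] == 1000))
})

test_that("porous slab volume has the constructed wall thickness", {
  slab <- simulateSignal(signalConfig("porous_volume",
    trueParams = list(type = "slab", thickness = 11,
                      shape = c(30, 20, 20))))
  th <- localThickness(slab)
  expect_true(all(th[voxels(slab) == 1L] == 11))
})

test_that("unknown signal kinds are rejected", {
  expect_error(signalConfig("raman_map"), "unknown signal kind")
  expect_error(signalConfig("pressure_flow", noiseSd = -1))
  expect_error(signalConfig("pressure_flow", nPoints = 1))
})
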