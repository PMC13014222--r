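# Morphometry: analytic-solid oracles for volume/area/sphericity, porosity
# and local-thickness behavior, including the exhaustive-search equivalence.

test_that("sphericity evaluates its closed form and rejects bad input", {
  expect_equal(sphericity(4 / 3 * pi, 4 * pi), 1)
  expect_equal(sphericity(1, 6), pi^(1 / 3) * 6^(2 / 3) / 6)
  expect_equal(sphericity(1, 6), 0.80600, tolerance = 1e-4)
  # monotone decreasing in area at fixed volume, -> 0 as A grows
  areas <- c(6, 10, 100, 1e6)
  ps <- sphericity(1, areas)
  expect_true(all(diff(ps) < 0))
  expect_lt(ps[4], 1e-3)
  expect_error(sphericity(0, 1), "positive")
  expect_error(sphericity(1, -2), "positive")
})

test_that("a rasterized r=20 sphere is measured within 3% of analytic", {
  vol <- rasterSphere(20)
  cells <- measureCells(vol)
  expect_equal(nrow(cells), 1)
  expect_lt(abs(cells$volume_um3 / 33510.32 - 1), 0.03)
  expect_lt(abs(cells$surface_um2 / (4 * pi * 400) - 1), 0.03)
  expect_lt(abs(cells$sphericity - 1), 0.03)
  expect_lt(abs(cells$projected_area_um2 / (pi * 400) - 1), 0.03)
  expect_equal(cells$eq_diameter_um,
               (6 * cells$volume_um3 / pi)^(1 / 3))
})

test_that("an empty volume yields an empty table, not an error", {
  cells <- measureCells(VoxelVolume(array(0L, c(6, 6, 6))))
  expect_equal(nrow(cells), 0)
})

test_that("per-label records are independent of label order in memory", {
  a <- array(0L, c(16, 40, 40))
  a[4:10, 4:12, 4:12] <- 7L
  a[4:12, 20:34, 20:34] <- 3L
  cells <- measureCells(VoxelVolume(a))
  expect_equal(cells$label, c(3L, 7L))  # sorted by label
  # same content with swapped label ids gives the same per-solid numbers
  b <- array(0L, c(16, 40, 40))
  b[4:10, 4:12, 4:12] <- 3L
  b[4:12, 20:34, 20:34] <- 7L
  cells2 <- measureCells(VoxelVolume(b))
  expect_equal(cells$volume_um3, rev(cells2$volume_um3))
  expect_equal(cells$surface_um2, rev(cells2$surface_um2))
})

test_that("anisotropic spacing is honored in volume, area and projection", {
  a <- array(0L, c(18, 22, 16))
  a[3:14, 3:18, 3:12] <- 1L   # 12 x 16 x 10 voxel box
  sp <- c(2, 1, 0.5)
  cells <- measureCells(VoxelVolume(a, sp))
  expect_equal(cells$volume_um3, 12 * 16 * 10 * prod(sp))
  expect_equal(cells$projected_area_um2, 16 * 10 * 1 * 0.5)
  # physical box is 24 x 16 x 5 um; meshed area close to exact (edges and
  # corners are rounded by the surface smoothing, a bounded deficit)
  exact <- 2 * (24 * 16 + 24 * 5 + 16 * 5)
  expect_lt(abs(cells$surface_um2 / exact - 1), 0.15)
  # and consistent with the same physical box rasterized isotropically
  b <- array(0L, c(28, 20, 9))
  b[3:26, 3:18, 3:7] <- 1L    # 24 x 16 x 5 voxels at unit spacing
  iso <- measureCells(VoxelVolume(b, c(1, 1, 1)))
  expect_lt(abs(cells$surface_um2 / iso$surface_um2 - 1), 0.05)
})

test_that("adding a protrusion strictly lowers sphericity", {
  base <- nicheConfig(nCells = 1, volumeShape = c(70, 70, 70),
                      diameterMedian = 24, diameterSdLog = 0,
                      protrusionRate = 0, seed = 8)
  withP <- nicheConfig(nCells = 1, volumeShape = c(70, 70, 70),
                       diameterMedian = 24, diameterSdLog = 0,
                       protrusionRate = 1, protrusionLengthMedian = 12,
                       protrusionLengthSdLog = 0, seed = 8)
  s0 <- measureCells(simulateNicheVolume(base)$volume)
  s1 <- measureCells(simulateNicheVolume(withP)$volume)
  expect_lt(s1$sphericity, s0$sphericity)
})

test_that("volumes are conserved across labels and background", {
  sim <- simulateNicheVolume(nicheConfig(nCells = 4,
    volumeShape = c(80, 160, 160), seed = 13))
  cells <- measureCells(sim$volume)
  v <- voxels(sim$volume)
  bg <- sum(v == 0L) * prod(voxelSpacing(sim$volume))
  expect_equal(sum(cells$volume_um3) + bg,
               prod(dim(v)) * prod(voxelSpacing(sim$volume)))
})

test_that("doubling resolution refines volume and pushes sphericity to 1", {
  coarse <- measureCells(rasterSphere(10))
  # same physical sphere sampled at half the voxel size
  fine <- measureCells(VoxelVolume(voxels(rasterSphere(20)),
                                   spacing = 0.5))
  expect_lt(abs(fine$volume_um3 / coarse$volume_um3 - 1), 0.01)
  expect_lte(abs(fine$sphericity - 1), abs(coarse$sphericity - 1) + 1e-6)
})

test_that("sphericity is scale-invariant for rasterized spheres", {
  p1 <- measureCells(rasterSphere(10))$sphericity
  p2 <- measureCells(rasterSphere(20))$sphericity
  expect_lt(abs(p1 - p2), 0.02)
})

test_that("porosity handles degenerate all-void/all-material volumes", {
  void <- VoxelVolume(array(0L, c(6, 6, 6)))
  rep0 <- porosityThickness(void)
  expect_equal(porosity(rep0), 1)
  expect_length(rep0@thicknessDensity, 0)

  solid <- VoxelVolume(array(1L, c(6, 6, 6)))
  rep1 <- porosityThickness(solid)
  expect_equal(porosity(rep1), 0)
  expect_length(rep1@separationDensity, 0)
})

test_that("slab wall thickness concentrates exactly at the slab width", {
  slab <- rasterSlab(11)
  rep <- porosityThickness(slab)
  expect_equal(porosity(rep), mean(voxels(slab) == 0L))
  th <- localThickness(slab)
  expect_true(all(th[voxels(slab) == 1L] == 11))
  expect_equal(sum(rep@thicknessDensity), 1)
})

test_that("local thickness equals the exhaustive inscribed-sphere search", {
  # sphere, slab and a random blob, all small enough for the O(n^2) oracle
  sph <- rasterSphere(6, margin = 2L)
  expect_equal(localThickness(sph), bruteLocalThickness(sph))

  slab <- rasterSlab(5, ny = 12L, nx = 12L, pad = 3L)
  expect_equal(localThickness(slab), bruteLocalThickness(slab))

  set.seed(42)
  blob <- array(0L, c(18, 18, 18))
  for (i in 1:3) {
    c0 <- sample(5:14, 3, replace = TRUE)
    r0 <- sample(2:4, 1)
    g <- expand.grid(z = 1:18, y = 1:18, x = 1:18)
    inside <- (g$z - c0[1])^2 + (g$y - c0[2])^2 + (g$x - c0[3])^2 <= r0^2
    blob[as.matrix(g[inside, ])] <- 1L
  }
  bv <- VoxelVolume(blob)
  expect_equal(localThickness(bv), bruteLocalThickness(bv))
})

test_that("random non-overlapping spheres have modal thickness near 2r", {
  vol <- simulateSignal(signalConfig("porous_volume",
    trueParams = list(type = "spheres", radius = 5, nSpheres = 4,
                      shape = c(40, 40, 40)), seed = 2))
  th <- localThickness(vol)
  vals <- th[voxels(vol) == 1L]
  mode <- as.numeric(names(which.max(table(vals))))
  expect_lt(abs(mode - 10), 1.5)
})

test_that("binary checks reject labeled input for porosity analysis", {
  a <- array(0L, c(5, 5, 5)); a[2, 2, 2] <- 4L
  expect_error(porosityThickness(VoxelVolume(a)), "binary")
})
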