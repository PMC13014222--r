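# Independent oracles and small fixture builders used across the suite.
# These deliberately use naive/exhaustive algorithms so the package's
# optimized implementations are checked against a separate route.

# Rasterize a sphere of radius r voxels (isotropic spacing 1) into a cube
# with `margin` empty voxels around it; voxel centers at integer offsets
# from the sphere center.
rasterSphere <- function(r, margin = 2L) {
  n <- 2L * (ceiling(r) + margin) + 1L
  c0 <- ceiling(r) + margin + 1L
  g <- seq_len(n) - c0
  d2 <- outer(outer(g^2, g^2, "+"), g^2, "+")
  VoxelVolume(array(as.integer(d2 <= r^2), dim = c(n, n, n)))
}

# Full-cross-section slab of thickness t voxels along z, with void above
# and below.
rasterSlab <- function(t, ny = 16L, nx = 16L, pad = 4L) {
  arr <- array(0L, dim = c(t + 2L * pad, ny, nx))
  arr[(pad + 1L):(pad + t), , ] <- 1L
  VoxelVolume(arr)
}

# Exhaustive largest-inscribed-sphere local thickness (isotropic spacing
# 1): for every material voxel c, the inscribed-sphere radius is the
# distance to the nearest void voxel minus half a voxel; the thickness at
# p is the largest sphere diameter over all centers whose sphere covers p.
# O(n^2) - only for small volumes.
bruteLocalThickness <- function(volume) {
  mask <- voxels(volume)
  dims <- dim(mask)
  matIdx <- which(mask == 1L)
  voidIdx <- which(mask == 0L)
  coords <- arrayInd(matIdx, dims)
  void <- arrayInd(voidIdx, dims)
  tv <- t(void)
  r <- vapply(seq_along(matIdx), function(i) {
    sqrt(min(colSums((tv - coords[i, ])^2))) - 0.5
  }, numeric(1))
  th <- numeric(length(matIdx))
  tc <- t(coords)
  for (ci in seq_along(matIdx)) {
    if (r[ci] <= 0) next
    cover <- colSums((tc - coords[ci, ])^2) <= r[ci]^2
    th[cover] <- pmax(th[cover], 2 * r[ci])
  }
  out <- array(0, dims)
  out[matIdx] <- th
  out
}

# Total-variation distance computed straight from two samples and shared
# edges, independently of the SizeHistogram path.
bruteTV <- function(a, b, edges) {
  pa <- tabulate(findInterval(a, edges, rightmost.closed = TRUE),
                 length(edges) - 1L) / length(a)
  pb <- tabulate(findInterval(b, edges, rightmost.closed = TRUE),
                 length(edges) - 1L) / length(b)
  sum(abs(pa - pb)) / 2
}

# Random probability vector (normalized gamma draws).
randomProportions <- function(k) {
  x <- rgamma(k, shape = 1)
  x / sum(x)
}

histFromProps <- function(props, id = "h") {
  new("SizeHistogram", edges = as.numeric(0:length(props)),
      proportions = props, n = 100L, groupId = id)
}
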