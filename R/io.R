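#' Construct a VoxelVolume
#'
#' @param voxels a 3D numeric or integer array in (z, y, x) axis order;
#'   values are coerced to integer labels (0 = background/void).
#' @param spacing micrometres per voxel along (z, y, x); a scalar is
#'   recycled to all three axes.
#' @return A \linkS4class{VoxelVolume}.
#' @examples
#' v <- VoxelVolume(array(0L, c(4, 8, 8)), spacing = 1)
#' voxelSpacing(v)
#' @export
VoxelVolume <- function(voxels, spacing = c(1, 1, 1)) {
  if (is.null(dim(voxels)) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array (z, y, x)")
  if (!is.integer(voxels)) {
    if (any(abs(voxels - round(voxels)) > 1e-6, na.rm = TRUE))
      stop("'voxels' must hold integer labels")
    voxels <- array(as.integer(round(voxels)), dim = dim(voxels))
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("VoxelVolume", voxels = voxels, spacing = as.numeric(spacing))
}

#' Read a label volume from a multi-page TIFF stack
#'
#' Pages are stacked along z; pixel values are read as stored integers
#' (uint8/uint16 label images with background 0).
#'
#' @param path TIFF file path.
#' @param spacing micrometres per voxel (z, y, x); scalar recycled.
#' @return A \linkS4class{VoxelVolume}.
#' @seealso [writeVoxelVolume()]
#' @export
readVoxelVolume <- function(path, spacing = c(1, 1, 1)) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0L, dim = c(length(pages), dim(pages[[1]])[1:2]))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # collapse grayscale channels
    arr[k, , ] <- as.integer(pg)
  }
  VoxelVolume(arr, spacing)
}

#' Write a label volume as a multi-page 16-bit TIFF stack
#'
#' Labels must fit in uint16 (0..65535); z slices become TIFF pages.
#'
#' @param volume a \linkS4class{VoxelVolume}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeVoxelVolume <- function(volume, path) {
  stopifnot(is(volume, "VoxelVolume"))
  v <- voxels(volume)
  if (max(v) > 65535L) stop("labels exceed uint16 range")
  pages <- lapply(seq_len(dim(v)[1]), function(k) v[k, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a wavenumber-absorbance spectrum from CSV
#'
#' Expects columns \code{wavenumber} and \code{absorbance}. A spectrum
#' stored with descending wavenumber (the native order of many FTIR
#' instruments) is reversed to ascending order with a warning.
#'
#' @param path CSV file path.
#' @return data.frame with ascending \code{wavenumber} and
#'   \code{absorbance}.
#' @export
readSpectrum <- function(path) {
  df <- read.csv(path)
  need <- c("wavenumber", "absorbance")
  if (!all(need %in% names(df)))
    stop("spectrum CSV must have columns: ", paste(need, collapse = ", "))
  if (is.unsorted(df$wavenumber)) {
    if (is.unsorted(rev(df$wavenumber)))
      stop("wavenumber column is neither ascending nor descending")
    warning("descending wavenumber axis: reversing to ascending order")
    df <- df[rev(seq_len(nrow(df))), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Read a per-group size table from CSV
#'
#' Expects columns \code{group} and \code{size} (one scalar cell size per
#' row, e.g. projected area in um^2).
#'
#' @param path CSV file path.
#' @return data.frame with columns \code{group}, \code{size}.
#' @export
readSizeTable <- function(path) {
  df <- read.csv(path)
  if (!all(c("group", "size") %in% names(df)))
    stop("size table must have columns: group, size")
  df
}
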