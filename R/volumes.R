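#' @useDynLib cellmapr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- core voxel containers ------------------------------------------------
#
# All volumes are R 3D arrays with dim c(Z, Y, X): first index is the
# z-plane, matching a multi-page TIFF where each page is a (y, x) image.
# Voxel indices are 1-based; the physical center of voxel i along an axis
# with spacing s is (i - 0.5) * s micrometres.

#' Create an image stack
#'
#' Bundles a 3D voxel grid with its per-axis physical spacing. Raw
#' light-sheet stacks are anisotropic (e.g. 1.625 x 1.625 um in-plane,
#' 6 um between planes), so the spacing travels with the data through
#' every resampling step.
#'
#' @param voxels 3D numeric/integer array, dim c(Z, Y, X), intensities in
#'   the unsigned 16-bit range.
#' @param spacing_um numeric length-3, micrometres per voxel as (z, y, x).
#' @return An `image_stack` object.
#' @export
image_stack <- function(voxels, spacing_um) {
  stopifnot(length(dim(voxels)) == 3, length(spacing_um) == 3)
  if (any(spacing_um <= 0)) stop("all spacings must be > 0")
  if (any(dim(voxels) <= 0)) stop("all dimensions must be > 0")
  structure(list(voxels = voxels, spacing_um = as.numeric(spacing_um)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d x %d x %d voxels (z,y,x), spacing %s um\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing_um, 4), collapse = " x ")))
  invisible(x)
}

#' Create a binary mask stack
#'
#' @param mask 3D array coercible to 0/1.
#' @param spacing_um numeric length-3 (z, y, x) micrometres per voxel.
#' @return A `mask_stack` object.
#' @export
mask_stack <- function(mask, spacing_um) {
  stopifnot(length(dim(mask)) == 3, length(spacing_um) == 3)
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0, 1, TRUE, FALSE)))
    stop("mask values must be 0/1")
  m <- array(as.integer(mask != 0), dim = dim(mask))
  structure(list(mask = m, spacing_um = as.numeric(spacing_um)),
            class = "mask_stack")
}

#' @export
print.mask_stack <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<mask_stack> %d x %d x %d, %d foreground voxels (%.2f%%)\n",
              d[1], d[2], d[3], sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' Create a probability stack
#'
#' Per-voxel foreground probabilities in [0, 1], the raw output of
#' sliding-window inference before binarization.
#'
#' @param values 3D numeric array with all values in [0, 1].
#' @param spacing_um numeric length-3 (z, y, x).
#' @return A `prob_stack` object.
#' @export
prob_stack <- function(values, spacing_um) {
  stopifnot(length(dim(values)) == 3)
  rng <- range(values)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("probabilities must lie in [0, 1]")
  structure(list(values = values, spacing_um = as.numeric(spacing_um)),
            class = "prob_stack")
}

# ---- 16-bit TIFF I/O ------------------------------------------------------

#' Read a multi-page TIFF into an image stack
#'
#' @param path TIFF file path.
#' @param spacing_um per-voxel spacing (z, y, x) in micrometres; TIFF does
#'   not reliably carry anisotropic 3D spacing, so it is supplied here.
#' @return An `image_stack` with integer intensities (0..65535).
#' @export
read_stack <- function(path, spacing_um) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  vox <- array(0L, dim = c(length(pages), d[1], d[2]))
  for (k in seq_along(pages)) vox[k, , ] <- pages[[k]]
  image_stack(vox, spacing_um)
}

#' Write an image stack as 16-bit multi-page TIFF
#'
#' @param stack an `image_stack` (or 3D array) with values in 0..65535.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  vox <- if (inherits(stack, "image_stack")) stack$voxels else stack
  vox <- pmin(pmax(vox, 0), 65535)
  pages <- lapply(seq_len(dim(vox)[1]), function(k) vox[k, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Write a binary mask as 8-bit multi-page TIFF
#' @param mask a `mask_stack` or 0/1 array.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- if (inherits(mask, "mask_stack")) mask$mask else mask
  pages <- lapply(seq_len(dim(m)[1]), function(k) (m[k, , ] != 0) * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}

#' Read an 8-bit mask TIFF
#' @param path file path.
#' @param spacing_um per-voxel spacing (z, y, x).
#' @return A `mask_stack`.
#' @export
read_mask <- function(path, spacing_um = c(1, 1, 1)) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  m <- array(0L, dim = c(length(pages), d[1], d[2]))
  for (k in seq_along(pages)) m[k, , ] <- as.integer(pages[[k]] > 0)
  mask_stack(m, spacing_um)
}

#' Write a labeled (or real-valued) volume as 32-bit float TIFF
#'
#' Values are stored scaled by 2^-24 so they fit the TIFF writer's [0, 1]
#' float range; scaling by a power of two is an exact exponent shift, so
#' any value in [0, 2^24] round-trips losslessly (integer labels exactly).
#' [read_label_tiff()] (and the pipeline) undo the scaling.
#'
#' @param labels 3D numeric/integer array with values in [0, 2^24].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(labels, path) {
  if (max(labels) > 2^24 || min(labels) < 0)
    stop("values must lie in [0, 2^24] for lossless float storage")
  pages <- lapply(seq_len(dim(labels)[1]), function(k) {
    m <- labels[k, , ] / 2^24
    storage.mode(m) <- "double"
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' Read a 32-bit float label volume written by [write_label_tiff()]
#' @param path TIFF path.
#' @param integer round to integer labels (default TRUE).
#' @return 3D array.
#' @export
read_label_tiff <- function(path, integer = TRUE) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  out <- array(0, dim = c(length(pages), d[1], d[2]))
  for (k in seq_along(pages)) out[k, , ] <- pages[[k]] * 2^24
  if (integer) array(as.integer(round(out)), dim = dim(out)) else out
}

# internal: gaussian smoothing of a 3D array, sigma per axis in voxels
smooth3d <- function(arr, sigma_vox) {
  gauss3d_cpp(arr, as.numeric(sigma_vox))
}
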