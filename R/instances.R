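# ---- instance extraction --------------------------------------------------
#
# A binary segmentation becomes discrete cells via 3D connected components
# (components numbered by first-voxel scan order, so labeling is
# deterministic), then a size filter with user-defined lower/upper bounds
# drops debris and fused clumps.

#' Connected components of a binary mask
#'
#' @param mask a [mask_stack()] (or 0/1 array).
#' @param connectivity 6, 18 or 26 (face / face+edge / face+edge+corner).
#' @return A `labeled_volume`: `labels` (3D integer grid, 0 = background)
#'   and `instances` (data.frame: label, z, y, x centroid, volume_vox,
#'   half-open bbox z0..x1 given as 1-based inclusive min / exclusive max).
#' @export
connected_components <- function(mask, connectivity = 26) {
  m <- if (inherits(mask, "mask_stack")) mask$mask else mask
  if (!all(m %in% c(0, 1))) stop("mask must be binary")
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  res <- cc3d_label_cpp(array(m != 0, dim = dim(m)), as.integer(connectivity))
  st <- res$stats
  instances <- data.frame(
    label = seq_len(nrow(st)),
    z = st[, "cz"], y = st[, "cy"], x = st[, "cx"],
    volume_vox = as.integer(st[, "volume_vox"]),
    z0 = as.integer(st[, "z0"]), z1 = as.integer(st[, "z1"]) + 1L,
    y0 = as.integer(st[, "y0"]), y1 = as.integer(st[, "y1"]) + 1L,
    x0 = as.integer(st[, "x0"]), x1 = as.integer(st[, "x1"]) + 1L
  )
  structure(list(labels = res$labels, instances = instances),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat(sprintf("<labeled_volume> %d instances, %d foreground voxels\n",
              nrow(x$instances), sum(x$instances$volume_vox)))
  invisible(x)
}

#' Filter instances by voxel volume
#'
#' Keeps instances with volume in `[min_vox, max_vox]` (inclusive bounds),
#' relabels survivors consecutively in their original order and clears the
#' removed voxels to background.
#'
#' @param vol a `labeled_volume`.
#' @param min_vox lower volume bound (>= 1).
#' @param max_vox upper volume bound (>= min_vox; `Inf` allowed).
#' @return A filtered `labeled_volume`.
#' @export
filter_by_size <- function(vol, min_vox = 4, max_vox = 5000) {
  stopifnot(inherits(vol, "labeled_volume"))
  if (min_vox < 1 || max_vox < min_vox)
    stop("need 1 <= min_vox <= max_vox")
  keep <- vol$instances$volume_vox >= min_vox &
    vol$instances$volume_vox <= max_vox
  old <- vol$instances$label[keep]
  map <- integer(max(vol$instances$label, 0L))
  map[old] <- seq_along(old)
  labels <- relabel_cpp(vol$labels, map)
  inst <- vol$instances[keep, , drop = FALSE]
  inst$label <- seq_len(nrow(inst))
  rownames(inst) <- NULL
  structure(list(labels = labels, instances = inst),
            class = "labeled_volume")
}

#' Write instances as a per-cell CSV
#' @param vol a `labeled_volume`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_instances_csv <- function(vol, path) {
  utils::write.csv(vol$instances, path, row.names = FALSE)
  invisible(path)
}

#' Read an instance CSV
#' @param path CSV written by [write_instances_csv()].
#' @return data.frame of instances.
#' @export
read_instances_csv <- function(path) {
  utils::read.csv(path)
}
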