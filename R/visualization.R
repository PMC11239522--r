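# ---- visualization --------------------------------------------------------
#
# Image-space output keeps the "threshold value = region id" trick: the
# colorized stack stores each cell's atlas region id over the cell's
# voxels, with a separate color lookup table, so viewers can threshold by
# region directly. Atlas-space output is a per-voxel density map, smoothed
# and optionally averaged per group.

#' Paint cells by their atlas region
#'
#' @param labeled a `labeled_volume` (instance labels in image space).
#' @param mapped per-cell table from [map_cells()]; its `label` column must
#'   match the labeled volume's instance labels.
#' @param ont the [ontology()].
#' @param unassigned_id region id painted for cells mapped outside the
#'   atlas (default: one above the ontology's largest id).
#' @return A `colorized_stack`: `ids` (3D grid of region ids, 0 where no
#'   cell) and `lut` (data.frame region_id, acronym, R, G, B).
#' @export
colorize_cells <- function(labeled, mapped, ont, unassigned_id = NULL) {
  stopifnot(inherits(labeled, "labeled_volume"))
  if (!all(mapped$label %in% labeled$instances$label))
    stop("mapped cells reference labels absent from the volume")
  unassigned_id <- unassigned_id %||% (max(ont$nodes$id) + 1L)
  nlab <- max(labeled$instances$label, 0L)
  map <- integer(nlab)
  rid <- mapped$region_id
  rid[rid == 0] <- unassigned_id
  map[mapped$label] <- rid
  ids <- relabel_cpp(labeled$labels, map)
  used <- sort(unique(rid))
  row <- match(used, ont$nodes$id)
  lut <- data.frame(region_id = used,
                    acronym = ifelse(is.na(row), "unassigned",
                                     ont$nodes$acronym[row]),
                    stringsAsFactors = FALSE)
  cols <- ifelse(is.na(row), "#808080", ont$nodes$color_hex[row])
  rgb <- t(vapply(cols, hex_to_rgb, integer(3)))
  lut$R <- rgb[, 1]; lut$G <- rgb[, 2]; lut$B <- rgb[, 3]
  rownames(lut) <- NULL
  structure(list(ids = ids, lut = lut), class = "colorized_stack")
}

#' Write a colorized stack (label TIFF + LUT CSV)
#' @param colorized a `colorized_stack`.
#' @param tiff_path output 32-bit label TIFF.
#' @param lut_path output LUT CSV.
#' @return invisibly, the tiff path.
#' @export
write_colorized <- function(colorized, tiff_path, lut_path) {
  write_label_tiff(colorized$ids, tiff_path)
  utils::write.csv(colorized$lut, lut_path, row.names = FALSE)
  invisible(tiff_path)
}

#' Cell density map in atlas space
#'
#' Histograms mapped cell centers at atlas resolution per sample
#' (optionally normalized by the sample's total mapped cells), smooths
#' with a Gaussian kernel, and averages over the samples of a group.
#' Unsmoothed maps integrate exactly to the (normalized) cell count.
#'
#' @param mapped_per_sample list of per-cell tables from [map_cells()]
#'   (one per sample).
#' @param atlas an [atlas_volume()].
#' @param sigma_vox Gaussian smoothing sigma in atlas voxels (0 = none).
#' @param normalize divide each sample's map by its total mapped cells.
#' @return A 3D array (atlas dims), the group-mean density map.
#' @export
density_map <- function(mapped_per_sample, atlas, sigma_vox = 2,
                        normalize = FALSE) {
  if (sigma_vox < 0) stop("sigma_vox must be >= 0")
  if (inherits(mapped_per_sample, "data.frame"))
    mapped_per_sample <- list(mapped_per_sample)
  ad <- dim(atlas$labels)
  acc <- array(0, dim = ad)
  for (mp in mapped_per_sample) {
    h <- array(0, dim = ad)
    inb <- !is.na(mp$atlas_z)
    if (any(inb)) {
      lin <- mp$atlas_z[inb] + ad[1] * (mp$atlas_y[inb] - 1) +
        ad[1] * ad[2] * (mp$atlas_x[inb] - 1)
      tab <- table(lin)
      h[as.integer(names(tab))] <- as.integer(tab)
    }
    if (normalize && sum(h) > 0) h <- h / sum(h)
    if (sigma_vox > 0) h <- gauss3d_cpp(h, rep(sigma_vox, 3))
    acc <- acc + h
  }
  acc / length(mapped_per_sample)
}

#' Projection figure of a density map
#'
#' Maximum- or mean-intensity projection along one axis, written as a PNG
#' with a colorbar.
#'
#' @param map 3D array (e.g. from [density_map()]).
#' @param axis 1 (z), 2 (y) or 3 (x).
#' @param output PNG path.
#' @param mode "max" or "mean" projection.
#' @param title figure title.
#' @return `output`, invisibly.
#' @export
projection_figure <- function(map, axis = 1, output, mode = c("max", "mean"),
                              title = "cell density") {
  mode <- match.arg(mode)
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3")
  proj <- apply(map, setdiff(1:3, axis), if (mode == "max") max else mean)
  grDevices::png(output, width = 640, height = 560)
  on.exit(grDevices::dev.off())
  pal <- grDevices::hcl.colors(64, "Inferno")
  rngz <- range(proj)
  if (rngz[1] == rngz[2]) rngz[2] <- rngz[1] + 1e-9
  graphics::layout(matrix(1:2, nrow = 1), widths = c(5, 1))
  graphics::par(mar = c(2, 2, 2, 1))
  graphics::image(t(proj)[, rev(seq_len(nrow(proj))), drop = FALSE],
                  col = pal, axes = FALSE, main = title, useRaster = TRUE,
                  zlim = rngz)
  graphics::par(mar = c(2, 1, 2, 2))
  graphics::image(1, seq(rngz[1], rngz[2], length.out = 64),
                  matrix(seq(rngz[1], rngz[2], length.out = 64), nrow = 1),
                  col = pal, axes = FALSE, xlab = "", ylab = "",
                  zlim = rngz)
  graphics::axis(4)
  invisible(output)
}

#' Compute a mean or max projection (no plotting)
#' @param map 3D array.
#' @param axis projection axis (1..3).
#' @param mode "max" or "mean".
#' @return 2D matrix.
#' @export
project_map <- function(map, axis = 1, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  apply(map, setdiff(1:3, axis), if (mode == "max") max else mean)
}
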