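# ---- mapping cells into atlas space --------------------------------------

#' Map cell center points into the atlas and assign regions
#'
#' Each cell's centroid goes voxel -> micrometre -> affine transform ->
#' atlas voxel (floor of the continuous coordinate; labels are categorical
#' so no interpolation) -> region label. Cells landing outside the atlas
#' bounds or on background keep `region_id` 0 and are reported, never
#' dropped.
#'
#' @param cells data.frame of instances (columns label, z, y, x,
#'   volume_vox), coordinates in stack voxel units (center of voxel i at
#'   i - 0.5).
#' @param transform an [affine_transform()] from stack micrometres to
#'   atlas micrometres.
#' @param atlas an [atlas_volume()].
#' @param stack_spacing_um spacing of the stack the coordinates live in;
#'   defaults to the transform's source spacing.
#' @return data.frame: the input columns plus atlas_z, atlas_y, atlas_x
#'   (1-based atlas voxel indices, NA if outside), region_id,
#'   region_acronym, region_color.
#' @export
map_cells <- function(cells, transform, atlas, stack_spacing_um = NULL) {
  stopifnot(inherits(transform, "affine_transform"),
            inherits(atlas, "atlas_volume"))
  sp <- stack_spacing_um %||% transform$source_spacing_um
  out <- cells
  n <- nrow(cells)
  ad <- dim(atlas$labels)
  if (n == 0) {
    out$atlas_z <- integer(0); out$atlas_y <- integer(0)
    out$atlas_x <- integer(0); out$region_id <- integer(0)
    out$region_acronym <- character(0); out$region_color <- character(0)
    return(out)
  }
  um <- cbind(cells$z * sp[1], cells$y * sp[2], cells$x * sp[3])
  at_um <- apply_transform(transform, um)
  vox <- floor(at_um / atlas$spacing_um) + 1L
  inside <- vox[, 1] >= 1 & vox[, 1] <= ad[1] &
    vox[, 2] >= 1 & vox[, 2] <= ad[2] &
    vox[, 3] >= 1 & vox[, 3] <= ad[3]
  region <- integer(n)
  if (any(inside)) {
    lin <- vox[inside, 1] + ad[1] * (vox[inside, 2] - 1) +
      ad[1] * ad[2] * (vox[inside, 3] - 1)
    region[inside] <- atlas$labels[lin]
  }
  nodes <- atlas$ontology$nodes
  row <- match(region, nodes$id)
  out$atlas_z <- ifelse(inside, vox[, 1], NA_integer_)
  out$atlas_y <- ifelse(inside, vox[, 2], NA_integer_)
  out$atlas_x <- ifelse(inside, vox[, 3], NA_integer_)
  out$region_id <- region
  out$region_acronym <- ifelse(is.na(row), "unassigned", nodes$acronym[row])
  out$region_color <- ifelse(is.na(row), "#000000", nodes$color_hex[row])
  out
}

#' Build the two canonical output tables
#'
#' The per-cell table has one detected cell per row with coordinates in
#' both spaces, volume and region identity/color. The region table has one
#' leaf region per row (zero-filled for empty regions) with cell count,
#' region volume from the atlas label grid, and density; an extra row with
#' region_id 0 collects unassigned cells.
#'
#' @param mapped data.frame from [map_cells()].
#' @param atlas an [atlas_volume()].
#' @param sample_id identifier recorded on the region table.
#' @return list with `cells` (per-cell table) and `regions` (region count
#'   table).
#' @export
make_tables <- function(mapped, atlas, sample_id = "sample") {
  nodes <- atlas$ontology$nodes
  vols <- atlas_region_volumes(atlas)
  counts <- table(factor(mapped$region_id, levels = vols$region_id))
  row <- match(vols$region_id, nodes$id)
  regions <- data.frame(
    sample_id = sample_id,
    region_id = vols$region_id,
    acronym = nodes$acronym[row],
    level = nodes$level[row],
    n_cells = as.integer(counts),
    region_volume_mm3 = vols$volume_mm3,
    density_cells_per_mm3 = ifelse(vols$volume_mm3 > 0,
                                   as.integer(counts) / vols$volume_mm3, 0),
    stringsAsFactors = FALSE
  )
  n_unassigned <- sum(mapped$region_id == 0)
  regions <- rbind(regions, data.frame(
    sample_id = sample_id, region_id = 0L, acronym = "unassigned",
    level = NA_integer_, n_cells = n_unassigned,
    region_volume_mm3 = NA_real_, density_cells_per_mm3 = NA_real_,
    stringsAsFactors = FALSE
  ))
  list(cells = mapped, regions = regions)
}

#' Aggregate a region count table to a structure level
#'
#' Each leaf's count is added to its unique ancestor at `level`; leaves
#' that sit above (shallower than) the requested level keep their own row.
#' Region volumes aggregate identically, so total cells and total volume
#' are conserved.
#'
#' @param regions region table from [make_tables()].
#' @param ont the [ontology()] the table's region ids come from.
#' @param level target structure level (1 = whole brain / root).
#' @return An aggregated region table of the same shape.
#' @export
aggregate_to_level <- function(regions, ont, level) {
  if (level < 1 || level > max(ont$nodes$level))
    stop("level outside the ontology's depth")
  leaf <- regions[regions$region_id != 0, , drop = FALSE]
  un <- regions[regions$region_id == 0, , drop = FALSE]
  anc <- ontology_ancestor_at_level(ont, leaf$region_id, level)
  agg_n <- tapply(leaf$n_cells, anc, sum)
  agg_v <- tapply(leaf$region_volume_mm3, anc, sum)
  ids <- as.integer(names(agg_n))
  row <- match(ids, ont$nodes$id)
  out <- data.frame(
    sample_id = leaf$sample_id[1] %||% "sample",
    region_id = ids,
    acronym = ont$nodes$acronym[row],
    level = ont$nodes$level[row],
    n_cells = as.integer(agg_n),
    region_volume_mm3 = as.numeric(agg_v),
    density_cells_per_mm3 = ifelse(as.numeric(agg_v) > 0,
                                   as.integer(agg_n) / as.numeric(agg_v), 0),
    stringsAsFactors = FALSE
  )
  rbind(out[order(out$region_id), , drop = FALSE], un)
}

#' Write cells in an SWC-like point format
#'
#' One point per cell (id, type, x, y, z, radius, parent = -1), compatible
#' with point-cloud transport tools that consume SWC.
#'
#' @param mapped per-cell table.
#' @param path output path.
#' @param radius point radius written for every cell.
#' @return `path`, invisibly.
#' @export
write_cells_swc <- function(mapped, path, radius = 1) {
  df <- data.frame(id = seq_len(nrow(mapped)), type = 1L,
                   x = mapped$x, y = mapped$y, z = mapped$z,
                   radius = radius, parent = -1L)
  utils::write.table(df, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
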