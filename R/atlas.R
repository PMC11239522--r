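# ---- atlas volume and toy atlas generator --------------------------------

#' Construct an atlas volume
#'
#' An isotropic region-label grid paired with its ontology, in the spirit
#' of the 50 um/voxel CCF3 label volume. Every nonzero label must be a leaf
#' region id; 0 is background (outside the atlas).
#'
#' @param labels 3D integer array of region labels.
#' @param spacing_um isotropic voxel size in micrometres.
#' @param ont an [ontology()].
#' @return An `atlas_volume` object.
#' @export
atlas_volume <- function(labels, spacing_um, ont) {
  stopifnot(length(dim(labels)) == 3, length(spacing_um) == 1,
            spacing_um > 0, inherits(ont, "ontology"))
  present <- setdiff(unique(as.vector(labels)), 0L)
  leaves <- ontology_leaves(ont)
  if (!all(present %in% leaves))
    stop("atlas labels contain non-leaf or unknown region ids")
  structure(list(labels = labels, spacing_um = as.numeric(spacing_um),
                 ontology = ont),
            class = "atlas_volume")
}

#' @export
print.atlas_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<atlas_volume> %d x %d x %d @ %g um/voxel, %d leaf regions\n",
              d[1], d[2], d[3], x$spacing_um,
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

#' Per-region voxel counts and volumes of an atlas
#' @param atlas an `atlas_volume`.
#' @return data.frame with region_id, n_vox, volume_mm3.
#' @export
atlas_region_volumes <- function(atlas) {
  tab <- table(factor(as.vector(atlas$labels),
                      levels = ontology_leaves(atlas$ontology)))
  vox_mm3 <- (atlas$spacing_um * 1e-3)^3
  data.frame(region_id = as.integer(names(tab)),
             n_vox = as.integer(tab),
             volume_mm3 = as.numeric(tab) * vox_mm3,
             row.names = NULL)
}

#' Generate a toy hierarchical atlas
#'
#' Builds a small stand-in for a reference atlas: the volume is partitioned
#' into a recursive rectangular hierarchy `levels` deep, plus one ventricle
#' leaf (a central tube, where the real brain's fluid-filled cavities would
#' accumulate label) and one fiber-tract leaf (a thin slab of "white
#' matter" that region statistics later exclude). Every voxel is labeled.
#'
#' @param shape integer length-3, atlas grid dims (z, y, x); each >= 8.
#' @param levels tree depth, 2..11.
#' @param regions_per_split children per anatomical node at each split.
#' @param seed integer; fixes split positions and region colors.
#' @param spacing_um isotropic atlas voxel size (default 50 um).
#' @return An `atlas_volume` whose ontology has one root, a ventricle leaf
#'   and a fiber-tract leaf at level 2, and
#'   `regions_per_split^(levels - 1)` anatomical leaves at level `levels`.
#' @export
generate_toy_atlas <- function(shape, levels, regions_per_split = 2,
                               seed = 1, spacing_um = 50) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 8))
    stop("shape must be three dims, each >= 8 voxels")
  if (levels < 2 || levels > 11) stop("levels must be in 2..11")
  if (regions_per_split < 2) stop("regions_per_split must be >= 2")

  with_seed(seed, {
    next_id <- 1L
    new_id <- function() { id <- next_id; next_id <<- next_id + 1L; id }

    root_id <- new_id()
    vent_id <- new_id()
    fib_id <- new_id()

    nodes <- data.frame(
      id = c(root_id, vent_id, fib_id),
      acronym = c("root", "VS", "fib"),
      name = c("whole brain", "ventricular systems", "fiber tracts"),
      parent_id = c(NA, root_id, root_id),
      level = c(1L, 2L, 2L),
      color_hex = c("#FFFFFF", "#AAAAFF", "#CCCCCC"),
      is_fiber_tract = c(FALSE, FALSE, TRUE),
      is_ventricle = c(FALSE, TRUE, FALSE),
      stringsAsFactors = FALSE
    )

    # recursive rectangular partition of boxes (1-based inclusive bounds)
    boxes <- list(list(id = root_id, lo = c(1L, 1L, 1L), hi = shape,
                       level = 1L, path = "A"))
    leaf_boxes <- list()
    frontier <- boxes
    for (lev in seq(2L, levels)) {
      nxt <- list()
      for (bx in frontier) {
        ext <- bx$hi - bx$lo + 1L
        ax <- which.max(ext)
        n <- regions_per_split
        # jittered cut positions along the longest axis
        w <- ext[ax] / n
        cuts <- round(cumsum(rep(w, n - 1)) +
                        stats::runif(n - 1, -0.1, 0.1) * w)
        cuts <- pmin(pmax(cuts, seq_len(n - 1)), ext[ax] - rev(seq_len(n - 1)))
        cuts <- sort(unique(c(0L, as.integer(cuts), ext[ax])))
        if (length(cuts) != n + 1) { # degenerate: fall back to even cuts
          cuts <- unique(round(seq(0, ext[ax], length.out = n + 1)))
        }
        for (j in seq_len(length(cuts) - 1)) {
          lo <- bx$lo; hi <- bx$hi
          lo[ax] <- bx$lo[ax] + cuts[j]
          hi[ax] <- bx$lo[ax] + cuts[j + 1] - 1L
          id <- new_id()
          path <- paste0(bx$path, ".", j)
          nodes <- rbind(nodes, data.frame(
            id = id, acronym = path, name = paste("area", path),
            parent_id = bx$id, level = lev,
            color_hex = sprintf("#%02X%02X%02X", sample(40:255, 1),
                                sample(40:255, 1), sample(40:255, 1)),
            is_fiber_tract = FALSE, is_ventricle = FALSE,
            stringsAsFactors = FALSE
          ))
          nxt[[length(nxt) + 1]] <- list(id = id, lo = lo, hi = hi,
                                         level = lev, path = path)
        }
      }
      frontier <- nxt
    }
    leaf_boxes <- frontier

    labels <- array(0L, dim = shape)
    for (bx in leaf_boxes) {
      labels[bx$lo[1]:bx$hi[1], bx$lo[2]:bx$hi[2], bx$lo[3]:bx$hi[3]] <- bx$id
    }

    # ventricle: central tube along z (middle ~60% of z, ~20% of y/x —
    # proportionally comparable to lateral ventricles, and several voxels
    # wide at the 25 um masking resolution so the lumen is resolvable)
    vz <- round(shape[1] * c(0.2, 0.8)); vz[1] <- max(1, vz[1])
    vy <- round(shape[2] * c(0.40, 0.60)); vx <- round(shape[3] * c(0.40, 0.60))
    labels[vz[1]:vz[2], vy[1]:vy[2], vx[1]:vx[2]] <- vent_id
    # fiber tract: thin slab in y across the full volume
    fy <- round(shape[2] * c(0.80, 0.86))
    labels[, fy[1]:fy[2], ] <- fib_id

    atlas_volume(labels, spacing_um, ontology(nodes))
  })
}

#' Render an intensity template from an atlas
#'
#' Gives each region a reproducible pseudo-intensity (bright ventricles,
#' dark fiber tracts, mid-range parenchyma) so the atlas can serve as the
#' fixed image for intensity-based registration.
#'
#' @param atlas an `atlas_volume`.
#' @return An [image_stack()] at the atlas spacing.
#' @export
atlas_template <- function(atlas) {
  nodes <- atlas$ontology$nodes
  lut <- integer(max(nodes$id) + 1L)
  for (i in seq_len(nrow(nodes))) {
    id <- nodes$id[i]
    lut[id + 1L] <-
      if (isTRUE(nodes$is_ventricle[i])) 3000L
      else if (isTRUE(nodes$is_fiber_tract[i])) 400L
      else 800L + (id * 97L) %% 600L
  }
  vox <- array(lut[atlas$labels + 1L], dim = dim(atlas$labels))
  image_stack(vox, rep(atlas$spacing_um, 3))
}
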