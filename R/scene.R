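# ---- synthetic cleared-brain scenes --------------------------------------
#
# The generator emulates what the pipeline's wet-lab input looks like:
# compact, roughly spherical immunolabeled somata (rendered as Gaussian
# blobs, isotropic in micrometres, into a possibly anisotropic voxel grid)
# on a noisy background with a smooth multiplicative illumination field and
# bright ventricle lumens. Ground truth (cells, label mask, ventricle mask,
# stack-to-atlas transform) is stored alongside, so every downstream stage
# can be scored without any imaging data.

#' Generate a synthetic cleared-brain scene
#'
#' Cell centers are drawn by a homogeneous spatial point process per atlas
#' region at the requested density (counts Poisson in the region's physical
#' volume), rejecting placements that would overlap an already accepted
#' cell or the ventricle lumen. Each cell is rendered as a 3D Gaussian blob
#' of peak amplitude `amplitude` over a background of `background` counts;
#' ventricle voxels get an elevated background; a low-order polynomial
#' illumination field multiplies the image; heteroscedastic Gaussian noise
#' (variance growing with intensity, mimicking photon noise) is added with
#' a standard deviation of `amplitude / snr` at background level.
#'
#' @param atlas an [atlas_volume()] from [generate_toy_atlas()].
#' @param upscale integer factor (scalar or per-axis (z, y, x)) between the
#'   atlas grid and the image stack grid; stack dims = atlas dims * upscale.
#' @param cells_per_mm3 either a single density applied to every anatomical
#'   leaf region, or a named numeric vector of densities keyed by region id.
#' @param cell_radius_um length-2 (mean, sd) of the cell radius in
#'   micrometres; radii are truncated to [0.5, 2] times the mean.
#' @param snr peak-amplitude-to-noise ratio (> 0).
#' @param illumination_gradient relative amplitude of the smooth
#'   multiplicative illumination field (0 = flat).
#' @param seed integer seed; the scene is a pure function of its arguments.
#' @param amplitude peak cell intensity above background, in counts.
#' @param background parenchyma background level, in counts.
#' @param ventricle_background background inside ventricles, in counts.
#' @return A `synthetic_scene`: `stack` (an [image_stack()]),
#'   `label_mask` and `ventricle_mask` (0/1 arrays of the same shape),
#'   `cells` (data.frame: label, z, y, x, volume_vox, radius_um,
#'   region_id), `atlas_transform` (ground-truth stack to atlas map),
#'   `atlas`, and `seed`.
#' @export
generate_scene <- function(atlas, upscale = 4, cells_per_mm3 = 2000,
                           cell_radius_um = c(7, 1.5), snr = 4,
                           illumination_gradient = 0.2, seed = 1,
                           amplitude = 3000, background = 1000,
                           ventricle_background = 4000) {
  stopifnot(inherits(atlas, "atlas_volume"))
  upscale <- as.integer(rep(upscale, length.out = 3))
  if (any(upscale < 1)) stop("upscale must be >= 1")
  if (snr <= 0) stop("snr must be > 0")

  leaves <- ontology_leaves(atlas$ontology)
  nodes <- atlas$ontology$nodes
  vent_ids <- nodes$id[nodes$is_ventricle]
  fib_ids <- nodes$id[ontology_is_fiber(atlas$ontology, nodes$id)]

  if (is.null(names(cells_per_mm3))) {
    if (length(cells_per_mm3) != 1)
      stop("cells_per_mm3 must be a scalar or a named vector")
    anat <- setdiff(leaves, c(vent_ids, fib_ids))
    dens <- stats::setNames(rep(cells_per_mm3, length(anat)), anat)
  } else {
    ids <- as.integer(names(cells_per_mm3))
    if (!all(ids %in% leaves))
      stop("density map names unknown region ids: ",
           paste(setdiff(ids, leaves), collapse = ", "))
    dens <- stats::setNames(as.numeric(cells_per_mm3), ids)
  }
  if (any(dens < 0)) stop("densities must be >= 0")

  ad <- dim(atlas$labels)
  sd3 <- ad * upscale
  spacing <- rep(atlas$spacing_um, 3) / upscale

  with_seed(seed, {
    # --- sample cell centers per region (micrometre coordinates) ---
    vols <- atlas_region_volumes(atlas)
    lab_vec <- as.vector(atlas$labels)
    vent_vox <- which(lab_vec %in% vent_ids)
    vent_um <- if (length(vent_vox)) {
      vz <- (vent_vox - 1) %% ad[1]
      vy <- ((vent_vox - 1) %/% ad[1]) %% ad[2]
      vx <- (vent_vox - 1) %/% (ad[1] * ad[2])
      cbind(vz + 0.5, vy + 0.5, vx + 0.5) * atlas$spacing_um
    } else NULL

    centers <- NULL; radii <- numeric(0); regions <- integer(0)
    r_mean <- cell_radius_um[1]; r_sd <- cell_radius_um[2]
    for (rid in as.integer(names(dens))) {
      d <- dens[[as.character(rid)]]
      if (d <= 0) next
      V <- vols$volume_mm3[vols$region_id == rid]
      n <- stats::rpois(1, d * V)
      if (n == 0) next
      vox <- which(lab_vec == rid)
      if (length(vox) == 0) next
      placed <- 0; attempts <- 0
      while (placed < n && attempts < 20 * n) {
        attempts <- attempts + 1
        v <- vox[sample.int(length(vox), 1)]
        vz <- (v - 1) %% ad[1]
        vy <- ((v - 1) %/% ad[1]) %% ad[2]
        vx <- (v - 1) %/% (ad[1] * ad[2])
        pt <- (c(vz, vy, vx) + stats::runif(3)) * atlas$spacing_um
        r <- min(max(stats::rnorm(1, r_mean, r_sd), 0.5 * r_mean), 2 * r_mean)
        ok <- TRUE
        if (!is.null(centers)) {
          d2 <- colSums((t(centers) - pt)^2)
          # keep blobs separated by more than the sum of radii plus one
          # voxel diagonal so ground-truth components stay distinct
          min_gap <- (radii + r + sqrt(sum(spacing^2)))^2
          if (any(d2 <= min_gap)) ok <- FALSE
        }
        if (ok && !is.null(vent_um)) {
          dv <- min(colSums((t(vent_um) - pt)^2))
          # ventricle voxel centers within r + half an atlas voxel diagonal
          if (dv <= (r + atlas$spacing_um * 0.87)^2) ok <- FALSE
        }
        if (ok) {
          centers <- rbind(centers, pt)
          radii <- c(radii, r)
          regions <- c(regions, rid)
          placed <- placed + 1
        }
      }
    }

    n_cells <- length(radii)
    if (n_cells > 0) {
      rb <- render_blobs_cpp(as.integer(sd3), spacing, centers,
                             sigma_um = radii / 1.5, radius_um = radii,
                             amplitude = amplitude)
      signal <- rb$intensity
      label_mask <- array(as.integer(rb$mask), dim = sd3)
      blob_vox <- rb$blob_vox
    } else {
      signal <- array(0, dim = sd3)
      label_mask <- array(0L, dim = sd3)
      blob_vox <- integer(0)
    }

    # --- background, ventricles, illumination, noise ---
    vent_mask_atlas <- array(as.integer(lab_vec %in% vent_ids), dim = ad)
    ventricle_mask <- upsample_nearest_int(vent_mask_atlas, upscale)
    bg <- array(background, dim = sd3)
    bg[ventricle_mask == 1] <- ventricle_background

    g <- illumination_gradient
    if (g > 0) {
      co <- stats::runif(4, -1, 1)
      u <- (seq_len(sd3[1]) - 0.5) / sd3[1] - 0.5
      v <- (seq_len(sd3[2]) - 0.5) / sd3[2] - 0.5
      w <- (seq_len(sd3[3]) - 0.5) / sd3[3] - 0.5
      field <- outer(outer(co[1] * u, co[2] * v, "+"), co[3] * w, "+") +
        outer(outer(u, v, "+"), w, "+")^2 * co[4]
      field <- field / max(abs(range(field)), 1e-9)
      illum <- 1 + g * field
    } else {
      illum <- 1
    }

    clean <- (bg + signal) * illum
    sigma0 <- amplitude / snr
    noise <- stats::rnorm(length(clean)) * sigma0 *
      sqrt(pmax(clean, 1) / background)
    vox <- round(pmin(pmax(clean + noise, 0), 65535))
    stack <- image_stack(array(as.integer(vox), dim = sd3), spacing)

    cells <- if (n_cells > 0) {
      data.frame(label = seq_len(n_cells),
                 z = centers[, 1] / spacing[1],
                 y = centers[, 2] / spacing[2],
                 x = centers[, 3] / spacing[3],
                 volume_vox = blob_vox,
                 radius_um = radii,
                 region_id = regions)
    } else {
      data.frame(label = integer(0), z = numeric(0), y = numeric(0),
                 x = numeric(0), volume_vox = integer(0),
                 radius_um = numeric(0), region_id = integer(0))
    }

    structure(list(
      stack = stack,
      label_mask = label_mask,
      ventricle_mask = ventricle_mask,
      cells = cells,
      atlas_transform = identity_transform(spacing, atlas$spacing_um),
      atlas = atlas,
      seed = seed
    ), class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  d <- dim(x$stack$voxels)
  cat(sprintf("<synthetic_scene> %d x %d x %d voxels, %d ground-truth cells\n",
              d[1], d[2], d[3], nrow(x$cells)))
  invisible(x)
}

# nearest-neighbour integer upsampling of a (small) integer array
upsample_nearest_int <- function(arr, factors) {
  d <- dim(arr)
  out <- arr[rep(seq_len(d[1]), each = factors[1]), , , drop = FALSE]
  out <- out[, rep(seq_len(d[2]), each = factors[2]), , drop = FALSE]
  out[, , rep(seq_len(d[3]), each = factors[3]), drop = FALSE]
}

#' Sample annotated patches from a scene
#'
#' Draws `n` axis-aligned patches (raw intensities paired with the
#' ground-truth binary label) at seeded uniform positions, emulating the
#' randomly sampled annotation patches a segmentation model is trained on.
#'
#' @param scene a `synthetic_scene`.
#' @param n number of patches (>= 1).
#' @param patch_size length-3 patch dims (z, y, x); must fit in the scene.
#' @param stratify_by_signal if TRUE, patches are ranked by foreground
#'   voxel count and tagged "high"/"low" relative to the median, so a
#'   train/test split can represent both strata proportionally (see
#'   [split_patches()]).
#' @param seed integer seed.
#' @return list of patches; each has `raw`, `label` (3D arrays), `corner`
#'   (1-based (z, y, x)), `fg_vox`, and optionally `stratum`.
#' @export
sample_patches <- function(scene, n, patch_size = c(64, 64, 64),
                           stratify_by_signal = FALSE, seed = 1) {
  stopifnot(inherits(scene, "synthetic_scene"), n >= 1)
  ps <- as.integer(rep(patch_size, length.out = 3))
  d <- dim(scene$stack$voxels)
  if (any(ps > d))
    stop("patch_size exceeds the scene on at least one axis")
  with_seed(seed, {
    patches <- vector("list", n)
    for (i in seq_len(n)) {
      corner <- vapply(1:3, function(a)
        sample.int(d[a] - ps[a] + 1L, 1), integer(1))
      idx <- lapply(1:3, function(a) corner[a]:(corner[a] + ps[a] - 1L))
      raw <- scene$stack$voxels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      lab <- scene$label_mask[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      patches[[i]] <- list(raw = raw, label = lab, corner = corner,
                           fg_vox = sum(lab))
    }
    if (stratify_by_signal) {
      fg <- vapply(patches, `[[`, numeric(1), "fg_vox")
      med <- stats::median(fg)
      for (i in seq_len(n))
        patches[[i]]$stratum <- if (fg[i] > med) "high" else "low"
    }
    patches
  })
}

#' Split patches into train and test sets, stratified by signal
#'
#' Patches are ranked by foreground voxel count and divided at the median
#' into high- and low-signal strata; the test set takes its proportional
#' share from each stratum, so both training and held-out sets see both
#' sparse and dense patches.
#'
#' @param patches list from [sample_patches()].
#' @param n_test number of test patches.
#' @param seed integer seed for the within-stratum draw.
#' @return list with `train` and `test` patch lists.
#' @export
split_patches <- function(patches, n_test, seed = 1) {
  n <- length(patches)
  stopifnot(n_test >= 1, n_test < n)
  fg <- vapply(patches, function(p) as.numeric(p$fg_vox), numeric(1))
  ord <- order(fg)                      # rank by signal
  half <- floor(n / 2)
  low <- ord[seq_len(half)]
  high <- ord[(half + 1):n]
  n_test_low <- round(n_test * length(low) / n)
  n_test_high <- n_test - n_test_low
  with_seed(seed, {
    test <- c(sample(low, n_test_low), sample(high, n_test_high))
  })
  list(train = patches[setdiff(seq_len(n), test)],
       test = patches[sort(test)])
}

#' Write a scene to disk in open formats
#'
#' Writes the raw stack (16-bit TIFF), the ground-truth mask (8-bit TIFF),
#' ground-truth cells (CSV), the ontology (structure-graph JSON) and the
#' ground-truth stack-to-atlas transform (JSON).
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stack(scene$stack, file.path(dir, "raw.tif"))
  write_mask(scene$label_mask, file.path(dir, "label_mask.tif"))
  write_mask(scene$ventricle_mask, file.path(dir, "ventricle_mask.tif"))
  utils::write.csv(scene$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  write_ontology_json(scene$atlas$ontology, file.path(dir, "ontology.json"))
  write_transform_json(scene$atlas_transform, file.path(dir, "transform.json"))
  invisible(dir)
}
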