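# ---- ventricle masking ----------------------------------------------------
#
# Ventricle lumens accumulate antibody and light up, producing spurious
# detections. The pre-processing mirrors the classic recipe: downsample the
# stack to an isotropic working resolution, classify ventricle vs
# parenchyma voxels with a random forest over multi-scale intensity
# features, upsample the binary mask back to stack resolution with
# per-plane bicubic interpolation, and zero the masked voxels.

#' Downsample a stack to an isotropic grid
#'
#' Anti-aliased local averaging: every input voxel contributes to the
#' output voxel whose physical box contains its center. Output dims are
#' `ceil(dim * spacing / target_um)` per axis.
#'
#' @param stack an [image_stack()].
#' @param target_um target isotropic voxel size; must be >= every input
#'   spacing (this op only goes down in resolution).
#' @return An [image_stack()] with spacing `c(target_um, target_um,
#'   target_um)`.
#' @export
downsample_iso <- function(stack, target_um = 25) {
  stopifnot(inherits(stack, "image_stack"))
  if (target_um < max(stack$spacing_um) - 1e-9)
    stop("target_um must be >= the largest input spacing (no upsampling)")
  res <- box_downsample_cpp(array(as.numeric(stack$voxels),
                                  dim = dim(stack$voxels)),
                            stack$spacing_um, target_um)
  image_stack(res$data, rep(target_um, 3))
}

# multi-scale voxel features: smoothed intensity, gradient magnitude and
# Laplacian of Gaussian at each physical scale
voxel_features <- function(stack, feature_scales_um) {
  arr <- array(as.numeric(stack$voxels), dim = dim(stack$voxels))
  sp <- stack$spacing_um
  feats <- list()
  for (s in feature_scales_um) {
    sig_vox <- s / sp
    sm <- gauss3d_cpp(arr, sig_vox)
    feats[[paste0("gauss_", s)]] <- as.vector(sm)
    feats[[paste0("gradmag_", s)]] <- as.vector(gradmag3d_cpp(sm, sp))
    feats[[paste0("log_", s)]] <- as.vector(laplacian3d_cpp(sm, sp))
  }
  as.data.frame(feats)
}

#' Train the ventricle voxel classifier
#'
#' Fits a random forest over per-voxel features (Gaussian-smoothed
#' intensity, gradient magnitude, Laplacian of Gaussian at the given
#' physical scales) to separate ventricle from parenchyma voxels on
#' downsampled stacks.
#'
#' @param stacks list of [image_stack()]s at the working resolution.
#' @param ventricle_labels list of [mask_stack()]s (1 = ventricle), paired
#'   voxelwise with `stacks`.
#' @param feature_scales_um physical feature scales in micrometres.
#' @param seed integer seed (forest training is deterministic given it).
#' @param n_per_class voxels subsampled per class per stack for training.
#' @return A `voxel_classifier` with the fitted forest, the feature spec
#'   and the target spacing.
#' @export
train_voxel_classifier <- function(stacks, ventricle_labels,
                                   feature_scales_um = c(25, 50, 100),
                                   seed = 1, n_per_class = 5000) {
  if (length(stacks) < 1 || length(stacks) != length(ventricle_labels))
    stop("need >= 1 stack with a paired label mask each")
  target <- stacks[[1]]$spacing_um[1]
  xs <- list(); ys <- list()
  for (i in seq_along(stacks)) {
    if (!all(dim(stacks[[i]]$voxels) == dim(ventricle_labels[[i]]$mask)))
      stop("stack ", i, " and its label mask differ in shape")
    f <- voxel_features(stacks[[i]], feature_scales_um)
    y <- as.vector(ventricle_labels[[i]]$mask)
    with_seed(derive_seed(seed, paste0("subsample", i)), {
      idx1 <- which(y == 1); idx0 <- which(y == 0)
      if (length(idx1) > n_per_class) idx1 <- sample(idx1, n_per_class)
      if (length(idx0) > n_per_class) idx0 <- sample(idx0, n_per_class)
      keep <- c(idx1, idx0)
      xs[[i]] <- f[keep, , drop = FALSE]
      ys[[i]] <- y[keep]
    })
  }
  x <- do.call(rbind, xs)
  y <- unlist(ys)
  if (length(unique(y)) < 2)
    stop("labels contain a single class; need both ventricle and parenchyma")
  df <- cbind(x, .class = factor(y, levels = c(0, 1)))
  fit <- ranger::ranger(dependent.variable.name = ".class", data = df,
                        num.trees = 100, probability = FALSE,
                        seed = derive_seed(seed, "forest"),
                        num.threads = 1)
  structure(list(model = fit,
                 feature_scales_um = feature_scales_um,
                 target_spacing_um = target),
            class = "voxel_classifier")
}

#' Predict a ventricle mask
#'
#' @param clf a `voxel_classifier`.
#' @param stack an [image_stack()] at the classifier's working spacing
#'   (within 1%).
#' @param largest_component if TRUE, keep only the largest connected
#'   ventricle component (removes speckle).
#' @return A [mask_stack()] with 1 = ventricle.
#' @export
predict_mask <- function(clf, stack, largest_component = FALSE) {
  stopifnot(inherits(clf, "voxel_classifier"), inherits(stack, "image_stack"))
  if (any(abs(stack$spacing_um - clf$target_spacing_um) >
          0.01 * clf$target_spacing_um))
    stop("stack spacing does not match the classifier's target spacing")
  f <- voxel_features(stack, clf$feature_scales_um)
  pred <- stats::predict(clf$model, data = f, num.threads = 1)
  m <- array(as.integer(as.character(pred$predictions)) ,
             dim = dim(stack$voxels))
  if (largest_component && any(m == 1)) {
    cc <- cc3d_label_cpp(array(m == 1, dim = dim(m)), 26L)
    big <- which.max(cc$stats[, "volume_vox"])
    m <- array(as.integer(cc$labels == big), dim = dim(m))
  }
  mask_stack(m, stack$spacing_um)
}

#' Upsample a binary mask to full stack dimensions
#'
#' Interpolates the mask continuously (bicubic per z-plane, to avoid
#' aliased ventricle edges; nearest across z, matching plane-wise masking)
#' and re-binarizes at `threshold`.
#'
#' @param mask a [mask_stack()] at the working resolution.
#' @param target_shape length-3 output dims (z, y, x); each >= the mask's.
#' @param threshold binarization threshold in (0, 1).
#' @param spacing_um spacing to record on the output mask.
#' @param dilate_vox 6-neighbourhood dilation iterations applied at the
#'   working resolution before interpolation. A suppression mask is safer
#'   slightly too large than too small: without a margin, interpolation
#'   leaves a thin bright rim of lumen unmasked, which downstream
#'   detection can mistake for cells.
#' @return A [mask_stack()] with dims exactly `target_shape`.
#' @export
upsample_mask <- function(mask, target_shape, threshold = 0.5,
                          spacing_um = NULL, dilate_vox = 0) {
  stopifnot(inherits(mask, "mask_stack"))
  target_shape <- as.integer(target_shape)
  if (any(target_shape < dim(mask$mask)))
    stop("target_shape must be >= the mask shape on every axis")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  m <- mask$mask
  if (dilate_vox > 0) for (i in seq_len(dilate_vox)) m <- dilate6(m)
  cont <- bicubic_resize_cpp(array(as.numeric(m), dim = dim(m)),
                             target_shape)
  out <- array(as.integer(cont >= threshold), dim = target_shape)
  if (is.null(spacing_um)) {
    spacing_um <- mask$spacing_um * dim(mask$mask) / target_shape
  }
  mask_stack(out, spacing_um)
}

#' Mask a stack and optionally pad it
#'
#' Sets voxels where the mask is 1 to zero (the masked regions never reach
#' cell detection) and optionally zero-pads symmetrically to `pad_to`.
#' The output stays in the unsigned 16-bit range.
#'
#' @param stack an [image_stack()].
#' @param mask a [mask_stack()] of identical shape (1 = remove).
#' @param pad_to optional length-3 dims to zero-pad to (centered).
#' @return An [image_stack()].
#' @export
apply_mask <- function(stack, mask, pad_to = NULL) {
  stopifnot(inherits(stack, "image_stack"), inherits(mask, "mask_stack"))
  if (!all(dim(stack$voxels) == dim(mask$mask)))
    stop("stack and mask shapes differ")
  vox <- stack$voxels
  vox[mask$mask == 1] <- 0L
  if (!is.null(pad_to)) {
    pad_to <- as.integer(pad_to)
    d <- dim(vox)
    if (any(pad_to < d)) stop("pad_to must be >= current dims")
    out <- array(0L, dim = pad_to)
    off <- (pad_to - d) %/% 2L
    out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]),
        off[3] + seq_len(d[3])] <- vox
    vox <- out
  }
  image_stack(vox, stack$spacing_um)
}

#' Save a ventricle classifier with a JSON sidecar
#'
#' The classifier payload is serialized (RDS) next to a small JSON file
#' recording the feature spec and target spacing, so masks are
#' reproducible and the model auditable without loading it.
#'
#' @param clf a `voxel_classifier`.
#' @param path output .rds path (sidecar gets ".json" appended).
#' @return `path`, invisibly.
#' @export
save_classifier <- function(clf, path) {
  saveRDS(clf, path)
  jsonlite::write_json(list(
    feature_scales_um = clf$feature_scales_um,
    features_per_scale = c("gaussian", "gradient_magnitude",
                           "laplacian_of_gaussian"),
    target_spacing_um = clf$target_spacing_um,
    classes = c("parenchyma", "ventricle")
  ), paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a ventricle classifier
#' @param path .rds path from [save_classifier()].
#' @return A `voxel_classifier`.
#' @export
load_classifier <- function(path) {
  clf <- readRDS(path)
  stopifnot(inherits(clf, "voxel_classifier"))
  clf
}

# one 6-neighbourhood binary dilation step
dilate6 <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, , ] <- pmax(out[-1, , ], m[-d[1], , ])
  out[-d[1], , ] <- pmax(out[-d[1], , ], m[-1, , ])
  out[, -1, ] <- pmax(out[, -1, ], m[, -d[2], ])
  out[, -d[2], ] <- pmax(out[, -d[2], ], m[, -1, ])
  out[, , -1] <- pmax(out[, , -1], m[, , -d[3]])
  out[, , -d[3]] <- pmax(out[, , -d[3]], m[, , -1])
  out
}
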