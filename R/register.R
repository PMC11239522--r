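# ---- affine registration to the atlas ------------------------------------
#
# A 12-parameter affine (translation, log-scale, rotation, shear) maximizing
# normalized mutual information between the downsampled brain and an atlas
# intensity template, initialized from image moments (center of mass and
# per-axis spread). Deliberately affine-only: deformable alignment is
# delegated to external tools via the transform import path.

# parameters -> 3x4 matrix (micrometre convention)
affine_params_to_matrix <- function(par) {
  t3 <- par[1:3]; s3 <- exp(par[4:6]); r3 <- par[7:9]; sh <- par[10:12]
  Rz <- matrix(c(1, 0, 0,
                 0, cos(r3[1]), -sin(r3[1]),
                 0, sin(r3[1]), cos(r3[1])), 3, byrow = TRUE)
  Ry <- matrix(c(cos(r3[2]), 0, sin(r3[2]),
                 0, 1, 0,
                 -sin(r3[2]), 0, cos(r3[2])), 3, byrow = TRUE)
  Rx <- matrix(c(cos(r3[3]), -sin(r3[3]), 0,
                 sin(r3[3]), cos(r3[3]), 0,
                 0, 0, 1), 3, byrow = TRUE)
  Sh <- matrix(c(1, sh[1], sh[2],
                 0, 1, sh[3],
                 0, 0, 1), 3, byrow = TRUE)
  lin <- Rz %*% Ry %*% Rx %*% Sh %*% diag(s3)
  cbind(lin, t3)
}

# Normalized mutual information between two intensity samples, with
# partial-volume (soft) bin assignment: each sample splits its mass
# linearly between the two nearest bins, which removes the hard bin edges
# that otherwise make the similarity landscape piecewise flat and trap
# simplex optimizers.
nmi_score <- function(a, b, bins = 32) {
  pj <- soft_joint_hist_cpp(as.numeric(a), as.numeric(b), as.integer(bins))
  pa <- rowSums(pj); pb <- colSums(pj)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  hj <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  (ha + hb) / max(hj, 1e-12)
}

#' Affine registration of a downsampled stack to an atlas template
#'
#' Estimates the 12-parameter affine map from moving-stack micrometre
#' coordinates to template (atlas) micrometre coordinates by maximizing
#' normalized mutual information over a seeded subsample of moving voxels,
#' with Nelder-Mead refinement in two stages (translation + scale first,
#' then the full parameter set). Initialization matches the centers of
#' mass and per-axis intensity spread of the two volumes.
#'
#' @param moving an [image_stack()] (isotropic, e.g. the downsampled
#'   brain).
#' @param atlas_template an [image_stack()] (isotropic atlas-space
#'   template, e.g. from [atlas_template()]).
#' @param init initialization scheme; only "moments" is implemented.
#' @param metric similarity metric; only "nmi" is implemented.
#' @param seed integer seed for the voxel subsample.
#' @param n_sample number of moving voxels used to evaluate the metric.
#' @return An [affine_transform()] mapping moving to template micrometres.
#' @export
register_affine <- function(moving, atlas_template, init = "moments",
                            metric = "nmi", seed = 1, n_sample = 20000) {
  stopifnot(inherits(moving, "image_stack"),
            inherits(atlas_template, "image_stack"))
  init <- match.arg(init, "moments")
  metric <- match.arg(metric, "nmi")
  mv <- as.numeric(moving$voxels)
  tv <- array(as.numeric(atlas_template$voxels),
              dim = dim(atlas_template$voxels))
  if (stats::sd(mv) < 1e-12 || stats::sd(tv) < 1e-12)
    stop("registration needs non-constant images")

  md <- dim(moving$voxels); msp <- moving$spacing_um
  tsp <- atlas_template$spacing_um[1]

  # moments: weighted center of mass and axis spread in micrometres
  moments_of <- function(arr, spacing) {
    d <- dim(arr)
    w <- pmax(as.numeric(arr) - stats::median(as.numeric(arr)), 0)
    if (sum(w) <= 0) w <- as.numeric(arr) - min(arr) + 1e-9
    iz <- ((seq_along(w) - 1) %% d[1] + 0.5) * spacing[1]
    iy <- (((seq_along(w) - 1) %/% d[1]) %% d[2] + 0.5) * spacing[2]
    ix <- ((seq_along(w) - 1) %/% (d[1] * d[2]) + 0.5) * spacing[3]
    cm <- c(sum(w * iz), sum(w * iy), sum(w * ix)) / sum(w)
    sdv <- sqrt(c(sum(w * (iz - cm[1])^2), sum(w * (iy - cm[2])^2),
                  sum(w * (ix - cm[3])^2)) / sum(w))
    list(cm = cm, sd = sdv)
  }
  mm <- moments_of(array(mv, dim = md), msp)
  tm <- moments_of(tv, rep(tsp, 3))
  s0 <- pmin(pmax(tm$sd / mm$sd, 0.5), 2)
  t0 <- tm$cm - s0 * mm$cm
  par0 <- c(t0, log(s0), rep(0, 6))

  mv_smooth <- as.numeric(gauss3d_cpp(array(mv, dim = md), c(1, 1, 1)))
  tv_smooth <- gauss3d_cpp(tv, c(1, 1, 1))
  pick <- with_seed(seed, sample.int(length(mv), min(n_sample, length(mv))))
  coords <- cbind(((pick - 1) %% md[1] + 0.5) * msp[1],
                  (((pick - 1) %/% md[1]) %% md[2] + 0.5) * msp[2],
                  ((pick - 1) %/% (md[1] * md[2]) + 0.5) * msp[3])

  # out-of-template landings read as intensity 0: misalignments pair real
  # structure with flat background and score poorly, so the optimizer
  # cannot inflate the metric by shrinking the overlap to a few points
  make_objective <- function(vals, template) {
    function(par12) {
      M <- affine_params_to_matrix(par12)
      tgt <- t(M %*% rbind(t(coords), 1)) / tsp  # voxel units
      s <- trilinear_sample_cpp(template, tgt, fill = 0)
      -nmi_score(vals, s)
    }
  }
  obj_smooth <- make_objective(mv_smooth[pick], tv_smooth)
  obj_full <- make_objective(mv[pick], tv)

  # coarse-to-fine with a multistart first stage: the moments guess is
  # biased when the moving volume has large empty borders, so several
  # jittered starts compete on the smoothed metric and the best one seeds
  # the refinement
  starts <- with_seed(derive_seed(seed, "starts"), {
    jit <- lapply(1:5, function(i)
      par0[1:6] + c(stats::rnorm(3, 0, 2 * tsp), stats::rnorm(3, 0, 0.05)))
    c(list(par0[1:6]), jit)
  })
  fits1 <- lapply(starts, function(p0)
    stats::optim(p0, function(p6) obj_smooth(c(p6, rep(0, 6))),
                 method = "Nelder-Mead",
                 control = list(maxit = 300, reltol = 1e-8)))
  best <- fits1[[which.min(vapply(fits1, `[[`, 0, "value"))]]
  fit2 <- stats::optim(c(best$par, rep(0, 6)), obj_smooth,
                       method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-9))
  fit3 <- stats::optim(fit2$par, obj_full, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-9))
  # fresh-simplex restart: Nelder-Mead can collapse prematurely in 12
  # dimensions, and a restart from the incumbent recovers it
  fit4 <- stats::optim(fit3$par, obj_full, method = "Nelder-Mead",
                       control = list(maxit = 1000, reltol = 1e-9))
  affine_transform(affine_params_to_matrix(fit4$par), msp, tsp)
}
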