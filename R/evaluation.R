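# ---- segmentation evaluation ----------------------------------------------
#
# Two-track scoring: volumetric (per-voxel confusion) and instance-wise.
# Instance semantics: a predicted cell overlapping any reference cell by at
# least one voxel is a TP; a predicted cell with zero reference overlap is
# an FP; a reference cell with zero predicted overlap is an FN. The rule is
# asymmetric by construction - two predictions covering one reference cell
# both count as TPs (and TP + FN can exceed the reference count) - and is
# kept exactly as defined. Counts are aggregated across patches first and
# the metric formulas applied once, globally.

#' Evaluation counts
#' @param vox_tp,vox_fp,vox_fn,vox_tn volumetric confusion counts.
#' @param inst_tp,inst_fp,inst_fn instance-level counts.
#' @return An `eval_counts` object (all counts default to zero).
#' @export
eval_counts <- function(vox_tp = 0, vox_fp = 0, vox_fn = 0, vox_tn = 0,
                        inst_tp = 0, inst_fp = 0, inst_fn = 0) {
  structure(list(vox_tp = vox_tp, vox_fp = vox_fp, vox_fn = vox_fn,
                 vox_tn = vox_tn, inst_tp = inst_tp, inst_fp = inst_fp,
                 inst_fn = inst_fn),
            class = "eval_counts")
}

#' Voxelwise confusion counts
#'
#' @param pred,ref binary masks ([mask_stack()] or 0/1 arrays) of equal
#'   shape.
#' @return An `eval_counts` with the volumetric fields set.
#' @export
voxel_confusion <- function(pred, ref) {
  p <- if (inherits(pred, "mask_stack")) pred$mask else pred
  r <- if (inherits(ref, "mask_stack")) ref$mask else ref
  if (!all(dim(p) == dim(r))) stop("pred and ref shapes differ")
  if (!all(p %in% c(0, 1)) || !all(r %in% c(0, 1)))
    stop("masks must be binary")
  eval_counts(vox_tp = sum(p == 1 & r == 1),
              vox_fp = sum(p == 1 & r == 0),
              vox_fn = sum(p == 0 & r == 1),
              vox_tn = sum(p == 0 & r == 0))
}

#' Instance-level matching counts
#'
#' @param pred,ref `labeled_volume`s (from [connected_components()]) of
#'   equal shape.
#' @param counts optional `eval_counts` whose volumetric fields are kept.
#' @return An `eval_counts` with the instance fields set.
#' @export
instance_match <- function(pred, ref, counts = eval_counts()) {
  stopifnot(inherits(pred, "labeled_volume"),
            inherits(ref, "labeled_volume"))
  if (!all(dim(pred$labels) == dim(ref$labels)))
    stop("pred and ref shapes differ")
  ov <- label_overlap_pairs_cpp(pred$labels, ref$labels)
  matched_pred <- unique(ov[, "label_a"])
  matched_ref <- unique(ov[, "label_b"])
  counts$inst_tp <- length(matched_pred)
  counts$inst_fp <- nrow(pred$instances) - length(matched_pred)
  counts$inst_fn <- nrow(ref$instances) - length(matched_ref)
  counts
}

# Dice / sensitivity / precision from TP, FP, FN; undefined denominators
# surface as NA - with a warning when the track was actually evaluated
# (some count is nonzero) - never as silent zeros
score_triplet <- function(tp, fp, fn, what, active = TRUE) {
  res <- c(dice = NA_real_, sensitivity = NA_real_, precision = NA_real_)
  if (2 * tp + fp + fn > 0) res["dice"] <- 2 * tp / (2 * tp + fp + fn)
  if (tp + fn > 0) res["sensitivity"] <- tp / (tp + fn)
  if (tp + fp > 0) res["precision"] <- tp / (tp + fp)
  if (anyNA(res) && active)
    warning(sprintf("%s: undefined metric(s) (zero denominator): %s", what,
                    paste(names(res)[is.na(res)], collapse = ", ")))
  res
}

#' Aggregate counts across patches and score globally
#'
#' Counts are summed across all patches first, then the Dice, sensitivity
#' and precision formulas are applied once - the global scores, not means
#' of per-patch scores. The instance F1 is the instance Dice
#' (harmonic mean of instance precision and sensitivity).
#'
#' @param per_patch list of `eval_counts` (length >= 1).
#' @return An `eval_scores` list: `volumetric` and `instance`, each with
#'   dice, sensitivity, precision; plus `f1` (= instance dice) and the
#'   summed `counts`.
#' @export
aggregate_and_score <- function(per_patch) {
  if (inherits(per_patch, "eval_counts")) per_patch <- list(per_patch)
  if (length(per_patch) < 1) stop("need at least one patch")
  tot <- eval_counts()
  for (pc in per_patch)
    for (f in names(tot)) tot[[f]] <- tot[[f]] + pc[[f]]
  vol <- score_triplet(tot$vox_tp, tot$vox_fp, tot$vox_fn, "volumetric",
                       active = tot$vox_tp + tot$vox_fp + tot$vox_fn +
                         tot$vox_tn > 0)
  inst <- score_triplet(tot$inst_tp, tot$inst_fp, tot$inst_fn, "instance",
                        active = tot$inst_tp + tot$inst_fp +
                          tot$inst_fn > 0)
  structure(list(volumetric = as.list(vol), instance = as.list(inst),
                 f1 = unname(inst["dice"]), counts = tot),
            class = "eval_scores")
}

#' @export
print.eval_scores <- function(x, ...) {
  cat(sprintf(
    "<eval_scores> volumetric dice %.4f | instance F1 %.4f (prec %.4f, sens %.4f)\n",
    x$volumetric$dice, x$f1, x$instance$precision, x$instance$sensitivity))
  invisible(x)
}

#' Instance Dice (F1) from precision and sensitivity
#'
#' The algebraic identity 2PS/(P+S): the instance Dice computed from
#' TP/FP/FN counts always equals the harmonic mean of the corresponding
#' precision and sensitivity.
#'
#' @param precision,sensitivity scalars in [0, 1].
#' @return the F1 score.
#' @export
f1_from_precision_sensitivity <- function(precision, sensitivity) {
  2 * precision * sensitivity / (precision + sensitivity)
}

#' Evaluate a segmentation against a reference, per patch and globally
#'
#' Convenience wrapper: runs voxel confusion and instance matching on each
#' pred/ref pair of binary masks and aggregates globally.
#'
#' @param pred_masks,ref_masks lists of binary arrays (paired).
#' @param connectivity connectivity for instance extraction.
#' @return An `eval_scores`.
#' @export
evaluate_patches <- function(pred_masks, ref_masks, connectivity = 26) {
  stopifnot(length(pred_masks) == length(ref_masks),
            length(pred_masks) >= 1)
  per <- lapply(seq_along(pred_masks), function(i) {
    p <- pred_masks[[i]]; r <- ref_masks[[i]]
    cnt <- voxel_confusion(p, r)
    instance_match(connected_components(p, connectivity),
                   connected_components(r, connectivity), cnt)
  })
  aggregate_and_score(per)
}
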