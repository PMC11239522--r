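# ---- 3D UNet segmentation core -------------------------------------------
#
# A symmetric 3D encoder-decoder ("BasicUNet"-style) voxel classifier:
# two 3x3x3 convolutions + Mish per encoder level with 2x max-pooling
# between levels, nearest-neighbour upsampling + skip concatenation + two
# convolutions per decoder level, and a 1x1x1 logit head. Trained with
# binary cross-entropy on annotated patches; whole stacks are segmented by
# sliding-window inference. The numerical engine lives in compiled code.

#' UNet configuration
#'
#' @param base_features channels at the first level (doubled per level).
#' @param depth number of encoder levels (>= 2).
#' @param lr initial learning rate.
#' @param batch_size training batch size.
#' @param epochs training epochs; the final epoch's weights are kept (no
#'   model selection).
#' @param seed integer seed controlling weight init, shuffling and
#'   augmentation.
#' @param activation only "mish" is implemented.
#' @param loss only "bce" (binary cross-entropy with logits).
#' @return A `unet_config`.
#' @export
unet_config <- function(base_features = 16, depth = 5, lr = 1e-3,
                        batch_size = 4, epochs = 500, seed = 1,
                        activation = "mish", loss = "bce") {
  if (depth < 2) stop("depth must be >= 2")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (lr <= 0) stop("lr must be > 0")
  if (!identical(activation, "mish")) stop('activation must be "mish"')
  if (!identical(loss, "bce")) stop('loss must be "bce"')
  structure(list(in_channels = 1L, out_channels = 1L,
                 base_features = as.integer(base_features),
                 depth = as.integer(depth), lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 activation = activation, loss = loss),
            class = "unet_config")
}

#' Build an (untrained) UNet
#'
#' @param config a [unet_config()]. The seed fully determines the initial
#'   weights.
#' @return A `unet_model` (config + compiled network handle).
#' @export
build_unet <- function(config) {
  stopifnot(inherits(config, "unet_config"))
  ptr <- unet_create(config$depth, config$base_features, config$seed)
  structure(list(ptr = ptr, config = config, training_log = NULL,
                 checkpoint_policy = "last"),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf(
    "<unet_model> depth %d, base %d, %s parameters%s\n",
    x$config$depth, x$config$base_features,
    format(n_params(x), big.mark = ","),
    if (is.null(x$training_log)) " (untrained)" else
      sprintf(", trained %d epochs", length(x$training_log))))
  invisible(x)
}

#' Number of trainable parameters
#' @param model a `unet_model`.
#' @return parameter count.
#' @export
n_params <- function(model) unet_n_params(model$ptr)

#' Raw forward pass
#'
#' Input dims must be divisible by 2^(depth-1); the sliding-window inferer
#' handles padding for arbitrary shapes.
#'
#' @param model a `unet_model`.
#' @param arr 3D array (already intensity-normalized).
#' @param sigmoid return probabilities (TRUE) or logits.
#' @return 3D array of the same shape.
#' @export
unet_predict <- function(model, arr, sigmoid = TRUE) {
  unet_forward(model$ptr, array(as.numeric(arr), dim = dim(arr)), sigmoid)
}

#' Robust intensity normalization
#'
#' Centers and scales a volume by a trimmed median/MAD estimate of its
#' background distribution: zero voxels (padding and masked-out regions)
#' are excluded, an outlier trim at `trim` MADs drops bright structures
#' (cell somata, ventricle lumens) from the statistics, and the volume is
#' mapped so that `median - halfwidth * MAD` becomes 0 and
#' `median + halfwidth * MAD` becomes 1. The upper tail stays linear -
#' somata live in the extreme top of the histogram and clipping them to
#' the brightest noise value would erase the contrast the detector needs.
#' Because the statistics ignore bright outliers, the mapping is nearly
#' invariant to whether ventricles are masked, so masked and unmasked
#' runs of the same stack see the same intensity scale. Applied per patch
#' at training and per stack at inference.
#'
#' @param arr numeric array.
#' @param trim outlier cut, in MADs, for the scale estimate.
#' @param halfwidth half-width of the [0, 1] target band, in MADs.
#' @return normalized array.
#' @export
normalize_intensity <- function(arr, trim = 3.5, halfwidth = 3) {
  v <- arr[arr > 0]
  if (length(v) < 2) return(array(0, dim = dim(arr)))
  med <- stats::median(v)
  md <- stats::mad(v)
  if (md <= 0) md <- stats::sd(v)
  if (md <= 0) return(array(0, dim = dim(arr)))
  keep <- v[abs(v - med) <= trim * md]
  if (length(keep) >= 2) {
    med <- stats::median(keep)
    md2 <- stats::mad(keep)
    if (md2 > 0) md <- md2
  }
  lo <- med - halfwidth * md
  out <- (arr - lo) / (2 * halfwidth * md)
  array(pmax(out, 0), dim = dim(arr))
}

# seeded flip / 90-degree-rotation augmentation of a paired patch;
# rotations act in the (y, x) plane, flips on any axis
augment_pair <- function(raw, lab) {
  for (a in 1:3) if (stats::runif(1) < 0.5) {
    idx <- rev(seq_len(dim(raw)[a]))
    if (a == 1) { raw <- raw[idx, , , drop = FALSE]; lab <- lab[idx, , , drop = FALSE] }
    if (a == 2) { raw <- raw[, idx, , drop = FALSE]; lab <- lab[, idx, , drop = FALSE] }
    if (a == 3) { raw <- raw[, , idx, drop = FALSE]; lab <- lab[, , idx, drop = FALSE] }
  }
  if (dim(raw)[2] == dim(raw)[3] && stats::runif(1) < 0.5) {
    raw <- aperm(raw, c(1, 3, 2)); lab <- aperm(lab, c(1, 3, 2))
  }
  list(raw = raw, lab = lab)
}

#' Train a UNet on annotated patches
#'
#' Patches are percentile-normalized, augmented with seeded flips and
#' in-plane 90-degree rotations, shuffled per epoch and fed in mini
#' batches. The optimizer is Adam with linear warmup over the first 5% of
#' steps and cosine decay to 10% of the peak rate. The returned model is
#' the final epoch's checkpoint together with the per-epoch loss log.
#'
#' @param model a `unet_model` from [build_unet()] (or a checkpoint to
#'   fine-tune).
#' @param patches list of patches, each a list with `raw` and `label`
#'   arrays of identical shape (labels strictly 0/1).
#' @param config optional [unet_config()] overriding the model's.
#' @param augment enable flip/rotation augmentation.
#' @param verbose print the per-epoch loss.
#' @return The trained `unet_model` with `training_log` (per-epoch mean
#'   BCE).
#' @export
train_unet <- function(model, patches, config = NULL, augment = TRUE,
                       verbose = FALSE) {
  stopifnot(inherits(model, "unet_model"))
  cfg <- config %||% model$config
  if (length(patches) < 1) stop("need at least one training patch")
  for (p in patches) {
    if (!all(dim(p$raw) == dim(p$label)))
      stop("raw and label shapes differ in a patch")
    if (!all(p$label %in% c(0, 1)))
      stop("label values must be 0/1")
  }
  xs <- lapply(patches, function(p)
    normalize_intensity(array(as.numeric(p$raw), dim = dim(p$raw))))
  ys <- lapply(patches, function(p)
    array(as.numeric(p$label), dim = dim(p$label)))

  n <- length(xs)
  steps_per_epoch <- ceiling(n / cfg$batch_size)
  total_steps <- cfg$epochs * steps_per_epoch
  warm <- max(1, round(0.05 * total_steps))
  lr_at <- function(step) {
    if (step <= warm) return(cfg$lr * step / warm)
    t <- (step - warm) / max(1, total_steps - warm)
    cfg$lr * (0.1 + 0.9 * 0.5 * (1 + cos(pi * t)))
  }

  log <- numeric(cfg$epochs)
  step <- 0
  with_seed(derive_seed(cfg$seed, "train"), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (b in seq_len(steps_per_epoch)) {
        take <- ord[((b - 1) * cfg$batch_size + 1):min(b * cfg$batch_size, n)]
        take <- take[!is.na(take)]
        bx <- list(); by <- list()
        for (i in seq_along(take)) {
          if (augment) {
            a <- augment_pair(xs[[take[i]]], ys[[take[i]]])
            bx[[i]] <- a$raw; by[[i]] <- a$lab
          } else {
            bx[[i]] <- xs[[take[i]]]; by[[i]] <- ys[[take[i]]]
          }
        }
        step <- step + 1
        loss <- unet_train_batch(model$ptr, bx, by, lr_at(step),
                                 0.9, 0.999, 1e-8)
        ep_loss <- ep_loss + loss; nb <- nb + 1
      }
      log[ep] <- ep_loss / nb
      if (verbose) message(sprintf("epoch %d/%d  loss %.5f", ep,
                                   cfg$epochs, log[ep]))
    }
  })
  model$training_log <- c(model$training_log, log)
  model$config <- cfg
  model
}

#' Sliding-window inference over a whole stack
#'
#' Tiles the (masked) stack with overlapping windows, runs the network per
#' window and blends overlapping predictions with Gaussian or uniform
#' weights. Borders are reflectively padded so every voxel is covered, and
#' the result is cropped back to the input shape.
#'
#' @param model a trained `unet_model` (or, for testing, a function
#'   mapping a 3D array to a same-shape probability array).
#' @param stack an [image_stack()] (raw intensities; normalization is
#'   applied internally over the whole stack).
#' @param window length-3 window dims; multiples of 2^(depth-1).
#' @param overlap fractional window overlap in [0, 1).
#' @param blend "gaussian" (default) or "uniform" blending weights.
#' @return A [prob_stack()] of the input shape.
#' @export
sliding_window_infer <- function(model, stack, window = c(64, 64, 64),
                                 overlap = 0.25, blend = "gaussian") {
  stopifnot(inherits(stack, "image_stack"))
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  blend <- match.arg(blend, c("gaussian", "uniform"))
  window <- as.integer(rep(window, length.out = 3))
  arr <- normalize_intensity(array(as.numeric(stack$voxels),
                                   dim = dim(stack$voxels)))
  d <- dim(arr)

  # reflect-pad so each axis holds at least one window
  pad_hi <- pmax(window - d, 0L)
  if (any(pad_hi > 0)) {
    idx <- lapply(1:3, function(a) {
      i <- seq_len(d[a])
      if (pad_hi[a] > 0) c(i, rev(i)[seq_len(pad_hi[a])]) else i
    })
    arr <- arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  dp <- dim(arr)

  stride <- pmax(1L, as.integer(round(window * (1 - overlap))))
  starts <- lapply(1:3, function(a) {
    s <- seq(1L, max(1L, dp[a] - window[a] + 1L), by = stride[a])
    if (s[length(s)] + window[a] - 1L < dp[a])
      s <- c(s, dp[a] - window[a] + 1L)
    unique(s)
  })

  w <- if (blend == "uniform") array(1, dim = window) else {
    g1 <- function(nw) exp(-0.5 * ((seq_len(nw) - (nw + 1) / 2) /
                                     (0.25 * nw))^2)
    outer(outer(g1(window[1]), g1(window[2])), g1(window[3]))
  }

  forward <- if (is.function(model)) model else
    function(a) unet_predict(model, a, sigmoid = TRUE)

  acc <- array(0, dim = dp)
  wacc <- array(0, dim = dp)
  for (sz in starts[[1]]) for (sy in starts[[2]]) for (sx in starts[[3]]) {
    iz <- sz:(sz + window[1] - 1L)
    iy <- sy:(sy + window[2] - 1L)
    ix <- sx:(sx + window[3] - 1L)
    p <- forward(arr[iz, iy, ix, drop = FALSE])
    acc[iz, iy, ix] <- acc[iz, iy, ix] + p * w
    wacc[iz, iy, ix] <- wacc[iz, iy, ix] + w
  }
  probs <- acc / wacc
  probs <- probs[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
  probs <- pmin(pmax(probs, 0), 1)
  prob_stack(array(probs, dim = d), stack$spacing_um)
}

#' Binarize a probability map
#'
#' Voxels with probability greater than or equal to the threshold become
#' foreground (ties count as foreground).
#'
#' @param prob a [prob_stack()].
#' @param threshold scalar in (0, 1).
#' @return A [mask_stack()].
#' @export
binarize <- function(prob, threshold = 0.5) {
  stopifnot(inherits(prob, "prob_stack"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  mask_stack(array(as.integer(prob$values >= threshold),
                   dim = dim(prob$values)), prob$spacing_um)
}

#' Save a model checkpoint
#'
#' Weights plus the embedded configuration and training log; the file is a
#' self-contained checkpoint loadable with [load_checkpoint()].
#'
#' @param model a `unet_model`.
#' @param path output file (.rds).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config,
               weights = unet_get_weights(model$ptr),
               training_log = model$training_log,
               checkpoint_policy = model$checkpoint_policy), path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path file written by [save_checkpoint()].
#' @return A `unet_model`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_unet(ck$config)
  unet_set_weights(model$ptr, ck$weights)
  model$training_log <- ck$training_log
  model
}

#' Extract model weights as plain R objects
#' @param model a `unet_model`.
#' @return list of per-layer `W`/`b`.
#' @export
model_weights <- function(model) unet_get_weights(model$ptr)
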