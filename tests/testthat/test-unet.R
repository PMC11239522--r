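# The 3D UNet: construction, gradients, training behaviour, inference.

test_that("config validation and parameter counting behave", {
  expect_error(unet_config(depth = 1), "depth")
  expect_error(unet_config(batch_size = 0), "batch_size")
  expect_error(unet_config(lr = 0), "lr")
  m8 <- build_unet(unet_config(base_features = 8, depth = 3, seed = 1))
  m16 <- build_unet(unet_config(base_features = 16, depth = 3, seed = 1))
  expect_gt(n_params(m16), n_params(m8))   # capacity grows with width
})

test_that("forward pass honours the shape contract", {
  m <- build_unet(unet_config(base_features = 8, depth = 3, seed = 2))
  x <- array(0, dim = c(32, 32, 32))
  p <- unet_predict(m, x, sigmoid = FALSE)
  expect_equal(dim(p), c(32, 32, 32))
  expect_true(all(is.finite(p)))
  expect_error(unet_predict(m, array(0, dim = c(30, 32, 32))), "divisible")
})

test_that("weight initialization is a pure function of the seed", {
  w1 <- model_weights(build_unet(unet_config(base_features = 4, depth = 3,
                                             seed = 7)))
  w2 <- model_weights(build_unet(unet_config(base_features = 4, depth = 3,
                                             seed = 7)))
  w3 <- model_weights(build_unet(unet_config(base_features = 4, depth = 3,
                                             seed = 8)))
  expect_identical(w1, w2)
  expect_false(identical(w1, w3))
})

test_that("analytic gradients match finite differences", {
  set.seed(5)
  m <- build_unet(unet_config(base_features = 2, depth = 2, seed = 3))
  x <- array(rnorm(8^3), dim = c(8, 8, 8))
  y <- array(rbinom(8^3, 1, 0.3), dim = c(8, 8, 8))
  g <- cellmapr:::unet_param_grads(m$ptr, x, y)
  w <- model_weights(m)
  loss_at <- function(wmod) {
    cellmapr:::unet_set_weights(m$ptr, wmod)
    cellmapr:::unet_loss(m$ptr, list(x), list(y))
  }
  pairs <- NULL
  for (li in seq_along(w)) {
    for (r in 1:5) {
      i <- sample(length(w[[li]]$W), 1)
      eps <- 1e-2
      wp <- w; wp[[li]]$W[i] <- wp[[li]]$W[i] + eps
      wm <- w; wm[[li]]$W[i] <- wm[[li]]$W[i] - eps
      fd <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
      pairs <- rbind(pairs, c(fd, g[[li]]$W[i]))
    }
  }
  cellmapr:::unet_set_weights(m$ptr, w)
  expect_gt(stats::cor(pairs[, 1], pairs[, 2]), 0.999)
  expect_lt(max(abs(pairs[, 1] - pairs[, 2])),
            0.02 * max(abs(pairs[, 1])) + 1e-4)
})

test_that("training reduces the loss and is reproducible", {
  scene <- tiny_scene()
  patches <- sample_patches(scene, 6, c(32, 32, 32), seed = 9)
  cfg <- unet_config(base_features = 4, depth = 3, lr = 1e-3,
                     batch_size = 2, epochs = 8, seed = 4)
  m <- train_unet(build_unet(cfg), patches)
  expect_length(m$training_log, 8)
  expect_lt(m$training_log[8], m$training_log[1])

  m2 <- train_unet(build_unet(cfg), patches)
  expect_identical(m$training_log, m2$training_log)  # seeded end to end
  expect_identical(model_weights(m), model_weights(m2))
})

test_that("all-background labels drive predictions below half", {
  set.seed(6)
  xs <- lapply(1:4, function(i)
    list(raw = array(runif(16^3, 0, 1000), dim = c(16, 16, 16)),
         label = array(0L, dim = c(16, 16, 16))))
  cfg <- unet_config(base_features = 4, depth = 2, lr = 1e-3,
                     batch_size = 4, epochs = 10, seed = 5)
  m <- train_unet(build_unet(cfg), xs)
  p <- unet_predict(m, normalize_intensity(xs[[1]]$raw))
  expect_true(all(p < 0.5))
})

test_that("training validates its inputs", {
  cfg <- unet_config(base_features = 4, depth = 2, seed = 1)
  m <- build_unet(cfg)
  bad_shape <- list(list(raw = array(0, dim = c(8, 8, 8)),
                         label = array(0, dim = c(8, 8, 4))))
  expect_error(train_unet(m, bad_shape), "shapes differ")
  bad_label <- list(list(raw = array(0, dim = c(8, 8, 8)),
                         label = array(0.5, dim = c(8, 8, 8))))
  expect_error(train_unet(m, bad_label), "0/1")
  expect_error(train_unet(m, list()), "at least one")
})

test_that("sliding-window inference blends correctly", {
  st <- image_stack(array(runif(40^3, 0, 4000), dim = c(40, 40, 40)),
                    c(1, 1, 1))
  # constant-output stub: blending any overlap must reproduce the constant
  stub <- function(a) array(0.3, dim = dim(a))
  for (ov in c(0, 0.5)) {
    pr <- sliding_window_infer(stub, st, window = c(16, 16, 16),
                               overlap = ov)
    expect_equal(dim(pr$values), c(40, 40, 40))
    expect_true(all(abs(pr$values - 0.3) < 1e-12))
  }
  # window covering the whole (padded) stack equals a single forward pass
  m <- build_unet(unet_config(base_features = 4, depth = 2, seed = 11))
  st2 <- image_stack(array(runif(32^3, 0, 4000), dim = c(32, 32, 32)),
                     c(1, 1, 1))
  pr1 <- sliding_window_infer(m, st2, window = c(32, 32, 32), overlap = 0)
  direct <- unet_predict(m, normalize_intensity(
    array(as.numeric(st2$voxels), dim = c(32, 32, 32))))
  expect_equal(as.vector(pr1$values), as.vector(direct), tolerance = 1e-6)
  # overlapping windows still yield finite probabilities everywhere
  pr2 <- sliding_window_infer(m, st2, window = c(16, 16, 16), overlap = 0.5)
  expect_false(anyNA(pr2$values))
  expect_true(all(pr2$values >= 0 & pr2$values <= 1))
})

test_that("binarization uses >= and is monotone in the threshold", {
  p3 <- prob_stack(array(0.3, dim = c(4, 4, 4)), c(1, 1, 1))
  expect_true(all(binarize(p3, 0.5)$mask == 0))
  p5 <- prob_stack(array(0.5, dim = c(4, 4, 4)), c(1, 1, 1))
  expect_true(all(binarize(p5, 0.5)$mask == 1))   # ties are foreground
  set.seed(3)
  pr <- prob_stack(array(runif(10^3), dim = c(10, 10, 10)), c(1, 1, 1))
  expect_gte(sum(binarize(pr, 0.3)$mask), sum(binarize(pr, 0.7)$mask))
})

test_that("checkpoints round-trip through disk", {
  scene <- tiny_scene()
  patches <- sample_patches(scene, 2, c(16, 16, 16), seed = 13)
  cfg <- unet_config(base_features = 4, depth = 2, lr = 1e-3,
                     batch_size = 2, epochs = 2, seed = 12)
  m <- train_unet(build_unet(cfg), patches)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  x <- normalize_intensity(array(as.numeric(patches[[1]]$raw),
                                 dim = c(16, 16, 16)))
  expect_equal(unet_predict(m, x), unet_predict(m2, x))
  expect_identical(m$training_log, m2$training_log)
})
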