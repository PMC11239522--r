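# Ventricle masking: downsampling, voxel classification, mask upsampling
# and application.

test_that("isotropic downsampling gets dims, spacing and intensities right", {
  st <- image_stack(array(500L, dim = c(160, 160, 160)),
                    c(6, 1.625, 1.625))
  ds <- downsample_iso(st, 25)
  expect_equal(dim(ds$voxels), c(39, 11, 11))   # ceil(dim * spacing / 25)
  expect_equal(ds$spacing_um, c(25, 25, 25))
  expect_true(all(abs(ds$voxels - 500) < 1e-9)) # mean of a constant

  iso <- image_stack(array(runif(20^3, 0, 1000), dim = c(20, 20, 20)),
                     c(25, 25, 25))
  same <- downsample_iso(iso, 25)
  expect_equal(dim(same$voxels), c(20, 20, 20))
  expect_equal(as.vector(same$voxels), as.vector(iso$voxels),
               tolerance = 1e-12)

  expect_error(downsample_iso(iso, 10), "target_um")
})

make_two_class_stack <- function(noise = 0) {
  vox <- array(1000, dim = c(20, 20, 20))
  lab <- array(0L, dim = c(20, 20, 20))
  vox[6:15, 6:15, 6:15] <- 2000          # "ventricle" at 2x parenchyma
  lab[6:15, 6:15, 6:15] <- 1L
  if (noise > 0) vox <- vox + array(rnorm(20^3, 0, noise), dim = dim(vox))
  list(stack = image_stack(vox, c(25, 25, 25)),
       labels = mask_stack(lab, c(25, 25, 25)))
}

test_that("voxel classifier separates a clean two-class volume perfectly", {
  tc <- make_two_class_stack()
  clf <- train_voxel_classifier(list(tc$stack), list(tc$labels), seed = 1)
  m <- predict_mask(clf, tc$stack)
  expect_identical(m$mask, tc$labels$mask)      # recovers the training label
  expect_true(all(m$mask %in% c(0L, 1L)))
  # an all-zero stack contains no ventricle
  zero <- image_stack(array(0L, dim = c(20, 20, 20)), c(25, 25, 25))
  expect_equal(sum(predict_mask(clf, zero)$mask), 0)
})

test_that("degenerate labels and spacing mismatches are rejected", {
  tc <- make_two_class_stack()
  allpar <- mask_stack(array(0L, dim = c(20, 20, 20)), c(25, 25, 25))
  expect_error(train_voxel_classifier(list(tc$stack), list(allpar)),
               "single class")
  clf <- train_voxel_classifier(list(tc$stack), list(tc$labels), seed = 1)
  wrong <- image_stack(array(0L, dim = c(10, 10, 10)), c(50, 50, 50))
  expect_error(predict_mask(clf, wrong), "spacing")
})

test_that("classifier generalizes across scenes from the same generator", {
  atlas <- tiny_atlas()
  sc_train <- generate_scene(atlas, upscale = 2, cells_per_mm3 = 400,
                             cell_radius_um = c(14, 3), seed = 21)
  sc_test <- generate_scene(atlas, upscale = 2, cells_per_mm3 = 400,
                            cell_radius_um = c(14, 3), seed = 22)
  down <- function(sc) {
    ds <- downsample_iso(sc$stack, 40)
    vm <- downsample_iso(image_stack(sc$ventricle_mask * 1000,
                                     sc$stack$spacing_um), 40)
    list(stack = ds, mask = mask_stack(array(as.integer(vm$voxels > 500),
                                             dim = dim(vm$voxels)),
                                       vm$spacing_um))
  }
  tr <- down(sc_train); te <- down(sc_test)
  clf <- train_voxel_classifier(list(tr$stack), list(tr$mask),
                                feature_scales_um = c(40, 80, 160), seed = 1)
  pred <- predict_mask(clf, te$stack)
  tp <- sum(pred$mask == 1 & te$mask$mask == 1)
  prec <- tp / max(sum(pred$mask == 1), 1)
  sens <- tp / max(sum(te$mask$mask == 1), 1)
  f1 <- 2 * prec * sens / max(prec + sens, 1e-9)
  expect_gte(f1, 0.9)
})

test_that("mask upsampling preserves constants and volume fractions", {
  ones <- mask_stack(array(1L, dim = c(8, 8, 8)), c(50, 50, 50))
  up <- upsample_mask(ones, c(16, 16, 16))
  expect_equal(dim(up$mask), c(16, 16, 16))
  expect_true(all(up$mask == 1))
  zeros <- mask_stack(array(0L, dim = c(8, 8, 8)), c(50, 50, 50))
  expect_true(all(upsample_mask(zeros, c(16, 16, 16))$mask == 0))

  # centered cube covering 50% of each in-plane axis, upsampled 4x
  m <- array(0L, dim = c(10, 10, 10))
  m[3:7, 3:7, 3:7] <- 1L    # 5^3 / 10^3 = 12.5% volume fraction
  cube <- mask_stack(m, c(50, 50, 50))
  up4 <- upsample_mask(cube, c(40, 40, 40), threshold = 0.5)
  frac_in <- mean(m); frac_up <- mean(up4$mask)
  expect_lt(abs(frac_up - frac_in) / frac_in, 0.1)

  expect_error(upsample_mask(cube, c(5, 40, 40)), "target_shape")
})

test_that("masking zeroes, pads and stays idempotent", {
  vox <- array(sample.int(4000, 6^3, replace = TRUE), dim = c(6, 6, 6))
  st <- image_stack(vox, c(1, 1, 1))
  none <- mask_stack(array(0L, dim = c(6, 6, 6)), c(1, 1, 1))
  all1 <- mask_stack(array(1L, dim = c(6, 6, 6)), c(1, 1, 1))
  expect_identical(apply_mask(st, none)$voxels, vox)
  expect_true(all(apply_mask(st, all1)$voxels == 0))

  half <- mask_stack(array(rbinom(6^3, 1, 0.4), dim = c(6, 6, 6)), c(1, 1, 1))
  once <- apply_mask(st, half)
  twice <- apply_mask(once, half)
  expect_identical(once$voxels, twice$voxels)

  pad <- apply_mask(st, none, pad_to = c(10, 10, 10))
  expect_equal(dim(pad$voxels), c(10, 10, 10))
  expect_identical(pad$voxels[3:8, 3:8, 3:8], vox)
  expect_equal(sum(pad$voxels) - sum(vox), 0)
})

test_that("down-then-up round trip of a smooth mask preserves volume", {
  set.seed(42)
  for (i in 1:5) {
    m <- array(0, dim = c(24, 24, 24))
    c0 <- runif(3, 9, 15); r <- runif(1, 5, 8)
    for (x in 1:24) for (y in 1:24) for (z in 1:24)
      if (sum((c(z, y, x) - c0)^2) < r^2) m[z, y, x] <- 1
    ms <- mask_stack(m, c(25, 25, 25))
    ds <- downsample_iso(image_stack(m * 1000, c(25, 25, 25)), 50)
    small <- mask_stack(array(as.integer(ds$voxels > 500),
                              dim = dim(ds$voxels)), c(50, 50, 50))
    up <- upsample_mask(small, c(24, 24, 24))
    expect_lt(abs(sum(up$mask) - sum(m)) / sum(m), 0.15)
  }
})
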