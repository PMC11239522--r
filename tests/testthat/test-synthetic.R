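# Synthetic atlas, ontology and scene generator.

test_that("toy atlas tiles the volume with the promised hierarchy", {
  atlas <- generate_toy_atlas(c(32, 32, 32), levels = 2,
                              regions_per_split = 2, seed = 7)
  expect_true(all(atlas$labels > 0))            # every voxel labeled
  expect_setequal(unique(atlas$ontology$nodes$level), c(1, 2))

  atlas3 <- generate_toy_atlas(c(32, 32, 32), levels = 3,
                               regions_per_split = 2, seed = 7)
  leaves <- ontology_leaves(atlas3$ontology)
  expect_length(leaves, 2^2 + 2)                # anatomical + ventricle + fiber
  counts <- table(as.vector(atlas3$labels))
  expect_equal(sum(counts), 32^3)               # leaves tile the volume
  expect_true(all(as.integer(names(counts)) %in% leaves))
})

test_that("toy atlas is deterministic and validates inputs", {
  a1 <- generate_toy_atlas(c(16, 16, 16), levels = 3, seed = 7)
  a2 <- generate_toy_atlas(c(16, 16, 16), levels = 3, seed = 7)
  expect_identical(a1$labels, a2$labels)
  expect_error(generate_toy_atlas(c(4, 16, 16), levels = 2), "shape")
  expect_error(generate_toy_atlas(c(16, 16, 16), levels = 1), "levels")
  expect_error(generate_toy_atlas(c(16, 16, 16), levels = 12), "levels")
})

test_that("ontology invariants are enforced", {
  ont <- tiny_atlas()$ontology
  nodes <- ont$nodes
  # levels step by one along parent links, exactly one root
  has_parent <- !is.na(nodes$parent_id)
  idx <- match(nodes$parent_id[has_parent], nodes$id)
  expect_true(all(nodes$level[has_parent] == nodes$level[idx] + 1))
  expect_equal(sum(!has_parent), 1)
  # invalid trees are rejected
  bad <- nodes; bad$parent_id[1] <- bad$id[2]  # root gets a parent -> cycle
  expect_error(ontology(bad))
  bad2 <- nodes; bad2$id[2] <- bad2$id[3]
  expect_error(ontology(bad2), "unique")
})

test_that("zero densities give an empty scene and seeds fix everything", {
  atlas <- tiny_atlas()
  s0 <- generate_scene(atlas, upscale = 2, cells_per_mm3 = 0, seed = 3)
  expect_equal(nrow(s0$cells), 0)
  expect_true(all(s0$label_mask == 0))

  s1 <- tiny_scene()
  s2 <- generate_scene(atlas, upscale = 4, cells_per_mm3 = 800,
                       cell_radius_um = c(20, 4), snr = 6, seed = 11)
  expect_identical(s1$stack$voxels, s2$stack$voxels)
  expect_identical(s1$cells, s2$cells)

  expect_error(generate_scene(atlas, cells_per_mm3 = c("999" = 10)),
               "unknown region")
})

test_that("ground truth is self-consistent", {
  scene <- tiny_scene()
  expect_gt(nrow(scene$cells), 30)
  # one connected component per ground-truth cell
  cc <- connected_components(scene$label_mask, 26)
  expect_equal(nrow(cc$instances), nrow(scene$cells))
  # intensities stay within the 16-bit range
  expect_true(all(scene$stack$voxels >= 0 & scene$stack$voxels <= 65535))
  # cells never overlap the ventricle lumen
  expect_equal(sum(scene$label_mask * scene$ventricle_mask), 0)
  # stored transform recovers every generating region (boundary cells exempt)
  mp <- map_cells(scene$cells, scene$atlas_transform, scene$atlas)
  expect_gte(mean(mp$region_id == scene$cells$region_id), 0.99)
})

test_that("per-region counts follow the Poisson law", {
  atlas <- tiny_atlas()
  leaves <- ontology_leaves(atlas$ontology)
  vols <- atlas_region_volumes(atlas)
  anat <- setdiff(leaves, atlas$ontology$nodes$id[
    atlas$ontology$nodes$is_ventricle | atlas$ontology$nodes$is_fiber_tract])
  rid <- anat[which.max(vols$volume_mm3[match(anat, vols$region_id)])]
  V <- vols$volume_mm3[vols$region_id == rid]
  d <- 400
  counts <- vapply(1:20, function(s) {
    sc <- generate_scene(atlas, upscale = 2,
                         cells_per_mm3 = stats::setNames(d, rid),
                         cell_radius_um = c(14, 3), seed = 100 + s)
    sum(sc$cells$region_id == rid)
  }, numeric(1))
  lambda <- d * V
  # mean of 20 seeds within 4 sd of the Poisson mean
  expect_lt(abs(mean(counts) - lambda), 4 * sqrt(lambda))
})

test_that("patch sampling respects sizes and placements", {
  scene <- tiny_scene()
  p <- sample_patches(scene, 5, c(32, 32, 32), seed = 1)
  expect_length(p, 5)
  for (pp in p) {
    expect_equal(dim(pp$raw), c(32, 32, 32))
    expect_equal(dim(pp$label), c(32, 32, 32))
    expect_equal(sum(pp$label), pp$fg_vox)
  }
  # a patch the size of the scene has only one placement
  d <- dim(scene$stack$voxels)
  p1 <- sample_patches(scene, 1, d, seed = 2)
  expect_identical(p1[[1]]$raw, scene$stack$voxels)
  expect_error(sample_patches(scene, 1, d + 1), "exceeds")
})

test_that("48 sampled patches split 39/9 with both strata represented", {
  scene <- tiny_scene()
  for (s in 1:10) {
    patches <- sample_patches(scene, 48, c(24, 24, 24),
                              stratify_by_signal = TRUE, seed = s)
    expect_length(patches, 48)
    expect_setequal(unique(vapply(patches, `[[`, "", "stratum")),
                    c("high", "low"))
    sp <- split_patches(patches, 9, seed = s)
    expect_length(sp$train, 39)
    expect_length(sp$test, 9)
    fg_train <- mean(vapply(sp$train, function(p) p$fg_vox, numeric(1)))
    fg_test <- mean(vapply(sp$test, function(p) p$fg_vox, numeric(1)))
    # stratified allocation keeps the signal balance comparable
    expect_lt(abs(fg_test - fg_train), 0.5 * fg_train)
  }
})

test_that("scenes round-trip through open file formats", {
  scene <- tiny_scene()
  dir <- withr::local_tempdir()
  write_scene(scene, dir)
  st <- read_stack(file.path(dir, "raw.tif"), scene$stack$spacing_um)
  expect_equal(st$voxels, scene$stack$voxels, ignore_attr = TRUE)
  ont <- read_ontology_json(file.path(dir, "ontology.json"))
  expect_equal(ont$nodes$id, scene$atlas$ontology$nodes$id)
  expect_equal(ont$nodes$level, scene$atlas$ontology$nodes$level)
  tx <- import_point_transform(file.path(dir, "transform.json"))
  expect_equal(tx$matrix, scene$atlas_transform$matrix)
})
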