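# Affine transforms, registration, cell-to-atlas mapping, tables and
# level aggregation.

test_that("transform files round-trip and invalid ones are rejected", {
  tx <- affine_transform(cbind(diag(3) * 2, c(10, -5, 0)),
                         c(5, 5, 5), 50)
  f <- withr::local_tempfile(fileext = ".json")
  write_transform_json(tx, f)
  tx2 <- import_point_transform(f)
  expect_equal(tx2$matrix, tx$matrix)
  expect_equal(tx2$source_spacing_um, tx$source_spacing_um)

  idf <- withr::local_tempfile(fileext = ".json")
  write_transform_json(identity_transform(c(1, 1, 1), 1), idf)
  idt <- import_point_transform(idf)
  expect_equal(idt$matrix, cbind(diag(3), 0))

  expect_error(affine_transform(cbind(matrix(0, 3, 3), 1), c(1, 1, 1), 1),
               "singular")
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("not json {", bad)
  expect_error(import_point_transform(bad), "malformed")
})

test_that("applying and inverting transforms is consistent", {
  tx <- affine_transform(cbind(matrix(c(1.1, 0, 0, 0.1, 0.9, 0, 0, 0, 1),
                                      3, 3, byrow = TRUE), c(5, -3, 2)),
                         c(1, 1, 1), 1)
  pts <- matrix(runif(30, -50, 50), ncol = 3)
  fwd <- apply_transform(tx, pts)
  back <- apply_transform(invert_transform(tx), fwd)
  expect_equal(back, pts, tolerance = 1e-9)
})

test_that("cells map to their atlas regions through the identity", {
  atlas <- tiny_atlas()
  # one cell centered inside a known voxel of a known region
  vox <- which(atlas$labels == ontology_leaves(atlas$ontology)[1],
               arr.ind = FALSE)[1]
  d <- dim(atlas$labels)
  z <- (vox - 1) %% d[1] + 1
  y <- ((vox - 1) %/% d[1]) %% d[2] + 1
  x <- (vox - 1) %/% (d[1] * d[2]) + 1
  cells <- data.frame(label = 1L, z = z - 0.5, y = y - 0.5, x = x - 0.5,
                      volume_vox = 10L)
  tx <- identity_transform(rep(atlas$spacing_um, 3), atlas$spacing_um)
  mp <- map_cells(cells, tx, atlas)
  expect_equal(mp$region_id, atlas$labels[z, y, x])
  expect_equal(mp$region_acronym,
               atlas$ontology$nodes$acronym[
                 match(mp$region_id, atlas$ontology$nodes$id)])

  # out-of-bounds cells are flagged with region 0, never dropped
  far <- data.frame(label = 1:2, z = c(-50, 5), y = c(5, 5), x = c(5, 5),
                    volume_vox = c(5L, 5L))
  mpf <- map_cells(far, tx, atlas)
  expect_equal(nrow(mpf), 2)                   # injective on cell identity
  expect_equal(mpf$region_id[1], 0L)
  expect_true(is.na(mpf$atlas_z[1]))
  expect_equal(mpf$region_acronym[1], "unassigned")
})

test_that("the two canonical tables conserve counts and densities", {
  atlas <- tiny_atlas()
  tx <- identity_transform(rep(atlas$spacing_um, 3), atlas$spacing_um)
  empty <- map_cells(data.frame(label = integer(0), z = numeric(0),
                                y = numeric(0), x = numeric(0),
                                volume_vox = integer(0)), tx, atlas)
  tabs0 <- make_tables(empty, atlas)
  expect_equal(nrow(tabs0$cells), 0)
  expect_true(all(tabs0$regions$n_cells == 0))
  expect_setequal(setdiff(tabs0$regions$region_id, 0),
                  ontology_leaves(atlas$ontology))

  scene <- tiny_scene()
  mp <- map_cells(scene$cells, scene$atlas_transform, atlas)
  tabs <- make_tables(mp, atlas, sample_id = "s1")
  expect_equal(sum(tabs$regions$n_cells), nrow(scene$cells))
  nz <- tabs$regions[tabs$regions$region_id != 0 &
                       tabs$regions$n_cells > 0, ]
  expect_equal(nz$density_cells_per_mm3,
               nz$n_cells / nz$region_volume_mm3)
})

test_that("level aggregation conserves totals and follows ancestors", {
  atlas <- generate_toy_atlas(c(16, 16, 16), levels = 4,
                              regions_per_split = 2, seed = 3)
  ont <- atlas$ontology
  scene <- generate_scene(atlas, upscale = 2, cells_per_mm3 = 600,
                          cell_radius_um = c(20, 4), seed = 5)
  mp <- map_cells(scene$cells, scene$atlas_transform, atlas)
  tabs <- make_tables(mp, atlas)
  total <- sum(tabs$regions$n_cells)
  for (lv in 1:4) {
    agg <- aggregate_to_level(tabs$regions, ont, lv)
    expect_equal(sum(agg$n_cells), total)      # conservation at every level
    expect_equal(sum(agg$region_volume_mm3, na.rm = TRUE),
                 sum(tabs$regions$region_volume_mm3, na.rm = TRUE),
                 tolerance = 1e-9)
    # agreement with an independent ancestor walk
    leaf <- tabs$regions[tabs$regions$region_id != 0, ]
    expected <- tapply(leaf$n_cells,
                       vapply(leaf$region_id, ancestor_oracle, 0,
                              ont = ont, level = lv), sum)
    got <- setNames(agg$n_cells, agg$region_id)
    for (id in names(expected))
      expect_equal(unname(got[id]), unname(expected[id]))
  }
  expect_error(aggregate_to_level(tabs$regions, ont, 12), "level")
  # aggregating at the leaf level keeps every leaf row
  aggL <- aggregate_to_level(tabs$regions, ont, 4)
  leafL <- tabs$regions[tabs$regions$region_id != 0, ]
  expect_setequal(aggL$region_id[aggL$region_id != 0], leafL$region_id)
})

test_that("self-registration is close to the identity", {
  atlas <- tiny_atlas()
  tpl <- atlas_template(atlas)
  tx <- register_affine(tpl, tpl, seed = 1)
  expect_lt(max(abs(tx$matrix[, 4])), atlas$spacing_um)  # < 1 voxel shift
  expect_lt(max(abs(tx$matrix[, 1:3] - diag(3))), 0.01)
})

test_that("registration recovers a known shift and scale", {
  atlas <- tiny_atlas()
  tpl <- atlas_template(atlas)
  d <- dim(tpl$voxels)
  # moving = template shifted by +2 voxels along z
  shifted <- array(0, dim = d)
  shifted[3:d[1], , ] <- tpl$voxels[1:(d[1] - 2), , ]
  mv <- image_stack(shifted, tpl$spacing_um)
  tx <- register_affine(mv, tpl, seed = 2)
  ctr <- (d / 2) * tpl$spacing_um
  mapped <- apply_transform(tx, matrix(ctr, 1))
  expected <- ctr - c(2, 0, 0) * tpl$spacing_um
  expect_lt(max(abs(mapped - expected)), tpl$spacing_um[1])  # within 1 voxel

  expect_error(register_affine(image_stack(array(1, dim = c(8, 8, 8)),
                                           c(1, 1, 1)), tpl),
               "non-constant")
})
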