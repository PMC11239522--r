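# ---- end-to-end pipeline orchestration ------------------------------------
#
# One config, one call, all stages: downsample -> ventricle mask (optional)
# -> sliding-window inference -> binarize -> connected components -> size
# filter -> register (or import a transform) -> map to atlas -> tables ->
# visualization. Every stage writes standard files (TIFF/CSV/JSON) into the
# output directory and is skipped on re-run when its outputs already exist,
# so partial results are reusable by the owning modules.

#' Pipeline configuration
#'
#' @param raw path to the raw 16-bit multi-page TIFF stack.
#' @param spacing_um stack voxel spacing (z, y, x) in micrometres.
#' @param model path to a model checkpoint from [save_checkpoint()].
#' @param atlas_labels path to the atlas label TIFF (32-bit, from
#'   [write_label_tiff()]).
#' @param ontology path to the ontology JSON.
#' @param atlas_spacing_um isotropic atlas voxel size.
#' @param out_dir output directory.
#' @param classifier optional path to a saved ventricle classifier (.rds);
#'   required when `mask_ventricles` is TRUE.
#' @param transform optional path to a transform JSON; when NULL the
#'   pipeline registers the downsampled stack to the atlas template.
#' @param mask_ventricles toggle the ventricle masking stage.
#' @param target_um working resolution for downsampling/masking.
#' @param window,overlap,threshold sliding-window inference knobs.
#' @param connectivity,min_size,max_size instance extraction knobs.
#' @param sigma_vox density-map smoothing sigma (atlas voxels).
#' @param upsample_threshold binarization threshold for the upsampled
#'   ventricle mask.
#' @param mask_dilate_vox safety dilation (working-resolution voxels) of
#'   the ventricle mask before upsampling; see [upsample_mask()].
#' @param seed integer seed for all stochastic stages.
#' @param sample_id identifier used in the output tables.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(raw, spacing_um, model, atlas_labels, ontology,
                            atlas_spacing_um, out_dir,
                            classifier = NULL, transform = NULL,
                            mask_ventricles = TRUE, target_um = 25,
                            window = c(64, 64, 64), overlap = 0.25,
                            threshold = 0.5, connectivity = 26,
                            min_size = 4, max_size = 5000, sigma_vox = 2,
                            upsample_threshold = 0.5, mask_dilate_vox = 1,
                            seed = 1, sample_id = "sample") {
  cfg <- list(raw = raw, spacing_um = as.numeric(spacing_um), model = model,
              atlas_labels = atlas_labels, ontology = ontology,
              atlas_spacing_um = atlas_spacing_um, out_dir = out_dir,
              classifier = classifier, transform = transform,
              mask_ventricles = isTRUE(mask_ventricles),
              target_um = target_um,
              window = as.integer(rep(window, length.out = 3)),
              overlap = overlap, threshold = threshold,
              connectivity = as.integer(connectivity),
              min_size = min_size, max_size = max_size,
              sigma_vox = sigma_vox,
              upsample_threshold = upsample_threshold,
              mask_dilate_vox = as.integer(mask_dilate_vox),
              seed = as.integer(seed), sample_id = sample_id,
              config_version = 1L)
  if (cfg$mask_ventricles && is.null(cfg$classifier))
    stop("mask_ventricles = TRUE requires a classifier path")
  structure(cfg, class = "pipeline_config")
}

#' Write a pipeline config as JSON
#' @param config a [pipeline_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a pipeline config from JSON
#' @param path JSON written by [write_pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$config_version <- NULL
  # max_size may serialize as string when infinite
  if (is.character(raw$max_size)) raw$max_size <- as.numeric(raw$max_size)
  do.call(pipeline_config, raw)
}

#' Run the full inference pipeline
#'
#' Executes every enabled stage, writing intermediates and a JSON run
#' report (stage status, timings, counts, seed) into the output directory.
#' Completed stages are skipped on re-run unless `force = TRUE`, and two
#' runs with the same config and seed produce identical tables.
#'
#' @param config a [pipeline_config()].
#' @param force recompute even when stage outputs exist.
#' @return the run report (list), invisibly; the tables and images live in
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  report <- list(package_version = as.character(utils::packageVersion("cellmapr")),
                 seed = config$seed, sample_id = config$sample_id,
                 stages = list())
  t_all <- proc.time()[3]
  path <- function(f) file.path(out, f)
  done <- function(...) all(file.exists(vapply(list(...), path, "")))
  stage <- function(name, outputs, fun) {
    t0 <- proc.time()[3]
    if (!force && do.call(done, as.list(outputs))) {
      report$stages[[name]] <<- list(status = "skipped (outputs exist)")
      return(invisible(NULL))
    }
    res <- fun()
    report$stages[[name]] <<- c(list(status = "done",
                                     seconds = round(proc.time()[3] - t0, 2)),
                                res)
    invisible(NULL)
  }
  fail <- function(name, e) {
    stop(sprintf("pipeline stage '%s' failed on input %s: %s", name,
                 config$raw, conditionMessage(e)), call. = FALSE)
  }

  atlas <- atlas_volume(read_label_tiff(config$atlas_labels),
                        config$atlas_spacing_um,
                        read_ontology_json(config$ontology))
  stack <- read_stack(config$raw, config$spacing_um)

  # 1. downsample for registration / masking
  stage("downsample", "downsampled.tif", function() {
    tryCatch({
      ds <- downsample_iso(stack, config$target_um)
      write_stack(ds, path("downsampled.tif"))
      list(dims = dim(ds$voxels))
    }, error = function(e) fail("downsample", e))
  })
  ds <- read_stack(path("downsampled.tif"), rep(config$target_um, 3))

  # 2. ventricle masking (optional)
  if (config$mask_ventricles) {
    stage("ventricle_mask", c("ventricle_mask.tif", "masked.tif"), function() {
      tryCatch({
        clf <- readRDS(config$classifier)
        m_ds <- predict_mask(clf, ds)
        m_full <- upsample_mask(m_ds, dim(stack$voxels),
                                threshold = config$upsample_threshold,
                                spacing_um = stack$spacing_um,
                                dilate_vox = config$mask_dilate_vox)
        masked <- apply_mask(stack, m_full)
        write_mask(m_full, path("ventricle_mask.tif"))
        write_stack(masked, path("masked.tif"))
        list(ventricle_voxels = sum(m_full$mask))
      }, error = function(e) fail("ventricle_mask", e))
    })
    work <- read_stack(path("masked.tif"), config$spacing_um)
  } else {
    work <- stack
  }

  # 3. deep-learning inference + binarization
  stage("inference", "segmentation.tif", function() {
    tryCatch({
      model <- load_checkpoint(config$model)
      prob <- sliding_window_infer(model, work, window = config$window,
                                   overlap = config$overlap)
      seg <- binarize(prob, config$threshold)
      write_mask(seg, path("segmentation.tif"))
      list(foreground_voxels = sum(seg$mask))
    }, error = function(e) fail("inference", e))
  })
  seg <- read_mask(path("segmentation.tif"), config$spacing_um)

  # 4. connected components + size filter
  stage("instances", "cells.csv", function() {
    tryCatch({
      cc <- connected_components(seg, config$connectivity)
      n_raw <- nrow(cc$instances)
      cc <- filter_by_size(cc, config$min_size, config$max_size)
      write_instances_csv(cc, path("cells.csv"))
      write_label_tiff(cc$labels, path("cell_labels.tif"))
      list(components = n_raw, cells_after_size_filter = nrow(cc$instances))
    }, error = function(e) fail("instances", e))
  })
  cells <- read_instances_csv(path("cells.csv"))

  # 5. atlas transform: import or register
  stage("transform", "transform.json", function() {
    tryCatch({
      if (!is.null(config$transform)) {
        tx <- import_point_transform(config$transform)
        write_transform_json(tx, path("transform.json"))
        list(source = "imported")
      } else {
        tx <- register_affine(ds, atlas_template(atlas),
                              seed = derive_seed(config$seed, "register"))
        write_transform_json(tx, path("transform.json"))
        list(source = "registered")
      }
    }, error = function(e) fail("transform", e))
  })
  tx <- import_point_transform(path("transform.json"))

  # 6. map cells and emit the two tables
  stage("map", c("cells_mapped.csv", "regions.csv"), function() {
    tryCatch({
      mapped <- map_cells(cells, tx, atlas,
                          stack_spacing_um = config$spacing_um)
      tabs <- make_tables(mapped, atlas, sample_id = config$sample_id)
      utils::write.csv(tabs$cells, path("cells_mapped.csv"),
                       row.names = FALSE)
      utils::write.csv(tabs$regions, path("regions.csv"), row.names = FALSE)
      list(cells_mapped = nrow(mapped),
           unassigned = sum(mapped$region_id == 0))
    }, error = function(e) fail("map", e))
  })

  # 7. visualization in both spaces
  stage("visualize", c("colorized.tif", "density.tif", "projection.png"),
        function() {
    tryCatch({
      mapped <- utils::read.csv(path("cells_mapped.csv"))
      labs <- structure(list(labels = read_label_tiff(path("cell_labels.tif")),
                             instances = cells),
                        class = "labeled_volume")
      col <- colorize_cells(labs, mapped, atlas$ontology)
      write_colorized(col, path("colorized.tif"), path("region_lut.csv"))
      dm <- density_map(list(mapped), atlas, sigma_vox = config$sigma_vox)
      write_label_tiff(array(dm, dim = dim(dm)), path("density.tif"))
      projection_figure(dm, axis = 1, path("projection.png"))
      list(painted_voxels = sum(col$ids != 0))
    }, error = function(e) fail("visualize", e))
  })

  report$total_seconds <- round(proc.time()[3] - t_all, 2)
  counts <- utils::read.csv(path("regions.csv"))
  report$total_cells <- sum(counts$n_cells)
  report$tables_md5 <- unname(tools::md5sum(path("regions.csv")))
  jsonlite::write_json(report, path("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}

#' Train (or fine-tune) a segmentation model from patch files
#'
#' Reads paired raw/label patch TIFFs, optionally splits off a held-out
#' test set stratified by signal, trains from scratch or from a starting
#' checkpoint, and writes the final checkpoint, the loss log and a
#' held-out evaluation report.
#'
#' @param patch_dir directory with `raw/` and `label/` subdirectories
#'   holding identically named multi-page TIFFs.
#' @param out_dir output directory.
#' @param config a [unet_config()].
#' @param start_checkpoint optional checkpoint path to fine-tune from.
#' @param n_test number of patches held out for evaluation (stratified by
#'   foreground count).
#' @param threshold binarization threshold for evaluation.
#' @return list with the trained model, its evaluation scores (or NULL)
#'   and the output paths.
#' @export
run_training <- function(patch_dir, out_dir, config,
                         start_checkpoint = NULL, n_test = 0,
                         threshold = 0.5) {
  raw_files <- sort(list.files(file.path(patch_dir, "raw"),
                               pattern = "\\.tif{1,2}$", full.names = TRUE))
  lab_files <- sort(list.files(file.path(patch_dir, "label"),
                               pattern = "\\.tif{1,2}$", full.names = TRUE))
  if (length(raw_files) == 0) stop("no raw patches found in ", patch_dir)
  if (!identical(basename(raw_files), basename(lab_files)))
    stop("unpaired patches: raw and label file names differ (",
         paste(symdiff_names(basename(raw_files), basename(lab_files)),
               collapse = ", "), ")")
  patches <- lapply(seq_along(raw_files), function(i) {
    raw <- read_stack(raw_files[i], c(1, 1, 1))$voxels
    lab <- read_mask(lab_files[i])$mask
    if (!all(dim(raw) == dim(lab)))
      stop("malformed patch pair: ", basename(raw_files[i]),
           " raw and label dims differ")
    list(raw = raw, label = lab, fg_vox = sum(lab))
  })
  if (n_test > 0) {
    sp <- split_patches(patches, n_test, seed = config$seed)
    train <- sp$train; test <- sp$test
  } else {
    train <- patches; test <- list()
  }
  model <- if (!is.null(start_checkpoint)) {
    ck <- load_checkpoint(start_checkpoint)
    if (ck$config$depth != config$depth ||
        ck$config$base_features != config$base_features)
      stop("starting checkpoint architecture is incompatible with config")
    ck
  } else build_unet(config)
  model <- train_unet(model, train, config = config)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  save_checkpoint(model, file.path(out_dir, "checkpoint.rds"))
  utils::write.csv(data.frame(epoch = seq_along(model$training_log),
                              loss = model$training_log),
                   file.path(out_dir, "loss_log.csv"), row.names = FALSE)
  scores <- NULL
  if (length(test) > 0) {
    preds <- lapply(test, function(p) {
      pr <- unet_predict(model, normalize_intensity(
        array(as.numeric(p$raw), dim = dim(p$raw))))
      array(as.integer(pr >= threshold), dim = dim(pr))
    })
    refs <- lapply(test, function(p) p$label)
    scores <- evaluate_patches(preds, refs)
    jsonlite::write_json(list(
      volumetric = scores$volumetric, instance = scores$instance,
      f1 = scores$f1, n_test_patches = length(test)
    ), file.path(out_dir, "evaluation.json"), auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
  }
  list(model = model, scores = scores, out_dir = out_dir)
}

symdiff_names <- function(a, b) union(setdiff(a, b), setdiff(b, a))
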