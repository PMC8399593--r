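# End-to-end orchestration: simulate -> preprocess -> split -> train ->
# segment -> evaluate, all deterministic functions of (config, master seed).
# Stage seeds are derived from the master seed by fixed offsets so any single
# stage can be reproduced in isolation.

stage_offsets <- c(simulate = 1000L, split = 2000L, init = 3000L, train = 4000L)

#' Full pipeline run configuration
#'
#' Bundles every stage's parameters with a single master seed and an output
#' root. Each stage derives its own seed as `master_seed + fixed offset`
#' (simulate +1000, split +2000, weight init +3000, training +4000).
#' Serializable to and from YAML with a stable round-trip.
#'
#' @param phantom a [phantom_config()] describing the synthetic images (its
#'   `seed` is overridden by the derived simulate seed).
#' @param n_images number of phantoms to simulate.
#' @param patch_height,patch_width network patch size (divisible by 8, exact
#'   tiling of the phantom).
#' @param clip_limit,tile_rows,tile_cols CLAHE parameters.
#' @param fractions train/validation/test fractions.
#' @param training a [training_config()] (its `seed` is overridden by the
#'   derived training seed).
#' @param tile_height,tile_width evaluation tile size for patch
#'   classification.
#' @param master_seed master seed for the whole run.
#' @param out_root output directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_config(), n_images = 6L,
                       patch_height = 80L, patch_width = 296L,
                       clip_limit = 0.01, tile_rows = 8L, tile_cols = 8L,
                       fractions = c(0.5, 0.25, 0.25),
                       training = training_config(class_weights = c(1, 25)),
                       tile_height = 40L, tile_width = 148L,
                       master_seed = 1L, out_root = tempfile("neovaseg_run_")) {
  assert_that(patch_height %% 8 == 0 && patch_width %% 8 == 0,
              "patch dimensions must be divisible by 8")
  assert_that(phantom$image_height %% patch_height == 0 &&
                phantom$image_width %% patch_width == 0,
              "patches must tile the phantom exactly")
  assert_that(patch_height %% tile_height == 0 && patch_width %% tile_width == 0,
              "evaluation tiles must tile the patch exactly")
  structure(list(phantom = phantom, n_images = as.integer(n_images),
                 patch_height = as.integer(patch_height),
                 patch_width = as.integer(patch_width),
                 clip_limit = clip_limit, tile_rows = as.integer(tile_rows),
                 tile_cols = as.integer(tile_cols), fractions = fractions,
                 training = training, tile_height = as.integer(tile_height),
                 tile_width = as.integer(tile_width),
                 master_seed = as.integer(master_seed), out_root = out_root),
            class = "run_config")
}

#' Serialize / restore a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `write_run_config()`: `path`, invisibly; `read_run_config()`: the
#'   restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  v <- unclass(config)
  v$phantom <- unclass(v$phantom)
  v$training <- unclass(v$training)
  yaml::write_yaml(v, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  v <- yaml::read_yaml(path)
  run_config(phantom = do.call(phantom_config, v$phantom),
             n_images = v$n_images, patch_height = v$patch_height,
             patch_width = v$patch_width, clip_limit = v$clip_limit,
             tile_rows = v$tile_rows, tile_cols = v$tile_cols,
             fractions = unlist(v$fractions),
             training = do.call(training_config, v$training[
               setdiff(names(v$training), character(0))]),
             tile_height = v$tile_height, tile_width = v$tile_width,
             master_seed = v$master_seed, out_root = v$out_root)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full segmentation pipeline
#'
#' Executes simulate -> preprocess -> split -> train -> segment -> evaluate
#' under the config's master seed, writing all intermediate artifacts
#' (phantom PNGs + manifest, training history CSV, model checkpoint, report
#' CSV) under `config$out_root`. Idempotent under a fixed seed: two runs with
#' the same config produce identical report files.
#'
#' @param config a [run_config()].
#' @param verbose print structured per-stage log lines.
#' @return The [evaluate_masks()] report for the test set, with attribute
#'   `out_dir` pointing at the artifact directory.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  log_line <- function(stage, key, value) {
    if (verbose) message(sprintf("stage=%s %s=%s", stage, key, value))
  }
  out <- config$out_root
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)

  ph_cfg <- config$phantom
  ph_cfg$seed <- config$master_seed + stage_offsets[["simulate"]]
  run_stage("simulate", {
    emit_dataset(ph_cfg, config$n_images, file.path(out, "phantoms"))
    log_line("simulate", "n_images", config$n_images)
  })

  grid <- patch_grid(config$patch_height, config$patch_width,
                     ph_cfg$image_height, ph_cfg$image_width)
  patches <- list(); masks <- list()
  run_stage("preprocess", {
    for (i in seq_len(config$n_images)) {
      cfg_i <- ph_cfg
      cfg_i$seed <- ph_cfg$seed + (i - 1L) * 1000L
      ph <- render_phantom(cfg_i)
      patches <- c(patches, preprocess_image(ph$image, grid,
                                             clip_limit = config$clip_limit,
                                             tile_rows = config$tile_rows,
                                             tile_cols = config$tile_cols))
      masks <- c(masks, preprocess_mask(ph$mask, grid))
    }
    log_line("preprocess", "n_patches", length(patches))
  })

  split <- run_stage("split", {
    split_dataset(seq_along(patches), config$fractions,
                  seed = config$master_seed + stage_offsets[["split"]])
  })

  fit <- run_stage("train", {
    aug <- augment_flips(patches[split$train], masks[split$train])
    spec <- build_reference_spec(config$patch_height, config$patch_width)
    model <- init_network(spec, seed = config$master_seed + stage_offsets[["init"]])
    tc <- config$training
    tc$seed <- config$master_seed + stage_offsets[["train"]]
    r <- train_network(model, list(train_x = aug$patches, train_y = aug$masks,
                                   val_x = patches[split$validation],
                                   val_y = masks[split$validation]),
                       tc, verbose = verbose)
    write_history_csv(r$history, file.path(out, "history.csv"))
    save_checkpoint(r$model, file.path(out, "model.rds"))
    log_line("train", "stop_reason", attr(r$history, "stop_reason"))
    r
  })

  report <- run_stage("evaluate", {
    preds <- lapply(patches[split$test], function(p) segment(fit$model, p))
    rep <- evaluate_masks(preds, masks[split$test],
                          config$tile_height, config$tile_width)
    write_report_csv(rep, file.path(out, "report.csv"))
    log_line("evaluate", "n_test", length(preds))
    rep
  })
  attr(report, "out_dir") <- out
  report
}

#' Build the packaged toy fixture set
#'
#' A deterministic six-phantom dataset with perturbed predictions and
#' independently tallied confusion counts, used by the evaluation regression
#' tests. Predictions are the ground truth shifted down-right by one pixel,
#' which yields non-trivial TP/FP/FN counts; the expected counts are computed
#' here by explicit per-pixel enumeration, independently of [confusion()].
#'
#' @param n_images number of phantoms (default 6).
#' @param seed master seed (default 99).
#' @return list with `images`, `masks`, `predictions` and `expected`, the
#'   latter a list of per-image `c(tp, tn, fp, fn)` vectors.
#' @export
make_fixtures <- function(n_images = 6L, seed = 99L) {
  cfg <- phantom_config(image_height = 96L, image_width = 96L, n_lesions = 1L,
                        vessel_branching_depth = 3L,
                        lesion_radius_range = c(8, 12),
                        lesion_vessel_count = 6L, noise_sd = 0, seed = seed)
  images <- list(); masks <- list(); preds <- list(); expected <- list()
  for (i in seq_len(n_images)) {
    cfg$seed <- seed + (i - 1L) * 1000L
    ph <- render_phantom(cfg)
    pred <- matrix(0L, nrow(ph$mask), ncol(ph$mask))
    pred[2:nrow(pred), 2:ncol(pred)] <- ph$mask[1:(nrow(pred) - 1), 1:(ncol(pred) - 1)]
    tp <- tn <- fp <- fn <- 0L
    for (r in seq_len(nrow(pred))) {
      for (c in seq_len(ncol(pred))) {
        if (pred[r, c] == 1 && ph$mask[r, c] == 1) tp <- tp + 1L
        else if (pred[r, c] == 0 && ph$mask[r, c] == 0) tn <- tn + 1L
        else if (pred[r, c] == 1) fp <- fp + 1L
        else fn <- fn + 1L
      }
    }
    images[[i]] <- ph$image; masks[[i]] <- ph$mask; preds[[i]] <- pred
    expected[[i]] <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  }
  list(images = images, masks = masks, predictions = preds, expected = expected)
}
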