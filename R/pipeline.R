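#' Experiment orchestration: simulate, tile, train, predict, evaluate
#'
#' [run_experiment()] drives the full pipeline from cohort manifests to
#' per-slide metrics: it pools labeled training patches from the training
#' cohort, augments the positive class, fits frozen YUV normalization
#' statistics, trains each candidate architecture, selects the one with
#' the highest mean per-slide validation tile AUC (ties broken by fewest
#' layers), then predicts a probability map for every test slide and
#' scores it pixel by pixel against ground truth. All randomness funnels
#' through one run seed, so a config + seed pair reproduces its outputs
#' byte for byte on one machine.
#'
#' @name pipeline
NULL

#' Build an experiment configuration
#'
#' @param train_manifest,val_manifest,test_manifest cohort manifests: data
#'   frames (or CSV paths) with columns `slide_id`, `slide_path`,
#'   `mask_path` as written by [generate_cohort()].
#' @param arch_names candidate architectures to train and select among.
#' @param tile_side_um physical tile side (default 200 um).
#' @param min_tissue_frac minimum tissue fraction per kept tile.
#' @param overlap_threshold positive-label overlap rule (default 0.8).
#' @param negative_overlap_max training negatives must come from
#'   non-invasive regions: tiles with ground-truth overlap above this value
#'   but below `overlap_threshold` are excluded from training and
#'   validation pools (default 0). Pixel-wise evaluation is unaffected.
#' @param input_side_px network input side (default 50 px).
#' @param train a [train_config()]; its seed is re-derived from `seed`.
#' @param threshold operating threshold for the binary prediction.
#' @param tissue_only evaluate metrics over tissue pixels only.
#' @param max_patches_per_class cap on training patches per class after
#'   augmentation (balanced seeded subsample); `Inf` disables the cap.
#' @param pooled_val_auc pool validation tiles across slides instead of
#'   averaging per-slide AUCs.
#' @param augmentation_factor orientations per positive training patch.
#' @param out_dir output directory for heatmaps, masks and CSVs; `NULL`
#'   keeps everything in memory.
#' @param seed global run seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(train_manifest, val_manifest, test_manifest,
                              arch_names = "three_layer",
                              tile_side_um = 200, min_tissue_frac = 0.5,
                              overlap_threshold = 0.8,
                              negative_overlap_max = 0,
                              input_side_px = 50L,
                              train = train_config(),
                              threshold = 0.5, tissue_only = FALSE,
                              max_patches_per_class = 256L,
                              pooled_val_auc = FALSE,
                              augmentation_factor = train$augmentation_factor,
                              out_dir = NULL, seed = 1L) {
  structure(list(train_manifest = train_manifest, val_manifest = val_manifest,
                 test_manifest = test_manifest, arch_names = arch_names,
                 tile_side_um = tile_side_um, min_tissue_frac = min_tissue_frac,
                 overlap_threshold = overlap_threshold,
                 negative_overlap_max = negative_overlap_max,
                 input_side_px = as.integer(input_side_px), train = train,
                 threshold = threshold, tissue_only = isTRUE(tissue_only),
                 max_patches_per_class = max_patches_per_class,
                 pooled_val_auc = isTRUE(pooled_val_auc),
                 augmentation_factor = as.integer(augmentation_factor),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' Any field of [experiment_config()] may appear in the file; `train:` is a
#' nested block passed to [train_config()].
#'
#' @param path YAML file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  tr <- do.call(train_config, y$train %||% list())
  y$train <- tr
  do.call(experiment_config, y)
}

# Structured run log: per-stage messages with elapsed time, silenced via
# options(wsidetect.verbose = FALSE) (tests) or suppressMessages().
run_log <- function(fmt, ...) {
  if (isFALSE(getOption("wsidetect.verbose", TRUE))) return(invisible())
  message(sprintf("[wsidetect %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

load_manifest <- function(m, what) {
  if (is.character(m) && length(m) == 1L) {
    if (!file.exists(m))
      stop_wsi(what, " manifest not found: ", m, class = "configuration_error")
    m <- read.csv(m, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(m) || nrow(m) == 0L)
    stop_wsi(what, " manifest is empty", class = "configuration_error")
  stopifnot(all(c("slide_id", "slide_path", "mask_path") %in% names(m)))
  m
}

# Tile one slide and return its labeled tile set plus what prediction needs.
tile_slide <- function(slide_path, mask_path, cfg) {
  slide <- read_slide(slide_path)
  gt <- read_mask(mask_path, expected_dims = dim(slide), mpp = slide$mpp,
                  slide_id = slide$slide_id)
  tissue <- segment_tissue(slide)
  tiles <- compute_tile_grid(slide, tile_side_um = cfg$tile_side_um,
                             tissue = tissue,
                             min_tissue_frac = cfg$min_tissue_frac)
  tiles <- label_tiles(tiles, gt, overlap_threshold = cfg$overlap_threshold,
                       negative_threshold = cfg$negative_overlap_max)
  list(slide = slide, gt = gt, tissue = tissue, tiles = tiles)
}

# Pool raw RGB training patches over a manifest.
collect_training_patches <- function(manifest, cfg) {
  xs <- list(); labels <- character()
  for (i in seq_len(nrow(manifest))) {
    ts <- tile_slide(manifest$slide_path[i], manifest$mask_path[i], cfg)
    labeled <- ts$tiles[ts$tiles$label != "unlabeled", ]
    if (nrow(labeled) == 0L) next
    ps <- extract_patches(ts$slide, labeled, out_side = cfg$input_side_px)
    xs[[length(xs) + 1L]] <- ps$x
    labels <- c(labels, ps$labels)
  }
  if (length(xs) == 0L)
    stop_wsi("no tissue tiles found in the training cohort",
             class = "configuration_error")
  structure(list(x = do.call(cbind, xs), labels = labels,
                 side = cfg$input_side_px, tiles = NULL),
            class = "patch_set")
}

# Balanced seeded subsample: at most k patches per class (k may be a
# named vector with per-class caps).
cap_patches <- function(patches, k, seed) {
  if (length(k) == 1L && !is.finite(k)) return(patches)
  caps <- if (length(k) == 1L) c(negative = k, positive = k) else k
  keep <- with_seed(seed, {
    unlist(lapply(c("negative", "positive"), function(cl) {
      idx <- which(patches$labels == cl)
      if (length(idx) > caps[[cl]]) sort(sample(idx, caps[[cl]])) else idx
    }))
  })
  patches$x <- patches$x[, keep, drop = FALSE]
  patches$labels <- patches$labels[keep]
  patches
}

validation_auc <- function(model, manifest, cfg) {
  aucs <- numeric(0); pooled_scores <- numeric(0); pooled_labels <- character(0)
  for (i in seq_len(nrow(manifest))) {
    ts <- tile_slide(manifest$slide_path[i], manifest$mask_path[i], cfg)
    labeled <- ts$tiles[ts$tiles$label != "unlabeled", ]
    if (nrow(labeled) == 0L) next
    ps <- extract_patches(ts$slide, labeled, out_side = cfg$input_side_px)
    ps <- normalize_patches(ps, model$norm_stats)
    p <- predict(model, ps)[, "p_positive"]
    aucs <- c(aucs, tile_auc(p, labeled$label))
    pooled_scores <- c(pooled_scores, p)
    pooled_labels <- c(pooled_labels, labeled$label)
  }
  if (cfg$pooled_val_auc) tile_auc(pooled_scores, pooled_labels)
  else mean(aucs, na.rm = TRUE)
}

predict_slide <- function(model, ts, cfg) {
  dims <- attr(ts$tiles, "slide_dims")
  if (nrow(ts$tiles) == 0L) {
    pm <- probability_map(matrix(0, dims[1], dims[2]), mpp = ts$slide$mpp,
                          slide_id = ts$slide$slide_id)
  } else {
    ps <- extract_patches(ts$slide, ts$tiles, out_side = cfg$input_side_px)
    ps <- normalize_patches(ps, model$norm_stats)
    p <- predict(model, ps)[, "p_positive"]
    pm <- stitch_probability_map(p, ts$tiles)
  }
  pm
}

n_layers <- function(arch_name)
  switch(arch_name, three_layer = 3L, four_layer = 4L, six_layer = 6L)

#' Evaluate a trained model on a cohort of slides
#'
#' Predicts a probability map for every slide of the manifest, thresholds
#' it, and scores it pixel by pixel against the cohort's ground-truth
#' masks. Used by [run_experiment()] for its test cohort; calling it
#' directly evaluates one trained model on additional cohorts (for
#' example a normal-control cohort) without retraining.
#'
#' @param model a fitted `convnet` carrying frozen `norm_stats`.
#' @param manifest cohort manifest (data frame or CSV path).
#' @param config the [experiment_config()] supplying tiling and threshold
#'   parameters.
#' @param cohort_id label for the summary.
#' @return List with `slide_metrics` (one row per slide) and `summary`
#'   (a [cohort_summary()]).
#' @export
evaluate_cohort <- function(model, manifest, config, cohort_id = "test") {
  cfg <- config
  manifest <- load_manifest(manifest, cohort_id)
  out_dir <- cfg$out_dir
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    ts <- tile_slide(manifest$slide_path[i], manifest$mask_path[i], cfg)
    pm <- predict_slide(model, ts, cfg)
    pred <- binarize_map(pm, threshold = cfg$threshold)
    met <- pixel_metrics(pred, ts$gt,
                         tissue = if (cfg$tissue_only) ts$tissue else NULL)
    if (!is.null(out_dir)) {
      write_heatmap(pm, file.path(out_dir, paste0(ts$slide$slide_id, "_heatmap.tif")))
      write_mask(pred, file.path(out_dir, paste0(ts$slide$slide_id, "_pred.png")))
    }
    rows[[i]] <- data.frame(slide_id = manifest$slide_id[i], t(met$metrics),
                            t(met$counts))
  }
  slide_metrics <- do.call(rbind, rows)
  list(slide_metrics = slide_metrics,
       summary = cohort_summary(slide_metrics, cohort_id = cohort_id))
}

#' Run a configured experiment end to end
#'
#' @param config an [experiment_config()] or a YAML path for
#'   [read_experiment_config()].
#' @return An `experiment_report`: the selected `model`, per-architecture
#'   validation AUCs (`val_auc`), per-slide `slide_metrics`, the cohort
#'   `summary`, the config and seed. When `config$out_dir` is set,
#'   heatmaps (16-bit TIFF), binary masks (PNG), `slide_metrics.csv`,
#'   `cohort_summary.csv` and `report.json` are written there.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  cfg <- config
  train_m <- load_manifest(cfg$train_manifest, "train")
  val_m <- load_manifest(cfg$val_manifest, "validation")
  test_m <- load_manifest(cfg$test_manifest, "test")

  # --- training pool: label, cap, augment positives, normalize ---
  # Source positives are subsampled so that after the augmentation factor
  # is applied the positive class meets the per-class cap; this keeps the
  # augmented pool within desk-scale memory.
  run_log("collecting training patches from %d slides", nrow(train_m))
  patches <- collect_training_patches(train_m, cfg)
  run_log("pooled %d patches (%d positive)", length(patches$labels),
          sum(patches$labels == "positive"))
  k <- cfg$max_patches_per_class
  if (is.finite(k))
    patches <- cap_patches(patches, c(negative = k,
                                      positive = max(1, round(k / cfg$augmentation_factor))),
                           seed = child_seed(cfg$seed, 1L))
  patches <- augment_positive_class(patches, factor = cfg$augmentation_factor)
  stats <- fit_normalization(patch_matrix_pixels(patch_matrix_to_yuv(patches$x)))
  patches <- normalize_patches(patches, stats)
  run_log("training pool: %d patches (%d positive) after augmentation x%d",
          length(patches$labels), sum(patches$labels == "positive"),
          cfg$augmentation_factor)

  # --- train candidates, select by mean validation tile AUC ---
  candidates <- list(); val_auc <- numeric(0)
  for (k in seq_along(cfg$arch_names)) {
    arch <- cfg$arch_names[k]
    tc <- cfg$train
    tc$seed <- as.integer(child_seed(cfg$seed, 10L + k))
    spec <- build_convnet(arch, input_side_px = cfg$input_side_px)
    run_log("training %s (%d epochs, batch %d)", arch, tc$epochs, tc$batch_size)
    model <- train_convnet(spec, patches, config = tc, norm_stats = stats)
    candidates[[arch]] <- model
    val_auc[arch] <- validation_auc(model, val_m, cfg)
    run_log("%s: final loss %.4f, validation tile AUC %.4f", arch,
            model$history$loss[tc$epochs], val_auc[arch])
  }
  best_auc <- max(val_auc)
  in_tie <- names(val_auc)[val_auc == best_auc]
  selected <- in_tie[which.min(vapply(in_tie, n_layers, integer(1)))]
  model <- candidates[[selected]]

  # --- test: predict, stitch, threshold, score ---
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run_log("selected %s; evaluating %d test slides", selected, nrow(test_m))
  ev <- evaluate_cohort(model, test_m, cfg, cohort_id = "test")
  slide_metrics <- ev$slide_metrics
  summ <- ev$summary
  run_log("done")

  report <- structure(list(model = model, selected_arch = selected,
                           val_auc = val_auc, slide_metrics = slide_metrics,
                           summary = summ, config = cfg, seed = cfg$seed,
                           threshold = cfg$threshold,
                           versions = list(
                             wsidetect = as.character(utils::packageVersion("wsidetect")),
                             R = paste(R.version$major, R.version$minor, sep = "."))),
                      class = "experiment_report")
  if (!is.null(out_dir)) {
    write.csv(slide_metrics, file.path(out_dir, "slide_metrics.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(summ), file.path(out_dir, "cohort_summary.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(selected_arch = selected, val_auc = as.list(val_auc),
           threshold = cfg$threshold, seed = cfg$seed,
           n_train = nrow(train_m), n_val = nrow(val_m), n_test = nrow(test_m),
           versions = report$versions),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> selected '%s' (validation AUC %s)\n",
              x$selected_arch,
              paste(sprintf("%s=%.4f", names(x$val_auc), x$val_auc),
                    collapse = ", ")))
  print(x$summary)
  invisible(x)
}

#' Compare two models' predictions on a shared test set
#'
#' Computes the Pearson correlation of each per-slide measure across the
#' slides both reports evaluated, plus a per-slide paired Dice table for
#' agreement scatter plots; slides whose Dice coefficients differ by more
#' than `disagreement_threshold` are flagged as disagreement cases.
#'
#' @param report_a,report_b `experiment_report`s evaluated on a shared
#'   test set.
#' @param disagreement_threshold flag slides with
#'   `|dice_a - dice_b| > disagreement_threshold` (default 0.2).
#' @param out optional path; when set, the per-slide paired table is
#'   written there as `agreement.csv`-style CSV.
#' @return A `model_agreement` list: `correlations` (named vector over the
#'   seven measures), `paired` (per-slide table with `dice_a`, `dice_b`,
#'   `flagged`), `n_shared`.
#' @export
compare_models <- function(report_a, report_b, disagreement_threshold = 0.2,
                           out = NULL) {
  a <- report_a$slide_metrics; b <- report_b$slide_metrics
  shared <- intersect(a$slide_id, b$slide_id)
  if (length(shared) == 0L)
    stop_wsi("the two reports share no test slides", class = "usage_error")
  a <- a[match(shared, a$slide_id), ]
  b <- b[match(shared, b$slide_id), ]
  correlations <- vapply(metric_names, function(m)
    metric_correlation(a[[m]], b[[m]]), numeric(1))
  diff <- abs(a$dice - b$dice)
  paired <- data.frame(slide_id = shared, dice_a = a$dice, dice_b = b$dice,
                       abs_diff = diff,
                       flagged = !is.na(diff) & diff > disagreement_threshold)
  if (!is.null(out)) write.csv(paired, out, row.names = FALSE)
  structure(list(correlations = correlations, paired = paired,
                 n_shared = length(shared),
                 disagreement_threshold = disagreement_threshold),
            class = "model_agreement")
}

#' @export
print.model_agreement <- function(x, ...) {
  cat(sprintf("<model_agreement> %d shared slides; flagged %d (|dice diff| > %g)\n",
              x$n_shared, sum(x$paired$flagged), x$disagreement_threshold))
  print(round(x$correlations, 4))
  invisible(x)
}
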