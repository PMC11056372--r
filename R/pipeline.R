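# End-to-end orchestration: preprocess -> segment -> features -> train ->
# predict -> evaluate, over a manifest (on disk) or an in-memory synthetic
# study, with per-stage logging and reproducible seeds.

#' Full run configuration
#'
#' A single nested configuration covering every stage. All defaults are those
#' of the individual stage constructors; the object can be serialized to and
#' parsed from a single JSON document ([run_config_from_json()]).
#'
#' @param preprocess a [preprocess_config()].
#' @param method segmentation method, `"as"` (adaptive snake) or `"rg"`
#'   (region growing).
#' @param snake a [snake_params()].
#' @param region a [region_grow_params()].
#' @param glcm_levels GLCM quantization levels.
#' @param classifier `"ann"` or `"svm"`.
#' @param train_fraction train split fraction.
#' @param seed integer seed used for splitting and training.
#' @return a `run_config` list.
#' @export
run_config <- function(preprocess = preprocess_config(), method = c("as", "rg"),
                       snake = snake_params(), region = region_grow_params(),
                       glcm_levels = 8L, classifier = c("ann", "svm"),
                       train_fraction = 0.8, seed = 1L) {
  method <- match.arg(method)
  classifier <- match.arg(classifier)
  structure(list(preprocess = preprocess, method = method, snake = snake,
                 region = region, glcm_levels = as.integer(glcm_levels),
                 classifier = classifier, train_fraction = train_fraction,
                 seed = as.integer(seed), schema = "dermoscan-run-config/1"),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' Unknown fields are rejected; missing fields take their defaults.
#'
#' @param path path to a JSON document whose top-level keys mirror the
#'   [run_config()] arguments (stage sub-configs as nested objects).
#' @return a `run_config`.
#' @export
run_config_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  build <- function(ctor, args) do.call(ctor, as.list(args))
  known <- c("preprocess", "method", "snake", "region", "glcm_levels",
             "classifier", "train_fraction", "seed", "schema")
  unknown <- setdiff(names(j), known)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  args <- list()
  if (!is.null(j$preprocess)) args$preprocess <- build(preprocess_config, j$preprocess)
  if (!is.null(j$snake)) args$snake <- build(snake_params, j$snake)
  if (!is.null(j$region)) args$region <- build(region_grow_params, j$region)
  for (f in c("method", "glcm_levels", "classifier", "train_fraction", "seed")) {
    if (!is.null(j[[f]])) args[[f]] <- j[[f]]
  }
  do.call(run_config, args)
}

segment_with <- function(gray, config, method = config$method) {
  if (method == "as") adaptive_snake(gray, config$snake)
  else region_growing(gray, config$region)
}

process_one <- function(image, config, truth_mask = NULL) {
  gray <- preprocess_pipeline(image, config$preprocess)
  mask <- segment_with(gray, config)
  score <- if (!is.null(truth_mask)) segmentation_accuracy(mask, truth_mask) else NULL
  fv <- extract_feature_vector(image, gray, mask, glcm_levels = config$glcm_levels)
  list(gray = gray, mask = mask, score = score, features = fv)
}

#' Run the full pipeline over a dataset manifest
#'
#' Executes preprocess, segmentation, feature extraction and (when labels for
#' two classes are present) the split/train/predict/evaluate chain. Per-image
#' failures are logged and skipped; the failure count is reported. When
#' `out_dir` is given, the feature table (CSV), predicted masks (PNG), the
#' metrics report (JSON) and a per-stage log are written there, and every
#' written file is listed in the returned report.
#'
#' @param manifest data frame (or CSV path) with columns `path`, optionally
#'   `mask_path` and `label`.
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return a `run_report` list: `features` (tibble), `segmentation` (tibble
#'   of per-image scores, when truth masks exist), `metrics` (tibble, when
#'   labels exist), `confusion`, `model`, `n_failed`, `timings`, `files`,
#'   `config`.
#' @export
run_pipeline <- function(manifest, config = run_config(), out_dir = NULL) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  stopifnot(inherits(config, "run_config"), "path" %in% names(manifest))
  n <- nrow(manifest)
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  }
  feats <- vector("list", n); scores <- vector("list", n)
  failed <- character(0)
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_len(n)) {
    res <- tryCatch({
      image <- read_image(manifest$path[i])
      truth <- if ("mask_path" %in% names(manifest) && nzchar(manifest$mask_path[i]) &&
                   !is.na(manifest$mask_path[i])) read_mask(manifest$mask_path[i]) else NULL
      r <- process_one(image, config, truth)
      if (!is.null(out_dir)) {
        mp <- file.path(out_dir, "masks", sprintf("mask_%03d.png", i))
        write_mask(r$mask, mp)
        files <- c(files, mp)
      }
      r
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, sprintf("%s: %s", manifest$path[i], conditionMessage(res)))
      next
    }
    id <- sprintf("sample_%03d", i)
    lbl <- if ("label" %in% names(manifest)) as.character(manifest$label[i]) else NA_character_
    feats[[i]] <- tibble::tibble(id = id, label = lbl, !!!as.list(res$features))
    if (!is.null(res$score)) scores[[i]] <- tibble::tibble(id = id, res$score)
  }
  seg_time <- proc.time()[["elapsed"]] - t0
  features <- dplyr::bind_rows(feats)
  segmentation <- dplyr::bind_rows(scores)

  metrics <- NULL; cm <- NULL; model <- NULL; preds <- NULL
  labels_ok <- nrow(features) > 0 && all(!is.na(features$label)) &&
    length(unique(features$label)) == 2 &&
    all(table(features$label) >= 2)  # stratified split needs 2 per class
  t1 <- proc.time()[["elapsed"]]
  if (labels_ok) {
    sp <- split_dataset(features, config$train_fraction, seed = config$seed)
    model <- if (config$classifier == "ann") train_ann(sp$train, seed = config$seed)
             else train_svm(sp$train, seed = config$seed)
    preds <- predict(model, sp$test)
    cm <- confusion_matrix(sp$test$label, preds, positive = "malignant")
    metrics <- compute_metrics(cm)
  }
  timings <- tibble::tibble(stage = c("image_processing", "classification"),
                            elapsed_s = c(seg_time, proc.time()[["elapsed"]] - t1))
  report <- structure(list(features = features, segmentation = segmentation,
                           metrics = metrics, confusion = cm, model = model,
                           predictions = preds, n_failed = length(failed),
                           failures = failed, timings = timings,
                           files = files, config = config),
                      class = "run_report")
  if (!is.null(out_dir)) {
    fp <- file.path(out_dir, "features.csv")
    utils::write.csv(features, fp, row.names = FALSE)
    files <- c(files, fp)
    if (!is.null(metrics)) {
      mp <- file.path(out_dir, "metrics.json")
      jsonlite::write_json(list(
        confusion = list(tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn),
        metrics = as.list(metrics), seed = config$seed
      ), mp, auto_unbox = TRUE, digits = NA, na = "null")
      files <- c(files, mp)
    }
    lp <- file.path(out_dir, "run.log")
    writeLines(c(sprintf("processed %d images, %d failed", n, length(failed)),
                 failed,
                 sprintf("%s: %.2fs", timings$stage, timings$elapsed_s),
                 sprintf("seed: %d", config$seed)), lp)
    files <- c(files, lp)
    report$files <- files
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<dermoscan run> %d samples (%d failed)\n",
              nrow(x$features) + x$n_failed, x$n_failed))
  if (nrow(x$segmentation) > 0) {
    cat(sprintf("  mean segmentation accuracy: %.4f\n", mean(x$segmentation$accuracy)))
  }
  if (!is.null(x$metrics)) {
    cat(sprintf("  %s held-out: accuracy %.3f, F1 %.3f, MCC %.3f\n",
                toupper(x$config$classifier), x$metrics$accuracy, x$metrics$f1,
                x$metrics$mcc))
  }
  invisible(x)
}

#' Run a seeded end-to-end synthetic study in memory
#'
#' Generates a labelled synthetic dataset, preprocesses every image, segments
#' it with both the adaptive snake and region growing (region growing seeded
#' at the truth-mask centroid, mirroring a clinician clicking the lesion),
#' scores both masks against the exact ground truth, extracts features from
#' the snake masks, and evaluates both classifiers on a stratified held-out
#' split.
#'
#' @param n_benign,n_malignant class sizes.
#' @param seed integer seed driving generation, splitting and training.
#' @param config a [run_config()].
#' @param n_segment_rg number of samples (from the start of the dataset) also
#'   segmented by region growing; `Inf` for all.
#' @return list with `segmentation` (per-sample tibble: `as_accuracy`,
#'   `rg_accuracy`, dice scores), `features`, `split`, and per-classifier
#'   `metrics` and confusion matrices.
#' @export
run_synthetic_study <- function(n_benign = 80L, n_malignant = 40L, seed = 1L,
                                config = run_config(), n_segment_rg = Inf) {
  samples <- generate_dataset(n_benign, n_malignant, seed = seed)
  n <- length(samples)
  seg <- vector("list", n); feats <- vector("list", n)
  for (i in seq_len(n)) {
    s <- samples[[i]]
    gray <- preprocess_pipeline(s$image, config$preprocess)
    as_mask <- adaptive_snake(gray, config$snake)
    as_score <- segmentation_accuracy(as_mask, s$truth_mask)
    rg_score <- NULL
    if (i <= n_segment_rg) {
      ctr <- round(colMeans(which(s$truth_mask == 1L, arr.ind = TRUE)))
      rgp <- config$region; rgp$seed <- as.integer(ctr)
      rg_mask <- region_growing(gray, rgp)
      rg_score <- segmentation_accuracy(rg_mask, s$truth_mask)
    }
    seg[[i]] <- tibble::tibble(
      id = sprintf("sample_%03d", i), label = s$spec$label,
      as_accuracy = as_score$accuracy, as_dice = as_score$dice,
      rg_accuracy = if (is.null(rg_score)) NA_real_ else rg_score$accuracy,
      rg_dice = if (is.null(rg_score)) NA_real_ else rg_score$dice)
    fv <- extract_feature_vector(s$image, gray, as_mask,
                                 glcm_levels = config$glcm_levels)
    feats[[i]] <- tibble::tibble(id = sprintf("sample_%03d", i),
                                 label = s$spec$label, !!!as.list(fv))
  }
  features <- dplyr::bind_rows(feats)
  sp <- split_dataset(features, config$train_fraction, seed = seed)
  ann <- train_ann(sp$train, seed = seed)
  svm <- train_svm(sp$train, seed = seed)
  res <- lapply(list(ann = ann, svm = svm), function(m) {
    pred <- predict(m, sp$test)
    cm <- confusion_matrix(sp$test$label, pred, positive = "malignant")
    list(model = m, confusion = cm, metrics = compute_metrics(cm))
  })
  list(segmentation = dplyr::bind_rows(seg), features = features, split = sp,
       ann = res$ann, svm = res$svm)
}
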