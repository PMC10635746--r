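#' Pipeline configuration
#'
#' Bundles every stage's settings with a single master seed that fans out
#' deterministically to the stages (phantom generation, model training,
#' fold splitting).
#'
#' @param out_dir directory for stage artifacts and the report.
#' @param data_dir directory with existing images + `labels.csv`; `NULL`
#'   (default) generates phantoms instead.
#' @param n_per_class phantoms per class when generating (default 50).
#' @param image_size phantom side length (default 128).
#' @param k cross-validation folds (default 5).
#' @param seed master seed.
#' @param fusion_variant `"disjoint_singleton"` or `"classical_ds"`.
#' @param preprocess apply median filter + equalization (default `TRUE`).
#' @param median_window median-filter window (default 3).
#' @param glcm a [glcm_spec].
#' @param mlp an [mlp_config] or `NULL` (sized to the feature table).
#' @param cnn a [cnn_config].
#' @param resume reuse stage artifacts already present in `out_dir`
#'   (default `TRUE`).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            data_dir = NULL,
                            n_per_class = 50L,
                            image_size = 128L,
                            k = 5L,
                            seed = 1L,
                            fusion_variant = "disjoint_singleton",
                            preprocess = TRUE,
                            median_window = 3L,
                            glcm = glcm_spec(),
                            mlp = NULL,
                            cnn = cnn_config(),
                            resume = TRUE) {
  fusion_variant <- match.arg(fusion_variant,
                              c("disjoint_singleton", "classical_ds"))
  structure(list(out_dir = out_dir, data_dir = data_dir,
                 n_per_class = as.integer(n_per_class),
                 image_size = as.integer(image_size),
                 k = as.integer(k), seed = as.integer(seed),
                 fusion_variant = fusion_variant,
                 preprocess = isTRUE(preprocess),
                 median_window = as.integer(median_window),
                 glcm = glcm, mlp = mlp, cnn = cnn,
                 resume = isTRUE(resume)),
            class = "pipeline_config")
}

#' Validate a raw YAML/JSON pipeline configuration
#'
#' Parses configuration text (or a file path), rejects unknown keys by name,
#' applies documented defaults for missing ones, and cross-validates the
#' result (e.g. `k` versus `n_per_class`).
#'
#' @param text YAML or JSON configuration text, or a path to such a file.
#' @return a [pipeline_config].
#' @examples
#' validate_config("out_dir: /tmp/run\nn_per_class: 10")
#' @export
validate_config <- function(text) {
  if (length(text) == 1L && !grepl("[:\n{]", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  raw <- yaml::yaml.load(text)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a key-value mapping", call. = FALSE)
  known <- c("out_dir", "data_dir", "n_per_class", "image_size", "k", "seed",
             "fusion_variant", "preprocess", "median_window", "resume",
             "glcm", "mlp", "cnn")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sub_known <- list(
    glcm = c("distance", "angles", "levels", "symmetric", "normalized",
             "aggregate"),
    mlp = c("hidden_layers", "epochs", "learning_rate"),
    cnn = c("input_size", "crop_frac", "epochs", "learning_rate",
            "batch_size", "momentum", "augment"))
  for (s in names(sub_known)) {
    bad <- setdiff(names(raw[[s]]), sub_known[[s]])
    if (length(bad) > 0L)
      stop("unknown config key(s): ", paste(paste0(s, ".", bad),
                                            collapse = ", "), call. = FALSE)
  }
  args <- raw[intersect(names(raw), c("out_dir", "data_dir", "n_per_class",
                                      "image_size", "k", "seed",
                                      "fusion_variant", "preprocess",
                                      "median_window", "resume"))]
  if (is.null(args$out_dir)) args$out_dir <- tempfile("dsmammo_run_")
  if (!is.null(raw$glcm)) args$glcm <- do.call(glcm_spec, raw$glcm)
  if (!is.null(raw$cnn)) args$cnn <- do.call(cnn_config, raw$cnn)
  cfg <- do.call(pipeline_config, args)
  if (!is.null(raw$mlp)) cfg$mlp_overrides <- raw$mlp
  n_cls <- if (is.null(cfg$data_dir)) cfg$n_per_class else NA_integer_
  if (!is.na(n_cls) && n_cls < cfg$k)
    stop(sprintf("k = %d folds but only %d samples per class", cfg$k, n_cls),
         call. = FALSE)
  cfg
}

#' Run the full diagnosis pipeline
#'
#' Executes the flowchart end to end: load or generate images, median
#' filter, histogram equalization, GLCM feature extraction, cross-validated
#' MLP and CNN training and prediction, Dempster-Shafer fusion, and
#' reporting. Stage artifacts are written to `out_dir` in open formats
#' (PGM images, CSV tables, JSON report); with `resume = TRUE`, a dataset
#' already on disk is reused instead of being regenerated. A run log with
#' one line per stage (input/output record counts) goes to
#' `<out_dir>/run.log`.
#'
#' @param config a [pipeline_config].
#' @param verbose also echo log lines to the console.
#' @return the [run_cv_experiment()] report, invisibly, with the artifact
#'   paths attached as attribute `"artifacts"`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (!inherits(config, "pipeline_config"))
    stop("`config` must be a pipeline_config", call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
  }

  img_dir <- file.path(config$out_dir, "images")
  if (!is.null(config$data_dir)) {
    ds <- read_phantom_dataset(config$data_dir)
    say("stage=load dir=%s images=%d", config$data_dir, length(ds$images))
  } else if (config$resume && file.exists(file.path(img_dir, "labels.csv"))) {
    ds <- read_phantom_dataset(img_dir)
    say("stage=generate resumed=TRUE images=%d", length(ds$images))
  } else {
    ds <- generate_phantom_dataset(
      config$n_per_class,
      phantom_spec("benign", image_size = config$image_size),
      seed = config$seed)
    write_phantom_dataset(ds, img_dir)
    say("stage=generate images=%d per_class=%d size=%d", length(ds$images),
        config$n_per_class, config$image_size)
  }
  labels <- as.character(ds$labels)

  if (config$preprocess) {
    images <- lapply(ds$images, function(im)
      equalize(median_filter(im, config$median_window)))
    say("stage=preprocess in=%d out=%d median_window=%d", length(ds$images),
        length(images), config$median_window)
  } else {
    images <- ds$images
    say("stage=preprocess skipped=TRUE")
  }

  feats <- features_for_dataset(images, config$glcm, labels)
  feat_path <- file.path(config$out_dir, "features.csv")
  utils::write.csv(feats, feat_path, row.names = FALSE)
  say("stage=features in=%d rows=%d cols=%d", length(images), nrow(feats),
      ncol(feats))

  mlp_cfg <- config$mlp
  if (is.null(mlp_cfg)) {
    mlp_args <- list(input_dim = ncol(feats) - 1L)
    if (!is.null(config$mlp_overrides))
      mlp_args <- utils::modifyList(mlp_args, config$mlp_overrides)
    mlp_cfg <- do.call(mlp_config, mlp_args)
  }
  report <- run_cv_experiment(images, labels, k = config$k,
                              seed = config$seed, glcm = config$glcm,
                              mlp = mlp_cfg, cnn = config$cnn,
                              frame = ds_frame(config$fusion_variant),
                              preprocess = FALSE)
  say("stage=cv folds=%d prob_rows_mlp=%d prob_rows_cnn=%d fused_rows=%d",
      config$k, report$counts[["prob_rows_mlp"]],
      report$counts[["prob_rows_cnn"]], report$counts[["fused_rows"]])

  probs_path <- file.path(config$out_dir, "probabilities.csv")
  utils::write.csv(data.frame(
    sample_id = seq_along(labels), true_label = labels,
    p1_benign = report$scores$mlp[, 1L],
    p1_malignant = report$scores$mlp[, 2L],
    p1_ignorant = report$scores$mlp[, 3L],
    p2_benign = report$scores$cnn[, 1L],
    p2_malignant = report$scores$cnn[, 2L],
    p2_ignorant = report$scores$cnn[, 3L]), probs_path, row.names = FALSE)
  fused_path <- file.path(config$out_dir, "fused.csv")
  utils::write.csv(data.frame(
    sample_id = seq_along(labels),
    m_benign = report$scores$fused[, 1L],
    m_malignant = report$scores$fused[, 2L],
    m_ignorance = report$scores$fused[, 3L],
    decided_label = report$predictions$fused), fused_path, row.names = FALSE)

  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(eval_report_summary(report), report_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("stage=report accuracy_mlp=%.4f accuracy_cnn=%.4f accuracy_fused=%.4f",
      report$accuracy[["mlp"]], report$accuracy[["cnn"]],
      report$accuracy[["fused"]])
  writeLines(log_lines, log_path)
  attr(report, "artifacts") <- c(images = img_dir, features = feat_path,
                                 probabilities = probs_path,
                                 fused = fused_path, report = report_path,
                                 log = log_path)
  invisible(report)
}

# serializable summary of an eval_report (used for the JSON artifact)
eval_report_summary <- function(report) {
  list(seed = report$seed, k = report$k,
       counts = as.list(report$counts),
       accuracy = as.list(report$accuracy),
       metrics = lapply(report$metrics, function(per_m)
         lapply(per_m, as.list)),
       confusion = lapply(report$confusion, function(per_m)
         lapply(per_m, function(cm)
           list(grid = unclass(as.matrix(cm$grid)), TP = cm$TP, FN = cm$FN,
                FP = cm$FP, TN = cm$TN, positive = cm$positive))),
       total_conflicts = report$total_conflicts)
}

#' Audit record counts across pipeline stages
#'
#' Verifies that every stage saw every sample: images in = feature rows =
#' probability rows (both sources) = fused rows.
#'
#' @param report an `eval_report` (from [run_pipeline()] or
#'   [run_cv_experiment()]).
#' @return `TRUE` invisibly; error if any stage dropped records.
#' @export
audit_record_counts <- function(report) {
  cnt <- report$counts
  if (length(unique(cnt)) != 1L)
    stop("record-count audit failed: ",
         paste(names(cnt), cnt, sep = "=", collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
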