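#' Stratified k-fold split
#'
#' Partitions `1:n` into `k` test folds. With `labels`, folds are stratified:
#' within each class the shuffled indices are dealt round-robin, and the
#' starting fold rotates with the accumulated remainder so fold sizes differ
#' by at most one overall as well as within each class. Deterministic given
#' `seed`.
#'
#' @param n number of samples (>= k).
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @param labels optional label vector for stratification.
#' @return a `fold_split` list: `test` (list of k index vectors), `train`
#'   (their complements), `k`, `seed`, `stratified`.
#' @export
kfold_split <- function(n, k = 5L, seed = 1L, labels = NULL) {
  n <- as.integer(n); k <- as.integer(k)
  if (is.na(n) || is.na(k) || k < 2L)
    stop("`k` must be >= 2", call. = FALSE)
  if (n < k) stop("`n` must be >= `k`", call. = FALSE)
  if (!is.null(labels) && length(labels) != n)
    stop("`labels` must have length `n`", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  test <- vector("list", k)
  if (is.null(labels)) {
    groups <- list(sample.int(n))
  } else {
    labels <- as.character(labels)
    groups <- lapply(unique(sort(labels)),
                     function(cl) sample(which(labels == cl)))
  }
  offset <- 0L
  for (g in groups) {
    fold_of <- ((seq_along(g) - 1L + offset) %% k) + 1L
    for (f in seq_len(k)) test[[f]] <- c(test[[f]], g[fold_of == f])
    offset <- (offset + length(g)) %% k
  }
  test <- lapply(test, sort)
  structure(list(test = test,
                 train = lapply(test, function(t) setdiff(seq_len(n), t)),
                 k = k, seed = seed, stratified = !is.null(labels)),
            class = "fold_split")
}

#' Confusion counts for a designated positive class
#'
#' Builds the full 3x3 count grid over the three classes, plus the binary
#' TP/FN/FP/TN counts for a designated positive class among benign and
#' malignant. Following the usual mammographic reporting population, the
#' binary counts are restricted to samples whose true class is benign or
#' malignant (normal/ignorant truths are excluded; the other mass class is
#' the negative).
#'
#' @param truth,predicted aligned label vectors.
#' @param positive `"benign"` or `"malignant"`.
#' @return a `confusion_matrix` list: `grid` (3x3 table, rows = truth),
#'   `TP`, `FN`, `FP`, `TN`, `positive`, `total`.
#' @export
confusion_counts <- function(truth, predicted, positive = "benign") {
  positive <- match.arg(positive, c("benign", "malignant"))
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("`truth` and `predicted` must align", call. = FALSE)
  bad <- setdiff(unique(c(truth, predicted)), mass_classes())
  if (length(bad) > 0L)
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  f <- function(x) factor(x, levels = mass_classes())
  grid <- table(truth = f(truth), predicted = f(predicted))
  negative <- setdiff(c("benign", "malignant"), positive)
  in_pop <- truth %in% c("benign", "malignant")
  t2 <- truth[in_pop]; p2 <- predicted[in_pop]
  structure(list(grid = grid,
                 TP = sum(t2 == positive & p2 == positive),
                 FN = sum(t2 == positive & p2 != positive),
                 FP = sum(t2 == negative & p2 == positive),
                 TN = sum(t2 == negative & p2 != positive),
                 positive = positive, total = sum(in_pop)),
            class = "confusion_matrix")
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `accuracy = (TP+TN)/(TP+FN+FP+TN)`. A ratio with a zero denominator is
#' reported as `NA` (undefined), never as 0.
#'
#' @param cm a [confusion_counts()] result, or a list with `TP`, `FN`,
#'   `FP`, `TN`.
#' @return named numeric vector `accuracy`, `sensitivity`, `specificity`.
#' @examples
#' classification_metrics(list(TP = 63, FN = 1, FP = 0, TN = 51))
#' @export
classification_metrics <- function(cm) {
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  total <- cm$TP + cm$FN + cm$FP + cm$TN
  c(accuracy = rat(cm$TP + cm$TN, total),
    sensitivity = rat(cm$TP, cm$TP + cm$FN),
    specificity = rat(cm$TN, cm$TN + cm$FP))
}

#' ROC curve for one class's score
#'
#' Sweeps thresholds over the scores (via pROC, with a fixed "higher score
#' means positive" direction) and returns the operating points sorted by
#' false-positive rate, always including (0,0) and (1,1).
#'
#' @param truth label vector.
#' @param scores numeric score for the positive class, one per sample.
#' @param positive the positive class name.
#' @return a data frame with columns `fpr`, `tpr`, plus the AUC as
#'   attribute `"auc"`.
#' @export
roc_points <- function(truth, scores, positive = "benign") {
  truth <- as.character(truth)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  y <- as.integer(truth == positive)
  if (length(unique(y)) < 2L)
    stop("ROC undefined: truth contains a single class", call. = FALSE)
  r <- pROC::roc(response = y, predictor = scores, levels = c(0L, 1L),
                 direction = "<", quiet = TRUE)
  pts <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  if (pts$fpr[1L] != 0 || pts$tpr[1L] != 0)
    pts <- rbind(data.frame(fpr = 0, tpr = 0), pts)
  n <- nrow(pts)
  if (pts$fpr[n] != 1 || pts$tpr[n] != 1)
    pts <- rbind(pts, data.frame(fpr = 1, tpr = 1))
  rownames(pts) <- NULL
  attr(pts, "auc") <- as.numeric(r$auc)
  pts
}

#' Cross-validated evaluation of MLP, CNN and their evidential fusion
#'
#' For each fold: GLCM features are computed on the preprocessed images, the
#' texture MLP and the image CNN are trained on the training folds, both
#' predict probability triples on the test fold, and the triples are fused
#' with Dempster's rule. Test-fold predictions are pooled over folds into a
#' single confusion matrix per method (MLP, CNN, fused). Deterministic given
#' `seed` (per-fold model seeds derive from it).
#'
#' @param images list of [gray_image]s.
#' @param labels class labels, one per image.
#' @param k folds (default 5).
#' @param seed master seed.
#' @param glcm a [glcm_spec].
#' @param mlp an [mlp_config] (`input_dim` must match the feature table) or
#'   `NULL` for defaults sized to the feature table.
#' @param cnn a [cnn_config].
#' @param frame a [ds_frame].
#' @param preprocess apply median filter + equalization before feature
#'   extraction and CNN input (default `TRUE`).
#' @return an `eval_report` list: per-method pooled predictions, 3-class
#'   accuracies, confusion matrices and metrics for both positive classes,
#'   ROC points, per-stage record counts, fold split and seed.
#' @export
run_cv_experiment <- function(images, labels, k = 5L, seed = 1L,
                              glcm = glcm_spec(), mlp = NULL,
                              cnn = cnn_config(), frame = ds_frame(),
                              preprocess = TRUE) {
  labels <- as.character(labels)
  n <- length(images)
  if (min(table(labels)) < k)
    stop("need at least `k` samples per class", call. = FALSE)
  if (preprocess)
    images <- lapply(images, function(im) equalize(median_filter(im)))
  feats <- features_for_dataset(images, glcm)
  if (is.null(mlp)) mlp <- mlp_config(input_dim = ncol(feats))

  split <- kfold_split(n, k, seed = seed, labels = labels)
  pred <- list(mlp = rep(NA_character_, n), cnn = rep(NA_character_, n),
               fused = rep(NA_character_, n))
  scores <- list(mlp = matrix(NA_real_, n, 3L,
                              dimnames = list(NULL, mass_classes())))
  scores$cnn <- scores$mlp
  scores$fused <- scores$mlp
  conflicts <- 0L
  for (f in seq_len(k)) {
    tr <- split$train[[f]]; te <- split$test[[f]]
    mlp_f <- mlp; mlp_f$seed <- seed + 100L * f
    cnn_f <- cnn; cnn_f$seed <- seed + 100L * f + 1L
    m1 <- train_mlp(as.matrix(feats[tr, , drop = FALSE]), labels[tr], mlp_f)
    m2 <- train_cnn(images[tr], labels[tr], cnn_f)
    p1 <- predict_proba(m1, as.matrix(feats[te, , drop = FALSE]))
    p2 <- predict_proba(m2, images[te])
    fused <- fuse_sources(p1, p2, frame)
    pred$mlp[te] <- mass_classes()[max.col(p1, ties.method = "first")]
    pred$cnn[te] <- mass_classes()[max.col(p2, ties.method = "first")]
    pred$fused[te] <- fused$decided_label
    scores$mlp[te, ] <- p1
    scores$cnn[te, ] <- p2
    scores$fused[te, ] <- as.matrix(
      fused[, c("m_benign", "m_malignant", "m_ignorance")])
    conflicts <- conflicts + sum(fused$conflict_flag)
  }

  methods <- c("mlp", "cnn", "fused")
  accuracy <- vapply(methods, function(m) mean(pred[[m]] == labels),
                     numeric(1))
  confusion <- list(); metrics <- list(); roc <- list()
  for (m in methods) {
    confusion[[m]] <- list()
    metrics[[m]] <- list()
    roc[[m]] <- list()
    for (pos in c("benign", "malignant")) {
      cm <- confusion_counts(labels, pred[[m]], positive = pos)
      confusion[[m]][[pos]] <- cm
      metrics[[m]][[pos]] <- classification_metrics(cm)
      roc[[m]][[pos]] <- tryCatch(
        roc_points(labels, scores[[m]][, pos], positive = pos),
        error = function(e) NULL)
    }
  }
  structure(list(predictions = pred, scores = scores,
                 accuracy = accuracy, confusion = confusion,
                 metrics = metrics, roc = roc,
                 counts = c(images = n, feature_rows = nrow(feats),
                            prob_rows_mlp = sum(!is.na(pred$mlp)),
                            prob_rows_cnn = sum(!is.na(pred$cnn)),
                            fused_rows = sum(!is.na(pred$fused))),
                 total_conflicts = conflicts,
                 split = split, k = k, seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %d samples, %d-fold CV, seed %d>\n",
              x$counts[["images"]], x$k, x$seed))
  cat(sprintf("  3-class accuracy: MLP %.4f | CNN %.4f | fused %.4f\n",
              x$accuracy[["mlp"]], x$accuracy[["cnn"]],
              x$accuracy[["fused"]]))
  for (pos in c("benign", "malignant")) {
    mm <- x$metrics$fused[[pos]]
    cat(sprintf("  fused (%s+): acc %.4f sens %.4f spec %.4f\n", pos,
                mm[["accuracy"]], mm[["sensitivity"]], mm[["specificity"]]))
  }
  invisible(x)
}
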