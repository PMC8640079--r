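# Evaluation scheme: stratified partitioning, confusion-matrix metrics
# (sensitivity, specificity, accuracy, weighted F1), rank-based ROC AUC,
# stratified cross-validation reports, and chi-squared homogeneity checks
# between partitions. Case is the positive class throughout.

#' Stratified random hold-out split
#'
#' The total test size is `ceiling(test_fraction * n)`; per-class test
#' counts are allocated proportionally to class sizes by largest
#' remainder (remainder ties go to the larger class), and membership is
#' drawn at random within class under the given seed.
#'
#' @param meta A [cohort_metadata()].
#' @param test_fraction Fraction of samples held out (default 0.2).
#' @param seed RNG seed (default 16).
#' @return List with character vectors `train_ids` and `test_ids`.
#' @export
stratified_holdout <- function(meta, test_fraction = 0.2, seed = 16) {
  stopifnot(inherits(meta, "cohort_metadata"))
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie in (0, 1)", call. = FALSE)
  }
  y <- assert_two_classes(meta$label)
  n <- length(y)
  n_by <- table(y)
  if (any(n_by < 2)) stop("each class needs at least 2 samples", call. = FALSE)
  n_test <- ceiling(test_fraction * n)
  quota <- n_test * as.numeric(n_by) / n
  base <- floor(quota)
  rem <- n_test - sum(base)
  if (rem > 0) {
    # largest remainder; ties favour the larger class
    ord <- order(-(quota - base), -as.numeric(n_by))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  names(base) <- names(n_by)
  if (any(base > as.numeric(n_by)) || any(base < 1)) {
    stop("infeasible allocation: a class is smaller than its quota",
         call. = FALSE)
  }
  seeds <- derive_seeds(seed, length(base))
  test_ids <- character(0)
  for (li in seq_along(base)) {
    ids <- meta$sample_id[y == names(base)[li]]
    test_ids <- c(test_ids,
                  with_seed(seeds[li], sample(ids, base[li])))
  }
  list(train_ids = setdiff(meta$sample_id, test_ids),
       test_ids = meta$sample_id[meta$sample_id %in% test_ids])
}

#' Confusion matrix from true and predicted labels
#'
#' @param truth,predicted Case/control label vectors of equal length.
#' @return Named list with integer counts `TP`, `FP`, `TN`, `FN`
#'   (case = positive class).
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- assert_two_classes(truth)
  predicted <- as_label_factor(predicted)
  list(TP = sum(truth == "case" & predicted == "case"),
       FP = sum(truth == "control" & predicted == "case"),
       TN = sum(truth == "control" & predicted == "control"),
       FN = sum(truth == "case" & predicted == "control"))
}

#' Sensitivity, specificity, accuracy and weighted F1 from a confusion matrix
#'
#' Weighted F1 is the class-size-weighted mean of the per-class F1 scores,
#' each class in turn treated as positive. All metrics are percentages.
#'
#' @param cm List with counts `TP`, `FP`, `TN`, `FN`, e.g. from
#'   [confusion_counts()].
#' @return Named list `SE`, `SP`, `accuracy`, `weighted_F1` (percent,
#'   unrounded; round to 2 decimals for reporting).
#' @export
confusion_metrics <- function(cm) {
  TP <- cm$TP; FP <- cm$FP; TN <- cm$TN; FN <- cm$FN
  stopifnot(all(c(TP, FP, TN, FN) >= 0))
  n_case <- TP + FN
  n_ctrl <- TN + FP
  if (n_case == 0 || n_ctrl == 0) {
    stop("need at least one case and one control", call. = FALSE)
  }
  n <- n_case + n_ctrl
  f1_case <- if (2 * TP + FP + FN == 0) 0 else 2 * TP / (2 * TP + FP + FN)
  f1_ctrl <- if (2 * TN + FN + FP == 0) 0 else 2 * TN / (2 * TN + FN + FP)
  list(SE = 100 * TP / n_case,
       SP = 100 * TN / n_ctrl,
       accuracy = 100 * (TP + TN) / n,
       weighted_F1 = 100 * (n_case * f1_case + n_ctrl * f1_ctrl) / n)
}

#' ROC AUC as the Mann-Whitney probability
#'
#' Equals `P(score_case > score_control) + 0.5 P(equal)` over all
#' case-control sample pairs, computed from midranks.
#'
#' @param y_true Case/control labels.
#' @param scores Finite numeric scores, higher = more case-like.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(y_true, scores) {
  y <- assert_two_classes(y_true)
  if (length(scores) != length(y) || !all(is.finite(scores))) {
    stop("scores must be finite and aligned with labels", call. = FALSE)
  }
  n_case <- sum(y == "case")
  n_ctrl <- sum(y == "control")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == "case"]) - n_case * (n_case + 1) / 2) / (n_case * n_ctrl)
}

#' Stratified cross-validated evaluation of a model configuration
#'
#' Assigns stratified folds, trains the configuration on each training
#' complement via [grid_search_train()], and scores the held-out fold:
#' sensitivity, specificity, weighted F1, accuracy and ROC AUC (all in
#' percent), with fold means and standard deviations in both the
#' population (divide-by-k) and sample conventions.
#'
#' @param X Samples x features matrix.
#' @param y Case/control labels.
#' @param cfg A [model_config()].
#' @param folds Number of stratified folds (default 3).
#' @param seed Seed for the fold assignment (default 16).
#' @return An object of class `reosig_eval`: `folds` (per-fold metric
#'   data.frame), `mean`, `sd_population`, `sd_sample`, `confusion`
#'   (per-fold confusion matrices) and `fold_id`.
#' @export
cross_validate <- function(X, y, cfg, folds = 3, seed = 16) {
  y <- assert_two_classes(y)
  X <- as.matrix(X)
  fold_id <- stratified_folds(y, folds, seed)
  rows <- vector("list", folds)
  cms <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    model <- grid_search_train(X[tr, , drop = FALSE], y[tr], cfg)
    pred <- predict(model, X[!tr, , drop = FALSE])
    score <- predict_score(model, X[!tr, , drop = FALSE])
    cm <- confusion_counts(y[!tr], pred)
    met <- confusion_metrics(cm)
    cms[[f]] <- cm
    rows[[f]] <- data.frame(fold = f, SE = met$SE, SP = met$SP,
                            weighted_F1 = met$weighted_F1,
                            accuracy = met$accuracy,
                            AUC = 100 * roc_auc(y[!tr], score))
  }
  perfold <- do.call(rbind, rows)
  metric_cols <- c("SE", "SP", "weighted_F1", "accuracy", "AUC")
  mu <- colMeans(perfold[metric_cols])
  sd_pop <- apply(perfold[metric_cols], 2,
                  function(v) sqrt(mean((v - mean(v))^2)))
  sd_smp <- apply(perfold[metric_cols], 2, sd)
  structure(list(folds = perfold, mean = as.list(mu),
                 sd_population = as.list(sd_pop),
                 sd_sample = as.list(sd_smp),
                 confusion = cms, fold_id = fold_id),
            class = "reosig_eval")
}

#' @export
print.reosig_eval <- function(x, ...) {
  cat("reosig_eval over", nrow(x$folds), "stratified folds (percent):\n")
  print(round(as.data.frame(x$folds), 2), row.names = FALSE)
  cat("mean:", paste(names(x$mean),
                     sprintf("%.2f", unlist(x$mean)), sep = "=",
                     collapse = " "), "\n")
  invisible(x)
}

#' Evaluate a trained model on a held-out test set
#'
#' @param model A trained `reosig_model`.
#' @param X_test Samples x features matrix with the model's columns.
#' @param y_test Case/control labels for the test samples.
#' @return List with the confusion matrix, percent metrics (`SE`, `SP`,
#'   `accuracy`, `weighted_F1`, `AUC`), and the per-sample scores.
#' @export
evaluate_on_test <- function(model, X_test, y_test) {
  y <- assert_two_classes(y_test)
  pred <- predict(model, X_test)
  score <- predict_score(model, X_test)
  cm <- confusion_counts(y, pred)
  met <- confusion_metrics(cm)
  met$AUC <- 100 * roc_auc(y, score)
  list(confusion = cm, metrics = met, scores = score)
}

#' Yates-corrected chi-squared homogeneity test for a 2x2 table
#'
#' Continuity-corrected chi-squared statistic (clamped at zero when the
#' correction exceeds the observed deviation) with a p-value from the
#' chi-squared distribution with one degree of freedom. Used to check
#' that a clinical characteristic is homogeneous across two partitions.
#'
#' @param a,b,c,d Non-negative counts, row-wise: the table is
#'   `rbind(c(a, b), c(c, d))`.
#' @return List with `chi2` and `p_value`.
#' @export
chi2_homogeneity_2x2 <- function(a, b, c, d) {
  x <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    stop("all table margins must be positive", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(x, correct = TRUE))
  list(chi2 = unname(ht$statistic), p_value = unname(ht$p.value))
}
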