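# Staged feature selection over screened REO pairs: random-forest
# impurity-importance ranking to a top-k shortlist, then SVM recursive
# feature elimination with stratified cross-validation.

# Tie-break key: pairs sort by their canonical (sorted-member) key, then
# by the directed id; non-pair features sort by name.
canonical_tie_rank <- function(feature_names) {
  parts <- strsplit(feature_names, "|", fixed = TRUE)
  key <- vapply(parts, function(p) {
    if (length(p) == 2) paste(sort(p), collapse = "|") else p[1]
  }, character(1))
  order(order(key, feature_names))
}

#' Rank screened pairs by random-forest impurity importance
#'
#' Trains an ensemble of classification trees on the ternary REO features
#' and ranks features by mean decrease in Gini impurity, normalised to sum
#' to one over all input features. Ties break by canonical pair order.
#'
#' @param X Samples x features matrix or data.frame of REO values (rows
#'   aligned with `y`); column names are directed pair ids.
#' @param y Case/control labels.
#' @param top_k Number of top-ranked features to return (default 400). If
#'   larger than the number of features, all are returned with a warning.
#' @param seed RNG seed for the forest (default 16).
#' @param ntree Number of trees (default 100).
#' @return Data.frame with columns `feature` and `importance`, in
#'   descending importance order, truncated to `top_k` rows.
#' @export
rank_by_forest_importance <- function(X, y, top_k = 400, seed = 16,
                                      ntree = 100) {
  y <- assert_two_classes(y)
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X needs feature column names", call. = FALSE)
  if (top_k > ncol(X)) {
    warning("top_k = ", top_k, " exceeds the ", ncol(X),
            " available features; returning all", call. = FALSE)
    top_k <- ncol(X)
  }
  fit <- with_seed(seed,
                   randomForest::randomForest(x = X, y = y, ntree = ntree,
                                              importance = FALSE))
  imp <- fit$importance[, "MeanDecreaseGini"]
  if (sum(imp) > 0) imp <- imp / sum(imp)
  ord <- order(-imp, canonical_tie_rank(colnames(X)))
  out <- data.frame(feature = colnames(X)[ord], importance = imp[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[seq_len(top_k), , drop = FALSE]
}

# Fit a linear soft-margin SVM and return squared feature weights,
# rounded to 8 significant digits relative to the largest weight so that
# mathematically tied weights compare equal regardless of floating-point
# summation order (duplicated or mirrored ternary columns tie exactly).
linear_svm_weights2 <- function(X, y, cost) {
  fit <- e1071::svm(x = X, y = y, kernel = "linear", cost = cost,
                    scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  out <- numeric(ncol(X))
  names(out) <- colnames(X)
  out[colnames(fit$SV)] <- w^2
  if (max(out) > 0) out <- round(out / max(out), 8)
  list(w2 = out, fit = fit)
}

# Full recursive elimination path on (X, y): at each step drop the
# `step` features with the smallest squared weight (ties eliminate the
# feature latest in canonical order). Returns surviving feature sets by
# size and, optionally, held-out accuracies from the model fitted at each
# size.
rfe_path <- function(X, y, cost = 1, step = 1L,
                     X_test = NULL, y_test = NULL) {
  features <- colnames(X)
  K <- length(features)
  tie <- canonical_tie_rank(features)
  names(tie) <- features
  sets <- vector("list", K)
  acc <- rep(NA_real_, K)
  current <- features
  while (length(current) >= 1) {
    k <- length(current)
    sets[[k]] <- current
    res <- linear_svm_weights2(X[, current, drop = FALSE], y, cost)
    if (!is.null(X_test)) {
      pred <- predict(res$fit, X_test[, current, drop = FALSE])
      acc[k] <- mean(pred == y_test)
    }
    if (k == 1) break
    nelim <- min(step, k - 1L)
    ord <- order(res$w2, -tie[current])
    current <- setdiff(current, current[ord[seq_len(nelim)]])
  }
  list(sets = sets, accuracy = acc)
}

#' SVM recursive feature elimination with stratified cross-validation
#'
#' For each stratified fold, recursive elimination runs on the training
#' portion with a linear soft-margin SVM; at every retained-set size the
#' fold model's accuracy on the held-out fold is recorded. The chosen
#' subset size is the smallest size attaining the maximal mean
#' cross-validated accuracy, and the returned subset is the one surviving
#' to that size when elimination is re-run on the full data.
#'
#' @param X Samples x features matrix of REO values, columns named.
#' @param y Case/control labels.
#' @param folds Number of stratified folds (default 3).
#' @param cost Soft-margin penalty of the linear base classifier
#'   (default 1).
#' @param step Features eliminated per iteration (default 1).
#' @param seed Seed for the fold assignment (default 16).
#' @return An object of class `svm_rfe`: list with `k` (sizes 1..K),
#'   `fold_accuracy` (K x folds matrix), `mean_accuracy`, `chosen_k`,
#'   `selected` (feature names at `chosen_k`, in canonical order) and
#'   `sets` (full-data surviving set per size).
#' @export
svm_rfe_cv <- function(X, y, folds = 3, cost = 1, step = 1, seed = 16) {
  y <- assert_two_classes(y)
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)
  if (is.null(colnames(X))) stop("X needs feature column names", call. = FALSE)
  K <- ncol(X)
  fold_id <- stratified_folds(y, folds, seed)
  fold_acc <- matrix(NA_real_, nrow = K, ncol = folds,
                     dimnames = list(NULL, paste0("fold", seq_len(folds))))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    path <- rfe_path(X[tr, , drop = FALSE], y[tr], cost = cost, step = step,
                     X_test = X[!tr, , drop = FALSE], y_test = y[!tr])
    fold_acc[, f] <- path$accuracy
  }
  mean_acc <- rowMeans(fold_acc)
  chosen_k <- which.max(mean_acc)  # smallest size among maximisers
  full_path <- rfe_path(X, y, cost = cost, step = step)
  sets <- full_path$sets
  selected <- sets[[chosen_k]]
  selected <- selected[order(canonical_tie_rank(selected))]
  structure(list(k = seq_len(K), fold_accuracy = fold_acc,
                 mean_accuracy = mean_acc, chosen_k = chosen_k,
                 selected = selected, sets = sets,
                 folds = folds, cost = cost, step = step, seed = seed),
            class = "svm_rfe")
}

#' @export
print.svm_rfe <- function(x, ...) {
  cat("svm_rfe: ", length(x$k), " feature sizes scored over ", x$folds,
      " stratified folds; chosen k = ", x$chosen_k,
      " (mean CV accuracy ", sprintf("%.4f", x$mean_accuracy[x$chosen_k]),
      ")\n", sep = "")
  invisible(x)
}

#' Extract the optimal feature subset from an RFE curve
#'
#' Returns the surviving feature set at the smallest size attaining the
#' maximal mean cross-validated accuracy.
#'
#' @param fit An `svm_rfe` object (or any list with `mean_accuracy` and
#'   `sets`).
#' @return Character vector of selected feature names; the chosen size is
#'   attached as attribute `k`.
#' @export
select_optimal_subset <- function(fit) {
  if (length(fit$mean_accuracy) == 0) stop("empty curve", call. = FALSE)
  k <- which.max(fit$mean_accuracy)
  out <- fit$sets[[k]]
  attr(out, "k") <- k
  out
}
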