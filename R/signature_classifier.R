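# Clinical-covariate encoding, signature feature assembly, and
# grid-searched classifier training for the four canonical model
# configurations (pairs-only / full signature x SVM / logistic).

#' Encode age in years as an ordinal three-class feature
#'
#' Ages below the first threshold map to -1, ages in `[t1, t2)` to 0 and
#' ages at or above the second threshold to +1. Thresholds default to 70
#' and 80 years; the boundary convention is left-closed (an age exactly at
#' a threshold falls in the upper class).
#'
#' @param age_years Numeric vector of non-negative ages.
#' @param thresholds Two increasing numbers, default `c(70, 80)`.
#' @return Integer vector in \{-1, 0, +1\}.
#' @export
encode_age <- function(age_years, thresholds = c(70, 80)) {
  if (any(age_years < 0)) stop("ages must be non-negative", call. = FALSE)
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  ifelse(age_years < thresholds[1], -1L,
         ifelse(age_years < thresholds[2], 0L, 1L))
}

#' Encode the APOE e4 allele count
#'
#' The default is the identity allele-count encoding (0, 1, 2). The
#' binarized mode groups carriers (1--2 alleles) against non-carriers.
#'
#' @param n_alleles Integer vector with values in \{0, 1, 2\}.
#' @param mode `"allele-count"` (default) or `"binarized"`.
#' @return Integer vector.
#' @export
encode_apoe <- function(n_alleles, mode = c("allele-count", "binarized")) {
  mode <- match.arg(mode)
  if (!all(n_alleles %in% 0:2)) {
    stop("APOE e4 allele counts must be 0, 1 or 2", call. = FALSE)
  }
  if (mode == "allele-count") as.integer(n_alleles)
  else as.integer(n_alleles > 0)
}

#' Assemble the qualitative-signature feature table
#'
#' Builds the samples x features table the classifiers consume: one REO
#' column per signature pair and, when `include_clinical` is set, the
#' encoded age class and APOE e4 columns. Rows follow `meta` order.
#'
#' @param em Numeric miRNA x sample matrix.
#' @param meta A [cohort_metadata()] aligned with `em`'s columns.
#' @param sig A [signature_file()].
#' @param include_clinical Append encoded clinical columns (default TRUE).
#' @return Numeric samples x features matrix; pair columns are named
#'   `"<i>|<j>"`, clinical columns `age_class` and `apoe_e4`.
#' @export
assemble_feature_table <- function(em, meta, sig, include_clinical = TRUE) {
  stopifnot(inherits(sig, "reosig_signature"))
  validate_expression_matrix(em, meta)
  X <- t(reo_feature_matrix(em, sig$pairs))
  if (include_clinical) {
    if (anyNA(meta$age_years) || anyNA(meta$apoe_e4_alleles)) {
      stop("clinical fields contain missing values", call. = FALSE)
    }
    X <- cbind(X,
               age_class = encode_age(meta$age_years,
                                      sig$clinical_config$age_thresholds),
               apoe_e4 = encode_apoe(meta$apoe_e4_alleles,
                                     sig$clinical_config$apoe_encoding))
  }
  rownames(X) <- meta$sample_id
  X
}

#' Model configuration for grid-searched training
#'
#' The four canonical configurations mirror the study design:
#' `dlb_model_config(1)` and `(2)` are the pairs-only SVM and logistic
#' models, `(3)` and `(4)` the signature (pairs + clinical) SVM and
#' logistic models. SVM grids span cost and gamma in
#' \{2e-4, 2e-3, 0.2, 2, 20, 200\} with RBF and linear kernels; logistic
#' grids span the inverse regularisation parameter C in
#' \{1e-4, 1e-3, 0.01, 0.1\} with an L2 penalty.
#'
#' @param family `"svm"` (soft-margin classifier) or `"logistic"`
#'   (L2-regularised logistic regression).
#' @param feature_set `"pairs"` or `"signature"` (pairs plus clinical).
#' @param grid Named list of hyperparameter candidate vectors: for
#'   `"svm"`, `cost`, `gamma`, `kernel`; for `"logistic"`, `C`.
#' @param cv_folds Stratified folds used by the grid search (default 3).
#' @param seed Seed for fold assignment and calibration (default 16).
#' @return An object of class `model_config`.
#' @export
model_config <- function(family = c("svm", "logistic"),
                         feature_set = c("pairs", "signature"),
                         grid = NULL, cv_folds = 3, seed = 16) {
  family <- match.arg(family)
  feature_set <- match.arg(feature_set)
  if (is.null(grid)) {
    grid <- if (family == "svm") {
      list(cost = c(0.0002, 0.002, 0.2, 2, 20, 200),
           gamma = c(0.0002, 0.002, 0.2, 2, 20, 200),
           kernel = c("rbf", "linear"))
    } else {
      list(C = c(0.0001, 0.001, 0.01, 0.1))
    }
  }
  if (length(grid) == 0 || any(lengths(grid) == 0)) {
    stop("hyperparameter grid must be non-empty", call. = FALSE)
  }
  need <- if (family == "svm") c("cost", "gamma", "kernel") else "C"
  miss <- setdiff(need, names(grid))
  if (length(miss) > 0) {
    stop("grid missing component(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  structure(list(family = family, feature_set = feature_set, grid = grid,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "model_config")
}

#' @rdname model_config
#' @param which Integer 1--4 selecting the canonical configuration.
#' @export
dlb_model_config <- function(which, cv_folds = 3, seed = 16) {
  stopifnot(which %in% 1:4)
  model_config(family = if (which %in% c(1, 3)) "svm" else "logistic",
               feature_set = if (which <= 2) "pairs" else "signature",
               cv_folds = cv_folds, seed = seed)
}

# Enumerate grid points in a fixed order (first component varies fastest);
# ties in the grid search resolve to the earliest point.
expand_grid_points <- function(grid) {
  g <- expand.grid(grid, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}

# Map the package's kernel names onto the backend's.
e1071_kernel <- function(kernel) {
  switch(kernel, rbf = "radial", linear = "linear",
         stop("unsupported kernel: ", kernel, call. = FALSE))
}

# Case-oriented decision values from a fitted e1071 SVM (positive =
# more case-like), independent of the backend's label ordering.
svm_decision_case <- function(fit, X) {
  dv <- attr(predict(fit, X, decision.values = TRUE), "decision.values")
  if (startsWith(colnames(dv)[1], "case")) drop(dv) else -drop(dv)
}

fit_svm_point <- function(X, y, point) {
  e1071::svm(x = X, y = y, kernel = e1071_kernel(point$kernel),
             cost = point$cost, gamma = point$gamma, scale = FALSE)
}

# glmnet needs >= 2 columns; pad single-feature designs with a zero column.
pad_design <- function(X) {
  if (ncol(X) >= 2) return(X)
  cbind(X, ".pad" = 0)
}

fit_logistic_point <- function(X, y, point) {
  glmnet::glmnet(pad_design(X), y, family = "binomial", alpha = 0,
                 lambda = 1 / (nrow(X) * point$C), standardize = FALSE,
                 maxit = 1e5)
}

predict_point <- function(family, fit, X) {
  if (family == "svm") {
    as.character(predict(fit, X))
  } else {
    p <- drop(predict(fit, pad_design(X), type = "response"))
    ifelse(p >= 0.5, "case", "control")
  }
}

#' Train a classifier by exhaustive grid search
#'
#' Every grid point is scored by mean stratified cross-validated accuracy
#' (`cfg$cv_folds` folds, seeded); the best point (ties resolve to the
#' earliest in enumeration order) is refitted on all of `X`. For the SVM
#' family a sigmoid (Platt) calibration mapping decision values to case
#' probabilities is fitted on out-of-fold decision values from the same
#' seeded folds, so probability scores are deterministic. The logistic
#' family is L2-penalised at `lambda = 1 / (n * C)` and emits response
#' probabilities directly.
#'
#' @param X Samples x features matrix from [assemble_feature_table()].
#' @param y Case/control labels aligned with `X` rows.
#' @param cfg A [model_config()].
#' @return An object of class `reosig_model` holding the refitted
#'   classifier, the chosen hyperparameters, the grid-point CV accuracies,
#'   the frozen feature list, and training provenance.
#' @export
grid_search_train <- function(X, y, cfg) {
  stopifnot(inherits(cfg, "model_config"))
  y <- assert_two_classes(y)
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)
  points <- expand_grid_points(cfg$grid)
  fold_id <- stratified_folds(y, cfg$cv_folds, cfg$seed)
  cv_acc <- vapply(points, function(pt) {
    accs <- vapply(seq_len(cfg$cv_folds), function(f) {
      tr <- fold_id != f
      fit <- if (cfg$family == "svm") {
        fit_svm_point(X[tr, , drop = FALSE], y[tr], pt)
      } else {
        fit_logistic_point(X[tr, , drop = FALSE], y[tr], pt)
      }
      mean(predict_point(cfg$family, fit, X[!tr, , drop = FALSE]) ==
             y[!tr])
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  best <- which.max(cv_acc)  # earliest grid point among ties
  point <- points[[best]]

  if (cfg$family == "svm") {
    fit <- fit_svm_point(X, y, point)
    # out-of-fold decision values -> sigmoid calibration
    dv_oof <- numeric(length(y))
    for (f in seq_len(cfg$cv_folds)) {
      tr <- fold_id != f
      fold_fit <- fit_svm_point(X[tr, , drop = FALSE], y[tr], point)
      dv_oof[!tr] <- svm_decision_case(fold_fit, X[!tr, , drop = FALSE])
    }
    calib <- suppressWarnings(
      glm((y == "case") ~ dv_oof, family = binomial()))
    calibration <- coef(calib)
  } else {
    fit <- fit_logistic_point(X, y, point)
    calibration <- NULL
  }
  structure(list(family = cfg$family, fit = fit, calibration = calibration,
                 hyperparameters = point, cv_accuracy = cv_acc,
                 grid_points = points, features = colnames(X),
                 config = cfg,
                 provenance = list(seed = cfg$seed, folds = cfg$cv_folds,
                                   n_train = nrow(X))),
            class = "reosig_model")
}

#' @export
print.reosig_model <- function(x, ...) {
  hp <- paste(names(x$hyperparameters), unlist(x$hyperparameters),
              sep = "=", collapse = ", ")
  cat("reosig_model (", x$family, "): ", length(x$features),
      " features; chosen ", hp, "; CV accuracy ",
      sprintf("%.4f", max(x$cv_accuracy)), "\n", sep = "")
  invisible(x)
}

check_feature_columns <- function(model, X) {
  X <- as.matrix(X)
  miss <- setdiff(model$features, colnames(X))
  extra <- setdiff(colnames(X), model$features)
  if (length(miss) > 0 || length(extra) > 0) {
    stop("feature columns do not match the model's training features.",
         if (length(miss) > 0)
           paste0(" Missing: ", paste(miss, collapse = ", "), "."),
         if (length(extra) > 0)
           paste0(" Unexpected: ", paste(extra, collapse = ", "), "."),
         call. = FALSE)
  }
  X[, model$features, drop = FALSE]
}

#' Case probability scores for new samples
#'
#' Scores lie in \[0, 1\], higher meaning more case-like: calibrated
#' sigmoid probabilities for the SVM family, response probabilities for
#' the logistic family.
#'
#' @param model A trained `reosig_model`.
#' @param X Samples x features matrix with the model's training columns.
#' @return Numeric vector of per-sample case probabilities.
#' @export
predict_score <- function(model, X) {
  stopifnot(inherits(model, "reosig_model"))
  X <- check_feature_columns(model, X)
  if (model$family == "svm") {
    dv <- svm_decision_case(model$fit, X)
    unname(stats::plogis(model$calibration[1] + model$calibration[2] * dv))
  } else {
    unname(drop(predict(model$fit, pad_design(X), type = "response")))
  }
}

#' Predict case/control labels
#'
#' Applies the 0.5 threshold to the calibrated case-probability scores
#' (both families), so label and score predictions are always consistent.
#'
#' @param object A trained `reosig_model`.
#' @param newdata Samples x features matrix.
#' @param ... Unused.
#' @return Character vector of `"case"` / `"control"` labels.
#' @export
predict.reosig_model <- function(object, newdata, ...) {
  s <- predict_score(object, newdata)
  ifelse(s >= 0.5, "case", "control")
}
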