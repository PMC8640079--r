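# Independent oracles and small fixture builders shared across tests.
# The oracles are deliberately naive (loops, no shared code with the
# package internals) so they can vouch for the vectorised implementations.

# Triple-loop reversed-stable screen: every pair, every sample, counted
# one by one. Pairs reported in control-majority direction.
naive_screen <- function(em, labels, threshold = 0.6) {
  ids <- sort(rownames(em))
  out <- list()
  for (a in seq_len(length(ids) - 1)) {
    for (b in (a + 1):length(ids)) {
      i <- ids[a]; j <- ids[b]
      s <- integer(ncol(em))
      for (k in seq_len(ncol(em))) {
        d <- em[i, k] - em[j, k]
        s[k] <- if (d > 0) 1L else if (d < 0) -1L else 0L
      }
      ctrl <- s[labels == "control"]; cas <- s[labels == "case"]
      np <- sum(ctrl == 1); nm <- sum(ctrl == -1)
      dir <- if (np >= nm) 1L else -1L
      fc <- max(np, nm) / length(ctrl)
      fk <- sum(cas == -dir) / length(cas)
      if (fc >= threshold && fk >= threshold) {
        pr <- if (dir == 1L) c(i, j) else c(j, i)
        out[[length(out) + 1L]] <-
          data.frame(mirna_i = pr[1], mirna_j = pr[2],
                     f_control = fc, f_case = fk,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(mirna_i = character(0), mirna_j = character(0),
                      f_control = numeric(0), f_case = numeric(0)))
  }
  do.call(rbind, out)
}

# Naive SVM-RFE elimination order: refit a linear SVM from scratch at
# every step, recompute the weight vector by explicit summation over
# support vectors, drop the smallest squared weight (ties drop the
# feature whose canonical sorted-member key is latest).
naive_rfe_order <- function(X, y, cost = 1) {
  key <- vapply(strsplit(colnames(X), "|", fixed = TRUE),
                function(p) paste(sort(p), collapse = "|"), character(1))
  names(key) <- colnames(X)
  current <- colnames(X)
  eliminated <- character(0)
  while (length(current) > 1) {
    fit <- e1071::svm(x = X[, current, drop = FALSE], y = y,
                      kernel = "linear", cost = cost, scale = FALSE)
    w <- rep(0, length(current))
    names(w) <- current
    for (sv in seq_len(nrow(fit$SV))) {
      w <- w + fit$coefs[sv, 1] * fit$SV[sv, current]
    }
    w2 <- w^2
    if (max(w2) > 0) w2 <- round(w2 / max(w2), 8)
    worst <- current[w2 == min(w2)]
    worst <- worst[order(key[worst], worst, decreasing = TRUE)][1]
    eliminated <- c(eliminated, worst)
    current <- setdiff(current, worst)
  }
  c(eliminated, current)
}

# Elimination order implied by an svm_rfe fit's full-data surviving sets.
rfe_elimination_order <- function(fit) {
  K <- length(fit$sets)
  ord <- character(0)
  for (k in K:2) ord <- c(ord, setdiff(fit$sets[[k]], fit$sets[[k - 1]]))
  c(ord, fit$sets[[1]])
}

# Trapezoidal area under the empirical ROC curve (independent of the
# package's rank-based AUC).
trapezoid_auc <- function(y, scores) {
  stopifnot(requireNamespace("pROC", quietly = TRUE))
  as.numeric(pROC::roc(response = y, predictor = scores,
                       levels = c("control", "case"), direction = "<",
                       quiet = TRUE)$auc)
}

# Small cohort for fast pipeline tests.
small_cohort <- function(seed = 1, m = 40, planted = 5, n = 60,
                         fidelity = 0.9, ...) {
  simulate_cohort(synthetic_spec(n_case = n, n_control = n, m_mirnas = m,
                                 planted_pairs = planted,
                                 fidelity = fidelity, seed = seed, ...))
}

# Directed pair ids "i|j" for a pairs data.frame.
pair_ids <- function(pairs) paste(pairs$mirna_i, pairs$mirna_j, sep = "|")

# A perfectly separable toy feature table: one column that equals the
# label sign plus a few noise columns.
separable_toy <- function(n = 30, noise_cols = 3, seed = 5) {
  set.seed(seed)
  y <- rep(c("control", "case"), each = n)
  X <- cbind(signal = ifelse(y == "case", 1, -1),
             matrix(sample(c(-1L, 0L, 1L), 2 * n * noise_cols,
                           replace = TRUE),
                    ncol = noise_cols,
                    dimnames = list(NULL, paste0("noise", seq_len(noise_cols)))))
  list(X = X, y = y)
}
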