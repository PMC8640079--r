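# Within-sample relative expression ordering (REO) features and the
# reversed-stable pair screen.

#' REO value of a single pair in a single sample
#'
#' The REO pattern of a pair with expression values `e_i`, `e_j` is +1 if
#' `e_i > e_j`, 0 if exactly equal, and -1 if `e_i < e_j`. Equality is
#' exact by default; `epsilon` widens the tie band to `|e_i - e_j| <=
#' epsilon` for data with quantised values.
#'
#' @param e_i,e_j Finite numeric vectors (recycled to common length).
#' @param epsilon Non-negative tie tolerance; default 0 (exact equality).
#' @return Integer vector with values in \{-1, 0, +1\}.
#' @export
reo_value <- function(e_i, e_j, epsilon = 0) {
  if (!all(is.finite(e_i)) || !all(is.finite(e_j))) {
    stop("expression values must be finite", call. = FALSE)
  }
  stopifnot(epsilon >= 0)
  d <- e_i - e_j
  ifelse(abs(d) <= epsilon, 0L, ifelse(d > 0, 1L, -1L))
}

#' Number of unordered feature pairs among m features
#'
#' @param m Integer, at least 2.
#' @return `m * (m - 1) / 2` as a double (exact for all practical m).
#' @export
count_pairs <- function(m) {
  if (length(m) != 1 || is.na(m) || m < 2 || m != floor(m)) {
    stop("m must be a single integer >= 2", call. = FALSE)
  }
  m * (m - 1) / 2
}

#' REO feature matrix for a list of directed pairs
#'
#' Entry `(p, s)` for pair `p = (i, j)` is `reo_value(em[i, s], em[j, s])`.
#' Rows are named `"<i>|<j>"`. Reversing a pair's direction negates its
#' whole row.
#'
#' @param em Numeric miRNA x sample matrix.
#' @param pairs Data.frame (or 2-column matrix) of directed pairs; columns
#'   `mirna_i`, `mirna_j` (or the first two columns).
#' @param epsilon Tie tolerance passed to [reo_value()].
#' @return Integer pairs x samples matrix with values in \{-1, 0, +1\}.
#' @export
reo_feature_matrix <- function(em, pairs, epsilon = 0) {
  validate_expression_matrix(em)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!all(c("mirna_i", "mirna_j") %in% colnames(pairs))) {
    colnames(pairs)[1:2] <- c("mirna_i", "mirna_j")
  }
  unknown <- setdiff(unique(c(pairs$mirna_i, pairs$mirna_j)), rownames(em))
  if (length(unknown) > 0) {
    stop("miRNA(s) not in expression matrix: ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  d <- em[pairs$mirna_i, , drop = FALSE] - em[pairs$mirna_j, , drop = FALSE]
  f <- matrix(ifelse(abs(d) <= epsilon, 0L, ifelse(d > 0, 1L, -1L)),
              nrow = nrow(pairs),
              dimnames = list(pair_id(pairs$mirna_i, pairs$mirna_j),
                              colnames(em)))
  f
}

#' Reversal stability of one REO feature row
#'
#' The control direction is the sign (+1 or -1) attained by the larger
#' fraction of control samples (an exact tie breaks toward +1);
#' `f_control` is that fraction and `f_case` the fraction of case samples
#' showing the opposite sign. Ties (REO value 0) count in the denominators
#' but in neither numerator.
#'
#' @param feature_row Integer vector in \{-1, 0, +1\}, one value per sample.
#' @param labels Case/control labels aligned with `feature_row`.
#' @return List with `control_direction`, `f_control`, `f_case`.
#' @export
reversal_stability <- function(feature_row, labels) {
  y <- assert_two_classes(labels)
  if (length(feature_row) != length(y)) {
    stop("feature_row and labels must have equal length", call. = FALSE)
  }
  if (!all(feature_row %in% c(-1L, 0L, 1L))) {
    stop("feature_row values must be -1, 0 or +1", call. = FALSE)
  }
  ctrl <- feature_row[y == "control"]
  case <- feature_row[y == "case"]
  n_plus <- sum(ctrl == 1L)
  n_minus <- sum(ctrl == -1L)
  dir <- if (n_plus >= n_minus) 1L else -1L
  list(control_direction = dir,
       f_control = max(n_plus, n_minus) / length(ctrl),
       f_case = sum(case == -dir) / length(case))
}

#' Screen all miRNA pairs for reversed stable pairs
#'
#' A pair is reversed stable at threshold `theta` when its REO pattern
#' agrees with the control-majority direction in at least a fraction
#' `theta` of controls and shows the opposite direction in at least a
#' fraction `theta` of cases. All `m (m - 1) / 2` pairs are examined in
#' fixed-size blocks, so the full pair x sample feature matrix is never
#' materialised at once.
#'
#' @param em Numeric miRNA x sample matrix.
#' @param meta A [cohort_metadata()] aligned with `em`'s columns.
#' @param threshold Consistency threshold in (0.5, 1\]; the comparison is
#'   inclusive (`>= threshold`). Default 0.60.
#' @param epsilon Tie tolerance passed to the REO computation.
#' @param block_size Number of pairs processed per block.
#' @return Data.frame of retained pairs, each reported in its
#'   control-majority direction (`mirna_i` above `mirna_j` in most
#'   controls): columns `mirna_i`, `mirna_j`, `f_control`, `f_case`,
#'   sorted by `min(f_control, f_case)` descending, then lexicographic
#'   pair id.
#' @export
screen_reversed_stable <- function(em, meta, threshold = 0.60, epsilon = 0,
                                   block_size = 50000L) {
  validate_expression_matrix(em, meta)
  if (threshold <= 0.5 || threshold > 1) {
    stop("threshold must lie in (0.5, 1]", call. = FALSE)
  }
  y <- assert_two_classes(meta$label)
  is_ctrl <- y == "control"
  is_case <- y == "case"
  n_ctrl <- sum(is_ctrl)
  n_case <- sum(is_case)

  allp <- canonical_pairs(rownames(em))
  hits <- list()
  for (start in seq(1L, nrow(allp), by = block_size)) {
    idx <- start:min(start + block_size - 1L, nrow(allp))
    blk <- allp[idx, , drop = FALSE]
    d <- em[blk$id_i, , drop = FALSE] - em[blk$id_j, , drop = FALSE]
    s <- sign(d)
    if (epsilon > 0) s[abs(d) <= epsilon] <- 0
    cp <- rowSums(s[, is_ctrl, drop = FALSE] == 1)
    cm <- rowSums(s[, is_ctrl, drop = FALSE] == -1)
    dir <- ifelse(cp >= cm, 1L, -1L)
    f_control <- pmax(cp, cm) / n_ctrl
    f_case <- rowSums(s[, is_case, drop = FALSE] == -dir) / n_case
    keep <- f_control >= threshold & f_case >= threshold
    if (any(keep)) {
      kd <- data.frame(mirna_i = blk$id_i[keep], mirna_j = blk$id_j[keep],
                       dir = dir[keep], f_control = f_control[keep],
                       f_case = f_case[keep], stringsAsFactors = FALSE)
      hits[[length(hits) + 1L]] <- kd
    }
  }
  if (length(hits) == 0) {
    return(data.frame(mirna_i = character(0), mirna_j = character(0),
                      f_control = numeric(0), f_case = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  flip <- out$dir == -1L
  tmp <- out$mirna_i[flip]
  out$mirna_i[flip] <- out$mirna_j[flip]
  out$mirna_j[flip] <- tmp
  out$dir <- NULL
  ord <- order(-pmin(out$f_control, out$f_case),
               pair_id(out$mirna_i, out$mirna_j))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
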