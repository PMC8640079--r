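# Internal helpers shared across modules: label handling, seeded RNG
# streams, stratified partitioning, canonical pair ordering.

LABEL_LEVELS <- c("control", "case")

# Coerce labels to a factor with levels (control, case); case is the
# positive class everywhere in the package.
as_label_factor <- function(labels) {
  x <- as.character(labels)
  bad <- setdiff(unique(x), LABEL_LEVELS)
  if (length(bad) > 0) {
    stop("labels must be 'case' or 'control'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(x, levels = LABEL_LEVELS)
}

assert_two_classes <- function(labels) {
  y <- as_label_factor(labels)
  n <- table(y)
  if (any(n == 0)) {
    stop("both classes must be present; got ", n[["case"]], " case(s) and ",
         n[["control"]], " control(s)", call. = FALSE)
  }
  y
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive n independent child seeds from one master seed. Components drawing
# from dedicated child streams are unaffected when other components are
# added or draw more numbers.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

# Stratified fold assignment: within each class, a seeded shuffle followed
# by contiguous chunks; remainder samples go to the lowest-numbered folds,
# so fold sizes within a class differ by at most one and the larger folds
# come first. Returns an integer vector in 1..k aligned with `labels`.
stratified_folds <- function(labels, k, seed) {
  y <- assert_two_classes(labels)
  k <- as.integer(k)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (any(table(y) < k)) {
    stop("each class needs at least k = ", k, " samples", call. = FALSE)
  }
  folds <- integer(length(y))
  seeds <- derive_seeds(seed, nlevels(y))
  for (li in seq_along(levels(y))) {
    idx <- which(y == levels(y)[li])
    idx <- with_seed(seeds[li], sample(idx))
    n <- length(idx)
    sizes <- rep(n %/% k, k) + as.integer(seq_len(k) <= n %% k)
    folds[idx] <- rep(seq_len(k), times = sizes)
  }
  folds
}

# Canonical enumeration of all unordered pairs: lexicographic over sorted
# ids, first member < second member. All downstream tie-breaking inherits
# this order. Returns a data.frame (id_i, id_j).
canonical_pairs <- function(ids) {
  ids <- sort(unique(as.character(ids)))
  m <- length(ids)
  if (m < 2) stop("need at least 2 ids to form pairs", call. = FALSE)
  first <- rep.int(seq_len(m - 1L), times = (m - 1L):1L)
  second <- sequence((m - 1L):1L) + first
  data.frame(id_i = ids[first], id_j = ids[second],
             stringsAsFactors = FALSE)
}

pair_id <- function(id_i, id_j) paste(id_i, id_j, sep = "|")

`%||%` <- function(a, b) if (is.null(a)) b else a
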