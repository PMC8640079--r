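# Reading, validation and serialisation of the tabular formats the
# pipeline touches: probe-level expression (TSV), cohort metadata
# (CSV/TSV), signatures (JSON) and evaluation reports (JSON/TSV).

#' Probe-level expression matrix with probe-to-miRNA annotation
#'
#' Light container for a probe x sample matrix of normalised continuous
#' expression values plus the annotation mapping each probe to a miRNA.
#'
#' @param values Numeric matrix, probes in rows (unique rownames), samples
#'   in columns (unique colnames). No missing values are allowed.
#' @param probe_to_mirna Named character vector mapping probe id to miRNA
#'   id; must cover every row of `values`.
#' @return An object of class `probe_matrix`.
#' @export
probe_matrix <- function(values, probe_to_mirna) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("values must have unique probe rownames", call. = FALSE)
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("values must have unique sample colnames", call. = FALSE)
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop("missing value for probe '", rownames(values)[bad[1]],
         "', sample '", colnames(values)[bad[2]], "'", call. = FALSE)
  }
  missing_ann <- setdiff(rownames(values), names(probe_to_mirna))
  if (length(missing_ann) > 0) {
    stop("probes without annotation: ",
         paste(head(missing_ann, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(values = values,
                 probe_to_mirna = probe_to_mirna[rownames(values)]),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat("probe_matrix:", nrow(x$values), "probes x", ncol(x$values),
      "samples;", length(unique(x$probe_to_mirna)), "distinct miRNAs\n")
  invisible(x)
}

#' Read a probe-level expression matrix and its probe annotation
#'
#' Expression files are tab-separated text with row identifiers in the
#' first column and a header row of sample identifiers (the orientation of
#' GEO series matrices). The annotation file is two tab-separated columns,
#' probe id then miRNA id, with a header. Probes absent from the annotation
#' are dropped with a warning reporting the count.
#'
#' @param path Path to the expression TSV.
#' @param annotation_path Path to the probe-to-miRNA annotation TSV.
#' @param transpose If `TRUE` the file is samples x probes and is
#'   transposed after reading.
#' @return A [probe_matrix()].
#' @export
read_expression <- function(path, annotation_path, transpose = FALSE) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate row identifiers in ", path, ": ",
         paste(head(unique(ids[duplicated(ids)]), 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(raw)[-1])) {
    stop("duplicate sample identifiers in ", path, call. = FALSE)
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  rownames(vals) <- ids
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  bad <- is.na(num) & !is.na(vals) & trimws(vals) != "" & vals != "NA"
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("non-numeric value '", vals[w[1], w[2]], "' at row '",
         rownames(vals)[w[1]], "', column '", colnames(vals)[w[2]], "'",
         call. = FALSE)
  }
  if (anyNA(num)) {
    w <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("missing value at row '", rownames(num)[w[1]], "', column '",
         colnames(num)[w[2]], "'", call. = FALSE)
  }
  if (transpose) num <- t(num)

  ann <- read.delim(annotation_path, header = TRUE, sep = "\t",
                    check.names = FALSE, colClasses = "character")
  if (ncol(ann) < 2) stop("annotation needs two columns", call. = FALSE)
  map <- ann[[2]]
  names(map) <- ann[[1]]
  unmapped <- setdiff(rownames(num), names(map))
  if (length(unmapped) > 0) {
    warning(length(unmapped), " probe(s) absent from annotation dropped",
            call. = FALSE)
    num <- num[setdiff(rownames(num), unmapped), , drop = FALSE]
  }
  if (nrow(num) == 0) stop("no annotated probes left", call. = FALSE)
  probe_matrix(num, map)
}

#' Collapse probe-level rows to miRNA-level rows
#'
#' A miRNA measured by several probes receives, per sample, the arithmetic
#' mean of its probe rows. Row order of the result is lexicographic over
#' miRNA ids, so collapsing is invariant to the probe order of the input.
#'
#' @param pm A [probe_matrix()].
#' @return Numeric miRNA x sample matrix (an expression matrix).
#' @export
collapse_probes <- function(pm) {
  stopifnot(inherits(pm, "probe_matrix"))
  if (nrow(pm$values) == 0) stop("empty probe matrix", call. = FALSE)
  groups <- factor(pm$probe_to_mirna)
  out <- rowsum(pm$values, group = groups) / as.vector(table(groups))
  out[sort(rownames(out)), , drop = FALSE]
}

#' Validate an expression matrix against cohort metadata
#'
#' Checks that a miRNA x sample matrix has unique ids, finite values and
#' sample columns identical in content and order to the metadata.
#'
#' @param em Numeric miRNA x sample matrix.
#' @param meta Optional [cohort_metadata()] to align against.
#' @return `em`, invisibly, after validation.
#' @export
validate_expression_matrix <- function(em, meta = NULL) {
  if (!is.matrix(em) || !is.numeric(em)) {
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(em)) || anyDuplicated(rownames(em))) {
    stop("expression matrix needs unique miRNA rownames", call. = FALSE)
  }
  if (is.null(colnames(em)) || anyDuplicated(colnames(em))) {
    stop("expression matrix needs unique sample colnames", call. = FALSE)
  }
  if (!all(is.finite(em))) {
    stop("expression matrix contains non-finite values", call. = FALSE)
  }
  if (!is.null(meta) && !identical(colnames(em), meta$sample_id)) {
    stop("sample columns must match metadata sample_id in content and order",
         call. = FALSE)
  }
  invisible(em)
}

#' Per-sample clinical metadata for a case/control cohort
#'
#' @param sample_id Unique sample identifiers.
#' @param label `"case"` or `"control"` per sample.
#' @param age_years Non-negative ages in years.
#' @param apoe_e4_alleles APOE e4 allele counts in \{0, 1, 2\}.
#' @param sex `"female"`, `"male"` or `"unknown"`.
#' @return A data.frame of class `cohort_metadata`.
#' @export
cohort_metadata <- function(sample_id, label, age_years, apoe_e4_alleles,
                            sex = "unknown") {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids", call. = FALSE)
  label <- as.character(as_label_factor(label))
  if (any(age_years < 0)) stop("ages must be non-negative", call. = FALSE)
  if (!all(apoe_e4_alleles %in% 0:2)) {
    stop("apoe_e4_alleles must be 0, 1 or 2", call. = FALSE)
  }
  sex <- as.character(sex)
  if (!all(sex %in% c("female", "male", "unknown"))) {
    stop("sex must be female, male or unknown", call. = FALSE)
  }
  out <- data.frame(sample_id = sample_id, label = label,
                    age_years = as.numeric(age_years),
                    apoe_e4_alleles = as.integer(apoe_e4_alleles),
                    sex = sex, stringsAsFactors = FALSE)
  class(out) <- c("cohort_metadata", "data.frame")
  out
}

#' Read cohort metadata from CSV or TSV
#'
#' Expects a header `sample_id,label,age_years,apoe_e4_alleles,sex`
#' (`sex` optional). The separator is inferred from the file extension
#' (`.tsv` means tab, anything else comma).
#'
#' @param path Path to the metadata table.
#' @return A [cohort_metadata()].
#' @export
read_metadata <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- read.delim(path, header = TRUE, sep = sep, check.names = TRUE,
                    stringsAsFactors = FALSE)
  need <- c("sample_id", "label", "age_years", "apoe_e4_alleles")
  miss <- setdiff(need, colnames(raw))
  if (length(miss) > 0) {
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cohort_metadata(raw$sample_id, raw$label, raw$age_years,
                  raw$apoe_e4_alleles,
                  if ("sex" %in% colnames(raw)) raw$sex else "unknown")
}

#' Write an expression matrix as a TSV
#'
#' Full-precision text representation (17 significant digits) so that a
#' write/read round trip reproduces the values bit-identically.
#'
#' @param em Numeric feature x sample matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path) {
  validate_expression_matrix(em)
  df <- data.frame(id = rownames(em),
                   format(em, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("id", colnames(em))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write cohort metadata as a CSV
#'
#' @param meta A [cohort_metadata()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  stopifnot(inherits(meta, "cohort_metadata"))
  write.table(meta, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a qualitative signature object
#'
#' A signature is an ordered list of directed miRNA pairs (the REO of
#' `mirna_i` versus `mirna_j` is the feature) plus the clinical-encoder
#' configuration and free-text provenance.
#'
#' @param pairs Data.frame with character columns `mirna_i`, `mirna_j`;
#'   no duplicate pairs, no self-pairs. May have zero rows.
#' @param clinical_config List with `age_thresholds` (two increasing
#'   numbers, default `c(70, 80)`) and `apoe_encoding` (`"allele-count"`
#'   or `"binarized"`).
#' @param provenance Optional named list of free-text metadata (threshold
#'   used, seeds, dataset hash, ...).
#' @return An object of class `reosig_signature`.
#' @export
signature_file <- function(pairs,
                           clinical_config = list(age_thresholds = c(70, 80),
                                                  apoe_encoding = "allele-count"),
                           provenance = list()) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (nrow(pairs) > 0) {
    if (!all(c("mirna_i", "mirna_j") %in% colnames(pairs))) {
      stop("pairs needs columns mirna_i and mirna_j", call. = FALSE)
    }
    pairs <- pairs[, c("mirna_i", "mirna_j")]
    pairs$mirna_i <- as.character(pairs$mirna_i)
    pairs$mirna_j <- as.character(pairs$mirna_j)
    if (any(pairs$mirna_i == pairs$mirna_j)) {
      stop("self-pairs (mirna_i == mirna_j) are not allowed", call. = FALSE)
    }
    if (anyDuplicated(pair_id(pairs$mirna_i, pairs$mirna_j))) {
      stop("duplicate pairs are not allowed", call. = FALSE)
    }
  } else {
    pairs <- data.frame(mirna_i = character(0), mirna_j = character(0),
                        stringsAsFactors = FALSE)
  }
  thr <- clinical_config$age_thresholds %||% c(70, 80)
  if (length(thr) != 2 || !(thr[1] < thr[2])) {
    stop("age_thresholds must be two increasing numbers", call. = FALSE)
  }
  enc <- clinical_config$apoe_encoding %||% "allele-count"
  if (!enc %in% c("allele-count", "binarized")) {
    stop("apoe_encoding must be 'allele-count' or 'binarized'", call. = FALSE)
  }
  structure(list(pairs = pairs,
                 clinical_config = list(age_thresholds = as.numeric(thr),
                                        apoe_encoding = enc),
                 provenance = provenance),
            class = "reosig_signature")
}

#' @export
print.reosig_signature <- function(x, ...) {
  cat("reosig_signature:", nrow(x$pairs), "directed pair(s); age thresholds",
      paste(x$clinical_config$age_thresholds, collapse = "/"),
      "; APOE encoding", x$clinical_config$apoe_encoding, "\n")
  invisible(x)
}

#' Write / read a signature as a self-describing JSON document
#'
#' `read_signature(write_signature(x, path))` reproduces `x` exactly.
#'
#' @param sig A [signature_file()] object.
#' @param path File path.
#' @return `write_signature` returns `path` invisibly; `read_signature`
#'   returns the signature object.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "reosig_signature"))
  doc <- list(format = "reosig-signature", version = 1L,
              pairs = sig$pairs, clinical_config = sig$clinical_config,
              provenance = sig$provenance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("pairs", "clinical_config")
  miss <- setdiff(need, names(doc))
  if (length(miss) > 0) {
    stop("signature file missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  pairs <- doc$pairs
  if (length(pairs) == 0) {
    pairs <- data.frame(mirna_i = character(0), mirna_j = character(0))
  }
  signature_file(pairs, doc$clinical_config,
                 as.list(doc$provenance %||% list()))
}

#' Write an evaluation report as JSON plus a flat per-fold TSV
#'
#' @param report An evaluation report from [cross_validate()] or
#'   [evaluate_on_test()].
#' @param json_path Path for the JSON document.
#' @param tsv_path Optional path for a flat TSV of the per-fold metrics.
#' @return `json_path`, invisibly.
#' @export
write_report <- function(report, json_path, tsv_path = NULL) {
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(tsv_path)) {
    write.table(report$folds, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(json_path)
}
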