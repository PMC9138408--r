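#' @keywords internal
"_PACKAGE"

# Group labels used throughout the two-group operations.
.GROUPS <- c("ETP", "NONETP")

#' Validate a gene-by-sample expression matrix
#'
#' An expression matrix is a numeric matrix of normalized log2-scale
#' intensities with unique, uppercase gene symbols as row names and unique
#' sample identifiers as column names. All entries must be finite.
#'
#' @param expr numeric matrix to validate.
#' @param require_positive if `TRUE`, additionally require all entries > 0
#'   (needed wherever ratios or geometric means are taken).
#' @return `expr`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_matrix <- function(expr, require_positive = FALSE) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix must carry gene symbols as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(expr))) {
    dup <- unique(rownames(expr)[duplicated(rownames(expr))])
    stop("duplicated gene symbols: ", paste(utils::head(dup, 5), collapse = ", "),
         " (collapse probes first)", call. = FALSE)
  }
  if (anyDuplicated(colnames(expr))) {
    stop("duplicated sample ids in expression matrix", call. = FALSE)
  }
  if (any(!is.finite(expr))) {
    bad <- which(!is.finite(expr), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 rownames(expr)[bad[1]], colnames(expr)[bad[2]]), call. = FALSE)
  }
  if (require_positive && any(expr <= 0)) {
    bad <- which(expr <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive expression value at gene '%s', sample '%s'",
                 rownames(expr)[bad[1]], colnames(expr)[bad[2]]), call. = FALSE)
  }
  invisible(expr)
}

#' Construct cohort labels
#'
#' @param sample_ids character vector of sample identifiers.
#' @param group character vector of group labels, `"ETP"` or `"NONETP"`,
#'   one per sample.
#' @param subtype optional extra subtype annotation (e.g. B-ALL, AML).
#' @return a data.frame of class `cohort_labels` with columns `sample_id`,
#'   `group` and optionally `subtype`.
#' @export
cohort_labels <- function(sample_ids, group, subtype = NULL) {
  sample_ids <- as.character(sample_ids)
  group <- as.character(group)
  if (length(sample_ids) != length(group)) {
    stop("sample_ids and group must have equal length", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample ids in labels", call. = FALSE)
  }
  bad <- setdiff(unique(group), .GROUPS)
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected ETP / NONETP)", call. = FALSE)
  }
  out <- data.frame(sample_id = sample_ids, group = group,
                    stringsAsFactors = FALSE)
  if (!is.null(subtype)) out$subtype <- as.character(subtype)
  class(out) <- c("cohort_labels", "data.frame")
  out
}

#' Sample ids belonging to a group
#'
#' @param labels a `cohort_labels` object.
#' @param group group label to extract.
#' @return character vector of sample ids.
#' @export
group_samples <- function(labels, group) {
  stopifnot(is.data.frame(labels))
  labels$sample_id[labels$group == group]
}

# Check labels cover the matrix columns and each requested group has at
# least min_n samples present in the matrix.
.check_groups <- function(expr, labels, min_n = 2) {
  missing_lab <- setdiff(colnames(expr), labels$sample_id)
  if (length(missing_lab)) {
    stop("samples without a group label: ",
         paste(utils::head(missing_lab, 5), collapse = ", "), call. = FALSE)
  }
  for (g in .GROUPS) {
    n <- sum(group_samples(labels, g) %in% colnames(expr))
    if (n < min_n) {
      stop(sprintf("group %s has %d sample(s) in the matrix; need at least %d",
                   g, n, min_n), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Run an expression with a locally seeded RNG, restoring the caller's
# RNG state afterwards so generators are pure functions of their seed.
.with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Deterministic, locale-independent ordering of character keys.
.radix_order <- function(...) order(..., method = "radix")
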