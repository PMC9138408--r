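#' Read a gene-by-sample expression TSV
#'
#' The first column holds gene symbols, remaining columns numeric
#' log2-scale expression with a header row of sample ids. Symbols are
#' stored uppercased (microarray annotations mix cases). Duplicate symbols
#' are collapsed by [collapse_probes()] using the max-mean rule.
#'
#' @param path file path.
#' @return a validated expression matrix.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    stop("empty or malformed expression file: ", path, call. = FALSE)
  }
  symbols <- toupper(trimws(raw[[1]]))
  num <- suppressWarnings(
    vapply(raw[-1], function(col) as.numeric(col), numeric(nrow(raw))))
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(NULL, colnames(raw)[-1]))
  if (any(!is.finite(num))) {
    bad <- which(!is.finite(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric expression value at row '%s', column '%s' in %s",
                 symbols[bad[1]], colnames(num)[bad[2]], path), call. = FALSE)
  }
  rownames(num) <- symbols
  if (anyDuplicated(symbols)) {
    num <- collapse_probes(num, stats::setNames(symbols, symbols))
  }
  validate_expression_matrix(num)
  num
}

#' Write an expression matrix as TSV
#'
#' Values are written with 15 significant digits so a read/write round
#' trip preserves them to at least 12 significant digits.
#'
#' @param expr expression matrix.
#' @param path output path.
#' @export
write_expression_tsv <- function(expr, path) {
  validate_expression_matrix(expr)
  df <- data.frame(gene = rownames(expr),
                   signif(expr, 15), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GEO Series Matrix file
#'
#' Parses the expression table between `!series_matrix_table_begin` and
#' `!series_matrix_table_end`. Sample ids are taken from
#' `!Sample_geo_accession`; sample titles (when present) are retained so
#' group labels can be mapped by the caller (see [labels_from_regex()]).
#' Group membership itself is never guessed.
#'
#' @param path file path.
#' @return list with `expr` (probe/gene matrix, ids uppercased, duplicates
#'   collapsed) and `samples` (data.frame: `sample_id`, `title`).
#' @export
read_series_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  strip <- function(x) gsub('^"|"$', "", x)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1 || length(end) != 1 || end <= begin + 1) {
    stop("missing or malformed !series_matrix_table_begin/end block in ",
         path, call. = FALSE)
  }
  acc_line <- grep("^!Sample_geo_accession", lines, value = TRUE)
  titles_line <- grep("^!Sample_title", lines, value = TRUE)
  tbl <- lines[(begin + 1):(end - 1)]
  cells <- strsplit(tbl, "\t", fixed = TRUE)
  header <- strip(cells[[1]])
  body <- cells[-1]
  ncol_expected <- length(header)
  widths <- lengths(body)
  if (any(widths != ncol_expected)) {
    stop(sprintf("series matrix row %d has %d fields; expected %d",
                 which(widths != ncol_expected)[1] + 1,
                 widths[widths != ncol_expected][1], ncol_expected),
         call. = FALSE)
  }
  ids <- toupper(strip(vapply(body, `[`, "", 1)))
  vals <- suppressWarnings(
    t(vapply(body, function(r) as.numeric(strip(r[-1])),
             numeric(ncol_expected - 1))))
  sample_ids <- if (length(acc_line)) {
    strip(strsplit(acc_line[1], "\t", fixed = TRUE)[[1]][-1])
  } else header[-1]
  colnames(vals) <- sample_ids
  rownames(vals) <- ids
  if (any(!is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value at probe '%s', sample '%s'",
                 ids[bad[1]], sample_ids[bad[2]]), call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    vals <- collapse_probes(vals, stats::setNames(ids, ids))
  }
  titles <- if (length(titles_line)) {
    strip(strsplit(titles_line[1], "\t", fixed = TRUE)[[1]][-1])
  } else rep(NA_character_, length(sample_ids))
  validate_expression_matrix(vals)
  list(expr = vals,
       samples = data.frame(sample_id = sample_ids, title = titles,
                            stringsAsFactors = FALSE))
}

#' Build cohort labels from sample titles and a regular expression
#'
#' @param samples data.frame with `sample_id` and `title` columns, as
#'   returned by [read_series_matrix()].
#' @param etp_regex regex; titles matching it are labelled `ETP`, the rest
#'   `NONETP`.
#' @return a [cohort_labels()] object.
#' @export
labels_from_regex <- function(samples, etp_regex) {
  stopifnot(all(c("sample_id", "title") %in% names(samples)))
  grp <- ifelse(grepl(etp_regex, samples$title), "ETP", "NONETP")
  cohort_labels(samples$sample_id, grp)
}

#' Collapse duplicate probes to gene symbols
#'
#' For each gene symbol the probe with the maximal mean expression across
#' samples is retained (a standard deterministic collapse policy).
#'
#' @param expr matrix whose rownames are probe ids (possibly duplicated
#'   after mapping).
#' @param mapping named character vector, probe id -> gene symbol.
#' @param unmapped `"drop"` (default) or `"keep"`: what to do with probes
#'   absent from the mapping.
#' @return matrix with one row per gene symbol (uppercased).
#' @export
collapse_probes <- function(expr, mapping, unmapped = c("drop", "keep")) {
  unmapped <- match.arg(unmapped)
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (length(mapping) == 0) {
    if (anyDuplicated(rownames(expr))) {
      stop("empty probe mapping but duplicated rows present", call. = FALSE)
    }
    return(expr)
  }
  probes <- rownames(expr)
  sym <- toupper(unname(mapping[probes]))
  keep <- !is.na(sym)
  if (unmapped == "keep") {
    sym[!keep] <- toupper(probes[!keep])
    keep <- rep(TRUE, length(sym))
  }
  expr <- expr[keep, , drop = FALSE]
  sym <- sym[keep]
  means <- rowMeans(expr)
  # per symbol, keep the row with the maximal mean (first on ties)
  ord <- order(sym, -means)
  pick <- ord[!duplicated(sym[ord])]
  pick <- sort(pick)
  out <- expr[pick, , drop = FALSE]
  rownames(out) <- sym[pick]
  out
}

#' Read a STRING-dialect interaction edge list
#'
#' Expects a whitespace/tab-separated table with two node columns and one
#' combined-confidence score column. Scores on the 0-1000 dialect are
#' divided by 1000. Duplicate undirected pairs are deduplicated keeping
#' the maximal confidence; self-pairs are dropped. Node symbols are
#' uppercased.
#'
#' @param path file path.
#' @param score_dialect `"0-1"` or `"0-1000"`.
#' @param columns integer or character vector of length 3 naming the
#'   node-A, node-B and score columns (default first three columns).
#' @param header does the file carry a header line?
#' @return data.frame with columns `node_a`, `node_b`, `confidence`.
#' @export
read_edge_list <- function(path, score_dialect = c("0-1", "0-1000"),
                           columns = 1:3, header = FALSE) {
  score_dialect <- match.arg(score_dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = header, stringsAsFactors = FALSE)
  if (is.character(columns)) columns <- match(columns, colnames(raw))
  if (length(columns) != 3 || any(is.na(columns)) || max(columns) > ncol(raw)) {
    stop("edge list must supply node-A, node-B and score columns", call. = FALSE)
  }
  a <- toupper(as.character(raw[[columns[1]]]))
  b <- toupper(as.character(raw[[columns[2]]]))
  s <- suppressWarnings(as.numeric(raw[[columns[3]]]))
  if (any(!is.finite(s))) {
    stop(sprintf("non-numeric confidence score at line %d",
                 which(!is.finite(s))[1] + as.integer(header)), call. = FALSE)
  }
  hi <- if (score_dialect == "0-1000") 1000 else 1
  if (any(s < 0 | s > hi)) {
    stop(sprintf("confidence score outside the %s dialect range at line %d",
                 score_dialect, which(s < 0 | s > hi)[1] + as.integer(header)),
         call. = FALSE)
  }
  conf <- if (score_dialect == "0-1000") s / 1000 else s
  keep <- a != b
  a <- a[keep]; b <- b[keep]; conf <- conf[keep]
  lo <- pmin(a, b); hi2 <- pmax(a, b)
  key <- paste(lo, hi2, sep = "\r")
  best <- tapply(conf, key, max)
  first <- !duplicated(key)
  out <- data.frame(node_a = lo[first], node_b = hi2[first],
                    confidence = as.numeric(best[key[first]]),
                    stringsAsFactors = FALSE)
  out <- out[.radix_order(out$node_a, out$node_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a GMT gene-set collection
#'
#' Tab-separated lines: set name, description, member genes. Set names
#' must be unique and gene lists non-empty; gene symbols are uppercased.
#'
#' @param path file path.
#' @return named list of character vectors with a `descriptions`
#'   attribute; class `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short)) {
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1]), call. = FALSE)
  }
  nm <- vapply(parts, `[`, "", 1)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name: ", nm[duplicated(nm)][1], call. = FALSE)
  }
  desc <- vapply(parts, `[`, "", 2)
  sets <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  empty <- which(!lengths(sets))
  if (length(empty)) {
    stop(sprintf("GMT set '%s' (line %d) has an empty gene list",
                 nm[empty[1]], empty[1]), call. = FALSE)
  }
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(desc, nm)
  class(sets) <- "gene_set_collection"
  sets
}

#' Read / write two-column cohort label TSVs
#'
#' @param labels a [cohort_labels()] object (for writing).
#' @param path file path.
#' @return [cohort_labels()] object (reader) or the path, invisibly
#'   (writer).
#' @export
read_labels_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop("label file must have sample_id and group columns", call. = FALSE)
  }
  cohort_labels(df$sample_id, df$group,
                subtype = if ("subtype" %in% names(df)) df$subtype else NULL)
}

#' @rdname read_labels_tsv
#' @export
write_labels_tsv <- function(labels, path) {
  stopifnot(inherits(labels, "cohort_labels"))
  utils::write.table(as.data.frame(labels), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read lineage scorecards as JSON
#'
#' The JSON array round-trips losslessly through [read_scorecards_json()].
#'
#' @param cards non-empty list of `lineage_scorecard` objects
#'   (see [score_cohort()]).
#' @param path file path.
#' @export
write_scorecards_json <- function(cards, path) {
  if (!length(cards)) stop("no scorecards to write", call. = FALSE)
  payload <- lapply(cards, function(cd) {
    stopifnot(inherits(cd, "lineage_scorecard"))
    list(sample_id = jsonlite::unbox(cd$sample_id),
         normalized = as.list(cd$normalized),
         tes = as.list(cd$tes),
         scores = as.list(cd$scores),
         assigned = as.list(cd$assigned))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scorecards_json
#' @export
read_scorecards_json <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(cd) {
    structure(list(
      sample_id = cd$sample_id,
      normalized = unlist(cd$normalized),
      tes = unlist(cd$tes),
      scores = unlist(cd$scores),
      assigned = as.character(unlist(cd$assigned))),
      class = "lineage_scorecard")
  })
}
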