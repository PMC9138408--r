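#' The hub-gene lineage panel
#'
#' The default panel maps each of the four developmental biases to the
#' hub genes skewed towards it -- myeloid: KIT, HGF, ANPEP, CXCL2;
#' B: NT5E, CXCL2; T: CDH2; unidentified: CD33, IL1B -- with the stemness
#' marker PROM1 as the reference gene. CXCL2 legitimately belongs to both
#' the myeloid and the B sets.
#'
#' @param myeloid,B,T,unidentified character vectors of gene symbols.
#' @param reference reference (stemness) gene; must not occur in any
#'   lineage set.
#' @return named list of class `hub_panel`.
#' @export
hub_panel <- function(myeloid = c("KIT", "HGF", "ANPEP", "CXCL2"),
                      B = c("NT5E", "CXCL2"),
                      T = "CDH2",
                      unidentified = c("CD33", "IL1B"),
                      reference = "PROM1") {
  panel <- list(myeloid = toupper(myeloid), B = toupper(B),
                T = toupper(T), unidentified = toupper(unidentified),
                reference = toupper(reference))
  class(panel) <- "hub_panel"
  validate_hub_panel(panel)
}

#' @rdname hub_panel
#' @param panel object to validate.
#' @export
validate_hub_panel <- function(panel) {
  need <- c("myeloid", "B", "T", "unidentified", "reference")
  if (!is.list(panel) || !all(need %in% names(panel))) {
    stop("hub panel needs myeloid/B/T/unidentified sets and a reference gene",
         call. = FALSE)
  }
  if (length(panel$reference) != 1) {
    stop("exactly one reference gene required", call. = FALSE)
  }
  for (l in c("myeloid", "B", "T", "unidentified")) {
    if (!length(panel[[l]])) {
      stop("lineage set '", l, "' must be non-empty", call. = FALSE)
    }
    if (panel$reference %in% panel[[l]]) {
      stop("reference gene must not belong to lineage set '", l, "'",
           call. = FALSE)
    }
  }
  if (!inherits(panel, "hub_panel")) class(panel) <- "hub_panel"
  panel
}

#' All gene symbols of a panel (lineage genes plus reference)
#'
#' @param panel a `hub_panel`.
#' @return character vector, reference gene last.
#' @export
panel_gene_symbols <- function(panel) {
  panel <- validate_hub_panel(panel)
  c(sort(unique(unlist(panel[c("myeloid", "B", "T", "unidentified")],
                       use.names = FALSE))),
    panel$reference)
}

#' Normalize expression to the cohort mean
#'
#' Each gene's expression is divided by its mean over the cohort samples,
#' so the cohort mean of every normalized gene row is exactly 1. Input
#' must be strictly positive (ratios and geometric means downstream are
#' undefined otherwise; no silent offset is applied).
#'
#' @param expr expression matrix restricted to the genes of interest.
#' @param cohort sample ids defining the normalization population
#'   (default: all columns).
#' @return normalized matrix over the cohort columns.
#' @export
normalize_to_cohort_mean <- function(expr, cohort = colnames(expr)) {
  if (!length(cohort)) stop("empty normalization cohort", call. = FALSE)
  missing <- setdiff(cohort, colnames(expr))
  if (length(missing)) {
    stop("cohort samples absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  x <- expr[, cohort, drop = FALSE]
  validate_expression_matrix(x, require_positive = TRUE)
  m <- rowMeans(x)
  x / m
}

#' Transformed expression scores (reference-ratio transform)
#'
#' Divides every gene's normalized expression by the normalized
#' expression of the reference (stemness) gene within the same sample;
#' the reference row is exactly 1 everywhere.
#'
#' @param normalized matrix from [normalize_to_cohort_mean()].
#' @param reference reference gene symbol (default `"PROM1"`).
#' @return TES matrix of the same shape.
#' @export
transformed_expression_scores <- function(normalized, reference = "PROM1") {
  reference <- toupper(reference)
  if (!reference %in% rownames(normalized)) {
    stop("reference gene absent: ", reference, call. = FALSE)
  }
  ref <- normalized[reference, ]
  if (any(ref <= 0)) {
    stop("non-positive normalized reference expression", call. = FALSE)
  }
  tes <- sweep(normalized, 2, ref, "/")
  tes[reference, ] <- 1
  tes
}

#' Lineage scores for one sample
#'
#' Geometric means of the sample's TES values over each lineage's panel
#' genes: myeloid `(KIT*HGF*ANPEP*CXCL2)^(1/4)`, B `(NT5E*CXCL2)^(1/2)`,
#' T `CDH2`, unidentified `(CD33*IL1B)^(1/2)` under the default panel.
#'
#' @param tes named numeric vector of TES values for one sample.
#' @param panel a [hub_panel()].
#' @return named numeric vector of the four lineage scores, all > 0.
#' @export
lineage_scores <- function(tes, panel = hub_panel()) {
  panel <- validate_hub_panel(panel)
  lineages <- c("myeloid", "B", "T", "unidentified")
  need <- unique(unlist(panel[lineages], use.names = FALSE))
  missing <- setdiff(need, names(tes))
  if (length(missing)) {
    stop("missing TES values for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(tes[need] <= 0) || any(!is.finite(tes[need]))) {
    stop("TES values must be positive and finite", call. = FALSE)
  }
  vapply(panel[lineages],
         function(g) exp(mean(log(tes[g]))),
         numeric(1))
}

#' Assign the lineage-bias set of a sample
#'
#' Every lineage whose score lies within the tolerance band of the
#' sample's maximum lineage score is assigned: with the default relative
#' reading, `L` is assigned iff `score_L >= (1 - tolerance) * max(scores)`
#' (so the maximum itself is always assigned). `mode = "absolute"` uses
#' `score_L >= max(scores) - tolerance` instead.
#'
#' @param scores named numeric vector of lineage scores, all > 0.
#' @param tolerance band width (default 0.10).
#' @param mode `"relative"` (default) or `"absolute"`.
#' @return character vector of assigned lineages (panel order).
#' @export
assign_lineages <- function(scores, tolerance = 0.10,
                            mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  if (tolerance < 0 || tolerance >= 1) {
    stop("tolerance must lie in [0, 1)", call. = FALSE)
  }
  if (any(scores <= 0) || any(!is.finite(scores))) {
    stop("lineage scores must be positive and finite", call. = FALSE)
  }
  mx <- max(scores)
  cut <- if (mode == "relative") (1 - tolerance) * mx else mx - tolerance
  names(scores)[scores >= cut]
}

#' Score a cohort of ETP samples for lineage bias
#'
#' The full per-sample scoring chain: restrict the matrix to the panel
#' genes, normalize each gene to its mean over the scored population
#' (the ETP cohort by default; `population = "all"` normalizes over every
#' labelled sample instead), transform to reference-ratio TES values,
#' aggregate to the four lineage scores by geometric means, and assign
#' the lineage-bias set of each sample.
#'
#' @param expr expression matrix (strictly positive for the panel genes).
#' @param labels a [cohort_labels()] object.
#' @param panel a [hub_panel()].
#' @param tolerance assignment band, see [assign_lineages()].
#' @param population `"scored"` (ETP cohort mean, default) or `"all"`.
#' @param mode tolerance mode, see [assign_lineages()].
#' @return list of `lineage_scorecard` objects, one per ETP sample, each
#'   with `sample_id`, `normalized`, `tes`, `scores`, `assigned`.
#' @export
score_cohort <- function(expr, labels, panel = hub_panel(),
                         tolerance = 0.10,
                         population = c("scored", "all"),
                         mode = c("relative", "absolute")) {
  population <- match.arg(population)
  mode <- match.arg(mode)
  panel <- validate_hub_panel(panel)
  validate_expression_matrix(expr)
  genes <- panel_gene_symbols(panel)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) {
    stop("panel genes absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  etp <- intersect(colnames(expr), group_samples(labels, "ETP"))
  if (!length(etp)) stop("no ETP samples to score", call. = FALSE)
  norm_pop <- if (population == "scored") etp else {
    intersect(colnames(expr), labels$sample_id)
  }
  normalized <- normalize_to_cohort_mean(expr[genes, , drop = FALSE],
                                         cohort = norm_pop)
  tes <- transformed_expression_scores(normalized, panel$reference)
  lapply(etp, function(s) {
    sc <- lineage_scores(tes[, s], panel)
    structure(list(sample_id = s,
                   normalized = normalized[, s],
                   tes = tes[, s],
                   scores = sc,
                   assigned = assign_lineages(sc, tolerance, mode)),
              class = "lineage_scorecard")
  })
}

#' Tabulate scorecards
#'
#' @param cards list of `lineage_scorecard` objects.
#' @return data.frame with one row per sample: the four lineage scores
#'   and the assigned set (`+`-joined).
#' @export
scorecards_table <- function(cards) {
  stopifnot(length(cards) > 0)
  do.call(rbind, lapply(cards, function(cd) {
    data.frame(sample_id = cd$sample_id,
               myeloid = cd$scores[["myeloid"]],
               B = cd$scores[["B"]],
               T = cd$scores[["T"]],
               unidentified = cd$scores[["unidentified"]],
               assigned = paste(cd$assigned, collapse = "+"),
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.lineage_scorecard <- function(x, ...) {
  cat("Lineage scorecard:", x$sample_id, "\n")
  cat("  scores:",
      paste(sprintf("%s=%.3f", names(x$scores), x$scores), collapse = "  "),
      "\n")
  cat("  assigned:", paste(x$assigned, collapse = " + "), "\n")
  invisible(x)
}
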