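#' Lineage marker panel for association analyses
#'
#' Known hematopoietic markers used to anchor the hub genes to lineages:
#' stemness CD34; myelo-monocytic CEBPA, CSF3R; B-lineage EBF1, PAX5,
#' CD19, CD79A; T-lineage CD7, HES1, BCL11B, CD1A; dendritic SPI1, ITGAX,
#' IRF8, TCF4. Unlike the scoring panel, a gene may appear in only one
#' lineage here.
#'
#' @param ... named character vectors overriding the default lineages.
#' @return named list of class `marker_panel`.
#' @export
marker_panel <- function(...) {
  panel <- list(stemness = "CD34",
                myelomonocytic = c("CEBPA", "CSF3R"),
                B = c("EBF1", "PAX5", "CD19", "CD79A"),
                T = c("CD7", "HES1", "BCL11B", "CD1A"),
                dendritic = c("SPI1", "ITGAX", "IRF8", "TCF4"))
  override <- list(...)
  panel[names(override)] <- lapply(override, toupper)
  panel <- lapply(panel, toupper)
  if (any(!lengths(panel))) stop("marker sets must be non-empty", call. = FALSE)
  all_genes <- unlist(panel, use.names = FALSE)
  if (anyDuplicated(all_genes)) {
    stop("a marker may belong to one lineage only: ",
         all_genes[duplicated(all_genes)][1], call. = FALSE)
  }
  class(panel) <- "marker_panel"
  panel
}

#' Normalize genes to a reference group's mean
#'
#' Divides each selected gene's expression by its mean over the reference
#' group's samples (e.g. the non-ETP cohort), yielding fold-change-like
#' co-expression values comparable across genes.
#'
#' @param expr expression matrix.
#' @param genes gene symbols to normalize.
#' @param reference_samples sample ids of the reference group.
#' @return normalized matrix (selected genes x all samples of `expr`).
#' @export
normalize_to_reference_group <- function(expr, genes, reference_samples) {
  validate_expression_matrix(expr)
  genes <- toupper(genes)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) {
    stop("genes absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ref <- intersect(colnames(expr), reference_samples)
  if (!length(ref)) stop("empty reference group", call. = FALSE)
  m <- rowMeans(expr[genes, ref, drop = FALSE])
  if (any(m == 0)) {
    stop("zero reference mean for gene ", genes[m == 0][1], call. = FALSE)
  }
  expr[genes, , drop = FALSE] / m
}

#' PCA map of genes over a cohort
#'
#' Genes are the observations (rows), samples the variables. Rows are
#' centered (each gene's mean over the cohort removed) so proximity on
#' the map reflects co-expression pattern rather than expression level;
#' optionally rows are scaled to unit variance. Coordinates are the
#' projections onto the top `n_components` principal axes, each axis
#' sign-fixed so its largest-magnitude loading is positive.
#'
#' @param normalized genes x samples matrix (>= 3 genes, >= 3 samples),
#'   typically from [normalize_to_reference_group()].
#' @param n_components number of axes to return (default 2).
#' @param scale_rows scale each centered row to unit variance?
#' @return list with `coordinates` (genes x components), `loadings`
#'   (samples x components), `explained_variance` (fractions over all
#'   components, non-increasing).
#' @export
pca_gene_map <- function(normalized, n_components = 2, scale_rows = FALSE) {
  x <- as.matrix(normalized)
  if (nrow(x) < 3 || ncol(x) < 3) {
    stop("need at least 3 genes and 3 samples", call. = FALSE)
  }
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant gene row: ", rownames(x)[sds == 0][1], call. = FALSE)
  }
  xc <- x - rowMeans(x)
  if (scale_rows) xc <- xc / sds
  sv <- svd(xc)
  k <- length(sv$d)
  scores <- sv$u %*% diag(sv$d, k, k)
  loadings <- sv$v
  # sign convention: largest-|loading| entry of each axis positive
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- sv$d^2 / sum(sv$d^2)
  nc <- min(n_components, k)
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(k)))
  list(coordinates = scores[, seq_len(nc), drop = FALSE],
       loadings = loadings[, seq_len(nc), drop = FALSE],
       explained_variance = ev)
}

#' Nearest-lineage-centroid labels on a PCA map
#'
#' A reproducible surrogate for manually drawn lineage demarcation
#' boundaries: each gene is labelled with the lineage whose member-gene
#' centroid (over the marker panel genes present on the map) is nearest
#' in the component space.
#'
#' @param coordinates genes x components matrix from [pca_gene_map()].
#' @param panel a [marker_panel()].
#' @return data.frame with `gene` and `nearest_lineage`.
#' @export
nearest_lineage_centroids <- function(coordinates, panel = marker_panel()) {
  cents <- lapply(panel, function(g) {
    g <- intersect(g, rownames(coordinates))
    if (!length(g)) return(NULL)
    colMeans(coordinates[g, , drop = FALSE])
  })
  cents <- cents[!vapply(cents, is.null, TRUE)]
  if (!length(cents)) stop("no panel genes on the map", call. = FALSE)
  cm <- do.call(rbind, cents)
  lab <- apply(coordinates, 1, function(pt) {
    rownames(cm)[which.min(colSums((t(cm) - pt)^2))]
  })
  data.frame(gene = rownames(coordinates), nearest_lineage = unname(lab),
             stringsAsFactors = FALSE)
}

#' Split a cohort at a gene's mean expression
#'
#' High group: samples with expression strictly above the cohort mean of
#' the gene; low group: the rest. Both groups are returned even if one is
#' empty.
#'
#' @param expr expression matrix.
#' @param cohort sample ids to bisect (>= 2).
#' @param gene gene symbol.
#' @return list with `high` and `low` character vectors of sample ids.
#' @export
bisect_cohort_by_gene <- function(expr, cohort, gene) {
  gene <- toupper(gene)
  if (!gene %in% rownames(expr)) {
    stop("gene absent from matrix: ", gene, call. = FALSE)
  }
  cohort <- intersect(colnames(expr), cohort)
  if (length(cohort) < 2) stop("cohort needs >= 2 samples", call. = FALSE)
  v <- expr[gene, cohort]
  m <- mean(v)
  list(high = cohort[v > m], low = cohort[v <= m])
}

#' Compare marker expression between two sample groups
#'
#' Per-marker two-tailed unpaired t-test ([welch_t_test()]) with BH
#' adjustment over the supplied marker list only (mirroring per-figure
#' comparisons). A `band` column flags significance: `"significant"`
#' (p < 0.05), `"quasi"` (0.05 < p < 0.1) or `"ns"`.
#'
#' @param expr expression matrix.
#' @param group_a,group_b sample id vectors (>= 2 each).
#' @param markers marker gene symbols, all present in the matrix.
#' @return data.frame with `gene`, `mean_a`, `mean_b`, `t`, `p`, `q`,
#'   `band`.
#' @export
compare_markers <- function(expr, group_a, group_b, markers) {
  validate_expression_matrix(expr)
  markers <- toupper(markers)
  missing <- setdiff(markers, rownames(expr))
  if (length(missing)) {
    stop("markers absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  a <- intersect(colnames(expr), group_a)
  b <- intersect(colnames(expr), group_b)
  if (length(a) < 2 || length(b) < 2) {
    stop("both groups need >= 2 samples", call. = FALSE)
  }
  rows <- lapply(markers, function(g) {
    ht <- welch_t_test(expr[g, a], expr[g, b])
    data.frame(gene = g, mean_a = mean(expr[g, a]), mean_b = mean(expr[g, b]),
               t = ht$t, p = ht$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$band <- ifelse(out$p < 0.05, "significant",
                     ifelse(out$p < 0.1, "quasi", "ns"))
  out
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation in the query list using
#' the upper-tail hypergeometric probability of observing at least the
#' attained overlap, with every set first intersected with the
#' background. Results are filtered by `p < p_thresh` and
#' `overlap >= min_overlap` and sorted by p.
#'
#' @param query gene symbols of interest (must be a subset of
#'   `background`).
#' @param background universe of gene symbols.
#' @param sets a `gene_set_collection` (see [read_gmt()]) or named list
#'   of character vectors.
#' @param p_thresh strict p-value gate (default 0.01).
#' @param min_overlap minimal overlap, inclusive (default 6,
#'   i.e. "overlap > 5 genes").
#' @param filter apply the gates? `FALSE` returns every set's result.
#' @return data.frame with `set`, `overlap`, `set_size`, `query_size`,
#'   `background_size`, `p`.
#' @export
ora_hypergeometric <- function(query, background, sets, p_thresh = 0.01,
                               min_overlap = 6, filter = TRUE) {
  query <- unique(toupper(query))
  background <- unique(toupper(background))
  stray <- setdiff(query, background)
  if (length(stray)) {
    stop("query genes outside background: ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  }
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(toupper(sets[[nm]])), background)
    K <- length(s)
    k <- length(intersect(s, query))
    p <- if (K == 0) 1 else stats::phyper(k - 1, K, N - K, n,
                                          lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, query_size = n,
               background_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (filter) {
    out <- out[out$p < p_thresh & out$overlap >= min_overlap, , drop = FALSE]
  }
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
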