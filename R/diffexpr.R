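#' Two-sample t-test (Welch by default)
#'
#' Closed-form two-tailed unpaired t-test. The Welch (unequal-variance)
#' form is the default; `var_equal = TRUE` gives the classical pooled
#' Student test. Degenerate input where both groups have zero variance is
#' reported as no evidence (`t = 0`, `p = 1`) rather than an error, so
#' cohort-level scans over thousands of genes never abort on flat rows.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param var_equal use the pooled-variance Student form?
#' @return list with `t`, `df` and two-sided `p`.
#' @export
welch_t_test <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values in t-test input", call. = FALSE)
  }
  nx <- length(x); ny <- length(y)
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    return(list(t = 0, df = NA_real_, p = 1))
  }
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- (mx - my) / se
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(t = t, df = df, p = max(p, .Machine$double.xmin))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the input and applies the BH step-up procedure (via
#' [stats::p.adjust()]): adjusted values are clipped at 1, monotone
#' non-decreasing in sorted-p order, and returned in the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of BH-adjusted values (q-values).
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Two-group differential expression
#'
#' Per-gene two-tailed unpaired t-test of ETP versus non-ETP samples with
#' BH FDR adjustment. Input values are log2 scale, so the fold-change gate
#' `fc_thresh = 2` is applied as `|log2FC| > 1` (strict, as are all
#' thresholds). A gene is `UP` iff `log2fc > log2(fc_thresh)` and
#' `q < fdr_thresh`; `DOWN` symmetric; otherwise `NS`. Genes with zero
#' variance in both groups are reported `NS` with `p = 1`.
#'
#' @param expr expression matrix (genes x samples, log2 scale).
#' @param labels a [cohort_labels()] object covering the samples.
#' @param fc_thresh linear fold-change threshold (default 2).
#' @param fdr_thresh FDR threshold (default 0.1).
#' @param var_equal pooled-variance Student test instead of Welch?
#' @return data.frame with columns `gene`, `mean_etp`, `mean_nonetp`,
#'   `log2fc`, `t`, `df`, `p`, `q`, `status`.
#' @export
differential_expression <- function(expr, labels, fc_thresh = 2,
                                    fdr_thresh = 0.1, var_equal = FALSE) {
  validate_expression_matrix(expr)
  .check_groups(expr, labels, min_n = 2)
  etp <- intersect(colnames(expr), group_samples(labels, "ETP"))
  non <- intersect(colnames(expr), group_samples(labels, "NONETP"))
  x <- expr[, etp, drop = FALSE]
  y <- expr[, non, drop = FALSE]
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- rep(nx + ny - 2, length(se))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- (mx - my) / se
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  flat <- se == 0
  t[flat] <- 0
  df[flat] <- NA_real_
  p[flat] <- 1
  q <- bh_adjust(p)
  lfc <- mx - my
  lgate <- log2(fc_thresh)
  status <- rep("NS", length(lfc))
  status[lfc > lgate & q < fdr_thresh] <- "UP"
  status[lfc < -lgate & q < fdr_thresh] <- "DOWN"
  data.frame(gene = rownames(expr), mean_etp = mx, mean_nonetp = my,
             log2fc = lfc, t = t, df = df, p = p, q = q, status = status,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a differential-expression table as TSV
#'
#' @param de result of [differential_expression()].
#' @param path output path.
#' @export
write_de_tsv <- function(de, path) {
  cols <- c("gene", "mean_etp", "mean_nonetp", "log2fc", "t", "df", "p",
            "q", "status")
  utils::write.table(de[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Select variably expressed genes within a group
#'
#' Genes whose sample standard deviation (n-1 denominator) across the
#' group's samples strictly exceeds `sd_thresh` (default 2 log2 units).
#'
#' @param expr expression matrix.
#' @param labels a [cohort_labels()] object.
#' @param group group whose samples define the spread (default `"ETP"`).
#' @param sd_thresh strict sd threshold (log2 units).
#' @return data.frame with columns `gene` and `sd`, plus attributes
#'   `threshold` and `group`.
#' @export
select_variable_genes <- function(expr, labels, group = "ETP",
                                  sd_thresh = 2) {
  validate_expression_matrix(expr)
  ids <- intersect(colnames(expr), group_samples(labels, group))
  if (length(ids) < 2) {
    stop("group ", group, " needs at least 2 samples in the matrix",
         call. = FALSE)
  }
  x <- expr[, ids, drop = FALSE]
  sds <- sqrt(rowSums((x - rowMeans(x))^2) / (ncol(x) - 1))
  keep <- sds > sd_thresh
  out <- data.frame(gene = rownames(expr)[keep], sd = unname(sds[keep]),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- sd_thresh
  attr(out, "group") <- group
  out
}

#' Intersect differential and variable signatures
#'
#' Intersects the up- and down-regulated gene sets with the variably
#' expressed set and returns the two intersections plus their union --
#' the signature from which the interaction network is built.
#'
#' @param up,down disjoint gene-symbol sets (from DE status).
#' @param variable variably expressed gene-symbol set.
#' @return list with `up_variable`, `down_variable`, `union`.
#' @export
intersect_signatures <- function(up, down, variable) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  variable <- unique(as.character(variable))
  clash <- intersect(up, down)
  if (length(clash)) {
    stop("genes flagged both UP and DOWN: ",
         paste(utils::head(clash, 5), collapse = ", "), call. = FALSE)
  }
  uv <- sort(intersect(up, variable))
  dv <- sort(intersect(down, variable))
  list(up_variable = uv, down_variable = dv, union = sort(c(uv, dv)))
}

#' Pairwise Pearson correlation between samples
#'
#' @param expr expression matrix with >= 2 genes.
#' @return symmetric sample-by-sample correlation matrix with unit
#'   diagonal.
#' @export
pairwise_sample_correlation <- function(expr) {
  validate_expression_matrix(expr)
  if (nrow(expr) < 2) stop("need at least 2 genes", call. = FALSE)
  sds <- apply(expr, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance sample: ", colnames(expr)[sds == 0][1], call. = FALSE)
  }
  stats::cor(expr)
}

#' Compare within-group correlation coefficients between cohorts
#'
#' Extracts the upper-triangle pairwise correlation coefficients within
#' the ETP and within the non-ETP group and compares the two coefficient
#' distributions with [welch_t_test()] (the transcriptome-tightness
#' contrast of the two cohorts).
#'
#' @param corr sample correlation matrix from
#'   [pairwise_sample_correlation()].
#' @param labels a [cohort_labels()] object.
#' @return list with `etp_coefficients`, `nonetp_coefficients`, `t`, `p`.
#' @export
intragroup_correlation_compare <- function(corr, labels) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  pull <- function(g) {
    ids <- intersect(colnames(corr), group_samples(labels, g))
    if (length(ids) < 2) {
      stop("group ", g, " needs at least 2 samples", call. = FALSE)
    }
    m <- corr[ids, ids, drop = FALSE]
    m[upper.tri(m)]
  }
  a <- pull("ETP")
  b <- pull("NONETP")
  ht <- welch_t_test(a, b)
  list(etp_coefficients = a, nonetp_coefficients = b, t = ht$t, p = ht$p)
}
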