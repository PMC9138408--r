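#' Configuration for the synthetic leukemia cohort generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: two sample groups (ETP vs non-ETP) on a normalized log2
#' intensity scale, a set of planted up/down-regulated genes, a set of genes
#' with inflated within-ETP variance, and a hub panel whose genes are
#' boosted in samples of their latent hematopoietic lineage.
#'
#' Defaults follow the discovery-cohort conditions of the analysis this
#' package implements: 12 ETP and 40 non-ETP samples, 75 planted
#' up-regulated and 33 down-regulated genes, log2 baselines in `[4, 10]`.
#'
#' @param n_etp,n_nonetp sample counts per group.
#' @param n_genes total number of genes (including the hub panel).
#' @param baseline_mean_range bounds for per-gene baseline means
#'   (log2 intensity); the lower bound should stay >= 4 so values remain
#'   strictly positive.
#' @param noise_sd per-measurement Gaussian noise sd (log2 units).
#' @param n_up,n_down counts of planted group-shifted genes.
#' @param de_shift log2 shift added (up) / subtracted (down) in ETP samples.
#' @param n_variance_inflated count of genes whose within-ETP sd is
#'   inflated.
#' @param inflation_factor multiplier (> 1) on `noise_sd` within ETP for
#'   variance-inflated genes.
#' @param hub_panel lineage panel (see [hub_panel()]); its genes are added
#'   as dedicated rows of the matrix.
#' @param lineage_boost log2 units added to a hub gene in ETP samples of a
#'   lineage that contains it. The reference gene carries no boost.
#' @param lineage_probs probability vector over the four lineages
#'   (myeloid, B, T, unidentified); must sum to 1.
#' @param mixed_prob probability that an ETP sample receives a second,
#'   distinct lineage label (mixed skew); 0 disables mixing.
#' @param seed integer RNG seed.
#' @return a list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_etp = 12, n_nonetp = 40, n_genes = 2000,
                              baseline_mean_range = c(4, 10),
                              noise_sd = 0.5,
                              n_up = 75, n_down = 33, de_shift = 2,
                              n_variance_inflated = 150,
                              inflation_factor = 5,
                              hub_panel = etplineage::hub_panel(),
                              lineage_boost = 2,
                              lineage_probs = c(myeloid = 0.4, B = 0.3,
                                                T = 0.1, unidentified = 0.2),
                              mixed_prob = 0,
                              seed = 1L) {
  counts <- c(n_etp = n_etp, n_nonetp = n_nonetp, n_genes = n_genes,
              n_up = n_up, n_down = n_down,
              n_variance_inflated = n_variance_inflated)
  if (any(counts < 0)) stop("all counts must be >= 0", call. = FALSE)
  if (length(baseline_mean_range) != 2 || diff(baseline_mean_range) < 0) {
    stop("baseline_mean_range must be increasing bounds", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (de_shift < 0) stop("de_shift must be >= 0", call. = FALSE)
  if (inflation_factor <= 1) stop("inflation_factor must be > 1", call. = FALSE)
  panel <- validate_hub_panel(hub_panel)
  lineages <- c("myeloid", "B", "T", "unidentified")
  if (!setequal(names(lineage_probs), lineages)) {
    stop("lineage_probs must be named over myeloid/B/T/unidentified",
         call. = FALSE)
  }
  lineage_probs <- lineage_probs[lineages]
  if (any(lineage_probs < 0) || abs(sum(lineage_probs) - 1) > 1e-9) {
    stop("lineage_probs must be non-negative and sum to 1", call. = FALSE)
  }
  if (mixed_prob < 0 || mixed_prob >= 1) {
    stop("mixed_prob must lie in [0, 1)", call. = FALSE)
  }
  panel_genes <- panel_gene_symbols(panel)
  if (n_up + n_down + n_variance_inflated + length(panel_genes) > n_genes) {
    stop("planted gene budgets (up + down + variance-inflated + hub panel) exceed n_genes",
         call. = FALSE)
  }
  structure(list(n_etp = n_etp, n_nonetp = n_nonetp, n_genes = n_genes,
                 baseline_mean_range = baseline_mean_range,
                 noise_sd = noise_sd, n_up = n_up, n_down = n_down,
                 de_shift = de_shift,
                 n_variance_inflated = n_variance_inflated,
                 inflation_factor = inflation_factor,
                 hub_panel = panel, lineage_boost = lineage_boost,
                 lineage_probs = lineage_probs, mixed_prob = mixed_prob,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Simulate an expression cohort with known ground truth
#'
#' Expression is drawn directly on the log2 scale: per-gene baselines are
#' uniform over `baseline_mean_range`, measurement noise is Gaussian.
#' Planted up (down) genes have their ETP-group mean shifted by
#' `+de_shift` (`-de_shift`); variance-inflated genes have within-ETP
#' noise sd `inflation_factor * noise_sd`; each ETP sample carries a latent
#' lineage label drawn from `lineage_probs`, and hub-panel genes of that
#' lineage are boosted by `lineage_boost`. The reference gene (PROM1 by
#' default) is never boosted. Values are floored at 0.1 so the matrix is
#' strictly positive. A single seeded RNG stream drives all draws in a
#' fixed order (baselines, noise, lineage labels), so identical configs
#' give bit-identical cohorts.
#'
#' @param config a [cohort_sim_config()].
#' @return list with elements `expr` (gene x sample matrix), `labels`
#'   (a [cohort_labels()] object) and `truth` (list: `up_genes`,
#'   `down_genes`, `variance_genes`, `sample_lineage`, `sample_lineage2`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  panel <- config$hub_panel
  panel_genes <- panel_gene_symbols(panel)
  n_other <- config$n_genes - length(panel_genes)
  other <- sprintf("GENE%05d", seq_len(n_other))
  genes <- c(panel_genes, other)
  samples <- c(sprintf("ETP%03d", seq_len(config$n_etp)),
               sprintf("NON%03d", seq_len(config$n_nonetp)))
  etp_idx <- seq_len(config$n_etp)
  n_samp <- length(samples)

  # planted sets are taken deterministically from the non-panel genes
  up_genes <- other[seq_len(config$n_up)]
  down_genes <- other[config$n_up + seq_len(config$n_down)]
  var_genes <- other[config$n_up + config$n_down +
                       seq_len(config$n_variance_inflated)]

  lineages <- c("myeloid", "B", "T", "unidentified")
  res <- .with_seed(config$seed, {
    baseline <- stats::runif(config$n_genes,
                             config$baseline_mean_range[1],
                             config$baseline_mean_range[2])
    noise <- matrix(stats::rnorm(config$n_genes * n_samp, sd = config$noise_sd),
                    nrow = config$n_genes)
    lin1 <- sample(lineages, config$n_etp, replace = TRUE,
                   prob = config$lineage_probs)
    lin2 <- rep(NA_character_, config$n_etp)
    if (config$mixed_prob > 0 && config$n_etp > 0) {
      mix <- stats::runif(config$n_etp) < config$mixed_prob
      for (i in which(mix)) {
        rest <- setdiff(lineages, lin1[i])
        lin2[i] <- sample(rest, 1)
      }
    }
    list(baseline = baseline, noise = noise, lin1 = lin1, lin2 = lin2)
  })

  expr <- res$baseline + res$noise
  dimnames(expr) <- list(genes, samples)

  if (config$n_variance_inflated > 0 && config$n_etp > 0) {
    vi <- match(var_genes, genes)
    expr[vi, etp_idx] <- res$baseline[vi] +
      res$noise[vi, etp_idx, drop = FALSE] * config$inflation_factor
  }
  if (config$n_up > 0) {
    expr[match(up_genes, genes), etp_idx] <-
      expr[match(up_genes, genes), etp_idx, drop = FALSE] + config$de_shift
  }
  if (config$n_down > 0) {
    expr[match(down_genes, genes), etp_idx] <-
      expr[match(down_genes, genes), etp_idx, drop = FALSE] - config$de_shift
  }
  if (config$lineage_boost != 0 && config$n_etp > 0) {
    boostable <- setdiff(panel_genes, panel$reference)
    for (i in etp_idx) {
      labs <- c(res$lin1[i], res$lin2[i])
      labs <- labs[!is.na(labs)]
      tg <- intersect(unique(unlist(panel[labs], use.names = FALSE)), boostable)
      if (length(tg)) {
        expr[match(tg, genes), i] <- expr[match(tg, genes), i] + config$lineage_boost
      }
    }
  }
  expr <- pmax(expr, 0.1)

  labels <- cohort_labels(samples,
                          rep(c("ETP", "NONETP"),
                              c(config$n_etp, config$n_nonetp)))
  truth <- list(up_genes = up_genes, down_genes = down_genes,
                variance_genes = var_genes,
                sample_lineage = stats::setNames(res$lin1,
                                                 samples[etp_idx]),
                sample_lineage2 = stats::setNames(res$lin2,
                                                  samples[etp_idx]))
  validate_expression_matrix(expr, require_positive = TRUE)
  list(expr = expr, labels = labels, truth = truth)
}

#' Simulate an interaction network with planted hub cliques
#'
#' Each planted hub node (`HUB001`, ...) is embedded in a dedicated clique
#' of `clique_size` nodes; every remaining node pair receives an edge
#' independently with `background_edge_prob`. All edge confidences are 1.0.
#' The result is a simple graph (no self-loops, no parallel edges),
#' reproducible under `seed`.
#'
#' @param n_nodes total node count.
#' @param planted_hubs number of planted hub cliques.
#' @param clique_size size of each planted clique (>= 3).
#' @param background_edge_prob probability of a background edge.
#' @param seed integer RNG seed.
#' @return list with `network` (an igraph object with a `confidence` edge
#'   attribute) and `truth` (list with `planted_hubs`, `clique_members`).
#' @export
generate_network <- function(n_nodes, planted_hubs = 0, clique_size = 3,
                             background_edge_prob = 0, seed = 1L) {
  if (background_edge_prob < 0 || background_edge_prob > 1) {
    stop("background_edge_prob must lie in [0, 1]", call. = FALSE)
  }
  if (planted_hubs > 0 && clique_size < 3) {
    stop("clique_size must be >= 3", call. = FALSE)
  }
  if (planted_hubs * clique_size > n_nodes) {
    stop("planted cliques exceed n_nodes", call. = FALSE)
  }
  if (n_nodes == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(list(network = g,
                truth = list(planted_hubs = character(0),
                             clique_members = list())))
  }
  hubs <- if (planted_hubs > 0) sprintf("HUB%03d", seq_len(planted_hubs)) else character(0)
  n_fill <- n_nodes - planted_hubs
  fill <- if (n_fill > 0) sprintf("NODE%04d", seq_len(n_fill)) else character(0)
  nodes <- c(hubs, fill)

  clique_members <- list()
  in_clique <- matrix(FALSE, n_nodes, n_nodes)
  edges <- character(0)
  fill_cursor <- 0
  for (h in seq_len(planted_hubs)) {
    members <- c(hubs[h], fill[fill_cursor + seq_len(clique_size - 1)])
    fill_cursor <- fill_cursor + clique_size - 1
    clique_members[[hubs[h]]] <- members
    idx <- match(members, nodes)
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (a < b) in_clique[idx[a], idx[b]] <- TRUE
      }
    }
    pairs <- utils::combn(members, 2)
    edges <- c(edges, as.vector(pairs))
  }

  if (background_edge_prob > 0 && n_nodes >= 2) {
    bg <- .with_seed(seed, {
      pr <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
      keep <- stats::runif(nrow(pr)) < background_edge_prob
      pr[keep & !in_clique[pr], , drop = FALSE]
    })
    if (nrow(bg)) {
      edges <- c(edges, as.vector(rbind(nodes[bg[, 1]], nodes[bg[, 2]])))
    }
  }

  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(nodes)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  g <- igraph::simplify(g)
  igraph::E(g)$confidence <- rep(1.0, igraph::ecount(g))
  list(network = g,
       truth = list(planted_hubs = hubs, clique_members = clique_members))
}

#' Write a simulated cohort to disk
#'
#' Serializes the expression matrix as TSV (genes in rows, header row of
#' sample ids), the labels as two-column TSV and the ground truth as JSON.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expr = file.path(dir, "expression.tsv"),
             labels = file.path(dir, "labels.tsv"),
             truth = file.path(dir, "truth.json"))
  write_expression_tsv(cohort$expr, paths[["expr"]])
  write_labels_tsv(cohort$labels, paths[["labels"]])
  truth <- cohort$truth
  truth$sample_lineage <- as.list(truth$sample_lineage)
  truth$sample_lineage2 <- as.list(truth$sample_lineage2)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(paths)
}
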