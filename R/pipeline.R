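#' Pipeline configuration
#'
#' Bundles every threshold of the discovery -> validation -> scoring
#' workflow, defaulting to the analysis' printed values: fold-change
#' gate 2, FDR 0.1, within-ETP sd gate 2, STRING confidence cutoff 0.4,
#' top 10 hubs, assignment tolerance 0.10.
#'
#' @param fc_thresh linear fold-change gate for DE.
#' @param fdr_thresh FDR gate for DE.
#' @param sd_thresh within-ETP sd gate for variable genes.
#' @param confidence_cutoff interaction-confidence cutoff.
#' @param top_k number of hub genes.
#' @param tolerance lineage-assignment band.
#' @param validation_fdr significance gate for the validation flag.
#' @param cutoff_rule ROC cutoff rule (see [optimal_cutoff()]).
#' @param seed integer seed recorded into provenance.
#' @param paths optional named list of input file paths (expression,
#'   labels, edges, gmt, panel).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(fc_thresh = 2, fdr_thresh = 0.1, sd_thresh = 2,
                            confidence_cutoff = 0.4, top_k = 10,
                            tolerance = 0.10, validation_fdr = 0.05,
                            cutoff_rule = "youden",
                            seed = 1L, paths = list()) {
  thresholds <- c(fc_thresh = fc_thresh, fdr_thresh = fdr_thresh,
                  sd_thresh = sd_thresh,
                  confidence_cutoff = confidence_cutoff,
                  top_k = top_k, tolerance = tolerance,
                  validation_fdr = validation_fdr)
  if (any(thresholds <= 0)) stop("all thresholds must be positive", call. = FALSE)
  structure(list(fc_thresh = fc_thresh, fdr_thresh = fdr_thresh,
                 sd_thresh = sd_thresh,
                 confidence_cutoff = confidence_cutoff, top_k = top_k,
                 tolerance = tolerance, validation_fdr = validation_fdr,
                 cutoff_rule = cutoff_rule,
                 seed = as.integer(seed), paths = paths),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path YAML file path.
#' @param config a `pipeline_config` (for writing).
#' @return `pipeline_config` (reader) or the path, invisibly (writer).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.write_provenance <- function(dir, config, stage) {
  jsonlite::write_json(
    list(stage = stage,
         package = "etplineage",
         version = as.character(utils::packageVersion("etplineage")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         config = unclass(config)),
    file.path(dir, paste0(stage, "_provenance.json")),
    auto_unbox = TRUE, null = "null")
}

#' Discovery stage: differential + variable genes, network, hubs
#'
#' Chains [differential_expression()] -> [select_variable_genes()] ->
#' [intersect_signatures()] -> [build_network()] (universe = the
#' signature union) -> [mcc_scores()] -> [top_hubs()]. An edge list whose
#' every edge falls below the confidence cutoff yields an empty network
#' and an empty hub list with an explicit warning rather than an error.
#'
#' @param expr discovery expression matrix.
#' @param labels a [cohort_labels()] object.
#' @param edges interaction edge list (see [read_edge_list()]).
#' @param config a [pipeline_config()].
#' @param output_dir if non-NULL, all intermediates are persisted there
#'   as TSV plus a provenance JSON.
#' @return list with `de`, `variable`, `signature`, `network`, `ranking`,
#'   `hubs`.
#' @export
run_discovery <- function(expr, labels, edges, config = pipeline_config(),
                          output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  de <- differential_expression(expr, labels, config$fc_thresh,
                                config$fdr_thresh)
  variable <- select_variable_genes(expr, labels, "ETP", config$sd_thresh)
  signature <- intersect_signatures(de$gene[de$status == "UP"],
                                    de$gene[de$status == "DOWN"],
                                    variable$gene)
  if (!length(signature$union)) {
    stop("discovery stage [signature]: no genes pass both the differential and the variability gates",
         call. = FALSE)
  }
  network <- build_network(edges, signature$union, config$confidence_cutoff)
  if (igraph::vcount(network) == 0) {
    warning("discovery stage [network]: no interactions at confidence >= ",
            config$confidence_cutoff, " among the signature genes; ",
            "hub list is empty", call. = FALSE)
    ranking <- structure(
      data.frame(gene = character(0), mcc = numeric(0),
                 degree = numeric(0), rank = integer(0)),
      class = c("hub_ranking", "data.frame"))
    hubs <- character(0)
  } else {
    ranking <- mcc_scores(network)
    hubs <- top_hubs(ranking, config$top_k)
  }
  out <- list(de = de, variable = variable, signature = signature,
              network = network, ranking = ranking, hubs = hubs)
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    write_de_tsv(de, file.path(output_dir, "differential_expression.tsv"))
    utils::write.table(variable, file.path(output_dir, "variable_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(signature$union, file.path(output_dir, "signature_union.txt"))
    write_network_tsv(network, file.path(output_dir, "network_edges.tsv"))
    write_ranking_tsv(ranking, file.path(output_dir, "hub_ranking.tsv"))
    writeLines(hubs, file.path(output_dir, "top_hubs.txt"))
    .write_provenance(output_dir, config, "discovery")
  }
  out
}

#' Validation stage: per-hub significance and classifier quality
#'
#' For each hub gene present in the validation matrix: a two-tailed
#' unpaired t-test between the groups (BH-adjusted over the hub list) and
#' a [evaluate_biomarker()] run. Direction defaults from the sign of the
#' group mean difference (higher in ETP -> `HIGH_IN_ETP`), overridable
#' per gene. `validated` flags hubs with `q` below the configured gate.
#' Hubs missing from the matrix are skipped with a warning.
#'
#' @param expr validation expression matrix.
#' @param labels a [cohort_labels()] object.
#' @param hubs character vector of hub genes (non-empty).
#' @param config a [pipeline_config()].
#' @param directions optional named vector of `"HIGH_IN_ETP"` /
#'   `"LOW_IN_ETP"` per gene.
#' @param output_dir optional persistence directory.
#' @return data.frame with per-hub statistics, AUC, cutoff, confusion
#'   percentages and the `validated` flag.
#' @export
run_validation <- function(expr, labels, hubs, config = pipeline_config(),
                           directions = NULL, output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!length(hubs)) stop("empty hub list", call. = FALSE)
  hubs <- toupper(hubs)
  present <- intersect(hubs, rownames(expr))
  absent <- setdiff(hubs, present)
  if (length(absent)) {
    warning("hub genes absent from validation matrix, skipped: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  if (!length(present)) stop("no hub genes present in matrix", call. = FALSE)
  etp <- intersect(colnames(expr), group_samples(labels, "ETP"))
  non <- intersect(colnames(expr), group_samples(labels, "NONETP"))
  rows <- lapply(present, function(g) {
    ht <- welch_t_test(expr[g, etp], expr[g, non])
    dir <- if (!is.null(directions) && g %in% names(directions)) {
      directions[[g]]
    } else if (mean(expr[g, etp]) >= mean(expr[g, non])) {
      "HIGH_IN_ETP"
    } else "LOW_IN_ETP"
    ev <- evaluate_biomarker(expr, labels, g, dir, config$cutoff_rule)
    data.frame(gene = g, mean_etp = mean(expr[g, etp]),
               mean_nonetp = mean(expr[g, non]),
               t = ht$t, p = ht$p, direction = dir, auc = ev$auc,
               cutoff = ev$cutoff,
               tp = ev$confusion[["TP"]], fn = ev$confusion[["FN"]],
               fp = ev$confusion[["FP"]], tn = ev$confusion[["TN"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$validated <- out$q < config$validation_fdr
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    utils::write.table(out, file.path(output_dir, "validation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .write_provenance(output_dir, config, "validation")
  }
  out
}

#' Scoring stage: personalized lineage bias per ETP sample
#'
#' Runs [score_cohort()] and summarizes the assigned lineage combinations
#' across samples.
#'
#' @param expr expression matrix.
#' @param labels a [cohort_labels()] object.
#' @param panel a [hub_panel()].
#' @param config a [pipeline_config()].
#' @param output_dir optional persistence directory (scorecards JSON +
#'   assignment TSV).
#' @return list with `cards`, `table` (per-sample scores), `summary`
#'   (counts per assigned combination, decreasing).
#' @export
run_scoring <- function(expr, labels, panel = hub_panel(),
                        config = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cards <- score_cohort(expr, labels, panel, config$tolerance)
  tab <- scorecards_table(cards)
  combo <- table(tab$assigned)
  summary <- data.frame(assigned = names(combo),
                        n = as.integer(combo),
                        stringsAsFactors = FALSE)
  summary <- summary[order(-summary$n, summary$assigned), , drop = FALSE]
  rownames(summary) <- NULL
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    write_scorecards_json(cards, file.path(output_dir, "scorecards.json"))
    utils::write.table(tab, file.path(output_dir, "assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .write_provenance(output_dir, config, "scoring")
  }
  list(cards = cards, table = tab, summary = summary)
}
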