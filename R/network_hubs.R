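#' Build a confidence-filtered interaction network
#'
#' Retains edges with confidence >= `confidence_cutoff` whose endpoints
#' both lie in `node_universe`, then drops isolated nodes (only nodes
#' connected to at least one edge are kept). The result is a simple
#' undirected igraph with a `confidence` edge attribute; confidences are
#' used for thresholding only, never as weights.
#'
#' @param edges data.frame with columns `node_a`, `node_b`, `confidence`
#'   (see [read_edge_list()]).
#' @param node_universe gene symbols eligible for the network.
#' @param confidence_cutoff minimal combined confidence (default 0.4).
#' @return igraph object.
#' @export
build_network <- function(edges, node_universe, confidence_cutoff = 0.4) {
  if (!length(node_universe)) stop("empty node universe", call. = FALSE)
  stopifnot(all(c("node_a", "node_b", "confidence") %in% names(edges)))
  if (any(edges$confidence < 0 | edges$confidence > 1)) {
    stop("edge confidences must lie in [0, 1]", call. = FALSE)
  }
  universe <- toupper(unique(as.character(node_universe)))
  keep <- edges$confidence >= confidence_cutoff &
    toupper(edges$node_a) %in% universe &
    toupper(edges$node_b) %in% universe &
    edges$node_a != edges$node_b
  e <- edges[keep, , drop = FALSE]
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(sort(unique(c(toupper(e$node_a), toupper(e$node_b)))))
  if (nrow(e)) {
    g <- igraph::add_edges(g, as.vector(rbind(toupper(e$node_a),
                                              toupper(e$node_b))))
    igraph::E(g)$confidence <- e$confidence
  }
  g <- igraph::simplify(g, edge.attr.comb = list(confidence = "max"))
  g
}

#' Enumerate all maximal cliques
#'
#' Bron-Kerbosch enumeration with pivoting (via [igraph::max_cliques()]).
#' Cliques of size 1 (isolated nodes) are excluded; every returned set is
#' a clique not properly contained in any other clique, and the list is
#' exhaustive.
#'
#' @param net simple undirected igraph.
#' @return list of character vectors of node names, each sorted; the list
#'   itself is sorted for reproducibility.
#' @export
enumerate_maximal_cliques <- function(net) {
  stopifnot(igraph::is_igraph(net))
  cl <- igraph::max_cliques(net, min = 2)
  out <- lapply(cl, function(v) sort(igraph::V(net)$name[as.integer(v)]))
  keys <- vapply(out, paste, "", collapse = "\r")
  out[.radix_order(keys)]
}

#' Maximal Clique Centrality scores
#'
#' `MCC(v)` is the sum over all maximal cliques `C` containing `v` of
#' `(|C| - 1)!`. For a node whose neighborhood contains no internal edge
#' the maximal cliques containing it are exactly its edges, so the sum
#' reduces to its degree (the star convention); isolated nodes score 0.
#'
#' @param net simple undirected igraph.
#' @return data.frame of class `hub_ranking` with columns `gene`, `mcc`,
#'   `degree`, `rank`, ordered by decreasing MCC with deterministic
#'   tie-breaking (higher degree, then lexicographic symbol).
#' @export
mcc_scores <- function(net) {
  stopifnot(igraph::is_igraph(net))
  genes <- igraph::V(net)$name
  mcc <- stats::setNames(numeric(length(genes)), genes)
  for (cl in igraph::max_cliques(net, min = 2)) {
    members <- genes[as.integer(cl)]
    mcc[members] <- mcc[members] + factorial(length(members) - 1)
  }
  deg <- igraph::degree(net)
  ord <- .radix_order(-mcc, -deg, genes)
  out <- data.frame(gene = genes[ord], mcc = unname(mcc[ord]),
                    degree = unname(deg[ord]), rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  class(out) <- c("hub_ranking", "data.frame")
  out
}

#' Top-k hub genes
#'
#' @param ranking a `hub_ranking` from [mcc_scores()].
#' @param k number of hubs (default 10); if fewer nodes exist, all are
#'   returned.
#' @return ordered character vector of gene symbols.
#' @export
top_hubs <- function(ranking, k = 10) {
  stopifnot(inherits(ranking, "hub_ranking"))
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (!nrow(ranking)) stop("empty hub ranking", call. = FALSE)
  utils::head(ranking$gene, k)
}

#' Shortest-path subnetwork spanning a set of hubs
#'
#' Union of the nodes and edges along every shortest path (unweighted
#' breadth-first, all tied shortest paths included) between each pair of
#' hubs. Hubs with no path to any other hub are retained as isolated
#' nodes and flagged via the vertex attribute `isolated_hub`.
#'
#' @param net simple undirected igraph.
#' @param hubs character vector of hub genes, all present in `net`.
#' @return igraph object with logical vertex attributes `is_hub` and
#'   `isolated_hub`.
#' @export
hub_subnetwork <- function(net, hubs) {
  if (!length(hubs)) stop("empty hub list", call. = FALSE)
  hubs <- unique(toupper(hubs))
  missing <- setdiff(hubs, igraph::V(net)$name)
  if (length(missing)) {
    stop("hubs absent from network: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  edge_from <- character(0); edge_to <- character(0)
  connected <- stats::setNames(rep(FALSE, length(hubs)), hubs)
  if (length(hubs) >= 2) {
    pairs <- utils::combn(hubs, 2)
    for (j in seq_len(ncol(pairs))) {
      sp <- suppressWarnings(
        igraph::all_shortest_paths(net, from = pairs[1, j],
                                   to = pairs[2, j]))
      paths <- if (!is.null(sp$vpaths)) sp$vpaths else sp$res
      for (pth in paths) {
        nm <- igraph::V(net)$name[as.integer(pth)]
        if (length(nm) >= 2) {
          edge_from <- c(edge_from, nm[-length(nm)])
          edge_to <- c(edge_to, nm[-1])
          connected[pairs[, j]] <- TRUE
        }
      }
    }
  }
  nodes <- sort(unique(c(hubs, edge_from, edge_to)))
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(nodes)
  if (length(edge_from)) {
    g <- igraph::add_edges(g, as.vector(rbind(edge_from, edge_to)))
    g <- igraph::simplify(g)
  }
  igraph::V(g)$is_hub <- igraph::V(g)$name %in% hubs
  igraph::V(g)$isolated_hub <- igraph::V(g)$name %in% hubs[!connected]
  g
}

#' Write a hub ranking or a network edge list as TSV
#'
#' @param ranking a `hub_ranking`.
#' @param net an igraph object.
#' @param path output path.
#' @export
write_ranking_tsv <- function(ranking, path) {
  utils::write.table(as.data.frame(ranking), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking_tsv
#' @export
write_network_tsv <- function(net, path) {
  el <- igraph::as_edgelist(net)
  conf <- if ("confidence" %in% igraph::edge_attr_names(net)) {
    igraph::E(net)$confidence
  } else rep(1.0, nrow(el))
  df <- data.frame(node_a = el[, 1], node_b = el[, 2], confidence = conf,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
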