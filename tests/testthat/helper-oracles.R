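# Independent oracles used to verify the package implementations.
# These deliberately use naive/brute-force routes, never the package code.

# Benjamini-Hochberg step-up, written out by hand: p_(i) * m / i,
# then cumulative minimum from the largest rank down, clipped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# All maximal cliques (size >= 2) of a graph given as an adjacency
# matrix, by exhaustive enumeration of all vertex subsets (n <= 15).
oracle_max_cliques <- function(adj) {
  n <- nrow(adj)
  names <- rownames(adj)
  cliques <- list()
  is_clique <- function(idx) {
    if (length(idx) < 2) return(FALSE)
    all(adj[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))] == 1)
  }
  for (code in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    if (!is_clique(idx)) next
    # maximal iff no outside vertex is adjacent to every member
    outside <- setdiff(seq_len(n), idx)
    extendable <- any(vapply(outside, function(v) all(adj[v, idx] == 1), TRUE))
    if (!extendable) cliques[[length(cliques) + 1]] <- sort(names[idx])
  }
  keys <- vapply(cliques, paste, "", collapse = "\r")
  cliques[order(keys, method = "radix")]
}

# MCC from an oracle clique list: sum of (|C|-1)! over maximal cliques
# containing each vertex (vertices in no clique of size >= 2 score 0).
oracle_mcc <- function(adj) {
  cl <- oracle_max_cliques(adj)
  mcc <- stats::setNames(numeric(nrow(adj)), rownames(adj))
  for (C in cl) mcc[C] <- mcc[C] + factorial(length(C) - 1)
  mcc
}

# Random simple graph on n named nodes with edge probability p;
# returns both the igraph and the adjacency matrix.
random_graph <- function(n, p, seed) {
  set.seed(seed)
  names <- sprintf("V%02d", seq_len(n))
  adj <- matrix(0, n, n, dimnames = list(names, names))
  if (n >= 2) {
    up <- which(upper.tri(adj), arr.ind = TRUE)
    on <- stats::runif(nrow(up)) < p
    adj[up[on, , drop = FALSE]] <- 1
    adj <- adj + t(adj)
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  list(graph = g, adj = adj)
}

# AUC by explicit pair counting: concordant pairs count 1, ties 0.5.
oracle_auc <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Hypergeometric upper tail by direct summation of the pmf.
oracle_hyper_upper <- function(k, K, N, n) {
  sum(vapply(k:min(K, n),
             function(i) choose(K, i) * choose(N - K, n - i),
             0)) / choose(N, n)
}

# Small strictly positive expression matrix with panel genes.
random_panel_matrix <- function(n_samples = 8, seed = 1, panel = hub_panel()) {
  set.seed(seed)
  genes <- panel_gene_symbols(panel)
  m <- matrix(stats::runif(length(genes) * n_samples, 1, 16),
              nrow = length(genes),
              dimnames = list(genes, sprintf("S%02d", seq_len(n_samples))))
  m
}
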