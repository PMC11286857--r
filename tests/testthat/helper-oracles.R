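# Independent brute-force oracles and tiny fixture builders used across the
# suite. The oracles deliberately share no code with the package internals.

# molnet from an edge list given as a character vector c("a","b", "b","c", ...)
mk_net <- function(...) {
  e <- matrix(c(...), ncol = 2, byrow = TRUE)
  suppressMessages(load_network(data.frame(from = e[, 1], to = e[, 2])))
}

# random connected graph: random tree plus extra edges
random_connected_net <- function(n, extra = n, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  from <- to <- character(0)
  for (i in 2:n) {
    from <- c(from, nodes[sample(i - 1L, 1L)])
    to <- c(to, nodes[i])
  }
  for (k in seq_len(extra)) {
    pair <- sample(n, 2L)
    from <- c(from, nodes[pair[1L]])
    to <- c(to, nodes[pair[2L]])
  }
  suppressMessages(load_network(data.frame(from, to)))
}

# Floyd-Warshall all-pairs shortest paths on a molnet (hop counts)
fw_distances <- function(net) {
  g <- net$graph
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  el <- igraph::as_edgelist(g)
  for (r in seq_len(nrow(el))) {
    D[el[r, 1], el[r, 2]] <- 1
    D[el[r, 2], el[r, 1]] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# brute-force closest distance: mean over A of min over Q, from an explicit
# all-pairs matrix
brute_closest <- function(D, Q, A) {
  mean(vapply(A, function(a) min(D[Q, a]), numeric(1)))
}

# brute-force separation via the nearest-opposite / nearest-other convention
brute_separation <- function(D, A, B) {
  nearest_other <- function(set) {
    if (length(set) == 1L) return(0)
    mean(vapply(set, function(g) min(D[g, setdiff(set, g)]), numeric(1)))
  }
  d_ab <- mean(c(vapply(A, function(a) min(D[a, B]), numeric(1)),
                 vapply(B, function(b) min(D[b, A]), numeric(1))))
  d_ab - (nearest_other(A) + nearest_other(B)) / 2
}

# brute-force AUC by enumerating all positive-negative comparisons
brute_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# exact hypergeometric upper tail by enumerating all draws of size n from the
# universe (small universes only)
brute_hyper_tail <- function(universe, pathway, n_query, k_obs) {
  draws <- utils::combn(universe, n_query)
  hits <- apply(draws, 2L, function(d) length(intersect(d, pathway)))
  mean(hits >= k_obs)
}

# small, fast generator settings for pipeline-level tests
small_cfg <- function(...) {
  synth_config(n_genes = 500, n_planted_pairs = 3, n_decoy_drugs = 6,
               disease_module_size = 30, drug_module_size = 16,
               n_other_diseases = 3, ...)
}
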