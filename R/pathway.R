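#' Hypergeometric over-representation test over gene-set collections
#'
#' One-sided (enrichment) hypergeometric test of a query gene set against
#' each pathway in a collection, relative to a caller-supplied background
#' universe. Query genes outside the universe are dropped with a warning.
#' Following common practice for pathway screens of this kind, raw p-values
#' are thresholded at `alpha` (default 0.05) with no multiplicity correction
#' by default; a `p_adjust` method can be requested.
#'
#' @param genes Character vector, the query gene set.
#' @param pathways Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Character vector, the background gene universe. Pathway
#'   genes outside the universe are ignored.
#' @param alpha Significance threshold on the (adjusted) p-value.
#' @param p_adjust Method for [stats::p.adjust()]; `"none"` by default.
#' @return `data.frame` with columns `pathway`, `size`, `overlap`, `p`,
#'   `p_adj`, `significant`, sorted by p.
#' @export
enrich <- function(genes, pathways, universe, alpha = 0.05, p_adjust = "none") {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stop("empty query gene set", call. = FALSE)
  universe <- unique(as.character(universe))
  outside <- setdiff(genes, universe)
  if (length(outside) > 0L) {
    warning(sprintf("%d query gene(s) outside the universe dropped", length(outside)),
            call. = FALSE)
    genes <- setdiff(genes, outside)
  }
  if (length(genes) == 0L) stop("no query genes in the universe", call. = FALSE)
  N <- length(universe)
  n <- length(genes)
  rows <- lapply(names(pathways), function(pw) {
    pg <- intersect(unique(pathways[[pw]]), universe)
    K <- length(pg)
    k <- length(intersect(genes, pg))
    # P(X >= k) for X ~ Hypergeom(N, K, n)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = p_adjust)
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p, out$pathway), ]
  rownames(out) <- NULL
  out
}

#' Coverage of a disease's enriched pathways by a drug pair
#'
#' The fraction of the pathways enriched in the disease module that are also
#' enriched in the union of the two drug modules:
#' `|target intersect drug_union| / |target|`.
#'
#' @param target_pathways Character vector of pathway ids enriched in the
#'   disease module (non-empty).
#' @param drug_pathways_union Character vector of pathway ids enriched in
#'   either drug module.
#' @return Coverage in \[0, 1\].
#' @export
pathway_coverage <- function(target_pathways, drug_pathways_union) {
  target <- unique(as.character(target_pathways))
  if (length(target) == 0L) stop("empty target pathway set", call. = FALSE)
  length(intersect(target, unique(as.character(drug_pathways_union)))) /
    length(target)
}

#' Largest-connected-component significance within a pathway subgraph
#'
#' Measures whether module genes cluster into a specific region of a
#' functional pathway: the size of the largest connected component (LCC)
#' formed by the module genes inside the pathway's induced interaction
#' subgraph, standardized against `n_perm` uniform random draws of the same
#' number of genes from the pathway. Clustering is called significant at
#' `z > 1.95`.
#'
#' @param pathway_subgraph A `molnet` (or igraph) induced on the pathway's
#'   genes; need not be connected.
#' @param module_genes Character vector of module genes (genes absent from
#'   the pathway are ignored).
#' @param n_perm Number of random draws (default 1000).
#' @param seed Optional integer seed.
#' @param z_threshold Significance cutoff on z (default 1.95).
#' @return List with `lcc_size`, `z` (`NA` when the module does not
#'   intersect the pathway or the null is degenerate), `significant`,
#'   `n_in_pathway`.
#' @export
lcc_zscore <- function(pathway_subgraph, module_genes, n_perm = 1000,
                       seed = NULL, z_threshold = 1.95) {
  g <- if (inherits(pathway_subgraph, "molnet")) pathway_subgraph$graph
       else pathway_subgraph
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) == 0L) stop("empty pathway subgraph", call. = FALSE)
  pw_genes <- igraph::V(g)$name
  inside <- intersect(unique(as.character(module_genes)), pw_genes)
  if (length(inside) == 0L) {
    return(list(lcc_size = 0L, z = NA_real_, significant = FALSE,
                n_in_pathway = 0L))
  }
  lcc_of <- function(genes) {
    sub <- igraph::induced_subgraph(g, genes)
    max(igraph::components(sub)$csize)
  }
  obs <- lcc_of(inside)
  draw_null <- function() {
    vapply(seq_len(n_perm), function(i) {
      lcc_of(sample(pw_genes, length(inside)))
    }, numeric(1))
  }
  null_sizes <- if (is.null(seed)) draw_null() else with_seed(seed, draw_null())
  sigma <- stats::sd(null_sizes)
  z <- if (!is.finite(sigma) || sigma == 0) NA_real_
       else (obs - mean(null_sizes)) / sigma
  list(lcc_size = as.integer(obs), z = z,
       significant = !is.na(z) && z > z_threshold,
       n_in_pathway = length(inside))
}

#' Filter differentially expressed genes by log2 fold change
#'
#' Genes whose absolute log2 fold change meets the threshold
#' (`|log2FC| >= threshold`; the boundary is included).
#'
#' @param table Named numeric vector (gene -> log2FC) or `data.frame` with
#'   columns `gene`, `log2fc`.
#' @param threshold Positive cutoff (default 1).
#' @return Character vector of DEG identifiers.
#' @export
deg_filter <- function(table, threshold = 1) {
  stopifnot(threshold > 0)
  if (is.data.frame(table)) {
    v <- table[[2L]]
    names(v) <- as.character(table[[1L]])
    table <- v
  }
  stopifnot(is.numeric(table), !is.null(names(table)))
  if (any(!is.finite(table))) stop("log2FC values must be finite", call. = FALSE)
  names(table)[abs(table) >= threshold]
}

#' Induce a pathway subgraph from the interaction network
#'
#' Convenience wrapper: the subgraph of the molecular network induced on the
#' pathway's genes (those present in the network).
#'
#' @param net A `molnet`.
#' @param pathway_genes Character vector of the pathway's genes.
#' @return A `molnet` on the induced subgraph (possibly disconnected).
#' @export
pathway_subgraph <- function(net, pathway_genes) {
  stopifnot(inherits(net, "molnet"))
  keep <- intersect(unique(as.character(pathway_genes)), network_genes(net))
  if (length(keep) == 0L) stop("no pathway genes on the network", call. = FALSE)
  as_molnet(igraph::induced_subgraph(net$graph, keep))
}
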