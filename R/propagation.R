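#' Symmetrically normalized adjacency matrix
#'
#' Computes `W' = D^{-1/2} W D^{-1/2}` from the (sparse, binary) adjacency
#' matrix of the network. The spectral radius of `W'` is at most 1, which
#' guarantees convergence of the propagation iteration for any mixing weight
#' `alpha` in (0, 1).
#'
#' @param net A connected `molnet` object.
#' @return A sparse symmetric [Matrix::Matrix] with dimnames set to the gene
#'   identifiers.
#' @export
normalize_adjacency <- function(net) {
  stopifnot(inherits(net, "molnet"))
  deg <- igraph::degree(net$graph)
  if (any(deg == 0)) {
    stop("isolated node(s) present; run giant_component() first", call. = FALSE)
  }
  A <- igraph::as_adjacency_matrix(net$graph, sparse = TRUE)
  dinv <- 1 / sqrt(deg)
  W <- Matrix::Diagonal(x = dinv) %*% A %*% Matrix::Diagonal(x = dinv)
  dimnames(W) <- list(names(deg), names(deg))
  W
}

#' Propagation configuration
#'
#' @param alpha Mixing weight in (0, 1): the fraction of score diffused from
#'   neighbors at each step; `1 - alpha` is retained from the prior. Default
#'   0.5.
#' @param tol Convergence threshold on the max absolute score change
#'   (default 1e-6).
#' @param max_iter Iteration cap (default 1000).
#' @param k Expansion size: number of neighbor candidates admitted into a
#'   module; `NULL` means "as many as the module has genes", `Inf` admits
#'   all candidates (the no-prior "neighbors" variant).
#' @param prior_agg How similarity-transferred prior values are combined
#'   when a gene belongs to several similar entities: `"max"` (strongest
#'   evidence, default) or `"sum"` (capped at 1).
#' @return A list of class `propagation_config`.
#' @export
propagation_config <- function(alpha = 0.5, tol = 1e-6, max_iter = 1000,
                               k = NULL, prior_agg = c("max", "sum")) {
  stopifnot(alpha > 0, alpha < 1, tol > 0, max_iter >= 1)
  structure(list(alpha = alpha, tol = tol, max_iter = max_iter, k = k,
                 prior_agg = match.arg(prior_agg)),
            class = "propagation_config")
}

#' Random-walk network propagation with prior knowledge
#'
#' Iterates the PRINCE-style update
#' \deqn{F_t = \alpha W' F_{t-1} + (1 - \alpha) Y}
#' on the normalized network `W'` until the maximum absolute change drops
#' below `tol` (or `max_iter` is reached, in which case the partial result is
#' flagged). The fixed point is the linear solve
#' `F* = (1 - alpha) (I - alpha W')^{-1} Y`; the iteration is used because it
#' only needs sparse matrix-vector products. Scores rank genes by their
#' probability of belonging to the seeded module.
#'
#' @param W Normalized adjacency from [normalize_adjacency()].
#' @param prior Named numeric vector `Y` of prior values in \[0, 1\] (genes
#'   not named get 0). Must be non-negative and not all zero.
#' @param config A [propagation_config()].
#' @return A `propagation_scores` object: list with `scores` (named numeric,
#'   all nodes), `iterations`, `converged`.
#' @export
propagate <- function(W, prior, config = propagation_config()) {
  stopifnot(inherits(config, "propagation_config"))
  nodes <- rownames(W)
  if (is.null(nodes)) stop("W must carry gene identifiers as dimnames", call. = FALSE)
  if (any(prior < 0)) stop("prior must be non-negative", call. = FALSE)
  y <- numeric(length(nodes)); names(y) <- nodes
  known <- intersect(names(prior), nodes)
  y[known] <- prior[known]
  if (all(y == 0)) stop("prior is all zero on the network", call. = FALSE)
  alpha <- config$alpha
  f <- y
  converged <- FALSE
  it <- 0L
  while (it < config$max_iter) {
    it <- it + 1L
    f_new <- alpha * as.numeric(W %*% f) + (1 - alpha) * y
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < config$tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("propagation did not converge in %d iterations; partial result",
                    config$max_iter), call. = FALSE)
  }
  names(f) <- nodes
  structure(list(scores = f, iterations = it, converged = converged),
            class = "propagation_scores")
}

#' @export
print.propagation_scores <- function(x, ...) {
  cat(sprintf("<propagation_scores> %d genes, %d iterations, %s\n",
              length(x$scores), x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Closed-form propagation fixed point
#'
#' Direct dense solve of `F* = (1 - alpha) (I - alpha W')^{-1} Y`. Intended
#' for small graphs, e.g. as an independent check of [propagate()].
#'
#' @inheritParams propagate
#' @return Named numeric vector of scores.
#' @export
propagate_exact <- function(W, prior, config = propagation_config()) {
  nodes <- rownames(W)
  y <- numeric(length(nodes)); names(y) <- nodes
  known <- intersect(names(prior), nodes)
  y[known] <- prior[known]
  M <- diag(length(nodes)) - config$alpha * as.matrix(W)
  f <- (1 - config$alpha) * solve(M, y)
  names(f) <- nodes
  f
}

#' Build a propagation prior from similar entities
#'
#' The prior `Y` assigns 1 to every gene of the entity's own module;
#' otherwise the similarity values of the similar entities whose modules
#' contain the gene are combined (`max` by default, or capped `sum`); genes
#' in no module get 0. This transfers evidence from related diseases (via
#' network-based disease similarity) or related drugs (via chemical
#' similarity).
#'
#' @param module The entity's own `gene_module` (or gene vector).
#' @param similar List of `list(module =, similarity =)` entries, with
#'   similarities in \[0, 1\]. May be empty (prior = module indicator).
#' @param prior_agg `"max"` or `"sum"`.
#' @return Named numeric vector, gene -> prior value in \[0, 1\].
#' @export
build_prior <- function(module, similar = list(), prior_agg = c("max", "sum")) {
  prior_agg <- match.arg(prior_agg)
  own <- if (inherits(module, "gene_module")) module$genes_on_network else
    unique(as.character(module))
  acc <- new.env(parent = emptyenv())
  for (s in similar) {
    sim <- s$similarity
    stopifnot(sim >= 0, sim <= 1)
    gs <- if (inherits(s$module, "gene_module")) s$module$genes_on_network else
      unique(as.character(s$module))
    for (g in gs) {
      prev <- if (is.null(acc[[g]])) 0 else acc[[g]]
      acc[[g]] <- if (prior_agg == "max") max(prev, sim) else min(1, prev + sim)
    }
  }
  genes <- unique(c(own, ls(acc)))
  y <- vapply(genes, function(g) {
    if (g %in% own) 1 else acc[[g]]
  }, numeric(1))
  names(y) <- genes
  y
}

#' Expand a module with top-scoring network neighbors
#'
#' Candidate genes are the direct network neighbors of the current module.
#' The `k` candidates with the highest propagation scores are added (ties by
#' lexicographic gene id); with `k = Inf`, or when no scores are supplied,
#' all neighbor candidates are admitted (the propagation-without-priors
#' "neighbors" variant). Original module genes are always retained.
#'
#' @param module A `gene_module` on the network.
#' @param scores A `propagation_scores` object (or named numeric vector), or
#'   `NULL` to admit all neighbors.
#' @param net A `molnet` object.
#' @param k Number of candidates to admit; default `NULL` means
#'   `length(module genes on network)`.
#' @return A new `gene_module` (id suffixed `+`).
#' @export
expand_module <- function(module, scores = NULL, net, k = NULL) {
  stopifnot(inherits(net, "molnet"))
  own <- module_genes(module, net)
  id <- if (inherits(module, "gene_module")) module$id else "module"
  if (is.null(k)) k <- length(own)
  nbr_idx <- unique(unlist(lapply(
    igraph::adjacent_vertices(net$graph, own), as.integer
  )))
  nbrs <- igraph::V(net$graph)$name[nbr_idx]
  candidates <- setdiff(nbrs, own)
  if (length(candidates) == 0L) {
    warning(sprintf("module '%s': no neighbor candidates; returned unchanged", id),
            call. = FALSE)
    added <- character(0)
  } else if (k == 0) {
    added <- character(0)
  } else if (is.null(scores) || is.infinite(k)) {
    added <- candidates
  } else {
    sc <- if (inherits(scores, "propagation_scores")) scores$scores else scores
    cand_sc <- sc[candidates]
    cand_sc[is.na(cand_sc)] <- 0
    ord <- order(-cand_sc, candidates, method = "radix")
    added <- candidates[ord][seq_len(min(k, length(candidates)))]
  }
  raw <- if (inherits(module, "gene_module")) module$genes else own
  build_module(unique(c(raw, added)), net, id = paste0(id, "+"))
}
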