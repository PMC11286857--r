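#' Closest-distance network proximity between two modules
#'
#' The observed closest distance between a query disease module `Q` and a
#' drug module `A`:
#' \deqn{d(Q, A) = \frac{1}{|A|} \sum_{a \in A} \min_{q \in Q} d(q, a)}
#' i.e. the average, over drug-module genes, of the shortest-path distance to
#' the nearest disease-module gene. Note the asymmetry: the mean runs over
#' `A`, the minimum over `Q`.
#'
#' @param net A `molnet` object (connected; use [giant_component()]).
#' @param Q,A `gene_module` objects or character vectors of genes on the
#'   network. `Q` is the query disease module, `A` the drug module.
#' @return The mean closest distance (non-negative real, in hops).
#' @export
closest_distance <- function(net, Q, A) {
  stopifnot(inherits(net, "molnet"))
  q <- module_genes(Q, net)
  a <- module_genes(A, net)
  if (length(q) == 0L || length(a) == 0L) stop("empty module", call. = FALSE)
  D <- dist_matrix(net)
  sub <- D[q, a, drop = FALSE]
  mins <- apply(sub, 2L, min)
  if (any(!is.finite(mins))) {
    stop("infinite shortest-path distance encountered; run giant_component() first",
         call. = FALSE)
  }
  mean(mins)
}

# z from an observed value and a permutation sample; sigma == 0 is flagged
# degenerate with z = 0.
standardize_against_null <- function(observed, null_values) {
  mu <- mean(null_values)
  sigma <- stats::sd(null_values)
  degenerate <- !is.finite(sigma) || sigma == 0
  if (degenerate) {
    warning("degenerate permutation null (sd = 0); z set to 0", call. = FALSE)
    z <- 0
  } else {
    z <- (observed - mu) / sigma
  }
  structure(list(d_observed = observed, mu = mu,
                 sigma = if (degenerate) 0 else sigma, z = z,
                 n_perm = length(null_values), degenerate = degenerate),
            class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf("<proximity_result> d = %.4f, mu = %.4f, sigma = %.4f, z = %.4f (%d permutations%s)\n",
              x$d_observed, x$mu, x$sigma, x$z, x$n_perm,
              if (isTRUE(x$degenerate)) ", degenerate" else ""))
  invisible(x)
}

#' Permutation z-score of network proximity
#'
#' Standardizes the observed closest distance `d(Q, A)` against a
#' degree-matched permutation null: in each repetition, *both* gene sets are
#' replaced by random sets of the same size and degree profile (drawn from
#' degree bins), and the closest distance is recomputed. After `n_perm`
#' repetitions (default 100) the null mean \eqn{\mu} and standard deviation
#' \eqn{\sigma} give
#' \deqn{z(Q, A) = \frac{d(Q, A) - \mu_{d(Q,A)}}{\sigma_{d(Q,A)}}.}
#' Negative z means the modules are closer than expected for their degrees.
#'
#' @inheritParams closest_distance
#' @param bins A `degree_bins` object; defaults to cached bins with
#'   `min_bin_size = 100`.
#' @param n_perm Number of permutations (>= 2; default 100).
#' @param seed Integer seed; per-permutation streams are derived by counter
#'   offset, so results are reproducible and independent of call order.
#' @return A `proximity_result`: list with `d_observed`, `mu`, `sigma`, `z`,
#'   `n_perm` and a `degenerate` flag (sd = 0 null).
#' @export
proximity_z <- function(net, Q, A, bins = NULL, n_perm = 100, seed = NULL) {
  stopifnot(n_perm >= 2)
  if (is.null(bins)) bins <- cached_bins(net)
  q <- module_genes(Q, net)
  a <- module_genes(A, net)
  obs <- closest_distance(net, q, a)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  null_d <- vapply(seq_len(n_perm), function(i) {
    qs <- degree_matched_sample(net, q, bins, seed = seed + 2L * i)
    as_ <- degree_matched_sample(net, a, bins, seed = seed + 2L * i + 1L)
    closest_distance(net, qs, as_)
  }, numeric(1))
  standardize_against_null(obs, null_d)
}

#' Min-max scale proximity z-scores to [0, 1]
#'
#' Inverts the sign of the z-scores and rescales them over the supplied
#' collection (e.g. all drugs for one query disease), so the most negative z
#' (closest module) maps to 1 and the most positive to 0:
#' \deqn{P = \frac{-z - \min(-z)}{\max(-z) - \min(-z)}.}
#'
#' @param z Named numeric vector of z-scores (>= 2 distinct values).
#' @return Named numeric vector of scaled proximities in \[0, 1\].
#' @export
scale_to_unit <- function(z) {
  stopifnot(is.numeric(z))
  if (length(z) < 2L || length(unique(z)) < 2L) {
    stop("need at least two distinct z-values to min-max scale", call. = FALSE)
  }
  nz <- -z
  (nz - min(nz)) / (max(nz) - min(nz))
}

#' Network-based separation between two modules
#'
#' The separation measure
#' \deqn{s_{AB} = \langle d_{AB} \rangle - \frac{\langle d_{AA} \rangle +
#'   \langle d_{BB} \rangle}{2}}
#' where \eqn{\langle d_{AA} \rangle} is the mean, over genes of `A`, of the
#' distance to the nearest *other* gene of `A` (0 when `A` has a single
#' gene), and \eqn{\langle d_{AB} \rangle} averages, over all genes of `A`
#' and `B`, the distance to the nearest gene of the opposite set (genes
#' shared by both sets contribute 0). Positive `s` indicates topologically
#' separated modules; negative `s`, overlapping neighborhoods.
#'
#' @inheritParams closest_distance
#' @param A,B `gene_module`s or character vectors on the network.
#' @return A `separation_result`: list with `d_AA`, `d_BB`, `d_AB`, `s`.
#' @export
separation <- function(net, A, B) {
  stopifnot(inherits(net, "molnet"))
  a <- module_genes(A, net)
  b <- module_genes(B, net)
  if (length(a) == 0L || length(b) == 0L) stop("empty module", call. = FALSE)
  D <- dist_matrix(net)
  d_AA <- within_distance(D, a)
  d_BB <- within_distance(D, b)
  sub <- D[a, b, drop = FALSE]
  # nearest opposite-set gene for every member of A and of B; shared genes
  # sit at distance 0 from themselves in the opposite set
  mins_a <- apply(sub, 1L, min)
  mins_b <- apply(sub, 2L, min)
  d_AB <- mean(c(mins_a, mins_b))
  s <- d_AB - (d_AA + d_BB) / 2
  structure(list(d_AA = d_AA, d_BB = d_BB, d_AB = d_AB, s = s),
            class = "separation_result")
}

# mean nearest-neighbor distance within a set (self excluded); 0 for singleton
within_distance <- function(D, genes) {
  if (length(genes) == 1L) return(0)
  sub <- D[genes, genes, drop = FALSE]
  diag(sub) <- Inf
  mean(apply(sub, 1L, min))
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf("<separation_result> d_AA = %.4f, d_BB = %.4f, d_AB = %.4f, s = %.4f\n",
              x$d_AA, x$d_BB, x$d_AB, x$s))
  invisible(x)
}
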