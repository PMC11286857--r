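#' Cosine transcriptional correlation between two signatures
#'
#' Cosine of the raw signed signature value vectors restricted to a gene set
#' (typically the overlap of two modules). No centering is applied: this is
#' the cosine coefficient, not Pearson correlation, and it is invariant to
#' positive rescaling of either vector.
#'
#' @param sig1,sig2 `expr_signature` objects (or named numeric vectors).
#' @param genes Optional character vector restricting the comparison; when
#'   `NULL` all genes present in both signatures are used.
#' @param min_overlap Minimum number of genes with values in both signatures
#'   (default 3). Below this the correlation is undefined: `NA` is returned
#'   with a warning so the caller can exclude or zero the pair.
#' @return Cosine coefficient in \[-1, 1\], or `NA` when undefined.
#' @export
cosine_correlation <- function(sig1, sig2, genes = NULL, min_overlap = 3) {
  v1 <- if (inherits(sig1, "expr_signature")) sig1$values else sig1
  v2 <- if (inherits(sig2, "expr_signature")) sig2$values else sig2
  shared <- intersect(names(v1), names(v2))
  if (!is.null(genes)) shared <- intersect(shared, genes)
  if (length(shared) < min_overlap) {
    warning(sprintf("cosine undefined: %d overlapping genes (< %d)",
                    length(shared), min_overlap), call. = FALSE)
    return(NA_real_)
  }
  x <- v1[shared]; y <- v2[shared]
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    warning("cosine undefined: zero-norm vector on the overlap", call. = FALSE)
    return(NA_real_)
  }
  sum(x * y) / (nx * ny)
}

#' Generalized (weighted) Jaccard similarity of count fingerprints
#'
#' For sparse non-negative count vectors `x`, `y` over the union of their
#' feature sets:
#' \deqn{J(x, y) = \frac{\sum_i \min(x_i, y_i)}{\sum_i \max(x_i, y_i)}}
#' The standard structural-similarity measure for count-type chemical
#' fingerprints (e.g. KCF-S); equals the set Jaccard index on binary vectors.
#'
#' @param x,y Named non-negative numeric vectors (feature -> count).
#' @return Similarity in \[0, 1\].
#' @export
weighted_jaccard <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), !is.null(names(x)), !is.null(names(y)))
  if (any(x < 0) || any(y < 0)) stop("fingerprint counts must be non-negative",
                                     call. = FALSE)
  feats <- union(names(x), names(y))
  xv <- numeric(length(feats)); names(xv) <- feats; xv[names(x)] <- x
  yv <- numeric(length(feats)); names(yv) <- feats; yv[names(y)] <- y
  denom <- sum(pmax(xv, yv))
  if (denom == 0) stop("both fingerprints are all-zero", call. = FALSE)
  sum(pmin(xv, yv)) / denom
}

#' Pairwise generalized Jaccard similarity matrix
#' @param fps Named list of fingerprint vectors (see [read_fingerprints()]).
#' @return Symmetric matrix with unit diagonal.
#' @export
fingerprint_similarity <- function(fps) {
  stopifnot(is.list(fps), length(fps) >= 1L, !is.null(names(fps)))
  n <- length(fps)
  m <- diag(1, n)
  dimnames(m) <- list(names(fps), names(fps))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        m[i, j] <- m[j, i] <- weighted_jaccard(fps[[i]], fps[[j]])
      }
    }
  }
  m
}

#' Network-based disease similarity
#'
#' Evaluates the proximity z-score between the query disease's
#' susceptibility-gene module and each other disease's specific-gene set,
#' then min-max scales the sign-inverted z over the disease collection
#' ([scale_to_unit()]): the disease whose genes sit closest to the query
#' module (most negative z) gets similarity 1, the farthest 0. Used as prior
#' knowledge for network propagation.
#'
#' @inheritParams proximity_z
#' @param Q Query disease module.
#' @param others Named list of `gene_module`s or gene vectors (>= 2
#'   diseases).
#' @return `data.frame` with columns `disease`, `z`, `similarity`.
#' @export
disease_similarity <- function(net, Q, others, bins = NULL, n_perm = 100,
                               seed = NULL) {
  stopifnot(is.list(others), length(others) >= 2L, !is.null(names(others)))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  z <- vapply(seq_along(others), function(i) {
    proximity_z(net, Q, others[[i]], bins = bins, n_perm = n_perm,
                seed = seed + i * 100003L)$z
  }, numeric(1))
  names(z) <- names(others)
  data.frame(disease = names(others), z = z,
             similarity = scale_to_unit(z),
             row.names = NULL, stringsAsFactors = FALSE)
}
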