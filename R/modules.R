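#' Construct an expression signature
#'
#' A signature maps genes to signed differential-expression values (fold
#' changes or characteristic scores) for one disease or drug. Values must be
#' finite and gene identifiers unique.
#'
#' @param id Entity identifier.
#' @param values Named numeric vector, gene -> signed value.
#' @param kind `"disease"` or `"drug"`.
#' @return An `expr_signature` object.
#' @export
expression_signature <- function(id, values, kind = c("disease", "drug")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(values), !is.null(names(values)))
  if (anyDuplicated(names(values))) stop("duplicate genes in signature", call. = FALSE)
  if (any(!is.finite(values))) stop("signature values must be finite", call. = FALSE)
  structure(list(id = id, values = values, kind = kind),
            class = "expr_signature")
}

#' @export
print.expr_signature <- function(x, ...) {
  cat(sprintf("<expr_signature> %s (%s), %d genes\n", x$id, x$kind,
              length(x$values)))
  invisible(x)
}

#' Select the top up- and down-regulated genes of a signature
#'
#' Implements the module-defining rule: the union of the
#' `floor(fraction * N)` genes with the most positive values and the
#' `floor(fraction * N)` genes with the most negative values, where `N` is
#' the signature size. Genes with value exactly 0 are never selected (both
#' sign classes require a strict sign). If one sign class has fewer genes
#' than requested, all genes of that sign are taken with a warning. Ties at
#' a cutoff are broken by lexicographic gene identifier, so the selection is
#' deterministic.
#'
#' @param sig An `expr_signature` (or named numeric vector).
#' @param fraction Proportion per sign class, in (0, 0.5); default 0.05
#'   (the top/bottom 5 percent rule).
#' @return Character vector of selected genes.
#' @export
top_fraction_genes <- function(sig, fraction = 0.05) {
  if (inherits(sig, "expr_signature")) sig <- sig$values
  stopifnot(is.numeric(sig), !is.null(names(sig)))
  if (!(fraction > 0 && fraction < 0.5)) {
    stop("fraction must lie strictly between 0 and 0.5", call. = FALSE)
  }
  if (all(sig == 0)) stop("signature is all zero; no signed genes to select",
                          call. = FALSE)
  k <- floor(fraction * length(sig))
  pick <- function(v, decreasing) {
    # order by value, ascending gene id as deterministic tie-break
    ord <- order(v, names(v), decreasing = c(decreasing, FALSE),
                 method = "radix")
    names(v)[ord][seq_len(min(k, length(v)))]
  }
  up <- pick(sig[sig > 0], decreasing = TRUE)
  down <- pick(sig[sig < 0], decreasing = FALSE)
  if (k > 0 && (length(up) < k || length(down) < k)) {
    warning(sprintf("fewer than %d genes on one sign (up: %d, down: %d); took all",
                    k, length(up), length(down)), call. = FALSE)
  }
  union(up, down)
}

#' Map a gene set onto the interaction network as a module
#'
#' A module records both the raw gene set and its subset present on the
#' network (`genes_on_network`); only the latter enters distance
#' computations. Dropped genes are reported.
#'
#' @param genes Character vector of gene identifiers.
#' @param net A `molnet` object.
#' @param id Module identifier.
#' @return A `gene_module` object.
#' @export
build_module <- function(genes, net, id = "module") {
  stopifnot(inherits(net, "molnet"))
  genes <- unique(as.character(genes))
  on_net <- intersect(genes, network_genes(net))
  if (length(on_net) == 0L) {
    stop(sprintf("module '%s': no genes present on the network", id),
         call. = FALSE)
  }
  dropped <- length(genes) - length(on_net)
  if (dropped > 0L) {
    message(sprintf("module '%s': %d of %d genes not on network, dropped",
                    id, dropped, length(genes)))
  }
  structure(list(id = id, genes = genes, genes_on_network = on_net),
            class = "gene_module")
}

#' @export
print.gene_module <- function(x, ...) {
  cat(sprintf("<gene_module> %s: %d genes (%d on network)\n",
              x$id, length(x$genes), length(x$genes_on_network)))
  invisible(x)
}

# Accept a gene_module or plain character vector; return network genes.
module_genes <- function(x, net = NULL) {
  g <- if (inherits(x, "gene_module")) x$genes_on_network else unique(as.character(x))
  if (!is.null(net)) check_genes_present(net, g, "module gene")
  g
}
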