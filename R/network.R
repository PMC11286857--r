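#' Load an undirected molecular interaction network from an edge list
#'
#' Reads a two-column edge list (gene identifier pairs) and returns a cleaned
#' undirected network: self-loops and duplicated interactions (unordered
#' pairs) are removed. Identifiers are treated as opaque strings; no ID
#' conversion is performed.
#'
#' @param edges Either a path to a TSV/CSV file (two columns, header
#'   optional, lines starting with `#` ignored) or a two-column
#'   `data.frame`/`matrix` of gene identifier pairs.
#' @return A `molnet` object wrapping an undirected [igraph::igraph] graph.
#'   `nodes` and `edges` counts of the cleaned network are reported via
#'   `message()`.
#' @examples
#' net <- load_network(data.frame(a = c("a", "b", "b"), b = c("b", "a", "c")))
#' network_size(net)  # 3 nodes, 2 edges
#' @export
load_network <- function(edges) {
  if (is.character(edges) && length(edges) == 1L) {
    edges <- read_edge_file(edges)
  }
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!is.data.frame(edges) || ncol(edges) < 2L) {
    stop("edge input must be a file path or a two-column table", call. = FALSE)
  }
  if (nrow(edges) == 0L) stop("edge list is empty", call. = FALSE)
  a <- trimws(as.character(edges[[1L]]))
  b <- trimws(as.character(edges[[2L]]))
  bad <- which(is.na(a) | is.na(b) | a == "" | b == "")
  if (length(bad) > 0L) {
    stop("malformed edge rows (empty identifier) at line(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  g <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  net <- as_molnet(g)
  message(sprintf("loaded network: %d nodes, %d edges (after removing self-loops/duplicates)",
                  igraph::vcount(g), igraph::ecount(g)))
  net
}

read_edge_file <- function(path) {
  if (!file.exists(path)) stop("edge file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("edge list is empty", call. = FALSE)
  sep <- if (grepl("\t", lines[[1L]])) "\t" else if (grepl(",", lines[[1L]])) "," else "[[:space:]]+"
  parts <- strsplit(lines, sep)
  nc <- lengths(parts)
  if (any(nc < 2L)) {
    stop("malformed edge rows (need two columns) at line(s): ",
         paste(utils::head(which(nc < 2L), 5L), collapse = ", "), call. = FALSE)
  }
  df <- data.frame(from = vapply(parts, `[[`, "", 1L),
                   to   = vapply(parts, `[[`, "", 2L),
                   stringsAsFactors = FALSE)
  # drop a header row if present (non-repeated tokens that also appear nowhere else)
  if (nrow(df) > 1L && (tolower(df$from[1L]) %in% c("from", "gene1", "genea", "source", "node1") ||
                        tolower(df$to[1L])   %in% c("to", "gene2", "geneb", "target", "node2"))) {
    df <- df[-1L, , drop = FALSE]
  }
  df
}

#' @rdname load_network
#' @param g An [igraph::igraph] undirected graph.
#' @export
as_molnet <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  structure(list(graph = g, cache = new.env(parent = emptyenv())),
            class = "molnet")
}

#' @export
print.molnet <- function(x, ...) {
  cat(sprintf("<molnet> %d nodes, %d edges, %s\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              if (igraph::is_connected(x$graph)) "connected" else "disconnected"))
  invisible(x)
}

#' Node and edge counts of a network
#' @param net A `molnet` object.
#' @return Named integer vector with elements `nodes` and `edges`.
#' @export
network_size <- function(net) {
  stopifnot(inherits(net, "molnet"))
  c(nodes = igraph::vcount(net$graph), edges = igraph::ecount(net$graph))
}

#' Gene identifiers present in the network
#' @param net A `molnet` object.
#' @export
network_genes <- function(net) {
  stopifnot(inherits(net, "molnet"))
  igraph::V(net$graph)$name
}

#' Extract the giant component
#'
#' Returns the induced subgraph on the largest connected node set; this is the
#' backbone on which all distances are computed, guaranteeing finite
#' shortest-path lengths. Ties in component size are broken by the
#' lexicographically smallest member, so the result is deterministic.
#'
#' @param net A `molnet` object.
#' @return A connected `molnet`.
#' @export
giant_component <- function(net) {
  stopifnot(inherits(net, "molnet"))
  g <- net$graph
  if (igraph::vcount(g) == 0L) stop("network is empty", call. = FALSE)
  comp <- igraph::components(g)
  sizes <- comp$csize
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1L) {
    # deterministic tie-break: component containing the smallest member name
    firsts <- vapply(biggest, function(ci) {
      min(igraph::V(g)$name[comp$membership == ci])
    }, "")
    biggest <- biggest[order(firsts)][1L]
  }
  keep <- igraph::V(g)[comp$membership == biggest]
  as_molnet(igraph::induced_subgraph(g, keep))
}

check_genes_present <- function(net, genes, what = "gene") {
  missing <- setdiff(genes, network_genes(net))
  if (length(missing) > 0L) {
    stop(sprintf("%s(s) absent from network: %s", what,
                 paste(utils::head(missing, 10L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Shortest-path lengths between two gene sets
#'
#' Unweighted (hop-count) breadth-first shortest paths on the interaction
#' network, for all source-target pairs.
#'
#' @param net A `molnet` object.
#' @param sources,targets Character vectors of gene identifiers; all must be
#'   present in the network.
#' @return Numeric matrix of path lengths, rows = sources, cols = targets.
#' @export
shortest_path_lengths <- function(net, sources, targets) {
  stopifnot(inherits(net, "molnet"))
  check_genes_present(net, unique(c(sources, targets)))
  igraph::distances(net$graph, v = sources, to = targets)
}

# Full all-pairs distance matrix, cached on the molnet object. All proximity
# and separation statistics reduce to submatrix min/mean operations on this.
dist_matrix <- function(net) {
  stopifnot(inherits(net, "molnet"))
  if (is.null(net$cache$D)) {
    net$cache$D <- igraph::distances(net$graph)
  }
  net$cache$D
}

#' Partition network nodes into degree bins
#'
#' Groups nodes by exact degree, then merges adjacent (ascending-degree) bins
#' until every bin holds at least `min_bin_size` nodes; a trailing undersized
#' bin is merged into its predecessor. The bins drive degree-matched random
#' sampling for the permutation null of the proximity z-score.
#'
#' @param net A `molnet` object.
#' @param min_bin_size Minimum nodes per bin (default 100). Use a value
#'   `>=` the node count to obtain a single bin (plain uniform sampling).
#' @return A `degree_bins` object: list with `bins` (list of character
#'   vectors partitioning the node set), `node2bin` (named integer lookup)
#'   and `min_bin_size`.
#' @export
make_degree_bins <- function(net, min_bin_size = 100) {
  stopifnot(inherits(net, "molnet"), min_bin_size >= 1)
  deg <- igraph::degree(net$graph)
  ord <- order(deg, names(deg))
  nodes <- names(deg)[ord]
  degs <- deg[ord]
  bins <- list()
  cur <- character(0)
  i <- 1L
  n <- length(nodes)
  while (i <= n) {
    d <- degs[[i]]
    # take the whole exact-degree group at once
    grp <- nodes[which(degs == d)]
    cur <- c(cur, grp)
    i <- max(which(degs == d)) + 1L
    if (length(cur) >= min_bin_size) {
      bins[[length(bins) + 1L]] <- cur
      cur <- character(0)
    }
  }
  if (length(cur) > 0L) {
    if (length(bins) > 0L) {
      bins[[length(bins)]] <- c(bins[[length(bins)]], cur)
    } else {
      bins[[1L]] <- cur
    }
  }
  node2bin <- integer(n)
  names(node2bin) <- unlist(bins, use.names = FALSE)
  for (b in seq_along(bins)) node2bin[bins[[b]]] <- b
  structure(list(bins = bins, node2bin = node2bin, min_bin_size = min_bin_size),
            class = "degree_bins")
}

#' @export
print.degree_bins <- function(x, ...) {
  cat(sprintf("<degree_bins> %d bins over %d nodes (min_bin_size = %d)\n",
              length(x$bins), length(x$node2bin), x$min_bin_size))
  invisible(x)
}

#' Draw a degree-matched random gene set
#'
#' Samples a random gene set with the same size and degree profile as a
#' template set: each template gene is replaced by a gene drawn uniformly from
#' its degree bin, without replacement within one draw. This is the
#' randomization behind the permutation null of the proximity z-score.
#'
#' @param net A `molnet` object.
#' @param template Character vector of genes (subset of the network nodes).
#' @param bins A `degree_bins` object from [make_degree_bins()]; computed on
#'   the fly (and cached) when `NULL`.
#' @param seed Optional integer; when given the draw is reproducible and the
#'   caller's RNG state is left untouched.
#' @return Character vector of sampled genes, `length(template)` long.
#' @export
degree_matched_sample <- function(net, template, bins = NULL, seed = NULL) {
  stopifnot(inherits(net, "molnet"))
  template <- unique(as.character(template))
  check_genes_present(net, template, "template gene")
  if (is.null(bins)) bins <- cached_bins(net)
  stopifnot(inherits(bins, "degree_bins"))
  draw <- function() {
    need <- table(bins$node2bin[template])
    out <- character(0)
    for (b in names(need)) {
      pool <- bins$bins[[as.integer(b)]]
      k <- as.integer(need[[b]])
      if (k > length(pool)) {
        stop(sprintf(paste0("degree bin %s exhausted (%d needed, %d available); ",
                            "increase min_bin_size when building degree bins"),
                     b, k, length(pool)), call. = FALSE)
      }
      out <- c(out, sample(pool, k, replace = FALSE))
    }
    out
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

cached_bins <- function(net, min_bin_size = 100) {
  key <- paste0("bins", min_bin_size)
  if (is.null(net$cache[[key]])) {
    net$cache[[key]] <- make_degree_bins(net, min_bin_size)
  }
  net$cache[[key]]
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
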