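# Orchestration: network -> modules -> proximity/separation -> similarity ->
# propagation -> scoring -> AUC, with and without propagation-based module
# amplification.

#' Pairwise separation matrix over drug modules
#'
#' Efficient all-pairs [separation()] sharing the cached distance matrix and
#' the per-module within-distances.
#'
#' @param net A `molnet`.
#' @param modules Named list of `gene_module`s (or gene vectors).
#' @return Symmetric numeric matrix of separation scores `s` (diagonal
#'   `-d_AA`, rarely of interest).
#' @export
separation_matrix <- function(net, modules) {
  stopifnot(is.list(modules), !is.null(names(modules)))
  D <- dist_matrix(net)
  gl <- lapply(modules, module_genes, net = net)
  within <- vapply(gl, function(g) within_distance(D, g), numeric(1))
  n <- length(gl)
  m <- matrix(0, n, n, dimnames = list(names(modules), names(modules)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      sub <- D[gl[[i]], gl[[j]], drop = FALSE]
      d_ab <- mean(c(apply(sub, 1L, min), apply(sub, 2L, min)))
      m[i, j] <- m[j, i] <- d_ab - (within[[i]] + within[[j]]) / 2
    }
  }
  m
}

# Shared per-bundle statistics for both pipeline modes: proximity z / P per
# drug, pairwise separation, and transcriptional correlation computed on raw
# module overlaps (base) and on propagation-expanded overlaps (netprop).
pipeline_stats <- function(bundle, n_perm = 100, seed = 1,
                           prop_config = propagation_config(),
                           min_bin_size = 100, min_overlap = 3) {
  net <- bundle$net
  bins <- make_degree_bins(net, min_bin_size)
  dis <- bundle$disease_module
  drugs <- bundle$drug_modules
  drug_ids <- names(drugs)

  z <- vapply(seq_along(drugs), function(i) {
    proximity_z(net, dis, drugs[[i]], bins = bins, n_perm = n_perm,
                seed = seed + i * 1000L)$z
  }, numeric(1))
  names(z) <- drug_ids
  P <- scale_to_unit(z)
  sep <- separation_matrix(net, drugs)

  C_base <- vapply(drug_ids, function(id) {
    genes <- intersect(module_genes(dis), module_genes(drugs[[id]]))
    suppressWarnings(cosine_correlation(bundle$disease_signature,
                                        bundle$drug_signatures[[id]],
                                        genes = genes,
                                        min_overlap = min_overlap))
  }, numeric(1))

  # --- propagation-amplified modules ---------------------------------------
  W <- normalize_adjacency(net)
  dis_sim <- disease_similarity(net, dis, bundle$other_disease_modules,
                                bins = bins, n_perm = n_perm,
                                seed = seed + 900000L)
  dis_prior <- build_prior(dis, similar = lapply(
    seq_len(nrow(dis_sim)), function(i) {
      list(module = bundle$other_disease_modules[[dis_sim$disease[i]]],
           similarity = dis_sim$similarity[i])
    }), prior_agg = prop_config$prior_agg)
  dis_scores <- propagate(W, dis_prior, prop_config)
  dis_exp <- expand_module(dis, dis_scores, net, k = prop_config$k)

  fp_sim <- fingerprint_similarity(bundle$fingerprints[drug_ids])
  drug_exp <- lapply(drug_ids, function(id) {
    sims <- lapply(setdiff(drug_ids, id), function(other) {
      list(module = drugs[[other]], similarity = fp_sim[id, other])
    })
    prior <- build_prior(drugs[[id]], similar = sims,
                         prior_agg = prop_config$prior_agg)
    scores <- propagate(W, prior, prop_config)
    expand_module(drugs[[id]], scores, net, k = prop_config$k)
  })
  names(drug_exp) <- drug_ids

  C_netprop <- vapply(drug_ids, function(id) {
    genes <- intersect(module_genes(dis_exp), module_genes(drug_exp[[id]]))
    suppressWarnings(cosine_correlation(bundle$disease_signature,
                                        bundle$drug_signatures[[id]],
                                        genes = genes,
                                        min_overlap = min_overlap))
  }, numeric(1))

  overlap_n <- function(dm) {
    vapply(drug_ids, function(id) length(intersect(
      module_genes(if (identical(dm, "raw")) dis else dis_exp),
      module_genes(if (identical(dm, "raw")) drugs[[id]] else drug_exp[[id]])
    )), integer(1))
  }

  list(z = z, P = P, sep = sep, C_base = C_base, C_netprop = C_netprop,
       disease_similarity = dis_sim,
       expanded_disease = dis_exp, expanded_drugs = drug_exp,
       overlap_raw = overlap_n("raw"), overlap_expanded = overlap_n("exp"))
}

#' Run the full prediction pipeline on a data bundle
#'
#' Executes proximity z-scores, scaled proximities, pairwise separations,
#' transcriptional correlations (on raw module overlaps in `"base"` mode, or
#' on propagation-expanded overlaps in `"netprop"` mode), scores and ranks
#' all drug pairs, and -- when known synergy labels are present -- evaluates
#' the ranking by ROC AUC.
#'
#' @param bundle A `synth_bundle` (or an equivalently shaped list of loaded
#'   inputs: `net`, `disease_module`, `disease_signature`,
#'   `other_disease_modules`, `drug_modules`, `drug_signatures`,
#'   `fingerprints`, optional `known_pairs`).
#' @param mode `"netprop"` (with propagation-based module amplification) or
#'   `"base"` (without).
#' @param n_perm Permutations for all proximity z-scores (default 100).
#' @param seed Integer seed; every random stage derives its stream from it.
#' @param prop_config A [propagation_config()].
#' @param min_bin_size Degree-bin size for the permutation null.
#' @param min_overlap Minimum gene overlap for a defined cosine correlation.
#' @param outdir Optional directory; when given, every intermediate (drug
#'   statistics, separation matrix, ranked pairs) is written as TSV.
#' @return List with `pairs` (ranked table from [rank_pairs()]),
#'   `drug_stats`, `auc` (or `NA` without labels), `mode`, `stats` (shared
#'   statistics, including both correlation variants).
#' @export
run_pipeline <- function(bundle, mode = c("netprop", "base"), n_perm = 100,
                         seed = 1, prop_config = propagation_config(),
                         min_bin_size = 100, min_overlap = 3, outdir = NULL) {
  mode <- match.arg(mode)
  stats <- pipeline_stats(bundle, n_perm = n_perm, seed = seed,
                          prop_config = prop_config,
                          min_bin_size = min_bin_size,
                          min_overlap = min_overlap)
  assemble_result(bundle, stats, mode, outdir)
}

assemble_result <- function(bundle, stats, mode, outdir = NULL) {
  C <- if (mode == "netprop") stats$C_netprop else stats$C_base
  drug_stats <- data.frame(drug = names(stats$z), z = unname(stats$z),
                           P = unname(stats$P), C = unname(C),
                           stringsAsFactors = FALSE)
  pairs <- rank_pairs(drug_stats, stats$sep)
  auc <- NA_real_
  if (!is.null(bundle$known_pairs) && nrow(bundle$known_pairs) > 0L) {
    lab <- match_known_pairs(pairs, bundle$known_pairs)
    auc <- ranking_auc(pairs$total, lab)
    pairs$known_synergistic <- lab
  }
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(drug_stats, file.path(outdir, paste0("drug_stats_", mode, ".tsv")))
    write_tsv(as.data.frame(stats$sep), file.path(outdir, "separation.tsv"))
    write_tsv(pairs, file.path(outdir, paste0("ranked_pairs_", mode, ".tsv")))
  }
  list(pairs = pairs, drug_stats = drug_stats, auc = auc, mode = mode,
       stats = stats)
}

#' Run both pipeline modes on one bundle and compare
#'
#' Shares all mode-independent statistics (proximity, separation, module
#' expansion) between the two runs, so the comparison isolates the effect of
#' propagation-based module amplification on the transcriptional-correlation
#' component.
#'
#' @inheritParams run_pipeline
#' @return List with `netprop` and `base` results (as [run_pipeline()]) and
#'   `auc` (named numeric vector of both AUCs).
#' @export
compare_modes <- function(bundle, n_perm = 100, seed = 1,
                          prop_config = propagation_config(),
                          min_bin_size = 100, min_overlap = 3) {
  stats <- pipeline_stats(bundle, n_perm = n_perm, seed = seed,
                          prop_config = prop_config,
                          min_bin_size = min_bin_size,
                          min_overlap = min_overlap)
  res_np <- assemble_result(bundle, stats, "netprop")
  res_b <- assemble_result(bundle, stats, "base")
  list(netprop = res_np, base = res_b,
       auc = c(netprop = res_np$auc, base = res_b$auc))
}
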