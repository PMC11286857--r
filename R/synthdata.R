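#' Configuration for the synthetic benchmark generator
#'
#' Defines the planted-structure study conditions under which the pipeline is
#' exercised and benchmarked offline. Defaults describe a 2,000-gene
#' preferential-attachment network carrying one query disease module, 10
#' planted synergistic drug pairs (20 drugs) and 30 decoy drugs, i.e.
#' C(50, 2) = 1,225 candidate pairs.
#'
#' @param n_genes Number of genes (>= 50; default 2000).
#' @param pa_m Edges attached per new node in the preferential-attachment
#'   graph (default 2).
#' @param pa_power Preferential-attachment exponent (default 1, linear).
#' @param n_other_diseases Additional diseases used as propagation priors
#'   (default 4).
#' @param n_planted_pairs Planted synergistic drug pairs (default 10; each
#'   pair contributes two drugs).
#' @param n_decoy_drugs Decoy drugs with random modules (default 30).
#' @param disease_module_size Genes in the query disease module (default 80).
#' @param drug_module_size Genes per drug module (default 40).
#' @param overlap_frac Fraction of each planted drug module drawn from the
#'   disease module itself (default 0.1, i.e. 4 of 40 genes, keeping raw
#'   module overlaps below ten genes as observed for real signatures); the
#'   rest comes from the disease module's network neighborhood.
#' @param rho Target correlation between the disease signature and planted
#'   drug signatures over the disease neighborhood (default 0.6).
#' @param background_sd Standard deviation of background signature noise on
#'   genes outside any planted support (default 0.2; planted values have
#'   unit scale).
#' @param plate_noise_sd Gaussian noise on simulated survival fractions
#'   (default 0.03).
#' @param ec50_range Range from which per-drug EC50 concentrations are drawn
#'   log-uniformly (default c(0.5, 5), arbitrary concentration units).
#' @param hill_slope Dose-response slope parameter (default 1; survival
#'   follows `2^-(c/EC50)^h`, so EC50 gives 50 percent survival).
#' @param bliss_excess Multiplicative excess kill over the Bliss expectation
#'   for planted-synergistic combination wells (default 0.3; 0 = additive).
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_genes = 2000, pa_m = 2, pa_power = 1,
                         n_other_diseases = 4, n_planted_pairs = 10,
                         n_decoy_drugs = 30, disease_module_size = 80,
                         drug_module_size = 40, overlap_frac = 0.1,
                         rho = 0.6, background_sd = 0.2,
                         plate_noise_sd = 0.03, ec50_range = c(0.5, 5),
                         hill_slope = 1, bliss_excess = 0.3) {
  stopifnot(n_genes >= 50, pa_m >= 1, n_planted_pairs >= 1,
            disease_module_size > 0, drug_module_size > 0,
            overlap_frac >= 0, overlap_frac <= 1, rho >= 0, rho <= 1,
            plate_noise_sd >= 0, bliss_excess >= 0, bliss_excess < 1,
            length(ec50_range) == 2L, all(ec50_range > 0))
  if (disease_module_size >= n_genes / 4 || drug_module_size >= n_genes / 4) {
    stop("module sizes must stay below n_genes / 4", call. = FALSE)
  }
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a connected scale-free-like gene network
#'
#' Barabasi-Albert preferential attachment ([igraph::sample_pa()]): connected
#' by construction, with a heavy-tailed degree distribution emulating the
#' hub structure of real interactomes.
#'
#' @param cfg A [synth_config()].
#' @param seed Integer seed; a fixed seed reproduces the edge list exactly.
#' @return A connected `molnet` with genes named `g0001`, `g0002`, ...
#' @export
generate_network <- function(cfg = synth_config(), seed = 1) {
  stopifnot(inherits(cfg, "synth_config"))
  g <- with_seed(seed, igraph::sample_pa(cfg$n_genes, power = cfg$pa_power,
                                         m = cfg$pa_m, directed = FALSE))
  igraph::V(g)$name <- sprintf("g%04d", seq_len(cfg$n_genes))
  as_molnet(igraph::simplify(g))
}

#' Plant disease/drug modules, signatures, fingerprints and synergy labels
#'
#' Builds the full planted benchmark on a given network:
#' * the query disease module is a breadth-first neighborhood of the
#'   highest-degree node;
#' * each planted synergistic drug pair consists of two disjoint modules
#'   drawn from the disease module's wider neighborhood (close to the
#'   disease, hence negative proximity z) plus a small slice of the disease
#'   module itself (`overlap_frac`); the two modules of a pair share no
#'   genes, so they are mutually separated (positive s);
#' * decoy drugs are uniform random gene sets;
#' * signatures cover the full gene universe with low-amplitude background
#'   noise; the disease signature carries unit-scale values on its module
#'   and neighborhood, and planted drug signatures are `rho`-correlated with
#'   it there, so the correlation becomes measurable once modules are
#'   expanded into the neighborhood;
#' * fingerprints are sparse count vectors; planted partners share a feature
#'   block (high chemical similarity), emulating combination-ready drug
#'   pairs;
#' * additional diseases (partially overlapping the query neighborhood)
#'   support the disease-similarity prior.
#'
#' @param net A connected `molnet` (from [generate_network()]).
#' @param cfg A [synth_config()].
#' @param seed Integer seed; all sub-streams derive from it.
#' @return A `synth_bundle` list: `net`, `cfg`, `disease_module`,
#'   `disease_signature`, `other_disease_modules`, `drug_modules`,
#'   `drug_signatures`, `fingerprints`, `known_pairs` (data.frame
#'   `drug_a`, `drug_b`, `synergistic`).
#' @export
plant_modules_and_signatures <- function(net, cfg = synth_config(), seed = 1) {
  stopifnot(inherits(net, "molnet"), inherits(cfg, "synth_config"))
  genes <- network_genes(net)
  n <- length(genes)
  ms <- cfg$disease_module_size
  ds <- cfg$drug_module_size
  ov <- round(cfg$overlap_frac * ds)
  body_ct <- ds - ov
  if (2 * ov > ms) {
    stop("infeasible geometry: pair overlap demand exceeds the disease module",
         call. = FALSE)
  }
  pool_needed <- 2L * cfg$n_planted_pairs * body_ct
  if (ms + pool_needed > n) {
    stop("infeasible geometry: neighborhood cannot host all planted drug modules",
         call. = FALSE)
  }
  with_seed(seed, {
    root <- genes[which.max(igraph::degree(net$graph))]
    ord <- igraph::V(net$graph)$name[
      as.integer(igraph::bfs(net$graph, root = root, order = TRUE)$order)]
    dis_mod_genes <- ord[seq_len(ms)]
    D <- dist_matrix(net)
    ring <- setdiff(names(which(
      apply(D[dis_mod_genes, , drop = FALSE], 2L, min) == 1)), dis_mod_genes)

    # --- drug modules -------------------------------------------------------
    # Each planted drug module is a cohesive "ball": the body_ct genes nearest
    # to an anchor node adjacent to the disease module (ties randomized), all
    # outside the disease module and disjoint from previously planted balls.
    # Cohesive balls around distinct anchors make the two modules of a pair
    # internally tight but mutually separated (positive s), while their
    # adjacency to the disease module keeps the proximity z negative.
    available <- setdiff(genes, dis_mod_genes)
    grow_ball <- function(anchor, size) {
      if (length(available) < size) {
        stop("infeasible geometry: neighborhood cannot host all planted drug modules",
             call. = FALSE)
      }
      d <- D[anchor, available]
      sel <- available[order(d, stats::runif(length(d)))][seq_len(size)]
      available <<- setdiff(available, sel)
      sel
    }
    pick_anchor <- function(away_from = NULL) {
      cand <- intersect(ring, available)
      if (length(cand) == 0L) cand <- available
      if (!is.null(away_from)) {
        far <- cand[D[away_from, cand] >= 3]
        if (length(far) > 0L) cand <- far
      }
      sample(cand, 1L)
    }
    drug_genes <- list()
    known <- NULL
    for (i in seq_len(cfg$n_planted_pairs)) {
      ov_genes <- if (ov > 0) sample(dis_mod_genes, 2L * ov) else character(0)
      a_id <- sprintf("drug_p%02da", i)
      b_id <- sprintf("drug_p%02db", i)
      anchor_a <- pick_anchor()
      ball_a <- grow_ball(anchor_a, body_ct)
      anchor_b <- pick_anchor(away_from = anchor_a)
      ball_b <- grow_ball(anchor_b, body_ct)
      drug_genes[[a_id]] <- c(ball_a, ov_genes[seq_len(ov)])
      drug_genes[[b_id]] <- c(ball_b, ov_genes[ov + seq_len(ov)])
      known <- rbind(known, data.frame(drug_a = a_id, drug_b = b_id,
                                       synergistic = TRUE,
                                       stringsAsFactors = FALSE))
    }
    for (j in seq_len(cfg$n_decoy_drugs)) {
      drug_genes[[sprintf("drug_d%02d", j)]] <- sample(genes, ds)
    }
    planted_body <- setdiff(unlist(drug_genes[seq_len(2L * cfg$n_planted_pairs)],
                                   use.names = FALSE), dis_mod_genes)
    neighborhood <- c(dis_mod_genes, planted_body)

    # --- signatures ---------------------------------------------------------
    base_sig <- function() {
      v <- stats::rnorm(n, 0, cfg$background_sd)
      names(v) <- genes
      v
    }
    dis_sig <- base_sig()
    dis_sig[neighborhood] <- stats::rnorm(length(neighborhood), 0, 1)
    drug_sigs <- list()
    planted_ids <- unlist(lapply(seq_len(cfg$n_planted_pairs), function(i) {
      c(sprintf("drug_p%02da", i), sprintf("drug_p%02db", i))
    }))
    for (id in names(drug_genes)) {
      v <- base_sig()
      if (id %in% planted_ids) {
        v[neighborhood] <- cfg$rho * dis_sig[neighborhood] +
          sqrt(1 - cfg$rho^2) * stats::rnorm(length(neighborhood), 0, 1)
      } else {
        own <- drug_genes[[id]]
        v[own] <- stats::rnorm(length(own), 0, 1)
      }
      drug_sigs[[id]] <- expression_signature(id, v, "drug")
    }

    # --- fingerprints -------------------------------------------------------
    feats <- sprintf("f%03d", 1:200)
    rand_fp <- function(block = NULL) {
      chosen <- unique(c(block, sample(feats, 30)))
      v <- stats::rpois(length(chosen), 2) + 1
      names(v) <- chosen
      v
    }
    fps <- list()
    for (i in seq_len(cfg$n_planted_pairs)) {
      shared <- sample(feats, 20)
      fps[[sprintf("drug_p%02da", i)]] <- rand_fp(shared)
      fps[[sprintf("drug_p%02db", i)]] <- rand_fp(shared)
    }
    for (j in seq_len(cfg$n_decoy_drugs)) {
      fps[[sprintf("drug_d%02d", j)]] <- rand_fp()
    }

    # --- auxiliary diseases for the similarity prior ------------------------
    others <- list()
    for (j in seq_len(cfg$n_other_diseases)) {
      others[[sprintf("disease_o%02d", j)]] <- unique(c(
        sample(neighborhood, min(ms %/% 2, length(neighborhood))),
        sample(genes, ms %/% 2)))
    }

    drug_modules <- lapply(names(drug_genes), function(id) {
      build_module(drug_genes[[id]], net, id = id)
    })
    names(drug_modules) <- names(drug_genes)
    other_modules <- lapply(names(others), function(id) {
      build_module(others[[id]], net, id = id)
    })
    names(other_modules) <- names(others)

    structure(list(
      net = net, cfg = cfg,
      disease_module = build_module(dis_mod_genes, net, id = "query_disease"),
      disease_signature = expression_signature("query_disease", dis_sig,
                                               "disease"),
      other_disease_modules = other_modules,
      drug_modules = drug_modules,
      drug_signatures = drug_sigs,
      fingerprints = fps,
      known_pairs = known,
      neighborhood = neighborhood
    ), class = "synth_bundle")
  })
}

#' Generate network, modules, signatures and labels in one call
#'
#' @inheritParams plant_modules_and_signatures
#' @param seed Integer seed governing both the network and the planted
#'   structure (sub-streams derived by offset).
#' @return A `synth_bundle` (see [plant_modules_and_signatures()]).
#' @export
synth_bundle <- function(cfg = synth_config(), seed = 1) {
  net <- generate_network(cfg, seed = seed)
  plant_modules_and_signatures(net, cfg, seed = seed + 1L)
}

#' @export
print.synth_bundle <- function(x, ...) {
  cat(sprintf("<synth_bundle> %d genes, %d drugs (%d planted pairs), %d extra diseases\n",
              x$cfg$n_genes, length(x$drug_modules), nrow(x$known_pairs),
              length(x$other_disease_modules)))
  invisible(x)
}

#' Read a fixture directory back into a pipeline bundle
#'
#' Inverse of [write_fixtures()]: reconstructs the network, modules,
#' signatures, fingerprints and labels from their plain-text serializations.
#' The first set in `disease_modules.gmt` is taken as the query disease.
#'
#' @param dir Directory written by [write_fixtures()] (or assembled by hand
#'   in the same layout).
#' @return A bundle list suitable for [run_pipeline()].
#' @export
read_fixtures <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("fixture file missing: ", p, call. = FALSE)
    p
  }
  net <- giant_component(suppressMessages(load_network(need("network_edges.tsv"))))
  dis_sets <- read_gmt(need("disease_modules.gmt"))
  drug_sets <- read_gmt(need("drug_modules.gmt"))
  sig_df <- utils::read.table(need("signatures.tsv"), sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  sigs <- lapply(split(sig_df, sig_df$entity), function(d) {
    stats::setNames(d$value, d$gene)
  })
  query_id <- names(dis_sets)[1L]
  drug_ids <- names(drug_sets)
  drug_modules <- lapply(drug_ids, function(id) {
    suppressMessages(build_module(drug_sets[[id]], net, id = id))
  })
  names(drug_modules) <- drug_ids
  other_ids <- names(dis_sets)[-1L]
  other_modules <- lapply(other_ids, function(id) {
    suppressMessages(build_module(dis_sets[[id]], net, id = id))
  })
  names(other_modules) <- other_ids
  kp_path <- file.path(dir, "known_pairs.tsv")
  known <- if (file.exists(kp_path)) {
    utils::read.table(kp_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  } else NULL
  list(
    net = net,
    disease_module = suppressMessages(build_module(dis_sets[[1L]], net,
                                                   id = query_id)),
    disease_signature = expression_signature(query_id, sigs[[query_id]],
                                             "disease"),
    other_disease_modules = other_modules,
    drug_modules = drug_modules,
    drug_signatures = lapply(stats::setNames(drug_ids, drug_ids), function(id) {
      expression_signature(id, sigs[[id]], "drug")
    }),
    fingerprints = read_fingerprints(need("fingerprints.tsv")),
    known_pairs = known
  )
}

#' Simulate a dose-response plate for a drug pair
#'
#' Single-drug survival follows `S(c) = 2^-(c / EC50)^h` (so `EC50` is the
#' 50-percent-survival concentration) measured on a 7-point twofold dilution
#' series around each drug's EC50, with Gaussian noise on the survival
#' fractions. Five combination wells pair the half-doses of matched grid
#' points `(c_i^A / 2, c_i^B / 2)`; their survival is the Bliss prediction
#' `S_A S_B`, multiplied by `(1 - bliss_excess)` when the pair is planted
#' synergistic. With `h = 1`, zero noise and `bliss_excess = 0` the
#' combination is an exact sham mixture, so the Loewe toxic unit is exactly
#' 1 (additivity control). A conservative plate-level synergy call -- every
#' evaluable combination well below the additivity line -- keeps the false
#' call rate on additive plates low under measurement noise.
#'
#' @param cfg A [synth_config()] (uses `ec50_range`, `hill_slope`,
#'   `plate_noise_sd`, `bliss_excess`).
#' @param synergistic Logical: plant a Bliss-excess synergy?
#' @param seed Integer seed (bit-reproducible plates).
#' @param drug_names Character vector of length 2.
#' @return A `dose_response_plate`: list with `curves` (two
#'   [dose_response()] objects) and `combos` (combination well table).
#' @export
generate_plate <- function(cfg = synth_config(), synergistic = FALSE,
                           seed = 1, drug_names = c("drugA", "drugB")) {
  stopifnot(inherits(cfg, "synth_config"), length(drug_names) == 2L)
  with_seed(seed, {
    lo <- log(cfg$ec50_range[1L]); hi <- log(cfg$ec50_range[2L])
    ec50 <- exp(stats::runif(2, lo, hi))
    h <- cfg$hill_slope
    surv_fun <- function(c_, e50) 2^(-(c_ / e50)^h)
    noisy <- function(s) {
      pmin(1.5, pmax(0, s + stats::rnorm(length(s), 0, cfg$plate_noise_sd)))
    }
    curves <- lapply(1:2, function(d) {
      conc <- ec50[d] * 2^seq(-3, 3)
      dose_response(conc, noisy(surv_fun(conc, ec50[d])),
                    drug = drug_names[d])
    })
    names(curves) <- drug_names
    grid_idx <- 2:6  # five wells, safely inside both curves' effect ranges
    combos <- do.call(rbind, lapply(grid_idx, function(i) {
      ca <- curves[[1L]]$concentration[i] / 2
      cb <- curves[[2L]]$concentration[i] / 2
      s_bliss <- surv_fun(ca, ec50[1L]) * surv_fun(cb, ec50[2L])
      s_obs <- s_bliss * (1 - if (synergistic) cfg$bliss_excess else 0)
      data.frame(drug_a = drug_names[1L], conc_a = ca,
                 drug_b = drug_names[2L], conc_b = cb,
                 survival = noisy(s_obs), stringsAsFactors = FALSE)
    }))
    structure(list(curves = curves, combos = combos,
                   ec50 = stats::setNames(ec50, drug_names),
                   synergistic = synergistic),
              class = "dose_response_plate")
  })
}

#' Write a synthetic fixture directory
#'
#' Serializes a bundle as plain-text files: edge list TSV, module GMTs,
#' signature TSVs, fingerprint TSV, known-pair labels TSV and a manifest
#' recording the configuration.
#'
#' @param bundle A `synth_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synth_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  el <- igraph::as_edgelist(bundle$net$graph)
  write_tsv(data.frame(from = el[, 1L], to = el[, 2L]),
            file.path(dir, "network_edges.tsv"))
  write_gmt(c(list(query_disease = bundle$disease_module$genes),
              lapply(bundle$other_disease_modules, `[[`, "genes")),
            file.path(dir, "disease_modules.gmt"))
  write_gmt(lapply(bundle$drug_modules, `[[`, "genes"),
            file.path(dir, "drug_modules.gmt"))
  sig_rows <- function(sig) data.frame(entity = sig$id,
                                       gene = names(sig$values),
                                       value = unname(sig$values))
  write_tsv(do.call(rbind, c(list(sig_rows(bundle$disease_signature)),
                             lapply(bundle$drug_signatures, sig_rows))),
            file.path(dir, "signatures.tsv"))
  fp_rows <- do.call(rbind, lapply(names(bundle$fingerprints), function(id) {
    data.frame(drug = id, feature = names(bundle$fingerprints[[id]]),
               count = unname(bundle$fingerprints[[id]]))
  }))
  write_tsv(fp_rows, file.path(dir, "fingerprints.tsv"))
  write_tsv(bundle$known_pairs, file.path(dir, "known_pairs.tsv"))
  cfg <- bundle$cfg
  manifest <- data.frame(key = names(cfg),
                         value = vapply(cfg, function(v)
                           paste(format(v), collapse = ","), ""))
  write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}
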