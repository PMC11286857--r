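test_that("over-representation p-values match closed forms", {
  universe <- sprintf("u%02d", 1:10)
  pathways <- list(pw = universe[1:5])
  # query = the whole pathway: p = 1 / C(10, 5)
  res <- enrich(universe[1:5], pathways, universe)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)
  expect_true(res$significant)
  # disjoint query cannot be enriched
  res0 <- enrich(universe[6:10], pathways, universe)
  expect_equal(res0$p, 1)
  expect_false(res0$significant)
})

test_that("over-representation matches exhaustive enumeration on small universes", {
  for (s in 1:5) {
    set.seed(s)
    universe <- letters[1:12]
    pw <- sample(universe, sample(3:6, 1))
    query <- sample(universe, sample(3:6, 1))
    k <- length(intersect(query, pw))
    res <- enrich(query, list(pw = pw), universe)
    expect_equal(res$p, brute_hyper_tail(universe, pw, length(query), k),
                 tolerance = 1e-12)
  }
})

test_that("enrich drops out-of-universe genes and validates input", {
  universe <- letters[1:8]
  expect_warning(res <- enrich(c("a", "b", "zz"), list(p1 = c("a", "b")),
                               universe), "dropped")
  expect_equal(res$overlap, 2L)
  expect_error(enrich(character(0), list(p1 = "a"), universe), "empty")
  # optional multiplicity correction is applied when requested
  pws <- list(p1 = letters[1:3], p2 = letters[4:6], p3 = letters[7:8])
  radj <- enrich(letters[1:3], pws, universe, p_adjust = "BH")
  expect_true(all(radj$p_adj >= radj$p))
})

test_that("pathway coverage is the covered fraction of disease pathways", {
  target <- sprintf("pw%03d", 1:187)
  covered <- target[1:151]
  drug_union <- c(covered, sprintf("other%02d", 1:18))  # 169 enriched total
  expect_equal(round(pathway_coverage(target, drug_union), 2), 0.81)
  expect_equal(pathway_coverage(target, c(target, "extra")), 1)
  expect_equal(pathway_coverage(target, "none"), 0)
  expect_error(pathway_coverage(character(0), "x"), "empty")
})

test_that("pathway coverage is monotone as the drug union grows", {
  target <- letters[1:10]
  cov <- vapply(1:10, function(k) pathway_coverage(target, letters[1:k]),
                numeric(1))
  expect_true(all(diff(cov) >= 0))
})

test_that("LCC size is measured on the pathway-induced subgraph", {
  net <- mk_net("a", "b", "b", "c", "c", "d", "d", "e", "x", "a")
  sub <- pathway_subgraph(net, c("a", "b", "c", "d", "e"))
  # module genes forming a connected chain of 4
  expect_equal(lcc_zscore(sub, c("a", "b", "c", "d"), n_perm = 50,
                          seed = 1)$lcc_size, 4L)
  expect_equal(lcc_zscore(sub, "c", n_perm = 10, seed = 1)$lcc_size, 1L)
  miss <- lcc_zscore(sub, c("zz", "qq"), n_perm = 10, seed = 1)
  expect_equal(miss$lcc_size, 0L)
  expect_true(is.na(miss$z))
  expect_false(miss$significant)
})

test_that("a clustered module is significant, and the null rate is controlled", {
  net <- random_connected_net(40, extra = 25, seed = 12)
  sub <- pathway_subgraph(net, network_genes(net))
  # a connected ball of genes: significantly clustered
  ball <- names(sort(fw_distances(net)["n01", ]))[1:8]
  r <- lcc_zscore(sub, ball, n_perm = 300, seed = 2)
  expect_equal(r$lcc_size, 8L)
  expect_gt(r$z, 1.95)
  expect_true(r$significant)

  # random same-size modules exceed z > 1.95 rarely
  hits <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    genes <- sample(network_genes(net), 8)
    isTRUE(lcc_zscore(sub, genes, n_perm = 100, seed = s)$significant)
  }, logical(1))
  expect_lte(mean(hits), 0.07)
})

test_that("DEG filtering includes the threshold boundary", {
  tab <- c(g1 = 1.2, g2 = -0.5, g3 = -1.0, g4 = 0.99)
  expect_setequal(deg_filter(tab), c("g1", "g3"))
  # at threshold 0.5 all four genes qualify (|0.99| >= 0.5 included too)
  expect_setequal(deg_filter(tab, threshold = 0.5), c("g1", "g2", "g3", "g4"))
  expect_equal(deg_filter(c(a = 0, b = 0)), character(0))
  expect_error(deg_filter(tab, threshold = 0), "> 0")
  # data.frame input
  df <- data.frame(gene = names(tab), log2fc = unname(tab))
  expect_setequal(deg_filter(df), c("g1", "g3"))
})
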