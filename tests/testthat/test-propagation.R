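test_that("adjacency normalization matches hand-derived weights", {
  # single edge: degrees 1, weight 1
  W <- normalize_adjacency(mk_net("a", "b"))
  expect_equal(W["a", "b"], 1)
  # triangle: all degrees 2, weights 1/2
  Wt <- normalize_adjacency(mk_net("a", "b", "b", "c", "c", "a"))
  expect_equal(Wt["a", "b"], 0.5)
  expect_equal(Wt["b", "c"], 0.5)
  # star with 3 leaves: hub degree 3, leaf degree 1 => 1/sqrt(3)
  Ws <- normalize_adjacency(mk_net("h", "l1", "h", "l2", "h", "l3"))
  expect_equal(Ws["h", "l1"], 1 / sqrt(3))
})

test_that("normalized adjacency has spectral radius at most 1", {
  net <- random_connected_net(20, extra = 15, seed = 3)
  W <- as.matrix(normalize_adjacency(net))
  expect_lte(max(abs(eigen(W, only.values = TRUE)$values)), 1 + 1e-10)
})

test_that("iterative propagation matches the closed-form linear solve", {
  for (s in 1:4) {
    net <- random_connected_net(sample(10:30, 1), extra = 20, seed = s)
    W <- normalize_adjacency(net)
    set.seed(s)
    prior <- stats::runif(5)
    names(prior) <- sample(network_genes(net), 5)
    for (alpha in c(0.3, 0.5, 0.8)) {
      cfg <- propagation_config(alpha = alpha, tol = 1e-8)
      it <- propagate(W, prior, cfg)
      ex <- propagate_exact(W, prior, cfg)
      expect_true(it$converged)
      expect_lt(max(abs(it$scores - ex[names(it$scores)])), 10 * cfg$tol)
    }
  }
})

test_that("as alpha approaches 0 the scores approach the prior", {
  net <- mk_net("a", "b", "b", "c")
  W <- normalize_adjacency(net)
  f <- propagate(W, c(a = 1), propagation_config(alpha = 1e-5))$scores
  expect_equal(unname(f["a"]), 1, tolerance = 1e-4)
  expect_equal(unname(f["c"]), 0, tolerance = 1e-4)
})

test_that("symmetric graphs with symmetric priors give symmetric scores", {
  net <- mk_net("a", "b", "b", "c")  # path; a and c are exchangeable
  W <- normalize_adjacency(net)
  f <- propagate(W, c(a = 0.7, c = 0.7))$scores
  expect_equal(unname(f["a"]), unname(f["c"]))
})

test_that("scores are monotone in the prior", {
  net <- random_connected_net(15, extra = 10, seed = 8)
  W <- normalize_adjacency(net)
  g <- network_genes(net)[4]
  prior <- c(0.5, 0.2); names(prior) <- network_genes(net)[c(1, 4)]
  f1 <- propagate(W, prior)$scores
  prior2 <- prior; prior2[g] <- 0.9
  f2 <- propagate(W, prior2)$scores
  expect_true(all(f2 >= f1 - 1e-12))
  expect_gt(f2[g], f1[g])
})

test_that("propagate validates priors and flags non-convergence", {
  W <- normalize_adjacency(mk_net("a", "b"))
  expect_error(propagate(W, c(a = -0.1)), "non-negative")
  expect_error(propagate(W, c(zz = 1)), "all zero")
  expect_warning(r <- propagate(W, c(a = 1),
                                propagation_config(tol = 1e-15, max_iter = 2)),
                 "converge")
  expect_false(r$converged)
})

test_that("build_prior combines own membership with similarity transfer", {
  own <- c("a", "b")
  expect_equal(build_prior(own), c(a = 1, b = 1))
  sims <- list(list(module = c("b", "c"), similarity = 0.4),
               list(module = c("c", "d"), similarity = 0.7))
  y <- build_prior(own, sims)
  expect_equal(y[["c"]], 0.7)   # max rule over the two similar entities
  expect_equal(y[["d"]], 0.7)
  expect_equal(y[["b"]], 1)     # own membership dominates
  y_sum <- build_prior(own, sims, prior_agg = "sum")
  expect_equal(y_sum[["c"]], min(1, 0.4 + 0.7))
})

test_that("expand_module admits top-k neighbor candidates", {
  net <- mk_net("a", "b", "b", "c")
  m <- build_module("b", net)
  expect_setequal(expand_module(m, NULL, net, k = 2)$genes_on_network,
                  c("a", "b", "c"))
  expect_setequal(expand_module(m, NULL, net, k = 0)$genes_on_network, "b")

  # scored expansion keeps the best-scoring candidate
  net2 <- mk_net("a", "b", "b", "c", "c", "d", "b", "e")
  m2 <- build_module("b", net2)
  sc <- c(a = 0.1, c = 0.9, e = 0.5, d = 0.3)
  expect_setequal(expand_module(m2, sc, net2, k = 1)$genes_on_network,
                  c("b", "c"))
  # output size = |module| + min(k, #candidates)
  for (k in 0:4) {
    expect_length(expand_module(m2, sc, net2, k = k)$genes_on_network,
                  1L + min(k, 3L))
  }
})

test_that("expansion warns when the module has no candidates", {
  net <- mk_net("a", "b")
  m <- build_module(c("a", "b"), net)
  expect_warning(out <- expand_module(m, NULL, net), "no neighbor")
  expect_setequal(out$genes_on_network, c("a", "b"))
})
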