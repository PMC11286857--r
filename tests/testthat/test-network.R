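test_that("load_network removes self-loops and duplicate interactions", {
  net <- mk_net("a", "b", "b", "a", "b", "b", "b", "c")
  expect_equal(unname(network_size(net)), c(3L, 2L))
  el <- igraph::as_edgelist(net$graph)
  expect_setequal(apply(el, 1, function(e) paste(sort(e), collapse = "-")),
                  c("a-b", "b-c"))

  path5 <- mk_net("a", "b", "b", "c", "c", "d", "d", "e")
  expect_equal(unname(network_size(path5)), c(5L, 4L))
})

test_that("load_network validates its input and reads files", {
  expect_error(load_network(data.frame(a = character(), b = character())),
               "empty")
  expect_error(load_network(data.frame(a = "x", b = "")), "line")

  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "from\tto", "a\tb", "b\tc"), tmp)
  net <- suppressMessages(load_network(tmp))
  expect_equal(unname(network_size(net)), c(3L, 2L))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "solo"), bad)
  expect_error(suppressMessages(load_network(bad)), "line")
})

test_that("giant_component keeps the largest component and is idempotent", {
  net <- mk_net("a", "b", "b", "c", "c", "d", "x", "y")  # sizes 4 and 2
  gc <- giant_component(net)
  expect_setequal(network_genes(gc), c("a", "b", "c", "d"))

  # connected graph is returned unchanged (identity case)
  con <- mk_net("a", "b", "b", "c")
  expect_equal(network_size(giant_component(con)), network_size(con))

  gc2 <- giant_component(gc)
  expect_equal(sort(network_genes(gc2)), sort(network_genes(gc)))
  expect_equal(network_size(gc2), network_size(gc))
})

test_that("giant_component breaks size ties deterministically", {
  net <- mk_net("b", "c", "a", "d")  # two components of size 2
  gc <- giant_component(net)
  expect_setequal(network_genes(gc), c("a", "d"))  # contains smallest name
})

test_that("shortest_path_lengths agrees with BFS on simple chains", {
  net <- mk_net("a", "b", "b", "c")
  d <- shortest_path_lengths(net, c("a"), c("c"))
  expect_equal(d["a", "c"], 2)
  expect_equal(shortest_path_lengths(net, "a", "a")["a", "a"], 0)
  expect_error(shortest_path_lengths(net, "a", "zz"), "zz")
})

test_that("shortest paths match a Floyd-Warshall oracle on random graphs", {
  for (s in 1:3) {
    net <- random_connected_net(30, extra = 25, seed = s)
    nodes <- network_genes(net)
    expect_equal(shortest_path_lengths(net, nodes, nodes)[nodes, nodes],
                 fw_distances(net)[nodes, nodes])
  }
})

test_that("degree bins partition the node set with the requested minimum size", {
  net <- random_connected_net(60, extra = 60, seed = 4)
  bins <- make_degree_bins(net, min_bin_size = 10)
  all_nodes <- unlist(bins$bins)
  expect_setequal(all_nodes, network_genes(net))
  expect_equal(anyDuplicated(all_nodes), 0L)
  expect_true(all(lengths(bins$bins) >= 10))

  single <- make_degree_bins(net, min_bin_size = 1000)
  expect_length(single$bins, 1L)
})

test_that("degree-matched sampling preserves size and is seed-reproducible", {
  net <- random_connected_net(50, extra = 50, seed = 5)
  bins <- make_degree_bins(net, min_bin_size = 10)
  tmpl <- network_genes(net)[1:7]
  s1 <- degree_matched_sample(net, tmpl, bins, seed = 42)
  s2 <- degree_matched_sample(net, tmpl, bins, seed = 42)
  expect_identical(s1, s2)
  expect_length(s1, 7L)
  expect_true(all(s1 %in% network_genes(net)))
  s3 <- degree_matched_sample(net, tmpl, bins, seed = 43)
  expect_false(identical(s1, s3))
})

test_that("an exhausted degree bin raises an informative error", {
  net <- mk_net("a", "b", "b", "c")
  fake_bins <- structure(list(bins = list("a"), node2bin = c(a = 1L, b = 1L),
                              min_bin_size = 1L), class = "degree_bins")
  expect_error(degree_matched_sample(net, c("a", "b"), fake_bins, seed = 1),
               "min_bin_size")
})

test_that("within a single bin sampling is uniform over members", {
  net <- mk_net("a", "b", "b", "c", "c", "d", "d", "e", "e", "f")
  bins <- make_degree_bins(net, min_bin_size = 100)  # one bin of 6
  n_draw <- 3000
  draws <- vapply(seq_len(n_draw), function(i) {
    degree_matched_sample(net, "a", bins, seed = i)
  }, "")
  counts <- table(factor(draws, levels = network_genes(net)))
  p <- 1 / 6
  sd3 <- 3 * sqrt(n_draw * p * (1 - p))
  expect_true(all(abs(counts - n_draw * p) <= sd3))
})
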