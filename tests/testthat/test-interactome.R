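test_that("edge-list loading deduplicates pairs and drops self-loops", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("1\t2", "2\t3", "4\t5"), f)
  net <- load_interactome(f, quiet = TRUE)
  expect_lte(igraph::vcount(net), 6L)
  expect_equal(igraph::ecount(net), 3L)

  # (a,b) and (b,a) are the same undirected interaction
  writeLines(c("1\t2", "2\t1", "1\t2", "2\t3"), f)
  net <- load_interactome(f, quiet = TRUE)
  expect_equal(igraph::ecount(net), 2L)

  # a self-interaction is dropped with a warning
  writeLines(c("1\t1", "1\t2"), f)
  expect_warning(net <- load_interactome(f, quiet = TRUE), "self-loop")
  expect_equal(igraph::ecount(net), 1L)

  # malformed rows skipped with a count, not fatal
  writeLines(c("1\t2", "orphan", "3\t4"), f)
  expect_warning(net <- load_interactome(f, quiet = TRUE), "unparsable")
  expect_equal(igraph::ecount(net), 2L)

  expect_error(load_interactome(tempfile()), "not found")
})

test_that("header rows are auto-detected, plain ID rows are not", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b", "10\t20", "20\t30"), f)
  expect_equal(igraph::ecount(load_interactome(f, quiet = TRUE)), 2L)
  writeLines(c("g1\tg2", "g2\tg3"), f)  # string IDs, no header
  expect_equal(igraph::ecount(load_interactome(f, quiet = TRUE)), 2L)
})

test_that("edge count equals unique unordered non-loop pairs on random input", {
  withr::with_seed(19, {
    for (rep in 1:5) {
      a <- sample(8, 60, replace = TRUE)
      b <- sample(8, 60, replace = TRUE)
      f <- tempfile(fileext = ".tsv")
      writeLines(paste(a, b, sep = "\t"), f)
      expected <- nrow(unique(cbind(pmin(a, b), pmax(a, b))[a != b, , drop = FALSE]))
      net <- suppressWarnings(load_interactome(f, quiet = TRUE))
      expect_equal(igraph::ecount(net), expected)
    }
  })
})

test_that("largest connected component matches a union-find oracle", {
  # path a-b-c
  net <- interactome_from_edges(data.frame(a = c("a", "b"), b = c("b", "c")))
  lcc <- largest_connected_component(net, c("a", "b", "c"))
  expect_equal(lcc$nodes, c("a", "b", "c"))
  expect_equal(lcc$n_edges, 2L)

  # two components: {a,b,c} triangle-path beats {d,e}
  net <- interactome_from_edges(
    data.frame(a = c("a", "b", "d"), b = c("b", "c", "e")))
  expect_equal(largest_connected_component(net, c("a", "b", "c", "d", "e"))$nodes,
               c("a", "b", "c"))

  # ties go to the lexicographically smallest member set
  net <- interactome_from_edges(data.frame(a = c("x", "a"), b = c("y", "b")))
  expect_equal(largest_connected_component(net, c("x", "y", "a", "b"))$nodes,
               c("a", "b"))

  # genes missing from the network are dropped with a warning
  expect_warning(lcc <- largest_connected_component(net, c("a", "b", "zz")),
                 "not in interactome")
  expect_equal(lcc$nodes, c("a", "b"))
  suppressWarnings(
    expect_warning(res <- largest_connected_component(net, "zz"),
                   "no input gene"))
  expect_equal(res$nodes, character(0))

  # random graphs vs the union-find oracle
  withr::with_seed(5, {
    for (rep in 1:10) {
      net <- random_graph(40, p = 0.06)
      genes <- sample(igraph::V(net)$name, 15)
      comps <- components_oracle(net, genes)
      sizes <- lengths(comps)
      best <- comps[sizes == max(sizes)]
      best <- lapply(best, sort)
      best <- best[[order(vapply(best, paste, "", collapse = "\r"))[1]]]
      expect_equal(largest_connected_component(net, genes)$nodes, best)
    }
  })
})

test_that("degree bins partition the node set and stay populated", {
  net <- random_graph(300, p = 0.03, seed = 2)
  bins <- degree_bins(net)
  expect_setequal(unlist(bins$members), igraph::V(net)$name)
  expect_equal(sum(lengths(bins$members)), igraph::vcount(net))
  if (length(bins$members) > 1L) {
    expect_true(all(lengths(bins$members) >= 20L))
  }
  # every node maps into exactly the bin listing it
  for (k in seq_along(bins$members)) {
    expect_true(all(bins$bin_of[bins$members[[k]]] == k))
  }
})

test_that("degree-preserving sampling preserves the bin histogram and the seed", {
  net <- random_graph(200, p = 0.04, seed = 3)
  bins <- degree_bins(net)
  genes <- withr::with_seed(4, sample(igraph::V(net)$name, 25))
  s1 <- degree_preserving_sample(net, genes, bins, rng_seed = 11)
  s2 <- degree_preserving_sample(net, genes, bins, rng_seed = 11)
  expect_identical(s1, s2)
  expect_length(s1, length(genes))
  expect_false(anyDuplicated(s1) > 0)
  expect_true(all(s1 %in% igraph::V(net)$name))
  expect_equal(table(bins$bin_of[s1]), table(bins$bin_of[genes]))
  expect_error(degree_preserving_sample(net, "nope", bins), "absent")
})

test_that("on a regular graph any subset is a valid degree-matched draw", {
  ring <- igraph::make_ring(12)
  igraph::V(ring)$name <- letters[1:12]
  s <- degree_preserving_sample(ring, c("a", "b", "c"), rng_seed = 1)
  expect_length(s, 3L)
  expect_true(all(s %in% letters[1:12]))
})

test_that("module significance flags a planted clique and not a lone gene", {
  withr::with_seed(8, {
    g <- igraph::sample_gnp(200, 0.015)
    igraph::V(g)$name <- sprintf("g%d", 1:200)
    clique <- sprintf("g%d", 1:10)
    g <- igraph::add_edges(g, t(utils::combn(clique, 2)))
    g <- igraph::simplify(g)
  })
  sig <- module_significance(g, clique, n_perm = 1000, rng_seed = 21)
  expect_equal(sig$observed_lcc_size, 10L)
  expect_lte(sig$p_value, 0.01)
  expect_equal(length(sig$null_lcc_sizes), 1000L)

  single <- module_significance(g, "g50", n_perm = 50, rng_seed = 1)
  expect_equal(single$observed_lcc_size, 1L)
  expect_equal(single$p_value, 1)
})

test_that("permutation p agrees with the exhaustive null on a tiny graph", {
  net <- interactome_from_edges(data.frame(
    a = c("a", "b", "c", "e", "f", "h"),
    b = c("b", "c", "d", "f", "g", "i")))
  net <- igraph::add_vertices(net, 1, name = "j")  # 10 nodes, one bin
  nodes <- igraph::V(net)$name
  genes <- c("a", "b", "c")
  # all C(10, 3) subsets: exact distribution of null LCC sizes
  subsets <- utils::combn(nodes, 3)
  null_exact <- apply(subsets, 2, function(s)
    length(suppressWarnings(largest_connected_component(net, s))$nodes))
  obs <- length(largest_connected_component(net, genes)$nodes)
  p_exact <- mean(null_exact >= obs)
  sig <- module_significance(net, genes, n_perm = 2000, rng_seed = 13)
  mc_err <- 3 * sqrt(p_exact * (1 - p_exact) / 2000) + 1 / 2000
  expect_lt(abs(sig$p_value - p_exact), mc_err)
})

test_that("module significance p is roughly uniform for random gene sets", {
  net <- random_graph(150, p = 0.04, seed = 31)
  bins <- degree_bins(net)
  ps <- withr::with_seed(32, vapply(1:40, function(i) {
    genes <- sample(igraph::V(net)$name, 12)
    module_significance(net, genes, n_perm = 200, bins = bins)$p_value
  }, 0))
  # LCC sizes are heavily tied small integers, so the permutation p is
  # discrete and conservative: check super-uniformity, not exact uniformity
  for (alpha in c(0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(ps <= alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / 40))
  }
  expect_gt(mean(ps), 0.5 - 3 * sqrt(1 / 12 / 40))
  expect_true(all(ps > 0) && all(ps <= 1))
})
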