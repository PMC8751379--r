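test_that("candidate windows are closed, truncated nearest-first", {
  loci <- data.frame(snp_id = "rs1", chr = "chr1", pos = 1000000L,
                     p_value = 1e-6)
  ann <- data.frame(gene_id = c("gA", "gB", "gC"), chr = "chr1",
                    tss = c(100000L, 1500000L, 2100000L))
  tab <- build_candidate_sets(loci, ann)
  expect_setequal(tab[["rs1"]]$candidates, c("gA", "gB"))

  # TSS exactly at the window edge (1 Mb away) is still inside
  ann_edge <- data.frame(gene_id = "gE", chr = "chr1", tss = 2000000L)
  tab <- build_candidate_sets(loci, ann_edge)
  expect_equal(tab[["rs1"]]$candidates, "gE")

  # 30 genes in window, default cap 20: the 20 nearest are kept
  ann30 <- data.frame(gene_id = sprintf("g%02d", 1:30), chr = "chr1",
                      tss = 1000000L + (1:30) * 20000L)
  tab <- build_candidate_sets(loci, ann30)
  expect_equal(tab[["rs1"]]$candidates, sprintf("g%02d", 1:20))

  # equal distance resolves to the smaller gene id
  ann_tie <- data.frame(gene_id = c("gZ", "gA"), chr = "chr1",
                        tss = c(900000L, 1100000L))
  tab <- build_candidate_sets(loci, ann_tie, max_candidates = 1)
  expect_equal(tab[["rs1"]]$candidates, "gA")

  # loci with no gene in the window are dropped with a warning
  loci2 <- rbind(loci, data.frame(snp_id = "rs2", chr = "chr9",
                                  pos = 5000000L, p_value = 1e-7))
  expect_warning(tab <- build_candidate_sets(loci2, ann), "dropped")
  expect_named(tab, "rs1")
  expect_error(build_candidate_sets(loci, ann[0, ]), "empty")
})

test_that("Bayes-factor weights follow RWR reachability", {
  path <- interactome_from_edges(data.frame(a = c("a", "b"), b = c("b", "c")))
  path <- igraph::add_vertices(path, 1, name = "iso")
  tm <- build_transition_matrix(path)
  W <- rwr_proximity_matrix(tm, rwr_config(tol = 1e-16))

  # nearer candidate to the conditioning set gets the larger weight,
  # consistent with the closed-form RWR oracle
  w <- bayes_factor_scores(W, c("a", "b"), "c")
  expect_gt(w[["b"]], w[["a"]])
  qa <- rwr_solve_oracle(path, "a"); qb <- rwr_solve_oracle(path, "b")
  expect_equal(unname(w["a"] / w["b"]), unname(qa["c"] / qb["c"]),
               tolerance = 1e-6)
  expect_equal(sum(w), 1)

  # an isolated candidate is unreachable: raw score 0
  w <- bayes_factor_scores(W, c("iso", "b"), "c")
  expect_equal(w[["iso"]], 0)

  # symmetric candidates (path ends vs the middle) get equal weight
  w <- bayes_factor_scores(W, c("a", "c"), "b")
  expect_equal(w[["a"]], w[["c"]], tolerance = 1e-9)

  # all-zero scores fall back to uniform; unknown candidates warn
  w <- suppressWarnings(bayes_factor_scores(W, c("x1", "x2"), "c"))
  expect_equal(unname(w), c(0.5, 0.5))
  expect_warning(bayes_factor_scores(W, c("x1", "b"), "c"), "absent")
  expect_equal(sum(bayes_factor_scores(W, c("a", "b"), character(0))), 1)
})

test_that("single-candidate loci converge immediately with frequency 1", {
  net <- interactome_from_edges(data.frame(a = c("a", "b"), b = c("b", "c")))
  W <- rwr_proximity_matrix(build_transition_matrix(net))
  tab <- toy_locus_table(list("a", "c"))
  post <- gibbs_sample(tab, W, gibbs_config(rng_seed = 1))
  expect_true(post$converged)
  expect_equal(unname(post$freq[["rs1"]]), 1)
  expect_equal(unname(post$freq[["rs2"]]), 1)
  expect_lte(post$rounds_used, 15L)
})

test_that("Gibbs frequencies sum to one per locus and are seed-reproducible", {
  sim <- simulate_interactome_with_module(
    benchmark_spec(n_nodes = 120, n_loci = 5, module_size = 8,
                   candidates_per_locus = 3, rng_seed = 5))
  gwas <- simulate_gwas_benchmark(sim$net, sim$planted,
    benchmark_spec(n_nodes = 120, n_loci = 5, module_size = 8,
                   candidates_per_locus = 3, rng_seed = 5))
  tm <- build_transition_matrix(sim$net)
  W <- rwr_proximity_matrix(tm, restrict_rows = cand_universe(gwas$locus_table))
  cfg <- gibbs_config(rng_seed = 42, max_rounds = 120)
  p1 <- suppressWarnings(gibbs_sample(gwas$locus_table, W, cfg))
  p2 <- suppressWarnings(gibbs_sample(gwas$locus_table, W, cfg))
  expect_identical(p1, p2)
  for (f in p1$freq) expect_equal(sum(f), 1, tolerance = 1e-9)
})

test_that("two-locus Gibbs matches the exact stationary distribution", {
  # arbitrary positive proximity kernel over 4 candidate genes
  genes <- c("u1", "u2", "v1", "v2")
  W <- withr::with_seed(7, matrix(runif(16, 0.2, 1.2), 4,
                                  dimnames = list(genes, genes)))
  tab <- toy_locus_table(list(c("u1", "u2"), c("v1", "v2")))
  exact <- gibbs_stationary_oracle(W, c("u1", "u2"), c("v1", "v2"))
  chains <- lapply(1:8, function(s) suppressWarnings(
    gibbs_sample(tab, W, gibbs_config(tol = 1e-12, max_rounds = 1260L,
                                      burn_in = 10L, rng_seed = 100 + s))))
  est1 <- sapply(chains, function(p) p$freq[["rs1"]][["u1"]])
  se <- sd(est1) / sqrt(length(est1))
  expect_lt(abs(mean(est1) - exact$locus1[["u1"]]), 3 * se + 0.005)
  est2 <- sapply(chains, function(p) p$freq[["rs2"]][["v1"]])
  se2 <- sd(est2) / sqrt(length(est2))
  expect_lt(abs(mean(est2) - exact$locus2[["v1"]]), 3 * se2 + 0.005)
})

test_that("per-round halting stops when a sweep repeats its selection", {
  genes <- c("u1", "u2", "v1", "v2")
  # near-deterministic kernel: u1 and v1 dominate
  W <- matrix(0.01, 4, 4, dimnames = list(genes, genes))
  W["u1", c("v1", "v2")] <- 5; W["v1", c("u1", "u2")] <- 5
  tab <- toy_locus_table(list(c("u1", "u2"), c("v1", "v2")))
  post <- gibbs_sample(tab, W, gibbs_config(rng_seed = 3, burn_in = 2L,
                                            halt_on = "per_round"))
  expect_true(post$converged)
  expect_lte(post$rounds_used, 30L)
})

test_that("risk-gene selection merges loci and defines background genes", {
  tab <- toy_locus_table(list(c("a", "b"), c("a", "c"), c("d", "e")))
  post <- structure(list(
    freq = list(rs1 = c(a = 0.6, b = 0.4),
                rs2 = c(a = 0.9, c = 0.1),
                rs3 = c(d = 0.5, e = 0.5)),  # tie: first (nearer) wins
    rounds_used = 10L, converged = TRUE), class = "posterior_table")
  rgs <- select_risk_genes(post, tab)
  expect_equal(rgs$risk_genes, c("a", "d"))      # a merged across two loci
  expect_equal(unname(rgs$per_locus_choice[c("rs1", "rs2", "rs3")]),
               c("a", "a", "d"))
  expect_equal(rgs$background_genes, c("b", "c", "e"))
  expect_length(intersect(rgs$risk_genes, rgs$background_genes), 0)
  expect_setequal(c(rgs$risk_genes, rgs$background_genes),
                  c("a", "b", "c", "d", "e"))
  expect_equal(unname(rgs$confidence["a"]), 0.9)  # max over loci
  post$freq <- post$freq[1:2]
  expect_error(select_risk_genes(post, tab), "does not cover")
})

test_that("planted-gene recovery improves with module density", {
  rec <- vapply(c(0.05, 0.45), function(dens) {
    spec <- benchmark_spec(n_nodes = 250, n_loci = 10, module_size = 12,
                           candidates_per_locus = 5, module_density = dens,
                           rng_seed = 9)
    sim <- simulate_interactome_with_module(spec)
    gwas <- simulate_gwas_benchmark(sim$net, sim$planted, spec)
    tm <- build_transition_matrix(sim$net)
    W <- rwr_proximity_matrix(tm, restrict_rows = cand_universe(gwas$locus_table))
    post <- suppressWarnings(
      gibbs_sample(gwas$locus_table, W, gibbs_config(rng_seed = 9)))
    rgs <- select_risk_genes(post, gwas$locus_table)
    mean(rgs$per_locus_choice[names(gwas$truth)] == gwas$truth)
  }, 0)
  expect_gt(rec[2], rec[1])
})
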