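# Synthetic benchmark generators.
#
# The generators emulate the statistical structure the algorithms assume:
# a sparse heavy-tailed interactome, GWAS loci whose true gene belongs to
# a densely interconnected planted module, and drugs whose targets are
# either proximal or distal to that module. Everything is a pure function
# of (spec, seed).

#' Benchmark specification
#'
#' Defaults define the package's standard desk-scale benchmark: a 500-node
#' preferential-attachment graph, a 20-gene planted module at internal
#' edge density 0.3, 20 loci with 5 candidates each, and 5 proximal vs 45
#' distal drugs with 3 targets each.
#'
#' @param n_nodes Background graph size.
#' @param edges_per_node Preferential-attachment edges added per node (or
#'   expected degree/2 for the `"er"` background).
#' @param background `"pa"` (preferential attachment, default) or `"er"`
#'   (uniform random, for calibration tests).
#' @param n_loci Number of GWAS loci.
#' @param candidates_per_locus Candidate genes per locus.
#' @param module_size Planted module size; defaults to `n_loci`.
#' @param module_density Internal edge density of the planted module, in
#'   (0, 1].
#' @param n_proximal,n_distal Numbers of proximal / distal drugs.
#' @param targets_per_drug Targets per drug.
#' @param distal_min_hops Minimum hop distance of distal-drug targets from
#'   the planted module.
#' @param rng_seed Integer seed; every generator is deterministic in it.
#' @return List of class `benchmark_spec`.
#' @export
benchmark_spec <- function(n_nodes = 500L, edges_per_node = 3L,
                           background = c("pa", "er"),
                           n_loci = 20L, candidates_per_locus = 5L,
                           module_size = NULL, module_density = 0.3,
                           n_proximal = 5L, n_distal = 45L,
                           targets_per_drug = 3L, distal_min_hops = 3L,
                           rng_seed = 7L) {
  module_size <- as.integer(module_size %||% n_loci)
  stopifnot(n_nodes > module_size, module_density > 0, module_density <= 1,
            n_loci >= 1L, candidates_per_locus >= 1L, module_size >= n_loci,
            n_proximal + n_distal >= 1L, targets_per_drug >= 1L)
  structure(list(n_nodes = as.integer(n_nodes),
                 edges_per_node = as.integer(edges_per_node),
                 background = match.arg(background),
                 n_loci = as.integer(n_loci),
                 candidates_per_locus = as.integer(candidates_per_locus),
                 module_size = module_size,
                 module_density = module_density,
                 n_proximal = as.integer(n_proximal),
                 n_distal = as.integer(n_distal),
                 targets_per_drug = as.integer(targets_per_drug),
                 distal_min_hops = as.integer(distal_min_hops),
                 rng_seed = as.integer(rng_seed)),
            class = "benchmark_spec")
}

#' Simulate an interactome with a planted dense module
#'
#' Generates a scale-free-like background graph (preferential attachment,
#' or uniform random with matched edge count for `background = "er"`),
#' picks a random planted gene set, and adds edges among the planted genes
#' until their internal edge density reaches `module_density`.
#'
#' @param spec A [benchmark_spec()].
#' @return List with `net` (igraph, nodes named g1..gN) and `planted`
#'   (sorted character vector).
#' @export
simulate_interactome_with_module <- function(spec = benchmark_spec()) {
  with_seed_if(spec$rng_seed, {
    g <- if (spec$background == "pa") {
      igraph::sample_pa(spec$n_nodes, power = 1, m = spec$edges_per_node,
                        directed = FALSE)
    } else {
      igraph::sample_gnm(spec$n_nodes,
                         min(spec$n_nodes * spec$edges_per_node,
                             choose(spec$n_nodes, 2L)))
    }
    igraph::V(g)$name <- sprintf("g%d", seq_len(spec$n_nodes))
    g <- igraph::simplify(g)
    planted <- sort(sample_vec(igraph::V(g)$name, spec$module_size))
    n_pairs <- choose(length(planted), 2L)
    target_edges <- ceiling(spec$module_density * n_pairs)
    if (target_edges > n_pairs) stop("module density infeasible")
    pairs <- t(utils::combn(planted, 2L))
    Ap <- igraph::as_adjacency_matrix(g, sparse = TRUE)[planted, planted]
    have <- Ap[pairs] > 0
    need <- target_edges - sum(have)
    if (need > 0) {
      add <- sample_vec(which(!have), need)
      g <- igraph::add_edges(g, t(pairs[add, , drop = FALSE]))
    }
    list(net = igraph::simplify(g), planted = planted)
  })
}

#' Simulate a GWAS benchmark over a planted module
#'
#' Each locus gets one planted (true) gene plus degree-matched decoys from
#' the non-planted nodes, placed on its own synthetic chromosome with SNP
#' and TSS coordinates consistent with [build_candidate_sets()] windows
#' (the true gene is *not* systematically the nearest to the SNP). Genes
#' are unique across loci.
#'
#' @param net Interactome from [simulate_interactome_with_module()].
#' @param planted Planted gene set.
#' @param spec A [benchmark_spec()].
#' @return List with `loci` (data frame), `annotations` (data frame),
#'   `locus_table` (via [build_candidate_sets()]) and `truth` (named
#'   character vector, SNP ID -> true gene).
#' @export
simulate_gwas_benchmark <- function(net, planted, spec = benchmark_spec()) {
  if (length(planted) < spec$n_loci) stop("need |planted| >= n_loci")
  bins <- degree_bins(net)
  nodes <- igraph::V(net)$name
  with_seed_if(spec$rng_seed + 1L, {
    true_genes <- sample_vec(planted, spec$n_loci)
    used <- character(0)
    loci <- data.frame(snp_id = sprintf("rs%04d", seq_len(spec$n_loci)),
                       chr = sprintf("chr%d", seq_len(spec$n_loci)),
                       pos = 50000000L,
                       p_value = signif(runif(spec$n_loci, 1e-9, 1e-5), 3),
                       stringsAsFactors = FALSE)
    ann <- vector("list", spec$n_loci)
    for (l in seq_len(spec$n_loci)) {
      tg <- true_genes[l]
      n_decoy <- spec$candidates_per_locus - 1L
      pool <- setdiff(bins$members[[bins$bin_of[[tg]]]], c(planted, used))
      if (length(pool) < n_decoy) {
        # widen to the whole non-planted node set, nearest degree first
        extra <- setdiff(nodes, c(planted, used, pool))
        extra <- extra[order(abs(bins$degree[extra] - bins$degree[[tg]]))]
        pool <- c(pool, extra)
        if (length(pool) < n_decoy) stop("not enough decoy genes")
      }
      decoys <- sample_vec(pool, n_decoy)
      used <- c(used, decoys)
      genes <- sample_vec(c(tg, decoys), n_decoy + 1L)  # shuffle rank order
      offsets <- 40000L * seq_along(genes) * rep_len(c(1L, -1L), length(genes))
      ann[[l]] <- data.frame(gene_id = genes,
                             symbol = genes,
                             chr = loci$chr[l],
                             tss = loci$pos[l] + offsets,
                             stringsAsFactors = FALSE)
    }
    annotations <- do.call(rbind, ann)
    table <- build_candidate_sets(loci, annotations)
    list(loci = loci, annotations = annotations, locus_table = table,
         truth = setNames(true_genes, loci$snp_id))
  })
}

#' Simulate a drug-target network around a planted module
#'
#' Proximal drugs draw their targets from the planted module and its 1-hop
#' neighbourhood — half of each drug's targets (rounded up) from the module
#' itself, the rest from the 1-hop fringe, emulating a drug that engages
#' the disease module directly plus immediate neighbours. Distal drugs
#' draw targets at least `distal_min_hops` hops from every planted gene,
#' degree-matched to the proximal pool where the (inherently peripheral)
#' distal pool allows.
#'
#' @param net Interactome graph.
#' @param planted Planted gene set.
#' @param spec A [benchmark_spec()].
#' @return List with `drug_targets` (named list) and `truth` (named
#'   character vector, drug -> "proximal" or "distal").
#' @export
simulate_drug_target_network <- function(net, planted, spec = benchmark_spec()) {
  nodes <- igraph::V(net)$name
  dmin <- apply(igraph::distances(net, v = planted), 2L, min)
  prox_pool <- nodes[dmin <= 1]
  dist_pool <- nodes[dmin >= spec$distal_min_hops]
  if (length(prox_pool) < spec$targets_per_drug) {
    stop("planted 1-hop neighbourhood too small for targets_per_drug")
  }
  if (spec$n_distal > 0L && length(dist_pool) < spec$targets_per_drug) {
    stop("distal pool (>= ", spec$distal_min_hops,
         " hops from module) too small for targets_per_drug")
  }
  deg <- igraph::degree(net)
  with_seed_if(spec$rng_seed + 2L, {
    dtn <- list()
    fringe <- setdiff(prox_pool, planted)
    for (i in seq_len(spec$n_proximal)) {
      n_in <- min(ceiling(spec$targets_per_drug / 2), length(planted))
      n_out <- spec$targets_per_drug - n_in
      dtn[[sprintf("drug_prox_%02d", i)]] <-
        c(sample_vec(planted, n_in),
          if (n_out > 0L) sample_vec(if (length(fringe)) fringe else prox_pool,
                                     n_out))
    }
    for (i in seq_len(spec$n_distal)) {
      ref <- sample_vec(prox_pool, spec$targets_per_drug)
      tg <- character(0)
      for (rdeg in deg[ref]) {
        avail <- setdiff(dist_pool, tg)
        avail <- avail[order(abs(deg[avail] - rdeg))]
        # nearest available degree; exact when the distal pool covers it
        tg <- c(tg, avail[1L + sample.int(min(3L, length(avail)), 1L) - 1L])
      }
      dtn[[sprintf("drug_dist_%02d", i)]] <- tg
    }
    truth <- setNames(rep(c("proximal", "distal"),
                          c(spec$n_proximal, spec$n_distal)), names(dtn))
    list(drug_targets = dtn, truth = truth)
  })
}

#' Simulate a lognormal expression matrix with tissue-elevated genes
#'
#' A simple genes x tissues TPM-like matrix: lognormal baseline, with the
#' first `n_specific` genes elevated `effect`-fold in the first tissue.
#' Emulates just enough structure to exercise the tissue-specificity
#' z-score and the expressed-gene filter; it does not model counts,
#' library sizes or covariance.
#'
#' @param n_genes,n_tissues Matrix dimensions.
#' @param n_specific Number of first-tissue-elevated genes.
#' @param effect Fold elevation of specific genes in tissue 1.
#' @param rng_seed Integer seed.
#' @return Numeric matrix with genes `g1..` and tissues `t1..`.
#' @export
simulate_expression_matrix <- function(n_genes = 200L, n_tissues = 10L,
                                       n_specific = 20L, effect = 4,
                                       rng_seed = 1L) {
  stopifnot(n_specific <= n_genes, n_tissues >= 2L)
  with_seed_if(rng_seed, {
    mat <- matrix(stats::rlnorm(n_genes * n_tissues, meanlog = 1, sdlog = 1),
                  nrow = n_genes,
                  dimnames = list(sprintf("g%d", seq_len(n_genes)),
                                  sprintf("t%d", seq_len(n_tissues))))
    mat[seq_len(n_specific), 1L] <- mat[seq_len(n_specific), 1L] * effect
    mat
  })
}

#' Write a benchmark to TSV files
#'
#' Writes `net.tsv`, `loci.tsv`, `genes.tsv`, `drug_targets.tsv` and
#' `truth.json` under `dir`, in the formats the package loaders read, so
#' generated benchmarks round-trip exactly.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [benchmark_spec()].
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
write_benchmark <- function(dir, spec = benchmark_spec()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_interactome_with_module(spec)
  gwas <- simulate_gwas_benchmark(sim$net, sim$planted, spec)
  drugs <- simulate_drug_target_network(sim$net, sim$planted, spec)
  el <- igraph::as_edgelist(sim$net)
  el <- data.frame(gene_a = pmin(el[, 1L], el[, 2L]),
                   gene_b = pmax(el[, 1L], el[, 2L]), stringsAsFactors = FALSE)
  el <- el[order(el$gene_a, el$gene_b), ]
  paths <- list(net = file.path(dir, "net.tsv"),
                loci = file.path(dir, "loci.tsv"),
                genes = file.path(dir, "genes.tsv"),
                drug_targets = file.path(dir, "drug_targets.tsv"),
                truth = file.path(dir, "truth.json"))
  write.table(el, paths$net, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(gwas$loci, paths$loci, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(gwas$annotations, paths$genes, sep = "\t", quote = FALSE,
              row.names = FALSE)
  dt <- data.frame(drug_id = rep(names(drugs$drug_targets),
                                 lengths(drugs$drug_targets)),
                   target = unlist(drugs$drug_targets, use.names = FALSE),
                   stringsAsFactors = FALSE)
  write.table(dt, paths$drug_targets, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(planted = sim$planted,
                            locus_truth = as.list(gwas$truth),
                            drug_truth = as.list(drugs$truth)),
                       paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(net = sim$net, planted = sim$planted, gwas = gwas,
                 drugs = drugs, paths = paths))
}
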