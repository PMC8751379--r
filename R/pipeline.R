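# End-to-end screen: GWAS loci -> risk genes -> module significance ->
# drug ranking, with a manifest recording every input digest, parameter
# and seed used.

default_screen_config <- function() {
  list(restart = 0.3, rwr_tol = 1e-6, rwr_max_iter = 10000L,
       prior_odds = 1, gibbs_tol = 1e-4, max_rounds = 1000L, burn_in = 10L,
       window_bp = 2e6, max_candidates = 20L,
       n_perm = 1000L, z_cutoff = -1.5, randomize = "both",
       module_n_perm = 1000L, seed = 1L)
}

#' Run the full gene-prioritization and drug-screening pipeline
#'
#' Chains [build_candidate_sets()], [rwr_proximity_matrix()],
#' [gibbs_sample()], [select_risk_genes()], [module_significance()] and
#' [screen_drugs()], writing `risk_genes.tsv`, `background_genes.tsv`,
#' `posterior.tsv`, `module_significance.json`, `module_null_sizes.tsv`,
#' `drug_ranking.tsv` and `manifest.json` to the output directory. The
#' manifest (input digests, every parameter, seed, package version) is
#' sufficient to reproduce the run.
#'
#' @param config Path to a YAML config file, or a named list. Required
#'   keys: `edges`, `loci`, `genes`, `drug_targets` (input file paths) and
#'   `out_dir`. Optional keys override the method's standard defaults:
#'   restart (0.3), rwr_tol (1e-6), prior_odds (1), gibbs_tol (1e-4),
#'   max_rounds (1000), burn_in (10), window_bp (2e6), max_candidates (20),
#'   n_perm (1000), z_cutoff (-1.5), randomize ("both"),
#'   module_n_perm (1000), seed (1).
#' @param quiet Suppress stage-progress messages.
#' @return Invisibly, a list with the in-memory results (`risk`, `post`,
#'   `module`, `ranking`, `manifest`) and `out_dir`.
#' @export
run_screen <- function(config, quiet = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_screen_config(), config)
  for (key in c("edges", "loci", "genes", "drug_targets", "out_dir")) {
    if (is.null(cfg[[key]])) stop("config is missing required key: ", key)
  }
  inputs <- c(edges = cfg$edges, loci = cfg$loci, genes = cfg$genes,
              drug_targets = cfg$drug_targets)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) stop("input file(s) not found: ",
                            paste(missing, collapse = ", "))
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()

  say("[1/5] loading inputs")
  net <- load_interactome(cfg$edges, quiet = quiet)
  loci <- read_gwas_loci(cfg$loci)
  ann <- read_gene_annotations(cfg$genes)
  dtn <- read_drug_targets(cfg$drug_targets)

  say("[2/5] building candidate sets and RWR proximity matrix")
  table <- build_candidate_sets(loci, ann, window_bp = cfg$window_bp,
                                max_candidates = cfg$max_candidates)
  tm <- build_transition_matrix(net)
  universe <- intersect(candidate_universe(table), tm$nodes)
  W <- rwr_proximity_matrix(tm, rwr_config(cfg$restart, cfg$rwr_tol,
                                           cfg$rwr_max_iter),
                            restrict_rows = universe)

  say("[3/5] Gibbs sampling risk genes")
  gcfg <- gibbs_config(prior_odds = cfg$prior_odds, tol = cfg$gibbs_tol,
                       max_rounds = cfg$max_rounds, burn_in = cfg$burn_in,
                       rng_seed = cfg$seed)
  post <- gibbs_sample(table, W, gcfg)
  risk <- select_risk_genes(post, table)
  say(sprintf("      %d risk genes (%d loci, %d rounds, converged: %s)",
              length(risk$risk_genes), length(table), post$rounds_used,
              post$converged))

  say("[4/5] disease-module significance")
  bins <- degree_bins(net)
  module <- module_significance(net, risk$risk_genes,
                                n_perm = cfg$module_n_perm, bins = bins,
                                rng_seed = cfg$seed + 1L)

  say("[5/5] drug screening by network proximity")
  ranking <- screen_drugs(net, risk$risk_genes, dtn,
                          z_cutoff = cfg$z_cutoff, n_perm = cfg$n_perm,
                          bins = bins, rng_seed = cfg$seed + 2L,
                          randomize = cfg$randomize)

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  write.table(data.frame(gene_id = risk$risk_genes,
                         confidence = risk$confidence[risk$risk_genes]),
              out("risk_genes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_set(risk$background_genes, out("background_genes.tsv"))
  post_df <- do.call(rbind, lapply(names(post$freq), function(sid) {
    data.frame(snp_id = sid, gene_id = names(post$freq[[sid]]),
               frequency = unname(post$freq[[sid]]), stringsAsFactors = FALSE)
  }))
  write.table(post_df, out("posterior.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(observed = module$observed_lcc_size,
                            observed_edges = module$observed_edges,
                            n_genes = module$n_genes_in_net,
                            n_perm = module$n_perm,
                            p_value = module$p_value),
                       out("module_significance.json"), auto_unbox = TRUE,
                       digits = NA)
  write.table(data.frame(null_lcc_size = module$null_lcc_sizes),
              out("module_null_sizes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(ranking, out("drug_ranking.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  digests <- tools::md5sum(inputs)
  names(digests) <- names(inputs)
  manifest <- list(
    inputs = as.list(digests),
    parameters = cfg[setdiff(names(cfg),
                             c("edges", "loci", "genes", "drug_targets", "out_dir"))],
    seeds = list(gibbs = cfg$seed, module = cfg$seed + 1L, screen = cfg$seed + 2L),
    package_version = as.character(utils::packageVersion("netprio")),
    gibbs_converged = post$converged,
    gibbs_rounds = post$rounds_used,
    skipped_drugs = as.list(attr(ranking, "skipped")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  say(sprintf("done in %.1f s; outputs in %s",
              as.numeric(difftime(Sys.time(), t0, units = "secs")),
              cfg$out_dir))
  invisible(list(risk = risk, post = post, module = module, ranking = ranking,
                 manifest = manifest, out_dir = cfg$out_dir))
}
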