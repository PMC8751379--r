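# Bayesian model selection of risk genes via Gibbs sampling.
#
# A candidate risk gene set (CRGS) is one gene per locus, (X_1, ..., X_L).
# Enumerating all combinations is infeasible, so the posterior over CRGS is
# explored by Gibbs sampling: each locus is resampled in turn conditional
# on the genes currently selected at the other loci, with sampling weights
# proportional to the Bayes factor of "candidate g is the risk gene" vs
# "it is not". With equal prior odds the Bayes factor reduces to the RWR
# reachability from the candidate to the currently selected genes, summed
# over those genes.

#' Gibbs sampler configuration
#'
#' @param prior_odds Prior odds P(M1)/P(M0) that a candidate is the risk
#'   gene at its locus; default 1 (equal priors).
#' @param tol Halting threshold on the sum of squared frequency differences
#'   across currently selected genes between consecutive rounds;
#'   default 1e-4.
#' @param max_rounds Maximum sampling rounds (sweeps over all loci).
#' @param burn_in Rounds discarded before frequencies accumulate.
#' @param rng_seed Optional integer seed.
#' @param halt_on `"cumulative"` compares cumulative post-burn-in sampling
#'   frequencies between consecutive rounds (default); `"per_round"`
#'   compares the per-round selections themselves (halts once a sweep
#'   repeats the previous selection exactly).
#' @return List of class `gibbs_config`.
#' @export
gibbs_config <- function(prior_odds = 1, tol = 1e-4, max_rounds = 1000L,
                         burn_in = 10L, rng_seed = NULL,
                         halt_on = c("cumulative", "per_round")) {
  stopifnot(prior_odds > 0, tol > 0, max_rounds >= 1L, burn_in >= 0L,
            max_rounds > burn_in)
  structure(list(prior_odds = prior_odds, tol = tol,
                 max_rounds = as.integer(max_rounds),
                 burn_in = as.integer(burn_in),
                 rng_seed = rng_seed,
                 halt_on = match.arg(halt_on)),
            class = "gibbs_config")
}

#' Bayes-factor sampling weights for one locus
#'
#' For each candidate g at the locus, the raw score is
#' `prior_odds * sum over x in selected_others of W[g, x]` — the summed RWR
#' reachability from g to the risk genes currently selected at the other
#' loci. Weights are the raw scores normalized to sum to one; if every raw
#' score is zero (disconnected candidates, or an empty conditioning set)
#' the weights are uniform.
#'
#' @param W RWR proximity matrix with candidate genes among its rows
#'   ([rwr_proximity_matrix()]).
#' @param candidates Candidate gene IDs at the locus.
#' @param selected_others Currently selected genes at the other loci (one
#'   entry per locus; repeats count once per locus).
#' @param prior_odds Prior odds P(M1)/P(M0).
#' @param warn_missing Warn about candidates absent from the rows of `W`
#'   (scored 0).
#' @return Named numeric weight vector summing to 1 over `candidates`.
#' @export
bayes_factor_scores <- function(W, candidates, selected_others,
                                prior_odds = 1, warn_missing = TRUE) {
  candidates <- as.character(candidates)
  if (!length(candidates)) stop("candidates must be nonempty")
  raw <- setNames(numeric(length(candidates)), candidates)
  known <- candidates %in% rownames(W)
  if (any(!known) && warn_missing) {
    warning("candidate(s) absent from proximity matrix scored 0: ",
            paste(head(candidates[!known], 5L), collapse = ", "))
  }
  others <- as.character(selected_others)
  others <- others[others %in% colnames(W)]
  if (length(others) && any(known)) {
    raw[known] <- prior_odds *
      rowSums(W[candidates[known], others, drop = FALSE])
  }
  tot <- sum(raw)
  if (tot <= 0) {
    return(setNames(rep(1 / length(candidates), length(candidates)), candidates))
  }
  raw / tot
}

#' Gibbs sampling of risk genes across GWAS loci
#'
#' Initializes one candidate per locus uniformly at random, then sweeps all
#' loci in order each round, resampling each locus from
#' [bayes_factor_scores()] conditional on the current selections at the
#' other loci. After `burn_in` rounds, per-gene sampling frequencies are
#' accumulated; the sampler halts when the sum of squared frequency
#' differences across the currently selected genes drops below `cfg$tol`,
#' or at `max_rounds` (then with `converged = FALSE` and a warning).
#'
#' @param table A [build_candidate_sets()] locus table.
#' @param W RWR proximity matrix whose rows cover the candidate genes.
#' @param cfg A [gibbs_config()].
#' @return Object of class `posterior_table`: list with `freq` (per locus,
#'   named frequency vector over its candidates, summing to 1),
#'   `rounds_used`, `converged`, and `last_selection`.
#' @export
gibbs_sample <- function(table, W, cfg = gibbs_config()) {
  cand <- locus_candidates(table)
  L <- length(cand)
  if (!L) stop("locus table is empty")
  if (any(vapply(cand, length, 0L) == 0L)) stop("every locus needs >= 1 candidate")
  missing <- setdiff(unlist(cand, use.names = FALSE), rownames(W))
  if (length(missing)) {
    warning(length(unique(missing)),
            " candidate gene(s) absent from proximity matrix will score 0")
  }
  with_seed_if(cfg$rng_seed, {
    sel <- vapply(cand, function(cs) sample_vec(cs, 1L), "")
    counts <- lapply(cand, function(cs) setNames(numeric(length(cs)), cs))
    freq <- prev_freq <- NULL
    prev_sel <- NULL
    converged <- FALSE
    round <- 0L
    while (round < cfg$max_rounds) {
      round <- round + 1L
      for (l in seq_len(L)) {
        w <- bayes_factor_scores(W, cand[[l]], sel[-l],
                                 prior_odds = cfg$prior_odds,
                                 warn_missing = FALSE)
        sel[l] <- sample_vec(cand[[l]], 1L, prob = w)
      }
      if (round <= cfg$burn_in) next
      denom <- round - cfg$burn_in
      for (l in seq_len(L)) counts[[l]][[sel[[l]]]] <- counts[[l]][[sel[[l]]]] + 1
      freq <- lapply(counts, function(x) x / denom)
      if (cfg$halt_on == "cumulative") {
        if (!is.null(prev_freq)) {
          stat <- sum(vapply(seq_len(L), function(l) {
            (freq[[l]][[sel[[l]]]] - prev_freq[[l]][[sel[[l]]]])^2
          }, 0))
          if (stat < cfg$tol) { converged <- TRUE; break }
        }
        prev_freq <- freq
      } else {
        if (!is.null(prev_sel) && all(sel == prev_sel)) { converged <- TRUE; break }
        prev_sel <- sel
      }
    }
    if (!converged) {
      warning("Gibbs sampler did not converge within ", cfg$max_rounds, " rounds")
    }
    structure(list(freq = freq, rounds_used = round, converged = converged,
                   last_selection = sel),
              class = "posterior_table")
  })
}

#' @export
print.posterior_table <- function(x, ...) {
  cat(sprintf("Posterior table: %d loci, %d rounds, converged: %s\n",
              length(x$freq), x$rounds_used, x$converged))
  top <- vapply(x$freq, max, 0)
  cat(sprintf("  top-candidate frequency: min %.2f, median %.2f, max %.2f\n",
              min(top), stats::median(top), max(top)))
  invisible(x)
}

#' Select risk genes and local background genes
#'
#' Per locus, picks the candidate with the highest sampling frequency
#' (frequency ties resolve to the candidate nearer the index SNP, then the
#' smaller gene ID — the order candidates are stored in). Risk genes
#' selected at several loci are merged; every candidate never selected
#' anywhere becomes a local background gene (LBG), the matched negative
#' control set.
#'
#' @param post A [gibbs_sample()] posterior table.
#' @param table The matching locus table.
#' @return Object of class `risk_gene_set`: list with `risk_genes` (sorted,
#'   deduplicated), `per_locus_choice` (named by SNP ID), `confidence`
#'   (per risk gene, its maximum sampling frequency over loci), and
#'   `background_genes`.
#' @export
select_risk_genes <- function(post, table) {
  if (!setequal(names(post$freq), names(table))) {
    stop("posterior table does not cover the loci of the locus table")
  }
  choice <- vapply(names(table), function(sid) {
    f <- post$freq[[sid]]
    names(f)[which.max(f)]  # candidates stored nearest-first, smaller-ID ties
  }, "")
  risk <- sort(unique(choice))
  confidence <- vapply(risk, function(g) {
    max(vapply(post$freq, function(f) if (g %in% names(f)) f[[g]] else 0, 0))
  }, 0)
  universe <- candidate_universe(table)
  structure(list(risk_genes = risk,
                 per_locus_choice = choice,
                 confidence = confidence,
                 background_genes = setdiff(universe, risk)),
            class = "risk_gene_set")
}

#' @export
print.risk_gene_set <- function(x, ...) {
  cat(sprintf("Risk gene set: %d risk genes from %d loci, %d background genes\n",
              length(x$risk_genes), length(x$per_locus_choice),
              length(x$background_genes)))
  invisible(x)
}
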