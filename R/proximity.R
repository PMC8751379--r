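# Closest network proximity between a disease module and drug target sets.
#
# <d_AB> = ( sum_{a in A} min_{b in B} d(a,b) + sum_{b in B} min_{a in A} d(a,b) )
#          / (|A| + |B|)
# with d(a,b) the unweighted shortest-path length. Significance comes from
# a degree-preserving permutation null: the same statistic on random gene
# sets matched in size and binned degree to A and B.

#' Read a drug-target table
#'
#' Expects a header with columns `drug_id` and `target` (aliases
#' `target_id`, `gene_id`, `entrez` accepted); an optional `category`
#' column is kept as an attribute for metadata filters.
#'
#' @param path Path to the drug-target TSV.
#' @return Named list mapping drug ID to a character vector of target gene
#'   IDs (deduplicated, nonempty).
#' @export
read_drug_targets <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  names(df) <- tolower(names(df))
  alias <- c(target_id = "target", gene_id = "target", entrez = "target",
             drug = "drug_id")
  hit <- names(df) %in% names(alias)
  names(df)[hit] <- alias[names(df)[hit]]
  if (!all(c("drug_id", "target") %in% names(df))) {
    stop("drug-target table must have columns drug_id, target")
  }
  df$drug_id <- as.character(df$drug_id)
  df$target <- as.character(df$target)
  dtn <- lapply(split(df$target, df$drug_id), unique)
  if (any(vapply(dtn, length, 0L) == 0L)) stop("every drug needs >= 1 target")
  if ("category" %in% names(df)) {
    attr(dtn, "category") <- vapply(split(df$category, df$drug_id),
                                    function(x) as.character(x[1L]), "")
  }
  dtn
}

map_into_net <- function(net, genes, label) {
  genes <- unique(as.character(genes))
  present <- genes[genes %in% igraph::V(net)$name]
  if (!length(present)) stop(label, " has no member mapped into the network")
  if (length(present) < length(genes)) {
    warning(length(genes) - length(present), " ", label,
            " member(s) not in network dropped")
  }
  present
}

#' Closest network distance between two gene sets
#'
#' Average, over both sets, of each member's shortest-path distance to its
#' nearest member of the other set. Pairs in different components have
#' infinite distance; such terms are excluded from both the numerator and
#' the denominator, and an all-infinite configuration is an error.
#'
#' @param net Interactome graph.
#' @param A,B Gene sets; members absent from `net` are dropped with a
#'   warning, and an entirely unmapped set is an error.
#' @return Non-negative scalar, symmetric in (A, B).
#' @export
closest_distance <- function(net, A, B) {
  a <- map_into_net(net, A, "A")
  b <- map_into_net(net, B, "B")
  D <- igraph::distances(net, v = a, to = b)
  terms <- c(apply(D, 1L, min), apply(D, 2L, min))
  finite <- is.finite(terms)
  if (!any(finite)) stop("no finite distance between A and B")
  sum(terms[finite]) / sum(finite)
}

#' Proximity z-score against a degree-preserving null
#'
#' Recomputes [closest_distance()] on `n_perm` degree-preserving random
#' replacements of the gene sets and standardizes the observed distance:
#' `z = (d_observed - null_mean) / null_sd`. An empirical one-sided
#' p-value (add-one estimator, small distances significant) is also
#' reported.
#'
#' @param net Interactome graph.
#' @param A Disease gene set.
#' @param B Drug target set.
#' @param n_perm Number of null draws (>= 2); default 1000.
#' @param bins Optional precomputed [degree_bins()].
#' @param rng_seed Optional integer seed.
#' @param randomize `"both"` (default) randomizes A and B; `"targets"`
#'   randomizes only B, for sensitivity analysis.
#' @return Object of class `proximity_result`: list with `d_observed`,
#'   `null_mean`, `null_sd`, `z` (NA with `degenerate = TRUE` when the
#'   null sd is 0), `p_value`, `n_perm`, `n_disease_in_net`,
#'   `n_targets_in_net`.
#' @export
proximity_z <- function(net, A, B, n_perm = 1000L, bins = NULL,
                        rng_seed = NULL, randomize = c("both", "targets")) {
  stopifnot(n_perm >= 2L)
  randomize <- match.arg(randomize)
  a <- map_into_net(net, A, "A")
  b <- map_into_net(net, B, "B")
  d_obs <- closest_distance(net, a, b)
  if (is.null(bins)) bins <- degree_bins(net)
  null_d <- with_seed_if(rng_seed, {
    vapply(seq_len(n_perm), function(i) {
      ar <- if (randomize == "both") degree_preserving_sample(net, a, bins) else a
      br <- degree_preserving_sample(net, b, bins)
      tryCatch(closest_distance(net, ar, br), error = function(e) NA_real_)
    }, 0)
  })
  null_d <- null_d[!is.na(null_d)]
  if (length(null_d) < 2L) stop("null distance distribution degenerate (< 2 finite draws)")
  m <- mean(null_d); s <- sd(null_d)
  degenerate <- s == 0
  structure(list(d_observed = d_obs,
                 null_mean = m, null_sd = s,
                 z = if (degenerate) NA_real_ else (d_obs - m) / s,
                 degenerate = degenerate,
                 p_value = (sum(null_d <= d_obs) + 1) / (length(null_d) + 1),
                 n_perm = length(null_d),
                 n_disease_in_net = length(a),
                 n_targets_in_net = length(b)),
            class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf("Network proximity: d = %.3f, null %.3f +/- %.3f, z = %.3f, P = %.4g (%d perms)\n",
              x$d_observed, x$null_mean, x$null_sd,
              if (x$degenerate) NA else x$z, x$p_value, x$n_perm))
  invisible(x)
}

#' Screen a drug library by network proximity
#'
#' Computes a [proximity_z()] result for every drug with at least one
#' target mapped into the network, and ranks drugs by ascending z-score.
#' Drugs with no mapped target, or whose distance is undefined
#' (fully disconnected from the module), are listed in the `skipped`
#' attribute rather than failing the screen.
#'
#' @param net Interactome graph.
#' @param A Disease gene set (e.g. the risk-gene module).
#' @param drug_targets Named list drug ID -> target gene IDs, as from
#'   [read_drug_targets()].
#' @param z_cutoff Selection cutoff; drugs with `z < z_cutoff` are flagged
#'   (default -1.5).
#' @param n_perm Null draws per drug (default 1000).
#' @param bins Optional precomputed [degree_bins()].
#' @param rng_seed Optional integer seed; fixes the whole screen.
#' @param randomize Passed to [proximity_z()].
#' @return Data frame with one row per screened drug: drug_id, n_targets,
#'   n_targets_in_net, d, null_mean, null_sd, z, p, selected; sorted by z
#'   ascending. Attribute `skipped` is a named character vector of
#'   drug -> reason.
#' @export
screen_drugs <- function(net, A, drug_targets, z_cutoff = -1.5,
                         n_perm = 1000L, bins = NULL, rng_seed = NULL,
                         randomize = "both") {
  if (!length(drug_targets)) stop("drug-target network is empty")
  a <- map_into_net(net, A, "disease set")
  if (is.null(bins)) bins <- degree_bins(net)
  drugs <- names(drug_targets)
  with_seed_if(rng_seed, {
    rows <- vector("list", length(drugs))
    skipped <- character(0)
    for (i in seq_along(drugs)) {
      tg <- unique(as.character(drug_targets[[i]]))
      mapped <- tg[tg %in% igraph::V(net)$name]
      if (!length(mapped)) {
        skipped[drugs[i]] <- "no target mapped into network"
        next
      }
      res <- tryCatch(
        suppressWarnings(proximity_z(net, a, mapped, n_perm = n_perm,
                                     bins = bins, randomize = randomize)),
        error = function(e) conditionMessage(e))
      if (is.character(res)) {
        skipped[drugs[i]] <- res
        next
      }
      rows[[i]] <- data.frame(drug_id = drugs[i],
                              n_targets = length(tg),
                              n_targets_in_net = length(mapped),
                              d = res$d_observed,
                              null_mean = res$null_mean,
                              null_sd = res$null_sd,
                              z = res$z,
                              p = res$p_value,
                              stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    if (is.null(out)) stop("no drug could be screened")
    out$selected <- !is.na(out$z) & out$z < z_cutoff
    out <- out[order(out$z), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "skipped") <- skipped
    out
  })
}
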