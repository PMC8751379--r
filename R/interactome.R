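# Interactome representation and connectivity analysis.
#
# The interactome is an undirected, unweighted igraph object whose vertex
# names are gene identifiers. Identifiers are opaque strings after
# validation, so Entrez IDs and synthetic labels behave identically.

#' Load a protein-protein interactome from an edge-list TSV
#'
#' Reads a two-column (or wider; extra columns ignored) tab-separated edge
#' list of gene identifiers and returns an undirected, simplified graph:
#' duplicate pairs (in either orientation) are collapsed and self-loops are
#' dropped, each with a reported count. A header row is auto-detected when
#' the first row is non-numeric and either the second row is numeric or the
#' first row uses common column-name vocabulary (gene/node/protein/source/
#' target/from/to/id).
#'
#' @param path Path to the edge-list TSV.
#' @param quiet Suppress the node/edge count message.
#' @return An undirected [igraph::igraph] with character vertex names.
#' @export
load_interactome <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("interactome file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = "character", quote = "",
                          showProgress = FALSE, data.table = TRUE)
  if (ncol(dt) < 2L) stop("edge list must have >= 2 tab-separated columns: ", path)
  a <- trimws(dt[[1L]]); b <- trimws(dt[[2L]])
  if (length(a) && looks_like_header(a[1L], b[1L],
                                     if (length(a) > 1L) a[2L] else NA,
                                     if (length(b) > 1L) b[2L] else NA)) {
    a <- a[-1L]; b <- b[-1L]
  }
  bad <- !nzchar(a) | !nzchar(b) | is.na(a) | is.na(b)
  if (any(bad)) {
    warning(sum(bad), " unparsable edge row(s) skipped")
    a <- a[!bad]; b <- b[!bad]
  }
  if (!length(a)) stop("no parsable edges in ", path)
  loops <- a == b
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    a <- a[!loops]; b <- b[!loops]
  }
  # canonical unordered orientation, then deduplicate
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(paste(lo, hi, sep = "\r"))
  net <- igraph::graph_from_edgelist(cbind(lo[keep], hi[keep]), directed = FALSE)
  if (!quiet) {
    message("interactome: ", igraph::vcount(net), " nodes, ",
            igraph::ecount(net), " edges (", sum(!keep), " duplicate pair(s) removed)")
  }
  net
}

looks_like_header <- function(a1, b1, a2, b2) {
  num <- function(x) !is.na(suppressWarnings(as.numeric(x)))
  if (num(a1) && num(b1)) return(FALSE)
  if (!is.na(a2) && num(a2) && num(b2)) return(TRUE)
  grepl("gene|node|protein|source|target|from|to|^id$|_id",
        paste(a1, b1), ignore.case = TRUE)
}

#' Build an interactome from an edge data frame
#'
#' @param edges Data frame or matrix whose first two columns are gene IDs.
#' @return Undirected simplified [igraph::igraph].
#' @export
interactome_from_edges <- function(edges) {
  el <- cbind(as.character(edges[[1L]]), as.character(edges[[2L]]))
  igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
}

#' Largest connected component of a gene set in the interactome
#'
#' Induces the subgraph on `genes` and returns its largest connected
#' component (the "disease module") and the number of interactions inside
#' it. Size ties are broken deterministically in favour of the component
#' whose sorted member list is lexicographically smallest.
#'
#' @param net Interactome graph.
#' @param genes Character vector of gene IDs; genes absent from `net` are
#'   dropped with a warning.
#' @return List with `nodes` (sorted character vector, possibly empty) and
#'   `n_edges` (integer count of edges inside the component).
#' @export
largest_connected_component <- function(net, genes) {
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("genes must be nonempty")
  present <- genes[genes %in% igraph::V(net)$name]
  if (length(present) < length(genes)) {
    warning(length(genes) - length(present), " gene(s) not in interactome dropped")
  }
  if (!length(present)) {
    warning("no input gene present in interactome")
    return(list(nodes = character(0), n_edges = 0L))
  }
  sub <- igraph::induced_subgraph(net, present)
  comp <- igraph::components(sub)
  best <- which(comp$csize == max(comp$csize))
  members <- lapply(best, function(k) sort(igraph::V(sub)$name[comp$membership == k]))
  if (length(members) > 1L) {
    keys <- vapply(members, paste, "", collapse = "\r")
    members <- members[order(keys)]
  }
  nodes <- members[[1L]]
  n_edges <- igraph::ecount(igraph::induced_subgraph(sub, nodes))
  list(nodes = nodes, n_edges = as.integer(n_edges))
}

#' Logarithmic degree bins for degree-preserving randomization
#'
#' Bins nodes by degree into intervals `[2^k, 2^(k+1))` (degree-0 nodes get
#' their own lowest bin) and merges any bin with fewer than `min_bin_size`
#' members into its lower neighbour (or upper neighbour for the lowest bin)
#' until every bin is adequately populated. This is the standard matching
#' scheme for degree-preserving nulls on heavy-tailed networks.
#'
#' @param net Interactome graph.
#' @param min_bin_size Minimum members per bin before merging stops.
#' @return Object of class `degree_bins`: list with `bin_of` (named integer
#'   bin index per node) and `members` (list of sorted node-name vectors).
#' @export
degree_bins <- function(net, min_bin_size = 20L) {
  deg <- igraph::degree(net)
  raw <- ifelse(deg == 0L, -1L, floor(log2(deg)))
  lev <- sort(unique(raw))
  counts <- vapply(lev, function(l) sum(raw == l), 0L)
  # merge under-populated bins into a neighbour, smallest-first
  while (length(lev) > 1L && any(counts < min_bin_size)) {
    i <- which(counts < min_bin_size)[1L]
    j <- if (i > 1L) i - 1L else i + 1L
    raw[raw == lev[i]] <- lev[j]
    counts[j] <- counts[j] + counts[i]
    lev <- lev[-i]; counts <- counts[-i]
  }
  idx <- match(raw, lev)
  names(idx) <- names(deg)
  members <- lapply(seq_along(lev), function(k) sort(names(idx)[idx == k]))
  structure(list(bin_of = idx, members = members, degree = deg),
            class = "degree_bins")
}

#' Degree-preserving random gene set
#'
#' Draws a random set of the same size as `genes` in which each input gene
#' is replaced by a node sampled (without replacement, within the bin) from
#' its own degree bin, preserving the binned degree histogram exactly.
#'
#' @param net Interactome graph.
#' @param genes Gene IDs, all present in `net`.
#' @param bins Precomputed [degree_bins()]; computed on the fly if `NULL`.
#' @param rng_seed Optional integer seed for reproducibility.
#' @return Character vector of `length(genes)` distinct node names.
#' @export
degree_preserving_sample <- function(net, genes, bins = NULL, rng_seed = NULL) {
  genes <- as.character(genes)
  if (is.null(bins)) bins <- degree_bins(net)
  idx <- bins$bin_of[genes]
  if (anyNA(idx)) stop("gene(s) absent from the binned network: ",
                       paste(head(genes[is.na(idx)], 5L), collapse = ", "))
  with_seed_if(rng_seed, {
    out <- character(0)
    for (b in sort(unique(idx))) {
      k <- sum(idx == b)
      pool <- bins$members[[b]]
      if (k > length(pool)) {
        # only reachable with bins built on a different graph
        warning("degree bin smaller than requested draws; merging all bins")
        pool <- sort(unlist(bins$members))
      }
      out <- c(out, sample_vec(pool, k))
    }
    out
  })
}

#' Disease-module significance by degree-preserving permutation
#'
#' Compares the observed largest-connected-component size of `genes` in the
#' interactome against LCC sizes of `n_perm` degree-preserving random gene
#' sets. The one-sided p-value uses the add-one estimator
#' `(# null >= observed + 1) / (n_perm + 1)`.
#'
#' @param net Interactome graph.
#' @param genes Gene IDs (those absent from `net` are dropped by
#'   [largest_connected_component()]).
#' @param n_perm Number of permutations (>= 1).
#' @param bins Optional precomputed [degree_bins()].
#' @param rng_seed Optional integer seed.
#' @return Object of class `module_significance`: list with
#'   `observed_lcc_size`, `observed_edges`, `lcc_nodes`, `null_lcc_sizes`,
#'   `n_perm`, `n_genes_in_net`, `p_value`.
#' @export
module_significance <- function(net, genes, n_perm = 1000L, bins = NULL,
                                rng_seed = NULL) {
  stopifnot(n_perm >= 1L)
  genes <- unique(as.character(genes))
  present <- genes[genes %in% igraph::V(net)$name]
  if (!length(present)) stop("no input gene present in interactome")
  if (length(present) < length(genes)) {
    warning(length(genes) - length(present), " gene(s) not in interactome dropped")
  }
  obs <- largest_connected_component(net, present)
  if (is.null(bins)) bins <- degree_bins(net)
  null_sizes <- with_seed_if(rng_seed, {
    vapply(seq_len(n_perm), function(i) {
      rnd <- degree_preserving_sample(net, present, bins)
      length(suppressWarnings(largest_connected_component(net, rnd))$nodes)
    }, 0L)
  })
  p <- (sum(null_sizes >= length(obs$nodes)) + 1) / (n_perm + 1)
  structure(list(observed_lcc_size = length(obs$nodes),
                 observed_edges = obs$n_edges,
                 lcc_nodes = obs$nodes,
                 null_lcc_sizes = null_sizes,
                 n_perm = as.integer(n_perm),
                 n_genes_in_net = length(present),
                 p_value = p),
            class = "module_significance")
}

#' @export
print.module_significance <- function(x, ...) {
  cat("Disease-module significance (degree-preserving permutation)\n")
  cat(sprintf("  observed LCC: %d of %d genes (%d internal edges)\n",
              x$observed_lcc_size, x$n_genes_in_net, x$observed_edges))
  cat(sprintf("  null LCC: mean %.2f (range %d-%d), %d permutations\n",
              mean(x$null_lcc_sizes), min(x$null_lcc_sizes),
              max(x$null_lcc_sizes), x$n_perm))
  cat(sprintf("  one-sided P = %.4g\n", x$p_value))
  invisible(x)
}
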