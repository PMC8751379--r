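# Independent oracles used to cross-check the package implementation.
# Each is written from first principles (adjacency lists, dense linear
# algebra, exhaustive enumeration) and never calls the code path it checks.

# Random named undirected graph (Erdos-Renyi).
random_graph <- function(n, p = 3 / n, seed = NULL) {
  g <- if (is.null(seed)) igraph::sample_gnp(n, p) else
    withr::with_seed(seed, igraph::sample_gnp(n, p))
  igraph::V(g)$name <- sprintf("n%d", seq_len(n))
  g
}

# Adjacency list keyed by node name.
adj_list <- function(net) {
  el <- igraph::as_edgelist(net)
  nodes <- igraph::V(net)$name
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(el))) {
    adj[[el[i, 1]]] <- c(adj[[el[i, 1]]], el[i, 2])
    adj[[el[i, 2]]] <- c(adj[[el[i, 2]]], el[i, 1])
  }
  adj
}

# Plain queue-based BFS hop distances from one source to all nodes.
bfs_oracle <- function(adj, from) {
  dist <- setNames(rep(Inf, length(adj)), names(adj))
  dist[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# Closest-distance statistic recomputed from the BFS oracle, with the same
# convention: infinite terms drop from numerator and denominator.
closest_distance_oracle <- function(net, A, B) {
  adj <- adj_list(net)
  dB <- sapply(A, function(a) min(bfs_oracle(adj, a)[B]))
  dA <- sapply(B, function(b) min(bfs_oracle(adj, b)[A]))
  terms <- c(dB, dA)
  terms <- terms[is.finite(terms)]
  sum(terms) / length(terms)
}

# Union-find connected components of the subgraph induced by `genes`.
components_oracle <- function(net, genes) {
  genes <- intersect(genes, igraph::V(net)$name)
  parent <- setNames(genes, genes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  el <- igraph::as_edgelist(net)
  keep <- el[, 1] %in% genes & el[, 2] %in% genes
  for (i in which(keep)) {
    ra <- find(el[i, 1]); rb <- find(el[i, 2])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(genes, find, "")
  unname(split(genes, roots))
}

# Dense closed-form RWR fixed point: q = r (I - (1 - r) W)^-1 s, with the
# same degree-normalized, isolated-self-loop operator convention.
rwr_solve_oracle <- function(net, seed_node, r = 0.3) {
  nodes <- igraph::V(net)$name
  A <- as.matrix(igraph::as_adjacency_matrix(net))
  deg <- colSums(A)
  W <- sweep(A, 2, ifelse(deg > 0, deg, 1), "/")
  diag(W)[deg == 0] <- 1
  s <- as.numeric(nodes == seed_node)
  q <- r * solve(diag(length(nodes)) - (1 - r) * W, s)
  setNames(q, nodes)
}

# Exhaustive two-sided Fisher p for a 2x2 table with fixed margins:
# sum of hypergeometric probabilities not exceeding the observed one
# (with the usual relative tolerance for ties).
fisher_oracle <- function(overlap, n_a, n_b, n_universe) {
  ks <- max(0, n_a + n_b - n_universe):min(n_a, n_b)
  probs <- stats::dhyper(ks, n_a, n_universe - n_a, n_b)
  p_obs <- stats::dhyper(overlap, n_a, n_universe - n_a, n_b)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact stationary marginals of the two-locus Gibbs sweep chain.
# States are (i, j) = candidate index at locus 1, locus 2. One sweep
# resamples locus 1 given j, then locus 2 given the new i; the stationary
# distribution is the left fixed vector of that 4x4 kernel.
gibbs_stationary_oracle <- function(W, cand1, cand2) {
  cond1 <- function(j) { w <- W[cand1, cand2[j]]; w / sum(w) }
  cond2 <- function(i) { w <- W[cand2, cand1[i]]; w / sum(w) }
  states <- expand.grid(i = seq_along(cand1), j = seq_along(cand2))
  Tm <- matrix(0, nrow(states), nrow(states))
  for (s in seq_len(nrow(states))) {
    p1 <- cond1(states$j[s])
    for (t in seq_len(nrow(states))) {
      Tm[s, t] <- p1[states$i[t]] * cond2(states$i[t])[states$j[t]]
    }
  }
  ev <- eigen(t(Tm))
  pi_vec <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  pi_vec <- pi_vec / sum(pi_vec)
  list(locus1 = setNames(tapply(pi_vec, states$i, sum)[as.character(seq_along(cand1))], cand1),
       locus2 = setNames(tapply(pi_vec, states$j, sum)[as.character(seq_along(cand2))], cand2))
}

# Small locus table built directly (bypassing coordinate plumbing).
toy_locus_table <- function(cands) {
  out <- lapply(seq_along(cands), function(l) {
    list(snp_id = sprintf("rs%d", l), chr = sprintf("chr%d", l),
         pos = 1000000L, p_value = 1e-6,
         candidates = cands[[l]],
         distance = setNames(seq_along(cands[[l]]) * 1000, cands[[l]]))
  })
  names(out) <- vapply(out, `[[`, "", "snp_id")
  structure(out, class = "locus_table")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

cand_universe <- function(tab) {
  sort(unique(unlist(lapply(tab, `[[`, "candidates"), use.names = FALSE)))
}
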