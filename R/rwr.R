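# Random walk with restart (RWR) network propagation.
#
# The walker at a node either moves to a uniformly chosen neighbour with
# probability 1 - r or restarts at the seed with probability r. Its fixed
# point q solves q = (1 - r) W q + r s, where W is the column-normalized
# adjacency operator; q measures seed-to-node proximity and is the
# Bayes-factor kernel of the gene-prioritization module.

#' RWR configuration
#'
#' @param restart Restart probability r in (0, 1); default 0.3.
#' @param tol Convergence threshold on the squared L2 norm of the update
#'   step, \eqn{|q_{t+1} - q_t|^2}; default 1e-6.
#' @param max_iter Maximum power-iteration steps before a non-convergence
#'   error.
#' @return List of class `rwr_config`.
#' @export
rwr_config <- function(restart = 0.3, tol = 1e-6, max_iter = 10000L) {
  stopifnot(restart > 0, restart < 1, tol > 0, max_iter >= 1L)
  structure(list(restart = restart, tol = tol, max_iter = as.integer(max_iter)),
            class = "rwr_config")
}

#' Column-stochastic transition operator of the interactome
#'
#' Column j distributes mass uniformly over node j's neighbours
#' (degree normalization). Isolated nodes self-loop so that probability
#' mass is conserved.
#'
#' @param net Interactome graph (nonempty).
#' @return Object of class `transition_matrix`: list with sparse operator
#'   `W` (dgCMatrix) and `nodes` (character vector fixing the order).
#' @export
build_transition_matrix <- function(net) {
  if (igraph::vcount(net) == 0L) stop("network is empty")
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  A <- methods::as(A, "dMatrix")
  deg <- Matrix::colSums(A)
  W <- A %*% Matrix::Diagonal(x = ifelse(deg > 0, 1 / deg, 0))
  iso <- which(deg == 0)
  if (length(iso)) {
    W <- W + Matrix::sparseMatrix(i = iso, j = iso, x = 1, dims = dim(A))
  }
  W <- methods::as(W, "CsparseMatrix")
  dimnames(W) <- dimnames(A)
  structure(list(W = W, nodes = colnames(A)), class = "transition_matrix")
}

#' Random walk with restart from a single seed
#'
#' Power iteration of \eqn{q_{t+1} = (1 - r) W q_t + r s} from
#' \eqn{q_0 = s}, stopping when the squared L2 norm of the step falls below
#' `cfg$tol`.
#'
#' @param tm A [build_transition_matrix()] object.
#' @param seed_node Name of the seed node.
#' @param cfg An [rwr_config()].
#' @return Named numeric vector of visiting probabilities (sums to 1).
#' @export
rwr <- function(tm, seed_node, cfg = rwr_config()) {
  i <- match(as.character(seed_node), tm$nodes)
  if (is.na(i)) stop("seed node not in network: ", seed_node)
  n <- length(tm$nodes)
  s <- numeric(n); s[i] <- 1
  r <- cfg$restart
  q <- s
  for (it in seq_len(cfg$max_iter)) {
    q1 <- (1 - r) * as.numeric(tm$W %*% q) + r * s
    res <- sum((q1 - q)^2)
    q <- q1
    if (res < cfg$tol) {
      names(q) <- tm$nodes
      return(q)
    }
  }
  stop(sprintf("RWR did not converge in %d iterations (last |dq|^2 = %.3g)",
               cfg$max_iter, res))
}

#' RWR proximity matrix
#'
#' One converged RWR vector per requested seed node: entry (i, j) is the
#' steady-state probability of node j when the walk is seeded at node i.
#' Each row sums to 1 and the diagonal entry is at least the restart
#' probability.
#'
#' @param tm A [build_transition_matrix()] object.
#' @param cfg An [rwr_config()].
#' @param restrict_rows Optional subset of node names to use as seeds
#'   (default: all nodes).
#' @return Dense numeric matrix, rows = seeds, columns = all nodes.
#' @export
rwr_proximity_matrix <- function(tm, cfg = rwr_config(), restrict_rows = NULL) {
  rows <- if (is.null(restrict_rows)) tm$nodes else unique(as.character(restrict_rows))
  missing <- setdiff(rows, tm$nodes)
  if (length(missing)) stop("restrict_rows not in network: ",
                            paste(head(missing, 5L), collapse = ", "))
  out <- t(vapply(rows, function(g) rwr(tm, g, cfg),
                  numeric(length(tm$nodes))))
  rownames(out) <- rows
  colnames(out) <- tm$nodes
  out
}
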