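# Expression-derived evidence layers.

#' Read an expression matrix
#'
#' First column = gene IDs, header = tissue or sample labels.
#'
#' @param path Path to the expression TSV.
#' @return Numeric matrix, rownames = genes, colnames = labels.
#' @export
read_expression_matrix <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  genes <- as.character(df[[1L]])
  mat <- as.matrix(df[-1L])
  mode(mat) <- "numeric"
  rownames(mat) <- genes
  if (anyDuplicated(colnames(mat))) stop("duplicate column labels")
  if (any(mat < 0, na.rm = TRUE)) stop("expression values must be non-negative")
  mat
}

#' Tissue-specificity z-score of gene expression
#'
#' Standardizes a gene's expression in one tissue against that gene's own
#' mean and standard deviation across all tissues:
#' `z_E(i, t) = (E(i, t) - <E(i)>) / delta_E(i)`.
#' A gene with zero cross-tissue variance gets z = 0 (with a warning) so
#' genome-wide sweeps never abort.
#'
#' @param mat Expression matrix (genes x tissues, e.g. TPM).
#' @param gene,tissue Optional single gene / tissue; when both are `NULL`
#'   the full z matrix is returned.
#' @param sd_type `"sample"` (n - 1 denominator, default) or
#'   `"population"`.
#' @param log2_transform Apply `log2(x + 1)` before scoring.
#' @return Scalar z-score, or the full z matrix when gene and tissue are
#'   `NULL`.
#' @export
tissue_specificity_z <- function(mat, gene = NULL, tissue = NULL,
                                 sd_type = c("sample", "population"),
                                 log2_transform = FALSE) {
  sd_type <- match.arg(sd_type)
  if (ncol(mat) < 2L) stop("need >= 2 tissues")
  if (log2_transform) mat <- log2(mat + 1)
  mu <- rowMeans(mat)
  n <- ncol(mat)
  ss <- rowSums((mat - mu)^2)
  sdv <- sqrt(ss / (if (sd_type == "sample") n - 1 else n))
  if (any(sdv == 0)) warning(sum(sdv == 0), " constant gene(s): z set to 0")
  z <- (mat - mu) / ifelse(sdv == 0, 1, sdv)
  z[sdv == 0, ] <- 0
  if (is.null(gene) && is.null(tissue)) return(z)
  if (!gene %in% rownames(mat)) stop("gene not in matrix: ", gene)
  if (!tissue %in% colnames(mat)) stop("tissue not in matrix: ", tissue)
  z[gene, tissue]
}

#' Expressed-gene filter
#'
#' Keeps genes whose expression is at least `cpm_threshold` (inclusive) in
#' strictly more than `sample_fraction` of the columns — i.e. CPM >= 0.5
#' in over 90% of samples at the defaults.
#'
#' @param mat Expression matrix in CPM units (caller's responsibility).
#' @param cpm_threshold Inclusive per-sample expression cutoff.
#' @param sample_fraction Strict fraction-of-samples cutoff.
#' @return Character vector of expressed gene IDs.
#' @export
expressed_gene_filter <- function(mat, cpm_threshold = 0.5,
                                  sample_fraction = 0.9) {
  frac <- rowMeans(mat >= cpm_threshold)
  rownames(mat)[frac > sample_fraction]
}

#' Differentially expressed gene set by fold change
#'
#' Two-sided fold change: a gene is differential when
#' `max(case/control, control/case)` strictly exceeds `fc_threshold`, so
#' both over- and under-expression count. Zero means are stabilized with a
#' small pseudocount before the ratio.
#'
#' @param case_mean,control_mean Named numeric vectors of mean expression;
#'   scored on the shared gene universe (disjoint universes are an error).
#' @param fc_threshold Strict fold-change cutoff (default 1.2).
#' @param pseudocount Added to zero means only (default 1e-9).
#' @return Character vector of differential gene IDs.
#' @export
differential_gene_set <- function(case_mean, control_mean, fc_threshold = 1.2,
                                  pseudocount = 1e-9) {
  shared <- intersect(names(case_mean), names(control_mean))
  if (!length(shared)) stop("case and control gene universes are disjoint")
  x <- case_mean[shared]; y <- control_mean[shared]
  x[x == 0] <- pseudocount
  y[y == 0] <- pseudocount
  fc <- pmax(x / y, y / x)
  shared[fc > fc_threshold]
}

#' Fisher's exact enrichment of one gene set in another
#'
#' Two-sided Fisher's exact test on the 2x2 table
#' (in both, in a only, in b only, in neither) over the given universe.
#' The odds ratio is the raw cross-product ratio `ad / bc`; zero cells are
#' reported via `or_zero` / `or_infinite` flags.
#'
#' @param set_a,set_b Gene sets, subsets of `universe`.
#' @param universe Background gene universe (>= 2 genes).
#' @return Object of class `enrichment_result`: list with `overlap`,
#'   `n_a`, `n_b`, `n_universe`, `odds_ratio`, `p_value`, `or_zero`,
#'   `or_infinite`, and the 2x2 `table`.
#' @export
fisher_enrichment <- function(set_a, set_b, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) < 2L) stop("universe must have >= 2 genes")
  set_a <- unique(as.character(set_a)); set_b <- unique(as.character(set_b))
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("set_a and set_b must be subsets of the universe")
  }
  ab <- length(intersect(set_a, set_b))
  a_only <- length(set_a) - ab
  b_only <- length(set_b) - ab
  rest <- length(universe) - ab - a_only - b_only
  tab <- matrix(c(ab, a_only, b_only, rest), nrow = 2L,
                dimnames = list(in_a = c("yes", "no"), in_b = c("yes", "no")))
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  num <- ab * rest; den <- a_only * b_only
  structure(list(overlap = ab, n_a = length(set_a), n_b = length(set_b),
                 n_universe = length(universe),
                 odds_ratio = if (den == 0) (if (num == 0) NaN else Inf) else num / den,
                 or_zero = num == 0 && den > 0,
                 or_infinite = den == 0 && num > 0,
                 p_value = p, table = tab),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Fisher enrichment: %d/%d vs %d/%d in universe %d; OR = %.3g, P = %.4g\n",
              x$overlap, x$n_a, x$overlap, x$n_b, x$n_universe,
              x$odds_ratio, x$p_value))
  invisible(x)
}
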