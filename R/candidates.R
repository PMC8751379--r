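# GWAS locus candidate-gene sets.

#' Read a GWAS index-SNP table
#'
#' Expects a header with columns `snp_id`, `chr`, `pos`, `p_value` (the
#' aliases `pval`, `p`, `chromosome`, `position`, `snp` are accepted).
#'
#' @param path Path to the loci TSV.
#' @return Data frame with columns snp_id, chr, pos, p_value.
#' @export
read_gwas_loci <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  names(df) <- tolower(names(df))
  alias <- c(snp = "snp_id", pval = "p_value", p = "p_value",
             chromosome = "chr", position = "pos")
  hit <- names(df) %in% names(alias)
  names(df)[hit] <- alias[names(df)[hit]]
  need <- c("snp_id", "chr", "pos", "p_value")
  if (!all(need %in% names(df))) {
    stop("loci table must have columns ", paste(need, collapse = ", "))
  }
  df <- df[need]
  df$snp_id <- as.character(df$snp_id)
  df$chr <- as.character(df$chr)
  df$pos <- as.integer(df$pos)
  df$p_value <- as.numeric(df$p_value)
  if (any(df$pos <= 0L)) stop("SNP positions must be positive")
  if (any(df$p_value <= 0 | df$p_value > 1)) stop("SNP p-values must be in (0, 1]")
  df
}

#' Read a gene annotation table
#'
#' Expects a header with columns `gene_id`, `chr`, `tss` (an optional
#' `symbol` column is kept if present).
#'
#' @param path Path to the annotation TSV.
#' @return Data frame with columns gene_id, chr, tss (and symbol if given).
#' @export
read_gene_annotations <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  names(df) <- tolower(names(df))
  if ("chromosome" %in% names(df)) names(df)[names(df) == "chromosome"] <- "chr"
  need <- c("gene_id", "chr", "tss")
  if (!all(need %in% names(df))) {
    stop("annotation table must have columns ", paste(need, collapse = ", "))
  }
  df$gene_id <- as.character(df$gene_id)
  df$chr <- as.character(df$chr)
  df$tss <- as.integer(df$tss)
  if (any(df$tss <= 0L)) stop("TSS positions must be positive")
  df[c(need, intersect("symbol", names(df)))]
}

#' Build per-locus candidate gene sets
#'
#' For each GWAS index SNP, collects the genes whose transcription start
#' site lies within the window centred on the SNP (closed interval, so a
#' TSS exactly `window_bp / 2` away is included) and keeps at most
#' `max_candidates` of them, nearest first; distance ties go to the
#' smaller gene ID. Loci with no candidate are dropped with a warning.
#'
#' @param loci Data frame as from [read_gwas_loci()].
#' @param annotations Data frame as from [read_gene_annotations()].
#' @param window_bp Full window width in bp centred at the SNP
#'   (default 2 Mb).
#' @param max_candidates Maximum candidates kept per locus (default 20).
#' @return Object of class `locus_table`: list of loci, each a list with
#'   `snp_id`, `chr`, `pos`, `p_value`, `candidates` (character vector,
#'   nearest first) and `distance` (named numeric, bp from SNP to TSS).
#' @export
build_candidate_sets <- function(loci, annotations, window_bp = 2e6,
                                 max_candidates = 20L) {
  if (!nrow(loci)) stop("loci table is empty")
  if (!nrow(annotations)) stop("annotation table is empty")
  half <- window_bp / 2
  out <- vector("list", nrow(loci))
  dropped <- character(0)
  for (i in seq_len(nrow(loci))) {
    snp <- loci[i, ]
    ann <- annotations[annotations$chr == snp$chr, , drop = FALSE]
    dist <- abs(ann$tss - snp$pos)
    keep <- dist <= half
    ann <- ann[keep, , drop = FALSE]; dist <- dist[keep]
    if (!nrow(ann)) { dropped <- c(dropped, snp$snp_id); next }
    ord <- order(dist, ann$gene_id)
    ord <- head(ord, max_candidates)
    out[[i]] <- list(snp_id = snp$snp_id, chr = snp$chr, pos = snp$pos,
                     p_value = snp$p_value,
                     candidates = ann$gene_id[ord],
                     distance = setNames(dist[ord], ann$gene_id[ord]))
  }
  if (length(dropped)) {
    warning(length(dropped), " locus/loci with no candidate gene dropped: ",
            paste(head(dropped, 5L), collapse = ", "))
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) stop("no locus retained any candidate gene")
  names(out) <- vapply(out, `[[`, "", "snp_id")
  structure(out, class = "locus_table")
}

#' @export
print.locus_table <- function(x, ...) {
  cat(sprintf("Locus table: %d loci, %d distinct candidate genes\n",
              length(x), length(unique(unlist(lapply(x, `[[`, "candidates"))))))
  sizes <- vapply(x, function(l) length(l$candidates), 0L)
  cat(sprintf("  candidates per locus: min %d, median %.0f, max %d\n",
              min(sizes), stats::median(sizes), max(sizes)))
  invisible(x)
}

locus_candidates <- function(table) lapply(table, `[[`, "candidates")

candidate_universe <- function(table) {
  sort(unique(unlist(locus_candidates(table), use.names = FALSE)))
}
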