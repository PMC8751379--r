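# Shared internal helpers.

# Evaluate `code` under a fixed RNG seed when `seed` is non-NULL, otherwise
# under the current RNG state. All user-facing stochastic entry points route
# through this so a single seed argument makes a whole call reproducible.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) return(code)
  withr::with_seed(as.integer(seed), code)
}

# sample() interprets a length-1 numeric x as 1:x; always index instead.
sample_vec <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a gene-set file
#'
#' One gene identifier per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to the gene-set file.
#' @return Character vector of gene identifiers, in file order, deduplicated.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop("gene-set file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  unique(lines[nzchar(lines)])
}

#' Write a gene-set file
#'
#' @param genes Character vector of gene identifiers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}
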