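# Internal numerical and bookkeeping helpers shared across modules.

# log(sum(exp(x))) without overflow; -Inf for empty input.
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference
# underflows or when b >= a (used for the two-distinct-causal mass,
# which is exactly zero in single-SNP regions).
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# Deterministic child seeds below 2^31, so one user-facing seed can
# drive several independent generators.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483647L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Provenance header written at the top of every TSV the package emits.
provenance_line <- function(params = NULL) {
  extra <- if (length(params)) {
    paste0(" ", paste(names(params), unlist(params), sep = "=", collapse = " "))
  } else ""
  sprintf("# locusweave %s%s", as.character(packageVersion("locusweave")), extra)
}

#' Write a tab-delimited result table with a provenance header
#'
#' All tabular outputs of the package go through this writer: one comment
#' line recording the package version and the parameters used, then a
#' standard header + rows TSV that `read.delim(comment.char = "#")` reads
#' back unchanged.
#'
#' @param x data frame to write.
#' @param path output file path.
#' @param params named list of parameters recorded in the header line.
#' @return `path`, invisibly.
#' @export
write_tsv_prov <- function(x, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line(params), con)
  suppressWarnings(write.table(x, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' Read a tab-delimited table written by [write_tsv_prov()]
#'
#' @param path file path.
#' @return data frame.
#' @export
read_tsv_prov <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
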