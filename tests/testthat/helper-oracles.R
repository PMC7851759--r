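# Independent oracles used to cross-check the package implementation.
# These deliberately use naive arithmetic (explicit loops, raw
# exponentials, closed-form tail sums) rather than the code paths they
# verify.

# Exhaustive enumeration of every single-SNV and SNV-pair causal
# configuration for the five-hypothesis posteriors; feasible for small
# regions and moderate log-ABFs.
oracle_coloc_enumeration <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4,
                                     p12 = 1e-5) {
  n <- length(labf1)
  bf1 <- exp(labf1)
  bf2 <- exp(labf2)
  h0 <- 1
  h1 <- p1 * sum(bf1)
  h2 <- p2 * sum(bf2)
  h3 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) h3 <- h3 + p1 * p2 * bf1[i] * bf2[j]
    }
  }
  h4 <- p12 * sum(bf1 * bf2)
  m <- c(h0, h1, h2, h3, h4)
  m / sum(m)
}

# Literal step-up definition of Benjamini-Hochberg rejection plus the
# adjusted q-values, written from the definition.
oracle_bh <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  crit <- alpha * seq_len(m) / m
  kmax <- if (any(ps <= crit)) max(which(ps <= crit)) else 0L
  reject_sorted <- seq_len(m) <= kmax
  q_sorted <- vapply(seq_len(m), function(i) {
    min(m * ps[i:m] / (i:m))
  }, 0)
  q <- numeric(m); q[o] <- pmin(q_sorted, 1)
  reject <- logical(m); reject[o] <- reject_sorted
  list(qvalue = q, significant = reject)
}

# Hypergeometric upper-tail probability by explicit tail summation.
oracle_hyper_tail <- function(n_universe, n_module, n_markers, overlap) {
  tmax <- min(n_module, n_markers)
  sum(vapply(overlap:tmax, function(t) {
    choose(n_markers, t) * choose(n_universe - n_markers, n_module - t) /
      choose(n_universe, n_module)
  }, 0))
}

# Small aligned GWAS/QTL summary-statistics pair used by several tests.
make_aligned_pair <- function(n = 5L, seed = 1L) {
  set.seed(seed)
  df <- function(beta) data.frame(
    variant_id = sprintf("rs%02d", seq_len(n)), chrom = "1",
    pos = 1000L * seq_len(n),
    effect_allele = rep("A", n), other_allele = rep("G", n),
    beta = beta, se = runif(n, 0.05, 0.2), pvalue = runif(n),
    eaf = runif(n, 0.1, 0.9), n = 1000L, info = NA_real_,
    stringsAsFactors = FALSE)
  list(gwas = df(rnorm(n, 0, 0.1)), qtl = df(rnorm(n, 0, 0.3)))
}

# Write a small summary-statistics file and return its path.
write_sumstats_fixture <- function(lines, dir = tempdir()) {
  path <- tempfile("sumstats", tmpdir = dir, fileext = ".tsv")
  writeLines(lines, path)
  path
}

sumstats_header <- paste("variant_id", "chrom", "pos", "effect_allele",
                         "other_allele", "beta", "se", "pvalue", "eaf",
                         "n", "info", sep = "\t")

sumstats_row <- function(id, chrom, pos, ea, oa, beta, se, p, eaf,
                         n = 1000, info = 0.9) {
  paste(id, chrom, pos, ea, oa, beta, se, p, eaf, n, info, sep = "\t")
}
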