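# Bayesian colocalization of two association signals over one region,
# from per-SNV Wakefield approximate Bayes factors, under the standard
# single-causal-variant assumption for each trait.
#
# Five hypotheses are weighed: H0 no causal variant for either trait,
# H1 causal for trait 1 only, H2 causal for trait 2 only, H3 two
# distinct causal variants, H4 one shared causal variant. All mass
# accumulation is in log space.

#' Colocalization priors
#'
#' Per-SNV prior probabilities of association with trait 1 (`p1`),
#' trait 2 (`p2`), or both (`p12`), plus the Gaussian prior SD on the
#' true effect used by the Wakefield approximate Bayes factor: 0.2 for
#' quantitative traits (SD units) and 0.15 for case-control traits
#' (log-odds units).
#'
#' @param p1,p2,p12 per-SNV prior probabilities (defaults 1e-4, 1e-4,
#'   1e-5).
#' @param prior_sd_quant prior effect SD for quantitative traits.
#' @param prior_sd_cc prior effect SD for case-control traits.
#' @return object of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         prior_sd_quant = 0.2, prior_sd_cc = 0.15) {
  if (!(p12 > 0 && p12 <= min(p1, p2))) {
    stop("coloc_priors: need 0 < p12 <= min(p1, p2)")
  }
  if (p1 + p2 + p12 >= 1) stop("coloc_priors: p1 + p2 + p12 must be < 1")
  if (prior_sd_quant <= 0 || prior_sd_cc <= 0) {
    stop("coloc_priors: prior SDs must be positive")
  }
  structure(list(p1 = p1, p2 = p2, p12 = p12,
                 prior_sd_quant = prior_sd_quant, prior_sd_cc = prior_sd_cc),
            class = "coloc_priors")
}

#' Wakefield approximate Bayes factor (natural log)
#'
#' For an estimated effect `beta` with standard error `se` and a
#' Gaussian effect prior with SD `prior_sd`, the log approximate Bayes
#' factor in favor of a nonzero effect is
#' `log ABF = 0.5 * log(1 - r) + 0.5 * r * z^2` with `z = beta/se`,
#' `V = se^2`, `W = prior_sd^2` and shrinkage `r = W / (W + V)`.
#' Vectorized over `beta` and `se`.
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), positive.
#' @param prior_sd prior effect SD, positive.
#' @return log approximate Bayes factor(s).
#' @export
wakefield_log_abf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop("wakefield_log_abf: se must be positive")
  if (prior_sd <= 0) stop("wakefield_log_abf: prior_sd must be positive")
  z2 <- (beta / se)^2
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  0.5 * log1p(-r) + 0.5 * r * z2
}

#' Five-hypothesis colocalization posteriors from log Bayes factors
#'
#' Accumulates the unnormalized hypothesis masses
#' `H0 = 1`, `H1 = p1 * S1`, `H2 = p2 * S2`,
#' `H3 = p1 * p2 * (S1 * S2 - S12)`, `H4 = p12 * S12`,
#' where `S1`, `S2` and `S12` are sums of `exp(labf1)`, `exp(labf2)` and
#' `exp(labf1 + labf2)` over SNVs, all in log space with log-sum-exp,
#' then normalizes. The per-SNV H4 contribution is the normalized
#' `exp(labf1_i + labf2_i)`; the top SNV is its argmax, ties broken by
#' lowest genomic position (input order when positions are absent).
#'
#' @param labf1,labf2 equal-length log-ABF vectors over harmonized SNVs.
#' @param priors a [coloc_priors()].
#' @param snp_id optional SNV identifiers.
#' @param pos optional SNV positions used for tie-breaking.
#' @return object of class `coloc_posterior`: `pph0`..`pph4`, `n_snps`,
#'   `per_snp_h4` (sums to 1), `top_snv`.
#' @export
coloc_posteriors <- function(labf1, labf2, priors = coloc_priors(),
                             snp_id = NULL, pos = NULL) {
  if (length(labf1) != length(labf2)) {
    stop("coloc_posteriors: log-ABF vectors differ in length")
  }
  n <- length(labf1)
  if (n == 0L) stop("coloc_posteriors: empty input")
  if (anyNA(labf1) || anyNA(labf2)) stop("coloc_posteriors: NA log-ABF")

  lS1 <- logsumexp(labf1)
  lS2 <- logsumexp(labf2)
  lS12 <- logsumexp(labf1 + labf2)

  lH <- c(
    h0 = 0,
    h1 = log(priors$p1) + lS1,
    h2 = log(priors$p2) + lS2,
    h3 = log(priors$p1) + log(priors$p2) + logdiffexp(lS1 + lS2, lS12),
    h4 = log(priors$p12) + lS12
  )
  post <- exp(lH - logsumexp(lH))
  post <- post / sum(post)

  l12 <- labf1 + labf2
  per_snp_h4 <- exp(l12 - logsumexp(l12))
  per_snp_h4 <- per_snp_h4 / sum(per_snp_h4)

  best <- max(per_snp_h4)
  cand <- which(per_snp_h4 >= best - 1e-15)
  top_i <- if (!is.null(pos)) cand[which.min(pos[cand])] else cand[1L]

  structure(list(
    pph0 = post[["h0"]], pph1 = post[["h1"]], pph2 = post[["h2"]],
    pph3 = post[["h3"]], pph4 = post[["h4"]],
    n_snps = n, per_snp_h4 = per_snp_h4,
    top_snv = if (!is.null(snp_id)) snp_id[top_i] else top_i
  ), class = "coloc_posterior")
}

#' @export
print.coloc_posterior <- function(x, ...) {
  cat(sprintf(
    "colocalization posteriors over %d SNVs\n  PPH0..4: %s\n  top SNV: %s\n",
    x$n_snps,
    paste(sprintf("%.4f", c(x$pph0, x$pph1, x$pph2, x$pph3, x$pph4)),
          collapse = " "),
    x$top_snv))
  invisible(x)
}

#' Colocalize one molecular feature against a GWAS signal
#'
#' Computes per-SNV Wakefield log-ABFs for each trait with the
#' trait-type-appropriate prior effect SD (case-control `cc` on the
#' log-odds scale, quantitative `quant` in SD units) and combines them
#' with [coloc_posteriors()]. Inputs must already be harmonized and
#' QC-filtered. `strong_coloc` flags PPH4 at or above `pph4_min`.
#'
#' @param gwas,qtl aligned summary-statistics data frames (equal rows,
#'   identical variant order).
#' @param priors a [coloc_priors()].
#' @param trait_types two-element character vector giving the GWAS and
#'   QTL trait types, each `"cc"` or `"quant"`.
#' @param feature_id,tissue,dataset labels carried into the result.
#' @param pph4_min strong-colocalization threshold (inclusive), 0.75.
#' @return object of class `feature_coloc`: labels, `posterior`,
#'   `strong_coloc`.
#' @export
colocalize_feature <- function(gwas, qtl, priors = coloc_priors(),
                               trait_types = c("cc", "quant"),
                               feature_id = "feature", tissue = "tissue",
                               dataset = "dataset", pph4_min = 0.75) {
  stopifnot(nrow(gwas) == nrow(qtl),
            all(trait_types %in% c("cc", "quant")), length(trait_types) == 2)
  if (!all(gwas$variant_id == qtl$variant_id)) {
    stop("colocalize_feature: inputs are not aligned; run harmonize_pair first")
  }
  if (nrow(gwas) < 2L) {
    warning("colocalize_feature: fewer than 2 SNVs; ",
            "two distinct causal variants cannot be distinguished (PPH3 = 0)")
  }
  sd1 <- if (trait_types[1] == "cc") priors$prior_sd_cc else priors$prior_sd_quant
  sd2 <- if (trait_types[2] == "cc") priors$prior_sd_cc else priors$prior_sd_quant
  labf1 <- wakefield_log_abf(gwas$beta, gwas$se, sd1)
  labf2 <- wakefield_log_abf(qtl$beta, qtl$se, sd2)
  post <- coloc_posteriors(labf1, labf2, priors,
                           snp_id = gwas$variant_id, pos = gwas$pos)
  structure(list(feature_id = feature_id, tissue = tissue, dataset = dataset,
                 posterior = post, strong_coloc = post$pph4 >= pph4_min),
            class = "feature_coloc")
}

#' Classify a gene's colocalization as expression, splicing, or none
#'
#' Expression: gene-level PPH4 at or above the threshold. Splicing: some
#' exon's PPH4 at or above the threshold while the gene level shows
#' evidence against a shared variant (gene PPH3 > gene PPH4). Expression
#' takes precedence when both rules fire.
#'
#' @param gene_result `feature_coloc` for the whole gene.
#' @param exon_results list of `feature_coloc` for the gene's exons.
#' @param pph4_min threshold (inclusive), default 0.75.
#' @return `"expression"`, `"splicing"`, or `"none"`.
#' @export
classify_splicing <- function(gene_result, exon_results = list(),
                              pph4_min = 0.75) {
  gp <- gene_result$posterior
  if (gp$pph4 >= pph4_min) return("expression")
  if (length(exon_results)) {
    exon_pph4 <- vapply(exon_results, function(x) x$posterior$pph4, 0)
    if (max(exon_pph4) >= pph4_min && gp$pph3 > gp$pph4) return("splicing")
  }
  "none"
}

#' Flatten feature colocalization results into a table
#'
#' @param results list of `feature_coloc` objects.
#' @return data frame with one row per feature x tissue: labels,
#'   `n_snps`, `pph0`..`pph4`, `top_snv`, `strong_coloc`.
#' @export
coloc_result_table <- function(results) {
  do.call(rbind, lapply(results, function(x) {
    p <- x$posterior
    data.frame(feature_id = x$feature_id, dataset = x$dataset,
               tissue = x$tissue, n_snps = p$n_snps,
               pph0 = p$pph0, pph1 = p$pph1, pph2 = p$pph2,
               pph3 = p$pph3, pph4 = p$pph4,
               top_snv = as.character(p$top_snv),
               strong_coloc = x$strong_coloc,
               stringsAsFactors = FALSE)
  }))
}
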