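# Cis methylation-QTL mapping: ordinary least squares of CpG
# methylation on genotype dosage with covariate adjustment, a windowed
# scan retaining each SNV's strongest CpG pair at 5% FDR, and CpG-to-
# gene mapping by distance to a transcription terminus.

# Build the OLS design matrix: intercept, dosage, expanded covariates.
mqtl_design <- function(dosage, covariates) {
  if (is.null(covariates) || !ncol(as.data.frame(covariates))) {
    X <- cbind(`(Intercept)` = 1, genotype = dosage)
  } else {
    covariates <- as.data.frame(covariates)
    mm <- stats::model.matrix(~ ., data = covariates)
    X <- cbind(mm[, 1L, drop = FALSE], genotype = dosage,
               mm[, -1L, drop = FALSE])
  }
  X
}

#' Fit one cis-mQTL linear model
#'
#' Ordinary least squares of a CpG's methylation beta values on genotype
#' dosage, adjusting for covariates (age at death, sex, population-
#' stratification components, batch, postmortem interval in the intended
#' application); the genotype coefficient is tested with a two-sided
#' t-test. Samples with missing covariates are dropped listwise. The
#' association is on beta values directly; set `m_values = TRUE` to
#' logit-transform first.
#'
#' @param dosage genotype dosage vector.
#' @param cpg_values methylation values in (0, 1), same length.
#' @param covariates data frame of covariates (factors allowed), or NULL.
#' @param m_values test on the logit (M-value) scale instead.
#' @return list with `beta_hat`, `se`, `pvalue`, `n_used`, `n_dropped`.
#' @export
fit_cis_mqtl <- function(dosage, cpg_values, covariates = NULL,
                         m_values = FALSE) {
  stopifnot(length(dosage) == length(cpg_values))
  y <- if (m_values) qlogis(cpg_values) else cpg_values
  keep <- is.finite(dosage) & is.finite(y)
  if (!is.null(covariates)) keep <- keep & complete.cases(covariates)
  n_dropped <- sum(!keep)
  if (n_dropped) {
    message("fit_cis_mqtl: ", n_dropped, " sample(s) dropped listwise")
  }
  y <- y[keep]; dosage <- dosage[keep]
  covariates <- if (!is.null(covariates)) {
    as.data.frame(covariates)[keep, , drop = FALSE]
  }
  if (sd(y) == 0) stop("fit_cis_mqtl: constant CpG vector, SE undefined")
  X <- mqtl_design(dosage, covariates)
  if (length(y) <= ncol(X) + 1L) {
    stop("fit_cis_mqtl: too few samples (", length(y), ") for ",
         ncol(X), " coefficients")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("fit_cis_mqtl: rank-deficient design; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- lm.fit(X, y)
  df <- length(y) - ncol(X)
  rss <- sum(fit$residuals^2)
  XtXinv <- chol2inv(qr.R(qrX))
  j <- match("genotype", colnames(X))
  se <- sqrt(rss / df * XtXinv[j, j])
  if (!is.finite(se) || se == 0) stop("fit_cis_mqtl: SE undefined")
  beta_hat <- fit$coefficients[j]
  tval <- beta_hat / se
  list(beta_hat = unname(beta_hat), se = se,
       pvalue = 2 * pt(-abs(tval), df), n_used = length(y),
       n_dropped = n_dropped)
}

#' Windowed cis-mQTL scan with strongest-pair retention
#'
#' Tests every SNV-CpG pair whose distance is within `window_bp`
#' (inclusive), applies BH-FDR across all tests in the scan, and retains
#' for each SNV its minimum-p CpG pair provided that pair's q-value is
#' at or below `fdr`.
#'
#' @param snvs list with `info` (data frame: snv_id, chrom, pos) and
#'   `dosage` (samples x SNVs matrix, columns in `info` order).
#' @param cpgs list with `info` (data frame: cpg_id, chrom, pos) and
#'   `beta` (CpGs x samples matrix, rows in `info` order).
#' @param covariates data frame of per-sample covariates, or NULL.
#' @param window_bp window half-width, default 500 kb.
#' @param fdr retention FDR level, default 0.05.
#' @param m_values passed to [fit_cis_mqtl()].
#' @return list with `pairs` (all tested pairs: snv_id, cpg_id,
#'   beta_hat, se, pvalue, qvalue, direction) and `retained` (the
#'   strongest pair per SNV passing FDR).
#' @export
scan_windows <- function(snvs, cpgs, covariates = NULL, window_bp = 500000L,
                         fdr = 0.05, m_values = FALSE) {
  sinfo <- snvs$info; cinfo <- cpgs$info
  rows <- list()
  for (i in seq_len(nrow(sinfo))) {
    inwin <- which(cinfo$chrom == sinfo$chrom[i] &
                   abs(cinfo$pos - sinfo$pos[i]) <= window_bp)
    for (j in inwin) {
      fit <- fit_cis_mqtl(snvs$dosage[, i], cpgs$beta[j, ], covariates,
                          m_values = m_values)
      rows[[length(rows) + 1L]] <- data.frame(
        snv_id = sinfo$snv_id[i], cpg_id = cinfo$cpg_id[j],
        beta_hat = fit$beta_hat, se = fit$se, pvalue = fit$pvalue,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    empty <- data.frame(snv_id = character(0), cpg_id = character(0),
                        beta_hat = numeric(0), se = numeric(0),
                        pvalue = numeric(0), qvalue = numeric(0),
                        direction = character(0), stringsAsFactors = FALSE)
    return(list(pairs = empty, retained = empty))
  }
  pairs <- do.call(rbind, rows)
  pairs$qvalue <- p.adjust(pairs$pvalue, method = "BH")
  pairs$direction <- ifelse(pairs$beta_hat >= 0, "positive", "negative")

  retained <- do.call(rbind, lapply(split(pairs, pairs$snv_id), function(d) {
    best <- d[which.min(d$pvalue), , drop = FALSE]
    if (best$qvalue <= fdr) best else NULL
  }))
  if (is.null(retained)) retained <- pairs[0, ]
  rownames(pairs) <- rownames(retained) <- NULL
  list(pairs = pairs, retained = retained)
}

#' Map a CpG site to nearby genes
#'
#' Returns the genes having a transcription start or end within
#' `flank_bp` (inclusive) of the CpG position, on the same chromosome;
#' strand-ignorant distance to either terminus.
#'
#' @param cpg list or one-row data frame with `chrom` and `pos`.
#' @param genes gene annotation data frame.
#' @param flank_bp flank distance, default 10 kb.
#' @return character vector of gene ids (possibly empty or multiple).
#' @export
map_cpg_to_gene <- function(cpg, genes, flank_bp = 10000L) {
  sel <- genes$chrom == cpg$chrom &
    (abs(genes$start - cpg$pos) <= flank_bp |
     abs(genes$end - cpg$pos) <= flank_bp)
  genes$gene_id[sel]
}
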