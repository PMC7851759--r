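# Weighted gene/CpG-level association from GWAS summary statistics
# (TWAS / MWAS): z = w' z_gwas / sqrt(w' R w) for per-SNV weights w
# predictive of the molecular trait and an LD matrix R, plus
# genome-wide BH-FDR and a greedy conditional analysis for loci with
# several significant features.

#' Per-feature SNV weight set
#'
#' @param feature_id feature label.
#' @param snv_ids SNV identifiers.
#' @param w numeric weights, same length as `snv_ids`, not all zero.
#' @param training_scheme `"top1"` or `"marginal"`.
#' @return object of class `weight_set`.
#' @export
weight_set <- function(feature_id, snv_ids, w,
                       training_scheme = c("top1", "marginal")) {
  training_scheme <- match.arg(training_scheme)
  if (length(w) != length(snv_ids)) {
    stop("weight_set: weights and snv_ids differ in length")
  }
  if (all(w == 0)) stop("weight_set: all-zero weight vector")
  structure(list(feature_id = feature_id, snv_ids = as.character(snv_ids),
                 w = as.numeric(w), training_scheme = training_scheme),
            class = "weight_set")
}

#' Train transparent SNV weights from QTL summary statistics
#'
#' `top1` puts weight 1 on the minimum-p SNV (ties broken by lowest
#' genomic position) and 0 elsewhere; `marginal` uses each SNV's
#' marginal z-score `beta/se`. These are deliberately simple,
#' scheme-annotated stand-ins for externally trained predictive models.
#'
#' @param qtl QTL summary-statistics data frame.
#' @param scheme `"top1"` or `"marginal"`.
#' @param feature_id label for the resulting weight set.
#' @return a [weight_set()].
#' @export
train_weights <- function(qtl, scheme = c("top1", "marginal"),
                          feature_id = "feature") {
  scheme <- match.arg(scheme)
  if (!nrow(qtl)) stop("train_weights: empty QTL input")
  if (scheme == "top1") {
    pmin_ <- min(qtl$pvalue)
    cand <- which(qtl$pvalue == pmin_)
    top <- cand[which.min(qtl$pos[cand])]
    w <- numeric(nrow(qtl)); w[top] <- 1
  } else {
    w <- qtl$beta / qtl$se
  }
  weight_set(feature_id, qtl$variant_id, w, scheme)
}

#' TWAS / MWAS association z-score
#'
#' `z = w' z_gwas / sqrt(w' R w)`. An optional ridge
#' `R <- (1 - lambda) R + lambda I` stabilizes the denominator when `R`
#' is estimated from a finite genotype reference; with the default
#' `ridge_lambda = 0` the statistic is the exact quadratic form.
#'
#' @param weights a [weight_set()].
#' @param gwas_z GWAS z-scores, aligned and ordered as `weights$snv_ids`.
#' @param ld LD (correlation) matrix in the same SNV order.
#' @param ridge_lambda ridge mixing weight in `[0, 1)`, default 0.
#' @return the association z-score.
#' @export
twas_zscore <- function(weights, gwas_z, ld, ridge_lambda = 0) {
  w <- weights$w
  if (length(gwas_z) != length(w) || nrow(ld) != length(w)) {
    stop("twas_zscore: weights, gwas_z and ld are not aligned")
  }
  if (all(w == 0)) stop("twas_zscore: all-zero weights")
  R <- if (ridge_lambda > 0) {
    (1 - ridge_lambda) * ld + diag(ridge_lambda, length(w))
  } else ld
  denom2 <- drop(crossprod(w, R %*% w))
  if (denom2 <= 0) stop("twas_zscore: non-positive w'Rw after regularization")
  drop(crossprod(w, gwas_z)) / sqrt(denom2)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted q-values with the usual cumulative-minimum
#' monotonicity enforcement, and significance flags at level `alpha`.
#'
#' @param pvalues p-values in (0, 1].
#' @param alpha FDR level, default 0.05.
#' @return data frame with `pvalue`, `qvalue`, `significant`.
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (!length(pvalues)) {
    return(data.frame(pvalue = numeric(0), qvalue = numeric(0),
                      significant = logical(0)))
  }
  q <- p.adjust(pvalues, method = "BH")
  data.frame(pvalue = pvalues, qvalue = q, significant = q <= alpha)
}

#' Run the weighted association scan over a set of features
#'
#' Computes the TWAS/MWAS z-score and two-sided normal p-value for each
#' weight set against one GWAS, then applies genome-wide BH-FDR across
#' the supplied features. FDR is intended to be applied separately per
#' analysis type (expression, splicing, methylation): call once per
#' type.
#'
#' @param weight_sets list of [weight_set()] objects.
#' @param gwas GWAS summary-statistics data frame (source of z-scores).
#' @param ld_list named list of LD matrices (per feature), or a single
#'   matrix shared by all features; row order must match each weight
#'   set's `snv_ids` as found in `gwas`.
#' @param alpha FDR level, default 0.05.
#' @param ridge_lambda ridge passed to [twas_zscore()]; use a small
#'   positive value (e.g. 0.01) when LD is estimated from a sample.
#' @return data frame: `feature_id`, `scheme`, `z_twas`, `pvalue`,
#'   `qvalue`, `significant`.
#' @export
twas_scan <- function(weight_sets, gwas, ld_list, alpha = 0.05,
                      ridge_lambda = 0) {
  zg_all <- setNames(gwas$beta / gwas$se, gwas$variant_id)
  rows <- lapply(weight_sets, function(ws) {
    if (!all(ws$snv_ids %in% names(zg_all))) {
      stop("twas_scan: feature ", ws$feature_id,
           " has SNVs absent from the GWAS")
    }
    zg <- zg_all[ws$snv_ids]
    ld <- if (is.list(ld_list)) ld_list[[ws$feature_id]] else ld_list
    z <- twas_zscore(ws, zg, ld, ridge_lambda)
    data.frame(feature_id = ws$feature_id, scheme = ws$training_scheme,
               z_twas = z, pvalue = 2 * pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  fdr <- bh_fdr(out$pvalue, alpha)
  out$qvalue <- fdr$qvalue
  out$significant <- fdr$significant
  rownames(out) <- NULL
  out
}

#' Conditional analysis of multiple significant features at one locus
#'
#' Greedy single-round forward selection: the feature with the largest
#' `|z|` is selected; every other feature's GWAS z-vector is
#' residualized on the selected feature's predicted-expression
#' direction, `z' = z - R w~ (w~' z)` with `w~ = w / sqrt(w' R w)`, and
#' its z-score recomputed from `z'`. Features whose conditional p-value
#' is at or above `alpha` are labeled `"joint"` (marginal once the
#' selected signal is removed), the others `"independent"`.
#'
#' @param results data frame from [twas_scan()] for the locus features.
#' @param weights named list of [weight_set()]s keyed by feature id.
#' @param gwas GWAS summary-statistics data frame covering the locus.
#' @param ld LD matrix over the union of the locus SNVs, with dimnames.
#' @param alpha conditional significance level, default 0.05.
#' @param ridge_lambda ridge passed to [twas_zscore()].
#' @return `results` with added `conditional_z` and `conditional_label`
#'   (`"selected"`, `"independent"`, or `"joint"`).
#' @export
conditional_analysis <- function(results, weights, gwas, ld, alpha = 0.05,
                                 ridge_lambda = 0) {
  stopifnot(nrow(results) >= 1, !is.null(rownames(ld)))
  snv_univ <- rownames(ld)
  zg <- setNames(gwas$beta / gwas$se, gwas$variant_id)[snv_univ]

  expand_w <- function(ws) {
    w <- numeric(length(snv_univ))
    idx <- match(ws$snv_ids, snv_univ)
    if (anyNA(idx)) stop("conditional_analysis: feature ", ws$feature_id,
                         " has SNVs outside the LD matrix")
    w[idx] <- ws$w
    w
  }

  sel_i <- which.max(abs(results$z_twas))
  sel_w <- expand_w(weights[[results$feature_id[sel_i]]])
  R <- if (ridge_lambda > 0) {
    (1 - ridge_lambda) * ld + diag(ridge_lambda, length(snv_univ))
  } else ld
  denom <- drop(crossprod(sel_w, R %*% sel_w))
  results$conditional_z <- NA_real_
  results$conditional_label <- NA_character_
  results$conditional_label[sel_i] <- "selected"
  results$conditional_z[sel_i] <- results$z_twas[sel_i]
  if (denom <= 0) {
    warning("conditional_analysis: singular denominator for selected ",
            "feature; remaining features skipped")
    return(results)
  }
  w_t <- sel_w / sqrt(denom)
  z_resid <- zg - drop(R %*% w_t) * drop(crossprod(w_t, zg))

  for (i in setdiff(seq_len(nrow(results)), sel_i)) {
    ws <- weights[[results$feature_id[i]]]
    w <- expand_w(ws)
    d2 <- drop(crossprod(w, R %*% w))
    if (d2 <= 0) {
      warning("conditional_analysis: singular denominator for feature ",
              ws$feature_id, "; skipped")
      next
    }
    cz <- drop(crossprod(w, z_resid)) / sqrt(d2)
    results$conditional_z[i] <- cz
    cp <- 2 * pnorm(-abs(cz))
    results$conditional_label[i] <- if (cp >= alpha) "joint" else "independent"
  }
  results
}
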