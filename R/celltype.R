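# Cell-type prevalence enrichment, coexpression-module eigengenes and
# membership (kME), and Fisher-exact marker enrichment of modules.

#' Cell-type prevalence enrichment of one gene
#'
#' For each cell type, the enrichment is the gene's mean expression in
#' that type divided by the unweighted mean of its per-type means across
#' all other types (so type sizes do not bias the ratio). The primary
#' cell type is the one with the highest enrichment; exact ties are
#' broken lexicographically and flagged ambiguous. A zero denominator
#' gives `Inf` with a warning.
#'
#' @param expr expression matrix, genes x cells, with gene rownames.
#' @param cell_labels cell-type label per column of `expr`.
#' @param gene_id gene to profile.
#' @return list: `gene_id`, `enrichment` (named per type),
#'   `primary_type`, `ambiguous`.
#' @export
prevalence_enrichment <- function(expr, cell_labels, gene_id) {
  stopifnot(ncol(expr) == length(cell_labels))
  types <- sort(unique(as.character(cell_labels)))
  if (length(types) < 2L) {
    stop("prevalence_enrichment: need at least 2 cell types")
  }
  if (!gene_id %in% rownames(expr)) {
    stop("prevalence_enrichment: gene '", gene_id, "' not in matrix")
  }
  x <- expr[gene_id, ]
  type_means <- vapply(types, function(t) mean(x[cell_labels == t]), 0)
  enrich <- vapply(seq_along(types), function(i) {
    other <- mean(type_means[-i])
    if (other == 0) {
      warning("prevalence_enrichment: zero mean outside type '",
              types[i], "'")
      if (type_means[i] == 0) return(NaN)
      return(Inf)
    }
    type_means[i] / other
  }, 0)
  names(enrich) <- types
  best <- max(enrich)
  cand <- which(enrich == best)
  list(gene_id = gene_id, enrichment = enrich,
       primary_type = types[cand[1L]], ambiguous = length(cand) > 1L)
}

#' Module eigengene (first principal component of a module)
#'
#' Gene rows are standardized (mean 0, SD 1; zero-variance rows dropped
#' with a warning) and the first right singular vector of the
#' standardized matrix is returned, with its sign fixed so that the mean
#' correlation with the member genes is non-negative.
#'
#' @param expr expression matrix, module genes x samples (>= 2 genes,
#'   >= 3 samples).
#' @return per-sample eigengene vector (unit length).
#' @export
module_eigengene <- function(expr) {
  stopifnot(nrow(expr) >= 2L, ncol(expr) >= 3L)
  sds <- apply(expr, 1L, sd)
  if (any(sds == 0)) {
    warning("module_eigengene: dropping ", sum(sds == 0),
            " zero-variance gene row(s)")
    expr <- expr[sds > 0, , drop = FALSE]
    if (nrow(expr) < 2L) stop("module_eigengene: fewer than 2 usable genes")
    sds <- sds[sds > 0]
  }
  zs <- (expr - rowMeans(expr)) / sds
  v <- svd(zs, nu = 0, nv = 1)$v[, 1L]
  memb_cor <- apply(zs, 1L, function(g) suppressWarnings(cor(g, v)))
  if (mean(memb_cor, na.rm = TRUE) < 0) v <- -v
  v
}

#' Module membership (kME) of a gene
#'
#' The absolute Pearson correlation between a gene's expression and a
#' module eigengene, so membership always lies in `[0, 1]`; set
#' `squared = TRUE` for squared correlation instead. The gene counts as
#' highly relevant to the module when membership exceeds 0.76 (strict).
#'
#' @param gene_expr per-sample expression of the gene (length >= 3).
#' @param eigengene per-sample module eigengene.
#' @param squared use squared correlation.
#' @param relevant_min relevance threshold (exclusive), default 0.76.
#' @return list: `kME`, `relevant`.
#' @export
module_membership <- function(gene_expr, eigengene, squared = FALSE,
                              relevant_min = 0.76) {
  stopifnot(length(gene_expr) == length(eigengene), length(gene_expr) >= 3L)
  if (sd(gene_expr) == 0 || sd(eigengene) == 0) {
    stop("module_membership: zero-variance input, correlation undefined")
  }
  r <- cor(gene_expr, eigengene)
  kME <- if (squared) r^2 else abs(r)
  list(kME = kME, relevant = kME > relevant_min)
}

#' Assign a gene to the coexpression module it is most correlated with
#'
#' Computes kME against each module eigengene and returns the module
#' maximizing it (ties broken lexicographically by module id, flagged).
#'
#' @param gene_expr per-sample expression of the gene.
#' @param eigengenes named list of module eigengene vectors.
#' @param squared passed to [module_membership()].
#' @return list: `module_id`, `kME` (per module, named), `ambiguous`.
#' @export
assign_to_module <- function(gene_expr, eigengenes, squared = FALSE) {
  stopifnot(length(eigengenes) >= 1L, !is.null(names(eigengenes)))
  ids <- sort(names(eigengenes))
  kme <- vapply(ids, function(m) {
    module_membership(gene_expr, eigengenes[[m]], squared = squared)$kME
  }, 0)
  best <- max(kme)
  cand <- which(kme == best)
  list(module_id = ids[cand[1L]], kME = kme, ambiguous = length(cand) > 1L)
}

#' Fisher exact marker enrichment of a module
#'
#' One-sided (upper tail) hypergeometric test of the overlap between a
#' module's genes and a cell-type marker set inside a gene universe.
#'
#' @param module_genes character vector, subset of `universe`.
#' @param markers character vector, subset of `universe`.
#' @param universe character vector of all genes considered.
#' @return list: `odds_ratio` (conditional MLE), `pvalue` (one-sided),
#'   `overlap`.
#' @export
fisher_marker_enrichment <- function(module_genes, markers, universe) {
  module_genes <- unique(module_genes); markers <- unique(markers)
  universe <- unique(universe)
  if (!all(module_genes %in% universe) || !all(markers %in% universe)) {
    stop("fisher_marker_enrichment: module and markers must lie in universe")
  }
  if (!length(module_genes) || !length(markers)) {
    warning("fisher_marker_enrichment: empty module or marker set")
    return(list(odds_ratio = NA_real_, pvalue = 1, overlap = 0L))
  }
  k <- length(intersect(module_genes, markers))
  tab <- matrix(c(k,
                  length(markers) - k,
                  length(module_genes) - k,
                  length(universe) - length(markers) - length(module_genes) + k),
                nrow = 2L)
  ft <- fisher.test(tab, alternative = "greater")
  list(odds_ratio = unname(ft$estimate), pvalue = ft$p.value, overlap = k)
}

#' Assign a module to the cell type whose markers it is most enriched in
#'
#' Runs [fisher_marker_enrichment()] against each marker set and returns
#' the minimum-p cell type.
#'
#' @param module_genes module gene set.
#' @param marker_sets named list of marker gene sets (one per cell type).
#' @param universe gene universe.
#' @return list: `cell_type`, `pvalues` (named), `odds_ratios` (named).
#' @export
assign_module_celltype <- function(module_genes, marker_sets, universe) {
  stopifnot(length(marker_sets) >= 1L, !is.null(names(marker_sets)))
  types <- sort(names(marker_sets))
  res <- lapply(types, function(t) {
    fisher_marker_enrichment(module_genes, marker_sets[[t]], universe)
  })
  p <- vapply(res, `[[`, 0, "pvalue")
  orr <- vapply(res, `[[`, 0, "odds_ratio")
  names(p) <- names(orr) <- types
  list(cell_type = types[which.min(p)], pvalues = p, odds_ratios = orr)
}
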