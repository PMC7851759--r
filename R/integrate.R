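# Evidence intersection across colocalization, TWAS/MWAS and
# methylation analyses, and the end-to-end pipeline driver.

#' Intersect expression colocalization with TWAS significance
#'
#' A gene becomes an expression candidate iff it shows strong
#' colocalization (PPH4 at or above `pph4_min`) in at least one tissue
#' of at least one dataset AND is TWAS-significant at FDR `fdr`.
#' Direction is the sign of the TWAS z-score.
#'
#' @param coloc_results data frame from [coloc_result_table()] over all
#'   datasets/tissues (gene-level rows, `feature_id` = gene).
#' @param twas_results data frame from [twas_scan()] keyed by gene.
#' @param pph4_min colocalization gate (inclusive), default 0.75.
#' @param fdr TWAS FDR gate (inclusive), default 0.05.
#' @return candidate-evidence data frame: gene_id, mechanism,
#'   direction, twas_z, twas_q, and list-columns `coloc_support`
#'   (dataset/tissue/pph4 rows) and `methylation_overlap` (empty).
#' @export
intersect_expression <- function(coloc_results, twas_results,
                                 pph4_min = 0.75, fdr = 0.05) {
  strong <- coloc_results[coloc_results$pph4 >= pph4_min, , drop = FALSE]
  sig <- twas_results[twas_results$qvalue <= fdr, , drop = FALSE]
  genes <- sort(intersect(unique(strong$feature_id), unique(sig$feature_id)))
  out <- lapply(genes, function(g) {
    tw <- sig[sig$feature_id == g, , drop = FALSE][1L, ]
    sup <- strong[strong$feature_id == g,
                  c("dataset", "tissue", "pph4", "top_snv"), drop = FALSE]
    data.frame(gene_id = g, mechanism = "expression",
               direction = if (tw$z_twas >= 0) "positive" else "negative",
               twas_z = tw$z_twas, twas_q = tw$qvalue,
               coloc_support = I(list(sup)),
               methylation_overlap = I(list(
                 data.frame(cpg_id = character(0), direction = character(0)))),
               stringsAsFactors = FALSE)
  })
  if (!length(out)) return(empty_candidates())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_candidates <- function() {
  data.frame(gene_id = character(0), mechanism = character(0),
             direction = character(0), twas_z = numeric(0),
             twas_q = numeric(0), coloc_support = I(list()),
             methylation_overlap = I(list()), stringsAsFactors = FALSE)
}

#' Intersect splicing colocalization with splicing TWAS significance
#'
#' Per dataset/tissue, a gene is splicing-classified when some exon
#' reaches PPH4 at or above `pph4_min` while the gene level shows
#' evidence against colocalization (gene PPH3 > gene PPH4); a gene that
#' is expression-classified in any tissue is never emitted as splicing.
#' The candidate additionally requires at least one significant isoform
#' in the splicing TWAS at FDR `fdr`.
#'
#' @param exon_coloc exon-level [coloc_result_table()] rows.
#' @param gene_coloc gene-level [coloc_result_table()] rows.
#' @param splicing_twas [twas_scan()] rows for isoforms, keyed to genes
#'   through `isoform_gene_map`.
#' @param exon_gene_map data frame: exon_id (= exon feature_id), gene_id.
#' @param isoform_gene_map data frame: isoform_id (= twas feature_id),
#'   gene_id; defaults to treating twas feature ids as gene ids.
#' @param pph4_min colocalization gate, default 0.75.
#' @param fdr splicing TWAS FDR gate, default 0.05.
#' @return candidate-evidence data frame (mechanism `"splicing"`), with
#'   the exon-level vs gene-level posterior contrast in `coloc_support`.
#' @export
intersect_splicing <- function(exon_coloc, gene_coloc, splicing_twas,
                               exon_gene_map, isoform_gene_map = NULL,
                               pph4_min = 0.75, fdr = 0.05) {
  exon_coloc$gene_id <- exon_gene_map$gene_id[
    match(exon_coloc$feature_id, exon_gene_map$exon_id)]
  if (is.null(isoform_gene_map)) {
    splicing_twas$gene_id <- splicing_twas$feature_id
  } else {
    splicing_twas$gene_id <- isoform_gene_map$gene_id[
      match(splicing_twas$feature_id, isoform_gene_map$isoform_id)]
  }
  sig <- splicing_twas[splicing_twas$qvalue <= fdr, , drop = FALSE]

  expression_anywhere <- unique(
    gene_coloc$feature_id[gene_coloc$pph4 >= pph4_min])

  genes <- sort(setdiff(unique(exon_coloc$gene_id), expression_anywhere))
  out <- lapply(genes, function(g) {
    fired <- FALSE
    support <- NULL
    gc_g <- gene_coloc[gene_coloc$feature_id == g, , drop = FALSE]
    ec_g <- exon_coloc[exon_coloc$gene_id == g, , drop = FALSE]
    for (i in seq_len(nrow(gc_g))) {
      exons <- ec_g[ec_g$dataset == gc_g$dataset[i] &
                    ec_g$tissue == gc_g$tissue[i], , drop = FALSE]
      if (!nrow(exons)) next
      best <- exons[which.max(exons$pph4), , drop = FALSE]
      if (best$pph4 >= pph4_min && gc_g$pph3[i] > gc_g$pph4[i]) {
        fired <- TRUE
        support <- rbind(support, data.frame(
          dataset = gc_g$dataset[i], tissue = gc_g$tissue[i],
          exon_id = best$feature_id, exon_pph4 = best$pph4,
          exon_pph3 = best$pph3, gene_pph3 = gc_g$pph3[i],
          gene_pph4 = gc_g$pph4[i], top_snv = best$top_snv,
          stringsAsFactors = FALSE))
      }
    }
    tw <- sig[sig$gene_id == g, , drop = FALSE]
    if (!fired || !nrow(tw)) return(NULL)
    tw <- tw[which.min(tw$qvalue), , drop = FALSE]
    data.frame(gene_id = g, mechanism = "splicing",
               direction = if (tw$z_twas >= 0) "positive" else "negative",
               twas_z = tw$z_twas, twas_q = tw$qvalue,
               coloc_support = I(list(support)),
               methylation_overlap = I(list(
                 data.frame(cpg_id = character(0), direction = character(0)))),
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(empty_candidates())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotate candidates with overlapping methylation findings
#'
#' Pure annotation: candidate membership is unchanged; a candidate gene
#' present in the methylation gene set gains its CpG(s) and direction(s)
#' in `methylation_overlap`.
#'
#' @param candidates candidate-evidence data frame.
#' @param mwas_genes data frame: gene_id, cpg_id, direction.
#' @return annotated `candidates`.
#' @export
overlay_methylation <- function(candidates, mwas_genes) {
  if (!nrow(candidates)) return(candidates)
  candidates$methylation_overlap <- I(lapply(candidates$gene_id, function(g) {
    hit <- mwas_genes[mwas_genes$gene_id == g,
                      c("cpg_id", "direction"), drop = FALSE]
    rownames(hit) <- NULL
    hit
  }))
  candidates
}

# ---- pipeline driver --------------------------------------------------

required_config_fields <- list(
  seed = NULL, out_dir = NULL,
  region = c("n_snps", "rho", "maf_range"),
  gwas = c("n_cases", "n_controls"),
  qtl = c("n"),
  genes = NULL
)

#' Validate a pipeline configuration
#'
#' Checks required sections and fields and threshold sanity before any
#' computation; a violation is fatal and names the offending field.
#'
#' @param config configuration list (parsed YAML).
#' @return the config with threshold defaults filled in, invisibly on
#'   error-free validation.
#' @export
validate_pipeline_config <- function(config) {
  for (sec in names(required_config_fields)) {
    if (is.null(config[[sec]])) {
      stop("pipeline config: missing required field '", sec, "'")
    }
    for (f in required_config_fields[[sec]]) {
      if (is.null(config[[sec]][[f]])) {
        stop("pipeline config: missing required field '", sec, ".", f, "'")
      }
    }
  }
  for (i in seq_along(config$genes)) {
    g <- config$genes[[i]]
    if (is.null(g$id)) stop("pipeline config: genes[", i, "].id missing")
    if (is.null(g$scenario) && is.null(g$mechanism)) {
      stop("pipeline config: genes[", i, "].scenario missing")
    }
  }
  th <- config$thresholds %||% list()
  defaults <- list(p_locus = 5e-8, locus_window_bp = 1e6, pph4_min = 0.75,
                   fdr = 0.05, mqtl_window_bp = 5e5, cpg_flank_bp = 1e4,
                   maf_min = 0.05, info_min = 0.5)
  for (nm in names(defaults)) th[[nm]] <- th[[nm]] %||% defaults[[nm]]
  config$thresholds <- th
  config$twas <- config$twas %||% list()
  config$twas$scheme <- config$twas$scheme %||% "top1"
  config$twas$ridge_lambda <- config$twas$ridge_lambda %||% 0.01
  config
}

# Simulate one gene's locus: GWAS + gene-level QTL (+ exon QTL for the
# splicing mechanism), harmonize, QC, colocalize, train weights.
run_gene_stage <- function(gene_cfg, idx, config) {
  th <- config$thresholds
  mech <- gene_cfg$mechanism %||% "expression"
  scenario <- gene_cfg$scenario %||%
    if (mech == "splicing") "distinct" else "shared"
  n_snps <- config$region$n_snps
  cfg <- sim_region_config(
    n_snps = n_snps, rho = config$region$rho,
    maf_range = unlist(config$region$maf_range),
    seed = derive_seed(config$seed, 10L * idx),
    chrom = as.character(idx),
    pos_start = 1000000L,
    pos_step = as.integer(config$region$pos_step %||% 5000L))
  ci_trait <- gene_cfg$causal_index %||% ceiling(n_snps / 2)
  ci_qtl <- switch(scenario,
                   shared = ci_trait,
                   distinct = if (ci_trait > n_snps / 2) 1L else n_snps,
                   ci_trait)
  causal <- causal_config(scenario, ci_trait, ci_qtl,
                          beta_trait = gene_cfg$beta_trait %||% 0.3,
                          beta_qtl = gene_cfg$beta_qtl %||% 1.0)
  sim <- simulate_trait_pair(cfg, causal,
                             n_cases = config$gwas$n_cases,
                             n_controls = config$gwas$n_controls,
                             n_qtl = config$qtl$n,
                             seed = derive_seed(config$seed, 10L * idx + 1L),
                             prevalence = config$gwas$prevalence %||% 0.5)
  h <- harmonize_pair(filter_qc(sim$gwas, th$maf_min, th$info_min),
                      filter_qc(sim$qtl, th$maf_min, th$info_min))
  keep <- match(h$gwas$variant_id, colnames(sim$ld_qtl))
  ld <- sim$ld_qtl[keep, keep, drop = FALSE]

  gene_coloc <- colocalize_feature(
    h$gwas, h$qtl, coloc_priors(), c("cc", "quant"),
    feature_id = gene_cfg$id, tissue = "region1", dataset = "synthetic",
    pph4_min = th$pph4_min)

  out <- list(gene_id = gene_cfg$id, mechanism = mech, sim = sim,
              harmonized = h, ld = ld, gene_coloc = gene_coloc,
              weights = train_weights(h$qtl, config$twas$scheme,
                                      feature_id = gene_cfg$id),
              chrom = cfg$chrom,
              lead_pos = h$gwas$pos[which.min(h$gwas$pvalue)],
              region_cfg = cfg)

  if (mech == "splicing") {
    exon_q <- simulate_qtl_cohort(
      cfg, causal_index = ci_trait,
      beta_qtl = gene_cfg$beta_qtl %||% 1.0, n_qtl = config$qtl$n,
      seed = derive_seed(config$seed, 10L * idx + 2L))
    he <- harmonize_pair(filter_qc(sim$gwas, th$maf_min, th$info_min),
                         filter_qc(exon_q$qtl, th$maf_min, th$info_min))
    exon_id <- paste0(gene_cfg$id, "_exon1")
    out$exon_coloc <- colocalize_feature(
      he$gwas, he$qtl, coloc_priors(), c("cc", "quant"),
      feature_id = exon_id, tissue = "region1", dataset = "synthetic",
      pph4_min = th$pph4_min)
    out$exon_gene_map <- data.frame(exon_id = exon_id,
                                    gene_id = gene_cfg$id,
                                    stringsAsFactors = FALSE)
    out$isoform_weights <- train_weights(he$qtl, config$twas$scheme,
                                         feature_id = exon_id)
    out$isoform_gwas <- he$gwas
    keep_e <- match(he$gwas$variant_id, colnames(exon_q$ld))
    out$isoform_ld <- exon_q$ld[keep_e, keep_e, drop = FALSE]
  }
  out
}

#' Run the synthetic end-to-end prioritization pipeline
#'
#' Executes summary-statistics simulation, harmonization and QC,
#' colocalization, (splicing) TWAS with genome-wide BH-FDR,
#' methylation-QTL scanning, and evidence intersection, with fixed
#' seeds derived from `config$seed`. All stage tables, the candidate
#' summary table and a run-manifest JSON are written under
#' `config$out_dir`.
#'
#' @param config a configuration list, or the path to a YAML file.
#' @return list with `candidates`, `coloc`, `twas`, `splicing_twas`,
#'   `mqtl`, `loci` and the output directory, invisibly writable.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_pipeline_config(config)
  th <- config$thresholds
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  stages <- lapply(seq_along(config$genes), function(i) {
    run_gene_stage(config$genes[[i]], i, config)
  })

  gene_coloc_tab <- coloc_result_table(lapply(stages, `[[`, "gene_coloc"))
  exon_stages <- stages[vapply(stages, function(s)
    !is.null(s$exon_coloc), TRUE)]
  exon_coloc_tab <- if (length(exon_stages)) {
    coloc_result_table(lapply(exon_stages, `[[`, "exon_coloc"))
  } else NULL

  # expression TWAS: FDR across all genes
  twas_tab <- do.call(rbind, lapply(stages, function(s) {
    zg <- setNames(s$harmonized$gwas$beta / s$harmonized$gwas$se,
                   s$harmonized$gwas$variant_id)
    z <- twas_zscore(s$weights, zg[s$weights$snv_ids],
                     s$ld[s$weights$snv_ids, s$weights$snv_ids, drop = FALSE],
                     ridge_lambda = config$twas$ridge_lambda)
    data.frame(feature_id = s$gene_id, scheme = s$weights$training_scheme,
               z_twas = z, pvalue = 2 * pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  }))
  fdr_t <- bh_fdr(twas_tab$pvalue, th$fdr)
  twas_tab$qvalue <- fdr_t$qvalue
  twas_tab$significant <- fdr_t$significant

  # splicing TWAS: FDR across isoforms, separately
  splicing_twas_tab <- NULL
  exon_gene_map <- NULL
  if (length(exon_stages)) {
    splicing_twas_tab <- do.call(rbind, lapply(exon_stages, function(s) {
      zg <- setNames(s$isoform_gwas$beta / s$isoform_gwas$se,
                     s$isoform_gwas$variant_id)
      w <- s$isoform_weights
      z <- twas_zscore(w, zg[w$snv_ids],
                       s$isoform_ld[w$snv_ids, w$snv_ids, drop = FALSE],
                       ridge_lambda = config$twas$ridge_lambda)
      data.frame(feature_id = w$feature_id, scheme = w$training_scheme,
                 z_twas = z, pvalue = 2 * pnorm(-abs(z)),
                 stringsAsFactors = FALSE)
    }))
    fdr_s <- bh_fdr(splicing_twas_tab$pvalue, th$fdr)
    splicing_twas_tab$qvalue <- fdr_s$qvalue
    splicing_twas_tab$significant <- fdr_s$significant
    exon_gene_map <- do.call(rbind, lapply(exon_stages, `[[`,
                                           "exon_gene_map"))
  }

  candidates <- intersect_expression(gene_coloc_tab, twas_tab,
                                     th$pph4_min, th$fdr)
  if (!is.null(exon_coloc_tab)) {
    iso_map <- data.frame(isoform_id = exon_gene_map$exon_id,
                          gene_id = exon_gene_map$gene_id,
                          stringsAsFactors = FALSE)
    sp <- intersect_splicing(exon_coloc_tab, gene_coloc_tab,
                             splicing_twas_tab, exon_gene_map, iso_map,
                             th$pph4_min, th$fdr)
    sp <- sp[!sp$gene_id %in% candidates$gene_id, , drop = FALSE]
    candidates <- rbind(candidates, sp)
  }

  # methylation overlay on candidate loci
  mqtl_tab <- NULL
  if (isTRUE(config$methylation$enabled %||% FALSE)) {
    mwas_genes <- NULL
    mq_all <- list()
    for (s in stages) {
      planted <- s$mechanism != "none" && s$gene_id %in% candidates$gene_id
      meth_seed <- derive_seed(config$seed,
                               1000L + match(s$gene_id,
                                             vapply(stages, `[[`, "",
                                                    "gene_id")))
      gmeth <- simulate_ld_genotypes(
        s$region_cfg, config$methylation$n_samples %||% 140L,
        draw_seed = meth_seed)
      lead_i <- which(gmeth$snp_id ==
                        s$harmonized$gwas$variant_id[
                          which.min(s$harmonized$gwas$pvalue)])
      meth <- simulate_methylation(
        gmeth,
        planted = list(snv_index = lead_i, cpg_index = 1L,
                       pos = s$lead_pos + 2000L,
                       effect = if (planted)
                         config$methylation$effect %||% 0.8 else 0),
        n_cpgs = config$methylation$n_cpgs %||% 15L,
        seed = derive_seed(meth_seed, 1L))
      scan <- scan_windows(
        snvs = list(info = data.frame(snv_id = gmeth$snp_id[lead_i],
                                      chrom = gmeth$chrom,
                                      pos = gmeth$pos[lead_i],
                                      stringsAsFactors = FALSE),
                    dosage = gmeth$genotypes[, lead_i, drop = FALSE]),
        cpgs = list(info = meth$cpgs, beta = meth$beta),
        covariates = meth$covariates,
        window_bp = th$mqtl_window_bp, fdr = th$fdr)
      if (nrow(scan$retained)) {
        genes_ann <- data.frame(
          gene_id = s$gene_id, chrom = s$chrom,
          start = s$lead_pos - 5000L, end = s$lead_pos + 5000L,
          stringsAsFactors = FALSE)
        for (r in seq_len(nrow(scan$retained))) {
          cp <- meth$cpgs[meth$cpgs$cpg_id == scan$retained$cpg_id[r], ]
          mapped <- map_cpg_to_gene(cp, genes_ann, th$cpg_flank_bp)
          if (length(mapped)) {
            mwas_genes <- rbind(mwas_genes, data.frame(
              gene_id = mapped, cpg_id = cp$cpg_id,
              direction = scan$retained$direction[r],
              stringsAsFactors = FALSE))
          }
        }
      }
      scan$pairs$gene_id <- s$gene_id
      mq_all[[s$gene_id]] <- scan$pairs
    }
    mqtl_tab <- do.call(rbind, mq_all)
    rownames(mqtl_tab) <- NULL
    if (!is.null(mwas_genes)) {
      candidates <- overlay_methylation(candidates, mwas_genes)
    }
  }

  # locus table from the simulated GWAS
  loci <- do.call(rbind, lapply(stages, function(s) {
    data.frame(gene_id = s$gene_id, chrom = s$chrom, lead_pos = s$lead_pos,
               lead_p = min(s$harmonized$gwas$pvalue),
               genome_wide = min(s$harmonized$gwas$pvalue) <= th$p_locus,
               stringsAsFactors = FALSE)
  }))

  summary_tab <- candidates[, c("gene_id", "mechanism", "direction",
                                "twas_z", "twas_q")]
  summary_tab$best_pph4 <- vapply(candidates$coloc_support, function(d) {
    if ("pph4" %in% names(d)) max(d$pph4) else max(d$exon_pph4)
  }, 0)
  summary_tab$top_snv <- vapply(candidates$coloc_support,
                                function(d) d$top_snv[1L], "")
  summary_tab$methylation_cpgs <- vapply(
    candidates$methylation_overlap,
    function(d) paste(d$cpg_id, collapse = ","), "")

  pp <- list(seed = config$seed)
  write_tsv_prov(gene_coloc_tab, file.path(config$out_dir, "coloc_gene.tsv"), pp)
  if (!is.null(exon_coloc_tab)) {
    write_tsv_prov(exon_coloc_tab, file.path(config$out_dir, "coloc_exon.tsv"), pp)
  }
  write_tsv_prov(twas_tab, file.path(config$out_dir, "twas.tsv"), pp)
  if (!is.null(splicing_twas_tab)) {
    write_tsv_prov(splicing_twas_tab,
                   file.path(config$out_dir, "twas_splicing.tsv"), pp)
  }
  if (!is.null(mqtl_tab)) {
    write_tsv_prov(mqtl_tab, file.path(config$out_dir, "mqtl.tsv"), pp)
  }
  write_tsv_prov(loci, file.path(config$out_dir, "loci.tsv"), pp)
  write_tsv_prov(summary_tab, file.path(config$out_dir, "candidates.tsv"), pp)
  jsonlite::write_json(
    list(package_version = as.character(packageVersion("locusweave")),
         seed = config$seed, thresholds = th,
         n_genes_configured = length(config$genes),
         n_candidates = nrow(candidates)),
    file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  list(candidates = candidates, summary = summary_tab,
       coloc = gene_coloc_tab, exon_coloc = exon_coloc_tab,
       twas = twas_tab, splicing_twas = splicing_twas_tab,
       mqtl = mqtl_tab, loci = loci, out_dir = config$out_dir)
}
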