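coloc_row <- function(gene, pph3, pph4, dataset = "ds1", tissue = "t1",
                      top = "rs1") {
  data.frame(feature_id = gene, dataset = dataset, tissue = tissue,
             n_snps = 10L, pph0 = 0, pph1 = 0, pph2 = 0,
             pph3 = pph3, pph4 = pph4, top_snv = top,
             strong_coloc = pph4 >= 0.75, stringsAsFactors = FALSE)
}

twas_row <- function(gene, z, q) {
  data.frame(feature_id = gene, scheme = "top1", z_twas = z,
             pvalue = 2 * pnorm(-abs(z)), qvalue = q,
             significant = q <= 0.05, stringsAsFactors = FALSE)
}

test_that("expression candidates require both the coloc and TWAS gates", {
  coloc <- rbind(coloc_row("A", 0.1, 0.90),   # strong coloc
                 coloc_row("B", 0.2, 0.60),   # weak coloc
                 coloc_row("C", 0.1, 0.80))   # strong coloc
  twas <- rbind(twas_row("A", -4, 0.001),     # significant
                twas_row("B", 5, 0.001),      # significant
                twas_row("C", 3, 0.20))       # not significant
  out <- intersect_expression(coloc, twas)
  expect_equal(out$gene_id, "A")              # only A passes both gates
  expect_equal(out$direction, "negative")
  expect_equal(out$mechanism, "expression")
  expect_equal(out$coloc_support[[1]]$pph4, 0.90)

  # union over tissues/datasets: one strong tissue suffices
  coloc2 <- rbind(coloc_row("D", 0.2, 0.40, tissue = "t1"),
                  coloc_row("D", 0.1, 0.76, tissue = "t2"))
  out2 <- intersect_expression(coloc2, twas_row("D", 2.5, 0.01))
  expect_equal(out2$gene_id, "D")

  expect_equal(nrow(intersect_expression(coloc_row("E", 0.1, 0.9),
                                         twas_row("F", 3, 0.01))), 0L)
})

test_that("splicing candidates follow the exon/gene contrast plus isoform FDR", {
  gene_coloc <- coloc_row("Z", 0.20, 0.07)
  exon_coloc <- coloc_row("Z_e1", 0.06, 0.93)
  emap <- data.frame(exon_id = "Z_e1", gene_id = "Z", stringsAsFactors = FALSE)
  imap <- data.frame(isoform_id = "Z_iso1", gene_id = "Z",
                     stringsAsFactors = FALSE)

  out <- intersect_splicing(exon_coloc, gene_coloc,
                            twas_row("Z_iso1", 3.5, 0.01), emap, imap)
  expect_equal(out$gene_id, "Z")
  expect_equal(out$mechanism, "splicing")
  expect_equal(out$coloc_support[[1]]$exon_pph4, 0.93)
  expect_equal(out$coloc_support[[1]]$gene_pph3, 0.20)

  # same coloc pattern but non-significant isoform: excluded
  out2 <- intersect_splicing(exon_coloc, gene_coloc,
                             twas_row("Z_iso1", 1.0, 0.2), emap, imap)
  expect_equal(nrow(out2), 0L)

  # an expression-classified gene is never emitted as splicing
  gene_expr <- coloc_row("Z", 0.05, 0.80)
  out3 <- intersect_splicing(exon_coloc, gene_expr,
                             twas_row("Z_iso1", 3.5, 0.01), emap, imap)
  expect_equal(nrow(out3), 0L)
})

test_that("methylation overlay annotates without changing membership", {
  coloc <- coloc_row("A", 0.1, 0.9)
  cands <- intersect_expression(coloc, twas_row("A", 4, 0.001))
  mwas <- data.frame(gene_id = c("A", "ZZZ"), cpg_id = c("cg1", "cg9"),
                     direction = c("negative", "positive"),
                     stringsAsFactors = FALSE)
  out <- overlay_methylation(cands, mwas)
  expect_equal(out$gene_id, "A")                       # no new candidates
  expect_equal(out$methylation_overlap[[1]]$cpg_id, "cg1")
  expect_equal(out$methylation_overlap[[1]]$direction, "negative")

  # empty MWAS set leaves all overlap fields empty
  out0 <- overlay_methylation(cands, mwas[0, ])
  expect_equal(nrow(out0$methylation_overlap[[1]]), 0L)
})

test_that("candidate set grows monotonically with looser thresholds", {
  set.seed(101)
  coloc <- do.call(rbind, lapply(1:20, function(i) {
    coloc_row(paste0("G", i), runif(1, 0, 0.5), runif(1))
  }))
  twas <- do.call(rbind, lapply(1:20, function(i) {
    twas_row(paste0("G", i), rnorm(1, 0, 3), runif(1, 0, 0.2))
  }))
  strict <- intersect_expression(coloc, twas, pph4_min = 0.9, fdr = 0.01)
  loose <- intersect_expression(coloc, twas, pph4_min = 0.6, fdr = 0.10)
  expect_true(all(strict$gene_id %in% loose$gene_id))
})

test_that("config validation is fatal before computation and names the field", {
  cfg <- list(seed = 1, out_dir = tempfile(),
              region = list(n_snps = 10, rho = 0.5, maf_range = c(0.1, 0.5)),
              gwas = list(n_cases = 100, n_controls = 100),
              qtl = list(n = 100),
              genes = list(list(id = "A", scenario = "shared")))
  expect_silent(validate_pipeline_config(cfg))

  bad <- cfg; bad$gwas$n_cases <- NULL
  expect_error(validate_pipeline_config(bad), "gwas.n_cases")
  bad2 <- cfg; bad2$genes[[1]]$id <- NULL
  expect_error(validate_pipeline_config(bad2), "genes\\[1\\].id")
  bad3 <- cfg; bad3$region <- NULL
  expect_error(validate_pipeline_config(bad3), "'region'")

  filled <- validate_pipeline_config(cfg)
  expect_equal(filled$thresholds$pph4_min, 0.75)
  expect_equal(filled$thresholds$p_locus, 5e-8)
})

test_that("the end-to-end pipeline recovers exactly the planted candidates", {
  make_cfg <- function(out_dir) list(
    seed = 2024, out_dir = out_dir,
    region = list(n_snps = 25, rho = 0.9, maf_range = c(0.1, 0.5)),
    gwas = list(n_cases = 1200, n_controls = 1200),
    qtl = list(n = 300),
    genes = list(
      list(id = "PLANTED_EXPR", scenario = "shared",
           beta_trait = 0.35, beta_qtl = 1.2),
      list(id = "QTL_ONLY", scenario = "qtl_only", beta_qtl = 1.0),
      list(id = "NULL_GENE", scenario = "null"),
      list(id = "PLANTED_SPLICE", mechanism = "splicing",
           beta_trait = 0.35, beta_qtl = 1.2)
    ),
    methylation = list(enabled = TRUE, n_cpgs = 8, effect = 0.8,
                       n_samples = 140)
  )
  out1 <- tempfile("pipe1")
  res <- run_pipeline(make_cfg(out1))

  expect_setequal(res$candidates$gene_id, c("PLANTED_EXPR", "PLANTED_SPLICE"))
  expect_equal(
    res$candidates$mechanism[res$candidates$gene_id == "PLANTED_EXPR"],
    "expression")
  expect_equal(
    res$candidates$mechanism[res$candidates$gene_id == "PLANTED_SPLICE"],
    "splicing")
  expect_true(all(file.exists(file.path(
    out1, c("coloc_gene.tsv", "twas.tsv", "candidates.tsv",
            "mqtl.tsv", "loci.tsv", "manifest.json")))))

  # candidates carry their planted methylation overlap
  ov <- res$candidates$methylation_overlap[[1]]
  expect_gt(nrow(ov), 0L)

  # rerun with the same config and seed: byte-identical outputs
  out2 <- tempfile("pipe2")
  run_pipeline(make_cfg(out2))
  for (f in c("coloc_gene.tsv", "twas.tsv", "candidates.tsv", "loci.tsv")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
})
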