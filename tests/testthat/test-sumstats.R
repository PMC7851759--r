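test_that("valid rows parse and invariant violations are rejected with reasons", {
  path <- write_sumstats_fixture(c(
    sumstats_header,
    sumstats_row("rs1", "1", 100, "A", "G", 0.1, 0.05, 0.01, 0.3),
    sumstats_row("rs2", "1", 200, "C", "T", -0.2, 0.08, 0.5, 0.6),
    sumstats_row("rs3", "2", 300, "G", "A", 0.05, 0.04, 0.9, 0.45)
  ))
  x <- read_sumstats(path)
  expect_equal(nrow(x), 3L)
  expect_equal(x$variant_id, c("rs1", "rs2", "rs3"))
  expect_equal(nrow(attr(x, "rejected")), 0L)

  path2 <- write_sumstats_fixture(c(
    sumstats_header,
    sumstats_row("rs1", "1", 100, "A", "G", 0.1, 0, 0.01, 0.3),      # se = 0
    sumstats_row("rs2", "1", 200, "I", "D", 0.1, 0.05, 0.01, 0.3),   # indel
    sumstats_row("rs3", "1", 300, "A", "A", 0.1, 0.05, 0.01, 0.3),   # same alleles
    sumstats_row("rs4", "1", 400, "A", "G", 0.1, 0.05, 1.5, 0.3),    # p > 1
    sumstats_row("rs5", "1", 500, "A", "G", 0.1, 0.05, 0.01, 0.3)    # fine
  ))
  x2 <- suppressMessages(read_sumstats(path2))
  expect_equal(x2$variant_id, "rs5")
  rej <- attr(x2, "rejected")
  expect_equal(nrow(rej), 4L)
  expect_setequal(rej$reason, c("nonpositive_se", "non_snv_allele",
                                "identical_alleles", "pvalue_out_of_range"))
})

test_that("a missing required column is fatal; dialect synonyms are accepted", {
  path <- write_sumstats_fixture(c(
    paste("snp", "chr", "bp", "a1", "a2", "b", "standard_error", "pval",
          "freq", sep = "\t"),
    paste("rs1", "1", 100, "A", "G", 0.1, 0.05, 0.01, 0.3, sep = "\t")
  ))
  x <- read_sumstats(path)
  expect_equal(x$beta, 0.1)
  expect_true(is.na(x$info))

  path2 <- write_sumstats_fixture(c(
    paste("snp", "chr", "bp", "a1", "a2", "b", "pval", "freq", sep = "\t"),
    paste("rs1", "1", 100, "A", "G", 0.1, 0.01, 0.3, sep = "\t")
  ))
  expect_error(read_sumstats(path2), "missing required column")
})

test_that("harmonization flips swapped alleles, drops ambiguous pairs, is idempotent", {
  gwas <- data.frame(
    variant_id = c("rs1", "rs2", "rs3", "rs4"), chrom = "1",
    pos = c(100L, 200L, 300L, 400L),
    effect_allele = c("A", "A", "C", "A"), other_allele = c("G", "T", "A", "G"),
    beta = c(0.1, 0.1, 0.1, 0.1), se = 0.05, pvalue = 0.01,
    eaf = c(0.3, 0.3, 0.3, 0.3), n = 1000L, info = NA_real_,
    stringsAsFactors = FALSE)
  qtl <- gwas
  # rs1: swapped alleles -> flip beta and eaf
  qtl$effect_allele[1] <- "G"; qtl$other_allele[1] <- "A"
  qtl$beta[1] <- -0.05; qtl$eaf[1] <- 0.3
  # rs2 is A/T ambiguous in both; rs3 unchanged; rs4 mismatching alleles
  # (A/C matches A/G in no orientation, flipped or not)
  qtl$effect_allele[4] <- "A"; qtl$other_allele[4] <- "C"

  h <- harmonize_pair(gwas, qtl)
  expect_equal(h$gwas$variant_id, c("rs1", "rs3"))
  expect_equal(h$qtl$beta[1], 0.05)
  expect_equal(h$qtl$eaf[1], 0.7)
  expect_equal(h$qtl$effect_allele, h$gwas$effect_allele)
  expect_equal(h$report$n_ambiguous_dropped, 1L)
  expect_equal(h$report$n_allele_mismatch_dropped, 1L)
  # identity row untouched
  expect_equal(h$qtl$beta[2], 0.1)

  # involution: harmonizing the harmonized pair changes nothing
  h2 <- harmonize_pair(h$gwas, h$qtl)
  expect_identical(h2$gwas, h$gwas)
  expect_identical(h2$qtl, h$qtl)
})

test_that("strand-flipped orientations align and multi-allelic duplicates resolve", {
  gwas <- data.frame(
    variant_id = "rs1", chrom = "1", pos = 100L,
    effect_allele = "A", other_allele = "G", beta = 0.1, se = 0.05,
    pvalue = 0.01, eaf = 0.3, n = 1000L, info = NA_real_,
    stringsAsFactors = FALSE)
  # same variant reported on the opposite strand (T/C == A/G flipped)
  qtl <- gwas
  qtl$effect_allele <- "T"; qtl$other_allele <- "C"
  h <- harmonize_pair(gwas, qtl)
  expect_equal(nrow(h$gwas), 1L)
  expect_equal(h$qtl$beta, 0.1)

  # duplicate position: the row whose alleles match the partner wins
  qtl2 <- rbind(qtl, qtl)
  qtl2$effect_allele <- c("T", "A"); qtl2$other_allele <- c("G", "G")
  qtl2$variant_id <- c("rs1_alt", "rs1")
  qtl2$pvalue <- c(1e-8, 0.5)
  h2 <- harmonize_pair(gwas, qtl2)
  expect_equal(h2$qtl$variant_id, "rs1")

  expect_error(harmonize_pair(gwas, transform(gwas, pos = 999L)),
               "no overlapping variants")
})

test_that("QC filter boundaries follow the MAF >= 0.05 and info > 0.5 rules", {
  rec <- data.frame(eaf = c(0.05, 0.951, 0.3, 0.3, 0.3),
                    info = c(0.9, 0.9, 0.5, NA, 0.51))
  out <- filter_qc(rec)
  # eaf 0.05 kept (inclusive), MAF 0.049 dropped, info 0.5 dropped
  # (strict), missing info passes, info 0.51 kept
  expect_equal(nrow(out), 3L)
  expect_equal(out$eaf, c(0.05, 0.3, 0.3))

  # monotone in both thresholds
  set.seed(42)
  rec2 <- data.frame(eaf = runif(200), info = runif(200))
  sizes <- sapply(c(0, 0.02, 0.05, 0.1, 0.3),
                  function(m) nrow(filter_qc(rec2, maf_min = m)))
  expect_true(all(diff(sizes) <= 0))
  sizes_i <- sapply(c(0, 0.3, 0.5, 0.8),
                    function(i) nrow(filter_qc(rec2, info_min = i)))
  expect_true(all(diff(sizes_i) <= 0))
})

test_that("risk locus selection uses inclusive p and closed window ends", {
  gwas <- data.frame(
    variant_id = c("lead", "nothit"), chrom = "1",
    pos = c(5000000L, 6000000L),
    effect_allele = "A", other_allele = "G", beta = 0.1, se = 0.05,
    pvalue = c(5e-8, 5.1e-8), eaf = 0.3, n = 1000L, info = NA_real_,
    stringsAsFactors = FALSE)
  genes <- data.frame(
    gene_id = c("at_edge", "outside", "inside"), chrom = "1",
    start = c(3500000L, 3000000L, 5500000L),
    end = c(4000000L, 3999999L, 5600000L),  # 4000000 = lead - 1 Mb exactly
    strand = "+", stringsAsFactors = FALSE)
  loci <- select_risk_loci(gwas, genes)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$lead_snv, "lead")
  expect_setequal(loci$genes[[1]], c("at_edge", "inside"))

  none <- select_risk_loci(transform(gwas, pvalue = 0.5), genes)
  expect_equal(nrow(none), 0L)
})

test_that("cis windows are closed intervals around genes and points", {
  rec <- data.frame(chrom = "1",
                    pos = c(4000000L, 3999999L, 5500000L, 5500001L),
                    variant_id = paste0("rs", 1:4), stringsAsFactors = FALSE)
  gene <- list(chrom = "1", start = 5000000L, end = 5000000L)
  w <- extract_cis_window(rec, gene, 1000000L)
  expect_setequal(w$variant_id, c("rs1", "rs3", "rs4"))

  point <- list(chrom = "1", pos = 5000000L)
  w2 <- extract_cis_window(rec, point, 500000L)
  expect_equal(w2$variant_id, "rs3")   # rs4 is 500,001 bp away
})

test_that("BED gene annotation converts to 1-based inclusive coordinates", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t999\t2000\tGENE1\t0\t+", bed)
  g <- read_gene_annotation(bed, format = "bed")
  expect_equal(g$start, 1000L)
  expect_equal(g$end, 2000L)

  out <- tempfile(fileext = ".bed")
  write_gene_bed(g, out)
  rt <- read_gene_annotation(out, format = "bed")
  expect_equal(rt$start, g$start)
  expect_equal(rt$end, g$end)
})
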