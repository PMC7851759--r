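# Reading, validation, harmonization and windowing of GWAS / QTL
# summary statistics, plus risk-locus selection.
#
# A summary-statistics table is a plain data.frame with one row per
# variant and the standard columns
#   variant_id, chrom, pos, effect_allele, other_allele,
#   beta, se, pvalue, eaf, n, info
# where `info` (imputation quality) may be NA. Coordinates are 1-based
# GRCh37 throughout; beta is the per-allele effect of the effect allele
# (log-odds for case-control traits).

VALID_ALLELES <- c("A", "C", "G", "T")

SUMSTATS_COLS <- c("variant_id", "chrom", "pos", "effect_allele",
                   "other_allele", "beta", "se", "pvalue", "eaf", "n", "info")

#' Column-name dialect for summary-statistics files
#'
#' Maps each standard column to the header names accepted for it. Supply
#' entries to override or extend the defaults, e.g.
#' `sumstats_dialect(beta = "log_or")`.
#'
#' @param ... named character vectors of accepted header names, one per
#'   standard column.
#' @return named list of accepted-name vectors.
#' @export
sumstats_dialect <- function(...) {
  dialect <- list(
    variant_id    = c("variant_id", "snp", "rsid", "markername", "id"),
    chrom         = c("chrom", "chr", "chromosome"),
    pos           = c("pos", "bp", "position", "base_pair_location"),
    effect_allele = c("effect_allele", "a1", "allele1", "ea"),
    other_allele  = c("other_allele", "a2", "allele2", "oa", "nea"),
    beta          = c("beta", "b", "effect", "log_odds"),
    se            = c("se", "standard_error", "stderr"),
    pvalue        = c("pvalue", "p", "pval", "p_value"),
    eaf           = c("eaf", "freq", "af", "effect_allele_frequency", "maf"),
    n             = c("n", "n_total", "samplesize"),
    info          = c("info", "imputation_r2", "rsq")
  )
  override <- list(...)
  for (nm in names(override)) dialect[[nm]] <- as.character(override[[nm]])
  dialect
}

# Map raw header names onto standard names; error on a missing required
# column. `info` and `n` are optional.
match_dialect <- function(header, dialect) {
  out <- character(0)
  lower <- tolower(header)
  for (std in names(dialect)) {
    hit <- which(lower %in% tolower(dialect[[std]]))
    if (length(hit)) out[std] <- header[hit[1L]]
  }
  required <- setdiff(SUMSTATS_COLS, c("info", "n"))
  missing <- setdiff(required, names(out))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  out
}

# Row-level invariant checks; returns a character reason or NA if valid.
row_reason <- function(df) {
  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) ifelse(is.na(reason) & bad, why, reason)
  reason <- flag(!df$effect_allele %in% VALID_ALLELES |
                 !df$other_allele %in% VALID_ALLELES, "non_snv_allele")
  reason <- flag(df$effect_allele == df$other_allele, "identical_alleles")
  reason <- flag(!is.finite(df$beta), "unparsable_beta")
  reason <- flag(!is.finite(df$se) | df$se <= 0, "nonpositive_se")
  reason <- flag(!is.finite(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1,
                 "pvalue_out_of_range")
  reason <- flag(!is.finite(df$eaf) | df$eaf < 0 | df$eaf > 1,
                 "eaf_out_of_range")
  reason <- flag(!is.finite(df$pos) | df$pos < 1 | df$pos != round(df$pos),
                 "bad_position")
  reason
}

#' Read and validate a summary-statistics file
#'
#' Reads a tab-delimited file with a header line, maps its columns through
#' a naming dialect, and applies the record invariants (positive SE,
#' frequency and p-value in range, single-nucleotide A/C/G/T alleles,
#' distinct alleles, integral 1-based position). Rows violating an
#' invariant are dropped and logged with a per-row reason, available as
#' `attr(x, "rejected")`.
#'
#' @param path path to a tab-delimited file with header.
#' @param dialect column-name map from [sumstats_dialect()].
#' @return validated summary-statistics data frame; rejected rows (with a
#'   `reason` column) in the `rejected` attribute.
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect()) {
  raw <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                    check.names = FALSE)
  cols <- match_dialect(names(raw), dialect)
  df <- data.frame(
    variant_id    = as.character(raw[[cols["variant_id"]]]),
    chrom         = as.character(raw[[cols["chrom"]]]),
    pos           = suppressWarnings(as.numeric(raw[[cols["pos"]]])),
    effect_allele = toupper(as.character(raw[[cols["effect_allele"]]])),
    other_allele  = toupper(as.character(raw[[cols["other_allele"]]])),
    beta          = suppressWarnings(as.numeric(raw[[cols["beta"]]])),
    se            = suppressWarnings(as.numeric(raw[[cols["se"]]])),
    pvalue        = suppressWarnings(as.numeric(raw[[cols["pvalue"]]])),
    eaf           = suppressWarnings(as.numeric(raw[[cols["eaf"]]])),
    stringsAsFactors = FALSE
  )
  df$n <- if ("n" %in% names(cols)) {
    suppressWarnings(as.integer(raw[[cols["n"]]]))
  } else NA_integer_
  df$info <- if ("info" %in% names(cols)) {
    suppressWarnings(as.numeric(raw[[cols["info"]]]))
  } else NA_real_

  reason <- row_reason(df)
  bad <- !is.na(reason)
  rejected <- df[bad, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[bad]
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  if (any(bad)) {
    message(sum(bad), " row(s) rejected while reading ", basename(path), ": ",
            paste(sprintf("%s (n=%d)", names(table(reason[bad])),
                          as.integer(table(reason[bad]))), collapse = ", "))
  }
  out$pos <- as.integer(out$pos)
  attr(out, "rejected") <- rejected
  out
}

#' Write a summary-statistics table
#'
#' Emits the standard tab-delimited dialect with a provenance header line.
#'
#' @param x summary-statistics data frame.
#' @param path output path.
#' @param params optional named list recorded in the provenance line.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path, params = NULL) {
  write_tsv_prov(x[, intersect(SUMSTATS_COLS, names(x)), drop = FALSE],
                 path, params)
}

# Strand-ambiguous (palindromic) allele pairs cannot be oriented from
# alleles alone and are dropped during harmonization.
is_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

flip_allele <- function(a) c(A = "T", T = "A", C = "G", G = "C")[a]

#' Harmonize a GWAS / QTL summary-statistics pair
#'
#' Restricts both tables to variants present in both (keyed by chromosome
#' and position), aligns the QTL effect allele to the GWAS effect allele —
#' negating the QTL beta and reflecting its allele frequency when the
#' alleles are swapped, also accepting the strand-flipped orientations —
#' and drops strand-ambiguous (A/T, C/G) variants and allele pairs that
#' match neither orientation. At duplicated positions (multi-allelics
#' split across rows) the row whose alleles match the partner file is
#' kept; if several match, the lowest p-value wins.
#'
#' Applying the function to its own output returns it unchanged.
#'
#' @param gwas,qtl summary-statistics data frames.
#' @return list with aligned `gwas` and `qtl` data frames (equal row
#'   count, identical variant order, string-equal alleles) and a `report`
#'   list of per-category drop counts.
#' @export
harmonize_pair <- function(gwas, qtl) {
  key <- function(x) paste(x$chrom, x$pos, sep = ":")
  dedup <- function(x, partner) {
    kx <- key(x); kp <- key(partner)
    dup_keys <- unique(kx[duplicated(kx)])
    if (!length(dup_keys)) return(x)
    keep <- rep(TRUE, nrow(x))
    for (k in dup_keys) {
      idx <- which(kx == k)
      pidx <- which(kp == k)
      palleles <- unlist(lapply(pidx, function(i)
        list(sort(c(partner$effect_allele[i], partner$other_allele[i])))),
        recursive = FALSE)
      matches <- vapply(idx, function(i) {
        any(vapply(palleles, function(al)
          identical(al, sort(c(x$effect_allele[i], x$other_allele[i]))),
          logical(1)))
      }, logical(1))
      cand <- if (any(matches)) idx[matches] else idx
      win <- cand[which.min(x$pvalue[cand])]
      keep[setdiff(idx, win)] <- FALSE
    }
    x[keep, , drop = FALSE]
  }
  gwas <- dedup(gwas, qtl)
  qtl <- dedup(qtl, gwas)

  kg <- key(gwas); kq <- key(qtl)
  shared <- intersect(kg, kq)
  if (!length(shared)) {
    stop("harmonize_pair: no overlapping variants between the two inputs ",
         "(gwas n=", nrow(gwas), ", qtl n=", nrow(qtl), ")")
  }
  g <- gwas[match(shared, kg), , drop = FALSE]
  q <- qtl[match(shared, kq), , drop = FALSE]

  amb <- is_ambiguous(g$effect_allele, g$other_allele) |
         is_ambiguous(q$effect_allele, q$other_allele)

  same  <- q$effect_allele == g$effect_allele & q$other_allele == g$other_allele
  swap  <- q$effect_allele == g$other_allele  & q$other_allele == g$effect_allele
  fsame <- flip_allele(q$effect_allele) == g$effect_allele &
           flip_allele(q$other_allele)  == g$other_allele
  fswap <- flip_allele(q$effect_allele) == g$other_allele &
           flip_allele(q$other_allele)  == g$effect_allele

  usable <- !amb & (same | swap | fsame | fswap)
  report <- list(
    n_shared = length(shared),
    n_ambiguous_dropped = sum(amb),
    n_allele_mismatch_dropped = sum(!amb & !(same | swap | fsame | fswap)),
    n_flipped = sum(usable & (swap | fswap)),
    n_aligned = sum(usable)
  )
  g <- g[usable, , drop = FALSE]
  q <- q[usable, , drop = FALSE]
  doswap <- (swap | fswap)[usable]
  q$beta[doswap] <- -q$beta[doswap]
  q$eaf[doswap] <- 1 - q$eaf[doswap]
  q$effect_allele <- g$effect_allele
  q$other_allele <- g$other_allele
  rownames(g) <- rownames(q) <- NULL
  list(gwas = g, qtl = q, report = report)
}

#' Filter summary statistics on allele frequency and imputation quality
#'
#' Keeps variants with minor allele frequency at or above `maf_min` and
#' imputation quality strictly above `info_min`; records without an
#' imputation-quality value pass that filter.
#'
#' @param records summary-statistics data frame.
#' @param maf_min minimum minor allele frequency (inclusive), default 0.05.
#' @param info_min imputation-quality threshold (exclusive), default 0.5.
#' @return filtered data frame.
#' @export
filter_qc <- function(records, maf_min = 0.05, info_min = 0.5) {
  maf <- pmin(records$eaf, 1 - records$eaf)
  info_ok <- is.na(records$info) | records$info > info_min
  out <- records[maf >= maf_min & info_ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene annotation as 1-based inclusive intervals
#'
#' Accepts BED (0-based half-open, no header: chrom, start, end, name,
#' score, strand) or a 1-based TSV dialect with header columns gene_id,
#' chrom, start, end, strand. BED coordinates are converted to 1-based
#' inclusive on read.
#'
#' @param path file path.
#' @param format `"bed"` or `"tsv"`.
#' @return data frame with columns gene_id, chrom, start, end, strand.
#' @export
read_gene_annotation <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                      comment.char = "#")
    genes <- data.frame(
      gene_id = as.character(raw[[4L]]),
      chrom = as.character(raw[[1L]]),
      start = as.integer(raw[[2L]]) + 1L,
      end = as.integer(raw[[3L]]),
      strand = if (ncol(raw) >= 6L) as.character(raw[[6L]]) else "+",
      stringsAsFactors = FALSE
    )
  } else {
    genes <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    need <- c("gene_id", "chrom", "start", "end")
    if (!all(need %in% names(genes))) {
      stop("gene annotation TSV must have columns: ",
           paste(need, collapse = ", "))
    }
    if (is.null(genes$strand)) genes$strand <- "+"
    genes$start <- as.integer(genes$start)
    genes$end <- as.integer(genes$end)
  }
  bad <- genes$start > genes$end
  if (any(bad)) stop("gene annotation: start > end for ",
                     paste(genes$gene_id[bad], collapse = ", "))
  genes
}

#' Write gene annotation as BED
#'
#' Converts the package's 1-based inclusive intervals to 0-based
#' half-open BED at the writer.
#'
#' @param genes gene annotation data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  bed <- data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene_id,
                    0L, genes$strand %||% "+")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line(), con)
  write.table(bed, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Select genome-wide significant risk loci and their genes
#'
#' One locus per variant with GWAS p-value at or below `p_thresh`
#' (inclusive, matching the conventional 5e-8 rule); each locus collects
#' every gene whose interval overlaps the closed window
#' `[lead_pos - window_bp, lead_pos + window_bp]`. With
#' `dedup_genes = TRUE` a gene appearing in several overlapping loci is
#' kept only in the locus with the most significant lead variant.
#'
#' @param gwas summary-statistics data frame.
#' @param genes gene annotation data frame.
#' @param p_thresh significance threshold, default 5e-8.
#' @param window_bp half-window around the lead variant, default 1 Mb.
#' @param dedup_genes deduplicate genes across overlapping loci.
#' @return data frame with columns lead_snv, chrom, lead_pos, start, end,
#'   pvalue and a list-column `genes`.
#' @export
select_risk_loci <- function(gwas, genes, p_thresh = 5e-8,
                             window_bp = 1e6, dedup_genes = FALSE) {
  hits <- gwas[gwas$pvalue <= p_thresh, , drop = FALSE]
  hits <- hits[order(hits$chrom, hits$pos), , drop = FALSE]
  loci <- data.frame(
    lead_snv = hits$variant_id, chrom = hits$chrom,
    lead_pos = hits$pos,
    start = hits$pos - as.integer(window_bp),
    end = hits$pos + as.integer(window_bp),
    pvalue = hits$pvalue, stringsAsFactors = FALSE
  )
  loci$genes <- lapply(seq_len(nrow(loci)), function(i) {
    sel <- genes$chrom == loci$chrom[i] &
      genes$end >= loci$start[i] & genes$start <= loci$end[i]
    unique(genes$gene_id[sel])
  })
  if (dedup_genes && nrow(loci) > 1L) {
    seen <- character(0)
    for (i in order(loci$pvalue)) {
      loci$genes[[i]] <- setdiff(loci$genes[[i]], seen)
      seen <- c(seen, loci$genes[[i]])
    }
  }
  rownames(loci) <- NULL
  loci
}

#' Extract variants in a cis window around a gene or position
#'
#' The window is closed on both ends: a gene anchor keeps variants with
#' `pos` in `[start - window_bp, end + window_bp]`; a point anchor (a
#' list or row with `chrom` and `pos`) keeps `[pos - window_bp,
#' pos + window_bp]`.
#'
#' @param records summary-statistics data frame.
#' @param anchor a one-row gene annotation (gene_id/chrom/start/end), a
#'   list with `chrom` and `pos`, or a gene_id looked up in `genes`.
#' @param window_bp half-window in base pairs.
#' @param genes optional gene annotation used to resolve a gene_id anchor.
#' @return the in-window subset of `records`.
#' @export
extract_cis_window <- function(records, anchor, window_bp, genes = NULL) {
  if (is.character(anchor) && length(anchor) == 1L) {
    if (is.null(genes)) stop("extract_cis_window: gene_id anchor needs `genes`")
    row <- genes[genes$gene_id == anchor, , drop = FALSE]
    if (!nrow(row)) stop("extract_cis_window: unknown anchor '", anchor, "'")
    anchor <- row[1L, ]
  }
  if (!is.null(anchor$start)) {
    chrom <- anchor$chrom; lo <- anchor$start - window_bp
    hi <- anchor$end + window_bp
  } else if (!is.null(anchor$pos)) {
    chrom <- anchor$chrom; lo <- anchor$pos - window_bp
    hi <- anchor$pos + window_bp
  } else {
    stop("extract_cis_window: anchor must carry start/end or pos")
  }
  out <- records[records$chrom == chrom & records$pos >= lo &
                 records$pos <= hi, , drop = FALSE]
  rownames(out) <- NULL
  out
}
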