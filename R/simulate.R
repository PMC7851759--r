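# Synthetic-data generators. Every generator is a pure function of
# (config, seed): the global RNG state is saved and restored, so calls
# are reproducible and do not perturb the caller's random stream.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration of a simulated LD region
#'
#' Describes a block of SNVs whose haplotypes are generated from an AR(1)
#' Gaussian copula: adjacent latent variables have correlation `rho`, so
#' LD decays geometrically with distance. Minor allele frequencies are
#' drawn uniformly in `maf_range`.
#'
#' @param n_snps number of SNVs (>= 1).
#' @param rho AR(1) correlation of adjacent latent variables, in `[0, 1)`.
#' @param maf_range two-element range of minor allele frequencies, within
#'   `[0, 0.5]`.
#' @param seed integer seed.
#' @param chrom chromosome label for emitted records.
#' @param pos_start position of the first SNV (1-based).
#' @param pos_step spacing between adjacent SNVs in bp.
#' @return object of class `sim_region_config`.
#' @export
sim_region_config <- function(n_snps, rho = 0.7, maf_range = c(0.05, 0.5),
                              seed = 1L, chrom = "1", pos_start = 1000000L,
                              pos_step = 5000L) {
  stopifnot(n_snps >= 1, rho >= 0, rho < 1,
            length(maf_range) == 2, maf_range[1] >= 0,
            maf_range[1] <= maf_range[2], maf_range[2] <= 0.5)
  structure(list(n_snps = as.integer(n_snps), rho = rho,
                 maf_range = maf_range, seed = as.integer(seed),
                 chrom = chrom, pos_start = as.integer(pos_start),
                 pos_step = as.integer(pos_step)),
            class = "sim_region_config")
}

# AR(1) latent Gaussian matrix: rows are draws, columns are SNVs.
ar1_gaussian <- function(n, m, rho) {
  z <- matrix(rnorm(n * m), n, m)
  if (rho > 0 && m > 1) {
    s <- sqrt(1 - rho^2)
    for (j in 2:m) z[, j] <- rho * z[, j - 1] + s * z[, j]
  }
  z
}

#' Simulate LD-structured genotypes
#'
#' Two haplotypes per individual are drawn by thresholding AR(1) latent
#' Gaussians at the quantile matching each SNV's minor allele frequency;
#' the genotype is the dosage (0/1/2) of the alternate allele. The
#' returned LD matrix is the empirical Pearson correlation of dosages.
#'
#' Region-level metadata (MAFs, alleles and positions) is a function of
#' the config seed alone, so two cohorts simulated from the same config
#' with different `draw_seed`s describe the same variants.
#'
#' @param cfg a [sim_region_config()].
#' @param n_individuals number of individuals (>= 2).
#' @param draw_seed seed for the haplotype draw (defaults to the config
#'   seed); the region's MAFs and alleles always come from the config seed.
#' @return list with `genotypes` (individuals x SNVs dosage matrix),
#'   `ld` (empirical correlation), `maf`, `snp_id`, `pos`, `chrom`,
#'   `alleles` (effect/other per SNV) and the config.
#' @export
simulate_ld_genotypes <- function(cfg, n_individuals, draw_seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_region_config"))
  if (n_individuals < 2) stop("simulate_ld_genotypes: n_individuals < 2")
  m <- cfg$n_snps
  meta <- with_seed(cfg$seed, {
    maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
    # non-palindromic allele pairs so harmonization is exercised cleanly
    pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
    al <- pairs[sample.int(4L, m, replace = TRUE), , drop = FALSE]
    list(maf = maf, al = al)
  })
  geno <- with_seed(draw_seed, {
    thresh <- qnorm(meta$maf)
    h1 <- ar1_gaussian(n_individuals, m, cfg$rho)
    h2 <- ar1_gaussian(n_individuals, m, cfg$rho)
    (sweep(h1, 2, thresh, "<") + 0) + (sweep(h2, 2, thresh, "<") + 0)
  })
  snp_id <- sprintf("rs%s_%05d", cfg$chrom, seq_len(m))
  pos <- cfg$pos_start + (seq_len(m) - 1L) * cfg$pos_step
  colnames(geno) <- snp_id
  ld <- if (m == 1L) {
    matrix(1, 1, 1)
  } else {
    r <- suppressWarnings(cor(geno))
    r[!is.finite(r)] <- 0; diag(r) <- 1
    r
  }
  list(genotypes = geno, ld = ld, maf = meta$maf, snp_id = snp_id, pos = pos,
       chrom = cfg$chrom,
       alleles = data.frame(effect_allele = meta$al[, 1],
                            other_allele = meta$al[, 2],
                            stringsAsFactors = FALSE),
       cfg = cfg)
}

# Bivariate standard normal CDF P(Z1 < t1, Z2 < t2 | cor = r) by
# one-dimensional quadrature; used to derive the copula-implied LD that
# the empirical LD should converge to.
bvn_cdf <- function(t1, t2, r) {
  if (abs(r) < 1e-12) return(pnorm(t1) * pnorm(t2))
  f <- function(x) dnorm(x) * pnorm((t2 - r * x) / sqrt(1 - r^2))
  stats::integrate(f, -Inf, t1, rel.tol = 1e-10)$value
}

#' Copula-implied LD of a simulated region
#'
#' Closed-form (quadrature) correlation of haplotype indicators implied
#' by the AR(1) Gaussian copula and the realized allele frequencies;
#' dosages inherit the same correlation. Used to check convergence of
#' the empirical LD.
#'
#' @param maf vector of minor allele frequencies actually used.
#' @param rho AR(1) latent correlation.
#' @return implied correlation matrix.
#' @export
copula_implied_ld <- function(maf, rho) {
  m <- length(maf)
  t <- qnorm(maf)
  R <- diag(m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      r <- rho^(j - i)
      p11 <- bvn_cdf(t[i], t[j], r)
      cov <- p11 - maf[i] * maf[j]
      R[i, j] <- R[j, i] <-
        cov / sqrt(maf[i] * (1 - maf[i]) * maf[j] * (1 - maf[j]))
    }
  }
  R
}

#' Causal-variant scenario for a trait / molecular-trait pair
#'
#' Mirrors the five colocalization hypotheses as generating regimes: no
#' causal variant (`null`), trait-only, QTL-only, two `distinct` causal
#' variants, or one `shared` causal variant.
#'
#' @param scenario one of `"shared"`, `"distinct"`, `"gwas_only"`,
#'   `"qtl_only"`, `"null"`.
#' @param causal_index_trait index of the trait causal SNV.
#' @param causal_index_qtl index of the molecular-trait causal SNV.
#' @param beta_trait log-odds per allele on the case-control trait.
#' @param beta_qtl effect per allele, in SD units, on the molecular trait.
#' @return object of class `causal_config`.
#' @export
causal_config <- function(scenario = c("shared", "distinct", "gwas_only",
                                       "qtl_only", "null"),
                          causal_index_trait = 1L, causal_index_qtl = 1L,
                          beta_trait = 0.2, beta_qtl = 0.5) {
  scenario <- match.arg(scenario)
  if (scenario == "shared" && causal_index_trait != causal_index_qtl) {
    stop("causal_config: shared scenario requires equal causal indices")
  }
  if (scenario == "distinct" && causal_index_trait == causal_index_qtl) {
    stop("causal_config: distinct scenario requires different causal indices")
  }
  if (scenario %in% c("null", "qtl_only")) beta_trait <- 0
  if (scenario %in% c("null", "gwas_only")) beta_qtl <- 0
  structure(list(scenario = scenario,
                 causal_index_trait = as.integer(causal_index_trait),
                 causal_index_qtl = as.integer(causal_index_qtl),
                 beta_trait = beta_trait, beta_qtl = beta_qtl),
            class = "causal_config")
}

# Marginal linear regression of y on each genotype column; closed-form
# OLS with intercept, vectorized across SNVs.
linear_scan <- function(G, y) {
  n <- length(y)
  gbar <- colMeans(G)
  Gc <- sweep(G, 2, gbar)
  yc <- y - mean(y)
  sxx <- colSums(Gc^2)
  sxy <- colSums(Gc * yc)
  beta <- sxy / sxx
  rss <- sum(yc^2) - beta * sxy
  se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df = n - 2)
  list(beta = beta, se = se, pvalue = pmin(pmax(p, .Machine$double.xmin), 1))
}

# Logistic regression of y on one genotype vector (with intercept).
# Falls back to a lightly ridged IRLS when the ML fit separates.
logistic_one <- function(g, y) {
  X <- cbind(1, g)
  fit <- suppressWarnings(stats::glm.fit(X, y, family = binomial()))
  co <- fit$coefficients
  ok <- fit$converged && all(is.finite(co)) && abs(co[2L]) < 15
  if (ok) {
    w <- fit$weights
    XtWX <- crossprod(X * sqrt(w))
    cov <- tryCatch(solve(XtWX), error = function(e) NULL)
    ok <- !is.null(cov) && all(is.finite(diag(cov))) && diag(cov)[2L] > 0
  }
  if (!ok) {
    warning("logistic fit separated; refitting with a small ridge penalty")
    b <- c(0, 0); lambda <- 1e-2
    for (it in 1:50) {
      eta <- drop(X %*% b)
      mu <- plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      z <- eta + (y - mu) / w
      XtWX <- crossprod(X * sqrt(w)) + diag(lambda, 2)
      b_new <- solve(XtWX, crossprod(X * w, z))
      if (max(abs(b_new - b)) < 1e-10) { b <- b_new; break }
      b <- b_new
    }
    co <- drop(b)
    cov <- solve(XtWX)
  }
  se <- sqrt(diag(cov))[2L]
  zstat <- co[2L] / se
  c(beta = unname(co[2L]), se = unname(se),
    pvalue = max(2 * pnorm(-abs(zstat)), .Machine$double.xmin))
}

make_sumstats_df <- function(geno_meta, beta, se, pvalue, eaf, n) {
  data.frame(
    variant_id = geno_meta$snp_id, chrom = geno_meta$chrom,
    pos = geno_meta$pos,
    effect_allele = geno_meta$alleles$effect_allele,
    other_allele = geno_meta$alleles$other_allele,
    beta = unname(beta), se = unname(se), pvalue = unname(pvalue),
    eaf = unname(eaf), n = as.integer(n), info = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Simulate paired GWAS and QTL summary statistics over one LD region
#'
#' The case-control trait follows a logistic model on the trait causal
#' dosage; cases and controls are sampled from the simulated population
#' until the requested counts are reached, and per-SNV marginal logistic
#' regressions produce the GWAS summary statistics. The quantitative
#' molecular trait is a linear model with unit-variance Gaussian noise
#' on an independent cohort drawn from the same LD structure, scanned by
#' per-SNV marginal linear regression.
#'
#' @param cfg a [sim_region_config()] describing the region (the GWAS and
#'   QTL cohorts are independent genotype draws from it).
#' @param causal a [causal_config()].
#' @param n_cases,n_controls case-control cohort sizes.
#' @param n_qtl molecular-trait cohort size.
#' @param seed integer seed (overrides the config seed for cohort draws).
#' @param prevalence baseline case probability at the genotype mean.
#' @param keep_genotypes also return the two genotype objects.
#' @return list with `gwas` and `qtl` summary-statistics data frames,
#'   `ld_qtl` (empirical LD in the QTL cohort), `truth`, and optionally
#'   the genotype objects.
#' @export
simulate_trait_pair <- function(cfg, causal, n_cases, n_controls, n_qtl,
                                seed = cfg$seed, prevalence = 0.5,
                                keep_genotypes = FALSE) {
  stopifnot(inherits(cfg, "sim_region_config"),
            inherits(causal, "causal_config"))
  if (max(causal$causal_index_trait, causal$causal_index_qtl) > cfg$n_snps) {
    stop("simulate_trait_pair: causal index exceeds n_snps")
  }
  # genotype panel large enough to fill both arms of the case-control draw
  n_pool <- ceiling(1.35 * (n_cases + n_controls) / min(prevalence,
                                                        1 - prevalence) / 2) * 2
  gpool <- simulate_ld_genotypes(cfg, n_pool, draw_seed = derive_seed(seed, 1L))
  gwas <- with_seed(derive_seed(seed, 3L), {
    gc_ <- gpool$genotypes[, causal$causal_index_trait]
    eta <- qlogis(prevalence) + causal$beta_trait * (gc_ - mean(gc_))
    status <- rbinom(n_pool, 1L, plogis(eta))
    case_idx <- which(status == 1L)
    ctrl_idx <- which(status == 0L)
    draws <- 0L
    while (length(case_idx) < n_cases || length(ctrl_idx) < n_controls) {
      draws <- draws + 1L
      extra <- simulate_ld_genotypes(
        cfg, n_pool, draw_seed = derive_seed(seed, 100L + draws))
      gce <- extra$genotypes[, causal$causal_index_trait]
      etae <- qlogis(prevalence) + causal$beta_trait * (gce - mean(gce))
      se_ <- rbinom(n_pool, 1L, plogis(etae))
      gpool$genotypes <- rbind(gpool$genotypes, extra$genotypes)
      status <- c(status, se_)
      case_idx <- which(status == 1L)
      ctrl_idx <- which(status == 0L)
    }
    keep <- c(case_idx[seq_len(n_cases)], ctrl_idx[seq_len(n_controls)])
    G <- gpool$genotypes[keep, , drop = FALSE]
    y <- status[keep]
    scan <- t(vapply(seq_len(ncol(G)), function(j) logistic_one(G[, j], y),
                     c(beta = 0, se = 0, pvalue = 0)))
    make_sumstats_df(gpool, scan[, "beta"], scan[, "se"], scan[, "pvalue"],
                     eaf = colMeans(G) / 2, n = n_cases + n_controls)
  })

  gq <- simulate_ld_genotypes(cfg, n_qtl, draw_seed = derive_seed(seed, 2L))
  qtl_y <- with_seed(derive_seed(seed, 4L), {
    causal$beta_qtl * gq$genotypes[, causal$causal_index_qtl] + rnorm(n_qtl)
  })
  scan_q <- linear_scan(gq$genotypes, qtl_y)
  qtl <- make_sumstats_df(gq, scan_q$beta, scan_q$se, scan_q$pvalue,
                          eaf = colMeans(gq$genotypes) / 2, n = n_qtl)

  out <- list(
    gwas = gwas, qtl = qtl, ld_qtl = gq$ld,
    truth = list(scenario = causal$scenario,
                 causal_trait = gpool$snp_id[causal$causal_index_trait],
                 causal_qtl = gq$snp_id[causal$causal_index_qtl],
                 beta_trait = causal$beta_trait, beta_qtl = causal$beta_qtl)
  )
  if (keep_genotypes) {
    out$genotypes_qtl <- gq
    out$qtl_phenotype <- qtl_y
  }
  out
}

#' Simulate a quantitative-trait QTL cohort alone
#'
#' Draws an independent cohort from the region config, generates the
#' molecular trait `y = beta_qtl * g + N(0, 1)` on the causal dosage,
#' and scans it by marginal linear regression. Used for exon-level or
#' additional molecular features sharing a region's GWAS.
#'
#' @param cfg a [sim_region_config()].
#' @param causal_index causal SNV index.
#' @param beta_qtl per-allele effect in SD units.
#' @param n_qtl cohort size.
#' @param seed integer seed for the cohort draw.
#' @return list with `qtl` summary statistics, `ld` (empirical), and
#'   `truth`.
#' @export
simulate_qtl_cohort <- function(cfg, causal_index, beta_qtl, n_qtl,
                                seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_region_config"), causal_index <= cfg$n_snps)
  gq <- simulate_ld_genotypes(cfg, n_qtl, draw_seed = derive_seed(seed, 21L))
  y <- with_seed(derive_seed(seed, 22L), {
    beta_qtl * gq$genotypes[, causal_index] + rnorm(n_qtl)
  })
  scan <- linear_scan(gq$genotypes, y)
  list(qtl = make_sumstats_df(gq, scan$beta, scan$se, scan$pvalue,
                              eaf = colMeans(gq$genotypes) / 2, n = n_qtl),
       ld = gq$ld,
       truth = list(causal_qtl = gq$snp_id[causal_index],
                    beta_qtl = beta_qtl))
}

#' Simulate CpG methylation with covariate structure
#'
#' CpGs are generated on the logit (M-value) scale as a linear model in
#' the planted genotype effect and in covariates with nonzero planted
#' coefficients (age at death, sex, two population-stratification
#' components, batch, postmortem interval), then mapped to beta values by
#' the inverse logit, so values lie strictly in (0, 1).
#'
#' @param genotypes a genotype object from [simulate_ld_genotypes()].
#' @param planted list with `snv_index`, `cpg_index` and `effect` (on the
#'   M-value scale, per allele); use `effect = 0` for a null region. An
#'   optional `pos` pins the planted CpG's genomic position.
#' @param n_cpgs number of CpG sites.
#' @param seed integer seed.
#' @param noise_sd residual SD on the M-value scale.
#' @param window_bp CpG positions are scattered within this distance of
#'   the region's SNVs.
#' @return list with `beta` (CpGs x samples matrix in (0,1)), `m_values`,
#'   `cpgs` annotation, `covariates` table, and `truth`.
#' @export
simulate_methylation <- function(genotypes, planted = list(snv_index = 1L,
                                                           cpg_index = 1L,
                                                           effect = 0),
                                 n_cpgs = 20L, seed = 1L, noise_sd = 0.5,
                                 window_bp = 400000L) {
  n <- nrow(genotypes$genotypes)
  with_seed(seed, {
    covar <- data.frame(
      age = rnorm(n, 75, 8),
      sex = rbinom(n, 1L, 0.5),
      pc1 = rnorm(n), pc2 = rnorm(n),
      batch = factor(sample(c("b1", "b2", "b3"), n, replace = TRUE)),
      pmi = rgamma(n, shape = 6, scale = 4)
    )
    anchor <- genotypes$pos[sample.int(length(genotypes$pos), n_cpgs,
                                       replace = TRUE)]
    cpg_pos <- anchor + sample(seq(-window_bp, window_bp), n_cpgs,
                               replace = TRUE)
    cpg_pos <- pmax(cpg_pos, 1L)
    if (!is.null(planted$pos)) cpg_pos[planted$cpg_index] <- planted$pos
    cpgs <- data.frame(cpg_id = sprintf("cg%07d", seq_len(n_cpgs)),
                       chrom = genotypes$chrom, pos = as.integer(cpg_pos),
                       stringsAsFactors = FALSE)
    # planted covariate coefficients (M-value scale) so adjustment matters
    cov_fx <- cbind(0.02 * covar$age, 0.3 * covar$sex, 0.2 * covar$pc1,
                    -0.15 * covar$pc2,
                    0.25 * (covar$batch == "b2") - 0.2 * (covar$batch == "b3"),
                    0.01 * covar$pmi)
    cov_shift <- rowSums(cov_fx)
    mu <- runif(n_cpgs, -1.5, 1.5)
    M <- matrix(rnorm(n_cpgs * n, 0, noise_sd), n_cpgs, n)
    M <- M + mu + matrix(cov_shift, n_cpgs, n, byrow = TRUE)
    if (planted$effect != 0) {
      g <- genotypes$genotypes[, planted$snv_index]
      M[planted$cpg_index, ] <- M[planted$cpg_index, ] + planted$effect * g
    }
    rownames(M) <- cpgs$cpg_id
    list(beta = plogis(M), m_values = M, cpgs = cpgs, covariates = covar,
         truth = list(snv_id = genotypes$snp_id[planted$snv_index],
                      cpg_id = cpgs$cpg_id[planted$cpg_index],
                      effect = planted$effect))
  })
}

#' Simulate cell-type-structured expression
#'
#' Each cell type gets `markers_per_type` marker genes whose mean
#' expression is `fold` times higher in their own type than elsewhere;
#' non-marker genes are exchangeable across types. Expression is gamma
#' noise around the type mean, keeping values positive.
#'
#' @param n_genes total number of genes.
#' @param cell_types character vector of cell-type names (>= 2).
#' @param markers_per_type markers planted per type.
#' @param fold marker fold-change (> 1).
#' @param n_cells_per_type cells simulated per type.
#' @param seed integer seed.
#' @return list with `expr` (genes x cells), `cell_labels`, and `markers`
#'   truth table (gene_id, cell_type).
#' @export
simulate_celltype_expression <- function(n_genes, cell_types,
                                         markers_per_type, fold,
                                         n_cells_per_type = 50L, seed = 1L) {
  stopifnot(length(cell_types) >= 2, fold > 1,
            n_genes >= markers_per_type * length(cell_types))
  with_seed(seed, {
    k <- length(cell_types)
    gene_id <- sprintf("GENE%04d", seq_len(n_genes))
    marker_idx <- matrix(seq_len(markers_per_type * k), ncol = k)
    markers <- data.frame(
      gene_id = gene_id[as.vector(marker_idx)],
      cell_type = rep(cell_types, each = markers_per_type),
      stringsAsFactors = FALSE
    )
    base_mu <- runif(n_genes, 2, 10)
    labels <- rep(cell_types, each = n_cells_per_type)
    mu <- matrix(base_mu, n_genes, k)
    for (j in seq_len(k)) mu[marker_idx[, j], j] <- base_mu[marker_idx[, j]] * fold
    shape <- 50
    expr <- matrix(0, n_genes, length(labels),
                   dimnames = list(gene_id, NULL))
    for (j in seq_len(k)) {
      cols <- which(labels == cell_types[j])
      expr[, cols] <- matrix(
        rgamma(n_genes * length(cols), shape = shape,
               scale = rep(mu[, j], length(cols)) / shape),
        n_genes, length(cols))
    }
    list(expr = expr, cell_labels = labels, markers = markers)
  })
}

#' Simulate a scored interactome with planted seed-to-mendelian bridges
#'
#' Background edges follow an Erdős–Rényi model over all node pairs with
#' probability `p_edge`; on top of it, exactly `n_bridges` two-hop paths
#' seed — internode — mendelian are planted to distinct mendelian
#' proteins. A disjoint null pool of `pool_size` genes is returned for
#' control-network sampling.
#'
#' @param n_background number of background proteins.
#' @param p_edge background edge probability.
#' @param seeds character vector of seed protein ids.
#' @param mendelian character vector of mendelian protein ids.
#' @param n_bridges number of planted bridges (<= `length(mendelian)`).
#' @param pool_size size of the null pool.
#' @param seed integer seed.
#' @return list with `graph` (an [interactome_graph()]), `null_pool`, and
#'   `truth` (bridged mendelian proteins and internodes).
#' @export
simulate_interactome <- function(n_background, p_edge, seeds, mendelian,
                                 n_bridges, pool_size, seed = 1L) {
  if (n_bridges > length(mendelian)) {
    stop("simulate_interactome: n_bridges exceeds the mendelian set size")
  }
  if (length(intersect(seeds, mendelian))) {
    stop("simulate_interactome: seeds and mendelian sets overlap")
  }
  with_seed(seed, {
    pool <- sprintf("POOL%03d", seq_len(pool_size))
    background <- if (n_background > 0) {
      sprintf("BG%04d", seq_len(n_background))
    } else character(0)
    bridge_nodes <- if (n_bridges > 0) {
      sprintf("BRIDGE%02d", seq_len(n_bridges))
    } else character(0)
    nodes <- c(seeds, mendelian, pool, background, bridge_nodes)
    if (anyDuplicated(nodes)) {
      stop("simulate_interactome: node name collision between input sets ",
           "and generated POOL/BG/BRIDGE ids")
    }
    # Erdős–Rényi background over non-bridge nodes
    base <- c(seeds, mendelian, pool, background)
    nb <- length(base)
    edges <- NULL
    if (p_edge > 0 && nb > 1) {
      n_pairs <- nb * (nb - 1) / 2
      n_draw <- rbinom(1L, n_pairs, p_edge)
      if (n_draw > 0) {
        pick <- sample.int(n_pairs, n_draw)
        # unrank upper-triangle pair indices
        i <- floor((2 * nb - 1 - sqrt((2 * nb - 1)^2 - 8 * pick)) / 2) + 1
        off <- pick - (i - 1) * (2 * nb - i) / 2
        j <- i + off
        edges <- data.frame(protein_a = base[i], protein_b = base[j],
                            score = runif(n_draw, 0.5, 1),
                            stringsAsFactors = FALSE)
      }
    }
    truth_mend <- character(0)
    if (n_bridges > 0) {
      targets <- sample(mendelian, n_bridges)
      anchor <- rep_len(seeds, n_bridges)
      planted <- rbind(
        data.frame(protein_a = anchor, protein_b = bridge_nodes,
                   score = 1, stringsAsFactors = FALSE),
        data.frame(protein_a = bridge_nodes, protein_b = targets,
                   score = 1, stringsAsFactors = FALSE)
      )
      edges <- rbind(edges, planted)
      truth_mend <- targets
    }
    if (is.null(edges)) {
      edges <- data.frame(protein_a = character(0), protein_b = character(0),
                          score = numeric(0), stringsAsFactors = FALSE)
    }
    graph <- interactome_graph(edges, nodes = nodes)
    list(graph = graph, null_pool = pool,
         truth = list(bridged_mendelian = truth_mend,
                      internodes = bridge_nodes))
  })
}
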