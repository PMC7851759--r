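---
title: "Statistical methods and design choices in locusweave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods and design choices in locusweave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locusweave)
```

`locusweave` integrates GWAS summary statistics with molecular QTL data to
prioritize candidate genes at risk loci. This vignette explains the models,
the tunable parameters and why their defaults are what they are, what the
synthetic-data generators do and do not emulate, and the numerical and
design decisions a maintainer should know about.

## Harmonization of summary statistics

Two summary-statistics tables are joined on (chromosome, position). The QTL
effect allele is aligned to the GWAS effect allele; when the alleles are
swapped the QTL beta is negated and its allele frequency reflected
(`eaf -> 1 - eaf`), and the strand-flipped versions of both orientations
are also accepted. Three groups are dropped rather than guessed at:

- **Strand-ambiguous variants** (A/T, C/G): allele identity cannot
  distinguish a strand flip from an allele swap. Frequency-based
  resolution is possible but fragile near MAF 0.5; dropping is the
  conservative default and the counts are reported.
- **Allele mismatches**: pairs matching neither orientation.
- **Multi-allelic duplicates**: at a duplicated position the row whose
  alleles match the partner file is kept; among several matches the
  lowest p-value wins, and the event is logged.

Harmonization is idempotent — applying it to its own output is the
identity — which the test suite asserts directly. QC keeps variants with
minor allele frequency at or above 0.05 (inclusive) and imputation quality
strictly above 0.5; records without an imputation-quality field pass that
filter, since several QTL resources do not publish it. Coordinates are
1-based inclusive everywhere; only the BED writer converts to 0-based
half-open.

## Colocalization

For each SNV and trait the Wakefield approximate Bayes factor compares a
nonzero-effect model with effect prior N(0, W) against the null:
`log ABF = 0.5 * log(1 - r) + 0.5 * r * z^2`, `r = W / (W + se^2)`.
Regional sums of per-SNV Bayes factors give the unnormalized masses of the
five hypotheses (H0 none, H1 trait-1 only, H2 trait-2 only, H3 two
distinct causal variants, H4 one shared causal variant):

H0 = 1, H1 = p1·S1, H2 = p2·S2, H3 = p1·p2·(S1·S2 − S12), H4 = p12·S12,

with S1, S2, S12 the sums of exp(labf1), exp(labf2), exp(labf1+labf2).
This is the exact single-causal-variant enumeration: S1·S2 − S12 is the
sum over ordered pairs of *distinct* SNVs, which the tests verify against
a literal double-loop enumeration to 1e-10 on fuzzed regions of up to six
SNVs.

Numerical choices:

- All mass accumulation uses log-sum-exp; raw exponentials of large ABFs
  never appear.
- In a single-SNV region S1·S2 = S12 holds *exactly* in floating point
  (both are the same product), so PPH3 is exactly zero, matching the fact
  that one SNV cannot carry two distinct causal variants.
- The top SNV is the argmax of the per-SNV H4 contribution
  (normalized exp(labf1+labf2)); ties break to the lowest genomic
  position so results are order-independent.

Parameters: the per-SNV priors default to p1 = p2 = 1e-4 and p12 = 1e-5,
the standard single-variant priors for this analysis. The prior effect SDs
are 0.2 for quantitative traits (SD units) and 0.15 for case-control
traits (log-odds units) — the conventional defaults of the colocalization
literature; the source analyses name only p1/p2/p12, so these two are
surfaced as explicit `coloc_priors()` fields rather than hidden constants,
and gene-level and exon-level runs share them unless the caller says
otherwise. Exactly one causal variant per trait per region is assumed; no
conditioning or masking extension is attempted.

A gene with PPH4 ≥ 0.75 (inclusive) in at least one tissue of at least one
dataset counts as strongly colocalized. The splicing call requires an exon
with PPH4 ≥ 0.75 while the gene level actively favors distinct variants
(gene PPH3 > gene PPH4); when both the gene and an exon colocalize,
expression takes precedence, because a gene-level shared variant already
explains the exon signal.

## TWAS / MWAS

The association statistic is `z = w' z_gwas / sqrt(w' R w)`. Externally
trained predictive weight models cannot be reproduced at the scale this
package targets, so two transparent schemes are provided and always
annotated in the output: `top1` (weight 1 on the minimum-p QTL SNV, ties
to the lowest position) and `marginal` (w = per-SNV z-scores). Under the
global null the statistic is standard normal, which the acceptance suite
checks with 10,000 simulated replicates (two-sided 5% rate within
[0.04, 0.06] and a Kolmogorov–Smirnov test at alpha 0.01).

`twas_zscore()` computes the exact quadratic form by default
(`ridge_lambda = 0`), so textbook cases reproduce exactly (one-hot weights
return the SNV's own z; w = (1,1), z = (2,0), r = 0.5 gives 2/sqrt(3)).
When R is *estimated* from a finite genotype sample the pipeline driver
passes `ridge_lambda = 0.01`, mixing `R <- 0.99 R + 0.01 I` before the
solve; sampling noise in estimated LD can otherwise drive `w'Rw` near or
below zero. Putting the ridge at the call site rather than inside the
statistic keeps the estimator honest where LD is known exactly and
regularized only where it is estimated.

FDR control is Benjamini–Hochberg, computed genome-wide but *separately
per analysis type* (expression, splicing, methylation), mirroring how the
three result lists are corrected in practice; the tests pin the q-values
and rejection set to a brute-force step-up implementation. Conditional
analysis is one greedy round: the largest-|z| feature is selected, the
GWAS z-vector is residualized on its normalized predicted-expression
direction (`z' = z - R w~ (w~' z)`, `w~ = w / sqrt(w'Rw)`), and remaining
features are relabeled `joint` (conditional p ≥ 0.05) or `independent`.
One round suffices for the single-vs-joint question; a full stepwise
joint model is deliberately out of scope.

## cis-mQTL mapping

Methylation beta values are regressed on genotype dosage with covariates
for age at death, sex, population-stratification components, batch and
postmortem interval; the genotype coefficient gets a two-sided t-test.
Association is on beta values directly, as is standard for this design; an
M-value (logit) switch exists but is off by default. Missing covariate
rows are dropped listwise and counted. Rank-deficient designs are fatal
and name the offending column — silently dropping a confounder would
change the estimand. The scan tests all SNV–CpG pairs within 500 kb
(closed window), applies BH-FDR *across all tests in the scan* (the
natural reading when one global 5% FDR is quoted; a per-SNV alternative
would be less conservative), and keeps each SNV's minimum-p pair when its
q ≤ 0.05. CpG→gene mapping takes every gene with a transcription start or
end within 10 kb (inclusive) of the CpG, strand-ignorant, which can
legitimately return several genes or none.

## Cell-type and coexpression annotation

Prevalence enrichment divides the mean expression in one cell type by the
*unweighted mean of the other types' per-type means* — pooling cells
instead would let abundant cell types dominate the denominator. The
primary type is the argmax; exact ties break lexicographically and are
flagged. Module eigengenes are the first right singular vector of the
row-standardized module matrix, sign-fixed so the mean correlation with
member genes is non-negative. Module membership kME is the absolute
Pearson correlation with the eigengene — the absolute value realizes a
membership that "is always between 0 and 1"; a squared-correlation switch
is provided since the literature is not unanimous. The relevance flag is
strict (kME > 0.76). Marker enrichment is the one-sided hypergeometric
(Fisher exact) upper tail, checked against closed-form tail summation.
Construction of the coexpression modules themselves (topological overlap,
k-means refinement) is out of scope: modules are inputs.

## Network permutation test

A mendelian protein counts as connected to the seed network when it is
adjacent to a seed or to any direct interactor of a seed — i.e. at most
two hops, the "second-degree" level; the hop depth is a parameter. The
count is set-valued (each mendelian protein once, however many paths).
Control networks redraw the seed set: B sets of the observed size, drawn
uniformly without replacement from a null pool, independently across
sets. The empirical p-value uses the add-one (permutation-inclusive)
convention p = (1 + #{null ≥ observed}) / (B + 1), which can never be
zero; with B = 1000 its floor is 1/1001, i.e. "< 1e-3" when no control
reaches the observed count. Edge scores are accepted and filterable
(`score_min`, default 0) but not re-derived. `permutation_test()` scores
control sets through a dense-adjacency fast path; the suite verifies it
replays exactly the counts that per-set `build_seed_network()`
construction produces.

## What the synthetic generators emulate — and what they do not

All generators are pure functions of (config, seed): they save and restore
the global RNG state, and identical inputs give identical outputs.

- **Genotypes**: two haplotypes per individual, each a thresholded AR(1)
  Gaussian copula, so LD decays geometrically (`rho^distance` on the
  latent scale) and the implied indicator correlation is available in
  closed form for convergence checks (asserted at n = 10,000 within
  0.03). Region metadata (MAFs, alleles) depends only on the region seed,
  so independent cohorts describe the same variants. Not emulated:
  recombination hotspots, population structure, sex chromosomes, real
  allele-frequency spectra.
- **Trait pairs**: the case-control trait is a logistic model on the
  causal dosage with cases and controls sampled from the simulated
  population until the requested counts are reached; summary statistics
  come from per-SNV logistic fits (with a small-ridge IRLS fallback on
  separation), not from an analytic shortcut, so downstream SE handling
  is realistic. The baseline prevalence parameter defaults to 0.5 —
  a sampling-efficiency choice for desk-scale cohorts, not an
  epidemiological claim. The molecular trait adds N(0,1) noise on an
  independent cohort.
- **Methylation**: CpGs are linear on the logit (M-value) scale with
  planted nonzero covariate coefficients — so covariate adjustment is
  testable — then inverse-logit mapped, keeping beta values strictly in
  (0,1). Array normalization artifacts and cell-composition effects are
  not modeled.
- **Cell-type expression**: gamma noise around per-type means with
  markers at a configurable fold-change; the plug-in check that a fold-5
  marker shows prevalence enrichment ≈ 5 within 10% sizes the noise.
- **Interactomes**: Erdős–Rényi background plus exactly `n_bridges`
  planted two-hop seed–internode–mendelian paths to distinct mendelian
  proteins, and a disjoint null pool (118 genes in the acceptance
  setting). Degree heterogeneity, hub structure and literature-curation
  bias of real interactomes are not emulated.

Consequently, passing tests demonstrate the *statistical machinery* —
calibration, recovery of planted truth, oracle equivalence — not the
biology of any real cohort.

## Problem sizes used by the acceptance checks

The statistical acceptance tests run at fixed, documented sizes chosen so
each check is decisive at desk scale: 1,000 fuzzed regions (≤ 6 SNVs) for
oracle equivalence; 100 replicates of 50-SNV regions with rho = 0.9,
5,000 cases / 5,000 controls and 300 QTL samples for colocalization
recovery (distinct-causal variants are placed at opposite region ends,
empirical r² < 0.1); 10,000 replicates of 3-SNV regions with 1,000 cases,
1,000 controls and 200 QTL samples for TWAS null calibration — cohorts
large enough that the logistic Wald z-scores are in their asymptotic
normal regime; 100 planted and 25 null methylation scans; and, for the permutation test, a
500-node graph (118-gene pool, 150 mendelian proteins, background edge
probability 0.006) with 500 outer replicates at B = 199 for null
uniformity — the mendelian set and edge density are sized so the
connectivity counts spread over many values, giving the discrete
empirical p-value enough resolution for a Kolmogorov–Smirnov uniformity
check — plus a planted-bridge configuration at B = 1000 whose observed
count exceeds every control, pinning the p-value to its 1/1001 floor.

## Known limitations

- Single-causal-variant colocalization only; allelic heterogeneity at a
  locus deflates PPH4.
- The transparent weight schemes are not predictive models; TWAS effect
  directions are trustworthy, effect magnitudes are scheme-dependent.
- The conditional analysis is one greedy round, not a joint model.
- The mQTL scan assumes a complete-case covariate table after listwise
  deletion and does not model cell composition.
- The permutation null conditions on the fixed graph; it randomizes seed
  identity, not graph topology.
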