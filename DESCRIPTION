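Package: locusweave
Title: Multi-Omic Candidate Gene Prioritization for GWAS Risk Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates genome-wide association study (GWAS) summary statistics
    with molecular quantitative trait locus (QTL) data to prioritize candidate
    genes at risk loci. Implements Bayesian colocalization of GWAS and QTL
    signals from Wakefield approximate Bayes factors, discrimination of
    splicing from expression effects using exon-level colocalization, weighted
    transcriptome- and methylome-wide association statistics with
    false-discovery-rate control and conditional analysis, cis methylation-QTL
    mapping with covariate adjustment, evidence intersection across analyses,
    cell-type prevalence and coexpression-module annotation, and a permutation
    test of protein-interaction-network connectivity to a mendelian disease
    gene set. A synthetic-data module generates LD-structured genotypes,
    paired case-control and molecular traits, methylation, cell-type-structured
    expression, and interactomes with planted seed-to-mendelian bridges, so
    the full pipeline is testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
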