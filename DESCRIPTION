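Package: pleiocca
Title: Cross-Trait Pleiotropy Mapping from GWAS Summary Statistics via
    Canonical Correlation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies pleiotropic variants and genes shared by two complex
    traits from univariate genome-wide association study (GWAS) summary
    statistics alone. Harmonizes two per-SNP effect tables onto a common
    effect allele, standardizes effects, prunes linkage disequilibrium (LD)
    against a reference genotype panel with a sliding-window r-squared rule,
    and assembles the summary-statistic covariance blocks of metaCCA-style
    canonical correlation analysis for single-SNP and multi-SNP (gene level)
    scans with Bartlett chi-square significance. Gene hits can be validated
    with a VEGAS-style sum-of-chi-square test using an LD-aware Monte Carlo
    null, and triangulated against external gene lists (drug targets, TWAS
    hits) with Venn-region accounting, gene classification and
    protein-protein-interaction graph summaries. A synthetic-data module
    simulates LD-blocked genotype panels, correlated phenotypes with shared
    and private causal SNPs, and the resulting two-cohort summary statistics
    with known ground truth, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
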