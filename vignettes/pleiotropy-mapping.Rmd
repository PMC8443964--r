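---
title: "Mapping cross-trait pleiotropy from GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cross-trait pleiotropy from GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(pleiocca)
```

## The problem and the model

Two genome-wide association studies (GWAS) of related diseases — say a heart
failure meta-analysis and a chronic kidney disease meta-analysis — each
publish per-SNP univariate regression results: an effect size $\beta$, its
standard error, the effect allele, and the sample size. Individual-level
genotypes are unavailable. The question is which variants and genes act on
*both* traits (pleiotropy).

Canonical correlation analysis (CCA) answers this jointly: for a set of $g$
genotypic variables $X$ and $p$ phenotypic variables $Y$, it finds the
linear combinations $Xa$, $Yb$ with maximal correlation; that maximum is the
leading canonical correlation $r_1$. CCA needs only the joint correlation
matrix

$$\Sigma \;=\; \begin{pmatrix} \Sigma_{XX} & \Sigma_{XY} \\
\Sigma_{XY}^T & \Sigma_{YY} \end{pmatrix},$$

and each block can be estimated from summary data:

* $\Sigma_{XY}$ — the standardized effects. For a per-allele effect
  $\beta$ with standard error $\mathrm{SE}$ and sample size $n$,
  $$\beta^{STD} = \frac{\beta}{\sqrt{n}\,\mathrm{SE}},$$
  which equals the Wald $z$ statistic over $\sqrt n$ and approximates the
  genotype–phenotype Pearson correlation (`standardize_beta()`). The
  approximation is exact only as $r \to 0$: algebraically
  $\beta^{STD} = r\sqrt{(n-2)/n}\,/\sqrt{1-r^2}$, so at $r = 0.3$ the
  relative distortion is already $\sim 4\%$. This is the regime argument
  behind the package's accuracy claims: for the small per-SNP correlations
  typical of complex traits the summary-based $r_1$ tracks the
  individual-level $r_1$ closely (the test suite demonstrates agreement
  within 0.02 at $n = 2000$ for blocks of up to 10 SNPs with per-SNP
  correlations around 0.1–0.2).
* $\Sigma_{XX}$ — the genotype correlations, estimated as Pearson
  correlations of dosage columns in an external reference panel
  (`genotype_corr()`), since LD is a population property the panel shares
  with the study cohorts.
* $\Sigma_{YY}$ — the trait correlations, estimated as the Pearson
  correlation between the two studies' standardized-effect vectors across
  all (pruned, genome-wide) SNPs (`estimate_sigma_yy()`). Genome-wide, most
  effects are null noise whose between-study correlation reflects the
  phenotypic correlation plus sample overlap; for disjoint cohorts it is
  close to zero even when the traits are biologically correlated, which is
  expected and correct for the test statistic. $\Sigma_{YY}$ is estimated
  once from all pruned SNPs, not per gene: per-gene estimates from a handful
  of effect pairs would be dominated by noise.

Estimated blocks need not be positive definite; `shrink_to_pd()` applies
convex shrinkage $(1-\lambda)M + \lambda I$ with the smallest grid
$\lambda \in \{0, 0.01, 0.02, \dots\}$ whose minimum eigenvalue reaches
$10^{-8}$ (both configurable). Correlation matrices keep their unit
diagonal under this map.

## Significance

The classical null distribution for canonical correlations is used: Wilks'
$\Lambda = \prod_i (1 - r_i^2)$ with Bartlett's chi-square approximation

$$-\Big(N - 1 - \tfrac{g+p+1}{2}\Big)\,\ln\Lambda \;\sim\; \chi^2_{gp},$$

implemented in `cca_pvalue()`. The choice is deliberate: it reduces to the
classical Pearson-correlation test at $g = p = 1$ (the suite checks
agreement within 5% there) and needs only $N$, $g$ and $p$, all available
from summary data; it is isolated so an F-approximation could be swapped in.
When the two studies' sample sizes differ, $N$ defaults to the smaller
total — the conservative choice, configurable via
`analysis_config(N = ...)` or `pipeline_config(n_effective = ...)`.

Multiple testing uses Bonferroni only, applied separately to the SNP scan
($\alpha/m_{\mathrm{SNPs}}$) and the gene scan ($\alpha/m_{\mathrm{genes}}$)
at $\alpha = 0.01$ by default. Thresholds are carried at full precision in
tables and manifests and shown at 3 significant figures in display; for
published analyses of this kind, note that a printed threshold and its
printed quotient occasionally disagree in the literature —
`bonferroni_threshold()` always computes the quotient.

## LD pruning

`window_prune()` implements PLINK-style windowed pruning on dosage
correlations: windows of 50 SNPs advancing by 5 (defaults), removing, for
every pair with $r^2 > 0.2$, the SNP with the smaller reference-panel MAF,
repeated to a fixed point where no window contains a violating pair. The
published descriptions of this procedure do not pin the iteration order, so
the package defines it exactly: pairs are examined windows-in-order, left
index then right index, the first violation's loser is removed (MAF ties:
the larger-position SNP), and the scan resumes. The implementation skips
windows proven clean (removal at position $k$ cannot affect windows ending
before $k$), which is provably equivalent to a full restart; the test suite
checks equality with an independently coded brute-force restart pruner.
Per-chromosome correlation matrices are held in memory, which is
comfortable to a few thousand SNPs per chromosome — the intended desk
scale.

The gene-level CCA scan uses the *pruned* SNP sets (as the statistic's
$\Sigma_{XX}$ must be well-conditioned), capped at
`max_gene_snps = 50` per gene keeping the highest-MAF SNPs — a
deterministic, logged rule for genes whose SNP count would approach $N$ or
make $\hat\Sigma_{XX}$ ill-conditioned. The VEGAS-style validation test
deliberately uses the *unpruned* annotated sets instead, because its
multivariate-normal null models LD directly.

## The gene-based validation test

`run_gene_tests()` reimplements the VEGAS statistic: per gene, the sum of
per-SNP $\chi^2 = (\beta/\mathrm{SE})^2$ over all annotated SNPs, with the
null distribution obtained by drawing $z \sim \mathcal N(0, R)$ for the
gene's (shrunk) LD correlation matrix $R$ and summing squares. The
empirical p-value uses the plus-one correction
$(\#\{T_{null} \ge T\} + 1)/(n_{sims}+1)$, so it is never zero and is
floored at $1/(n_{sims}+1)$. Simulation counts start at $10^4$ and escalate
tenfold (to a configurable cap, default $10^6$) while the p-value is below
$10\alpha$, concentrating effort on borderline genes. The plain all-SNP
statistic with a 0 kb gene flank is implemented; top-percentage variants
are out of scope. Under identity LD the test is exactly the
$\chi^2_k$ tail, which the suite verifies at $k \in \{1, 3, 10\}$.

## The synthetic-data generator

`simulate_panel()` / `simulate_bundle()` emulate the statistical structure
the pipeline assumes, with known ground truth:

* **LD**: per block of `block_size` SNPs, two latent haplotype vectors
  follow a first-order autoregressive Gaussian with adjacent correlation
  `rho`, thresholded at the MAF quantile and summed into 0/1/2 dosages.
  This gives Hardy–Weinberg margins and controllable within-block $r^2$
  with independence across blocks. One caveat is intrinsic to thresholding:
  a pair with very different MAFs cannot reach high allelic $r^2$ no matter
  how large the latent correlation, so realized LD is attenuated for
  MAF-mismatched pairs — as it is in real genotypes.
* **Phenotypes**: additive in the standardized causal dosages
  (shared/pleiotropic and per-trait private sets) plus bivariate noise with
  correlation `pheno_corr`; re-standardized to unit variance.
* **Studies**: two disjoint cohorts, each analyzed for one trait by exact
  closed-form univariate OLS (`compute_univariate_gwas()`); the reference
  panel is a third disjoint sample, with the option of reusing study
  genotypes for oracle-equivalence checks.

Defaults describe a realistic desk-scale experiment: cohorts of 5000,
panels of 1000, 1000 SNPs in 10-SNP blocks with `rho = 0.7`, MAF uniform
on (0.05, 0.5), standardized causal effects of 0.15, `pheno_corr = 0.2`.
What the generator does *not* model: population structure and genomic
inflation, imputation error, missing dosages, multi-allelic variants,
sample overlap between studies. Calibration and power results on simulated
data therefore show the statistics behave as designed under clean
assumptions — not that real meta-analyses are free of confounding.

Two deliberate choices in the verification experiments: the SNP-level null
calibration uses `rho = 0` (independent SNPs) so the binomial error bound
on the rejection rate is exact, while the 200-gene null calibration of the
gene test uses LD blocks (`rho = 0.5`) — there the genes, not the SNPs, are
the independent units. The oracle-equivalence experiments use per-SNP
standardized effects around 0.1, the complex-trait regime where the
$\beta^{STD} \approx r$ approximation is accurate (see above); at much
larger effects the known $1/\sqrt{1-r^2}$ distortion dominates and the
summary-based $r_1$ drifts upward.

## Numerical details

* Canonical correlations are computed as singular values of the whitened
  cross block $K_X^{-T}\,\Sigma_{XY}\,K_Y^{-1}$ (Cholesky whitening), then
  clipped to $[0,1]$; an eigendecomposition of
  $\Sigma_{XX}^{-1}\Sigma_{XY}\Sigma_{YY}^{-1}\Sigma_{XY}^T$ is the
  independent cross-check in the tests.
* $\Lambda$ is floored at $10^{-300}$ and p-values at the smallest positive
  double, keeping them in $(0, 1]$.
* Harmonization drops palindromic (A/T, C/G) SNPs unconditionally — the
  conservative standard, since strand cannot be resolved without
  frequencies — aligns swapped and strand-complemented alleles (flipping
  the sign of $\beta$ where the effect allele switches), and drops anything
  else as irreconcilable. Duplicate SNP IDs keep the first occurrence.
  Missing per-SNP sample sizes fall back to the study total.
* Gene coordinates are 1-based inclusive (glist dialect); SNPs in
  overlapping genes count for each gene; the gene flank defaults to 0 kb
  and is configurable.

## A worked run

```{r, eval = FALSE}
cfg <- sim_config(n_snps = 500, n_ref = 600, n_study_1 = 2000,
                  n_study_2 = 2000, seed = 17)
bundle <- simulate_bundle(cfg, "inputs")
pcfg <- pipeline_config(
  study_1 = bundle$paths$study_1, study_2 = bundle$paths$study_2,
  panel = bundle$paths$panel, panel_map = bundle$paths$panel_map,
  gene_ranges = bundle$paths$gene_ranges, outdir = "out")
res <- run_pipeline(pcfg)
sum(res$snp_scan$SIG); sum(res$gene_scan$SIG)
bundle$truth$pleiotropic_genes   # compare with res$triangulated
```

The run directory contains every stage table (`snp_scan.tsv`,
`gene_scan.tsv`, the two gene-test tables, Venn membership/regions, the
triangulated gene list) and `manifest.json` recording each stage's record
counts, drop reasons and the exact thresholds applied, so a rerun with the
same configuration is verifiably identical.

## Known limitations

* Only the leading canonical correlation is tested per unit; no sequential
  dimension tests, colocalization, or conditional analysis.
* $\Sigma_{YY}$ from effect correlations absorbs sample overlap between
  studies into the trait correlation; the package does not attempt to
  separate the two.
* The Bartlett approximation assumes $N \gg g + p$; the gene scan enforces
  $g \le \min(\texttt{max\_gene\_snps}, N - p - 2)$.
* External evidence (drug-target lists, TWAS hits, known-disease genes,
  interaction edges) enters only as prepared files; no database queries or
  identifier alias resolution are performed.
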