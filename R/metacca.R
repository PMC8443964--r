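# Summary-statistic canonical correlation analysis: covariance-block
# assembly, canonical correlations, Bartlett chi-square significance, and
# the SNP-level and gene-level scans.

#' Analysis configuration for the CCA scans
#'
#' @param N effective sample size; the smallest total sample size among the
#'   included studies is the conservative choice when studies differ.
#' @param alpha family-wise error target for the Bonferroni threshold
#'   (default 0.01).
#' @param max_gene_snps cap on SNPs analyzed jointly per gene; genes over
#'   the cap keep the SNPs of highest reference-panel MAF (default 50).
#' @param shrink_step,eps shrinkage grid step and eigenvalue floor passed
#'   to [shrink_to_pd()].
#' @param seed integer seed for any downstream randomness.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(N, alpha = 0.01, max_gene_snps = 50L,
                            shrink_step = 0.01, eps = 1e-8, seed = 1L) {
  N <- as.numeric(N)
  if (!is.finite(N) || N < 3) stop("N must be >= 3")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (max_gene_snps < 1L) stop("max_gene_snps must be >= 1")
  structure(list(N = N, alpha = alpha,
                 max_gene_snps = as.integer(max_gene_snps),
                 shrink_step = shrink_step, eps = eps,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Standardized effect matrix (genotype-phenotype covariance block)
#'
#' Builds the g x p matrix whose column k holds
#' `standardize_beta(beta_k, se_k, n_k)` for study k, rows in the genomic
#' order of the harmonized pair. These standardized effects approximate the
#' genotype-phenotype correlations, i.e. the cross-covariance block of the
#' joint correlation matrix used by the CCA scans.
#'
#' @param pair a non-empty [harmonize()] result.
#' @return g x 2 numeric matrix, rownames = SNP IDs, colnames = study
#'   labels.
#' @export
build_sigma_xy <- function(pair) {
  stopifnot(inherits(pair, "harmonized_pair"))
  if (!nrow(pair)) stop("empty harmonized pair")
  s <- cbind(standardize_beta(pair$beta_1, pair$se_1, pair$n_1),
             standardize_beta(pair$beta_2, pair$se_2, pair$n_2))
  rownames(s) <- pair$snp
  colnames(s) <- attr(pair, "labels") %||% c("study_1", "study_2")
  s
}

#' Phenotypic correlation from standardized effects
#'
#' Estimates the p x p trait correlation matrix as the Pearson correlation
#' between the studies' standardized-effect vectors across all g SNPs:
#' under the null most effects are noise whose between-study correlation
#' reflects phenotypic correlation (plus sample overlap, absent for
#' disjoint cohorts). The estimate is shrunk to positive definiteness.
#'
#' @param s standardized effect matrix from [build_sigma_xy()], g >= 3.
#' @param shrink_step,eps passed to [shrink_to_pd()].
#' @return a `pheno_corr`: matrix `R`, shrinkage `lambda`, `n_snps`.
#' @export
estimate_sigma_yy <- function(s, shrink_step = 0.01, eps = 1e-8) {
  if (nrow(s) < 3L) stop("at least 3 SNPs required to estimate trait correlation")
  r <- stats::cor(s)
  diag(r) <- 1
  sh <- shrink_to_pd(r, step = shrink_step, eps = eps)
  structure(list(R = sh$matrix, lambda = sh$lambda, n_snps = nrow(s)),
            class = "pheno_corr")
}

#' Assemble the full joint covariance matrix
#'
#' Stacks the genotype block, the genotype-phenotype block and the
#' phenotype block into the (g+p) x (g+p) joint correlation matrix; if the
#' result is not positive definite it is shrunk as a whole and the
#' shrinkage recorded.
#'
#' @param xx g x g genotype correlation ([genotype_corr()] or matrix).
#' @param xy g x p standardized effect rows for the SNP set.
#' @param yy p x p trait correlation ([estimate_sigma_yy()] or matrix).
#' @param shrink_step,eps passed to [shrink_to_pd()].
#' @return list with `sigma` (the block matrix) and `lambda`.
#' @export
assemble_full_cov <- function(xx, xy, yy, shrink_step = 0.01, eps = 1e-8) {
  xx <- .mat(xx); yy <- .mat(yy); xy <- as.matrix(xy)
  if (nrow(xy) != nrow(xx) || ncol(xy) != nrow(yy))
    stop("dimension mismatch between covariance blocks")
  sigma <- rbind(cbind(xx, xy), cbind(t(xy), yy))
  ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  lambda <- 0
  if (ev < eps) {
    sh <- shrink_to_pd(sigma, step = shrink_step, eps = eps)
    sigma <- sh$matrix
    lambda <- sh$lambda
  }
  list(sigma = sigma, lambda = lambda)
}

#' Canonical correlations from covariance blocks
#'
#' The canonical correlations between the genotype set and the phenotype
#' set are the singular values of the whitened cross-block
#' `Kx^-T %*% xy %*% Ky^-1` (Kx, Ky upper Cholesky factors of xx, yy) —
#' equivalently the square roots of the eigenvalues of
#' `solve(xx) %*% xy %*% solve(yy) %*% t(xy)`. Values are clipped to
#' \[0, 1\].
#'
#' @param xx g x g positive-definite genotype correlation.
#' @param xy g x p cross block.
#' @param yy p x p positive-definite trait correlation.
#' @return numeric vector of min(g, p) canonical correlations, descending.
#' @export
canonical_corr <- function(xx, xy, yy) {
  xx <- .mat(xx); yy <- .mat(yy)
  xy <- matrix(as.numeric(xy), nrow = nrow(xx))
  kx <- tryCatch(chol(xx), error = function(e)
    stop("genotype block not positive definite; apply shrink_to_pd() first"))
  ky <- tryCatch(chol(yy), error = function(e)
    stop("phenotype block not positive definite; apply shrink_to_pd() first"))
  a <- forwardsolve(t(kx), xy)
  b <- t(forwardsolve(t(ky), t(a)))
  d <- svd(b, nu = 0, nv = 0)$d
  pmin(pmax(d, 0), 1)
}

#' Bartlett chi-square significance of canonical correlations
#'
#' Wilks' Lambda `prod(1 - r_i^2)` is converted to Bartlett's statistic
#' `-(N - 1 - (g + p + 1)/2) * log(Lambda)`, referred to a chi-square with
#' `g * p` degrees of freedom. At g = p = 1 this reduces to the classical
#' test of a Pearson correlation, which is why it is adopted here: it needs
#' only N, g and p, all available from summary data.
#'
#' @param r canonical correlation(s).
#' @param N effective sample size, must exceed g + p + 1.
#' @param g,p numbers of genotypic and phenotypic variables.
#' @return list with `statistic`, `df`, `p_value` (clipped into (0, 1\]).
#' @export
cca_pvalue <- function(r, N, g, p) {
  if (N <= g + p + 1) stop("N must exceed g + p + 1")
  lambda <- prod(pmax(1 - r^2, 1e-300))
  stat <- max(-(N - 1 - (g + p + 1) / 2) * log(lambda), 0)
  df <- g * p
  pv <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df,
       p_value = max(pv, .Machine$double.xmin))
}

#' Single-SNP, multi-phenotype CCA scan
#'
#' For each SNP (g = 1, genotype block \[1\]) the canonical correlation
#' with the phenotype set is `sqrt(b %*% solve(yy) %*% b)` for its
#' standardized-effect row b, with Bartlett chi-square significance and a
#' Bonferroni flag at `cfg$alpha / m`.
#'
#' @param s standardized effect matrix ([build_sigma_xy()]).
#' @param yy trait correlation ([estimate_sigma_yy()] or matrix).
#' @param cfg an [analysis_config()].
#' @param map optional data.frame (`snp`, `chr`, `pos`) adding genomic
#'   columns and ordering (e.g. the harmonized pair).
#' @return data.frame `SNP (CHR POS) R PVAL NEGLOG10P SIG`, attribute
#'   `threshold` = the Bonferroni threshold applied.
#' @export
univariate_snp_scan <- function(s, yy, cfg, map = NULL) {
  stopifnot(inherits(cfg, "analysis_config"))
  yi <- solve(.mat(yy))
  p <- ncol(s)
  q <- rowSums((s %*% yi) * s)
  r <- sqrt(pmin(pmax(q, 0), 1))
  if (cfg$N <= 1 + p + 1) stop("N must exceed g + p + 1")
  stat <- pmax(-(cfg$N - 1 - (1 + p + 1) / 2) * log(pmax(1 - r^2, 1e-300)), 0)
  pv <- pmax(stats::pchisq(stat, df = p, lower.tail = FALSE),
             .Machine$double.xmin)
  thr <- bonferroni_threshold(cfg$alpha, nrow(s))
  out <- data.frame(SNP = rownames(s), R = r, PVAL = pv,
                    NEGLOG10P = -log10(pv), SIG = pv < thr,
                    stringsAsFactors = FALSE)
  if (!is.null(map)) {
    i <- match(out$SNP, map$snp)
    out$CHR <- map$chr[i]
    out$POS <- map$pos[i]
    out <- out[order(out$CHR, out$POS),
               c("SNP", "CHR", "POS", "R", "PVAL", "NEGLOG10P", "SIG")]
  }
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Multi-SNP (gene-level), multi-phenotype CCA scan
#'
#' Per gene: its pruned SNP set forms the genotype block (reference-panel
#' correlation, shrunk to positive definiteness); genes over
#' `cfg$max_gene_snps` keep the SNPs of highest reference MAF (the block
#' must also stay well below N, so g is additionally capped at
#' N - p - 2). Reports the leading canonical correlation, its Bartlett
#' p-value, the SNP count used, and the shrinkage applied. Genes with no
#' usable SNP are skipped and listed in the `skipped` attribute.
#'
#' @param s standardized effect matrix restricted to the pruned SNP set.
#' @param panel a [ref_panel()].
#' @param yy trait correlation.
#' @param annotation a [annotate_snps()] result.
#' @param cfg an [analysis_config()].
#' @return data.frame `GENE CHR START END NSNPS R1 PVAL LAMBDA SIG` with
#'   attributes `threshold` and `skipped`.
#' @export
gene_level_scan <- function(s, panel, yy, annotation, cfg) {
  stopifnot(inherits(cfg, "analysis_config"),
            inherits(annotation, "snp_annotation"))
  p <- ncol(s)
  gmax <- min(cfg$max_gene_snps, as.integer(cfg$N) - p - 2L)
  genes <- annotation$genes
  rows <- vector("list", nrow(genes))
  skipped <- character(0)
  for (i in seq_len(nrow(genes))) {
    gname <- genes$GENE[i]
    snps <- intersect(annotation$gene_snps[[gname]], rownames(s))
    snps <- intersect(snps, panel$map$SNP)
    if (!length(snps)) {
      skipped <- c(skipped, gname)
      next
    }
    if (length(snps) > gmax) {
      maf <- panel$maf[match(snps, panel$map$SNP)]
      snps <- snps[order(maf, decreasing = TRUE)[seq_len(gmax)]]
      snps <- snps[order(match(snps, panel$map$SNP))]  # restore genomic order
    }
    xx <- genotype_corr(panel, snps)
    sh <- shrink_to_pd(xx$R, step = cfg$shrink_step, eps = cfg$eps)
    r <- canonical_corr(sh$matrix, s[snps, , drop = FALSE], yy)
    pv <- cca_pvalue(r, cfg$N, g = length(snps), p = p)
    rows[[i]] <- data.frame(GENE = gname, CHR = genes$CHR[i],
                            START = genes$START[i], END = genes$END[i],
                            NSNPS = length(snps), R1 = r[1],
                            PVAL = pv$p_value, LAMBDA = sh$lambda,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no gene had any SNP with summary statistics")
  thr <- bonferroni_threshold(cfg$alpha, nrow(out))
  out$SIG <- out$PVAL < thr
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  attr(out, "skipped") <- skipped
  out
}
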