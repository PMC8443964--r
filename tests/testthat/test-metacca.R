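make_pair <- function(beta1, se1, beta2, se2, n1 = 1000, n2 = 1000) {
  m <- length(beta1)
  a <- read_sumstats(write_sumstats_file(
    sumstats_df(sprintf("rs%03d", 1:m), beta1, se1, n = n1)), label = "t1")
  b <- read_sumstats(write_sumstats_file(
    sumstats_df(sprintf("rs%03d", 1:m), beta2, se2, n = n2)), label = "t2")
  harmonize(a, b)
}

test_that("the standardized effect matrix applies the per-column formula", {
  pair <- make_pair(0.1, 0.02, -0.2, 0.04, n1 = 100, n2 = 100)
  s <- build_sigma_xy(pair)
  expect_equal(unname(s[1, ]), c(0.5, -0.5))
  expect_identical(rownames(s), "rs001")
  pair0 <- pair[0, ]
  class(pair0) <- class(pair)
  expect_error(build_sigma_xy(pair0), "empty")
})

test_that("trait correlation is the column correlation, shrunk to PD", {
  set.seed(71)
  x <- rnorm(100)
  s <- cbind(x, x)
  yy <- estimate_sigma_yy(s)
  expect_gt(yy$lambda, 0)  # perfect correlation needs shrinkage
  expect_equal(yy$R[1, 2], (1 - yy$lambda) * 1)
  expect_gte(min(eigen(yy$R, symmetric = TRUE)$values), 1e-8)

  yn <- estimate_sigma_yy(cbind(x, -x))
  expect_equal(yn$R[1, 2], -(1 - yn$lambda))

  s2 <- matrix(rnorm(2 * 5000), ncol = 2)
  y2 <- estimate_sigma_yy(s2)
  expect_lt(abs(y2$R[1, 2]), 0.04)
  expect_equal(y2$lambda, 0)
  expect_error(estimate_sigma_yy(s2[1:2, ]), "3 SNPs")
})

test_that("the assembled joint covariance is symmetric and PD", {
  set.seed(72)
  p <- simulate_panel(small_cfg(n_ref = 500L, n_snps = 10L, rho = 0.6))
  xx <- genotype_corr(p, p$map$SNP[1:4])
  xy <- matrix(rnorm(8, sd = 0.05), 4, 2)
  yy <- estimate_sigma_yy(matrix(rnorm(200), ncol = 2))
  full <- assemble_full_cov(xx, xy, yy)
  expect_identical(full$sigma, t(full$sigma))
  expect_gte(min(eigen(full$sigma, symmetric = TRUE)$values), 1e-8)
  # zero cross block makes it block-diagonal
  bd <- assemble_full_cov(diag(1), matrix(0, 1, 2), diag(2))
  expect_equal(bd$sigma, diag(3))
  expect_error(assemble_full_cov(diag(2), matrix(0, 1, 2), diag(2)),
               "dimension")
})

test_that("canonical correlations match the eigen oracle", {
  expect_equal(canonical_corr(diag(1), matrix(0.3), diag(1)), 0.3)
  expect_equal(canonical_corr(diag(3), matrix(0, 3, 2), diag(2)), c(0, 0))

  set.seed(73)
  for (rep in 1:5) {
    xx <- crossprod(matrix(rnorm(9), 3)) + diag(3)
    d <- sqrt(diag(xx)); xx <- xx / outer(d, d)
    yy <- crossprod(matrix(rnorm(4), 2)) + diag(2)
    d <- sqrt(diag(yy)); yy <- yy / outer(d, d)
    xy <- matrix(rnorm(6, sd = 0.2), 3, 2)
    r <- canonical_corr(xx, xy, yy)
    # independent route: eigenvalues of xx^-1 xy yy^-1 xy^T
    ev <- eigen(solve(xx) %*% xy %*% solve(yy) %*% t(xy))$values
    oracle <- sort(sqrt(pmin(pmax(Re(ev), 0), 1)), decreasing = TRUE)[1:2]
    expect_equal(r, oracle, tolerance = 1e-8)
  }
  expect_error(canonical_corr(matrix(c(1, 1, 1, 1), 2), matrix(0, 2, 2),
                              diag(2)), "positive definite")
})

test_that("canonical correlations agree with individual-level CCA", {
  # reference panel = study genotypes, phenotypes fully observed
  devs <- c()
  for (seed in c(81L, 82L)) {
    cfg <- small_cfg(n_ref = 2000L, n_snps = 5L, block_size = 5L,
                     rho = 0.4, n_pleiotropic = 2L, n_private_1 = 0L,
                     n_private_2 = 0L, effect_size = 0.1,
                     pheno_corr = 0.3, seed = seed)
    p <- simulate_panel(cfg)
    truth <- make_ground_truth(p, cfg)
    y <- simulate_phenotypes(p$geno, truth, cfg, seed = seed + 100L)
    s <- cbind(
      standardize_beta(compute_univariate_gwas(p$geno, y[, 1])$beta,
                       compute_univariate_gwas(p$geno, y[, 1])$se, 2000),
      standardize_beta(compute_univariate_gwas(p$geno, y[, 2])$beta,
                       compute_univariate_gwas(p$geno, y[, 2])$se, 2000))
    r1 <- canonical_corr(genotype_corr(p, p$map$SNP), s, cor(y))[1]
    r1_ind <- cancor(p$geno, y)$cor[1]
    devs <- c(devs, abs(r1 - r1_ind))
  }
  expect_lt(max(devs), 0.02)
})

test_that("Bartlett p-values are calibrated at the scalar limit", {
  null <- cca_pvalue(c(0, 0), N = 100, g = 2, p = 2)
  expect_equal(null$statistic, 0)
  expect_equal(null$p_value, 1)

  # monotone decreasing in r1
  ps <- sapply(c(0.05, 0.1, 0.2, 0.4), function(r)
    cca_pvalue(r, N = 500, g = 2, p = 2)$p_value)
  expect_true(all(diff(ps) < 0))

  # scalar case vs the classical correlation t-test
  r <- 0.05; N <- 10000
  p_cca <- cca_pvalue(r, N, 1, 1)$p_value
  tstat <- r * sqrt((N - 2) / (1 - r^2))
  p_t <- 2 * pt(-abs(tstat), df = N - 2)
  expect_lt(max(p_cca / p_t, p_t / p_cca), 1.05)

  expect_error(cca_pvalue(0.1, N = 4, g = 2, p = 2), "N must exceed")
})

test_that("the SNP scan reduces to the closed form at identity Sigma_YY", {
  set.seed(74)
  s <- matrix(runif(200, -0.5, 0.5), 100, 2,
              dimnames = list(sprintf("rs%03d", 1:100), NULL))
  cfg <- analysis_config(N = 1000)
  scan <- univariate_snp_scan(s, diag(2), cfg)
  expect_equal(scan$R, unname(sqrt(rowSums(s^2))), tolerance = 1e-8)
  # and each row matches the full canonical_corr machinery
  r5 <- canonical_corr(diag(1), s[5, , drop = FALSE], diag(2))
  expect_equal(scan$R[5], r5, tolerance = 1e-12)
  # null rows give r = 0, p = 1
  s0 <- rbind(s, null = c(0, 0))
  scan0 <- univariate_snp_scan(s0, diag(2), cfg)
  expect_equal(scan0$R[101], 0)
  expect_equal(scan0$PVAL[101], 1)
})

test_that("scan results are invariant to rescaling a study's beta and se", {
  pair <- make_pair(c(0.1, -0.05, 0.02), c(0.02, 0.03, 0.04),
                    c(0.2, 0.01, -0.1), c(0.05, 0.02, 0.03))
  s1 <- build_sigma_xy(pair)
  pair2 <- pair
  pair2$beta_1 <- pair2$beta_1 * 3.7
  pair2$se_1 <- pair2$se_1 * 3.7
  class(pair2) <- class(pair)
  attr(pair2, "labels") <- attr(pair, "labels")
  s2 <- build_sigma_xy(pair2)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("a pleiotropic SNP attains the smallest scan p-value", {
  cfg <- small_cfg(n_snps = 200L, n_ref = 500L, n_study_1 = 5000L,
                   n_study_2 = 5000L, rho = 0, n_pleiotropic = 1L,
                   n_private_1 = 0L, n_private_2 = 0L,
                   effect_size = 0.15, seed = 91L)
  b <- simulate_bundle(cfg, tempfile("power"))
  s1 <- read_sumstats(b$paths$study_1)
  s2 <- read_sumstats(b$paths$study_2)
  pair <- harmonize(s1, s2)
  s <- build_sigma_xy(pair)
  yy <- estimate_sigma_yy(s)
  scan <- univariate_snp_scan(s, yy, analysis_config(N = 5000), map = pair)
  expect_identical(scan$SNP[which.min(scan$PVAL)], b$truth$pleiotropic)
})

test_that("gene scan: one-SNP genes equal the SNP scan; null genes are null", {
  p <- simulate_panel(small_cfg(n_ref = 800L, n_snps = 12L,
                                block_size = 4L, rho = 0.5, seed = 92L))
  s <- matrix(c(0.03, -0.01, 0.02, 0.05, 0, 0.01, -0.02, 0.04, 0.02,
                0.01, 0.03, -0.03,
                0.01, 0.02, -0.02, 0.03, 0, -0.01, 0.02, 0.01, -0.01,
                0.02, 0.01, 0.02), 12, 2,
              dimnames = list(p$map$SNP, NULL))
  genes <- data.frame(CHR = 1L, START = c(1000L, 2000L),
                      END = c(1000L, 12000L), GENE = c("ONE", "REST"))
  pair <- data.frame(snp = p$map$SNP, chr = 1L, pos = p$map$POS)
  ann <- annotate_snps(pair, genes)
  cfg <- analysis_config(N = 2000)
  gs <- gene_level_scan(s, p, diag(2), ann, cfg)
  snp_scan <- univariate_snp_scan(s, diag(2), cfg)
  expect_equal(gs$R1[gs$GENE == "ONE"], snp_scan$R[1], tolerance = 1e-10)
  expect_equal(gs$NSNPS[gs$GENE == "ONE"], 1L)

  # all-zero effects: r1 = 0, p = 1
  s0 <- s; s0[] <- 0
  gs0 <- gene_level_scan(s0, p, diag(2), ann, cfg)
  expect_equal(gs0$R1, c(0, 0))
  expect_equal(gs0$PVAL, c(1, 1))
})

test_that("gene scan caps the SNP block at the highest-MAF subset", {
  p <- simulate_panel(small_cfg(n_ref = 500L, n_snps = 10L,
                                block_size = 10L, rho = 0.3, seed = 93L))
  s <- matrix(rnorm(20, sd = 0.02), 10, 2, dimnames = list(p$map$SNP, NULL))
  genes <- data.frame(CHR = 1L, START = 1000L, END = 10000L, GENE = "BIG")
  ann <- annotate_snps(data.frame(snp = p$map$SNP, chr = 1L,
                                  pos = p$map$POS), genes)
  gs <- gene_level_scan(s, p, diag(2), ann,
                        analysis_config(N = 2000, max_gene_snps = 4L))
  expect_equal(gs$NSNPS, 4L)
})
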