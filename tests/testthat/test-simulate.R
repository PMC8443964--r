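test_that("invalid simulation configurations are rejected", {
  expect_error(small_cfg(n_snps = 0L), "n_snps")
  expect_error(small_cfg(rho = 1), "rho")
  expect_error(small_cfg(maf_range = c(0, 0.5)), "maf_range")
  expect_error(small_cfg(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(small_cfg(n_pleiotropic = 200L), "exceed")
  expect_error(small_cfg(pheno_corr = 1.5), "pheno_corr")
})

test_that("panel simulation is deterministic and respects dosage coding", {
  cfg <- small_cfg()
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$geno, p2$geno)
  expect_true(all(p1$geno %in% 0:2))
  expect_identical(dim(p1$geno), c(cfg$n_ref, cfg$n_snps))
  expect_false(any(p1$maf == 0))
  # a different seed changes the draw
  p3 <- simulate_panel(small_cfg(seed = 12L))
  expect_false(identical(p1$geno, p3$geno))
})

test_that("empirical MAF tracks the target within sampling error", {
  cfg <- small_cfg(n_ref = 1000L, n_snps = 200L)
  p <- simulate_panel(cfg)
  bound <- 4 * sqrt(p$maf_target * (1 - p$maf_target) / (2 * cfg$n_ref))
  expect_true(all(abs(p$freq_a1 - p$maf_target) <= bound))
})

test_that("AR blocks create within-block LD; rho = 0 gives independence", {
  # matched MAFs isolate the AR construction: mismatched margins attenuate
  # the allelic correlation of thresholded variables below the latent rho
  p <- simulate_panel(small_cfg(n_ref = 1000L, n_snps = 40L,
                                block_size = 2L, rho = 0.99,
                                maf_range = c(0.3, 0.3)))
  within <- sapply(seq(1, 39, by = 2), function(i)
    ld_r2(p, p$map$SNP[i], p$map$SNP[i + 1]))
  expect_true(all(within > 0.5))

  p0 <- simulate_panel(small_cfg(n_ref = 1000L, n_snps = 40L, rho = 0))
  pairs <- combn(40, 2)[, seq(1, 700, by = 7)]
  r2s <- apply(pairs, 2, function(ij)
    ld_r2(p0, p0$map$SNP[ij[1]], p0$map$SNP[ij[2]]))
  expect_lt(mean(r2s), 3 / 1000)
})

test_that("phenotype generation honours noise correlation and effects", {
  cfg <- small_cfg(n_pleiotropic = 0L, n_private_1 = 0L, n_private_2 = 0L,
                   pheno_corr = 0.8)
  p <- simulate_panel(cfg)
  g <- simulate_cohort(p, 5000L, seed = 21L)
  truth <- make_ground_truth(p, cfg)
  y <- simulate_phenotypes(g, truth, cfg, seed = 22L)
  expect_equal(unname(colMeans(y)), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(y, 2, sd)), c(1, 1), tolerance = 1e-10)
  expect_lt(abs(cor(y[, 1], y[, 2]) - 0.8), 0.05)

  cfg0 <- small_cfg(n_pleiotropic = 0L, n_private_1 = 0L,
                    n_private_2 = 0L, pheno_corr = 0)
  y0 <- simulate_phenotypes(g, make_ground_truth(p, cfg0), cfg0, seed = 23L)
  expect_lt(abs(cor(y0[, 1], y0[, 2])), 4 / sqrt(nrow(y0)))
})

test_that("a single causal SNP's effect is recovered by regression", {
  cfg <- small_cfg(n_pleiotropic = 1L, n_private_1 = 0L,
                   n_private_2 = 0L, effect_size = 0.3)
  p <- simulate_panel(cfg)
  g <- simulate_cohort(p, 4000L, seed = 31L)
  truth <- make_ground_truth(p, cfg)
  y <- simulate_phenotypes(g, truth, cfg, seed = 32L)
  xs <- as.vector(scale(g[, truth$pleiotropic]))
  fit <- lm(y[, 1] ~ xs)
  est <- coef(summary(fit))["xs", ]
  # effect applied before restandardization; the attenuation is sd(y_raw)
  atten <- sqrt(1 + 0.3^2)
  expect_lt(abs(est["Estimate"] - 0.3 / atten), 3 * est["Std. Error"])
})

test_that("unknown causal SNPs raise a consistency error", {
  cfg <- small_cfg()
  p <- simulate_panel(cfg)
  g <- simulate_cohort(p, 100L, seed = 1L)
  truth <- make_ground_truth(p, cfg)
  truth$effects_1 <- c(truth$effects_1, nope = 0.1)
  expect_error(simulate_phenotypes(g, truth, cfg), "absent")
})

test_that("univariate GWAS matches OLS identities", {
  set.seed(41)
  n <- 1000L
  g <- matrix(rbinom(n * 5, 2, 0.3), n, 5,
              dimnames = list(NULL, paste0("s", 1:5)))
  y <- rnorm(n)
  gw <- compute_univariate_gwas(g, y)
  # beta of standardized variables equals the Pearson correlation
  gs <- scale(g[, 1]); ys <- as.vector(scale(y))
  gw1 <- compute_univariate_gwas(matrix(gs, dimnames = list(NULL, "s1")), ys)
  expect_equal(gw1$beta, cor(gs, ys)[1, 1], tolerance = 1e-10)
  # asymptotic SE for standardized variables under the null: 1/sqrt(n)
  expect_lt(abs(gw1$se * sqrt(n) - 1), 0.1)
  # agreement with lm() on raw dosages
  fit <- coef(summary(lm(y ~ g[, 3])))
  expect_equal(gw$beta[3], fit[2, 1], tolerance = 1e-12)
  expect_equal(gw$se[3], fit[2, 2], tolerance = 1e-12)
})

test_that("null SNPs show no systematic effect over replicates", {
  set.seed(42)
  betas <- replicate(500, {
    g <- rbinom(200, 2, 0.3)
    y <- rnorm(200)
    gw <- compute_univariate_gwas(matrix(g, dimnames = list(NULL, "s1")), y)
    gw$beta
  })
  expect_lt(abs(mean(betas)), 4 * sd(betas) / sqrt(500))
})

test_that("monomorphic SNPs are flagged with undefined SE", {
  g <- cbind(s1 = rep(1L, 50), s2 = rbinom(50, 2, 0.4))
  gw <- compute_univariate_gwas(g, rnorm(50))
  expect_true(gw$monomorphic[1])
  expect_true(is.na(gw$se[1]))
  expect_false(gw$monomorphic[2])
})

test_that("study files round-trip through write and read", {
  cfg <- small_cfg(n_snps = 50L)
  b <- simulate_bundle(cfg, tempfile("bundle"))
  s <- read_sumstats(b$paths$study_1, label = "s1")
  expect_identical(s$data$snp, b$panel$map$SNP)
  orig <- compute_univariate_gwas(
    simulate_cohort(b$panel, cfg$n_study_1, seed = 1L), rnorm(cfg$n_study_1))
  # line count: header + one line per SNP
  expect_length(readLines(b$paths$study_1), 50L + 1L)
  reread <- read_sumstats(b$paths$study_1)
  expect_equal(reread$data$beta, s$data$beta, tolerance = 1e-6)

  # empty results give a header-only file and an empty read
  path <- tempfile(fileext = ".tsv")
  write_study(orig[0, ], b$panel$map, path)
  expect_length(readLines(path), 1L)
})

test_that("bundles are reproducible and internally consistent", {
  cfg <- small_cfg(n_snps = 60L)
  b1 <- simulate_bundle(cfg, tempfile("b1"))
  b2 <- simulate_bundle(cfg, tempfile("b2"))
  expect_identical(b1$panel$geno, b2$panel$geno)
  expect_identical(readLines(b1$paths$study_1), readLines(b2$paths$study_1))
  expect_true(all(b1$truth$pleiotropic %in% b1$panel$map$SNP))
  expect_true(all(b1$truth$pleiotropic_genes %in% b1$genes$GENE))
  # panel round-trips through its files
  p <- read_panel(b1$paths$panel, b1$paths$panel_map)
  expect_identical(unname(p$geno), unname(b1$panel$geno))
})
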