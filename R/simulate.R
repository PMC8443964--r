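# Synthetic GWAS generator: LD-blocked genotype panels, two correlated
# phenotypes with shared (pleiotropic) and private causal SNPs, and the
# per-SNP univariate regression summary statistics of two disjoint cohorts.

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic GWAS generator. Genotypes are
#' drawn per LD block from a latent Gaussian with first-order autoregressive
#' (AR(1)) correlation `rho` between adjacent SNPs, thresholded into two
#' haplotypes at the MAF quantile, so dosages are Hardy-Weinberg binomial
#' with controllable pairwise LD and no coalescent machinery. Phenotypes are
#' additive in the standardized causal dosages plus bivariate Gaussian noise
#' with correlation `pheno_corr`.
#'
#' @param n_ref number of reference-panel individuals.
#' @param n_study_1,n_study_2 cohort sizes of the two (disjoint) GWAS.
#' @param n_snps total number of SNPs.
#' @param block_size SNPs per LD block (>= 1).
#' @param rho within-block adjacent-SNP latent correlation, in (-1, 1).
#' @param maf_range length-2 minor-allele-frequency bounds in (0, 0.5].
#' @param n_pleiotropic number of causal SNPs shared by both phenotypes.
#' @param n_private_1,n_private_2 causal SNPs private to each phenotype.
#' @param effect_size per-causal-SNP effect on the standardized-genotype
#'   scale (applied before the phenotype is re-standardized).
#' @param pheno_corr residual correlation between the two phenotypes,
#'   in \[-1, 1\].
#' @param seed integer seed; all randomness of the generator flows from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_snps = 100, n_ref = 200, seed = 1)
sim_config <- function(n_ref = 1000L, n_study_1 = 5000L, n_study_2 = 5000L,
                       n_snps = 1000L, block_size = 10L, rho = 0.7,
                       maf_range = c(0.05, 0.5),
                       n_pleiotropic = 10L, n_private_1 = 10L,
                       n_private_2 = 10L, effect_size = 0.15,
                       pheno_corr = 0.2, seed = 42L) {
  cfg <- list(n_ref = as.integer(n_ref), n_study_1 = as.integer(n_study_1),
              n_study_2 = as.integer(n_study_2), n_snps = as.integer(n_snps),
              block_size = as.integer(block_size), rho = rho,
              maf_range = as.numeric(maf_range),
              n_pleiotropic = as.integer(n_pleiotropic),
              n_private_1 = as.integer(n_private_1),
              n_private_2 = as.integer(n_private_2),
              effect_size = effect_size, pheno_corr = pheno_corr,
              seed = as.integer(seed))
  if (cfg$n_snps < 1L || cfg$n_ref < 2L)
    stop("invalid sim_config: n_snps >= 1 and n_ref >= 2 required")
  if (cfg$block_size < 1L) stop("invalid sim_config: block_size >= 1 required")
  if (!(cfg$rho > -1 && cfg$rho < 1))
    stop("invalid sim_config: rho must lie in (-1, 1)")
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    stop("invalid sim_config: maf_range bounds must satisfy 0 < lo <= hi <= 0.5")
  counts <- c(cfg$n_pleiotropic, cfg$n_private_1, cfg$n_private_2)
  if (any(counts < 0L)) stop("invalid sim_config: causal counts must be >= 0")
  if (sum(counts) > cfg$n_snps)
    stop("invalid sim_config: causal SNP counts exceed n_snps")
  if (abs(cfg$pheno_corr) > 1)
    stop("invalid sim_config: pheno_corr must lie in [-1, 1]")
  if (cfg$n_study_1 < 3L || cfg$n_study_2 < 3L)
    stop("invalid sim_config: cohort sizes must be >= 3")
  structure(cfg, class = "sim_config")
}

.ar1_chol <- function(b, rho) {
  if (b == 1L) return(matrix(1, 1L, 1L))
  chol(rho ^ abs(outer(seq_len(b), seq_len(b), "-")))
}

# latent AR(1) haplotype pairs thresholded at the MAF quantile
.draw_genotypes <- function(n, maf, blocks, rho) {
  m <- length(maf)
  thr <- stats::qnorm(maf)
  geno <- matrix(0L, n, m)
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    k <- length(idx)
    L <- .ar1_chol(k, rho)
    tm <- matrix(thr[idx], n, k, byrow = TRUE)
    h1 <- (matrix(stats::rnorm(n * k), n, k) %*% L) < tm
    h2 <- (matrix(stats::rnorm(n * k), n, k) %*% L) < tm
    geno[, idx] <- h1 + h2
  }
  storage.mode(geno) <- "integer"
  geno
}

#' Construct a reference panel from a dosage matrix
#'
#' Validates dosages (values 0/1/2, no missingness), computes per-SNP minor
#' allele frequencies, and drops monomorphic SNPs (a panel never retains
#' them, since they carry no LD information).
#'
#' @param geno samples x SNPs integer dosage matrix with SNP column names.
#' @param map data.frame with columns `SNP`, `CHR`, `POS`, `A1`, `A2`
#'   ordered by chromosome then position, matching `geno` columns.
#' @param blocks,rho,maf_target optional generative parameters kept so
#'   further cohorts can be drawn from the same law ([simulate_cohort()]).
#' @return an object of class `ref_panel`.
#' @export
ref_panel <- function(geno, map, blocks = NULL, rho = NULL,
                      maf_target = NULL) {
  geno <- as.matrix(geno)
  if (anyNA(geno)) stop("missing dosages are not supported")
  if (!all(geno %in% 0:2)) stop("dosages must take values 0, 1 or 2")
  if (is.null(colnames(geno))) colnames(geno) <- map$SNP
  if (!identical(colnames(geno), as.character(map$SNP)))
    stop("panel map SNP order must match dosage columns")
  if (anyDuplicated(map$SNP)) stop("panel SNP IDs must be unique")
  freq <- colMeans(geno) / 2
  maf <- pmin(freq, 1 - freq)
  mono <- maf == 0
  if (any(mono)) {
    warning(sprintf("dropping %d monomorphic SNP(s) from the panel",
                    sum(mono)))
    geno <- geno[, !mono, drop = FALSE]
    map <- map[!mono, , drop = FALSE]
    freq <- freq[!mono]
    maf <- maf[!mono]
    if (!is.null(blocks)) blocks <- blocks[!mono]
    if (!is.null(maf_target)) maf_target <- maf_target[!mono]
  }
  structure(list(geno = geno, map = map, maf = unname(maf),
                 freq_a1 = unname(freq), blocks = blocks, rho = rho,
                 maf_target = maf_target),
            class = "ref_panel")
}

#' @export
print.ref_panel <- function(x, ...) {
  cat(sprintf("<ref_panel> %d samples x %d SNPs, MAF in [%.3f, %.3f]\n",
              nrow(x$geno), ncol(x$geno), min(x$maf), max(x$maf)))
  invisible(x)
}

#' Simulate an LD-blocked reference genotype panel
#'
#' Draws per-SNP target MAFs uniformly from `cfg$maf_range`, then dosages
#' block by block from the thresholded latent AR(1) model. SNPs are placed
#' on one chromosome at 1 kb spacing; each LD block is a contiguous run of
#' `cfg$block_size` SNPs, independent of the next block. Deterministic
#' given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return a [ref_panel()] whose `blocks`, `rho` and `maf_target` fields
#'   allow further cohorts to be drawn from the same generative law.
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  m <- cfg$n_snps
  blocks <- rep(seq_len(ceiling(m / cfg$block_size)),
                each = cfg$block_size)[seq_len(m)]
  maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  geno <- .draw_genotypes(cfg$n_ref, maf, blocks, cfg$rho)
  ids <- sprintf("snp%05d", seq_len(m))
  colnames(geno) <- ids
  map <- data.frame(SNP = ids, CHR = 1L, POS = 1000L * seq_len(m),
                    A1 = "A", A2 = "G", stringsAsFactors = FALSE)
  ref_panel(geno, map, blocks = blocks, rho = cfg$rho, maf_target = maf)
}

#' Draw a study cohort from the panel's generative law
#'
#' Simulates genotypes for `n` new individuals sharing the panel's SNPs,
#' MAFs and LD structure, so study cohorts and the reference panel are
#' disjoint samples from one population.
#'
#' @param panel a [ref_panel()] carrying `blocks`, `rho`, `maf_target`.
#' @param n cohort size.
#' @param seed integer seed.
#' @return samples x SNPs dosage matrix with SNP column names.
#' @export
simulate_cohort <- function(panel, n, seed) {
  if (is.null(panel$blocks) || is.null(panel$maf_target))
    stop("panel lacks generative parameters; use simulate_panel()")
  set.seed(seed)
  geno <- .draw_genotypes(n, panel$maf_target, panel$blocks, panel$rho)
  colnames(geno) <- panel$map$SNP
  geno
}

#' Sample a causal architecture
#'
#' Chooses disjoint pleiotropic and phenotype-private causal SNP sets at
#' random from the panel and assigns each the configured effect size.
#'
#' @param panel a [ref_panel()].
#' @param cfg a [sim_config()].
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return an object of class `ground_truth`: SNP ID vectors
#'   `pleiotropic`, `private_1`, `private_2` and named per-SNP effect
#'   vectors `effects_1`, `effects_2`.
#' @export
make_ground_truth <- function(panel, cfg, seed = cfg$seed) {
  set.seed(seed)
  total <- cfg$n_pleiotropic + cfg$n_private_1 + cfg$n_private_2
  ids <- panel$map$SNP
  if (total > length(ids)) stop("not enough SNPs in panel for causal counts")
  pick <- if (total > 0L) sample(ids, total) else character(0)
  pleio <- pick[seq_len(cfg$n_pleiotropic)]
  priv1 <- pick[cfg$n_pleiotropic + seq_len(cfg$n_private_1)]
  priv2 <- pick[cfg$n_pleiotropic + cfg$n_private_1 +
                  seq_len(cfg$n_private_2)]
  e <- cfg$effect_size
  structure(list(
    pleiotropic = pleio, private_1 = priv1, private_2 = priv2,
    effects_1 = stats::setNames(rep(e, length(pleio) + length(priv1)),
                                c(pleio, priv1)),
    effects_2 = stats::setNames(rep(e, length(pleio) + length(priv2)),
                                c(pleio, priv2))),
    class = "ground_truth")
}

#' Simulate the two phenotypes of a cohort
#'
#' `phenotype_k = sum(effect * standardized dosage) + noise`, with bivariate
#' Gaussian noise of correlation `cfg$pheno_corr`; each phenotype is then
#' standardized to zero mean and unit variance.
#'
#' @param geno cohort dosage matrix (samples x SNPs, named columns).
#' @param truth a [make_ground_truth()] object; every causal SNP must exist
#'   among `geno`'s columns.
#' @param cfg a [sim_config()] (supplies `pheno_corr`).
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return n x 2 matrix with columns `pheno_1`, `pheno_2`.
#' @export
simulate_phenotypes <- function(geno, truth, cfg, seed = cfg$seed) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(seed)
  n <- nrow(geno)
  pc <- cfg$pheno_corr
  e1 <- stats::rnorm(n)
  e2 <- pc * e1 + sqrt(max(0, 1 - pc^2)) * stats::rnorm(n)
  y <- cbind(e1, e2)
  for (k in 1:2) {
    eff <- truth[[paste0("effects_", k)]]
    if (length(eff)) {
      missing <- setdiff(names(eff), colnames(geno))
      if (length(missing))
        stop(sprintf("causal SNP(s) absent from genotypes: %s",
                     paste(missing, collapse = ", ")))
      xs <- scale(geno[, names(eff), drop = FALSE])
      if (anyNA(xs)) stop("monomorphic causal SNP in cohort")
      y[, k] <- as.vector(xs %*% eff) + y[, k]
    }
    y[, k] <- as.vector(scale(y[, k]))
  }
  colnames(y) <- c("pheno_1", "pheno_2")
  y
}

#' Per-SNP univariate GWAS
#'
#' Simple linear regression of one phenotype on each dosage column, giving
#' the slope, its standard error, the effect-allele frequency and the sample
#' size — the summary statistics a GWAS publishes. Monomorphic SNPs have no
#' defined SE; they are flagged and their `beta`/`se` set to `NA` so
#' downstream readers exclude them.
#'
#' @param geno dosage matrix (samples x SNPs, named columns).
#' @param pheno numeric phenotype vector, `length(pheno) == nrow(geno)`,
#'   n >= 3.
#' @return data.frame with columns `snp`, `beta`, `se`, `freq`, `n`,
#'   `monomorphic`.
#' @export
compute_univariate_gwas <- function(geno, pheno) {
  n <- length(pheno)
  if (n < 3L) stop("at least 3 individuals required")
  if (nrow(geno) != n) stop("genotype and phenotype dimensions differ")
  gc <- scale(geno, scale = FALSE)
  yc <- pheno - mean(pheno)
  sxx <- colSums(gc^2)
  sxy <- as.vector(crossprod(gc, yc))
  syy <- sum(yc^2)
  mono <- sxx == 0
  beta <- ifelse(mono, NA_real_, sxy / sxx)
  rss <- pmax(syy - beta * sxy, 0)
  se <- ifelse(mono, NA_real_, sqrt(rss / (n - 2) / sxx))
  data.frame(snp = colnames(geno), beta = beta, se = se,
             freq = colMeans(geno) / 2, n = n, monomorphic = mono,
             stringsAsFactors = FALSE)
}

#' Write a summary-statistics file
#'
#' Tab-separated, header `SNP CHR POS A1 A2 BETA SE FREQ N`, missing values
#' as `NA` — the dialect read back by [read_sumstats()].
#'
#' @param gwas output of [compute_univariate_gwas()] (or any data.frame
#'   with `snp`, `beta`, `se`, `freq`, `n`).
#' @param map SNP map data.frame (`SNP`, `CHR`, `POS`, `A1`, `A2`); output
#'   rows follow its order.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_study <- function(gwas, map, path) {
  i <- match(map$SNP, gwas$snp)
  keep <- !is.na(i)
  map <- map[keep, , drop = FALSE]
  i <- i[keep]
  out <- data.frame(SNP = map$SNP, CHR = map$CHR, POS = map$POS,
                    A1 = map$A1, A2 = map$A2,
                    BETA = gwas$beta[i], SE = gwas$se[i],
                    FREQ = gwas$freq[i], N = gwas$n[i],
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a reference panel (dosage matrix + SNP map)
#'
#' Dosage file: tab-separated with a SNP-ID header row and one sample per
#' line. Map file: `SNP CHR POS A1 A2`.
#'
#' @param panel a [ref_panel()].
#' @param geno_path,map_path output files.
#' @return `geno_path`, invisibly.
#' @export
write_panel <- function(panel, geno_path, map_path) {
  utils::write.table(panel$geno, geno_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(panel$map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(geno_path)
}

#' Read a reference panel written by [write_panel()]
#' @param geno_path,map_path dosage and SNP-map files.
#' @return a [ref_panel()] (monomorphic SNPs dropped with a warning).
#' @export
read_panel <- function(geno_path, map_path) {
  geno <- as.matrix(utils::read.table(geno_path, header = TRUE, sep = "\t",
                                      check.names = FALSE))
  map <- utils::read.table(map_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  ref_panel(geno, map)
}

#' One gene range per LD block
#'
#' Builds a gene-range table (glist dialect: `CHR START END GENE`,
#' 1-based inclusive) covering each LD block of a simulated panel, so every
#' annotated gene corresponds to one block of correlated SNPs.
#'
#' @param panel a [ref_panel()] with a `blocks` field (or `block_size` used
#'   to partition SNPs sequentially).
#' @param block_size fallback block length when `panel$blocks` is `NULL`.
#' @return data.frame `CHR START END GENE`.
#' @export
make_gene_ranges <- function(panel, block_size = 10L) {
  blocks <- panel$blocks %||%
    rep(seq_len(ceiling(ncol(panel$geno) / block_size)),
        each = block_size)[seq_len(ncol(panel$geno))]
  sp <- split(seq_along(blocks), blocks)
  do.call(rbind, lapply(names(sp), function(b) {
    idx <- sp[[b]]
    data.frame(CHR = panel$map$CHR[idx[1]],
               START = min(panel$map$POS[idx]),
               END = max(panel$map$POS[idx]),
               GENE = sprintf("GENE%04d", as.integer(b)),
               stringsAsFactors = FALSE)
  }))
}

#' Write gene ranges in glist dialect (whitespace-separated, no header)
#' @param genes data.frame `CHR START END GENE`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_ranges <- function(genes, path) {
  utils::write.table(genes[, c("CHR", "START", "END", "GENE")], path,
                     sep = " ", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read gene ranges in glist dialect
#' @param path whitespace-separated `CHR START END GENE` file, no header.
#' @return data.frame `CHR START END GENE`.
#' @export
read_gene_ranges <- function(path) {
  g <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("CHR", "START", "END", "GENE"))
  if (any(g$START > g$END)) stop("gene ranges must satisfy START <= END")
  g
}

#' Simulate a complete input bundle on disk
#'
#' Generates a reference panel, two disjoint study cohorts, correlated
#' phenotypes with a known causal architecture, per-cohort univariate GWAS
#' summary statistics (study 1 analyzes phenotype 1, study 2 phenotype 2),
#' a per-block gene-range file and a ground-truth record, and writes them
#' all under `dir`. All randomness flows from `cfg$seed` via sub-seeds
#' recorded in the bundle manifest.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if absent).
#' @return invisibly, a list with the file `paths`, the in-memory `panel`,
#'   `truth` (including `pleiotropic_genes`), and `genes`.
#' @export
simulate_bundle <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  sub <- sample.int(2147483646L, 6L)
  pcfg <- cfg
  pcfg$seed <- sub[1]
  panel <- simulate_panel(pcfg)
  truth <- make_ground_truth(panel, cfg, seed = sub[2])
  g1 <- simulate_cohort(panel, cfg$n_study_1, seed = sub[3])
  g2 <- simulate_cohort(panel, cfg$n_study_2, seed = sub[4])
  y1 <- simulate_phenotypes(g1, truth, cfg, seed = sub[5])
  y2 <- simulate_phenotypes(g2, truth, cfg, seed = sub[6])
  gw1 <- compute_univariate_gwas(g1, y1[, 1])
  gw2 <- compute_univariate_gwas(g2, y2[, 2])
  genes <- make_gene_ranges(panel)
  blk <- panel$blocks[match(truth$pleiotropic, panel$map$SNP)]
  truth$pleiotropic_genes <- sort(unique(sprintf("GENE%04d", blk)))
  paths <- list(study_1 = file.path(dir, "study1.tsv"),
                study_2 = file.path(dir, "study2.tsv"),
                panel = file.path(dir, "panel.tsv"),
                panel_map = file.path(dir, "panel_map.tsv"),
                gene_ranges = file.path(dir, "genes.txt"),
                truth = file.path(dir, "truth.json"),
                manifest = file.path(dir, "bundle_manifest.json"))
  write_study(gw1, panel$map, paths$study_1)
  write_study(gw2, panel$map, paths$study_2)
  write_panel(panel, paths$panel, paths$panel_map)
  write_gene_ranges(genes, paths$gene_ranges)
  jsonlite::write_json(list(pleiotropic = truth$pleiotropic,
                            private_1 = truth$private_1,
                            private_2 = truth$private_2,
                            effect_size = cfg$effect_size,
                            pleiotropic_genes = truth$pleiotropic_genes),
                       paths$truth, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(config = unclass(cfg), sub_seeds = sub),
                       paths$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(paths = paths, panel = panel, truth = truth,
                 genes = genes))
}
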