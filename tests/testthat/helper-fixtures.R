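# Shared fixtures: small configurations, in-memory panels and a
# brute-force pruning oracle independent of the package implementation.

small_cfg <- function(...) {
  defaults <- list(n_snps = 100L, n_ref = 400L, n_study_1 = 1000L,
                   n_study_2 = 1000L, block_size = 5L, rho = 0.5,
                   n_pleiotropic = 2L, n_private_1 = 2L, n_private_2 = 2L,
                   effect_size = 0.15, pheno_corr = 0.2, seed = 11L)
  over <- list(...)
  defaults[names(over)] <- over
  do.call(sim_config, defaults)
}

# build a ref_panel directly from a dosage matrix (one chromosome)
panel_from_matrix <- function(geno, chr = 1L) {
  m <- ncol(geno)
  ids <- sprintf("s%03d", seq_len(m))
  colnames(geno) <- ids
  map <- data.frame(SNP = ids, CHR = chr, POS = 100L * seq_len(m),
                    A1 = "A", A2 = "G", stringsAsFactors = FALSE)
  ref_panel(geno, map)
}

# write a minimal sumstats file and return its path
write_sumstats_file <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  path
}

sumstats_df <- function(snp, beta, se, a1 = "A", a2 = "G",
                        chr = 1L, pos = seq_along(snp) * 100L,
                        freq = 0.3, n = 1000L) {
  data.frame(SNP = snp, CHR = chr, POS = pos, A1 = a1, A2 = a2,
             BETA = beta, SE = se, FREQ = freq, N = n,
             stringsAsFactors = FALSE)
}

# Independent brute-force fixed-point pruner: full restart after every
# removal; first violating pair in window scan order (windows in order of
# start, pairs by left then right index); smaller MAF removed, ties ->
# larger position. Correlations computed here, not via the package.
brute_force_prune <- function(geno, maf, window, step, r2_max) {
  r2 <- suppressWarnings(cor(geno))^2
  r2[!is.finite(r2)] <- 0
  kept <- seq_len(ncol(geno))
  repeat {
    mk <- length(kept)
    if (mk < 2L) break
    victim <- NA_integer_
    for (s0 in seq.int(1L, mk, by = step)) {
      e0 <- min(s0 + window - 1L, mk)
      if (e0 <= s0) next
      for (i in s0:(e0 - 1L)) {
        for (j in (i + 1L):e0) {
          if (r2[kept[i], kept[j]] > r2_max) {
            mi <- maf[kept[i]]; mj <- maf[kept[j]]
            victim <- if (mi < mj) i else if (mj < mi) j else max(i, j)
            break
          }
        }
        if (!is.na(victim)) break
      }
      if (!is.na(victim)) break
    }
    if (is.na(victim)) break
    kept <- kept[-victim]
  }
  kept
}

# scan the kept set for any remaining violating window pair
count_violations <- function(geno, kept_idx, window, step, r2_max) {
  r2 <- suppressWarnings(cor(geno[, kept_idx, drop = FALSE]))^2
  r2[!is.finite(r2)] <- 0
  mk <- length(kept_idx)
  bad <- 0L
  for (s0 in seq.int(1L, mk, by = step)) {
    e0 <- min(s0 + window - 1L, mk)
    if (e0 <= s0) next
    sub <- r2[s0:e0, s0:e0]
    bad <- bad + sum(sub[upper.tri(sub)] > r2_max)
  }
  bad
}
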