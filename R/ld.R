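# LD from the reference panel: pairwise r2, windowed pruning, genotypic
# correlation blocks and shrinkage to positive definiteness.

#' Pairwise LD between two SNPs
#'
#' Squared Pearson correlation of the two dosage vectors (allelic
#' correlation, the quantity PLINK-style pruning thresholds).
#'
#' @param panel a [ref_panel()].
#' @param snp_i,snp_j SNP IDs present in the panel.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(panel, snp_i, snp_j) {
  for (s in c(snp_i, snp_j))
    if (!s %in% panel$map$SNP) stop(sprintf("SNP not in panel: %s", s))
  x <- panel$geno[, snp_i]
  y <- panel$geno[, snp_j]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("monomorphic SNP has no defined LD")
  min(stats::cor(x, y)^2, 1)
}

#' Genotypic correlation block for a SNP set
#'
#' Pearson correlation matrix of the requested dosage columns — the
#' genotype-genotype covariance block of summary-statistic CCA (no
#' shrinkage applied here; see [shrink_to_pd()]).
#'
#' @param panel a [ref_panel()].
#' @param snp_ids one or more SNP IDs present in the panel.
#' @return an `ld_block`: `snps`, correlation matrix `R`, `lambda = 0`.
#' @export
genotype_corr <- function(panel, snp_ids) {
  if (!length(snp_ids)) stop("at least one SNP required")
  miss <- setdiff(snp_ids, panel$map$SNP)
  if (length(miss)) stop(sprintf("SNP(s) not in panel: %s",
                                 paste(miss, collapse = ", ")))
  r <- stats::cor(panel$geno[, snp_ids, drop = FALSE])
  dimnames(r) <- list(snp_ids, snp_ids)
  structure(list(snps = snp_ids, R = r, lambda = 0),
            class = "ld_block")
}

#' Shrink a correlation matrix to positive definiteness
#'
#' Returns `(1 - lambda) * M + lambda * I` with the smallest `lambda` on
#' the grid `0, step, 2*step, ...` whose smallest eigenvalue is at least
#' `eps`. For a correlation matrix the unit diagonal is preserved. This is
#' the convex shrinkage toward the identity used to make estimated
#' covariance blocks numerically invertible before CCA.
#'
#' @param m square symmetric matrix.
#' @param step grid step for lambda (default 0.01).
#' @param eps minimum acceptable smallest eigenvalue (default 1e-8).
#' @return list with elements `matrix` and `lambda`.
#' @export
shrink_to_pd <- function(m, step = 0.01, eps = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (max(abs(m - t(m))) > 1e-8) stop("matrix must be symmetric")
  m <- (m + t(m)) / 2
  id <- diag(nrow(m))
  lambda <- 0
  repeat {
    if (lambda > 1) stop("shrinkage lambda would exceed 1; degenerate input")
    m2 <- (1 - lambda) * m + lambda * id
    ev <- min(eigen(m2, symmetric = TRUE, only.values = TRUE)$values)
    if (ev >= eps) return(list(matrix = m2, lambda = lambda))
    lambda <- lambda + step
  }
}

# prune one chromosome; X columns ordered by position
.prune_chrom <- function(x, maf, window, step, r2_max) {
  m <- ncol(x)
  if (m < 2L) return(seq_len(m))
  r2 <- suppressWarnings(stats::cor(x))^2
  r2[!is.finite(r2)] <- 0
  kept <- seq_len(m)
  clean_end <- 0L  # all windows ending at or before this kept-index are clean
  repeat {
    mk <- length(kept)
    if (mk < 2L) break
    removed <- FALSE
    for (s0 in seq.int(1L, mk, by = step)) {
      e0 <- min(s0 + window - 1L, mk)
      if (e0 <= s0 || e0 <= clean_end) next
      sub <- r2[kept[s0:e0], kept[s0:e0], drop = FALSE]
      hit <- which(upper.tri(sub) & sub > r2_max, arr.ind = TRUE)
      if (nrow(hit) == 0L) {
        clean_end <- e0
        next
      }
      hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
      p1 <- s0 - 1L + hit[1, 1]
      p2 <- s0 - 1L + hit[1, 2]
      # remove the smaller-MAF SNP; ties broken by larger genomic position
      k <- if (maf[kept[p1]] < maf[kept[p2]]) p1
      else if (maf[kept[p2]] < maf[kept[p1]]) p2
      else max(p1, p2)
      kept <- kept[-k]
      clean_end <- min(clean_end, k - 1L)
      removed <- TRUE
      break
    }
    if (!removed) break
  }
  kept
}

#' Windowed LD pruning
#'
#' Sliding-window pruning of a genomically ordered SNP list against the
#' reference panel: within each window of `window` SNPs (windows advance by
#' `step`), for every pair with r-squared above `r2_max` the SNP with the
#' smaller reference-panel MAF is removed (ties: the SNP at the larger
#' position); the scan repeats until no window contains a violating pair.
#' Pairs are examined in order of left then right index, and the first
#' violating pair's loser is removed before rescanning, which makes the
#' result deterministic. Chromosomes are processed independently; genomic
#' order is preserved in the output.
#'
#' @param panel a [ref_panel()].
#' @param snps SNP IDs to prune, sorted by chromosome then position
#'   (default: all panel SNPs).
#' @param window window size in SNPs (default 50).
#' @param step window step in SNPs (default 5).
#' @param r2_max LD threshold (default 0.2).
#' @return character vector of kept SNP IDs in genomic order, with
#'   attribute `n_removed`.
#' @export
window_prune <- function(panel, snps = panel$map$SNP, window = 50L,
                         step = 5L, r2_max = 0.2) {
  window <- as.integer(window)
  step <- as.integer(step)
  if (step < 1L || window < step) stop("require window >= step >= 1")
  i <- match(snps, panel$map$SNP)
  if (anyNA(i)) stop("all SNPs must be present in the panel")
  chr <- panel$map$CHR[i]
  pos <- panel$map$POS[i]
  if (!identical(order(chr, pos), seq_along(i)))
    stop("SNPs must be sorted by chromosome then position")
  kept <- character(0)
  for (ch in unique(chr)) {
    sel <- which(chr == ch)
    kc <- .prune_chrom(panel$geno[, i[sel], drop = FALSE],
                       panel$maf[i[sel]], window, step, r2_max)
    kept <- c(kept, snps[sel][kc])
  }
  structure(kept, n_removed = length(snps) - length(kept))
}
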