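# Reading, harmonizing, annotating and standardizing GWAS summary statistics.

.default_cols <- c(snp = "SNP", chr = "CHR", pos = "POS", a1 = "A1",
                   a2 = "A2", beta = "BETA", se = "SE", freq = "FREQ",
                   n = "N")

.complement <- function(x) chartr("ACGT", "TGCA", x)

#' Read and validate one study's GWAS summary statistics
#'
#' Reads a tab-separated effect table, resolves columns through
#' `column_map` (so downloads with non-standard headers can be ingested),
#' and enforces the record invariants: numeric beta, SE > 0, alleles in
#' A/C/G/T, unique SNP IDs (first occurrence kept). Rows failing a check
#' are dropped and counted per reason in the attached drop log.
#'
#' @param path tab-separated file with a header row.
#' @param label study label (defaults to the file name).
#' @param column_map named character vector overriding the default header
#'   names; canonical names are `snp, chr, pos, a1, a2, beta, se, freq, n`
#'   (the last two optional). E.g. `c(beta = "Effect", se = "StdErr")`.
#' @param study_n study-level sample size; required when the file has no
#'   per-SNP `n` column, and used as the fallback for missing per-SNP n.
#' @return an object of class `study_summary`: `label`, `data` (validated
#'   per-SNP records), `study_n`, and `drops` (named drop counts).
#' @export
read_sumstats <- function(path, label = basename(path), column_map = NULL,
                          study_n = NULL) {
  if (!file.exists(path)) stop(sprintf("summary file not found: %s", path))
  cmap <- .default_cols
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(cmap))
    if (length(bad)) stop(sprintf("unknown column_map field(s): %s",
                                  paste(bad, collapse = ", ")))
    cmap[names(column_map)] <- column_map
  }
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "")
  for (f in c("snp", "chr", "pos", "a1", "a2", "beta", "se"))
    if (!cmap[[f]] %in% names(raw))
      stop(sprintf("missing mandatory column '%s' (header '%s') in %s",
                   f, cmap[[f]], path))
  grab <- function(f) if (cmap[[f]] %in% names(raw)) raw[[cmap[[f]]]] else NULL
  d <- data.frame(snp = as.character(grab("snp")),
                  chr = as.character(grab("chr")),
                  pos = suppressWarnings(as.integer(grab("pos"))),
                  a1 = toupper(as.character(grab("a1"))),
                  a2 = toupper(as.character(grab("a2"))),
                  beta = suppressWarnings(as.numeric(grab("beta"))),
                  se = suppressWarnings(as.numeric(grab("se"))),
                  stringsAsFactors = FALSE)
  d$freq <- if (!is.null(grab("freq")))
    suppressWarnings(as.numeric(grab("freq"))) else NA_real_
  d$n <- if (!is.null(grab("n")))
    suppressWarnings(as.numeric(grab("n"))) else NA_real_
  if (is.null(study_n)) {
    if (all(is.na(d$n)))
      stop("study_n is required when the file carries no sample-size column")
    study_n <- max(d$n, na.rm = TRUE)
  }
  d$n[is.na(d$n)] <- study_n

  drops <- c(bad_beta = 0L, bad_se = 0L, bad_allele = 0L, duplicate = 0L)
  ok <- is.finite(d$beta)
  drops["bad_beta"] <- sum(!ok)
  bad_se <- ok & (!is.finite(d$se) | d$se <= 0)
  drops["bad_se"] <- sum(bad_se)
  ok <- ok & !bad_se
  bad_al <- ok & (!(d$a1 %in% c("A", "C", "G", "T")) |
                    !(d$a2 %in% c("A", "C", "G", "T")) | d$a1 == d$a2)
  drops["bad_allele"] <- sum(bad_al)
  ok <- ok & !bad_al
  d <- d[ok, , drop = FALSE]
  dup <- duplicated(d$snp)
  if (any(dup)) {
    drops["duplicate"] <- sum(dup)
    warning(sprintf("%d duplicated SNP ID(s) in %s; keeping first occurrence",
                    sum(dup), label))
    d <- d[!dup, , drop = FALSE]
  }
  rownames(d) <- NULL
  structure(list(label = label, data = d, study_n = study_n,
                 drops = drops),
            class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("<study_summary> %s: %d SNPs, study n = %g (dropped: %s)\n",
              x$label, nrow(x$data), x$study_n,
              paste(sprintf("%s=%d", names(x$drops), x$drops),
                    collapse = ", ")))
  invisible(x)
}

#' Harmonize two studies onto a common effect allele
#'
#' Intersects the two studies by SNP ID and aligns study b's effects to
#' study a's allele frame: a direct match passes through; swapped alleles
#' flip the sign of beta; alleles matching after strand complementation are
#' aligned likewise. Strand-ambiguous (palindromic A/T, C/G) SNPs are
#' always dropped, as are SNPs whose alleles cannot be reconciled. Output
#' is ordered by chromosome then position.
#'
#' @param a,b `study_summary` objects (both non-empty).
#' @return a `harmonized_pair`: data.frame `snp, chr, pos, a1, a2, beta_1,
#'   se_1, n_1, beta_2, se_2, n_2` with attributes `study_n` (both totals),
#'   `labels`, and `drops` (ambiguous / mismatched counts).
#' @export
harmonize <- function(a, b) {
  stopifnot(inherits(a, "study_summary"), inherits(b, "study_summary"))
  if (!nrow(a$data) || !nrow(b$data)) stop("both studies must be non-empty")
  da <- a$data
  db <- b$data
  common <- intersect(da$snp, db$snp)
  if (!length(common)) stop("no shared SNPs between the two studies")
  ia <- match(common, da$snp)
  ib <- match(common, db$snp)
  a1a <- da$a1[ia]; a2a <- da$a2[ia]
  a1b <- db$a1[ib]; a2b <- db$a2[ib]
  palin <- a1a == .complement(a2a)
  same <- a1b == a1a & a2b == a2a
  swap <- a1b == a2a & a2b == a1a
  strand <- .complement(a1b) == a1a & .complement(a2b) == a2a
  strand_swap <- .complement(a1b) == a2a & .complement(a2b) == a1a
  usable <- !palin & (same | swap | strand | strand_swap)
  flip <- ifelse(swap | strand_swap, -1, 1)
  u <- which(usable)
  out <- data.frame(snp = common[u], chr = da$chr[ia][u],
                    pos = da$pos[ia][u], a1 = a1a[u], a2 = a2a[u],
                    beta_1 = da$beta[ia][u], se_1 = da$se[ia][u],
                    n_1 = da$n[ia][u],
                    beta_2 = flip[u] * db$beta[ib][u],
                    se_2 = db$se[ib][u], n_2 = db$n[ib][u],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chr, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            study_n = c(a$study_n, b$study_n),
            labels = c(a$label, b$label),
            drops = c(ambiguous = sum(palin),
                      mismatch = sum(!palin &
                                       !(same | swap | strand | strand_swap))),
            class = c("harmonized_pair", "data.frame"))
}

#' Standardize GWAS effect sizes
#'
#' `beta_std = beta / (sqrt(n) * se)`: the per-allele effect divided by the
#' square root of the sample size times its standard error. This equals the
#' Wald z statistic over `sqrt(n)` and, for standardized genotype and
#' phenotype, approximates the genotype-phenotype Pearson correlation — the
#' entries of the genotype-phenotype covariance block of summary-statistic
#' CCA. Vectorized; magnitudes above 1 trigger a warning (they signal
#' inconsistent inputs, since a correlation cannot exceed 1).
#'
#' @param beta,se effect sizes and standard errors (se > 0).
#' @param n sample size(s), >= 1.
#' @return numeric vector of standardized effects.
#' @export
#' @examples
#' standardize_beta(0.1, 0.02, 100)  # 0.5
standardize_beta <- function(beta, se, n) {
  if (any(!is.finite(se)) || any(se <= 0)) stop("se must be positive")
  if (any(!is.finite(n)) || any(n < 1)) stop("n must be >= 1")
  out <- beta / (sqrt(n) * se)
  if (any(abs(out) > 1, na.rm = TRUE))
    warning("standardized |beta| > 1; check beta/se/n consistency")
  out
}

#' Assign SNPs to gene intervals
#'
#' Each SNP is assigned to every gene whose interval (optionally extended
#' by a symmetric flank) contains its position on the same chromosome;
#' overlapping genes both receive the SNP. SNPs falling in no gene are
#' flagged unannotated and excluded from gene-level analyses.
#'
#' @param pair a [harmonize()] result (or any data.frame with `snp`,
#'   `chr`, `pos`).
#' @param genes gene ranges (`CHR START END GENE`, 1-based inclusive).
#' @param flank symmetric flank in base pairs added to each gene (default
#'   0).
#' @return an object of class `snp_annotation`: `genes` (the ranges),
#'   `gene_snps` (named list of SNP IDs per gene), `retained` (SNPs in at
#'   least one gene, genomic order), `unannotated` (excluded SNPs).
#' @export
annotate_snps <- function(pair, genes, flank = 0) {
  if (any(genes$START > genes$END)) stop("gene ranges must satisfy START <= END")
  chr <- as.character(pair$chr)
  gene_snps <- lapply(seq_len(nrow(genes)), function(i) {
    hit <- chr == as.character(genes$CHR[i]) &
      pair$pos >= genes$START[i] - flank &
      pair$pos <= genes$END[i] + flank
    pair$snp[hit]
  })
  names(gene_snps) <- genes$GENE
  retained <- pair$snp[pair$snp %in% unique(unlist(gene_snps))]
  structure(list(genes = genes, gene_snps = gene_snps,
                 retained = retained,
                 unannotated = setdiff(pair$snp, retained)),
            class = "snp_annotation")
}

#' Read a gene list (one symbol per line, `#` comments allowed)
#'
#' Symbols are whitespace-trimmed, upper-cased and de-duplicated — the
#' normalization applied before any set operation.
#'
#' @param path text file.
#' @return character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- sub("#.*$", "", x)
  x <- toupper(trimws(x))
  unique(x[nzchar(x)])
}

#' Read an undirected edge list (two tab-separated columns)
#' @param path text file, optional `#` comments.
#' @return data.frame with columns `from`, `to`.
#' @export
read_edge_list <- function(path) {
  e <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "#",
                         col.names = c("from", "to"))
  e$from <- toupper(trimws(e$from))
  e$to <- toupper(trimws(e$to))
  e
}
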