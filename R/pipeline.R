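# End-to-end orchestration: read -> harmonize -> annotate -> prune ->
# standardize -> trait correlation -> SNP scan -> gene scan -> gene test ->
# report, with a machine-readable run manifest.

#' Pipeline configuration
#'
#' Collects every input path and stage parameter of [run_pipeline()].
#' Defaults mirror the standard settings: pruning window 50 SNPs, step 5,
#' r-squared 0.2; alpha 0.01 for the SNP and gene Bonferroni families and
#' for the gene-based test.
#'
#' @param study_1,study_2 summary-statistics files.
#' @param panel,panel_map reference-panel dosage and SNP-map files.
#' @param gene_ranges glist-dialect gene-range file.
#' @param outdir output directory.
#' @param column_map_1,column_map_2 per-study column maps
#'   ([read_sumstats()]).
#' @param study_n_1,study_n_2 study-level sample sizes (required if the
#'   files carry no per-SNP n).
#' @param prune_window,prune_step,prune_r2 pruning parameters.
#' @param alpha_snp,alpha_gene,alpha_vegas family-wise error targets.
#' @param n_effective override for the effective sample size N; default is
#'   the smaller of the two study totals (the conservative choice).
#' @param max_gene_snps cap on SNPs per gene in the CCA gene scan.
#' @param vegas_sims,vegas_cap gene-test simulation count and escalation
#'   cap.
#' @param shrink_step,eps shrinkage settings.
#' @param seed integer seed.
#' @param drug_targets,twas_1,twas_2,known_1,known_2 optional gene-list
#'   files (drug targets, external TWAS hits per disease, known disease
#'   genes per disease).
#' @param edges optional two-column edge-list file for the network
#'   summary.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(study_1, study_2, panel, panel_map, gene_ranges,
                            outdir,
                            column_map_1 = NULL, column_map_2 = NULL,
                            study_n_1 = NULL, study_n_2 = NULL,
                            prune_window = 50L, prune_step = 5L,
                            prune_r2 = 0.2,
                            alpha_snp = 0.01, alpha_gene = 0.01,
                            alpha_vegas = 0.01,
                            n_effective = NULL, max_gene_snps = 50L,
                            vegas_sims = 10000L, vegas_cap = 1000000L,
                            shrink_step = 0.01, eps = 1e-8, seed = 1L,
                            drug_targets = NULL, twas_1 = NULL,
                            twas_2 = NULL, known_1 = NULL, known_2 = NULL,
                            edges = NULL) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop(sprintf("unknown config key(s): %s",
                                paste(bad, collapse = ", ")))
  do.call(pipeline_config, y)
}

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

#' Run the full pleiotropy pipeline
#'
#' Executes the stages in order — read both studies, harmonize, annotate
#' SNPs to genes, LD-prune against the panel, standardize effects,
#' estimate the trait correlation from all pruned genome-wide effects,
#' single-SNP CCA scan, gene-level CCA scan, gene-based validation test on
#' each study, and (when gene lists are supplied) the triangulation report
#' — writing each table plus a JSON manifest of per-stage record counts
#' and every threshold actually applied. A rerun with the same
#' configuration reproduces identical outputs.
#'
#' @param cfg a [pipeline_config()] or the path to a YAML config file.
#' @return invisibly, a list with `outdir`, `manifest` and the result
#'   tables.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  req <- c("study_1", "study_2", "panel", "panel_map", "gene_ranges")
  for (f in req)
    if (!file.exists(cfg[[f]]))
      stop(sprintf("pipeline input '%s' not found: %s", f, cfg[[f]]))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(parameters = cfg[setdiff(names(cfg),
                                            c("column_map_1",
                                              "column_map_2"))],
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  s1 <- read_sumstats(cfg$study_1, label = "study_1",
                      column_map = cfg$column_map_1,
                      study_n = cfg$study_n_1)
  s2 <- read_sumstats(cfg$study_2, label = "study_2",
                      column_map = cfg$column_map_2,
                      study_n = cfg$study_n_2)
  note("read", n_study_1 = nrow(s1$data), n_study_2 = nrow(s2$data),
       drops_study_1 = as.list(s1$drops), drops_study_2 = as.list(s2$drops))

  pair <- harmonize(s1, s2)
  note("harmonize", n_shared = nrow(pair),
       drops = as.list(attr(pair, "drops")))

  panel <- read_panel(cfg$panel, cfg$panel_map)
  in_panel <- pair$snp %in% panel$map$SNP
  pair2 <- pair[in_panel, , drop = FALSE]
  class(pair2) <- class(pair)
  attributes(pair2)[c("study_n", "labels")] <-
    attributes(pair)[c("study_n", "labels")]
  note("panel_overlap", n_in_panel = nrow(pair2),
       n_dropped_not_in_panel = sum(!in_panel))

  genes <- read_gene_ranges(cfg$gene_ranges)
  annotation <- annotate_snps(pair2, genes)
  note("annotate", n_annotated = length(annotation$retained),
       n_unannotated = length(annotation$unannotated),
       n_genes = nrow(genes))

  kept <- window_prune(panel, snps = annotation$retained,
                       window = cfg$prune_window, step = cfg$prune_step,
                       r2_max = cfg$prune_r2)
  note("prune", n_kept = length(kept),
       n_removed = attr(kept, "n_removed"),
       window = cfg$prune_window, step = cfg$prune_step,
       r2_max = cfg$prune_r2)

  pruned <- pair2[match(kept, pair2$snp), , drop = FALSE]
  class(pruned) <- class(pair)
  attributes(pruned)[c("study_n", "labels")] <-
    attributes(pair)[c("study_n", "labels")]
  s_all <- build_sigma_xy(pruned)
  yy <- estimate_sigma_yy(s_all, shrink_step = cfg$shrink_step,
                          eps = cfg$eps)
  note("trait_correlation", r12 = yy$R[1, 2], lambda = yy$lambda,
       n_snps_used = yy$n_snps)

  n_eff <- cfg$n_effective %||% min(attr(pair, "study_n"))
  acfg <- analysis_config(N = n_eff, alpha = cfg$alpha_snp,
                          max_gene_snps = cfg$max_gene_snps,
                          shrink_step = cfg$shrink_step, eps = cfg$eps,
                          seed = cfg$seed)
  snp_scan <- univariate_snp_scan(s_all, yy, acfg, map = pruned)
  note("snp_scan", n_tested = nrow(snp_scan),
       n_significant = sum(snp_scan$SIG),
       bonferroni_threshold = attr(snp_scan, "threshold"),
       n_effective = n_eff)

  gcfg <- analysis_config(N = n_eff, alpha = cfg$alpha_gene,
                          max_gene_snps = cfg$max_gene_snps,
                          shrink_step = cfg$shrink_step, eps = cfg$eps,
                          seed = cfg$seed)
  gene_scan <- gene_level_scan(s_all, panel, yy, annotation, gcfg)
  note("gene_scan", n_tested = nrow(gene_scan),
       n_significant = sum(gene_scan$SIG),
       bonferroni_threshold = attr(gene_scan, "threshold"),
       n_skipped_zero_snp = length(attr(gene_scan, "skipped")))

  vegas <- list()
  for (k in 1:2) {
    st <- if (k == 1L) s1 else s2
    vegas[[k]] <- run_gene_tests(st, annotation, panel,
                                 alpha = cfg$alpha_vegas,
                                 n_sims = cfg$vegas_sims,
                                 sims_cap = cfg$vegas_cap,
                                 shrink_step = cfg$shrink_step,
                                 eps = cfg$eps, seed = cfg$seed + k)
    note(paste0("gene_test_study_", k),
         n_tested = nrow(vegas[[k]]), n_significant = sum(vegas[[k]]$SIG),
         alpha = cfg$alpha_vegas)
  }

  out <- list(snp_scan = snp_scan, gene_scan = gene_scan,
              gene_test_1 = vegas[[1]], gene_test_2 = vegas[[2]])
  .write_tsv(snp_scan, file.path(cfg$outdir, "snp_scan.tsv"))
  .write_tsv(gene_scan, file.path(cfg$outdir, "gene_scan.tsv"))
  .write_tsv(vegas[[1]], file.path(cfg$outdir, "gene_test_study1.tsv"))
  .write_tsv(vegas[[2]], file.path(cfg$outdir, "gene_test_study2.tsv"))

  # triangulation: CCA-significant genes backed by at least one
  # validation source (gene test per disease, external TWAS lists)
  sets <- list(cca = gene_scan$GENE[gene_scan$SIG],
               vegas_1 = vegas[[1]]$GENE[vegas[[1]]$SIG],
               vegas_2 = vegas[[2]]$GENE[vegas[[2]]$SIG])
  if (!is.null(cfg$twas_1)) sets$twas_1 <- read_gene_list(cfg$twas_1)
  if (!is.null(cfg$twas_2)) sets$twas_2 <- read_gene_list(cfg$twas_2)
  inter <- intersect_gene_sets(sets)
  rule <- paste("cca & (",
                paste(setdiff(names(sets), "cca"), collapse = " | "), ")")
  triangulated <- select_genes(inter$membership, rule)
  .write_tsv(inter$membership, file.path(cfg$outdir, "gene_membership.tsv"))
  .write_tsv(inter$regions, file.path(cfg$outdir, "venn_regions.tsv"))
  writeLines(triangulated, file.path(cfg$outdir, "triangulated_genes.txt"))
  note("triangulation", rule = rule, n_selected = length(triangulated))
  out$triangulated <- triangulated

  if (!is.null(cfg$drug_targets)) {
    targets <- read_gene_list(cfg$drug_targets)
    overlap <- intersect(gene_set(sets$cca), targets)
    writeLines(overlap, file.path(cfg$outdir, "drug_target_overlap.txt"))
    note("drug_targets", n_targets = length(targets),
         n_overlap = length(overlap))
    out$drug_target_overlap <- overlap
  }
  if (!is.null(cfg$known_1) && !is.null(cfg$known_2)) {
    pv <- stats::setNames(gene_scan$PVAL, gene_scan$GENE)
    cls <- classify_genes(triangulated, read_gene_list(cfg$known_1),
                          read_gene_list(cfg$known_2), pvals = pv)
    .write_tsv(cls, file.path(cfg$outdir, "gene_classification.tsv"))
    note("classification", n_confirmed = sum(cls$status == "confirmed"),
         n_potential = sum(cls$status == "potential"),
         n_novel = sum(cls$status == "novel"))
    out$classification <- cls
  }
  if (!is.null(cfg$edges)) {
    gs <- graph_summary(read_edge_list(cfg$edges))
    note("network", n_nodes = gs$n_nodes, n_edges = gs$n_edges,
         mean_degree = round(gs$mean_degree, 2))
    out$network <- gs
  }

  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  out$manifest <- manifest
  out$outdir <- cfg$outdir
  invisible(out)
}
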