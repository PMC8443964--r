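# Reporting: Bonferroni thresholds, gene-set intersections (Venn regions
# and triangulation rules), gene classification, and graph summaries.

#' Bonferroni-corrected significance threshold
#'
#' `alpha / m` for m tests. The quotient is returned at full precision;
#' human-readable output shows 3 significant figures (e.g. 0.01/15302 ->
#' 6.54e-7). Note that for some published thresholds the printed figure and
#' the printed quotient disagree; this function always computes the
#' quotient.
#'
#' @param alpha family-wise error target, in (0, 1).
#' @param m number of tests, >= 1.
#' @return the threshold `alpha / m`.
#' @export
#' @examples
#' signif(bonferroni_threshold(0.01, 15302), 3)  # 6.54e-07
bonferroni_threshold <- function(alpha, m) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Normalize a gene set
#'
#' Upper-cases, trims whitespace and de-duplicates symbols; no alias
#' resolution is attempted (inputs are assumed pre-normalized to standard
#' symbols).
#'
#' @param genes character vector of symbols.
#' @return normalized unique character vector.
#' @export
gene_set <- function(genes) {
  g <- toupper(trimws(as.character(genes)))
  unique(g[nzchar(g)])
}

#' Intersect labelled gene sets: membership table and Venn regions
#'
#' @param sets named list (>= 2) of gene-symbol vectors; labels must be
#'   syntactic names (letters, digits, `_`, `.`).
#' @return list with `membership` (data.frame: `gene` plus one logical
#'   column per set) and `regions` (data.frame: `region` such as
#'   `"A&B"`, `count`); region counts sum to the size of the union.
#' @export
intersect_gene_sets <- function(sets) {
  if (length(sets) < 2L) stop("at least two gene sets required")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("gene sets must be named")
  sets <- lapply(sets, gene_set)
  universe <- sort(unique(unlist(sets)))
  mem <- data.frame(gene = universe, stringsAsFactors = FALSE)
  for (nm in names(sets)) mem[[nm]] <- universe %in% sets[[nm]]
  pattern <- apply(mem[names(sets)], 1, function(row)
    paste(names(sets)[row], collapse = "&"))
  tab <- table(pattern)
  regions <- data.frame(region = names(tab), count = as.integer(tab),
                        stringsAsFactors = FALSE)
  list(membership = mem, regions = regions)
}

#' Select genes by a set-algebra rule
#'
#' Evaluates a rule such as `"metaCCA & (VEGAS_HF | VEGAS_CKD | TWAS_HF)"`
#' over the membership table — the triangulation selector "significant in
#' the primary scan AND in at least one validation set". Only set labels,
#' `&`, `|`, `!` and parentheses are allowed.
#'
#' @param membership the `membership` element of [intersect_gene_sets()].
#' @param rule character rule over the set labels.
#' @return character vector of selected gene symbols.
#' @export
select_genes <- function(membership, rule) {
  labels <- setdiff(names(membership), "gene")
  tokens <- regmatches(rule, gregexpr("[A-Za-z._][A-Za-z0-9._]*", rule))[[1]]
  bad <- setdiff(tokens, labels)
  if (length(bad))
    stop(sprintf("unknown set label(s) in rule: %s",
                 paste(bad, collapse = ", ")))
  leftover <- gsub("[A-Za-z._][A-Za-z0-9._]*|[&|!() ]", "", rule)
  if (nzchar(leftover))
    stop(sprintf("rule contains unsupported characters: %s", leftover))
  env <- as.list(membership[labels])
  sel <- eval(parse(text = rule)[[1]], envir = env)
  membership$gene[sel]
}

#' Classify selected genes against known-disease-gene lists
#'
#' Status rules: `confirmed` — present in both known lists; `potential` —
#' in exactly one; `novel` — in neither. The three statuses partition the
#' selected set.
#'
#' @param selected gene symbols to classify.
#' @param known_1,known_2 known-gene lists for the two diseases.
#' @param pvals optional named numeric vector (e.g. gene-scan p-values)
#'   used to sort the output ascending.
#' @return data.frame `gene status in_known_1 in_known_2` (+ `pval` when
#'   supplied).
#' @export
classify_genes <- function(selected, known_1, known_2, pvals = NULL) {
  selected <- gene_set(selected)
  known_1 <- gene_set(known_1)
  known_2 <- gene_set(known_2)
  in1 <- selected %in% known_1
  in2 <- selected %in% known_2
  status <- ifelse(in1 & in2, "confirmed",
                   ifelse(in1 | in2, "potential", "novel"))
  out <- data.frame(gene = selected, status = status,
                    in_known_1 = in1, in_known_2 = in2,
                    stringsAsFactors = FALSE)
  if (!is.null(pvals)) {
    out$pval <- unname(pvals[out$gene])
    out <- out[order(out$pval), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Summary statistics of an undirected graph
#'
#' Node count, edge count (after collapsing duplicate edges regardless of
#' orientation) and mean degree `2 * E / N`; self-loops are rejected.
#' `mean_degree` is returned at full precision and displayed rounded to 2
#' decimals.
#'
#' @param edges two-column data.frame or matrix of endpoint labels.
#' @return object of class `graph_summary`: `n_nodes`, `n_edges`,
#'   `mean_degree`.
#' @export
#' @examples
#' graph_summary(data.frame(from = c("A", "B"), to = c("B", "C")))
graph_summary <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("edge list must have two columns")
  from <- as.character(edges[[1]])
  to <- as.character(edges[[2]])
  if (any(from == to)) stop("self-loops are not allowed in the graph")
  key <- paste(pmin(from, to), pmax(from, to), sep = "\r")
  key <- unique(key)
  nodes <- unique(c(from, to))
  structure(list(n_nodes = length(nodes), n_edges = length(key),
                 mean_degree = 2 * length(key) / length(nodes)),
            class = "graph_summary")
}

#' @export
print.graph_summary <- function(x, ...) {
  cat(sprintf("graph: %d nodes, %d edges, mean degree %.2f\n",
              x$n_nodes, x$n_edges, round(x$mean_degree, 2)))
  invisible(x)
}
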