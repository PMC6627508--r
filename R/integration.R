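#' Pairwise cross-study reproducibility of effect estimates
#'
#' For every pair of studies, the Pearson correlation of their per-gene
#' estimate vectors over shared genes — the study-level reproducibility
#' check; the median of the upper triangle summarizes it. Pairs sharing
#' fewer than `min_shared` genes are left missing and excluded from the
#' median.
#'
#' @param estimates data.frame of per-study effect estimates (one analysis
#'   type).
#' @param analysis optionally restrict to one analysis type first.
#' @param min_shared floor on shared genes per pair (default 30).
#' @return list with `matrix` (symmetric, unit diagonal) and `median`.
#' @export
reproducibility_matrix <- function(estimates, analysis = NULL,
                                   min_shared = 30L) {
  if (!is.null(analysis)) estimates <- estimates[estimates$analysis == analysis, ]
  split_est <- split(estimates, estimates$study_id)
  ids <- names(split_est)
  if (length(ids) < 2L) stop("need at least 2 studies")
  vecs <- lapply(split_est, function(d) stats::setNames(d$estimate, d$gene_id))
  k <- length(ids)
  M <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  diag(M) <- 1
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    shared <- intersect(names(vecs[[i]]), names(vecs[[j]]))
    if (length(shared) < min_shared) next
    r <- stats::cor(vecs[[i]][shared], vecs[[j]][shared])
    M[i, j] <- M[j, i] <- r
  }
  upper <- M[upper.tri(M)]
  list(matrix = M, median = stats::median(upper, na.rm = TRUE))
}

#' Pair two meta-result tables gene by gene
#'
#' Inner-joins two meta-analysis results tables on gene id and reports the
#' Pearson correlation of the chosen summary fields — e.g. summary SMD in
#' one histology versus the other, or summary SMD versus survival z-score.
#' An optional gene-set highlighting column supports downstream plotting.
#'
#' @param results_a,results_b meta result tables ([meta_table()] output).
#' @param field_a,field_b column to compare from each table (default
#'   "summary"; "z_score" for survival comparisons).
#' @param highlight optional named list of gene sets; the first set
#'   containing a gene labels it in a `highlight` column.
#' @param min_shared minimum gene-id intersection (default 30).
#' @return list with `table` (gene_id, value_a, value_b[, highlight]) and
#'   `r` (Pearson correlation).
#' @export
compare_summaries <- function(results_a, results_b,
                              field_a = "summary", field_b = field_a,
                              highlight = NULL, min_shared = 30L) {
  shared <- intersect(results_a$gene_id, results_b$gene_id)
  if (length(shared) == 0L) stop("no shared genes between the two tables")
  if (length(shared) < min_shared)
    stop("only ", length(shared), " shared genes (need ", min_shared, ")")
  a <- results_a[match(shared, results_a$gene_id), field_a]
  b <- results_b[match(shared, results_b$gene_id), field_b]
  tab <- data.frame(gene_id = shared, value_a = a, value_b = b,
                    stringsAsFactors = FALSE)
  if (!is.null(highlight)) {
    lab <- rep(NA_character_, nrow(tab))
    for (nm in rev(names(highlight)))
      lab[tab$gene_id %in% highlight[[nm]]] <- nm
    tab$highlight <- lab
  }
  list(table = tab, r = stats::cor(a, b))
}

#' Meta-analysis of a two-group expression difference for one gene
#'
#' Per study, computes Hedges' G of the gene's tumor expression between two
#' levels of a grouping column (e.g. mutant vs WT for a driver gene, or a
#' histology contrast across a mixed cohort), applies the per-group
#' inclusion rule, and pools qualifying studies by random-effects
#' meta-analysis. Refuses informatively when fewer than `min_k` studies
#' qualify.
#'
#' @param bundles list of `study_bundle`s.
#' @param gene gene id.
#' @param group_column column of the sample table to split on.
#' @param group_a,group_b the two levels (estimate is A minus B).
#' @param min_per_group per-study floor on each group's size (default 10).
#' @param min_k minimum qualifying studies (default 3).
#' @param tumor_only restrict to tumor samples (default TRUE).
#' @return a `meta_result`.
#' @export
group_difference_meta <- function(bundles, gene, group_column,
                                  group_a, group_b,
                                  min_per_group = 10L, min_k = 3L,
                                  tumor_only = TRUE) {
  rows <- list(); counts <- list()
  for (b in bundles) {
    if (!gene %in% rownames(b$expr)) next
    s <- b$samples
    use <- if (tumor_only) s$tissue == "tumor" else rep(TRUE, nrow(s))
    grp <- s[[group_column]]
    if (is.null(grp)) next
    ia <- use & !is.na(grp) & grp == group_a
    ib <- use & !is.na(grp) & grp == group_b
    counts[[b$study_id]] <- c(sum(ia), sum(ib))
    if (sum(ia) < min_per_group || sum(ib) < min_per_group) next
    x_a <- b$expr[gene, ia]; x_b <- b$expr[gene, ib]
    if (stats::var(x_a) + stats::var(x_b) <= 0) next
    rows[[b$study_id]] <- hedges_g(x_a, x_b, gene_id = gene,
                                   study_id = b$study_id)
  }
  est <- do.call(rbind, rows)
  if (is.null(est) || nrow(est) < min_k) {
    msg <- paste(vapply(names(counts), function(id)
      sprintf("%s: %d vs %d", id, counts[[id]][1], counts[[id]][2]), ""),
      collapse = "; ")
    stop("fewer than ", min_k, " qualifying studies for ", gene,
         " (", group_a, " vs ", group_b, "); per-study group sizes: ", msg)
  }
  random_effects_meta(est)
}

#' Meta-analysis of the correlation between two genes
#'
#' Per study, the Pearson correlation of two genes' expression over tumor
#' samples, pooled on the Fisher-z scale across qualifying studies
#' (n >= `min_n` per study, >= `min_k` studies). The summary is reported
#' back-transformed by [forest_data()] / `tanh`.
#'
#' @param bundles list of `study_bundle`s.
#' @param gene_a,gene_b gene ids.
#' @param tumor_only restrict to tumor samples (default TRUE).
#' @param min_n per-study floor on paired samples (default 10).
#' @param min_k minimum qualifying studies (default 3).
#' @return a `meta_result` on the Fisher-z scale; `tanh(summary)` and the
#'   tanh-transformed CI give the summary correlation.
#' @export
gene_pair_correlation_meta <- function(bundles, gene_a, gene_b,
                                       tumor_only = TRUE,
                                       min_n = 10L, min_k = 3L) {
  pair_id <- paste(gene_a, gene_b, sep = ":")
  rows <- list()
  for (b in bundles) {
    if (!all(c(gene_a, gene_b) %in% rownames(b$expr))) next
    use <- if (tumor_only) b$samples$tissue == "tumor"
           else rep(TRUE, nrow(b$samples))
    x <- b$expr[gene_a, use]; y <- b$expr[gene_b, use]
    keep <- !is.na(x) & !is.na(y)
    if (sum(keep) < min_n) next
    if (stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0) next
    rows[[b$study_id]] <- pearson_fisherz(x[keep], y[keep],
                                          gene_id = pair_id,
                                          study_id = b$study_id)
  }
  est <- do.call(rbind, rows)
  if (is.null(est) || nrow(est) < min_k)
    stop("fewer than ", min_k, " qualifying studies for pair ", pair_id)
  random_effects_meta(est)
}

#' Rank of a gene's summary estimate among all genes
#'
#' Position of the gene when all genes are sorted by their summary estimate
#' in the stated direction (1 = most extreme); tied genes share the minimum
#' rank.
#'
#' @param results a meta results table.
#' @param gene gene id.
#' @param direction "positive" (largest first, default) or "negative".
#' @return list with `rank` and `total`.
#' @export
rank_gene <- function(results, gene, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (!gene %in% results$gene_id) {
    near <- utils::head(agrep(gene, results$gene_id, value = TRUE,
                              max.distance = 0.2), 5)
    stop("gene ", gene, " not in results table",
         if (length(near)) paste0("; nearest matches: ",
                                  paste(near, collapse = ", ")) else "")
  }
  vals <- results$summary
  if (direction == "positive") vals <- -vals
  rk <- rank(vals, ties.method = "min")
  list(rank = rk[match(gene, results$gene_id)], total = nrow(results))
}

#' Survival meta-analysis of a clinical covariate
#'
#' Per study, a univariate Cox model of overall survival on an encoded
#' clinical covariate over tumor samples with survival data (age in
#' decades by default, gender as a male-vs-female indicator, stage as
#' ordinal numeric), pooled across qualifying studies by random-effects
#' meta-analysis of the log hazard ratios. Studies with a constant
#' covariate or a flagged (non-converged) fit are excluded.
#'
#' @param bundles list of `study_bundle`s.
#' @param covariate column name in the sample tables.
#' @param encoding "default" (age/10, male indicator, ordinal stage) or
#'   "identity" (use values as is; factors become their ordinal codes).
#' @param min_n per-study floor on informative samples (default 10).
#' @param min_k minimum qualifying studies (default 3).
#' @return a `meta_result` (LOGHR scale).
#' @export
clinical_covariate_meta <- function(bundles, covariate,
                                    encoding = c("default", "identity"),
                                    min_n = 10L, min_k = 3L) {
  encoding <- match.arg(encoding)
  rows <- list()
  for (b in bundles) {
    s <- b$samples
    if (is.null(s[[covariate]])) next
    use <- s$tissue == "tumor" & !is.na(s$os_time) & !is.na(s$os_event) &
      !is.na(s[[covariate]])
    if (sum(use) < min_n) next
    v <- s[[covariate]][use]
    x <- if (encoding == "default" && covariate == "age") as.numeric(v) / 10
         else if (encoding == "default" && covariate == "gender")
           as.numeric(v == "M")
         else if (is.character(v) || is.factor(v))
           as.numeric(factor(v))
         else as.numeric(v)
    if (stats::sd(x) == 0) next
    r <- tryCatch(
      cox_association(x, s$os_time[use], s$os_event[use],
                      gene_id = covariate, study_id = b$study_id),
      error = function(e) NULL)
    if (is.null(r) || r$flagged) next
    r$flagged <- NULL
    rows[[b$study_id]] <- r
  }
  est <- do.call(rbind, rows)
  if (is.null(est) || nrow(est) < min_k)
    stop("fewer than ", min_k, " qualifying studies for covariate ", covariate)
  random_effects_meta(est)
}
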