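#' Write a cohort to a directory of per-study TSV bundles
#'
#' One subdirectory per study containing `expr.tsv` (genes x samples; the
#' first column holds gene ids) and `clinical.tsv` (one row per sample).
#' If a `synthetic_truth` is supplied it is serialized to `truth.json` at
#' the cohort root. The same layout is read back by [read_cohort()] and is
#' the expected layout for user-supplied real data.
#'
#' @param studies list of `study_bundle`s.
#' @param dir output directory (created if needed).
#' @param truth optional `synthetic_truth`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(studies, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in studies) {
    sd <- file.path(dir, b$study_id)
    dir.create(sd, showWarnings = FALSE)
    expr_df <- data.frame(gene_id = rownames(b$expr), b$expr,
                          check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(expr_df, file.path(sd, "expr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(b$samples, file.path(sd, "clinical.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  }
  if (!is.null(truth)) {
    tr <- truth
    tr$config <- unclass(tr$config)
    tr$risk <- lapply(tr$risk, as.list)
    jsonlite::write_json(unclass(tr), file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }
  invisible(dir)
}

#' Read a cohort from a directory of per-study TSV bundles
#'
#' Inverse of [write_cohort()]: expects per-study subdirectories each with
#' `expr.tsv` and `clinical.tsv`, cross-checks that expression columns and
#' clinical rows agree, and validates each bundle's invariants. Samples
#' with missing survival are loaded as is (they are excluded only from
#' survival operations downstream).
#'
#' @param dir cohort directory.
#' @return named list of `study_bundle`s.
#' @export
read_cohort <- function(dir) {
  subs <- list.dirs(dir, recursive = FALSE)
  subs <- subs[file.exists(file.path(subs, "expr.tsv"))]
  if (length(subs) == 0L) stop("no study subdirectories with expr.tsv under ", dir)
  studies <- lapply(subs, function(sd) {
    sid <- basename(sd)
    expr_df <- utils::read.delim(file.path(sd, "expr.tsv"),
                                 check.names = FALSE,
                                 stringsAsFactors = FALSE)
    samples <- utils::read.delim(file.path(sd, "clinical.tsv"),
                                 stringsAsFactors = FALSE)
    gene_ids <- expr_df[[1]]
    X <- as.matrix(expr_df[, -1, drop = FALSE])
    if (!is.numeric(X)) {
      bad <- which(!vapply(expr_df[, -1, drop = FALSE], is.numeric, TRUE))
      stop("non-numeric expression values in study ", sid,
           ", column(s): ", paste(names(bad), collapse = ", "))
    }
    rownames(X) <- gene_ids
    if (!setequal(colnames(X), samples$sample_id)) {
      off <- c(setdiff(colnames(X), samples$sample_id),
               setdiff(samples$sample_id, colnames(X)))
      stop("sample ids disagree between expr.tsv and clinical.tsv in study ",
           sid, ": ", paste(off, collapse = ", "))
    }
    X <- X[, as.character(samples$sample_id), drop = FALSE]
    study_bundle(sid, X, samples)
  })
  names(studies) <- vapply(studies, `[[`, "", "study_id")
  message(length(studies), " studies read: ",
          paste(vapply(studies, function(b)
            sprintf("%s (%d genes x %d samples)", b$study_id,
                    nrow(b$expr), ncol(b$expr)), ""), collapse = ", "))
  studies
}

#' Run the full multi-study analysis pipeline
#'
#' Orchestrates the standard order of operations on a cohort:
#' per-study effect estimation (tumor-vs-normal SMD and/or gene-wise
#' survival log HR), inclusion-rule filtering, gene-wise random-effects
#' meta-analysis, optional preranked gene-set enrichment on the summary
#' statistics, cross-study reproducibility, and the SMD-versus-survival-z
#' comparison. Results are written as TSV under one directory per
#' analysis, with a JSON manifest recording the configuration, seed,
#' package version and per-stage gene/study counts. Deterministic for a
#' fixed cohort and seed.
#'
#' @param bundles list of `study_bundle`s (or a cohort directory path).
#' @param out_dir output directory.
#' @param analyses subset of c("SMD", "LOGHR") (default both).
#' @param gmt optional path to a GMT file for enrichment.
#' @param seed seed for the enrichment permutation null.
#' @param n_perm permutations for enrichment (default 2000).
#' @param min_per_group,min_informative,min_k inclusion rules (defaults
#'   10 / 10 / 3).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(bundles, out_dir, analyses = c("SMD", "LOGHR"),
                         gmt = NULL, seed = 1L, n_perm = 2000L,
                         min_per_group = 10L, min_informative = 10L,
                         min_k = 3L) {
  if (is.character(bundles)) bundles <- read_cohort(bundles)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all_genes <- unique(unlist(lapply(bundles, function(b) rownames(b$expr))))
  manifest <- list(seed = seed, analyses = analyses,
                   package_version = as.character(utils::packageVersion("lungmeta")),
                   n_studies = length(bundles),
                   studies = vapply(bundles, function(b)
                     ncol(b$expr), 0L),
                   counts = list(), warnings = list())
  gene_sets <- if (!is.null(gmt)) read_gmt(gmt) else NULL
  meta_tabs <- list()
  for (an in analyses) {
    eff <- if (an == "SMD")
      lapply(bundles, smd_table)
    else
      lapply(bundles, loghr_table)
    masked_per_study <- lapply(eff, attr, "masked_genes")
    eff <- do.call(rbind, eff)
    estimated_genes <- unique(eff$gene_id)
    genes_masked <- setdiff(all_genes, estimated_genes)
    qual <- qualify_studies(eff, analysis = an,
                            min_per_group = min_per_group,
                            min_informative = min_informative, min_k = min_k)
    res <- meta_table(qual$estimates, min_k = min_k)
    genes_filtered <- setdiff(estimated_genes, res$gene_id)
    sub <- file.path(out_dir, tolower(an))
    dir.create(sub, showWarnings = FALSE)
    utils::write.table(res, file.path(sub, "results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (length(bundles) >= 2L && length(unique(eff$study_id)) >= 2L) {
      rep_m <- reproducibility_matrix(eff)
      utils::write.table(
        data.frame(study_id = rownames(rep_m$matrix), rep_m$matrix,
                   check.names = FALSE),
        file.path(sub, "reproducibility.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$counts[[an]]$reproducibility_median <- rep_m$median
    }
    if (!is.null(gene_sets) && nrow(res) > 0) {
      stat <- if (an == "LOGHR") stats::setNames(res$z_score, res$gene_id)
              else stats::setNames(res$summary, res$gene_id)
      enr <- gsea_preranked(stat, gene_sets, n_perm = n_perm, seed = seed)
      utils::write.table(enr, file.path(sub, "enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    manifest$counts[[an]] <- c(manifest$counts[[an]], list(
      genes_in = length(all_genes),
      genes_masked = length(genes_masked),
      genes_filtered = length(genes_filtered),
      genes_in_results = nrow(res),
      studies_dropped = length(unique(qual$dropped_studies$study_id))))
    manifest$warnings[[an]] <- list(
      masked_genes_per_study = vapply(masked_per_study, length, 0L),
      dropped_gene_examples = utils::head(qual$dropped_genes, 20))
    if (nrow(res) == 0)
      warning("meta stage for ", an, " emitted zero genes ",
              "(inclusion rules: >= ", min_k, " qualifying studies)")
    meta_tabs[[an]] <- res
  }
  if (all(c("SMD", "LOGHR") %in% names(meta_tabs)) &&
      length(intersect(meta_tabs$SMD$gene_id, meta_tabs$LOGHR$gene_id)) >= 30) {
    cmp <- compare_summaries(meta_tabs$SMD, meta_tabs$LOGHR,
                             field_a = "summary", field_b = "z_score")
    utils::write.table(cmp$table, file.path(out_dir, "smd_vs_survival_z.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$smd_vs_survival_z_r <- cmp$r
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
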