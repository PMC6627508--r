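#' Pooled-sample differential expression across studies
#'
#' Concatenates all samples of all studies, ignoring study identity, and
#' performs a per-gene Welch two-sample t-test of tumor versus normal —
#' the naive "just pool everything" analysis whose anti-conservatism under
#' study batch structure the permutation experiment demonstrates.
#'
#' @param bundles list of `study_bundle`s (genes are intersected).
#' @return data.frame with gene_id, t, df, p (two-sided); genes constant
#'   within either pooled group are masked (attribute `masked_genes`).
#' @export
pooled_differential <- function(bundles) {
  if (length(bundles) < 1L) stop("no studies supplied")
  genes <- Reduce(intersect, lapply(bundles, function(b) rownames(b$expr)))
  if (length(genes) == 0L) stop("no shared genes across studies")
  X <- do.call(cbind, lapply(bundles, function(b) b$expr[genes, , drop = FALSE]))
  tissue <- unlist(lapply(bundles, function(b) b$samples$tissue))
  if (!all(c("tumor", "normal") %in% tissue))
    stop("both tumor and normal labels must be present in the pool")
  tum <- tissue == "tumor"
  n1 <- sum(tum); n2 <- sum(!tum)
  m1 <- rowMeans(X[, tum, drop = FALSE]); m2 <- rowMeans(X[, !tum, drop = FALSE])
  v1 <- row_vars(X[, tum, drop = FALSE]); v2 <- row_vars(X[, !tum, drop = FALSE])
  se2 <- v1 / n1 + v2 / n2
  ok <- is.finite(se2) & se2 > 0
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  out <- data.frame(gene_id = genes, t = tt, df = df, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)[ok, ]
  attr(out, "masked_genes") <- genes[!ok]
  out
}

#' Permute tumor/normal labels
#'
#' Shuffles the tissue labels, by default independently within each study so
#' per-study tumor/normal counts (and hence study composition) are
#' preserved; a global permutation across the pooled samples is available
#' behind `within_study = FALSE`. Deterministic per seed.
#'
#' @param bundles list of `study_bundle`s.
#' @param seed integer seed.
#' @param within_study permute within each study (default TRUE).
#' @return the bundles with permuted tissue labels.
#' @export
permute_labels <- function(bundles, seed, within_study = TRUE) {
  set.seed(as.integer(seed))
  if (within_study) {
    for (i in seq_along(bundles))
      bundles[[i]]$samples$tissue <- sample(bundles[[i]]$samples$tissue)
  } else {
    all_lab <- unlist(lapply(bundles, function(b) b$samples$tissue))
    all_lab <- sample(all_lab)
    off <- 0L
    for (i in seq_along(bundles)) {
      n <- nrow(bundles[[i]]$samples)
      bundles[[i]]$samples$tissue <- all_lab[off + seq_len(n)]
      off <- off + n
    }
  }
  bundles
}

ks_uniform <- function(p, alternative = "two.sided") {
  p <- p[is.finite(p)]
  unname(suppressWarnings(stats::ks.test(p, "punif",
                                         alternative = alternative))$statistic)
}

significant_fraction <- function(p, alpha, correction) {
  m <- length(p)
  adj <- switch(correction,
                bonferroni = pmin(1, p * m),
                bh = stats::p.adjust(p, method = "BH"),
                none = p,
                stop("unknown correction: ", correction))
  mean(adj < alpha)
}

#' Pooled-vs-meta label-permutation inflation experiment
#'
#' Permutes the tumor/normal labels once (within study), then runs both the
#' pooled-sample Welch analysis and the per-study effect-size +
#' random-effects meta-analysis path on the permuted data. Under the
#' permutation null every p-value vector should be uniform; study batch
#' structure inflates the pooled path while the meta path stays calibrated.
#'
#' @param bundles list of `study_bundle`s.
#' @param seed seed for the permutation.
#' @param alpha significance level applied after correction (default 0.05).
#' @param correction "bonferroni" (default), "bh" or "none".
#' @param min_k gene inclusion rule for the meta path (default 3 studies).
#' @return list of class `inflation_report` with elements `p_pooled`,
#'   `p_meta` (per-gene p data.frames), `sig_fraction` (named vector for
#'   the two paths), `ks` (two-sided KS statistics of each p-vector
#'   against Uniform(0,1)), `ks_anticons` (the one-sided KS deviation in
#'   the anti-conservative direction, the relevant measure of inflation —
#'   a merely conservative p-vector scores near 0), `qq` (long data.frame
#'   of sorted observed vs expected -log10 p per path), and the settings
#'   used.
#' @export
inflation_experiment <- function(bundles, seed, alpha = 0.05,
                                 correction = "bonferroni", min_k = 3L) {
  perm <- permute_labels(bundles, seed)
  pooled <- pooled_differential(perm)
  eff <- do.call(rbind, lapply(perm, smd_table))
  qual <- qualify_studies(eff, analysis = "SMD", min_k = min_k)
  meta <- meta_table(qual$estimates, min_k = min_k)
  qq_one <- function(p, path) {
    p <- sort(p[is.finite(p)])
    data.frame(path = path,
               expected = -log10(stats::ppoints(length(p))),
               observed = sort(-log10(p), decreasing = TRUE) * 1, # descending obs
               stringsAsFactors = FALSE)
  }
  qq <- rbind(qq_one(pooled$p, "pooled"), qq_one(meta$p, "meta"))
  structure(list(
    p_pooled = pooled[, c("gene_id", "p")],
    p_meta = meta[, c("gene_id", "p")],
    sig_fraction = c(pooled = significant_fraction(pooled$p, alpha, correction),
                     meta = significant_fraction(meta$p, alpha, correction)),
    ks = c(pooled = ks_uniform(pooled$p), meta = ks_uniform(meta$p)),
    # one-sided deviation in the inflating direction (observed p smaller
    # than uniform); a conservative p-vector scores ~0 here
    ks_anticons = c(pooled = ks_uniform(pooled$p, "greater"),
                    meta = ks_uniform(meta$p, "greater")),
    qq = qq, alpha = alpha, correction = correction, seed = seed
  ), class = "inflation_report")
}

#' @export
print.inflation_report <- function(x, ...) {
  cat(sprintf("inflation_report (%s at alpha=%g): pooled sig frac %.4f (KS %.4f) vs meta %.4f (KS %.4f)\n",
              x$correction, x$alpha, x$sig_fraction[["pooled"]],
              x$ks[["pooled"]], x$sig_fraction[["meta"]], x$ks[["meta"]]))
  invisible(x)
}

#' PCA tumor/normal separation check for one study
#'
#' Centers genes, projects samples onto the first two principal components
#' and scores how well the tumor/normal partition separates in that plane
#' by the mean silhouette width.
#'
#' @param bundle a `study_bundle` with >= 3 samples and both tissue labels.
#' @return list with `scores` (per-sample PC1/PC2 data.frame) and
#'   `silhouette` (mean width; NA with a `flag` when only one label is
#'   present).
#' @export
pca_separation <- function(bundle) {
  s <- bundle$samples
  if (nrow(s) < 3L) stop("need at least 3 samples")
  X <- bundle$expr[stats::complete.cases(bundle$expr), , drop = FALSE]
  pc <- stats::prcomp(t(X), center = TRUE, scale. = FALSE, rank. = 2)
  sc <- data.frame(sample_id = s$sample_id, tissue = s$tissue,
                   PC1 = pc$x[, 1], PC2 = pc$x[, 2],
                   stringsAsFactors = FALSE, row.names = NULL)
  if (length(unique(s$tissue)) < 2L)
    return(list(scores = sc, silhouette = NA_real_,
                flag = "single tissue label; separation undefined"))
  sil <- cluster::silhouette(as.integer(factor(s$tissue)),
                             stats::dist(sc[, c("PC1", "PC2")]))
  list(scores = sc, silhouette = mean(sil[, "sil_width"]), flag = NULL)
}
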