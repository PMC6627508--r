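#' Apply study/gene inclusion rules to per-study effect estimates
#'
#' A study's estimate qualifies for the tumor-vs-normal (SMD) analysis only
#' if both groups have at least `min_per_group` samples; for the survival
#' (LOGHR) and correlation (FISHERZ) analyses only if at least
#' `min_informative` informative samples contributed. A gene is retained
#' only if at least `min_k` qualifying studies contribute an estimate.
#'
#' @param estimates data.frame of effect estimates (rows from
#'   [smd_table()], [loghr_table()], [pearson_fisherz()], ...).
#' @param analysis restrict to one analysis type (default: use the
#'   `analysis` column as is; all rows must share one type).
#' @param min_per_group per-group floor for SMD studies (default 10).
#' @param min_informative floor on informative samples for LOGHR / FISHERZ
#'   studies (default 10).
#' @param min_k minimum number of qualifying studies per gene (default 3).
#' @return list with `estimates` (qualifying rows), `dropped_studies`
#'   (study/gene rows removed by the per-study rule), `dropped_genes`
#'   (genes removed by the `min_k` rule) and `counts` (a summary used by
#'   pipeline manifests).
#' @export
qualify_studies <- function(estimates, analysis = NULL,
                            min_per_group = 10L, min_informative = 10L,
                            min_k = 3L) {
  if (!is.null(analysis)) estimates <- estimates[estimates$analysis == analysis, ]
  if (nrow(estimates) == 0L)
    return(list(estimates = estimates, dropped_studies = estimates,
                dropped_genes = character(0),
                counts = c(rows_in = 0L, rows_dropped = 0L, genes_dropped = 0L)))
  ok <- ifelse(estimates$analysis == "SMD",
               estimates$n1 >= min_per_group & estimates$n2 >= min_per_group,
               estimates$n >= min_informative)
  kept <- estimates[ok, ]
  k_per_gene <- table(kept$gene_id)
  good_genes <- names(k_per_gene)[k_per_gene >= min_k]
  dropped_genes <- setdiff(unique(estimates$gene_id), good_genes)
  out <- kept[kept$gene_id %in% good_genes, ]
  list(estimates = out,
       dropped_studies = estimates[!ok, ],
       dropped_genes = dropped_genes,
       counts = c(rows_in = nrow(estimates), rows_dropped = sum(!ok),
                  genes_dropped = length(dropped_genes)))
}

# restricted maximum-likelihood tau2 by direct maximization of the
# restricted log-likelihood (one-dimensional, bounded search)
reml_tau2 <- function(y, v) {
  nll <- function(tau2) {
    w <- 1 / (v + tau2)
    mu <- sum(w * y) / sum(w)
    0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (y - mu)^2))
  }
  upper <- max(stats::var(y) * 4, max(v) * 4, 1e-3)
  opt <- stats::optimize(nll, c(0, upper), tol = 1e-12)
  if (nll(0) <= opt$objective) 0 else opt$minimum
}

# closed-form DerSimonian-Laird pooling of one gene's estimates
dl_core <- function(y, v) {
  k <- length(y)
  w <- 1 / v
  sw <- sum(w)
  yf <- sum(w * y) / sw
  Q <- sum(w * (y - yf)^2)
  cval <- sw - sum(w^2) / sw
  tau2 <- max(0, (Q - (k - 1)) / cval)
  ws <- 1 / (v + tau2)
  summ <- sum(ws * y) / sum(ws)
  se <- sqrt(1 / sum(ws))
  z <- summ / se
  I2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  c(k = k, summary = summ, se = se,
    ci_low = summ - 1.96 * se, ci_high = summ + 1.96 * se,
    z_score = z, p = 2 * stats::pnorm(-abs(z)), Q = Q, tau2 = tau2, I2 = I2)
}

#' Random-effects meta-analysis of one gene's per-study estimates
#'
#' DerSimonian-Laird inverse-variance random-effects pooling:
#' fixed-effect weights \eqn{w_i = 1/v_i} give Cochran's
#' \eqn{Q = \sum w_i (y_i - \hat y_{FE})^2}; the between-study variance is
#' \eqn{\hat\tau^2 = \max\{0, (Q - (k-1)) / (\sum w - \sum w^2/\sum w)\}};
#' random-effects weights \eqn{w_i^* = 1/(v_i + \hat\tau^2)} yield the
#' summary estimate, its SE, a Wald z and two-sided normal p, a 95% CI, and
#' \eqn{I^2 = \max\{0, (Q-(k-1))/Q\} \times 100}.
#'
#' @param estimates data.frame of >= 3 effect estimates for one gene and
#'   one analysis type, with positive variances.
#' @param method between-study variance estimator: `"DL"`
#'   (DerSimonian-Laird, closed form, default) or `"REML"` (restricted
#'   maximum likelihood, for sensitivity analyses).
#' @param knapp_hartung apply the Knapp-Hartung adjustment: the summary SE
#'   is rescaled by the weighted residual mean square and inference uses a
#'   t distribution with k - 1 df (default FALSE, plain Wald).
#' @return object of class `meta_result`: the summary fields plus
#'   `per_study` (the input rows with their normalized random-effects
#'   weights). For LOGHR results report `exp(summary)` as the HR; for
#'   FISHERZ report `tanh(summary)` as the correlation (see
#'   [forest_data()]).
#' @export
random_effects_meta <- function(estimates, method = c("DL", "REML"),
                                knapp_hartung = FALSE) {
  method <- match.arg(method)
  if (length(unique(estimates$gene_id)) != 1L ||
      length(unique(estimates$analysis)) != 1L)
    stop("estimates must be for a single gene and analysis")
  if (nrow(estimates) < 3L)
    stop("at least 3 qualifying studies are required (got ",
         nrow(estimates), ")")
  if (any(estimates$variance <= 0)) stop("nonpositive variance")
  y <- estimates$estimate; v <- estimates$variance
  s <- dl_core(y, v)
  if (method == "REML") {
    tau2 <- reml_tau2(y, v)
    ws0 <- 1 / (v + tau2)
    summ <- sum(ws0 * y) / sum(ws0)
    se <- sqrt(1 / sum(ws0))
    z <- summ / se
    s[["tau2"]] <- tau2; s[["summary"]] <- summ; s[["se"]] <- se
    s[["z_score"]] <- z; s[["p"]] <- 2 * stats::pnorm(-abs(z))
    s[["ci_low"]] <- summ - 1.96 * se; s[["ci_high"]] <- summ + 1.96 * se
  }
  k <- nrow(estimates)
  ws <- 1 / (v + s[["tau2"]])
  if (knapp_hartung) {
    q <- sum(ws * (y - s[["summary"]])^2) / (k - 1)
    se <- sqrt(q / sum(ws))
    tcrit <- stats::qt(0.975, df = k - 1)
    s[["se"]] <- se
    s[["z_score"]] <- s[["summary"]] / se
    s[["p"]] <- 2 * stats::pt(-abs(s[["z_score"]]), df = k - 1)
    s[["ci_low"]] <- s[["summary"]] - tcrit * se
    s[["ci_high"]] <- s[["summary"]] + tcrit * se
  }
  per_study <- estimates
  per_study$weight <- ws / sum(ws)
  structure(list(
    gene_id = estimates$gene_id[1], analysis = estimates$analysis[1],
    k = as.integer(s[["k"]]), summary = s[["summary"]], se = s[["se"]],
    ci_low = s[["ci_low"]], ci_high = s[["ci_high"]],
    z_score = s[["z_score"]], p = s[["p"]], Q = s[["Q"]],
    tau2 = s[["tau2"]], I2 = s[["I2"]], per_study = per_study
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("meta_result %s [%s]: k=%d summary=%.4f (95%% CI %.4f..%.4f) p=%.3g tau2=%.4f I2=%.1f%%\n",
              x$gene_id, x$analysis, x$k, x$summary, x$ci_low, x$ci_high,
              x$p, x$tau2, x$I2))
  invisible(x)
}

#' Gene-wise random-effects meta-analysis table
#'
#' Vectorized DerSimonian-Laird pooling of a (typically pre-qualified)
#' estimates table, one output row per gene with >= `min_k` studies.
#' Bonferroni and Benjamini-Hochberg adjusted p-values are appended across
#' the emitted genes.
#'
#' @param estimates data.frame of effect estimates, one analysis type.
#' @param min_k minimum studies per gene (default 3).
#' @return data.frame with columns gene_id, analysis, k, summary, se,
#'   ci_low, ci_high, z_score, p, p_bonf, p_bh, Q, tau2, I2.
#' @export
meta_table <- function(estimates, min_k = 3L) {
  if (length(unique(estimates$analysis)) > 1L)
    stop("meta_table expects a single analysis type")
  if (nrow(estimates) == 0L)
    return(data.frame(gene_id = character(0), analysis = character(0),
                      k = integer(0), summary = numeric(0), se = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      z_score = numeric(0), p = numeric(0),
                      p_bonf = numeric(0), p_bh = numeric(0), Q = numeric(0),
                      tau2 = numeric(0), I2 = numeric(0)))
  if (any(estimates$variance <= 0)) stop("nonpositive variance")
  genes <- unique(estimates$gene_id)
  studies <- unique(estimates$study_id)
  gi <- match(estimates$gene_id, genes)
  si <- match(estimates$study_id, studies)
  Y <- matrix(NA_real_, length(genes), length(studies))
  V <- matrix(NA_real_, length(genes), length(studies))
  Y[cbind(gi, si)] <- estimates$estimate
  V[cbind(gi, si)] <- estimates$variance
  W <- 1 / V
  k <- rowSums(!is.na(Y))
  sw <- rowSums(W, na.rm = TRUE)
  yf <- rowSums(W * Y, na.rm = TRUE) / sw
  Q <- rowSums(W * (Y - yf)^2, na.rm = TRUE)
  cval <- sw - rowSums(W^2, na.rm = TRUE) / sw
  tau2 <- pmax(0, (Q - (k - 1)) / cval)
  Ws <- 1 / (V + tau2)
  sws <- rowSums(Ws, na.rm = TRUE)
  summ <- rowSums(Ws * Y, na.rm = TRUE) / sws
  se <- sqrt(1 / sws)
  z <- summ / se
  p <- 2 * stats::pnorm(-abs(z))
  I2 <- ifelse(Q > 0, pmax(0, (Q - (k - 1)) / Q) * 100, 0)
  out <- data.frame(gene_id = genes, analysis = estimates$analysis[1],
                    k = as.integer(k), summary = summ, se = se,
                    ci_low = summ - 1.96 * se, ci_high = summ + 1.96 * se,
                    z_score = z, p = p, Q = Q, tau2 = tau2, I2 = I2,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[out$k >= min_k, ]
  out$p_bonf <- pmin(1, out$p * nrow(out))
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out[, c("gene_id", "analysis", "k", "summary", "se", "ci_low", "ci_high",
          "z_score", "p", "p_bonf", "p_bh", "Q", "tau2", "I2")]
}

#' Forest-plot table for a meta result
#'
#' One row per contributing study plus a summary row, on the natural
#' reporting scale of the analysis: estimates and CI bounds are
#' exponentiated to hazard ratios for LOGHR and back-transformed with
#' `tanh` to correlations for FISHERZ; SMD stays as is. Random-effects
#' weights are reported in percent.
#'
#' @param result a `meta_result`.
#' @return data.frame with columns row ("study"/"summary"), study_id,
#'   estimate, ci_low, ci_high, weight_pct.
#' @export
forest_data <- function(result) {
  stopifnot(inherits(result, "meta_result"))
  ps <- result$per_study
  lo <- ps$estimate - 1.96 * sqrt(ps$variance)
  hi <- ps$estimate + 1.96 * sqrt(ps$variance)
  est <- ps$estimate
  tr <- switch(result$analysis, LOGHR = exp, FISHERZ = tanh, identity)
  out <- data.frame(row = c(rep("study", nrow(ps)), "summary"),
                    study_id = c(ps$study_id, "summary"),
                    estimate = tr(c(est, result$summary)),
                    ci_low = tr(c(lo, result$ci_low)),
                    ci_high = tr(c(hi, result$ci_high)),
                    weight_pct = c(ps$weight * 100, 100),
                    stringsAsFactors = FALSE)
  out
}
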