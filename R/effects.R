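#' Hedges' G standardized mean difference
#'
#' Computes the bias-corrected standardized mean difference between two
#' groups (here: tumor minus normal), with its large-sample variance:
#' \deqn{d = (\bar x_1 - \bar x_2)/s_p,\quad
#'       g = J\,d,\quad J = 1 - \frac{3}{4(n_1+n_2-2)-1},}
#' \deqn{\mathrm{var}(g) = \frac{n_1+n_2}{n_1 n_2} + \frac{g^2}{2(n_1+n_2)}.}
#'
#' @param x_tumor,x_normal numeric vectors of expression values for the two
#'   groups; each must have length >= 2 and finite values.
#' @param gene_id,study_id identifiers carried into the result.
#' @return one-row data.frame with columns `study_id`, `gene_id`, `analysis`
#'   ("SMD"), `estimate`, `variance`, `n1`, `n2`, `n`.
#' @export
hedges_g <- function(x_tumor, x_normal, gene_id = NA_character_,
                     study_id = NA_character_) {
  n1 <- length(x_tumor); n2 <- length(x_normal)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  if (!all(is.finite(x_tumor)) || !all(is.finite(x_normal)))
    stop("non-finite expression values")
  s1 <- stats::var(x_tumor); s2 <- stats::var(x_normal)
  sp2 <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2)
  if (sp2 <= 0)
    stop("zero pooled SD for gene ", gene_id, " (degenerate input)")
  d <- (mean(x_tumor) - mean(x_normal)) / sqrt(sp2)
  J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  g <- J * d
  v <- (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2))
  data.frame(study_id = study_id, gene_id = gene_id, analysis = "SMD",
             estimate = g, variance = v, n1 = n1, n2 = n2, n = n1 + n2,
             events = NA_integer_, stringsAsFactors = FALSE)
}

# row variances without matrixStats
row_vars <- function(X) {
  n <- ncol(X)
  m <- rowMeans(X)
  rowSums((X - m)^2) / (n - 1)
}

#' Per-gene tumor-vs-normal Hedges' G for one study
#'
#' Vectorized application of [hedges_g()] across all genes of a study
#' bundle. Genes with zero pooled variance are masked (dropped from the
#' output, recorded in the `masked_genes` attribute) rather than erroring.
#'
#' @param bundle a `study_bundle`.
#' @return data.frame of effect estimates (one row per unmasked gene) with
#'   attribute `masked_genes`.
#' @export
smd_table <- function(bundle) {
  tum <- bundle$samples$tissue == "tumor"
  n1 <- sum(tum); n2 <- sum(!tum)
  if (n1 < 2L || n2 < 2L)
    stop("study ", bundle$study_id, " needs >= 2 samples per group")
  Xt <- bundle$expr[, tum, drop = FALSE]
  Xn <- bundle$expr[, !tum, drop = FALSE]
  s1 <- row_vars(Xt); s2 <- row_vars(Xn)
  sp2 <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2)
  ok <- is.finite(sp2) & sp2 > 0
  d <- (rowMeans(Xt) - rowMeans(Xn)) / sqrt(sp2)
  J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  g <- J * d
  v <- (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2))
  out <- data.frame(study_id = bundle$study_id,
                    gene_id = rownames(bundle$expr),
                    analysis = "SMD", estimate = g, variance = v,
                    n1 = n1, n2 = n2, n = n1 + n2, events = NA_integer_,
                    stringsAsFactors = FALSE, row.names = NULL)[ok, ]
  attr(out, "masked_genes") <- rownames(bundle$expr)[!ok]
  out
}

#' Standardize expression within a study
#'
#' Per gene, subtracts the mean and divides by the SD computed over the
#' scoped samples (the study's tumor samples for survival analysis, or all
#' samples), then applies that transform to every sample. Genes with zero
#' scoped SD are masked: their rows become NA and they are listed in the
#' bundle's `masked_genes` element (with a warning). Idempotent up to
#' numerical tolerance.
#'
#' @param bundle a `study_bundle`.
#' @param scope `"tumor_only"` (default; the scope used for survival
#'   association) or `"all"`.
#' @return the bundle with standardized expression.
#' @export
standardize_expression <- function(bundle, scope = c("tumor_only", "all")) {
  scope <- match.arg(scope)
  cols <- if (scope == "tumor_only") bundle$samples$tissue == "tumor"
          else rep(TRUE, nrow(bundle$samples))
  if (sum(cols) < 2L) stop("fewer than 2 samples in scope for study ",
                           bundle$study_id)
  Xs <- bundle$expr[, cols, drop = FALSE]
  m <- rowMeans(Xs)
  sdv <- sqrt(row_vars(Xs))
  bad <- !is.finite(sdv) | sdv <= 0
  sdv[bad] <- 1
  bundle$expr <- (bundle$expr - m) / sdv
  if (any(bad)) {
    bundle$expr[bad, ] <- NA_real_
    warning(sum(bad), " constant gene(s) masked during standardization in study ",
            bundle$study_id)
  }
  bundle$masked_genes <- union(bundle$masked_genes, rownames(bundle$expr)[bad])
  bundle
}

#' Univariate Cox proportional-hazards association
#'
#' Fits the univariate Cox model of overall survival on a standardized
#' expression (or encoded clinical) covariate, maximizing the partial
#' likelihood with the Efron correction for tied event times, and returns
#' the log hazard ratio per unit of the covariate with its variance
#' (inverse observed information).
#'
#' @param z_expr numeric covariate (expression standardized to SD 1 via
#'   [standardize_expression()] for the per-1-SD interpretation).
#' @param os_time positive survival times.
#' @param os_event 0/1 event indicators.
#' @param gene_id,study_id identifiers carried into the result.
#' @return one-row data.frame with `estimate` (log HR), `variance`, `n`,
#'   `events`, plus a logical `flagged` column set when the fit hit the
#'   iteration limit or an infinite-coefficient (monotone-likelihood)
#'   condition.
#' @export
cox_association <- function(z_expr, os_time, os_event,
                            gene_id = NA_character_, study_id = NA_character_) {
  keep <- !is.na(z_expr) & !is.na(os_time) & !is.na(os_event)
  z <- z_expr[keep]; ti <- os_time[keep]; ev <- os_event[keep]
  n <- length(z)
  if (n < 3L) stop("too few informative samples")
  if (sum(ev) < 2L) stop("fewer than 2 events")
  if (stats::sd(z) == 0) stop("constant covariate for ", gene_id,
                              ": zero information")
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(ti, ev) ~ z, ties = "efron",
                    control = survival::coxph.control(eps = 1e-10,
                                                      iter.max = 50)),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  v <- unname(fit$var[1, 1])
  if (!is.finite(beta) || !is.finite(v) || abs(beta) > 15) flagged <- TRUE
  data.frame(study_id = study_id, gene_id = gene_id, analysis = "LOGHR",
             estimate = beta, variance = v, n1 = NA_integer_, n2 = NA_integer_,
             n = n, events = sum(ev), flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Per-gene survival association for one study
#'
#' Standardizes expression over the study's tumor samples (unless `bundle`
#' is already standardized and `standardize = FALSE`) and fits
#' [cox_association()] per gene on the tumor samples with non-missing
#' survival. Masked (constant) genes and flagged (non-converged) fits
#' contribute no estimate.
#'
#' @param bundle a `study_bundle`.
#' @param standardize standardize first (default TRUE).
#' @param scope standardization scope, see [standardize_expression()].
#' @return data.frame of LOGHR effect estimates with attribute
#'   `masked_genes` (constant or flagged genes).
#' @export
loghr_table <- function(bundle, standardize = TRUE, scope = "tumor_only") {
  if (standardize)
    bundle <- suppressWarnings(standardize_expression(bundle, scope))
  s <- bundle$samples
  use <- s$tissue == "tumor" & !is.na(s$os_time) & !is.na(s$os_event)
  ti <- s$os_time[use]; ev <- s$os_event[use]
  X <- bundle$expr[, use, drop = FALSE]
  rows <- vector("list", nrow(X))
  masked <- character(0)
  if (sum(ev) >= 2L && length(ti) >= 3L) {
    for (i in seq_len(nrow(X))) {
      z <- X[i, ]
      g <- rownames(X)[i]
      if (anyNA(z) || stats::sd(z) == 0) { masked <- c(masked, g); next }
      r <- cox_association(z, ti, ev, gene_id = g, study_id = bundle$study_id)
      if (r$flagged) { masked <- c(masked, g); next }
      rows[[i]] <- r
    }
  } else {
    masked <- rownames(X)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(study_id = character(0), gene_id = character(0),
                      analysis = character(0), estimate = numeric(0),
                      variance = numeric(0), n1 = integer(0), n2 = integer(0),
                      n = integer(0), events = integer(0), flagged = logical(0))
  out$flagged <- NULL
  attr(out, "masked_genes") <- masked
  out
}

#' Pearson correlation on the Fisher-z scale
#'
#' Computes the sample Pearson correlation of two vectors and returns its
#' Fisher z transform `atanh(r)` with variance `1/(n-3)`, the per-study
#' input to a correlation meta-analysis. Correlations are clamped to
#' `|r| <= 1 - 1e-12` before the transform.
#'
#' @param x,y numeric vectors of equal length >= 4; neither may be constant.
#' @param gene_id label for the pair (e.g. "geneA:geneB").
#' @param study_id study identifier.
#' @return one-row data.frame of an effect estimate with `analysis`
#'   "FISHERZ"; the correlation is recoverable as `tanh(estimate)`.
#' @export
pearson_fisherz <- function(x, y, gene_id = NA_character_,
                            study_id = NA_character_) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector for pair ", gene_id)
  r <- stats::cor(x, y)
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  data.frame(study_id = study_id, gene_id = gene_id, analysis = "FISHERZ",
             estimate = atanh(r), variance = 1 / (n - 3),
             n1 = NA_integer_, n2 = NA_integer_, n = n, events = NA_integer_,
             stringsAsFactors = FALSE)
}
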