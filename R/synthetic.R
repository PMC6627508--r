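#' Configuration for a synthetic multi-study cohort
#'
#' Describes the data-generating process for a collection of expression
#' studies with known ground truth: per-gene true tumor-vs-normal
#' standardized mean differences (SMD) with between-study heterogeneity,
#' per-gene true log hazard ratios acting on standardized tumor expression,
#' study-level batch structure (additive per-gene offsets and one
#' multiplicative scale per study), censored survival, optional mutation
#' subgroups with expression shifts, and optional correlated gene pairs.
#'
#' Normal-tissue expression of gene \eqn{g} in study \eqn{s} is drawn as
#' \eqn{N(\mu_g + b_{sg}, (\sigma_g c_s)^2)}; tumor samples are shifted by
#' \eqn{\delta_{sg}\,\sigma_g c_s} where \eqn{\delta_{sg} \sim
#' N(\mathrm{true\_smd}_g, \tau^2)}. Survival times for tumor samples follow
#' an exponential proportional-hazards model with linear predictor
#' \eqn{\sum_g \beta_g z_{gi}} (\eqn{z} = expression standardized over the
#' study's tumor samples), with independent exponential censoring calibrated
#' to the requested censoring rate.
#'
#' @param n_studies number of studies.
#' @param genes number of genes.
#' @param samples_per_study integer range `c(min, max)`; each study's size is
#'   drawn uniformly from it (a scalar fixes the size).
#' @param tumor_fraction either a single proportion in (0,1) (every study
#'   uses it) or a range `c(lo, hi)` from which each study's tumor fraction
#'   is drawn uniformly. Varying fractions across studies mimic the uneven
#'   availability of adjacent-normal samples in real cohorts and are what
#'   makes naive sample pooling anti-conservative under batch structure.
#' @param true_smd per-gene vector of population SMDs (tumor minus normal);
#'   a scalar is recycled.
#' @param tau2_smd between-study variance of the realized per-study SMD.
#' @param true_loghr per-gene vector of log hazard ratios per 1 SD of
#'   expression; a scalar is recycled.
#' @param censoring_rate target proportion of censored tumor samples, in [0,1).
#' @param batch_shift_sd SD of the per-study, per-gene additive batch offset.
#' @param batch_scale_range range `c(lo, hi)`, `0 < lo <= hi`, of the
#'   per-study multiplicative scale applied to residual SDs.
#' @param corr_pairs list of `list(gene_a, gene_b, rho)` (indices or gene ids)
#'   giving target Pearson correlations, imposed on the residual noise via a
#'   Gaussian copula so marginal SMD structure is preserved.
#' @param mutation_genes list of `list(label, prevalence, shift)`; tumor
#'   samples are labelled mutant with the given prevalence and the per-gene
#'   `shift` (in within-group SD units; scalar recycled) is added to mutant
#'   tumors.
#' @param covariate_loghr named vector with elements `age_decade`, `male`,
#'   `stage` giving log-hazard contributions of the clinical covariates
#'   (age in decades centred at 65, male indicator, ordinal stage centred
#'   at 2). Defaults to zeros.
#' @param histology histology label given to every sample ("ADC" or "SQCC").
#' @param gene_dropout proportion of genes dropped at random per study
#'   (crude emulation of platform panels); default 0.
#' @param baseline_median_months median survival (months) for a tumor sample
#'   at linear predictor 0.
#' @param mu_mean,mu_sd mean/SD of per-gene baseline log-expression levels.
#' @param sigma_range range of per-gene residual SDs.
#' @param seed integer seed; all randomness derives from it.
#'
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_studies,
                             genes,
                             samples_per_study = c(80L, 200L),
                             tumor_fraction = c(0.25, 0.85),
                             true_smd = 0,
                             tau2_smd = 0,
                             true_loghr = 0,
                             censoring_rate = 0.3,
                             batch_shift_sd = 0.5,
                             batch_scale_range = c(0.8, 1.25),
                             corr_pairs = list(),
                             mutation_genes = list(),
                             covariate_loghr = c(age_decade = 0, male = 0, stage = 0),
                             histology = "ADC",
                             gene_dropout = 0,
                             baseline_median_months = 36,
                             mu_mean = 7,
                             mu_sd = 2,
                             sigma_range = c(0.4, 0.8),
                             seed = 1L) {
  if (length(n_studies) != 1L || n_studies < 1L) stop("n_studies must be a positive integer")
  if (length(genes) != 1L || genes < 1L) stop("genes must be a positive integer")
  if (length(samples_per_study) == 1L) samples_per_study <- rep(samples_per_study, 2L)
  samples_per_study <- as.integer(samples_per_study)
  if (samples_per_study[1] > samples_per_study[2] || samples_per_study[1] < 4L)
    stop("samples_per_study must be an increasing range with min >= 4")
  if (length(tumor_fraction) == 1L) tumor_fraction <- rep(tumor_fraction, 2L)
  if (any(tumor_fraction <= 0) || any(tumor_fraction >= 1) ||
      tumor_fraction[1] > tumor_fraction[2])
    stop("tumor_fraction must lie in (0, 1)")
  if (length(true_smd) == 1L) true_smd <- rep(true_smd, genes)
  if (length(true_loghr) == 1L) true_loghr <- rep(true_loghr, genes)
  if (length(true_smd) != genes) stop("true_smd must have length `genes`")
  if (length(true_loghr) != genes) stop("true_loghr must have length `genes`")
  if (tau2_smd < 0) stop("tau2_smd must be >= 0")
  if (censoring_rate < 0 || censoring_rate >= 1) stop("censoring_rate must be in [0, 1)")
  if (batch_shift_sd < 0) stop("batch_shift_sd must be >= 0")
  if (batch_scale_range[1] <= 0 || batch_scale_range[1] > batch_scale_range[2])
    stop("batch_scale_range must satisfy 0 < lo <= hi")
  if (gene_dropout < 0 || gene_dropout >= 1) stop("gene_dropout must be in [0, 1)")
  cov_def <- c(age_decade = 0, male = 0, stage = 0)
  cov_def[names(covariate_loghr)] <- covariate_loghr
  for (cp in corr_pairs) {
    if (length(cp) < 3L) stop("corr_pairs entries must be list(gene_a, gene_b, rho)")
    rho <- cp[[3]]
    if (abs(rho) >= 1) stop("corr_pairs rho must be in (-1, 1)")
  }
  structure(list(
    n_studies = as.integer(n_studies), genes = as.integer(genes),
    samples_per_study = samples_per_study, tumor_fraction = tumor_fraction,
    true_smd = true_smd, tau2_smd = tau2_smd, true_loghr = true_loghr,
    censoring_rate = censoring_rate, batch_shift_sd = batch_shift_sd,
    batch_scale_range = batch_scale_range, corr_pairs = corr_pairs,
    mutation_genes = mutation_genes, covariate_loghr = cov_def,
    histology = histology, gene_dropout = gene_dropout,
    baseline_median_months = baseline_median_months,
    mu_mean = mu_mean, mu_sd = mu_sd, sigma_range = sigma_range,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Construct a study bundle
#'
#' A study bundle is the unit over which all per-study estimators run: an
#' expression matrix (genes x samples, log-scale continuous values) plus a
#' sample annotation table.
#'
#' @param study_id study identifier.
#' @param expr numeric matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @param samples data.frame with one row per sample; must contain columns
#'   `sample_id`, `tissue` ("tumor"/"normal"); typically also `histology`,
#'   `os_time` (months, NA allowed), `os_event` (0/1, NA allowed) and
#'   optional covariate / mutation-status columns.
#' @return object of class `study_bundle`.
#' @export
study_bundle <- function(study_id, expr, samples) {
  b <- structure(list(study_id = study_id, expr = expr, samples = samples),
                 class = "study_bundle")
  validate_bundle(b)
  b
}

#' Validate a study bundle's invariants
#'
#' Checks sample-id uniqueness, agreement between expression columns and the
#' sample table, positivity of non-missing survival times and 0/1 coding of
#' the event indicator.
#'
#' @param bundle a `study_bundle`.
#' @return the bundle, invisibly; errors describe the offending samples.
#' @export
validate_bundle <- function(bundle) {
  s <- bundle$samples
  if (anyDuplicated(s$sample_id))
    stop("duplicate sample ids in study ", bundle$study_id, ": ",
         paste(unique(s$sample_id[duplicated(s$sample_id)]), collapse = ", "))
  if (!identical(colnames(bundle$expr), as.character(s$sample_id)))
    stop("expression columns do not match the sample table in study ",
         bundle$study_id)
  if (!is.numeric(bundle$expr))
    stop("expression matrix must be numeric in study ", bundle$study_id)
  if (!all(s$tissue %in% c("tumor", "normal")))
    stop("tissue must be 'tumor' or 'normal' in study ", bundle$study_id)
  if (!is.null(s$os_time)) {
    bad <- !is.na(s$os_time) & s$os_time <= 0
    if (any(bad))
      stop("non-positive os_time for samples ",
           paste(s$sample_id[bad], collapse = ", "), " in study ", bundle$study_id)
    ev <- s$os_event[!is.na(s$os_event)]
    if (!all(ev %in% c(0, 1)))
      stop("os_event must be 0/1 in study ", bundle$study_id)
  }
  invisible(bundle)
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("study_bundle", x$study_id, ":", nrow(x$expr), "genes x",
      ncol(x$expr), "samples (", sum(x$samples$tissue == "tumor"), "tumor /",
      sum(x$samples$tissue == "normal"), "normal )\n")
  invisible(x)
}

# deterministic per-study substream seed derived from the global seed
study_seed <- function(seed, s) {
  as.integer((as.double(seed) + 7919 * s) %% 2147483647)
}

# solve for an exponential censoring rate achieving the target censored
# proportion given heterogeneous event rates
censoring_rate_solve <- function(lambda, target) {
  if (target <= 0) return(0)
  f <- function(lc) mean(lc / (lc + lambda)) - target
  upper <- max(lambda) * target / (1 - target) * 100 + 1
  stats::uniroot(f, lower = 1e-12, upper = upper, tol = 1e-10)$root
}

#' Generate a synthetic multi-study cohort with known truth
#'
#' Draws a list of study bundles from the data-generating process described
#' in [synthetic_config()], together with the ground truth needed to test
#' parameter recovery downstream.
#'
#' @param config a `synthetic_config`.
#' @return list with elements `studies` (list of `study_bundle`) and `truth`
#'   (class `synthetic_truth`: the config echo, realized per-study per-gene
#'   SMD draws, per-study batch offsets and scales, per-gene baseline
#'   levels/SDs, and per-sample latent risk scores for tumor samples).
#' @examples
#' cfg <- synthetic_config(n_studies = 3, genes = 20, seed = 7,
#'                         samples_per_study = c(40, 60))
#' cohort <- generate_cohort(cfg)
#' cohort$studies[[1]]
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) stop("config must be a synthetic_config")
  G <- config$genes
  S <- config$n_studies
  gene_ids <- sprintf("gene_%05d", seq_len(G))

  set.seed(config$seed)
  mu <- stats::rnorm(G, config$mu_mean, config$mu_sd)
  sigma <- stats::runif(G, config$sigma_range[1], config$sigma_range[2])
  names(mu) <- names(sigma) <- gene_ids

  # resolve correlation-pair gene indices once
  pairs <- lapply(config$corr_pairs, function(cp) {
    idx <- function(g) if (is.character(g)) match(g, gene_ids) else as.integer(g)
    list(a = idx(cp[[1]]), b = idx(cp[[2]]), rho = cp[[3]])
  })

  delta_mat <- matrix(NA_real_, G, S, dimnames = list(gene_ids, NULL))
  offset_mat <- matrix(NA_real_, G, S, dimnames = list(gene_ids, NULL))
  scales <- numeric(S)
  risk <- vector("list", S)
  studies <- vector("list", S)

  for (s in seq_len(S)) {
    set.seed(study_seed(config$seed, s))
    sid <- sprintf("study_%02d", s)
    n_s <- if (config$samples_per_study[1] == config$samples_per_study[2])
      config$samples_per_study[1] else
      sample(seq(config$samples_per_study[1], config$samples_per_study[2]), 1L)
    f_s <- stats::runif(1, config$tumor_fraction[1], config$tumor_fraction[2])
    n_t <- min(max(2L, as.integer(round(f_s * n_s))), n_s - 2L)
    n_n <- n_s - n_t
    tumor <- c(rep(TRUE, n_t), rep(FALSE, n_n))

    b <- stats::rnorm(G, 0, config$batch_shift_sd)
    c_s <- stats::runif(1, config$batch_scale_range[1], config$batch_scale_range[2])
    delta <- stats::rnorm(G, config$true_smd, sqrt(config$tau2_smd))

    Z <- matrix(stats::rnorm(G * n_s), G, n_s)
    for (p in pairs)  # Gaussian copula on the residual noise
      Z[p$b, ] <- p$rho * Z[p$a, ] + sqrt(1 - p$rho^2) * Z[p$b, ]

    sd_g <- sigma * c_s
    X <- (mu + b) + sd_g * Z
    X[, tumor] <- X[, tumor] + sd_g * delta
    dimnames(X) <- list(gene_ids,
                        sprintf("%s_S%03d", sid, seq_len(n_s)))

    age <- round(stats::rnorm(n_s, 65, 10))
    gender <- sample(c("M", "F"), n_s, replace = TRUE)
    stage <- ifelse(tumor, sample(1:3, n_s, replace = TRUE,
                                  prob = c(0.45, 0.35, 0.20)), NA_integer_)

    # mutation subgroups (tumor samples only)
    mut_cols <- list()
    for (m in config$mutation_genes) {
      status <- rep(NA_character_, n_s)
      is_mut <- tumor & stats::runif(n_s) < m$prevalence
      status[tumor] <- ifelse(is_mut[tumor], "mutant", "WT")
      shift <- m$shift
      if (length(shift) == 1L) shift <- rep(shift, G)
      if (any(is_mut))
        X[, is_mut] <- X[, is_mut] + sd_g * shift
      mut_cols[[paste0(m$label, "_status")]] <- status
    }

    # survival: exponential PH on tumor samples, expression standardized
    # over the study's tumor samples
    Xt <- X[, tumor, drop = FALSE]
    zt <- (Xt - rowMeans(Xt)) / apply(Xt, 1, stats::sd)
    zt[!is.finite(zt)] <- 0
    eta <- as.vector(colSums(zt * config$true_loghr))
    cl <- config$covariate_loghr
    eta <- eta + cl[["age_decade"]] * (age[tumor] - 65) / 10 +
      cl[["male"]] * (gender[tumor] == "M") +
      cl[["stage"]] * (stage[tumor] - 2)
    lambda0 <- log(2) / config$baseline_median_months
    lam <- lambda0 * exp(eta)
    t_event <- stats::rexp(n_t, lam)
    if (config$censoring_rate > 0) {
      lc <- censoring_rate_solve(lam, config$censoring_rate)
      t_cens <- stats::rexp(n_t, lc)
      os_time_t <- pmin(t_event, t_cens)
      os_event_t <- as.integer(t_event <= t_cens)
    } else {
      os_time_t <- t_event
      os_event_t <- rep(1L, n_t)
    }
    os_time <- rep(NA_real_, n_s); os_time[tumor] <- os_time_t
    os_event <- rep(NA_integer_, n_s); os_event[tumor] <- os_event_t

    samples <- data.frame(
      sample_id = colnames(X),
      tissue = ifelse(tumor, "tumor", "normal"),
      histology = config$histology,
      os_time = os_time, os_event = os_event,
      age = age, gender = gender, stage = stage,
      stringsAsFactors = FALSE
    )
    for (nm in names(mut_cols)) samples[[nm]] <- mut_cols[[nm]]

    if (config$gene_dropout > 0) {
      keep <- stats::runif(G) >= config$gene_dropout
      X <- X[keep, , drop = FALSE]
    }

    studies[[s]] <- study_bundle(sid, X, samples)
    delta_mat[, s] <- delta
    offset_mat[, s] <- b
    scales[s] <- c_s
    risk[[s]] <- stats::setNames(eta, colnames(Xt))
  }
  names(studies) <- vapply(studies, `[[`, "", "study_id")
  colnames(delta_mat) <- colnames(offset_mat) <- names(studies)
  truth <- structure(list(
    config = config, realized_smd = delta_mat, batch_offsets = offset_mat,
    batch_scales = stats::setNames(scales, names(studies)),
    mu = mu, sigma = sigma, risk = risk
  ), class = "synthetic_truth")
  list(studies = studies, truth = truth)
}
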