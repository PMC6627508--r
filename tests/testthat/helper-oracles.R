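# Independent oracles, coded directly from the textbook formulas and kept
# separate from the package implementations they check.

# Hedges' G with small-sample correction, literal transcription
oracle_hedges <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  s_pooled <- sqrt(((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2))
  d <- (mean(x1) - mean(x2)) / s_pooled
  J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  g <- J * d
  list(g = g, var = (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2)))
}

# DerSimonian-Laird pooling, literal transcription
oracle_dl <- function(y, v) {
  k <- length(y)
  w <- 1 / v
  mu_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - mu_fe)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (v + tau2)
  mu <- sum(ws * y) / sum(ws)
  se <- sqrt(1 / sum(ws))
  list(summary = mu, se = se, Q = Q, tau2 = tau2,
       I2 = if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0)
}

# Efron-corrected Cox partial log-likelihood for a single covariate,
# evaluated by direct summation over event times
oracle_cox_loglik <- function(beta, x, time, event) {
  r <- exp(beta * x)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    sum_r <- sum(r[R]); sum_d <- sum(r[D])
    for (l in seq_len(d) - 1)
      ll <- ll - log(sum_r - l / d * sum_d)
    ll <- ll + beta * sum(x[D])
  }
  ll
}

oracle_cox_beta <- function(x, time, event, interval = c(-10, 10)) {
  optimize(function(b) oracle_cox_loglik(b, x, time, event),
           interval = interval, maximum = TRUE, tol = 1e-10)$maximum
}

# GSEA running sum stepped explicitly, position by position
oracle_es_walk <- function(stats_vec, gene_set, weight = 1) {
  ord <- order(-stats_vec, names(stats_vec), method = "radix")
  sorted <- stats_vec[ord]
  hit <- names(sorted) %in% gene_set
  N <- length(sorted); m <- sum(hit)
  denom <- sum(abs(sorted[hit])^weight)
  running <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- if (hit[i]) {
      cur + (if (denom > 0) abs(sorted[i])^weight / denom else 1 / m)
    } else cur - 1 / (N - m)
    running[i] <- cur
  }
  running[which.max(abs(running))]
}

# exhaustive permutation p-value over all same-size gene subsets
oracle_gsea_exhaustive_p <- function(stats_vec, gene_set) {
  es <- oracle_es_walk(stats_vec, gene_set)
  m <- length(intersect(gene_set, names(stats_vec)))
  combs <- combn(names(stats_vec), m)
  nulls <- apply(combs, 2, function(g) oracle_es_walk(stats_vec, g))
  same <- nulls * sign(es) > 0
  (1 + sum(abs(nulls[same]) >= abs(es))) / (1 + sum(same))
}

# small default cohort used across tests
make_cohort <- function(n_studies = 4, genes = 30, seed = 1,
                        samples_per_study = c(60, 90), ...) {
  generate_cohort(synthetic_config(n_studies = n_studies, genes = genes,
                                   seed = seed,
                                   samples_per_study = samples_per_study,
                                   ...))
}

gene_id <- function(i) sprintf("gene_%05d", i)
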