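fake_estimates <- function(y, v, gene = "g1", analysis = "SMD") {
  data.frame(study_id = sprintf("s%d", seq_along(y)), gene_id = gene,
             analysis = analysis, estimate = y, variance = v,
             n1 = 20L, n2 = 20L, n = 40L, events = NA_integer_,
             stringsAsFactors = FALSE)
}

test_that("homogeneous limit: k identical estimates give Q = 0 and se/sqrt(k)", {
  est <- fake_estimates(rep(0.4, 5), rep(0.09, 5))
  m <- random_effects_meta(est)
  expect_equal(m$Q, 0)
  expect_equal(m$tau2, 0)
  expect_equal(m$summary, 0.4)
  expect_equal(m$se, sqrt(0.09 / 5))
  expect_equal(m$I2, 0)
  expect_equal(sum(m$per_study$weight), 1, tolerance = 1e-9)
})

test_that("DerSimonian-Laird output matches the hand-coded oracle and metafor", {
  y <- c(0.2, 0.5, 0.9); v <- c(0.04, 0.05, 0.1)
  m <- random_effects_meta(fake_estimates(y, v))
  o <- oracle_dl(y, v)
  expect_equal(m$summary, o$summary, tolerance = 1e-10)
  expect_equal(m$se, o$se, tolerance = 1e-10)
  expect_equal(m$tau2, o$tau2, tolerance = 1e-10)
  expect_equal(m$I2, o$I2, tolerance = 1e-10)
  skip_if_not_installed("metafor")
  r <- metafor::rma(yi = y, vi = v, method = "DL")
  expect_equal(m$summary, as.numeric(r$b), tolerance = 1e-10)
  expect_equal(m$se, r$se, tolerance = 1e-10)
  expect_equal(m$tau2, r$tau2, tolerance = 1e-10)
})

test_that("REML and Knapp-Hartung sensitivity options match metafor", {
  skip_if_not_installed("metafor")
  set.seed(4)
  y <- rnorm(7, 0.3, 0.4); v <- runif(7, 0.02, 0.15)
  est <- fake_estimates(y, v)
  m_reml <- random_effects_meta(est, method = "REML")
  r_reml <- metafor::rma(yi = y, vi = v, method = "REML",
                         control = list(tol = 1e-10))
  expect_equal(m_reml$tau2, r_reml$tau2, tolerance = 1e-4)
  expect_equal(m_reml$summary, as.numeric(r_reml$b), tolerance = 1e-6)
  m_kh <- random_effects_meta(est, knapp_hartung = TRUE)
  r_kh <- metafor::rma(yi = y, vi = v, method = "DL", test = "knha")
  expect_equal(m_kh$se, r_kh$se, tolerance = 1e-8)
  expect_equal(m_kh$p, r_kh$pval, tolerance = 1e-8)
  expect_equal(m_kh$ci_low, r_kh$ci.lb, tolerance = 1e-8)
})

test_that("negating estimates negates the summary; Q, tau2, I2 unchanged", {
  set.seed(1)
  y <- rnorm(6); v <- runif(6, 0.02, 0.2)
  m1 <- random_effects_meta(fake_estimates(y, v))
  m2 <- random_effects_meta(fake_estimates(-y, v))
  expect_equal(m2$summary, -m1$summary)
  expect_equal(m2$Q, m1$Q)
  expect_equal(m2$tau2, m1$tau2)
  expect_equal(m2$I2, m1$I2)
})

test_that("meta rejects k < 3 and nonpositive variances", {
  expect_error(random_effects_meta(fake_estimates(c(1, 2), c(1, 1))), "3")
  expect_error(random_effects_meta(fake_estimates(c(1, 2, 3), c(1, 0, 1))),
               "variance")
})

test_that("adding a near-infinite-variance study barely moves the summary", {
  y <- c(0.2, 0.3, 0.25, 0.5); v <- c(0.02, 0.03, 0.04, 0.02)
  m1 <- random_effects_meta(fake_estimates(y, v))
  m2 <- random_effects_meta(fake_estimates(c(y, 5), c(v, 1e8)))
  expect_lt(abs(m2$summary - m1$summary), 1e-3)
})

test_that("qualification implements the 10-per-group and 3-study rules", {
  est <- rbind(
    data.frame(study_id = "s1", gene_id = "gA", analysis = "SMD",
               estimate = 0.1, variance = 0.02, n1 = 50L, n2 = 9L, n = 59L,
               events = NA_integer_),
    data.frame(study_id = c("s2", "s3", "s4"), gene_id = "gA",
               analysis = "SMD", estimate = c(0.2, 0.3, 0.1),
               variance = 0.02, n1 = 20L, n2 = 15L, n = 35L,
               events = NA_integer_),
    data.frame(study_id = c("s2", "s3"), gene_id = "gB", analysis = "SMD",
               estimate = c(0.4, 0.5), variance = 0.02, n1 = 20L, n2 = 15L,
               n = 35L, events = NA_integer_))
  q <- qualify_studies(est, "SMD")
  # the 9-normal study is dropped; gB has only 2 qualifying studies
  expect_false("s1" %in% q$estimates$study_id)
  expect_false("gB" %in% q$estimates$gene_id)
  expect_true("gB" %in% q$dropped_genes)
  expect_equal(sort(unique(q$estimates$study_id)), c("s2", "s3", "s4"))
  expect_equal(unname(q$counts["rows_dropped"]), 1L)
  # survival rule keys on informative n
  est_hr <- data.frame(study_id = c("s1", "s2", "s3"), gene_id = "gA",
                       analysis = "LOGHR", estimate = 0.1, variance = 0.01,
                       n1 = NA_integer_, n2 = NA_integer_,
                       n = c(9L, 30L, 30L), events = 5L)
  q2 <- qualify_studies(est_hr, "LOGHR")
  expect_equal(nrow(q2$estimates), 0L)  # only 2 qualifying studies remain
  expect_equal(q2$dropped_studies$study_id, "s1")
})

test_that("meta_table agrees with per-gene random_effects_meta", {
  co <- make_cohort(n_studies = 5, genes = 25, seed = 31, true_smd = 0.3)
  eff <- do.call(rbind, lapply(co$studies, smd_table))
  mt <- meta_table(eff)
  for (g in c(gene_id(2), gene_id(19))) {
    m <- random_effects_meta(eff[eff$gene_id == g, ])
    row <- mt[mt$gene_id == g, ]
    expect_equal(row$summary, m$summary, tolerance = 1e-12)
    expect_equal(row$se, m$se, tolerance = 1e-12)
    expect_equal(row$tau2, m$tau2, tolerance = 1e-12)
    expect_equal(row$p, m$p, tolerance = 1e-12)
  }
  expect_true(all(mt$ci_low <= mt$summary & mt$summary <= mt$ci_high))
  expect_true(all(mt$tau2 >= 0 & mt$I2 >= 0 & mt$I2 <= 100))
})

test_that("forest data reports on the natural scale with normalized weights", {
  est <- fake_estimates(c(0.5, -0.5, 0.2, -0.2), rep(0.04, 4),
                        analysis = "LOGHR")
  m <- random_effects_meta(est)
  f <- forest_data(m)
  expect_equal(f$estimate[f$row == "summary"], exp(m$summary))
  expect_equal(sum(f$weight_pct[f$row == "study"]), 100, tolerance = 0.01)
  # symmetric inputs pool to summary log HR 0 -> HR 1
  expect_equal(f$estimate[f$row == "summary"], 1, tolerance = 1e-12)

  mz <- random_effects_meta(fake_estimates(atanh(c(0.9, 0.85, 0.95)),
                                           rep(1 / 27, 3),
                                           analysis = "FISHERZ"))
  fz <- forest_data(mz)
  expect_true(all(fz$ci_low > -1 & fz$ci_high < 1))
})

test_that("CI coverage of true SMD stays near nominal on synthetic cohorts", {
  set.seed(5)
  true_smd <- rnorm(400, 0, 0.5)
  cfg <- synthetic_config(n_studies = 8, genes = 400, seed = 206,
                          samples_per_study = c(120, 120),
                          tumor_fraction = 0.5, true_smd = true_smd,
                          tau2_smd = 0.02)
  co <- generate_cohort(cfg)
  eff <- do.call(rbind, lapply(co$studies, smd_table))
  mt <- meta_table(qualify_studies(eff, "SMD")$estimates)
  tr <- true_smd[match(mt$gene_id, gene_id(seq_along(true_smd)))]
  cov <- mean(mt$ci_low <= tr & tr <= mt$ci_high)
  expect_gte(cov, 0.90)
  expect_lte(cov, 0.99)
})
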