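test_that("reproducibility matrix is symmetric with matched-truth studies agreeing", {
  set.seed(20)
  true_smd <- rnorm(120, 0, 0.8)
  co <- make_cohort(n_studies = 4, genes = 120, seed = 22,
                    samples_per_study = c(150, 150), true_smd = true_smd,
                    tau2_smd = 0.005)
  eff <- do.call(rbind, lapply(co$studies, smd_table))
  rp <- reproducibility_matrix(eff)
  expect_equal(rp$matrix, t(rp$matrix))
  expect_equal(unname(diag(rp$matrix)), rep(1, 4))
  expect_gt(rp$median, 0.9)
})

test_that("independent-noise estimates give near-zero median reproducibility", {
  set.seed(23)
  est <- do.call(rbind, lapply(1:5, function(s)
    data.frame(study_id = sprintf("s%d", s), gene_id = gene_id(1:200),
               analysis = "SMD", estimate = rnorm(200), variance = 0.05,
               n1 = 20L, n2 = 20L, n = 40L, events = NA_integer_)))
  rp <- reproducibility_matrix(est)
  expect_lt(abs(rp$median), 0.05 + 2 / sqrt(200))
})

test_that("pairs below the shared-gene floor are left missing", {
  est <- rbind(
    data.frame(study_id = "s1", gene_id = gene_id(1:40), analysis = "SMD",
               estimate = rnorm(40), variance = 0.05, n1 = 20L, n2 = 20L,
               n = 40L, events = NA_integer_),
    data.frame(study_id = "s2", gene_id = gene_id(1:40), analysis = "SMD",
               estimate = rnorm(40), variance = 0.05, n1 = 20L, n2 = 20L,
               n = 40L, events = NA_integer_),
    data.frame(study_id = "s3", gene_id = gene_id(36:45), analysis = "SMD",
               estimate = rnorm(10), variance = 0.05, n1 = 20L, n2 = 20L,
               n = 40L, events = NA_integer_))
  rp <- reproducibility_matrix(est, min_shared = 30)
  expect_true(is.na(rp$matrix["s1", "s3"]))
  expect_false(is.na(rp$matrix["s1", "s2"]))
  expect_equal(rp$median, rp$matrix["s1", "s2"])
})

test_that("compare_summaries joins on genes and reports Pearson r", {
  co <- make_cohort(n_studies = 4, genes = 60, seed = 25, true_smd = 0.4)
  eff <- do.call(rbind, lapply(co$studies, smd_table))
  mt <- meta_table(qualify_studies(eff, "SMD")$estimates)
  self <- compare_summaries(mt, mt)
  expect_equal(self$r, 1)
  hl <- compare_summaries(mt, mt,
                          highlight = list(top = gene_id(1:5)))
  expect_equal(sum(hl$table$highlight == "top", na.rm = TRUE), 5L)
  # two independent null tables are uncorrelated
  mk_null <- function(seed) {
    con <- make_cohort(n_studies = 4, genes = 200, seed = seed, true_smd = 0)
    e <- do.call(rbind, lapply(con$studies, smd_table))
    meta_table(qualify_studies(e, "SMD")$estimates)
  }
  r_null <- compare_summaries(mk_null(26), mk_null(27))$r
  expect_lt(abs(r_null), 0.15)
  expect_error(compare_summaries(mt[1:5, ], mt[30:40, ]), "shared")
})

test_that("group difference meta recovers shifts and is antisymmetric", {
  cfg <- synthetic_config(n_studies = 6, genes = 3, seed = 500,
                          samples_per_study = c(120, 120),
                          tumor_fraction = c(0.6, 0.9),
                          mutation_genes = list(list(label = "EGFR",
                                                     prevalence = 0.35,
                                                     shift = c(0.8, 0, 0))))
  co <- generate_cohort(cfg)
  m <- group_difference_meta(co$studies, gene_id(1), "EGFR_status",
                             "mutant", "WT")
  expect_true(m$ci_low <= 0.8 && 0.8 <= m$ci_high)
  m_swap <- group_difference_meta(co$studies, gene_id(1), "EGFR_status",
                                  "WT", "mutant")
  expect_equal(m_swap$summary, -m$summary, tolerance = 1e-12)

  # gene absent from some studies is silently excluded; k reflects it
  co2 <- co
  co2$studies[[1]]$expr <- co2$studies[[1]]$expr[-1, , drop = FALSE]
  m2 <- group_difference_meta(co2$studies, gene_id(1), "EGFR_status",
                              "mutant", "WT")
  expect_equal(m2$k, m$k - 1L)

  # informative refusal listing group sizes when too few studies qualify
  cfg_small <- synthetic_config(n_studies = 3, genes = 3, seed = 501,
                                samples_per_study = c(30, 30),
                                mutation_genes = list(list(label = "EGFR",
                                                           prevalence = 0.05,
                                                           shift = c(0, 0, 0))))
  co3 <- generate_cohort(cfg_small)
  expect_error(group_difference_meta(co3$studies, gene_id(1), "EGFR_status",
                                     "mutant", "WT"),
               "group sizes")
})

test_that("gene-pair correlation meta recovers rho and handles identity", {
  cfg <- synthetic_config(n_studies = 8, genes = 2, seed = 600,
                          samples_per_study = c(100, 140),
                          corr_pairs = list(list(1, 2, 0.5)))
  co <- generate_cohort(cfg)
  m <- gene_pair_correlation_meta(co$studies, gene_id(1), gene_id(2))
  expect_gt(tanh(m$summary), 0.35)
  expect_lt(tanh(m$summary), 0.65)
  m_self <- gene_pair_correlation_meta(co$studies, gene_id(1), gene_id(1))
  expect_gt(tanh(m_self$summary), 0.999)
  expect_error(gene_pair_correlation_meta(co$studies[1:2], gene_id(1),
                                          gene_id(2)), "qualifying")
})

test_that("rank_gene uses minimum-tie ranking and matches a sort oracle", {
  set.seed(30)
  tab <- data.frame(gene_id = gene_id(1:100), summary = rnorm(100))
  top <- tab$gene_id[which.max(tab$summary)]
  expect_equal(rank_gene(tab, top, "positive")$rank, 1L)
  expect_equal(rank_gene(tab, top, "positive")$total, 100L)
  # independent sort-and-search oracle
  g <- gene_id(37)
  ord <- tab$gene_id[order(-tab$summary)]
  expect_equal(rank_gene(tab, g, "positive")$rank, match(g, ord))
  ord_neg <- tab$gene_id[order(tab$summary)]
  expect_equal(rank_gene(tab, g, "negative")$rank, match(g, ord_neg))
  # ties share the minimum rank
  tied <- data.frame(gene_id = gene_id(1:5), summary = rep(1, 5))
  for (gg in tied$gene_id)
    expect_equal(rank_gene(tied, gg)$rank, 1L)
  expect_error(rank_gene(tab, "gene_99999"), "not in results")
})

test_that("clinical covariate meta encodes age in decades and recovers effects", {
  cfg <- synthetic_config(n_studies = 6, genes = 2, seed = 700,
                          samples_per_study = c(150, 200),
                          tumor_fraction = c(0.6, 0.9),
                          covariate_loghr = c(age_decade = 0.3))
  co <- generate_cohort(cfg)
  m <- clinical_covariate_meta(co$studies, "age")
  expect_true(m$ci_low <= 0.3 && 0.3 <= m$ci_high)
  # identity encoding on raw years gives exactly 1/10 the decade log HR
  m_raw <- clinical_covariate_meta(co$studies, "age", encoding = "identity")
  expect_equal(m_raw$per_study$estimate * 10, m$per_study$estimate,
               tolerance = 1e-8)
  m_g <- clinical_covariate_meta(co$studies, "gender")
  expect_s3_class(m_g, "meta_result")
  expect_true(abs(m_g$summary) < 1)  # null gender effect
})
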