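test_that("hedges_g matches the textbook formula and its null/antisymmetry", {
  tum <- c(3, 4, 5, 6); nor <- c(1, 2, 3, 4)
  g <- hedges_g(tum, nor, gene_id = "g1", study_id = "s1")
  o <- oracle_hedges(tum, nor)
  expect_equal(g$estimate, o$g, tolerance = 1e-12)
  expect_equal(g$variance, o$var, tolerance = 1e-12)

  # identical group means -> g = 0 and the variance reduces to (n1+n2)/(n1 n2)
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 1, 5)
  g0 <- hedges_g(a, b)
  expect_equal(g0$estimate, 0)
  expect_equal(g0$variance, 10 / 25)

  # swapping groups negates the estimate, variance unchanged
  gs <- hedges_g(nor, tum)
  expect_equal(gs$estimate, -g$estimate)
  expect_equal(gs$variance, g$variance)

  expect_error(hedges_g(c(1, 1), c(1, 1), gene_id = "gX"), "gX")
  expect_error(hedges_g(1, c(1, 2)), "at least 2")
})

test_that("hedges_g agrees with metafor's SMD up to its exact-J correction", {
  skip_if_not_installed("metafor")
  set.seed(1)
  x1 <- rnorm(40, 1); x2 <- rnorm(35)
  g <- hedges_g(x1, x2)
  es <- metafor::escalc(measure = "SMD",
                        m1i = mean(x1), m2i = mean(x2),
                        sd1i = sd(x1), sd2i = sd(x2),
                        n1i = 40, n2i = 35)
  # metafor uses the exact gamma-function J; ours is the 1 - 3/(4m-1) form
  expect_equal(g$estimate, as.numeric(es$yi), tolerance = 1e-3)
  expect_equal(g$variance, as.numeric(es$vi), tolerance = 1e-3)
})

test_that("hedges_g is invariant to common positive affine transforms", {
  set.seed(7)
  for (i in 1:10) {
    x1 <- rnorm(15, 2); x2 <- rnorm(12)
    a <- runif(1, 0.1, 5); b <- rnorm(1, 0, 10)
    g1 <- hedges_g(x1, x2)
    g2 <- hedges_g(a * x1 + b, a * x2 + b)
    expect_equal(g1$estimate, g2$estimate, tolerance = 1e-10)
    expect_equal(g1$variance, g2$variance, tolerance = 1e-10)
  }
})

test_that("smd_table equals gene-wise hedges_g and masks constant genes", {
  co <- make_cohort(seed = 13, genes = 12)
  b <- co$studies[[1]]
  b$expr[3, ] <- 5  # constant gene
  tab <- smd_table(b)
  expect_false(gene_id(3) %in% tab$gene_id)
  expect_identical(attr(tab, "masked_genes"), gene_id(3))
  tum <- b$samples$tissue == "tumor"
  for (g in c(gene_id(1), gene_id(7))) {
    ref <- hedges_g(b$expr[g, tum], b$expr[g, !tum])
    row <- tab[tab$gene_id == g, ]
    expect_equal(row$estimate, ref$estimate, tolerance = 1e-12)
    expect_equal(row$variance, ref$variance, tolerance = 1e-12)
  }
})

test_that("standardization hits mean 0 / SD 1 on scope and is idempotent", {
  co <- make_cohort(seed = 4, genes = 8)
  b <- co$studies[[1]]
  for (scope in c("tumor_only", "all")) {
    s1 <- standardize_expression(b, scope)
    cols <- if (scope == "tumor_only") s1$samples$tissue == "tumor"
            else rep(TRUE, nrow(s1$samples))
    expect_lt(max(abs(rowMeans(s1$expr[, cols]))), 1e-12)
    expect_lt(max(abs(apply(s1$expr[, cols], 1, sd) - 1)), 1e-12)
    s2 <- standardize_expression(s1, scope)
    expect_equal(s1$expr, s2$expr, tolerance = 1e-12)
  }
  b$expr[2, ] <- 7
  expect_warning(sm <- standardize_expression(b), "masked")
  expect_true(all(is.na(sm$expr[2, ])))
  expect_true(gene_id(2) %in% sm$masked_genes)
})

test_that("cox_association matches brute-force partial-likelihood maximization", {
  # n = 6, no ties, all events, alternating covariate
  x <- c(-1, 1, -1, 1, -1, 1)
  ti <- 1:6; ev <- rep(1, 6)
  fit <- cox_association(x, ti, ev)
  expect_equal(fit$estimate, oracle_cox_beta(x, ti, ev), tolerance = 1e-6)

  # with tied event times (Efron correction exercised)
  set.seed(2)
  x2 <- rnorm(8); t2 <- c(2, 2, 3, 3, 3, 5, 6, 7); e2 <- c(1, 1, 1, 0, 1, 1, 0, 1)
  fit2 <- cox_association(x2, t2, e2)
  expect_equal(fit2$estimate, oracle_cox_beta(x2, t2, e2), tolerance = 1e-6)
})

test_that("cox_association rejects degenerate input and is time-scale invariant", {
  expect_error(cox_association(rep(1, 6), 1:6, rep(1, 6)), "information")
  expect_error(cox_association(rnorm(6), 1:6, rep(0, 6)), "events")
  set.seed(3)
  x <- rnorm(30); ti <- rexp(30); ev <- rbinom(30, 1, 0.7)
  f1 <- cox_association(x, ti, ev)
  f2 <- cox_association(x, ti * 1000, ev)
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-8)
  expect_equal(f1$variance, f2$variance, tolerance = 1e-8)
})

test_that("cox_association recovers a known log hazard ratio", {
  # simulation recovery at moderate scale: true beta 0.5, ~30% censoring
  betas <- vapply(1:40, function(i) {
    cfg <- synthetic_config(n_studies = 1, genes = 1, seed = 9000 + i,
                            samples_per_study = c(250, 250),
                            tumor_fraction = 0.8, true_loghr = 0.5,
                            censoring_rate = 0.3, batch_shift_sd = 0)
    lt <- loghr_table(generate_cohort(cfg)$studies[[1]])
    lt$estimate[1]
  }, 0)
  expect_lt(abs(mean(betas) - 0.5), 0.05)
})

test_that("pearson_fisherz clamps, signs and scales correctly", {
  x <- 1:10
  self <- pearson_fisherz(x, x)
  expect_equal(tanh(self$estimate), 1 - 1e-12, tolerance = 1e-10)
  set.seed(5)
  neg <- pearson_fisherz(x, -x + rnorm(10, 0, 1e-3))
  expect_lt(neg$estimate, 0)
  expect_equal(neg$variance, 1 / 7)
  expect_error(pearson_fisherz(rep(1, 10), 1:10, gene_id = "a:b"), "a:b")
  expect_error(pearson_fisherz(1:3, 3:1), "at least 4")
})

test_that("Fisher-z variance matches its sampling distribution at n = 10", {
  set.seed(8)
  rho <- 0.6; n <- 10; reps <- 10000
  zs <- vapply(seq_len(reps), function(i) {
    x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    atanh(cor(x, y))
  }, 0)
  expect_lt(abs(var(zs) - 1 / 7) / (1 / 7), 0.10)
})
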