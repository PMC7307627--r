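# ROI statistics: t tests, BH q values, DTI ~ AI + CD regressions, chi
# projection and the cohort report tables.

test_that("unpaired t matches the textbook pooled formula", {
  r <- unpaired_t(c(1, 2, 3), c(4, 5, 6))
  o <- oracle_pooled_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, o$t, tolerance = 1e-12)
  expect_equal(abs(r$t), 3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  expect_equal(r$p, o$p, tolerance = 1e-12)

  set.seed(21)
  for (i in 1:20) {
    a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1), 0.5)
    r <- unpaired_t(a, b); o <- oracle_pooled_t(a, b)
    expect_equal(r$t, o$t, tolerance = 1e-10)
    expect_equal(r$p, o$p, tolerance = 1e-10)
    # anti-symmetry under group swap
    s <- unpaired_t(b, a)
    expect_equal(s$t, -r$t, tolerance = 1e-10)
    expect_equal(s$p, r$p, tolerance = 1e-10)
  }
})

test_that("degenerate zero-variance groups follow the stated conventions", {
  same <- unpaired_t(c(2, 2, 2), c(2, 2))
  expect_equal(same$t, 0); expect_equal(same$p, 1); expect_true(same$degenerate)
  diffg <- unpaired_t(c(3, 3), c(1, 1, 1))
  expect_equal(diffg$t, Inf); expect_equal(diffg$p, 0)
})

test_that("pooled t equals Welch t for equal sizes and variances", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)   # equal n, equal sample variance
  expect_equal(unpaired_t(a, b, var_equal = TRUE)$t,
               unpaired_t(a, b, var_equal = FALSE)$t, tolerance = 1e-12)
})

test_that("BH q values equal the exhaustive step-up definition", {
  expect_equal(bh_fdr(0.5), 0.5)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(33)
  for (m in 1:8) {
    for (rep in 1:25) {
      p <- round(runif(m), 3)
      expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
    }
  }
  # q >= p and monotone in p
  p <- runif(40)
  q <- bh_fdr(p)
  expect_true(all(q >= p - 1e-12))
  expect_true(all(diff(q[order(p)]) > -1e-12))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("regression recovers a noiseless linear response exactly", {
  set.seed(5)
  d <- tibble::tibble(
    region = "ec", level = -3.60,
    AI = runif(20, 0.4, 0.9), CD = runif(20, 0.3, 0.6))
  d$FA <- 2 * d$AI + 3 * d$CD + 1
  r <- suppressWarnings(   # a perfect fit is the point of this case
    fit_dti_histology_regression(d, "FA", "ec", level = -3.60))
  expect_equal(r$beta_AI, 2, tolerance = 1e-10)
  expect_equal(r$beta_CD, 3, tolerance = 1e-10)
  expect_equal(r$intercept, 1, tolerance = 1e-10)
  expect_equal(r$r2_adj, 1, tolerance = 1e-10)
})

test_that("regression outputs equal the normal-equations oracle", {
  set.seed(6)
  for (rep in 1:10) {
    d <- tibble::tibble(
      region = "cc",
      AI = runif(25, 0.3, 0.9), CD = runif(25, 0.3, 0.6))
    d$AD <- 1.2e-3 * d$AI - 0.4e-3 * d$CD + rnorm(25, 1e-3, 1e-4)
    r <- fit_dti_histology_regression(d, "AD", "cc")
    o <- oracle_ols(d$AD, cbind(d$AI, d$CD))
    expect_equal(c(r$intercept, r$beta_AI, r$beta_CD), o$beta, tolerance = 1e-10)
    expect_equal(c(r$t_AI, r$t_CD), o$t[2:3], tolerance = 1e-10)
    expect_equal(r$r2_adj, o$r2_adj, tolerance = 1e-10)
    expect_equal(r$F, o$F, tolerance = 1e-8)
  }
})

test_that("collinear or undersized families are rejected by name", {
  d <- tibble::tibble(region = "ec", AI = c(0.1, 0.2, 0.3, 0.4))
  d$CD <- 2 * d$AI; d$FA <- rnorm(4)
  expect_error(fit_dti_histology_regression(d, "FA", "ec"), "collinear")
  expect_error(fit_dti_histology_regression(d[1:3, ], "FA", "ec"), "fewer than 4")
})

test_that("chi projection is the interceptless fitted combination", {
  rec <- tibble::tibble(AI = c(0.7, 0.2), CD = c(0.5, 0.1))
  expect_equal(chi_projection(list(beta_AI = 1, beta_CD = 1), rec), c(1.2, 0.3))
  expect_equal(chi_projection(list(beta_AI = 0, beta_CD = 0), rec), c(0, 0))

  set.seed(12)
  d <- tibble::tibble(region = "ec", AI = runif(30), CD = runif(30))
  d$FA <- 0.5 * d$AI - 0.2 * d$CD + rnorm(30, 0, 0.05)
  r <- fit_dti_histology_regression(d, "FA", "ec")
  # correlation with chi equals the multiple correlation sqrt(R^2)
  expect_equal(cor(d$FA, r$chi), sqrt(r$r2), tolerance = 1e-10)
})

test_that("regression F null rate is calibrated at the 5 percent level", {
  set.seed(77)
  hits <- 0L
  n_sim <- 400
  for (i in seq_len(n_sim)) {
    d <- tibble::tibble(region = "ec", AI = rnorm(28), CD = rnorm(28),
                        FA = rnorm(28))   # response independent of predictors
    r <- fit_dti_histology_regression(d, "FA", "ec")
    if (r$p_model < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / n_sim, 0.025)
  expect_lt(hits / n_sim, 0.075)
})

test_that("cohort analysis emits the full contrast and regression tables", {
  coh <- gen_cohort(cohort_spec(seed = 31))
  expect_equal(nrow(coh), (6 + 8) * 2 * (3 + 3 + 5))
  out <- analyze_cohort(coh)
  expect_equal(nrow(out$t_table), 44L)          # 11 region-levels x 2 hemis x 2 measures
  expect_equal(nrow(out$regression_table), 32L) # (4 + 4 + 8) families x 2 responses
  expect_true(all(out$t_table$q >= out$t_table$p - 1e-12))
  expect_true(all(out$t_table$df == 12))
  # region families match the reporting scheme
  fams <- unique(out$regression_table$family[out$regression_table$level == -3.6])
  expect_setequal(fams, c("cc", "ec", "S1", "ic", "VPL",
                          "cc + ec", "cc + ec + ic", "S1 + VPL"))
  expect_error(regions_at_level(2.5), "unknown bregma level")
})

test_that("missing region records yield NA rows with a warning", {
  coh <- gen_cohort(cohort_spec(seed = 31))
  cut <- coh[!(coh$region == "ic" & coh$hemisphere == "ipsilateral"), ]
  w <- capture_warnings(out <- analyze_cohort(cut))
  expect_true(any(grepl("missing records", w)))
  bad <- out$t_table[out$t_table$region == "ic" &
                       out$t_table$hemisphere == "ipsilateral", ]
  expect_true(all(is.na(bad$t)))
})

test_that("null cohorts flag about as often as alpha allows", {
  # equalize the groups: flags must be FDR-rare across 150 cohorts
  spec <- cohort_spec(seed = 1)
  spec$params$AI_mean <- 0.5; spec$params$AI_sd <- 0.05
  spec$params$CD_mean <- 0.4; spec$params$CD_sd <- 0.04
  n_flag <- 0L
  for (s in 1:150) {
    spec$seed <- s
    out <- analyze_cohort(gen_cohort(spec))
    n_flag <- n_flag + sum(out$t_table$significant)
  }
  # 44 BH-corrected tests per cohort under the global null: flags are rare
  expect_lt(n_flag / (150 * 44), 0.01)
})

test_that("swapping group labels negates the t statistics", {
  coh <- gen_cohort(cohort_spec(seed = 13))
  swapped <- coh
  swapped$group <- ifelse(coh$group == "sham", "mTBI", "sham")
  t1 <- analyze_cohort(coh)$t_table
  t2 <- analyze_cohort(swapped)$t_table
  expect_equal(t1$t, -t2$t, tolerance = 1e-10)
  expect_equal(t1$p, t2$p, tolerance = 1e-10)
})
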