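test_that("identical groups give a zero t statistic with p = 1", {
  df <- tiny_panel_df()
  df$sex <- c("male", "male", "female", "female")
  df$updrs2 <- 5L
  gc <- compare_adl_by(cohort_panel(df), "sex")
  expect_equal(gc$test, "two_sample_t")
  expect_equal(gc$statistic, 0)
  expect_equal(gc$p_value, 1)
})

test_that("two-sample t matches the closed form on a known-parameter draw", {
  set.seed(61)
  n <- 50
  df <- data.frame(
    subject_id = sprintf("S%03d", 1:(2 * n)), visit = 0L,
    rbdsq = 3, gds15 = 2, moca = 27,
    updrs2 = c(rnorm(n, 0, 1), rnorm(n, 1, 1)),
    stringsAsFactors = FALSE)
  df <- ref_covariates(df)
  df$sex <- rep(c("male", "female"), each = n)
  p <- as_panel(df, 1L)
  gc <- compare_adl_by(p, "sex")
  # direct pooled-variance formula on the same draw
  g1 <- df$updrs2[1:n]; g2 <- df$updrs2[(n + 1):(2 * n)]
  sp <- sqrt(((n - 1) * var(g1) + (n - 1) * var(g2)) / (2 * n - 2))
  t_direct <- (mean(g1) - mean(g2)) / (sp * sqrt(2 / n))
  expect_equal(gc$statistic, t_direct, tolerance = 1e-10)
  # and the drawn statistic sits near its theoretical value of -5
  expect_lt(abs(abs(gc$statistic) - 5), 3)

  # three nonempty levels switch to one-way ANOVA
  df$age_band <- rep(c(">65", "56-65", "<56"), length.out = 2 * n)
  gc3 <- compare_adl_by(as_panel(df, 1L), "age_band")
  expect_equal(gc3$test, "one_way_anova")
  expect_gte(gc3$p_value, 0)
  expect_lte(gc3$p_value, 1)
})

test_that("degenerate groupings are rejected", {
  df <- tiny_panel_df()        # all covariates at reference levels
  expect_error(compare_adl_by(cohort_panel(df), "race"),
               "fewer than 2 nonempty levels")
  expect_error(compare_adl_by(cohort_panel(df), "handedness"),
               "unknown covariate")
})

test_that("correlation matrix is symmetric with unit diagonal and exact p for self-pairs", {
  p <- simulate_cohort(dgp_config(n_subjects = 80), seed = 71)
  cm <- correlations(p)
  expect_equal(unname(diag(cm$r)), rep(1, 4))
  expect_equal(cm$r, t(cm$r))
  expect_true(all(abs(cm$r) <= 1, na.rm = TRUE))
  cmb <- correlations(p, scope = "baseline")
  expect_equal(max(cmb$n), length(unique(p$subject_id)))
})

test_that("estimated correlation is within Fisher-z sampling error of truth", {
  set.seed(81)
  n <- 1e4
  x <- rnorm(n)
  m <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n)              # cor(x, m) = 0.5
  df <- data.frame(subject_id = sprintf("S%05d", 1:n), visit = 0L,
                   rbdsq = x, gds15 = m, moca = rnorm(n), updrs2 = rnorm(n),
                   stringsAsFactors = FALSE)
  cm <- correlations(as_panel(ref_covariates(df), 1L))
  expect_lt(abs(atanh(cm$r["rbdsq", "gds15"]) - atanh(0.5)),
            3 / sqrt(n - 3))
})

test_that("zero-variance variables are flagged, not silent NaN", {
  df <- tiny_panel_df()
  df$moca <- 25L
  cm <- correlations(cohort_panel(df))
  expect_true("moca" %in% cm$undefined)
  expect_true(all(is.na(cm$r["moca", setdiff(cm$variables, "moca")])))
  expect_equal(cm$r["moca", "moca"], 1)
})

test_that("default synthetic cohort reproduces the qualitative sign pattern", {
  p <- simulate_cohort(dgp_config(), seed = 91)
  r <- correlations(p)$r
  expect_gt(r["rbdsq", "gds15"], 0)
  expect_gt(r["rbdsq", "updrs2"], 0)
  expect_gt(r["gds15", "updrs2"], 0)
  expect_lt(r["moca", "rbdsq"], 0)
  expect_lt(r["moca", "gds15"], 0)
  expect_lt(r["moca", "updrs2"], 0)
})
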