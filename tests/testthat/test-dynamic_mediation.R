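# Reduced iteration counts keep these fits to a few seconds each; the
# model and sampler are identical to the full-length configuration.

quick_spec <- function(mediator = "gds15", basis = "linear", seed = 1,
                       n_iter = 600, n_warmup = 200, ...) {
  dynmed_spec(mediator = mediator, basis = basis, n_iter = n_iter,
              n_warmup = n_warmup, n_chains = 2, seed = seed, ...)
}

test_that("posterior draws are reproducible and order-invariant", {
  p <- simulate_cohort(dgp_config(n_subjects = 60), seed = 2)
  f1 <- suppressWarnings(fit_dynamic_mediation(p, quick_spec(seed = 9)))
  f2 <- suppressWarnings(fit_dynamic_mediation(p, quick_spec(seed = 9)))
  expect_identical(f1$draws_m, f2$draws_m)
  expect_identical(f1$draws_y, f2$draws_y)
  expect_equal(nrow(f1$draws_m), 2 * (600 - 200))

  # shuffling panel rows leaves the posterior unchanged
  perm <- as.data.frame(p)[sample(nrow(p)), ]
  pp <- cohort_panel(perm)
  f3 <- suppressWarnings(fit_dynamic_mediation(pp, quick_spec(seed = 9)))
  expect_equal(f1$draws_m, f3$draws_m)

  ie1 <- indirect_effect_curve(f1, c(0.25, 0.5, 0.75))
  ie3 <- indirect_effect_curve(f3, c(0.25, 0.5, 0.75))
  expect_equal(ie1, ie3)
})

test_that("constant configured paths are recovered with OLS cross-check", {
  cfg <- dgp_config(
    n_subjects = 400,
    alpha_fn = list(gds15 = function(t) rep(0.5, length(t)),
                    moca = function(t) rep(0, length(t))),
    beta_fn = list(gds15 = function(t) rep(0.4, length(t)),
                   moca = function(t) rep(0, length(t))),
    tau_fn = function(t) rep(0, length(t)),
    random_effect_sd = c(gds15 = 0.5, moca = 0.5, updrs2 = 0.5),
    noise_sd = c(gds15 = 0.5, moca = 0.5, updrs2 = 0.5),
    clipping = FALSE)
  p <- simulate_cohort(cfg, seed = 13)
  fit <- suppressWarnings(
    fit_dynamic_mediation(p, quick_spec(n_iter = 900, n_warmup = 300,
                                        seed = 5)))
  ie <- indirect_effect_curve(fit, c(0.25, 0.5, 0.75), scale = "raw")
  for (i in 1:3) {
    expect_gt(0.20, ie$ci_low[i] - 0.02)
    expect_lt(0.20, ie$ci_high[i] + 0.02)
  }
  # independent route: per-visit OLS product of coefficients at t = 0.5
  d <- as.data.frame(p)[as.data.frame(p)$visit == 4L, ]
  ols <- unname(coef(lm(gds15 ~ rbdsq, d))["rbdsq"] *
                  coef(lm(updrs2 ~ gds15 + rbdsq, d))["gds15"])
  expect_lt(abs(ie$ie_mean[2] - ols), 4 * ie$ie_sd[2])
})

test_that("posterior path coefficients agree with an lme4 REML fit", {
  skip_if_not_installed("lme4")
  cfg <- dgp_config(n_subjects = 250, clipping = FALSE)
  p <- simulate_cohort(cfg, seed = 17)
  fit <- suppressWarnings(
    fit_dynamic_mediation(p, quick_spec(n_iter = 900, n_warmup = 300,
                                        seed = 3, standardize = FALSE)))
  d <- as.data.frame(p)
  d$t <- normalize_time(d$visit, 9)
  lf <- lme4::lmer(gds15 ~ t * rbdsq + sex + age_band + edu_band + race +
                     family_history + duration_band + (1 | subject_id),
                   data = d, REML = TRUE)
  co <- lme4::fixef(lf)
  # alpha(t) = alpha[1] + alpha[2] t on the linear basis
  am <- colMeans(fit$draws_m[, c("alpha[1]", "alpha[2]")])
  se <- sqrt(diag(as.matrix(stats::vcov(lf))))
  expect_lt(abs(am[1] - co["rbdsq"]), 3 * se["rbdsq"] + 0.02)
  expect_lt(abs(am[2] - co["t:rbdsq"]), 3 * se["t:rbdsq"] + 0.02)
})

test_that("null exposure-mediator path gives credible intervals covering zero", {
  zero <- function(t) rep(0, length(t))
  cfg <- dgp_config(n_subjects = 250,
                    alpha_fn = list(gds15 = zero, moca = zero),
                    clipping = FALSE)
  p <- simulate_cohort(cfg, seed = 23)
  fit <- suppressWarnings(fit_dynamic_mediation(p, quick_spec(seed = 7)))
  ie <- indirect_effect_curve(fit, c(0.25, 0.5, 0.75))
  expect_true(all(ie$ci_low <= 0 & ie$ci_high >= 0))
})

test_that("IE summaries follow grid order and handle degenerate draws", {
  p <- simulate_cohort(dgp_config(n_subjects = 50), seed = 29)
  fit <- suppressWarnings(fit_dynamic_mediation(p, quick_spec(seed = 11)))
  ie <- indirect_effect_curve(fit, c(0.25, 0.5, 0.75))
  expect_equal(ie$t, c(0.25, 0.5, 0.75))
  expect_true(all(ie$ci_low <= ie$ci_high))
  expect_error(indirect_effect_curve(fit, numeric(0)), "empty")
  expect_error(indirect_effect_curve(fit, c(0.5, 1.5)), "\\[0, 1\\]")

  # collapse every draw to its posterior mean: sd 0, interval width 0
  degen <- fit
  degen$draws_m <- matrix(colMeans(fit$draws_m), 2,
                          ncol(fit$draws_m), byrow = TRUE,
                          dimnames = list(NULL, colnames(fit$draws_m)))
  degen$draws_y <- matrix(colMeans(fit$draws_y), 2,
                          ncol(fit$draws_y), byrow = TRUE,
                          dimnames = list(NULL, colnames(fit$draws_y)))
  degen$chain_id <- 1:2
  ied <- indirect_effect_curve(degen, 0.5)
  expect_equal(ied$ie_sd, 0)
  expect_equal(ied$ci_low, ied$ie_mean)
  expect_equal(ied$ci_high, ied$ie_mean)
})

test_that("standardized and raw-scale fits agree after back-transformation", {
  cfg <- dgp_config(n_subjects = 300, clipping = FALSE)
  p <- simulate_cohort(cfg, seed = 37)
  f_std <- suppressWarnings(
    fit_dynamic_mediation(p, quick_spec(n_iter = 900, n_warmup = 300,
                                        seed = 19)))
  f_raw <- suppressWarnings(
    fit_dynamic_mediation(p, quick_spec(n_iter = 900, n_warmup = 300,
                                        seed = 19, standardize = FALSE)))
  g <- c(0.25, 0.5, 0.75)
  back <- indirect_effect_curve(f_std, g, scale = "raw")
  raw <- indirect_effect_curve(f_raw, g)
  expect_lt(max(abs(back$ie_mean - raw$ie_mean) /
                  sqrt(back$ie_sd^2 + raw$ie_sd^2)), 3)
})

test_that("diagnostics flag poor mixing and degenerate chains without crashing", {
  p <- simulate_cohort(dgp_config(n_subjects = 50), seed = 43)
  fit <- suppressWarnings(fit_dynamic_mediation(p, quick_spec(seed = 13)))
  d <- diagnose(fit)
  expect_true(all(c("rhat", "ess", "flagged") %in% names(d$table)))
  expect_true(all(d$table$ess >= 0))

  # constant chains: Rhat undefined but flagged
  const <- fit
  const$draws_m[] <- 1
  dc <- diagnose(const)
  expect_true(all(is.na(dc$table$rhat[dc$table$equation == "mediator"])))
  expect_true(all(dc$table$flagged[dc$table$equation == "mediator"]))

  # truncated chains raise ESS flags
  short <- fit
  keep <- c(1:10, which(fit$chain_id == 2)[1:10])
  short$draws_m <- fit$draws_m[keep, , drop = FALSE]
  short$draws_y <- fit$draws_y[keep, , drop = FALSE]
  short$chain_id <- fit$chain_id[keep]
  ds <- diagnose(short)
  expect_true(any(ds$table$flagged))

  single <- fit
  single$chain_id <- rep(1L, length(fit$chain_id))
  expect_error(diagnose(single), "2 chains")

  # trace export is long-format per chain
  tr <- diagnose(fit, trace_parameters = "alpha[1]")$trace
  expect_equal(sort(unique(tr$chain)), 1:2)
  expect_equal(nrow(tr), nrow(fit$draws_m))
})

test_that("degenerate designs are rejected", {
  df <- as.data.frame(simulate_cohort(dgp_config(n_subjects = 30),
                                      seed = 47))
  df$rbdsq <- 5L
  expect_error(fit_dynamic_mediation(cohort_panel(df), quick_spec()),
               "constant")
})
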