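test_that("simulation is reproducible and per-subject streams are stable", {
  cfg <- dgp_config(n_subjects = 25)
  a <- simulate_cohort(cfg, seed = 11)
  b <- simulate_cohort(cfg, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(simulate_cohort(cfg, seed = 12)),
                         as.data.frame(a)))
  # enlarging the cohort leaves existing subjects untouched
  big <- as.data.frame(simulate_cohort(dgp_config(n_subjects = 50),
                                       seed = 11))
  big <- big[big$subject_id %in% unique(a$subject_id), ]
  rownames(big) <- NULL
  expect_equal(big, as.data.frame(a))
})

test_that("clipped panels respect every scale range invariant", {
  rng <- scale_ranges()
  for (s in c(21, 22)) {
    p <- simulate_cohort(dgp_config(n_subjects = 40), seed = s)
    for (v in names(rng)) {
      expect_true(all(p[[v]] >= rng[[v]][1] & p[[v]] <= rng[[v]][2]))
      expect_true(all(p[[v]] == floor(p[[v]])))
    }
  }
})

test_that("a null exposure-mediator path yields near-zero correlation", {
  zero <- function(t) rep(0, length(t))
  cfg <- dgp_config(n_subjects = 2000,
                    alpha_fn = list(gds15 = zero, moca = zero),
                    clipping = FALSE)
  p <- simulate_cohort(cfg, seed = 31)
  expect_lt(abs(cor(p$rbdsq, p$gds15)), 0.05)
  expect_lt(abs(cor(p$rbdsq, p$moca)), 0.05)
})

test_that("per-visit OLS product of coefficients recovers the configured IE", {
  cfg <- dgp_config(
    n_subjects = 1500,
    alpha_fn = list(gds15 = function(t) rep(0.5, length(t)),
                    moca = function(t) rep(0, length(t))),
    beta_fn = list(gds15 = function(t) rep(0.4, length(t)),
                   moca = function(t) rep(0, length(t))),
    tau_fn = function(t) rep(0, length(t)),
    noise_sd = c(gds15 = 0.3, moca = 0.3, updrs2 = 0.3),
    clipping = FALSE)
  p <- simulate_cohort(cfg, seed = 41)
  for (k in c(2L, 6L)) {
    d <- as.data.frame(p)[as.data.frame(p)$visit == k, ]
    fm <- lm(gds15 ~ rbdsq, data = d)
    fy <- lm(updrs2 ~ gds15 + rbdsq, data = d)
    a <- coef(fm)["rbdsq"]; b <- coef(fy)["gds15"]
    se <- sqrt(b^2 * vcov(fm)["rbdsq", "rbdsq"] +
                 a^2 * vcov(fy)["gds15", "gds15"])
    expect_lt(abs(unname(a * b) - 0.20), 3 * se + 1e-8)
  }
})

test_that("true_effects is the analytic pointwise product of the paths", {
  cfg <- dgp_config(alpha_fn = list(gds15 = function(t) t,
                                    moca = function(t) 0.2 + 0.2 * t),
                    beta_fn = list(gds15 = function(t) rep(1, length(t)),
                                   moca = function(t) 0.3 + 0.3 * t))
  te <- true_effects(cfg, c(0, 0.5, 1))
  expect_equal(te$ie_gds15, c(0, 0.5, 1))
  expect_equal(te$ie_moca[3], 0.4 * 0.6)
  expect_equal(te$ie_total, te$ie_gds15 + te$ie_moca)
  zero <- function(t) rep(0, length(t))
  cfg0 <- dgp_config(alpha_fn = list(gds15 = zero, moca = zero))
  expect_true(all(true_effects(cfg0, seq(0, 1, 0.1))$ie_gds15 == 0))
  expect_error(true_effects(cfg, c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(true_effects(cfg, numeric(0)), "\\[0, 1\\]")
})

test_that("discrete toy sampling matches its probability tables", {
  # deterministic chain: X=1 a.s., M1 copies X, M2 copies M1, Y copies M2
  cp <- toy_cpts(px = 1, m1 = c(0, 1),
                 m2 = matrix(c(0, 0, 1, 1), 2, 2),
                 y = array(rep(c(0, 1), each = 4), c(2, 2, 2)))
  p <- simulate_toy_discrete(50, cp, seed = 1)
  expect_true(all(p$rbdsq == 1 & p$gds15 == 1 & p$moca == 1 &
                    p$updrs2 == 1))

  cp2 <- random_cpts(7)
  expect_identical(as.data.frame(simulate_toy_discrete(100, cp2, seed = 3)),
                   as.data.frame(simulate_toy_discrete(100, cp2, seed = 3)))

  # marginal outcome frequency within binomial sampling error
  cp3 <- toy_cpts(px = 0.5, m1 = c(0.3, 0.6),
                  m2 = matrix(0.5, 2, 2), y = array(0.3, c(2, 2, 2)))
  n <- 1e5
  p3 <- simulate_toy_discrete(n, cp3, seed = 5)
  expect_lt(abs(mean(p3$updrs2) - 0.3), 3 * sqrt(0.3 * 0.7 / n))

  expect_error(toy_cpts(px = 0.5, m1 = c(0.2, 1.4), m2 = matrix(0.5, 2, 2),
                        y = array(0.5, c(2, 2, 2))), "m1")
})
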