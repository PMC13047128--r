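test_that("saturated component models reproduce CPT conditional means", {
  cp <- random_cpts(101)
  panel <- simulate_toy_discrete(4000, cp, seed = 2)
  spec <- gformula_spec(contrast = list(x_high = 1, x_low = 0),
                        forms = "saturated", n_mc = 1000, seed = 3)
  mobj <- suppressWarnings(fit_component_models(panel, spec))
  for (x in 0:1) {
    nd <- data.frame(x = x)
    phat <- predict(mobj$models$m1_base$fit, nd)
    n_x <- sum(panel$rbdsq == x)
    se <- sqrt(cp$m1[x + 1] * (1 - cp$m1[x + 1]) / n_x)
    expect_lt(abs(phat - cp$m1[x + 1]), 4 * se + 1e-8)
  }
  # refitting the same panel is deterministic
  mobj2 <- suppressWarnings(fit_component_models(panel, spec))
  expect_identical(coef(mobj$models$y_final$fit),
                   coef(mobj2$models$y_final$fit))
})

test_that("constant mediators and rank-deficient designs are flagged", {
  p <- simulate_cohort(dgp_config(n_subjects = 60), seed = 3)
  df <- as.data.frame(p)
  df$moca <- 25L
  w <- capture_warnings(
    fit_component_models(cohort_panel(df), gformula_spec(n_mc = 100)))
  expect_true(any(grepl("degenerate component model", w)))

  df2 <- as.data.frame(p)
  df2$gds15 <- df2$rbdsq          # perfectly collinear mediator
  expect_error(
    suppressWarnings(
      fit_component_models(cohort_panel(df2), gformula_spec(n_mc = 100))),
    "rank-deficient")
})

test_that("decomposition additivity holds to machine precision", {
  p <- simulate_cohort(dgp_config(n_subjects = 150), seed = 5)
  mobj <- fit_component_models(p, gformula_spec(n_mc = 3000, seed = 7))
  ps <- decompose_pathspecific(mobj)
  expect_equal(ps$te, ps$de + ps$ie_joint + ps$xi, tolerance = 1e-12)
  expect_equal(ps$ie_joint,
               sum(ps$per_mediator) + ps$interaction_remainder,
               tolerance = 1e-12)
  tw <- decompose_twoway(mobj)
  expect_equal(tw$te, ps$te)
  expect_equal(tw$ie_joint, ps$ie_joint)
})

test_that("single-visit linear toy matches the closed-form path-tracing", {
  panel <- make_linear_panel(6000, a1 = 0.5, b1 = 0.4, cdir = 0.3,
                             seed = 12)
  spec <- gformula_spec(contrast = list(x_high = 1, x_low = 0),
                        n_mc = 50000, seed = 2)
  mobj <- fit_component_models(panel, spec)
  tw <- decompose_twoway(mobj)
  # uncertainty of the fitted paths dominates the n_mc error here
  d <- as.data.frame(panel)
  fm <- lm(gds15 ~ rbdsq, d); fy <- lm(updrs2 ~ rbdsq + gds15 + moca, d)
  se_a <- sqrt(vcov(fm)["rbdsq", "rbdsq"])
  se_b <- sqrt(vcov(fy)["gds15", "gds15"])
  se_c <- sqrt(vcov(fy)["rbdsq", "rbdsq"])
  se_ie <- sqrt(0.4^2 * se_a^2 + 0.5^2 * se_b^2)
  expect_lt(abs(tw$de - 0.30), 3 * se_c + 0.01)
  expect_lt(abs(tw$ie_joint - 0.20), 3 * se_ie + 0.01)
  expect_lt(abs(tw$te - 0.50), 3 * sqrt(se_c^2 + se_ie^2) + 0.02)
  # the engine reproduces the product of the coefficients it was fed
  a <- coef(fm)["rbdsq"]; b <- coef(fy)["gds15"]
  expect_lt(abs(tw$ie_joint - unname(a * b)), 0.01)
})

test_that("null mediation paths give a joint indirect effect compatible with zero", {
  zero <- function(t) rep(0, length(t))
  cfg <- dgp_config(n_subjects = 120,
                    alpha_fn = list(gds15 = zero, moca = zero),
                    clipping = FALSE)
  p <- simulate_cohort(cfg, seed = 19)
  spec <- gformula_spec(n_mc = 2000, n_boot = 25, seed = 21)
  bs <- gformula_bootstrap(p, spec, n_mc_boot = 1500)
  ci <- bs$ci[bs$ci$component == "ie_joint", ]
  expect_lte(ci$ci_low, 0)
  expect_gte(ci$ci_high, 0)
})

test_that("path-specific contributions isolate the active mediator", {
  # second mediator has a null exposure path: its contribution ~ 0
  panel <- make_linear_panel(5000, a1 = 0.5, b1 = 0.4, a2 = 0, b2 = 0.3,
                             seed = 23)
  spec <- gformula_spec(contrast = list(x_high = 1, x_low = 0),
                        n_mc = 40000, seed = 5)
  ps <- decompose_pathspecific(fit_component_models(panel, spec))
  expect_lt(abs(ps$per_mediator["moca"]), 0.03)
  expect_lt(abs(ps$per_mediator["gds15"] - 0.20), 0.04)

  # independent mediators: order of the cascade does not matter
  panel2 <- make_linear_panel(5000, a1 = 0.5, b1 = 0.4, a2 = 0.25,
                              b2 = 0.4, seed = 29)
  s_ab <- gformula_spec(mediators = c("gds15", "moca"),
                        contrast = list(x_high = 1, x_low = 0),
                        n_mc = 40000, seed = 6)
  s_ba <- gformula_spec(mediators = c("moca", "gds15"),
                        contrast = list(x_high = 1, x_low = 0),
                        n_mc = 40000, seed = 6)
  p_ab <- decompose_pathspecific(fit_component_models(panel2, s_ab))
  p_ba <- decompose_pathspecific(fit_component_models(panel2, s_ba))
  expect_lt(abs(p_ab$per_mediator["gds15"] - p_ba$per_mediator["gds15"]),
            0.03)
  expect_lt(abs(p_ab$per_mediator["moca"] - p_ba$per_mediator["moca"]),
            0.03)
  expect_lt(abs(p_ab$per_mediator["gds15"] - 0.20), 0.04)
  expect_lt(abs(p_ab$per_mediator["moca"] - 0.10), 0.04)
})

test_that("Monte Carlo engine converges to the enumeration oracle", {
  cp <- random_cpts(211)
  or <- enumerate_oracle(cp)
  mobj <- component_models_from_cpts(cp)
  err <- vapply(c(1e3, 1e4, 1e5), function(n_mc) {
    mc <- decompose_pathspecific(mobj, n_mc = n_mc, seed = 31)
    max(abs(c(mc$te - or$te, mc$de - or$de,
              mc$per_mediator - or$per_mediator)))
  }, 0)
  expect_lt(err[3], 0.01)
  # error shrinks roughly like 1/sqrt(n_mc) across two decades
  expect_lt(err[3], err[1])
  # CPT-backed decompositions have no anchor discrepancy
  mc <- decompose_twoway(mobj, n_mc = 1e4, seed = 33)
  expect_equal(mc$xi, 0)
})

test_that("deterministic and independent toys enumerate exactly", {
  yarr <- array(0, c(2, 2, 2)); yarr[, 2, ] <- 1   # Y copies M1
  cp <- toy_cpts(px = 0.5, m1 = c(0, 1), m2 = matrix(0, 2, 2), y = yarr)
  or <- enumerate_oracle(cp)
  expect_equal(or$te, 1)
  expect_equal(or$de, 0)
  expect_equal(unname(or$per_mediator["gds15"]), 1)

  cp0 <- toy_cpts(px = 0.5, m1 = c(0.4, 0.4),
                  m2 = matrix(0.3, 2, 2), y = array(0.6, c(2, 2, 2)))
  or0 <- enumerate_oracle(cp0)
  expect_equal(or0$te, 0)
  expect_equal(or0$de, 0)
  expect_equal(unname(or0$per_mediator), c(0, 0))
})

test_that("bootstrap intervals are ordered, seeded and reproducible", {
  p <- simulate_cohort(dgp_config(n_subjects = 80), seed = 41)
  spec <- gformula_spec(n_mc = 1500, n_boot = 2, seed = 43)
  b1 <- gformula_bootstrap(p, spec, n_mc_boot = 1000)
  expect_true(all(b1$ci$ci_low <= b1$ci$ci_high))
  expect_equal(b1$n_boot_done, 2L)
  b2 <- gformula_bootstrap(p, spec, n_mc_boot = 1000)
  expect_identical(b1$ci, b2$ci)
})

test_that("equal contrast regimes are rejected", {
  expect_error(gformula_spec(contrast = list(x_high = 3, x_low = 3)),
               "must differ")
})
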