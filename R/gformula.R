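# Mediational g-formula for two time-varying mediators: parametric
# component models, Monte Carlo counterfactual simulation under
# exposure regimes, two-way and path-specific effect decompositions
# with common random numbers, an exact enumeration oracle for binary
# toys, and a subject-level bootstrap.

#' Specification for the mediational g-formula
#'
#' @param mediators Ordered character vector of mediators (order fixes
#'   the path-specific cascade; default depression before cognition).
#' @param contrast `NULL` (default) for a data-adaptive contrast —
#'   sustained exposure at the per-visit 90th percentile of RBDSQ
#'   (`x_high`) versus the 10th percentile (`x_low`) — or a list with
#'   numeric `x_high`, `x_low` (scalars or per-visit trajectories).
#' @param forms `"default"`: linear component models with visit
#'   dummies, one-visit lags of exposure and mediators, and baseline
#'   covariates; `"saturated"`: fully interacted exposure/mediator
#'   terms without covariates (exact for binary toys).
#' @param n_mc Monte Carlo pseudo-subjects (default 10000).
#' @param n_boot Bootstrap replicates for [gformula_bootstrap()]
#'   (default 500).
#' @param seed Integer seed.
#' @return List of class `gformula_spec`.
#' @export
gformula_spec <- function(mediators = c("gds15", "moca"),
                          contrast = NULL,
                          forms = c("default", "saturated"),
                          n_mc = 10000L, n_boot = 500L, seed = 1L) {
  forms <- match.arg(forms)
  stopifnot(length(mediators) >= 1L,
            all(mediators %in% c("gds15", "moca")),
            n_mc >= 1L, n_boot >= 1L)
  if (!is.null(contrast)) {
    stopifnot(is.list(contrast), !is.null(contrast$x_high),
              !is.null(contrast$x_low))
    if (isTRUE(all(contrast$x_high == contrast$x_low))) {
      stop("contrast regimes x_high and x_low must differ", call. = FALSE)
    }
  }
  structure(list(exposure = "rbdsq", mediators = mediators,
                 outcome = "updrs2", contrast = contrast, forms = forms,
                 n_mc = as.integer(n_mc), n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "gformula_spec")
}

# long frame with lags, visit dummies and covariate dummy columns
gf_frame <- function(panel) {
  df <- as.data.frame(panel)
  df <- df[order(df$subject_id, df$visit), , drop = FALSE]
  K <- attr(panel, "n_visits")
  lag1 <- function(v) {
    stats::ave(v, df$subject_id, FUN = function(z) c(NA, z[-length(z)]))
  }
  D <- data.frame(subject_id = df$subject_id, visit = df$visit,
                  x = df$rbdsq, m1 = df$gds15, m2 = df$moca,
                  y = df$updrs2, stringsAsFactors = FALSE)
  D$x_lag <- lag1(D$x); D$m1_lag <- lag1(D$m1); D$m2_lag <- lag1(D$m2)
  for (k in seq_len(K - 1L)) D[[paste0("v", k)]] <- as.integer(D$visit == k)
  C <- covariate_design(df)
  keep <- apply(C, 2, stats::sd) > 0
  C <- C[, keep, drop = FALSE]
  cov_names <- character(0)
  if (ncol(C) > 0L) {
    cov_names <- make.names(colnames(C), unique = TRUE)
    colnames(C) <- cov_names
    D <- cbind(D, C)
  }
  list(frame = D, K = K, cov_names = cov_names)
}

# assemble "resp ~ ..." from a term list, dropping zero-variance
# predictors (constant lags of a degenerate mediator, empty dummies)
gf_formula <- function(resp, terms, data) {
  keep <- terms[vapply(terms, function(v) {
    stats::sd(data[[v]], na.rm = TRUE) > 0
  }, TRUE)]
  if (length(keep) == 0L) keep <- "1"
  paste(resp, "~", paste(keep, collapse = " + "))
}

fit_one_lm <- function(formula_str, data, name) {
  f <- stats::as.formula(formula_str)
  resp <- all.vars(f)[1]
  yv <- data[[resp]]
  if (stats::sd(yv) == 0) {
    warning("degenerate component model '", name,
            "': constant response", call. = FALSE)
  }
  fit <- stats::lm(f, data = data)
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient design in component model '", name, "'",
         call. = FALSE)
  }
  list(fit = fit, sigma = summary(fit)$sigma,
       binary = all(yv %in% c(0, 1)), name = name)
}

#' Fit the g-formula component models
#'
#' Fits one parametric regression per component of the factorization:
#' each mediator at baseline and at follow-up visits (with visit
#' dummies and one-visit lags of exposure and both mediators), the
#' end-of-follow-up outcome given final exposure and mediators, and an
#' unmediated total-effect anchor model of the outcome on exposure
#' history only. Baseline covariates enter every model (`forms =
#' "default"`). Responses observed to be 0/1 are simulated as
#' Bernoulli; others as Gaussian.
#'
#' @param panel A `cohort_panel` (the outcome needs to be observed at
#'   the final visit; mediators at every visit).
#' @param spec A [gformula_spec()].
#' @return Object of class `gformula_models` holding the fitted
#'   components, the covariate resampling pool, and the resolved
#'   exposure contrast trajectories.
#' @export
fit_component_models <- function(panel, spec) {
  stopifnot(inherits(spec, "gformula_spec"))
  gf <- gf_frame(panel)
  D <- gf$frame; K <- gf$K
  cov <- gf$cov_names
  two_med <- length(spec$mediators) == 2L
  base <- D[D$visit == 0L & !is.na(D$m1) & !is.na(D$m2), , drop = FALSE]
  models <- list()
  if (spec$forms == "saturated") {
    models$m1_base <- fit_one_lm("m1 ~ x", base, "m1_base")
    models$m2_base <- fit_one_lm("m2 ~ x * m1", base, "m2_base")
  } else {
    models$m1_base <- fit_one_lm(gf_formula("m1", c("x", cov), base),
                                 base, "m1_base")
    models$m2_base <- fit_one_lm(gf_formula("m2", c("x", "m1", cov), base),
                                 base, "m2_base")
  }
  if (K > 1L) {
    fol <- D[D$visit > 0L, , drop = FALSE]
    fol <- fol[stats::complete.cases(fol[c("m1", "m2", "x", "x_lag",
                                           "m1_lag", "m2_lag")]), ,
               drop = FALSE]
    vdum <- if (K > 2L) paste0("v", 2:(K - 1L)) else character(0)
    lags <- c("x_lag", "m1_lag", "m2_lag")
    if (spec$forms == "saturated") {
      models$m1_follow <- fit_one_lm("m1 ~ x * m1_lag * m2_lag", fol,
                                     "m1_follow")
      models$m2_follow <- fit_one_lm("m2 ~ x * m1 * m2_lag", fol,
                                     "m2_follow")
    } else {
      models$m1_follow <- fit_one_lm(
        gf_formula("m1", c("x", lags, vdum, cov), fol), fol, "m1_follow")
      models$m2_follow <- fit_one_lm(
        gf_formula("m2", c("x", "m1", lags, vdum, cov), fol), fol,
        "m2_follow")
    }
  }
  fin <- D[D$visit == K - 1L & !is.na(D$y), , drop = FALSE]
  if (nrow(fin) < 5L) stop("too few final-visit outcome rows", call. = FALSE)
  if (K > 1L) {
    xh <- stats::aggregate(x ~ subject_id, data = D[D$visit < K - 1L, ],
                           FUN = mean)
    names(xh)[2] <- "x_hist"
    fin <- merge(fin, xh, by = "subject_id", all.x = TRUE)
    fin <- fin[!is.na(fin$x_hist), , drop = FALSE]
  } else {
    fin$x_hist <- fin$x
  }
  meds <- if (two_med) c("m1", "m2") else
    if (spec$mediators == "gds15") "m1" else "m2"
  if (spec$forms == "saturated") {
    y_form <- paste("y ~", paste(c("x", meds), collapse = " * "))
    models$y_final <- fit_one_lm(y_form, fin, "y_final")
    models$y_total <- fit_one_lm("y ~ x", fin, "y_total")
  } else {
    models$y_final <- fit_one_lm(
      gf_formula("y", c("x", meds, cov), fin), fin, "y_final")
    models$y_total <- fit_one_lm(
      gf_formula("y", c("x", if (K > 1L) "x_hist" else NULL, cov), fin),
      fin, "y_total")
  }

  contrast <- spec$contrast
  if (is.null(contrast)) {
    qs <- vapply(0:(K - 1L), function(k) {
      xs <- D$x[D$visit == k & !is.na(D$x)]
      stats::quantile(xs, c(0.1, 0.9), names = FALSE)
    }, numeric(2))
    contrast <- list(x_high = qs[2, ], x_low = qs[1, ])
  }
  contrast$x_high <- rep_len(contrast$x_high, K)
  contrast$x_low <- rep_len(contrast$x_low, K)

  cov_pool <- unique(D[D$visit == 0L,
                       c("subject_id", gf$cov_names), drop = FALSE])
  structure(list(models = models, spec = spec, K = K,
                 cov_names = gf$cov_names, cov_pool = cov_pool,
                 contrast = contrast, type = "fitted"),
            class = "gformula_models")
}

#' @export
print.gformula_models <- function(x, ...) {
  cat("g-formula component models (", x$type, "): ",
      paste(names(x$models), collapse = ", "), "\n", sep = "")
  cat("  visits:", x$K, " contrast x_high =",
      paste(round(x$contrast$x_high, 2), collapse = ","), " x_low =",
      paste(round(x$contrast$x_low, 2), collapse = ","), "\n")
  invisible(x)
}

#' Wrap discrete-toy CPTs as g-formula component models
#'
#' Gives conditional probability tables the same interface as fitted
#' component models, so the Monte Carlo engine can be compared to the
#' exact enumeration oracle on identical inputs.
#'
#' @param cpts A [toy_cpts()] object.
#' @param contrast Exposure contrast (default 1 vs 0).
#' @return A `gformula_models` of type `"cpt"`.
#' @export
component_models_from_cpts <- function(cpts,
                                       contrast = list(x_high = 1,
                                                       x_low = 0)) {
  stopifnot(inherits(cpts, "toy_cpts"))
  K <- cpts$n_visits
  structure(list(models = NULL, cpts = cpts, K = K,
                 cov_names = character(0), cov_pool = NULL,
                 contrast = list(x_high = rep_len(contrast$x_high, K),
                                 x_low = rep_len(contrast$x_low, K)),
                 spec = NULL, type = "cpt"),
            class = "gformula_models")
}

# predicted mean from a fitted component given a newdata frame
gf_predict <- function(model, newdata) {
  as.numeric(stats::predict(model$fit, newdata = newdata))
}

# realize a simulated value: Gaussian residual or Bernoulli draw,
# using pre-generated standard normals (eps) and uniforms (u)
gf_realize <- function(model, mu, eps, u) {
  if (model$binary) {
    as.integer(u < pmin(pmax(mu, 0), 1))
  } else {
    mu + model$sigma * eps
  }
}

# Monte Carlo cascade for fitted models under per-role exposure
# assignments e = list(m1, m2, y), each a trajectory of length K.
# rnd holds the common random numbers.
mc_cascade_fitted <- function(mobj, e, rnd) {
  K <- mobj$K
  n <- nrow(rnd$cov)
  newd <- as.data.frame(rnd$cov)
  m1 <- m2 <- NULL
  m1_prev <- m2_prev <- x1_prev <- x2_prev <- NULL
  for (k in 0:(K - 1L)) {
    if (k == 0L) {
      newd$x <- rep(e$m1[1], n)
      mu1 <- gf_predict(mobj$models$m1_base, newd)
      m1 <- gf_realize(mobj$models$m1_base, mu1, rnd$eps_m1[, 1],
                       rnd$u_m1[, 1])
      newd$x <- rep(e$m2[1], n); newd$m1 <- m1
      mu2 <- gf_predict(mobj$models$m2_base, newd)
      m2 <- gf_realize(mobj$models$m2_base, mu2, rnd$eps_m2[, 1],
                       rnd$u_m2[, 1])
    } else {
      for (j in seq_len(mobj$K - 1L)) {
        newd[[paste0("v", j)]] <- as.integer(j == k)
      }
      newd$m1_lag <- m1; newd$m2_lag <- m2
      newd$x <- rep(e$m1[k + 1L], n); newd$x_lag <- rep(e$m1[k], n)
      mu1 <- gf_predict(mobj$models$m1_follow, newd)
      m1 <- gf_realize(mobj$models$m1_follow, mu1, rnd$eps_m1[, k + 1L],
                       rnd$u_m1[, k + 1L])
      newd$x <- rep(e$m2[k + 1L], n); newd$x_lag <- rep(e$m2[k], n)
      newd$m1 <- m1
      mu2 <- gf_predict(mobj$models$m2_follow, newd)
      m2 <- gf_realize(mobj$models$m2_follow, mu2, rnd$eps_m2[, k + 1L],
                       rnd$u_m2[, k + 1L])
    }
  }
  newd$x <- rep(e$y[K], n)
  newd$x_hist <- rep(if (K > 1L) mean(e$y[1:(K - 1L)]) else e$y[1], n)
  newd$m1 <- m1; newd$m2 <- m2
  mu_y <- gf_predict(mobj$models$y_final, newd)
  y <- gf_realize(mobj$models$y_final, mu_y, rnd$eps_y, rnd$u_y)
  mean(y)
}

mc_cascade_cpt <- function(mobj, e, rnd) {
  cp <- mobj$cpts
  u <- rnd
  m1 <- as.integer(u$u_m1[, 1] < cp$m1[e$m1[1] + 1L])
  m2 <- as.integer(u$u_m2[, 1] < cp$m2[cbind(e$m2[1] + 1L, m1 + 1L)])
  if (cp$n_visits == 2L) {
    m1b <- as.integer(u$u_m1[, 2] <
                        cp$m1_2[cbind(e$m1[2] + 1L, m1 + 1L, m2 + 1L)])
    m2b <- as.integer(u$u_m2[, 2] <
                        cp$m2_2[cbind(e$m2[2] + 1L, m1b + 1L, m2 + 1L)])
    m1 <- m1b; m2 <- m2b
  }
  K <- cp$n_visits
  py <- cp$y[cbind(e$y[K] + 1L, m1 + 1L, m2 + 1L)]
  mean(as.integer(u$u_y < py))
}

# draw the common random numbers once per decomposition
gf_rng <- function(mobj, n_mc, seed) {
  set.seed(seed)
  K <- mobj$K
  out <- list(
    u_m1 = matrix(stats::runif(n_mc * K), n_mc, K),
    u_m2 = matrix(stats::runif(n_mc * K), n_mc, K),
    u_y = stats::runif(n_mc))
  if (mobj$type == "fitted") {
    out$eps_m1 <- matrix(stats::rnorm(n_mc * K), n_mc, K)
    out$eps_m2 <- matrix(stats::rnorm(n_mc * K), n_mc, K)
    out$eps_y <- stats::rnorm(n_mc)
    idx <- sample.int(nrow(mobj$cov_pool), n_mc, replace = TRUE)
    cov <- mobj$cov_pool[idx, mobj$cov_names, drop = FALSE]
    rownames(cov) <- NULL
    out$cov <- cov
  }
  out
}

# anchor total effect from the unmediated outcome model
gf_anchor_te <- function(mobj, rnd) {
  if (mobj$type != "fitted") return(NULL)
  K <- mobj$K
  newd <- as.data.frame(rnd$cov)
  lp <- function(traj) {
    newd$x <- rep(traj[K], nrow(newd))
    newd$x_hist <- rep(if (K > 1L) mean(traj[1:(K - 1L)]) else traj[1],
                       nrow(newd))
    mean(gf_predict(mobj$models$y_total, newd))
  }
  lp(mobj$contrast$x_high) - lp(mobj$contrast$x_low)
}

# Full decomposition from an evaluator of counterfactual means.
# The evaluator receives per-role exposure trajectories: `m1` feeds the
# gds15 models, `m2` the moca models, `y` the outcome model. Mediators
# not declared in `mediators` are tied to the outcome's exposure (their
# response to exposure then counts as part of the direct path).
gf_decompose_core <- function(evaluate, contrast, mediators,
                              te_anchor = NULL) {
  h <- contrast$x_high; l <- contrast$x_low
  mk <- function(switched, y_high) {
    ey <- if (y_high) h else l
    role <- function(med) {
      if (med %in% mediators) (if (med %in% switched) h else l) else ey
    }
    list(m1 = role("gds15"), m2 = role("moca"), y = ey)
  }
  s_lll <- evaluate(mk(character(0), FALSE))
  s_base <- evaluate(mk(character(0), TRUE))   # direct-effect term
  per <- stats::setNames(numeric(length(mediators)), mediators)
  prev <- s_base
  switched <- character(0)
  for (m in mediators) {
    switched <- c(switched, m)
    cur <- evaluate(mk(switched, TRUE))
    per[m] <- cur - prev
    prev <- cur
  }
  s_hhh <- prev
  te_model <- s_hhh - s_lll
  de <- s_base - s_lll
  ie_joint <- s_hhh - s_base
  te <- if (is.null(te_anchor)) te_model else te_anchor
  xi <- te - de - ie_joint
  share <- function(v) if (te == 0) NA_real_ else 100 * v / te
  list(te = te, te_model = te_model, de = de, ie_joint = ie_joint,
       xi = xi,
       de_share = share(de), ie_share = share(ie_joint),
       per_mediator = per, per_mediator_share = vapply(per, share, 0),
       interaction_remainder = ie_joint - sum(per))
}

#' Two-way decomposition via the mediational g-formula
#'
#' Simulates `n_mc` pseudo-subjects forward through the component
#' models under the high and low exposure regimes with common random
#' numbers, and decomposes the total effect into a direct effect, a
#' joint indirect effect through all mediators, and the residual xi
#' between the anchored total effect and the model-estimated sum
#' (`te = de + ie_joint + xi` holds to machine precision). Percentage
#' shares are component/te x 100 (undefined when te = 0).
#'
#' @param mobj Fitted [fit_component_models()] output (or
#'   [component_models_from_cpts()]; there the anchor equals the
#'   model-simulated total effect and xi is 0).
#' @param n_mc Monte Carlo size (defaults to the spec's `n_mc`, or
#'   10000 for CPT models).
#' @param seed Seed for the common random numbers (defaults to the
#'   spec's seed).
#' @return List of class `mediation_decomposition`.
#' @export
decompose_twoway <- function(mobj, n_mc = NULL, seed = NULL) {
  dec <- gf_decompose(mobj, n_mc, seed)
  structure(dec[c("te", "te_model", "de", "ie_joint", "xi", "de_share",
                  "ie_share", "n_mc")],
            class = "mediation_decomposition")
}

#' Path-specific decomposition via the mediational g-formula
#'
#' Allocates the joint indirect effect to the individual mediators by
#' sequential (cascading) exposure switches in the declared mediator
#' order: mediator j's contribution is the change in the mean
#' counterfactual outcome when the exposure seen by mediator j's models
#' switches from low to high, with earlier mediators already switched
#' and later mediators still at low. With common random numbers the
#' contributions and the interaction remainder partition the joint
#' indirect effect exactly.
#'
#' @inheritParams decompose_twoway
#' @return List of class `pathspecific_decomposition` with
#'   `per_mediator`, `per_mediator_share`, `interaction_remainder`, and
#'   the two-way components.
#' @export
decompose_pathspecific <- function(mobj, n_mc = NULL, seed = NULL) {
  dec <- gf_decompose(mobj, n_mc, seed)
  structure(dec, class = "pathspecific_decomposition")
}

# shared engine behind both decompositions
gf_decompose <- function(mobj, n_mc = NULL, seed = NULL) {
  stopifnot(inherits(mobj, "gformula_models"))
  spec <- mobj$spec
  if (is.null(n_mc)) n_mc <- if (!is.null(spec)) spec$n_mc else 10000L
  if (is.null(seed)) seed <- if (!is.null(spec)) spec$seed else 1L
  rnd <- gf_rng(mobj, n_mc, seed)
  evaluate <- if (mobj$type == "fitted") {
    function(e) mc_cascade_fitted(mobj, e, rnd)
  } else {
    function(e) mc_cascade_cpt(mobj, e, rnd)
  }
  mediators <- if (!is.null(spec)) spec$mediators else c("gds15", "moca")
  dec <- gf_decompose_core(evaluate, mobj$contrast, mediators,
                           te_anchor = gf_anchor_te(mobj, rnd))
  dec$n_mc <- n_mc
  dec
}

#' Exact g-formula decomposition of a discrete toy
#'
#' Enumerates every configuration of the binary mediator trajectories
#' and sums the conditional probability tables exactly — no Monte
#' Carlo. Serves as the oracle the simulation engine is validated
#' against. Refuses state spaces above 10^6 configurations.
#'
#' @param cpts A [toy_cpts()] object.
#' @param contrast Exposure contrast regimes (default 1 vs 0).
#' @param mediators Declared mediator order (`m1` maps to `gds15`).
#' @return List of class `pathspecific_decomposition` (xi = 0 by
#'   construction: the enumerated total effect is the anchor).
#' @export
enumerate_oracle <- function(cpts, contrast = list(x_high = 1, x_low = 0),
                             mediators = c("gds15", "moca")) {
  stopifnot(inherits(cpts, "toy_cpts"))
  V <- cpts$n_visits
  if (2^(2 * V) > 1e6) stop("state space above enumeration cap",
                            call. = FALSE)
  contrast <- list(x_high = rep_len(contrast$x_high, V),
                   x_low = rep_len(contrast$x_low, V))
  evaluate <- function(e) {
    if (V == 1L) {
      states <- expand.grid(m1 = 0:1, m2 = 0:1)
      p <- ifelse(states$m1 == 1, cpts$m1[e$m1[1] + 1L],
                  1 - cpts$m1[e$m1[1] + 1L]) *
        ifelse(states$m2 == 1,
               cpts$m2[cbind(e$m2[1] + 1L, states$m1 + 1L)],
               1 - cpts$m2[cbind(e$m2[1] + 1L, states$m1 + 1L)])
      ey <- cpts$y[cbind(e$y[1] + 1L, states$m1 + 1L, states$m2 + 1L)]
      sum(p * ey)
    } else {
      states <- expand.grid(m1a = 0:1, m2a = 0:1, m1b = 0:1, m2b = 0:1)
      pr <- function(p, val) ifelse(val == 1, p, 1 - p)
      p <- pr(cpts$m1[e$m1[1] + 1L], states$m1a) *
        pr(cpts$m2[cbind(e$m2[1] + 1L, states$m1a + 1L)], states$m2a) *
        pr(cpts$m1_2[cbind(e$m1[2] + 1L, states$m1a + 1L,
                           states$m2a + 1L)], states$m1b) *
        pr(cpts$m2_2[cbind(e$m2[2] + 1L, states$m1b + 1L,
                           states$m2a + 1L)], states$m2b)
      ey <- cpts$y[cbind(e$y[2] + 1L, states$m1b + 1L, states$m2b + 1L)]
      sum(p * ey)
    }
  }
  dec <- gf_decompose_core(evaluate, contrast, mediators)
  dec$n_mc <- Inf
  structure(dec, class = "pathspecific_decomposition")
}

#' @export
print.mediation_decomposition <- function(x, ...) {
  cat("Two-way mediational g-formula decomposition\n")
  cat(sprintf("  total effect        %8.3f\n", x$te))
  cat(sprintf("  direct effect       %8.3f (%s%%)\n", x$de,
              formatC(x$de_share, digits = 2, format = "f")))
  cat(sprintf("  joint indirect      %8.3f (%s%%)\n", x$ie_joint,
              formatC(x$ie_share, digits = 2, format = "f")))
  cat(sprintf("  xi (residual)       %8.3f\n", x$xi))
  invisible(x)
}

#' @export
print.pathspecific_decomposition <- function(x, ...) {
  cat("Path-specific mediational g-formula decomposition\n")
  cat(sprintf("  total effect        %8.3f\n", x$te))
  cat(sprintf("  direct effect       %8.3f\n", x$de))
  cat(sprintf("  joint indirect      %8.3f\n", x$ie_joint))
  for (m in names(x$per_mediator)) {
    cat(sprintf("    via %-6s        %8.3f (%s%%)\n", m,
                x$per_mediator[[m]],
                formatC(x$per_mediator_share[[m]], digits = 2,
                        format = "f")))
  }
  cat(sprintf("  interaction remainder %6.3g\n", x$interaction_remainder))
  invisible(x)
}

#' Subject-level bootstrap for the g-formula decompositions
#'
#' Resamples subjects with replacement, refits the component models and
#' recomputes both decompositions per replicate, returning percentile
#' 95% intervals for every component. The exposure contrast is resolved
#' once on the original panel and held fixed across replicates.
#' Replicates whose refit fails are counted; more than 10% failures is
#' an error.
#'
#' @param panel A `cohort_panel`.
#' @param spec A [gformula_spec()] (`n_boot` replicates,
#'   `n_mc` pseudo-subjects per replicate).
#' @param n_mc_boot Monte Carlo size within each replicate (default:
#'   `spec$n_mc`).
#' @param level Interval level (default 0.95).
#' @return List of class `gformula_bootstrap`: `estimate` (full-sample
#'   path-specific decomposition), `ci` (data frame: component,
#'   estimate, ci_low, ci_high), `n_boot_done`, `n_failed`.
#' @export
gformula_bootstrap <- function(panel, spec, n_mc_boot = NULL,
                               level = 0.95) {
  stopifnot(inherits(spec, "gformula_spec"))
  if (is.null(n_mc_boot)) n_mc_boot <- spec$n_mc
  mobj <- fit_component_models(panel, spec)
  est <- gf_decompose(mobj, n_mc = spec$n_mc, seed = spec$seed)
  spec_fixed <- spec
  spec_fixed$contrast <- mobj$contrast

  df <- as.data.frame(panel)
  ids <- unique(df$subject_id)
  rows_by_id <- split(seq_len(nrow(df)), df$subject_id)
  comp_names <- c("te", "de", "ie_joint", "xi",
                  paste0("ie_", names(est$per_mediator)))
  boot_vals <- matrix(NA_real_, spec$n_boot, length(comp_names),
                      dimnames = list(NULL, comp_names))
  n_failed <- 0L
  for (b in seq_len(spec$n_boot)) {
    set.seed((as.numeric(spec$seed) + 33311 * b) %% 2147483647)
    pick <- sample(ids, length(ids), replace = TRUE)
    idx <- unlist(rows_by_id[pick], use.names = FALSE)
    bdf <- df[idx, , drop = FALSE]
    bdf$subject_id <- rep(sprintf("B%05d", seq_along(pick)),
                          lengths(rows_by_id[pick]))
    bpanel <- structure(bdf, class = c("cohort_panel", "data.frame"),
                        n_visits = attr(panel, "n_visits"))
    res <- tryCatch({
      bm <- suppressWarnings(fit_component_models(bpanel, spec_fixed))
      d <- gf_decompose(bm, n_mc = n_mc_boot,
                        seed = (as.numeric(spec$seed) + 7127 * b) %%
                          2147483647)
      c(d$te, d$de, d$ie_joint, d$xi, d$per_mediator)
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else boot_vals[b, ] <- res
  }
  if (n_failed > 0.1 * spec$n_boot) {
    stop("bootstrap failed in ", n_failed, " of ", spec$n_boot,
         " replicates", call. = FALSE)
  }
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ok <- stats::complete.cases(boot_vals)
  ci <- data.frame(
    component = comp_names,
    estimate = c(est$te, est$de, est$ie_joint, est$xi, est$per_mediator),
    ci_low = apply(boot_vals[ok, , drop = FALSE], 2, stats::quantile,
                   probs = qs[1]),
    ci_high = apply(boot_vals[ok, , drop = FALSE], 2, stats::quantile,
                    probs = qs[2]),
    row.names = NULL)
  structure(list(estimate = structure(est,
                                      class = "pathspecific_decomposition"),
                 ci = ci, n_boot_done = sum(ok), n_failed = n_failed,
                 level = level, contrast = mobj$contrast),
            class = "gformula_bootstrap")
}

#' @export
print.gformula_bootstrap <- function(x, ...) {
  cat("g-formula decomposition with subject bootstrap (",
      x$n_boot_done, " replicates)\n", sep = "")
  print(transform(x$ci, estimate = round(estimate, 3),
                  ci_low = round(ci_low, 3), ci_high = round(ci_high, 3)),
        row.names = FALSE)
  invisible(x)
}
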