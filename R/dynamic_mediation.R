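# Bayesian dynamic (time-varying-coefficient) single-mediator
# mediation model, fitted by a blocked Gibbs sampler.
#
# Mediator equation:  M_ik = a0(t) + alpha(t) X_ik + gamma_M' C_i + u_i^M + e
# Outcome equation:   Y_ik = b0(t) + beta(t) M_ik + tau(t) X_ik
#                            + gamma_Y' C_i + u_i^Y + e'
# a0, alpha, b0, beta, tau live on a common spline (or linear) basis of
# normalized study time t in [0, 1]; u are subject random intercepts.
# With Gaussian errors, Gaussian coefficient priors and inverse-gamma
# variance priors every full conditional is conjugate, and the two
# equations share no parameters, so their posteriors factorize and are
# sampled independently. The indirect effect at time t is
# IE(t) = alpha(t) * beta(t), summarized over paired posterior draws.

#' Specification of the dynamic mediation model
#'
#' @param mediator `"gds15"` (depression) or `"moca"` (cognition).
#' @param basis `"bspline"` (default: cubic B-spline on `[0, 1]`) or
#'   `"linear"` (intercept + t; useful for small samples and fast
#'   simulation studies).
#' @param df Basis dimension for the B-spline (default 5). Each of
#'   a0, alpha, b0, beta, tau uses this basis.
#' @param priors List: `coef_sd` Gaussian prior SD for all regression
#'   and basis weights (default 2, on standardized data); `var_shape`,
#'   `var_rate` inverse-gamma shape/rate for the residual variances
#'   (default 2, 1); `re_var_shape`, `re_var_rate` for the random-
#'   intercept variances (default 2, 0.5).
#' @param n_iter MCMC iterations per chain (default 10000).
#' @param n_warmup Burn-in discarded per chain (default 5000).
#' @param n_chains Number of chains (default 4; at least 2, needed for
#'   split-Rhat).
#' @param seed Integer seed; chains use deterministic derived streams.
#' @param standardize Z-score X, M and Y before fitting (default TRUE);
#'   IE(t) is then on the standardized scale and can be mapped back to
#'   raw ADL points per exposure point by `sd(X)/sd(Y)` (see
#'   [indirect_effect_curve()]).
#' @return List of class `dynmed_spec`.
#' @export
dynmed_spec <- function(mediator = c("gds15", "moca"),
                        basis = c("bspline", "linear"),
                        df = 5L,
                        priors = list(),
                        n_iter = 10000L, n_warmup = 5000L, n_chains = 4L,
                        seed = 1L, standardize = TRUE) {
  mediator <- match.arg(mediator)
  basis <- match.arg(basis)
  defaults <- list(coef_sd = 2, var_shape = 2, var_rate = 1,
                   re_var_shape = 2, re_var_rate = 0.5)
  priors <- utils::modifyList(defaults, priors)
  stopifnot(n_iter > n_warmup, n_warmup >= 0, n_chains >= 2, df >= 2)
  structure(list(mediator = mediator, basis = basis, df = as.integer(df),
                 priors = priors, n_iter = as.integer(n_iter),
                 n_warmup = as.integer(n_warmup),
                 n_chains = as.integer(n_chains), seed = as.integer(seed),
                 standardize = isTRUE(standardize)),
            class = "dynmed_spec")
}

# basis constructor: returns list(eval = function(t) matrix, dim)
make_time_basis <- function(type, df) {
  if (type == "linear") {
    list(eval = function(t) cbind(1, t), dim = 2L)
  } else {
    ref <- splines::bs(seq(0, 1, length.out = 50), df = df,
                       intercept = TRUE, Boundary.knots = c(0, 1))
    list(eval = function(t) {
      m <- stats::predict(ref, t)
      attributes(m) <- list(dim = dim(m))
      m
    }, dim = as.integer(df))
  }
}

# One-equation Gibbs sampler for y = W theta + u[subj] + e.
# Returns draws matrix (rows = retained iterations over all chains) of
# theta columns, then sigma2, sigma2_u; plus chain index per row.
gibbs_lmm <- function(y, W, subj, priors, n_iter, n_warmup, n_chains,
                      seed) {
  n <- length(y); p <- ncol(W)
  m <- max(subj)
  ns <- tabulate(subj, m)
  WtW <- crossprod(W)
  prior_prec <- diag(1 / priors$coef_sd^2, p)
  n_keep <- n_iter - n_warmup
  draws <- matrix(NA_real_, n_keep * n_chains, p + 2L)
  chain_id <- rep(seq_len(n_chains), each = n_keep)
  ls_fit <- tryCatch(
    qr.coef(qr(cbind(W)), y), error = function(e) rep(0, p))
  ls_fit[is.na(ls_fit)] <- 0

  for (ch in seq_len(n_chains)) {
    set.seed((as.numeric(seed) + 104729 * ch) %% 2147483647)
    theta <- ls_fit + stats::rnorm(p, 0, 0.25)
    sigma2 <- max(stats::var(y), 1e-6) * stats::runif(1, 0.5, 1.5)
    sigma2_u <- sigma2 / 2
    u <- rep(0, m)
    for (it in seq_len(n_iter)) {
      # coefficient block
      r <- y - u[subj]
      post_prec <- WtW / sigma2 + prior_prec
      R <- chol(post_prec)
      mu <- backsolve(R, forwardsolve(t(R), crossprod(W, r) / sigma2))
      theta <- as.numeric(mu + backsolve(R, stats::rnorm(p)))
      # subject random intercepts
      resid <- y - as.numeric(W %*% theta)
      rs <- as.numeric(rowsum(resid, subj))
      v_u <- 1 / (ns / sigma2 + 1 / sigma2_u)
      u <- v_u * rs / sigma2 + sqrt(v_u) * stats::rnorm(m)
      # variances
      ssr <- sum((resid - u[subj])^2)
      sigma2 <- 1 / stats::rgamma(1, priors$var_shape + n / 2,
                                  rate = priors$var_rate + ssr / 2)
      sigma2_u <- 1 / stats::rgamma(1, priors$re_var_shape + m / 2,
                                    rate = priors$re_var_rate +
                                      sum(u^2) / 2)
      if (it > n_warmup) {
        draws[(ch - 1L) * n_keep + (it - n_warmup), ] <-
          c(theta, sigma2, sigma2_u)
      }
    }
  }
  colnames(draws) <- c(colnames(W), "sigma2", "sigma2_u")
  list(draws = draws, chain_id = chain_id)
}

#' Fit the Bayesian dynamic mediation model
#'
#' Samples the joint posterior of the two-equation time-varying-
#' coefficient model by a conjugate blocked Gibbs sampler (see the
#' package vignette for the model and priors). Rows with a missing
#' value in exposure, mediator or outcome are dropped (counted in the
#' returned object). A warning is attached when any split-Rhat exceeds
#' 1.05; run [diagnose()] for the full convergence report.
#'
#' @param panel A `cohort_panel`.
#' @param spec A [dynmed_spec()].
#' @return Object of class `dynmed_fit`: posterior draws for both
#'   equations, chain indexing, the basis, standardization scales and
#'   metadata. Retained draws number `n_chains * (n_iter - n_warmup)`.
#' @export
fit_dynamic_mediation <- function(panel, spec) {
  stopifnot(inherits(spec, "dynmed_spec"))
  df <- as.data.frame(panel)
  n_visits <- attr(panel, "n_visits")
  vars <- c("rbdsq", spec$mediator, "updrs2")
  keep <- stats::complete.cases(df[vars])
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < 10L) stop("too few complete rows to fit", call. = FALSE)
  x <- df$rbdsq; mm <- df[[spec$mediator]]; y <- df$updrs2
  if (stats::sd(x) == 0) {
    stop("degenerate design: exposure is constant", call. = FALSE)
  }
  if (stats::sd(mm) == 0) {
    stop("degenerate design: mediator is constant", call. = FALSE)
  }
  scales <- c(x = 1, m = 1, y = 1)
  centers <- c(x = 0, m = 0, y = 0)
  if (spec$standardize) {
    scales <- c(x = stats::sd(x), m = stats::sd(mm), y = stats::sd(y))
    centers <- c(x = mean(x), m = mean(mm), y = mean(y))
    x <- (x - centers["x"]) / scales["x"]
    mm <- (mm - centers["m"]) / scales["m"]
    y <- (y - centers["y"]) / scales["y"]
  }
  tt <- normalize_time(df$visit, n_visits)
  basis <- make_time_basis(spec$basis, spec$df)
  B <- basis$eval(tt)
  C <- covariate_design(df)
  lab <- function(stem, k) paste0(stem, "[", seq_len(k), "]")
  W_m <- cbind(B, B * x, C)
  colnames(W_m) <- c(lab("a0", basis$dim), lab("alpha", basis$dim),
                     paste0("gammaM_", colnames(C)))
  W_y <- cbind(B, B * mm, B * x, C)
  colnames(W_y) <- c(lab("b0", basis$dim), lab("beta", basis$dim),
                     lab("tau", basis$dim), paste0("gammaY_", colnames(C)))
  subj <- as.integer(factor(df$subject_id))

  fit_m <- gibbs_lmm(y = mm, W = W_m, subj = subj, priors = spec$priors,
                     n_iter = spec$n_iter, n_warmup = spec$n_warmup,
                     n_chains = spec$n_chains, seed = spec$seed)
  fit_y <- gibbs_lmm(y = y, W = W_y, subj = subj, priors = spec$priors,
                     n_iter = spec$n_iter, n_warmup = spec$n_warmup,
                     n_chains = spec$n_chains,
                     seed = spec$seed + 499979L)

  out <- structure(list(
    spec = spec, basis = basis,
    draws_m = fit_m$draws, draws_y = fit_y$draws,
    chain_id = fit_m$chain_id,
    scales = scales, centers = centers,
    n_obs = nrow(df), n_subjects = max(subj), n_dropped = n_dropped,
    n_visits = n_visits), class = "dynmed_fit")
  rhat <- tryCatch(split_rhat_all(out), error = function(e) NULL)
  if (!is.null(rhat) && any(!is.na(rhat) & rhat > 1.05)) {
    bad <- names(rhat)[!is.na(rhat) & rhat > 1.05]
    out$convergence_warning <- paste0(
      "split-Rhat > 1.05 for: ", paste(utils::head(bad, 8), collapse = ", "))
    warning(out$convergence_warning, call. = FALSE)
  }
  out
}

#' @export
print.dynmed_fit <- function(x, ...) {
  cat("Bayesian dynamic mediation fit: mediator =", x$spec$mediator,
      "\n  basis:", x$spec$basis, "(dim", x$basis$dim, ")",
      "\n  draws:", nrow(x$draws_m), "retained over", x$spec$n_chains,
      "chains;", x$n_obs, "rows /", x$n_subjects, "subjects",
      if (x$n_dropped > 0) paste0(" (", x$n_dropped, " incomplete dropped)"),
      "\n")
  if (!is.null(x$convergence_warning)) cat(" ", x$convergence_warning, "\n")
  invisible(x)
}

# posterior draws of a coefficient curve at times t: draws %*% basis'
curve_draws <- function(fit, stem, which_eq, t) {
  A <- fit$basis$eval(t)                     # length(t) x dim
  d <- if (which_eq == "m") fit$draws_m else fit$draws_y
  cols <- paste0(stem, "[", seq_len(fit$basis$dim), "]")
  d[, cols, drop = FALSE] %*% t(A)           # n_draws x length(t)
}

#' Indirect-effect curve IE(t) with credible bands
#'
#' For each requested time, computes `alpha(t) * beta(t)` draw by draw
#' (the mediator- and outcome-equation posteriors are independent given
#' the data; draws are paired by index) and summarizes the posterior
#' mean, SD and equal-tailed 95% credible interval.
#'
#' @param fit A `dynmed_fit`.
#' @param t_grid Times in `[0, 1]` (nonempty).
#' @param scale `"fitted"` reports IE on the scale the model was fitted
#'   on (standardized by default); `"raw"` multiplies by
#'   `sd(Y)/sd(X)` computed at fit time, giving ADL points per exposure
#'   point.
#' @param level Credible level (default 0.95).
#' @return Data frame: `t`, `ie_mean`, `ie_sd`, `ci_low`, `ci_high`.
#' @export
indirect_effect_curve <- function(fit, t_grid, scale = c("fitted", "raw"),
                                  level = 0.95) {
  stopifnot(inherits(fit, "dynmed_fit"))
  scale <- match.arg(scale)
  if (length(t_grid) == 0L) stop("t_grid is empty", call. = FALSE)
  if (any(t_grid < 0 | t_grid > 1)) {
    stop("t_grid values must lie in [0, 1]", call. = FALSE)
  }
  a <- curve_draws(fit, "alpha", "m", t_grid)
  b <- curve_draws(fit, "beta", "y", t_grid)
  ie <- a * b
  if (scale == "raw") {
    # alpha_std = alpha_raw * sd(X)/sd(M), beta_std = beta_raw * sd(M)/sd(Y)
    # so IE_raw = IE_std * sd(Y)/sd(X)
    ie <- ie * unname(fit$scales["y"] / fit$scales["x"])
  }
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  data.frame(
    t = t_grid,
    ie_mean = colMeans(ie),
    ie_sd = apply(ie, 2, stats::sd),
    ci_low = apply(ie, 2, stats::quantile, probs = qs[1]),
    ci_high = apply(ie, 2, stats::quantile, probs = qs[2]),
    row.names = NULL)
}

#' Direct- and path-coefficient curves
#'
#' Posterior summaries of a single time-varying coefficient curve
#' (`alpha`, `beta`, `tau`, `a0` or `b0`) on the fitted scale.
#'
#' @param fit A `dynmed_fit`.
#' @param stem Curve name.
#' @param t_grid Times in `[0, 1]`.
#' @param level Credible level.
#' @return Data frame: `t`, `mean`, `sd`, `ci_low`, `ci_high`.
#' @export
coefficient_curve <- function(fit, stem = c("alpha", "beta", "tau", "a0",
                                            "b0"),
                              t_grid, level = 0.95) {
  stem <- match.arg(stem)
  if (any(t_grid < 0 | t_grid > 1) || length(t_grid) == 0L) {
    stop("t_grid values must lie in [0, 1]", call. = FALSE)
  }
  eq <- if (stem %in% c("a0", "alpha")) "m" else "y"
  d <- curve_draws(fit, stem, eq, t_grid)
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  data.frame(t = t_grid, mean = colMeans(d), sd = apply(d, 2, stats::sd),
             ci_low = apply(d, 2, stats::quantile, probs = qs[1]),
             ci_high = apply(d, 2, stats::quantile, probs = qs[2]),
             row.names = NULL)
}

# split-Rhat for one parameter vector given chain ids
split_rhat <- function(x, chain_id) {
  halves <- unlist(lapply(split(x, chain_id), function(v) {
    h <- length(v) %/% 2L
    list(v[seq_len(h)], v[(h + 1L):(2L * h)])
  }), recursive = FALSE)
  mns <- vapply(halves, mean, 0)
  vrs <- vapply(halves, stats::var, 0)
  n <- length(halves[[1]]); m <- length(halves)
  W <- mean(vrs)
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- n * stats::var(mns)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence diagnostics for a dynamic mediation fit
#'
#' Split-Rhat and effective sample size per scalar parameter of both
#' equations, with flags at Rhat > 1.05 or ESS < 400, and an optional
#' per-chain trace export. Constant chains give `NA` Rhat and are
#' flagged rather than erroring.
#'
#' @param fit A `dynmed_fit` (at least 2 chains by construction).
#' @param trace_parameters Optional character vector of parameter names
#'   to include as long-format traces in `$trace` (default none).
#' @return List of class `dynmed_convergence`: `table` (parameter,
#'   equation, rhat, ess, flagged), `any_flagged`, `trace`.
#' @export
diagnose <- function(fit, trace_parameters = character()) {
  stopifnot(inherits(fit, "dynmed_fit"))
  if (length(unique(fit$chain_id)) < 2L) {
    stop("diagnostics need at least 2 chains", call. = FALSE)
  }
  per_eq <- function(d, eq) {
    ess <- vapply(seq_len(ncol(d)), function(j) {
      sum(vapply(split(d[, j], fit$chain_id),
                 function(v) as.numeric(coda::effectiveSize(v)), 0))
    }, 0)
    rhat <- vapply(seq_len(ncol(d)), function(j) {
      split_rhat(d[, j], fit$chain_id)
    }, 0)
    data.frame(parameter = colnames(d), equation = eq, rhat = rhat,
               ess = ess, stringsAsFactors = FALSE)
  }
  tab <- rbind(per_eq(fit$draws_m, "mediator"),
               per_eq(fit$draws_y, "outcome"))
  tab$flagged <- is.na(tab$rhat) | tab$rhat > 1.05 | tab$ess < 400
  trace <- NULL
  if (length(trace_parameters) > 0L) {
    all_d <- cbind(fit$draws_m,
                   `colnames<-`(fit$draws_y, paste0("Y.",
                                                    colnames(fit$draws_y))))
    keep <- intersect(c(trace_parameters, paste0("Y.", trace_parameters)),
                      colnames(all_d))
    trace <- do.call(rbind, lapply(keep, function(p) {
      data.frame(parameter = p, chain = fit$chain_id,
                 iter = stats::ave(seq_along(fit$chain_id), fit$chain_id,
                                   FUN = seq_along),
                 value = all_d[, p], stringsAsFactors = FALSE)
    }))
  }
  structure(list(table = tab, any_flagged = any(tab$flagged),
                 trace = trace), class = "dynmed_convergence")
}

#' @export
print.dynmed_convergence <- function(x, ...) {
  cat("Convergence:", sum(x$table$flagged), "of", nrow(x$table),
      "parameters flagged (Rhat > 1.05 or ESS < 400)\n")
  cat(sprintf("  max Rhat = %.3f, min ESS = %.0f\n",
              max(x$table$rhat, na.rm = TRUE), min(x$table$ess)))
  invisible(x)
}

# max split-Rhat over all parameters, used by the fit-time warning
split_rhat_all <- function(fit) {
  d <- cbind(fit$draws_m, fit$draws_y)
  out <- vapply(seq_len(ncol(d)), function(j) {
    split_rhat(d[, j], fit$chain_id)
  }, 0)
  names(out) <- c(colnames(fit$draws_m), colnames(fit$draws_y))
  out
}
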