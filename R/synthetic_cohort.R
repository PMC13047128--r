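# Synthetic PPMI-like cohort generator: a linear Gaussian
# time-varying-coefficient mediation DGP with subject random
# intercepts, plus tiny binary toys with retained conditional
# probability tables for exact oracles.

#' Default marginal frequencies of the baseline covariates
#'
#' Category frequencies used to sample synthetic demographics,
#' matching the composition of a typical early-PD cohort (about two
#' thirds male, three quarters over 65, predominantly White, mostly
#' without first-degree family history).
#'
#' @return Named list of named probability vectors (each sums to 1).
#' @export
covariate_frequencies <- function() {
  list(
    sex            = c(male = 0.6528, female = 0.3472),
    age_band       = c(">65" = 0.7478, "56-65" = 0.2196, "<56" = 0.0326),
    edu_band       = c("13-23" = 0.7656, "<13" = 0.2226, ">23" = 0.0118),
    race           = c(White = 0.9614, Black = 0.0059, Asian = 0.0148,
                       other = 0.0179),
    family_history = c(none = 0.6143, "first-degree" = 0.2166,
                       "non-first-degree" = 0.1691),
    duration_band  = c(">10" = 0.5967, "5-10" = 0.2433, "<5" = 0.1602)
  )
}

#' Data-generating-process configuration
#'
#' Defines the joint two-mediator time-varying mediation model the
#' generator samples from. For subject i at visit k (time t = k/8):
#' \deqn{M_{j,ik} = a_j(t) + \alpha_j(t) X_{ik} + \gamma_j' C_i + u^{M_j}_i + \epsilon}
#' \deqn{Y_{ik} = b_0(t) + \sum_j \beta_j(t) (M_{j,ik} - c_j) + \tau(t) X_{ik} + \gamma_Y' C_i + u^Y_i + \epsilon'}
#' with exposure X a rounded truncated AR(1) Gaussian, baseline-fixed
#' covariates C, independent subject random intercepts u, and Gaussian
#' residuals. Mediators are conditionally independent given (X, C), so
#' each single-mediator submodel is correctly specified. The mediator
#' centering constants c_j only shift the outcome intercept.
#'
#' Default path functions are affine increasing in t and calibrated so
#' each mediator's indirect effect roughly doubles between t = 0.25 and
#' t = 0.75, with the MoCA paths negative on both legs (worse RBD lowers
#' cognition; lower cognition raises ADL limitation), giving a positive
#' indirect effect on the harm scale for both mediators.
#'
#' @param n_subjects Number of subjects (default 337).
#' @param n_visits Number of annual visits (default 9).
#' @param alpha_fn Named list (`gds15`, `moca`) of functions of
#'   normalized time: exposure-to-mediator paths.
#' @param beta_fn Named list of functions: mediator-to-outcome paths.
#' @param tau_fn Function: direct exposure-to-outcome path.
#' @param m_intercept Named list of functions: mediator intercepts a_j(t).
#' @param y_intercept Function: outcome intercept b_0(t).
#' @param m_center Named numeric: centering constants c_j for the
#'   mediators in the outcome equation.
#' @param covariate_effects Named list (`gds15`, `moca`, `updrs2`) of
#'   named numeric vectors of effects on the dummy-coded covariate
#'   columns (names as produced by the internal design matrix, e.g.
#'   `sex_female`); unnamed columns default to 0.
#' @param random_effect_sd Named numeric: SDs of the subject random
#'   intercepts for `gds15`, `moca`, `updrs2` (all >= 0).
#' @param noise_sd Named numeric: residual SDs (all > 0).
#' @param exposure_model List with `mean`, `sd`, `ar1`: RBDSQ is a
#'   rounded, range-truncated Gaussian AR(1) process within subject.
#' @param clipping If `TRUE` (default) all emitted scores are rounded
#'   and truncated to their scale ranges; turn off for exact
#'   linear-Gaussian data.
#' @param seed Default master seed used by [simulate_cohort()].
#' @return A list of class `dgp_config`.
#' @export
dgp_config <- function(n_subjects = 337L,
                       n_visits = 9L,
                       alpha_fn = list(
                         gds15 = function(t) 0.10 + 0.16 * t,
                         moca  = function(t) -(0.12 + 0.18 * t)),
                       beta_fn = list(
                         gds15 = function(t) 0.35 + 0.25 * t,
                         moca  = function(t) -(0.30 + 0.28 * t)),
                       tau_fn = function(t) 0.25 + 0.10 * t,
                       m_intercept = list(
                         gds15 = function(t) 2.0 + 1.0 * t,
                         moca  = function(t) 27 - 1.5 * t),
                       y_intercept = function(t) 1.0 + 2.0 * t,
                       m_center = c(gds15 = 2.5, moca = 26),
                       covariate_effects = list(
                         gds15  = c(sex_female = 0.3),
                         moca   = c("edu_band_<13" = -0.5),
                         updrs2 = c(sex_female = -0.3, "age_band_<56" = 0.5)),
                       random_effect_sd = c(gds15 = 1.2, moca = 1.5,
                                            updrs2 = 2.0),
                       noise_sd = c(gds15 = 1.5, moca = 1.8, updrs2 = 2.5),
                       exposure_model = list(mean = 4, sd = 2.5, ar1 = 0.7),
                       clipping = TRUE,
                       seed = 20260320L) {
  stopifnot(n_subjects >= 2L, n_visits >= 2L,
            all(random_effect_sd >= 0), all(noise_sd > 0),
            abs(exposure_model$ar1) < 1)
  med <- c("gds15", "moca")
  if (!all(med %in% names(alpha_fn)) || !all(med %in% names(beta_fn))) {
    stop("alpha_fn and beta_fn must be named lists over gds15 and moca",
         call. = FALSE)
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_visits = as.integer(n_visits),
    alpha_fn = alpha_fn, beta_fn = beta_fn, tau_fn = tau_fn,
    m_intercept = m_intercept, y_intercept = y_intercept,
    m_center = m_center, covariate_effects = covariate_effects,
    random_effect_sd = random_effect_sd, noise_sd = noise_sd,
    exposure_model = exposure_model, clipping = isTRUE(clipping),
    seed = as.integer(seed)), class = "dgp_config")
}

clip_score <- function(x, rng) pmin(pmax(round(x), rng[1]), rng[2])

# covariate effect lookup: partial named vector over design columns
cov_contrib <- function(design, effects) {
  if (is.null(effects) || length(effects) == 0L) return(rep(0, nrow(design)))
  unknown <- setdiff(names(effects), colnames(design))
  if (length(unknown) > 0L) {
    stop("unknown covariate effect name(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  as.numeric(design[, names(effects), drop = FALSE] %*% effects)
}

#' Simulate a synthetic cohort panel
#'
#' Draws a full panel from the configured DGP. Per-subject random
#' streams are derived deterministically from the master seed, so
#' enlarging `n_subjects` extends the cohort without reshuffling the
#' subjects already present.
#'
#' @param config A [dgp_config()].
#' @param seed Master seed; defaults to `config$seed`.
#' @return A `cohort_panel` (see [cohort_panel()]).
#' @export
#' @examples
#' panel <- simulate_cohort(dgp_config(n_subjects = 20), seed = 1)
#' head(panel)
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "dgp_config"))
  K <- config$n_visits
  t <- normalize_time(0:(K - 1L), K)
  rng <- scale_ranges()
  freq <- covariate_frequencies()
  med <- c("gds15", "moca")

  one_subject <- function(i) {
    set.seed((as.numeric(seed) + 7919 * i) %% 2147483647)
    covs <- vapply(freq, function(p) sample(names(p), 1L, prob = p), "")
    # exposure: stationary latent AR(1)
    rho <- config$exposure_model$ar1
    z <- numeric(K); z[1] <- stats::rnorm(1)
    if (K > 1L) for (k in 2:K) {
      z[k] <- rho * z[k - 1] + sqrt(1 - rho^2) * stats::rnorm(1)
    }
    x <- config$exposure_model$mean + config$exposure_model$sd * z
    if (config$clipping) x <- clip_score(x, rng$rbdsq)
    u <- stats::rnorm(3) * config$random_effect_sd[c(med, "updrs2")]
    eps <- matrix(stats::rnorm(3 * K), K, 3) %*%
      diag(config$noise_sd[c(med, "updrs2")])
    list(subject_id = sprintf("S%04d", i), covs = covs, x = x, u = u,
         eps = eps)
  }

  subs <- lapply(seq_len(config$n_subjects), one_subject)
  df <- data.frame(
    subject_id = rep(vapply(subs, `[[`, "", "subject_id"), each = K),
    visit = rep(0:(K - 1L), config$n_subjects),
    stringsAsFactors = FALSE)
  for (v in names(freq)) {
    df[[v]] <- rep(vapply(subs, function(s) s$covs[[v]], ""), each = K)
  }
  design <- covariate_design(df)
  x <- unlist(lapply(subs, `[[`, "x"))
  tt <- rep(t, config$n_subjects)

  m_val <- list()
  for (j in seq_along(med)) {
    mj <- med[j]
    m <- config$m_intercept[[mj]](tt) + config$alpha_fn[[mj]](tt) * x +
      cov_contrib(design, config$covariate_effects[[mj]]) +
      rep(vapply(subs, function(s) s$u[j], 0), each = K) +
      unlist(lapply(subs, function(s) s$eps[, j]))
    if (config$clipping) m <- clip_score(m, rng[[mj]])
    m_val[[mj]] <- m
  }
  y <- config$y_intercept(tt) + config$tau_fn(tt) * x +
    cov_contrib(design, config$covariate_effects$updrs2) +
    rep(vapply(subs, function(s) s$u[3], 0), each = K) +
    unlist(lapply(subs, function(s) s$eps[, 3]))
  for (mj in med) {
    y <- y + config$beta_fn[[mj]](tt) * (m_val[[mj]] - config$m_center[[mj]])
  }
  if (config$clipping) y <- clip_score(y, rng$updrs2)

  df$rbdsq <- x; df$gds15 <- m_val$gds15; df$moca <- m_val$moca
  df$updrs2 <- y
  if (config$clipping) {
    cohort_panel(df, n_visits = K)
  } else {
    # continuous scores: bypass integer-range validation but keep the class
    df <- df[panel_cols()]
    structure(df, class = c("cohort_panel", "data.frame"),
              n_visits = K,
              validation_report = c(visit_range = 0L, score_range = 0L,
                                    bad_covariate = 0L, duplicate = 0L))
  }
}

#' Analytic true effect curves of a DGP
#'
#' The indirect effect of mediator j at time t is the product of the
#' configured paths, `alpha_j(t) * beta_j(t)`; the direct effect is
#' `tau(t)`. No sampling is involved.
#'
#' @param config A [dgp_config()].
#' @param t_grid Numeric vector of times in `[0, 1]`.
#' @return Data frame with columns `t`, `ie_gds15`, `ie_moca`,
#'   `ie_total` (sum over mediators) and `de`.
#' @export
#' @examples
#' true_effects(dgp_config(), c(0.25, 0.5, 0.75))
true_effects <- function(config, t_grid) {
  stopifnot(inherits(config, "dgp_config"))
  if (length(t_grid) == 0L || any(t_grid < 0 | t_grid > 1)) {
    stop("t_grid values must lie in [0, 1]", call. = FALSE)
  }
  ie1 <- config$alpha_fn$gds15(t_grid) * config$beta_fn$gds15(t_grid)
  ie2 <- config$alpha_fn$moca(t_grid) * config$beta_fn$moca(t_grid)
  data.frame(t = t_grid, ie_gds15 = ie1, ie_moca = ie2,
             ie_total = ie1 + ie2, de = config$tau_fn(t_grid))
}

#' Conditional probability tables for a binary mediation toy
#'
#' Describes a fully discrete single- or two-visit system with binary
#' exposure X, mediators M1, M2 (M2 downstream of M1 within visit) and
#' a binary end-of-follow-up outcome Y. Used both to sample toy panels
#' ([simulate_toy_discrete()]) and as an exactly enumerable model for
#' the g-formula oracle ([enumerate_oracle()]).
#'
#' For `n_visits = 1`: `m1[x+1]` is P(M1 = 1 | X = x); `m2[x+1, m1+1]`;
#' `y[x+1, m1+1, m2+1]`. For `n_visits = 2` additionally `m1_2[x2+1,
#' m1_1+1, m2_1+1]`, `m2_2[x2+1, m1_2+1, m2_1+1]`, and `y` is indexed by
#' the final visit's (x, m1, m2). `px` gives P(X = 1) per visit for
#' observational sampling.
#'
#' @param px Numeric, P(X = 1) per visit (recycled).
#' @param m1,m2,y Probability arrays as described above.
#' @param m1_2,m2_2 Second-visit mediator tables (2-visit toys only).
#' @param n_visits 1 or 2.
#' @return List of class `toy_cpts`.
#' @export
toy_cpts <- function(px, m1, m2, y, m1_2 = NULL, m2_2 = NULL,
                     n_visits = 1L) {
  n_visits <- as.integer(n_visits)
  stopifnot(n_visits %in% c(1L, 2L))
  px <- rep_len(px, n_visits)
  m1 <- array(m1, dim = 2)
  m2 <- array(m2, dim = c(2, 2))
  y <- array(y, dim = c(2, 2, 2))
  check01 <- function(p, nm) {
    if (any(is.na(p)) || any(p < -1e-9) || any(p > 1 + 1e-9)) {
      stop("probabilities in '", nm, "' must lie in [0, 1]", call. = FALSE)
    }
  }
  check01(px, "px"); check01(m1, "m1"); check01(m2, "m2"); check01(y, "y")
  if (n_visits == 2L) {
    if (is.null(m1_2) || is.null(m2_2)) {
      stop("2-visit toys need m1_2 and m2_2 tables", call. = FALSE)
    }
    m1_2 <- array(m1_2, dim = c(2, 2, 2))
    m2_2 <- array(m2_2, dim = c(2, 2, 2))
    check01(m1_2, "m1_2"); check01(m2_2, "m2_2")
  }
  structure(list(px = px, m1 = m1, m2 = m2, y = y, m1_2 = m1_2,
                 m2_2 = m2_2, n_visits = n_visits), class = "toy_cpts")
}

#' Sample a panel from a discrete toy
#'
#' Samples `n_subjects` independent trajectories exactly from the
#' conditional probability tables. Binary values are written into the
#' score columns (0/1 are valid on every scale); covariates are set to
#' their reference levels. The CPTs are retained as an attribute so the
#' exact g-formula can be enumerated alongside.
#'
#' @param n_subjects Number of subjects.
#' @param cpts A [toy_cpts()] object.
#' @param seed Integer seed.
#' @return A `cohort_panel` with attribute `cpts`.
#' @export
simulate_toy_discrete <- function(n_subjects, cpts, seed) {
  stopifnot(inherits(cpts, "toy_cpts"), n_subjects >= 1L)
  set.seed(seed)
  V <- cpts$n_visits
  draw <- function(p) as.integer(stats::runif(n_subjects) < p)
  x1 <- draw(cpts$px[1])
  m1 <- draw(cpts$m1[x1 + 1L])
  m2 <- draw(cpts$m2[cbind(x1 + 1L, m1 + 1L)])
  if (V == 1L) {
    y <- draw(cpts$y[cbind(x1 + 1L, m1 + 1L, m2 + 1L)])
    df <- data.frame(subject_id = sprintf("T%05d", seq_len(n_subjects)),
                     visit = 0L, rbdsq = x1, gds15 = m1, moca = m2,
                     updrs2 = y, stringsAsFactors = FALSE)
  } else {
    x2 <- draw(cpts$px[2])
    m1b <- draw(cpts$m1_2[cbind(x2 + 1L, m1 + 1L, m2 + 1L)])
    m2b <- draw(cpts$m2_2[cbind(x2 + 1L, m1b + 1L, m2 + 1L)])
    y <- draw(cpts$y[cbind(x2 + 1L, m1b + 1L, m2b + 1L)])
    id <- sprintf("T%05d", seq_len(n_subjects))
    df <- data.frame(
      subject_id = rep(id, each = 2L), visit = rep(0:1, n_subjects),
      rbdsq = as.vector(rbind(x1, x2)), gds15 = as.vector(rbind(m1, m1b)),
      moca = as.vector(rbind(m2, m2b)),
      updrs2 = as.vector(rbind(NA_integer_, y)), stringsAsFactors = FALSE)
  }
  ref <- vapply(covariate_levels(), `[[`, "", 1L)
  for (v in names(ref)) df[[v]] <- ref[[v]]
  # NA outcome at the non-final toy visit is intentional (end-of-follow-up Y)
  out <- structure(df[panel_cols()],
                   class = c("cohort_panel", "data.frame"),
                   n_visits = V,
                   validation_report = c(visit_range = 0L, score_range = 0L,
                                         bad_covariate = 0L, duplicate = 0L))
  attr(out, "cpts") <- cpts
  out
}
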