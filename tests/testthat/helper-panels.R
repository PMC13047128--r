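# Shared fixture builders. Panels are always generated in code.

ref_covariates <- function(df) {
  ref <- vapply(covariate_levels(), `[[`, "", 1L)
  for (v in names(ref)) df[[v]] <- ref[[v]]
  df
}

# wrap a data frame as a cohort_panel without integer-score validation
# (for continuous linear-Gaussian toys)
as_panel <- function(df, n_visits = 1L) {
  structure(df[longmed:::panel_cols()],
            class = c("cohort_panel", "data.frame"),
            n_visits = as.integer(n_visits),
            validation_report = c(visit_range = 0L, score_range = 0L,
                                  bad_covariate = 0L, duplicate = 0L))
}

# single-visit linear-Gaussian mediation toy:
#   M1 = a1 X + e, M2 = a2 X + e, Y = b1 M1 + b2 M2 + cdir X + e
make_linear_panel <- function(n, a1 = 0.5, b1 = 0.4, a2 = 0, b2 = 0,
                              cdir = 0.3, sdx = 1.5, sd_noise = 0.5,
                              seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n, 0, sdx)
  m1 <- a1 * x + stats::rnorm(n, 0, sd_noise)
  m2 <- a2 * x + stats::rnorm(n, 0, sd_noise)
  y <- b1 * m1 + b2 * m2 + cdir * x + stats::rnorm(n, 0, sd_noise)
  df <- data.frame(subject_id = sprintf("S%05d", seq_len(n)), visit = 0L,
                   rbdsq = x, gds15 = m1, moca = m2, updrs2 = y,
                   stringsAsFactors = FALSE)
  as_panel(ref_covariates(df), n_visits = 1L)
}

# a tiny handmade valid integer panel (2 subjects x 2 visits)
tiny_panel_df <- function() {
  df <- data.frame(
    subject_id = c("A", "A", "B", "B"),
    visit = c(0L, 1L, 0L, 1L),
    rbdsq = c(3L, 4L, 6L, 7L),
    gds15 = c(2L, 3L, 5L, 6L),
    moca = c(27L, 26L, 24L, 23L),
    updrs2 = c(4L, 5L, 10L, 12L),
    stringsAsFactors = FALSE)
  ref_covariates(df)
}

# seeded random single-visit binary toy CPTs
random_cpts <- function(seed) {
  set.seed(seed)
  toy_cpts(px = 0.5, m1 = stats::runif(2), m2 = matrix(stats::runif(4), 2),
           y = array(stats::runif(8), c(2, 2, 2)))
}
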