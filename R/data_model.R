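# Domain model: validated long-format cohort panels, scale ranges,
# clinical cut-offs, and study-time normalization.

#' Scale ranges for the analysis variables
#'
#' Integer score ranges of the four rating scales used throughout the
#' package: RBDSQ (REM sleep behavior disorder screening questionnaire,
#' exposure), GDS-15 (geriatric depression scale, mediator), MoCA
#' (Montreal cognitive assessment, mediator; higher is better), and
#' MDS-UPDRS Part II (activities of daily living, outcome).
#'
#' @return Named list of `c(min, max)` integer vectors.
#' @export
#' @examples
#' scale_ranges()$rbdsq
scale_ranges <- function() {
  list(
    rbdsq  = c(0L, 13L),
    gds15  = c(0L, 15L),
    moca   = c(0L, 30L),
    updrs2 = c(0L, 52L)
  )
}

#' Covariate band levels
#'
#' Baseline-fixed categorical covariates and their admissible levels.
#' The first level of each set is the modal category in a typical PD
#' cohort and is used as the dummy-coding reference.
#'
#' @return Named list of character vectors.
#' @export
covariate_levels <- function() {
  list(
    sex            = c("male", "female"),
    age_band       = c(">65", "56-65", "<56"),
    edu_band       = c("13-23", "<13", ">23"),
    race           = c("White", "Black", "Asian", "other"),
    family_history = c("none", "first-degree", "non-first-degree"),
    duration_band  = c(">10", "5-10", "<5")
  )
}

panel_score_cols <- function() c("rbdsq", "gds15", "moca", "updrs2")
panel_cov_cols   <- function() names(covariate_levels())
panel_cols <- function() {
  c("subject_id", "visit", panel_score_cols(), panel_cov_cols())
}

#' Construct a validated cohort panel
#'
#' A cohort panel is a long-format data frame with one row per
#' subject-visit, carrying the four scale scores and the baseline
#' covariate bands. `cohort_panel()` checks the schema, the score
#' ranges, visit indices, uniqueness of (subject, visit) pairs, and
#' that covariates are constant within subject.
#'
#' @param df Data frame with columns `subject_id`, `visit`, `rbdsq`,
#'   `gds15`, `moca`, `updrs2`, `sex`, `age_band`, `edu_band`, `race`,
#'   `family_history`, `duration_band`. Missing scores are allowed
#'   (`NA`); covariates must be non-missing.
#' @param n_visits Number of scheduled visits (default 9: baseline plus
#'   eight annual follow-ups). Visit indices must lie in
#'   `0:(n_visits - 1)`.
#' @param strict If `TRUE` (default) any invariant violation is an
#'   error; if `FALSE` offending rows are dropped and counted in the
#'   `validation_report` attribute.
#' @return A data frame of class `cohort_panel` with attributes
#'   `n_visits` and `validation_report` (named integer vector of rows
#'   dropped per reason; all zero in strict mode).
#' @export
cohort_panel <- function(df, n_visits = 9L, strict = TRUE) {
  df <- as.data.frame(df)
  missing_cols <- setdiff(panel_cols(), names(df))
  if (length(missing_cols) > 0L) {
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[panel_cols()]
  df$subject_id <- as.character(df$subject_id)
  df$visit <- as.integer(df$visit)
  for (v in panel_score_cols()) df[[v]] <- as.numeric(df[[v]])

  report <- c(visit_range = 0L, score_range = 0L, bad_covariate = 0L,
              duplicate = 0L)
  bad <- rep(FALSE, nrow(df))

  viol <- is.na(df$visit) | df$visit < 0L | df$visit > n_visits - 1L
  if (any(viol)) {
    if (strict) stop("visit index outside 0..", n_visits - 1L, " in row(s) ",
                     paste(utils::head(which(viol), 5L), collapse = ", "),
                     call. = FALSE)
    report["visit_range"] <- sum(viol & !bad); bad <- bad | viol
  }

  rng <- scale_ranges()
  for (v in panel_score_cols()) {
    x <- df[[v]]
    viol <- !is.na(x) & (x < rng[[v]][1] | x > rng[[v]][2] | x != floor(x))
    if (any(viol)) {
      if (strict) stop(v, " outside its scale range [", rng[[v]][1], ", ",
                       rng[[v]][2], "] in row(s) ",
                       paste(utils::head(which(viol), 5L), collapse = ", "),
                       call. = FALSE)
      report["score_range"] <- report["score_range"] + sum(viol & !bad)
      bad <- bad | viol
    }
  }

  lev <- covariate_levels()
  for (v in panel_cov_cols()) {
    x <- as.character(df[[v]])
    viol <- is.na(x) | !(x %in% lev[[v]])
    if (any(viol)) {
      if (strict) stop("invalid ", v, " value in row(s) ",
                       paste(utils::head(which(viol), 5L), collapse = ", "),
                       call. = FALSE)
      report["bad_covariate"] <- report["bad_covariate"] + sum(viol & !bad)
      bad <- bad | viol
    }
    df[[v]] <- x
  }

  dup <- duplicated(df[c("subject_id", "visit")]) & !bad
  if (any(dup)) {
    if (strict) stop("duplicate (subject_id, visit) pair(s)", call. = FALSE)
    report["duplicate"] <- sum(dup); bad <- bad | dup
  }

  df <- df[!bad, , drop = FALSE]
  rownames(df) <- NULL

  # covariates must be baseline-fixed within subject
  for (v in panel_cov_cols()) {
    n_lev <- tapply(df[[v]], df$subject_id, function(x) length(unique(x)))
    if (any(n_lev > 1L)) {
      stop("covariate '", v, "' varies within subject ",
           names(n_lev)[which(n_lev > 1L)[1]], call. = FALSE)
    }
  }

  structure(df, class = c("cohort_panel", "data.frame"),
            n_visits = as.integer(n_visits), validation_report = report)
}

#' @export
print.cohort_panel <- function(x, ...) {
  cat("Cohort panel:", length(unique(x$subject_id)), "subjects,",
      nrow(x), "subject-visits,", attr(x, "n_visits"), "scheduled visits\n")
  rep <- attr(x, "validation_report")
  if (!is.null(rep) && sum(rep) > 0L) {
    cat("Rows dropped in lenient validation:",
        paste(names(rep)[rep > 0], rep[rep > 0], sep = "=", collapse = ", "),
        "\n")
  }
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Read a cohort panel from CSV
#'
#' Expects the long-format schema documented in [cohort_panel()]:
#' one row per subject-visit, UTF-8, empty fields for missing scores.
#'
#' @param path CSV file path.
#' @param strict Passed to [cohort_panel()].
#' @inheritParams cohort_panel
#' @return A `cohort_panel`.
#' @export
load_cohort <- function(path, n_visits = 9L, strict = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"),
                        na.strings = c("", "NA"))
  cohort_panel(df, n_visits = n_visits, strict = strict)
}

#' Write a cohort panel to CSV
#'
#' Inverse of [load_cohort()]: `load_cohort(write_cohort(p, f))`
#' reproduces `p`.
#'
#' @param panel A `cohort_panel`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(panel, path) {
  utils::write.csv(as.data.frame(panel)[panel_cols()], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Map a visit index to normalized study time
#'
#' Min-max normalization of the visit index onto the unit interval:
#' visit `k` of an `n_visits`-point design maps to `k / (n_visits - 1)`,
#' so baseline is 0 and the final visit is 1. For the 9-visit annual
#' design, follow-ups 2, 4 and 6 map to 0.25, 0.50 and 0.75.
#'
#' @param visit Integer visit index (vectorized), `0 <= visit <= n_visits - 1`.
#' @param n_visits Number of scheduled visits (>= 2).
#' @return Numeric vector of times in `[0, 1]`.
#' @export
#' @examples
#' normalize_time(c(0, 2, 4, 6, 8), 9)
normalize_time <- function(visit, n_visits = 9L) {
  if (n_visits < 2L) stop("n_visits must be at least 2", call. = FALSE)
  if (any(visit < 0 | visit > n_visits - 1L)) {
    stop("visit index outside 0..", n_visits - 1L, call. = FALSE)
  }
  visit / (n_visits - 1)
}

#' Depression severity category from a GDS-15 score
#'
#' GDS-15 cut-offs: below 5 no depression, 5-9 mild, 10 and above
#' moderate to severe.
#'
#' @param gds15 Integer score(s) in 0..15.
#' @return Factor with levels `none`, `mild`, `moderate_severe`.
#' @export
categorize_depression <- function(gds15) {
  if (any(is.na(gds15)) || any(gds15 < 0 | gds15 > 15)) {
    stop("gds15 must lie in 0..15", call. = FALSE)
  }
  cut(gds15, breaks = c(-Inf, 4.5, 9.5, Inf),
      labels = c("none", "mild", "moderate_severe"))
}

#' Cognitive status category from a MoCA score
#'
#' MoCA cut-off: 26 and above is normal cognition, below 26 impaired.
#'
#' @param moca Integer score(s) in 0..30.
#' @return Factor with levels `normal`, `impaired`.
#' @export
categorize_cognition <- function(moca) {
  if (any(is.na(moca)) || any(moca < 0 | moca > 30)) {
    stop("moca must lie in 0..30", call. = FALSE)
  }
  factor(ifelse(moca >= 26, "normal", "impaired"),
         levels = c("normal", "impaired"))
}

#' Complete-case filter on the analysis variables
#'
#' Drops subject-visits with a missing value in any of the four
#' analysis scores and reports how many rows each variable removed.
#' Covariates are validated non-missing at construction, so only the
#' scores are examined.
#'
#' @param panel A `cohort_panel`.
#' @return List with elements `panel` (filtered `cohort_panel`) and
#'   `report` (named integer vector: rows with a missing value per
#'   score variable, plus `total_removed`).
#' @export
complete_case_filter <- function(panel) {
  df <- as.data.frame(panel)
  miss <- vapply(panel_score_cols(), function(v) is.na(df[[v]]),
                 logical(nrow(df)))
  if (nrow(df) == 1L) miss <- matrix(miss, nrow = 1L)
  any_miss <- rowSums(miss) > 0
  report <- c(colSums(miss), total_removed = sum(any_miss))
  kept <- df[!any_miss, , drop = FALSE]
  if (nrow(kept) == 0L) {
    stop("no analyzable data: every row has a missing analysis variable",
         call. = FALSE)
  }
  list(panel = cohort_panel(kept, n_visits = attr(panel, "n_visits")),
       report = report)
}

# Dummy-coded design columns for the baseline covariates, reference =
# first (modal) level of each set. Returns a plain numeric matrix.
covariate_design <- function(df) {
  lev <- covariate_levels()
  cols <- lapply(names(lev), function(v) {
    f <- factor(df[[v]], levels = lev[[v]])
    m <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(m) <- paste0(v, "_", lev[[v]][-1])
    m
  })
  do.call(cbind, cols)
}
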