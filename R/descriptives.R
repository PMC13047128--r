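# Baseline group comparisons of ADL and the exposure/mediator/outcome
# correlation matrix.

#' Compare baseline ADL scores across levels of a covariate
#'
#' Uses baseline (visit 0) MDS-UPDRS-II scores only. Two nonempty
#' levels give a classic equal-variance two-sample t-test; three or
#' more give a one-way ANOVA. Empty levels are dropped. No
#' multiple-testing correction is applied.
#'
#' @param panel A `cohort_panel`.
#' @param grouping One of the covariate names (see [covariate_levels()]).
#' @return List of class `group_comparison`: `grouping`, `levels` (data
#'   frame: level, n, percent, mean, sd), `statistic`, `p_value`,
#'   `test` (`"two_sample_t"` or `"one_way_anova"`).
#' @export
compare_adl_by <- function(panel, grouping) {
  if (!grouping %in% panel_cov_cols()) {
    stop("unknown covariate: ", grouping, call. = FALSE)
  }
  base <- as.data.frame(panel)
  base <- base[base$visit == 0L & !is.na(base$updrs2), , drop = FALSE]
  if (nrow(base) == 0L) stop("no baseline rows with ADL scores", call. = FALSE)
  f <- factor(base[[grouping]], levels = covariate_levels()[[grouping]])
  f <- droplevels(f)
  if (nlevels(f) < 2L) {
    stop("grouping '", grouping, "' has fewer than 2 nonempty levels",
         call. = FALSE)
  }
  y <- base$updrs2
  tab <- data.frame(
    level = levels(f),
    n = as.integer(table(f)),
    percent = round(100 * as.integer(table(f)) / length(y), 2),
    mean = as.numeric(tapply(y, f, mean)),
    sd = as.numeric(tapply(y, f, stats::sd)),
    stringsAsFactors = FALSE)
  if (nlevels(f) == 2L) {
    if (stats::var(y) == 0) {
      stat <- 0; p <- 1           # identical scores in both groups
    } else {
      tt <- stats::t.test(y ~ f, var.equal = TRUE)
      stat <- unname(tt$statistic); p <- tt$p.value
    }
    test <- "two_sample_t"
  } else {
    av <- summary(stats::aov(y ~ f))[[1]]
    stat <- av[["F value"]][1]; p <- av[["Pr(>F)"]][1]
    test <- "one_way_anova"
  }
  structure(list(grouping = grouping, levels = tab, statistic = stat,
                 p_value = p, test = test), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Baseline ADL by", x$grouping, "(", x$test, ")\n")
  print(x$levels, row.names = FALSE)
  cat(sprintf("statistic = %.3f, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Pairwise Pearson correlations of the analysis variables
#'
#' Correlation matrix of RBDSQ, GDS-15, MoCA and UPDRS-II with
#' two-sided p-values, computed on complete pairs. `scope = "pooled"`
#' (default) uses all subject-visits; `scope = "baseline"` uses visit 0
#' only. A variable with zero variance yields flagged `NA` entries
#' (recorded in `undefined`), never a silent NaN.
#'
#' @param panel A `cohort_panel`.
#' @param scope `"pooled"` or `"baseline"`.
#' @return List of class `correlation_matrix`: `variables`, `r`, `p`,
#'   `n` (pairwise complete counts), `undefined` (character vector of
#'   degenerate variables), `scope`.
#' @export
correlations <- function(panel, scope = c("pooled", "baseline")) {
  scope <- match.arg(scope)
  df <- as.data.frame(panel)
  if (scope == "baseline") df <- df[df$visit == 0L, , drop = FALSE]
  vars <- panel_score_cols()
  m <- as.matrix(df[vars])
  if (sum(stats::complete.cases(m)) < 3L) {
    stop("need at least 3 complete rows in scope", call. = FALSE)
  }
  k <- length(vars)
  r <- diag(1, k); p <- matrix(NA_real_, k, k); n <- matrix(0L, k, k)
  dimnames(r) <- dimnames(p) <- dimnames(n) <- list(vars, vars)
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  undefined <- vars[!is.na(sds) & sds == 0]
  diag(p) <- 0; diag(n) <- colSums(!is.na(m))
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    ok <- stats::complete.cases(m[, c(i, j)])
    n[i, j] <- n[j, i] <- sum(ok)
    if (vars[i] %in% undefined || vars[j] %in% undefined || sum(ok) < 3L) {
      r[i, j] <- r[j, i] <- NA_real_
      next
    }
    ct <- stats::cor.test(m[ok, i], m[ok, j], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  structure(list(variables = vars, r = r, p = p, n = n,
                 undefined = undefined, scope = scope,
                 note = "no multiple-testing correction applied"),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  cat("Pearson correlations (", x$scope, " scope)\n", sep = "")
  print(round(x$r, digits))
  if (length(x$undefined) > 0L) {
    cat("zero-variance variable(s):", paste(x$undefined, collapse = ", "),
        "\n")
  }
  invisible(x)
}
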