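# Cohort-level and survival statistics: Mann-Whitney, Spearman, chi-squared
# (no continuity correction), median/positive dichotomization, Kaplan-Meier
# with log-rank, and univariate Cox fits. Standard fits are delegated to
# stats and survival; this module fixes the conventions (two-sided, exact
# small-sample Mann-Whitney, strict median split).

#' Two-sided Mann-Whitney comparison of two independent groups
#'
#' Exact p-value for combined n <= 20 without ties, normal approximation
#' with tie correction otherwise.
#'
#' @param x,y Numeric vectors (both nonempty).
#' @return One-row tibble `statistic` (U), `p_value`, `exact`.
#' @export
compare_groups <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty group", call. = FALSE)
  exact <- (length(x) + length(y)) <= 20 && !anyDuplicated(c(x, y))
  w <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                           correct = !exact))
  tibble::tibble(statistic = unname(w$statistic), p_value = w$p.value,
                 exact = exact)
}

#' Spearman rank correlation
#'
#' Two-tailed Spearman's rank correlation on average-ranked data, p-value by
#' the t approximation.
#'
#' @param x,y Numeric vectors, n >= 4.
#' @return One-row tibble `rho`, `p_value`, `n`; `rho` is `NA`-flagged for a
#'   constant vector.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_,
                          n = length(x)))
  }
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  tibble::tibble(rho = rho, p_value = p, n = n)
}

#' Pearson chi-squared test on an r x c contingency table
#'
#' No continuity correction; statistic `sum((O - E)^2 / E)` with expected
#' counts from the margins, `df = (r-1)(c-1)`, upper-tail p-value.
#'
#' @param table Matrix of counts, >= 2 rows and columns, no zero margin.
#' @return One-row tibble `statistic`, `df`, `p_value`.
#' @export
contingency_chi2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) >= 2, ncol(table) >= 2, all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin in contingency table", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value)
}

#' Dichotomize a biomarker
#'
#' Median rule: `"high"` iff value strictly above the median (values equal
#' to the median go `"low"`); positive rule: `"positive"` iff value strictly
#' above 0 (expression-style markers where 0 means absent).
#'
#' @param values Named numeric vector (names are patient ids) or plain
#'   vector.
#' @param rule `"median"` or `"positive"`.
#' @return Tibble `patient`, `value`, `group`.
#' @export
dichotomize <- function(values, rule = c("median", "positive")) {
  rule <- match.arg(rule)
  patient <- names(values) %||% as.character(seq_along(values))
  if (rule == "median") {
    if (length(values) < 2) stop(">= 2 patients required", call. = FALSE)
    if (length(unique(values)) == 1) {
      stop("degenerate median split: all values identical", call. = FALSE)
    }
    grp <- ifelse(values > stats::median(values), "high", "low")
  } else {
    grp <- ifelse(values > 0, "positive", "negative")
  }
  tibble::tibble(patient = patient, value = unname(values),
                 group = unname(grp))
}

#' Kaplan-Meier curves and two-sided log-rank test
#'
#' Product-limit estimates per group and the log-rank statistic over pooled
#' event times. Groups with zero events are allowed but flagged.
#'
#' @param records Tibble `patient`, `time`, `event` (1 = death,
#'   0 = censored).
#' @param groups Named group assignment (names = patient ids) or a vector
#'   aligned with `records`.
#' @return An object of class `km_logrank`: list with `curves` (tibble
#'   `group`, `time`, `n_risk`, `n_event`, `surv`), `statistic`, `df`,
#'   `p_value`, `zero_event_groups`.
#' @export
km_logrank <- function(records, groups) {
  if (!is.null(names(groups))) groups <- groups[records$patient]
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop(">= 2 groups required", call. = FALSE)
  if (sum(records$event) < 1) stop("no events", call. = FALSE)
  fit <- survival::survfit(
    survival::Surv(records$time, records$event) ~ groups)
  sm <- summary(fit, censored = TRUE)
  curves <- tibble::tibble(
    group = sub("^groups=", "", as.character(sm$strata)),
    time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
    surv = sm$surv)
  sd <- survival::survdiff(
    survival::Surv(records$time, records$event) ~ groups)
  zero_ev <- names(table(groups))[tapply(records$event, groups, sum) == 0]
  structure(list(curves = curves, statistic = unname(sd$chisq),
                 df = length(sd$n) - 1,
                 p_value = stats::pchisq(sd$chisq, length(sd$n) - 1,
                                         lower.tail = FALSE),
                 zero_event_groups = zero_ev),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("<km_logrank> chisq = %.3f on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @export
tidy.km_logrank <- function(x, ...) x$curves

#' @export
glance.km_logrank <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron tie handling on one continuous (or
#' two-group) covariate; reports the hazard ratio per unit with 95% CI.
#'
#' @param records Tibble `patient`, `time`, `event`.
#' @param covariate Numeric vector aligned with `records` (or named by
#'   patient).
#' @param min_n,min_events Minimum patients (10) and events (5).
#' @return An object of class `cox_fit`: list with `hr`, `ci_lower`,
#'   `ci_upper`, `log_hr`, `se`, `p_value`, `n`, `n_events`.
#' @export
cox_univariate <- function(records, covariate, min_n = 10, min_events = 5) {
  if (!is.null(names(covariate))) covariate <- covariate[records$patient]
  if (nrow(records) < min_n) stop("fewer than ", min_n, " patients",
                                  call. = FALSE)
  if (sum(records$event) < min_events) stop("fewer than ", min_events,
                                            " events", call. = FALSE)
  if (stats::sd(covariate) == 0) {
    stop("degenerate fit: constant covariate", call. = FALSE)
  }
  fit <- survival::coxph(
    survival::Surv(records$time, records$event) ~ covariate,
    ties = "efron")
  if (!is.finite(fit$coefficients) || !all(is.finite(sqrt(diag(fit$var))))) {
    stop("Cox fit did not converge: coef = ", fit$coefficients,
         call. = FALSE)
  }
  beta <- unname(fit$coefficients)
  se <- sqrt(diag(fit$var))[1]
  structure(list(hr = exp(beta), ci_lower = exp(beta - 1.96 * se),
                 ci_upper = exp(beta + 1.96 * se), log_hr = beta, se = se,
                 p_value = summary(fit)$coefficients[1, "Pr(>|z|)"],
                 n = nrow(records), n_events = sum(records$event)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> HR = %.3f (95%% CI %.3f-%.3f), p = %.4g (n = %d, %d events)\n",
              x$hr, x$ci_lower, x$ci_upper, x$p_value, x$n, x$n_events))
  invisible(x)
}

#' @export
tidy.cox_fit <- function(x, ...) {
  tibble::tibble(term = "covariate", estimate = x$log_hr, std_error = x$se,
                 hr = x$hr, ci_lower = x$ci_lower, ci_upper = x$ci_upper,
                 p_value = x$p_value)
}

#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, hr = x$hr,
                 p_value = x$p_value)
}
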