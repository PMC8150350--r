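#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function from right-censored time/event data
#' (times in months). Censoring tied with an event time is handled
#' events-first, the product-limit convention.
#'
#' @param times non-negative follow-up times, months
#' @param events logical (or 0/1) event indicators; `FALSE` = censored
#' @return a `km_curve` object: list with `times` (distinct event times,
#'   increasing), `survival` (step-function values), `at_risk` (risk-set
#'   size at each event time), `n_events` (total events), `n`
#' @examples
#' km_estimate(c(1, 2, 3), c(TRUE, FALSE, TRUE))
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop("empty survival input", call. = FALSE)
  if (length(times) != length(events)) {
    stop("times and events differ in length", call. = FALSE)
  }
  if (any(times < 0)) stop("negative survival times", call. = FALSE)
  events <- as.logical(events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  keep <- fit$n.event > 0
  structure(list(times = fit$time[keep],
                 survival = fit$surv[keep],
                 at_risk = fit$n.risk[keep],
                 n_events = sum(fit$n.event),
                 n = length(times)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", x$n, "subjects,", x$n_events, "events\n")
  if (length(x$times)) {
    print(data.frame(time = x$times, at_risk = x$at_risk,
                     survival = signif(x$survival, 4)), row.names = FALSE)
  }
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' Right-continuous step-function value; `S(0) = 1` and the last value is
#' carried forward beyond the last event time. Five-year rates are read at
#' `t = 60` months.
#'
#' @param curve a [km_estimate()] object
#' @param t time in months, `t >= 0`
#' @return survival probability in \[0, 1\]
#' @export
survival_at <- function(curve, t) {
  if (any(t < 0)) stop("negative time", call. = FALSE)
  vapply(t, function(tt) {
    i <- findInterval(tt, curve$times)
    if (i == 0) 1 else curve$survival[i]
  }, numeric(1))
}

#' Log-rank test across groups
#'
#' Standard k-group log-rank chi-square comparing survival distributions.
#'
#' @param times,events as in [km_estimate()]
#' @param group group labels, at least two non-empty groups
#' @return list `statistic` (chi-square), `df`, `p_value`
#' @export
logrank_test <- function(times, events, group) {
  group <- factor(group)
  if (any(table(group) == 0) || nlevels(group) < 2) {
    stop("log-rank test needs >= 2 non-empty groups", call. = FALSE)
  }
  if (!any(as.logical(events))) stop("no events observed", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(times, as.logical(events)) ~ group)
  df <- nlevels(group) - 1
  list(statistic = sd$chisq, df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Median potential follow-up by reverse Kaplan-Meier
#'
#' Inverts the event indicator (censoring becomes the "event") and returns
#' the median of the resulting curve: the median follow-up the cohort would
#' have had in the absence of deaths. Returns `NA` when the reversed curve
#' never reaches 0.5 (median not reached).
#'
#' @param times,events as in [km_estimate()]
#' @return median potential follow-up in months, or `NA_real_`
#' @export
reverse_km_followup <- function(times, events) {
  rev_curve <- km_estimate(times, !as.logical(events))
  reached <- which(rev_curve$survival <= 0.5)
  if (!length(reached)) return(NA_real_)
  rev_curve$times[min(reached)]
}

COX_COVARIATES <- c("pT", "pN", "L", "age", "gender", "margin",
                    "adj_chemo", "grade")

#' Multivariable Cox proportional-hazards model
#'
#' Fits the hazard of the chosen endpoint on a patient-level indicator
#' (PD-L1 status or phenotype) adjusted for the eight standard
#' clinico-pathological covariates: pT stage, pN stage, lymphovascular
#' invasion (L), age, gender, resection margin status, receipt of adjuvant
#' platinum-containing chemotherapy, and tumor grade. Ties are handled by
#' the Efron approximation. Rows with missing covariates are complete-case
#' excluded with a message reporting the count.
#'
#' @param annotations annotation data frame (a cohort's `annotations`
#'   element) carrying the endpoint columns and covariates
#' @param indicator data frame `patient_id`, `indicator` (logical, factor
#'   or numeric patient-level variable of interest)
#' @param endpoint `"dss"` (disease-specific survival) or `"dfs"`
#'   (disease-free survival)
#' @param covariates covariate column names to adjust for (default the
#'   eight standard ones; pass `character(0)` for an unadjusted fit)
#' @return data frame of `HazardEstimate` rows — `variable`, `hr`,
#'   `ci_low`, `ci_high`, `p_value` (Wald) — with the indicator term(s)
#'   first; the full [survival::coxph()] fit is attached as attribute
#'   `fit`
#' @export
cox_multivariable <- function(annotations, indicator,
                              endpoint = c("dss", "dfs"),
                              covariates = COX_COVARIATES) {
  endpoint <- match.arg(endpoint)
  d <- merge(annotations, indicator, by = "patient_id")
  d$.time <- d[[paste0(endpoint, "_time")]]
  d$.event <- as.logical(d[[paste0(endpoint, "_event")]])
  model_cols <- c(".time", ".event", "indicator", covariates)
  complete <- stats::complete.cases(d[model_cols])
  if (any(!complete)) {
    message("cox_multivariable: excluding ", sum(!complete),
            " row(s) with missing values")
    d <- d[complete, , drop = FALSE]
  }
  if (is.logical(d$indicator)) d$indicator <- factor(d$indicator,
                                                     c(FALSE, TRUE))
  fml <- stats::reformulate(c("indicator", covariates),
                            response = "survival::Surv(.time, .event)")
  fit <- survival::coxph(fml, data = d, ties = "efron")
  if (!fit$iter || any(is.na(stats::coef(fit)))) {
    stop("Cox model did not converge or dropped terms (possible complete ",
         "separation); coefficients: ",
         paste(signif(stats::coef(fit), 3), collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  est <- data.frame(variable = rownames(sm$coefficients),
                    hr = sm$coefficients[, "exp(coef)"],
                    ci_low = sm$conf.int[, "lower .95"],
                    ci_high = sm$conf.int[, "upper .95"],
                    p_value = sm$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  ind_first <- order(!startsWith(est$variable, "indicator"))
  est <- est[ind_first, , drop = FALSE]
  rownames(est) <- NULL
  attr(est, "fit") <- fit
  est
}

#' Five-year survival rates by group
#'
#' Kaplan-Meier estimate evaluated at 60 months for each level of a
#' grouping variable.
#'
#' @param times,events as in [km_estimate()]
#' @param group group labels
#' @return data frame `group`, `n`, `five_year_rate`
#' @export
five_year_rates <- function(times, events, group) {
  group <- factor(group)
  do.call(rbind, lapply(levels(group), function(g) {
    sel <- group == g
    data.frame(group = g, n = sum(sel),
               five_year_rate = survival_at(
                 km_estimate(times[sel], events[sel]), 60),
               stringsAsFactors = FALSE)
  }))
}
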