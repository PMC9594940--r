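# Kaplan-Meier disease-free and overall survival, with the study's
# exclusion rule (treatment-unrelated deaths removed entirely from the
# analysis set) and rate-at-time queries on the right-continuous step
# function.

#' Remove treatment-unrelated deaths from the survival analysis set
#'
#' Patients flagged `death_unrelated = 1` are removed entirely (not
#' censored), matching an analysis set reduced from 31 enrolled to 29
#' analysed patients when two deaths were unrelated to treatment.
#'
#' @param cases Case-level data frame with a `death_unrelated` column
#'   (0/1, `NA` treated as 0) and a `case_id` column.
#' @return List with `analysed` (retained rows, untouched) and
#'   `excluded_ids`.
#' @export
filter_survival_cohort <- function(cases) {
  df <- as.data.frame(cases)
  flag <- df$death_unrelated
  flag[is.na(flag)] <- 0
  drop <- flag == 1
  if (all(drop)) warning("all patients excluded from the survival analysis")
  list(analysed = df[!drop, , drop = FALSE],
       excluded_ids = df$case_id[drop])
}

#' Kaplan-Meier product-limit fit
#'
#' Thin wrapper over [survival::survfit()] for a single group.  Ties of
#' events and censorings at the same time are handled events-first, the
#' product-limit convention.
#'
#' @param time Non-negative follow-up times (months).
#' @param event Binary event indicator (1 = event, 0 = censored).
#' @return A `km_curve`: `time`, `surv` (survival just after each time),
#'   `n_risk`, `n_event`, `n_censor`, `n_start`.
#' @export
km_fit <- function(time, event) {
  if (!length(time)) stop("empty survival input")
  if (anyNA(time) || anyNA(event)) stop("times and events must not be missing")
  if (any(time < 0)) stop("times must be non-negative")
  if (!all(event %in% c(0, 1))) stop("events must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(list(time = fit$time, surv = fit$surv,
                 n_risk = fit$n.risk, n_event = fit$n.event,
                 n_censor = fit$n.censor, n_start = sum(fit$n)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d events, last time %.1f\n",
              x$n_start, sum(x$n_event), max(x$time)))
  invisible(x)
}

#' Survival rate at a time point
#'
#' Evaluates the right-continuous step function S(t): at an event time the
#' post-event value applies.  Querying beyond the last observed time returns
#' the last value with an extrapolation warning.
#'
#' @param curve A `km_curve` from [km_fit()].
#' @param t Time(s), same units as the fit.
#' @return Survival probability(ies) in `[0, 1]`.
#' @export
rate_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  if (anyNA(t) || any(t < 0)) stop("t must be non-negative")
  if (any(t > max(curve$time)))
    warning("time beyond last observation: returning the last estimate (extrapolation)")
  idx <- findInterval(t, curve$time)
  ifelse(idx == 0, 1, curve$surv[pmax(idx, 1)])
}

#' Kaplan-Meier curves and rates by group
#'
#' Fits one curve per group level and tabulates survival rates at the
#' requested time points (12 and 24 months by default, the study's 1- and
#' 2-year rates).  Empty groups are dropped with a warning.
#'
#' @param time,event Survival input as in [km_fit()].
#' @param group Grouping vector (factor/character/logical), same length.
#' @param at Time points for the rate table.
#' @return List with `curves` (named list of `km_curve`) and `rates`
#'   (data frame `group`, `time`, `rate_percent`).
#' @export
km_by_group <- function(time, event, group, at = c(12, 24)) {
  if (length(time) != length(event) || length(time) != length(group))
    stop("time, event and group must have the same length")
  if (anyNA(group)) stop("group must not be missing")
  levs <- if (is.factor(group)) levels(group) else sort(unique(as.character(group)))
  group <- as.character(group)
  empty <- setdiff(levs, unique(group))
  if (length(empty))
    warning("empty group(s) dropped: ", paste(empty, collapse = ", "))
  levs <- setdiff(levs, empty)
  curves <- lapply(levs, function(g) km_fit(time[group == g], event[group == g]))
  names(curves) <- levs
  rates <- do.call(rbind, lapply(levs, function(g) {
    r <- suppressWarnings(rate_at(curves[[g]], at))
    data.frame(group = g, time = at, rate_percent = 100 * r,
               stringsAsFactors = FALSE)
  }))
  rownames(rates) <- NULL
  list(curves = curves, rates = rates)
}

#' Median follow-up with range
#'
#' Simple median of the observed follow-up times with the min-max range
#' (the convention behind summaries like "36.9 (18.6-45.2) months"); the
#' reverse-KM estimate is available as an alternative for censoring-aware
#' follow-up.
#'
#' @param times Observed follow-up times (months).
#' @param event Event indicators, required only for `method =
#'   "reverse-km"` (follow-up is the censoring-distribution median).
#' @param method `"simple"` (default) or `"reverse-km"`.
#' @return List with `median`, `min`, `max`.
#' @export
median_followup <- function(times, event = NULL,
                            method = c("simple", "reverse-km")) {
  method <- match.arg(method)
  if (!length(times)) stop("no follow-up times")
  if (anyNA(times)) stop("times must not be missing")
  med <- if (method == "simple") {
    stats::median(times)
  } else {
    if (is.null(event)) stop("reverse-km requires event indicators")
    fit <- survival::survfit(survival::Surv(times, 1 - event) ~ 1)
    unname(summary(fit)$table["median"])
  }
  list(median = med, min = min(times), max = max(times))
}
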