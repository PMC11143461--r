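#' Keep only the first encounter per patient
#'
#' Survival analyses use the earliest ED encounter of each patient in the
#' study period; ties on the arrival timestamp are broken by the lower
#' encounter id (noted via [message()]).
#'
#' @param encounters Encounter table with `encounter_id`, `patient_id`,
#'   `arrival_date`.
#' @return Subset of `encounters`, one row per patient.
#' @export
first_encounter_filter <- function(encounters) {
  ord <- order(encounters$patient_id, encounters$arrival_date,
               encounters$encounter_id)
  enc <- encounters[ord, , drop = FALSE]
  key <- paste(enc$patient_id, enc$arrival_date)
  first_rows <- !duplicated(enc$patient_id)
  if (any(key %in% key[first_rows] & !first_rows)) {
    message("tied first-arrival timestamps; keeping lower encounter id")
  }
  out <- enc[first_rows, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Follow-up time and event indicator with administrative censoring
#'
#' Time runs from each encounter's arrival to the death date when known,
#' otherwise to the administrative censoring date (the last date with
#' reliable mortality ascertainment).
#'
#' @param encounters Encounter table (`patient_id`, `arrival_date`).
#' @param outcomes Outcome table (`patient_id`, `death_date`, `NA` when no
#'   death is known by the censoring date).
#' @param censor_date Administrative censoring `Date`.
#' @return Data frame with `time` (days, > 0) and `event` (0/1).
#' @export
encounter_survival <- function(encounters, outcomes, censor_date) {
  death <- outcomes$death_date[match(encounters$patient_id,
                                     outcomes$patient_id)]
  event <- as.integer(!is.na(death) & death <= censor_date)
  time <- ifelse(event == 1L,
                 as.numeric(death - encounters$arrival_date),
                 as.numeric(censor_date - encounters$arrival_date))
  data.frame(time = time, event = event)
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t)` is the product over event times `t_i <= t` of `(1 - d_i / n_i)`
#' with `d_i` deaths and `n_i` at risk; records censored at `t_i` stay in
#' the risk set for deaths at `t_i` (deaths processed before censorings).
#' The curve is truncated at the horizon.  Estimation is delegated to
#' [survival::survfit()].
#'
#' @param time Follow-up days, strictly positive.
#' @param event 0/1 event indicator (1 = death observed).
#' @param horizon Truncation horizon in days; 183 days stands in for
#'   6 months.  Default 183.
#' @param stratum Label carried into the result.
#' @return Object of class `km_curve`: data frame with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`; attributes `n`, `horizon`,
#'   `stratum`.
#' @export
km_estimate <- function(time, event, horizon = 183, stratum = "total") {
  if (any(time <= 0)) {
    stop("non-positive follow-up time(s); day-1 deaths are excluded upstream")
  }
  event <- as.integer(event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$time <= horizon
  out <- data.frame(time = fit$time[keep], n_risk = fit$n.risk[keep],
                    n_event = fit$n.event[keep],
                    n_censor = fit$n.censor[keep],
                    survival = fit$surv[keep])
  structure(out, class = c("km_curve", "data.frame"),
            n = length(time), horizon = horizon, stratum = stratum,
            n_events = sum(out$n_event), n_censored = sum(out$n_censor))
}

#' Six-month mortality implied by a survival curve
#'
#' `1 - S(horizon)`, the cumulative mortality at the truncation horizon.
#'
#' @param curve A [km_estimate()] result.
#' @return Scalar in [0, 1].
#' @export
km_mortality <- function(curve) {
  ev <- curve$survival[curve$n_event > 0]
  if (length(ev) == 0L) return(0)
  1 - min(ev)
}

#' Kaplan-Meier curves for risk strata and the serious-illness screen
#'
#' One curve for the total population, one per model-risk stratum
#' (score strictly greater than each cutoff) and one for encounters
#' meeting the serious-illness screen.  Strata without records are
#' skipped with a note.
#'
#' @param time,event See [km_estimate()] (first encounters).
#' @param scores Model risk scores aligned with `time`.
#' @param si_flags Logical serious-illness screen (or `NULL` to omit).
#' @param cutoffs Risk cutoffs, default `c(0.05, 0.1, 0.2, 0.3)`.
#' @param horizon Truncation horizon in days.
#' @return Named list of `km_curve` objects.
#' @export
stratified_km <- function(time, event, scores, si_flags = NULL,
                          cutoffs = c(0.05, 0.1, 0.2, 0.3), horizon = 183) {
  out <- list(total = km_estimate(time, event, horizon, "total"))
  for (ct in cutoffs) {
    lab <- sprintf("risk>%g%%", 100 * ct)
    idx <- scores > ct
    if (!any(idx)) {
      message("stratum ", lab, " is empty; skipped")
      next
    }
    out[[lab]] <- km_estimate(time[idx], event[idx], horizon, lab)
  }
  if (!is.null(si_flags)) {
    idx <- as.logical(si_flags)
    if (any(idx)) {
      out[["serious_illness"]] <-
        km_estimate(time[idx], event[idx], horizon, "serious_illness")
    } else {
      message("serious-illness stratum is empty; skipped")
    }
  }
  out
}

#' @export
plot.km_curve <- function(x, ...) {
  plot(stats::stepfun(x$time, c(1, x$survival)), do.points = FALSE,
       xlim = c(0, attr(x, "horizon")), ylim = c(0, 1),
       xlab = "Days since ED arrival", ylab = "Survival",
       main = attr(x, "stratum"), ...)
  invisible(x)
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf(
    "Kaplan-Meier curve [%s]: n=%d, %d events / %d censored by day %d; 1-S = %.3f\n",
    attr(x, "stratum"), attr(x, "n"), attr(x, "n_events"),
    attr(x, "n_censored"), attr(x, "horizon"), km_mortality(x)))
  invisible(x)
}
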