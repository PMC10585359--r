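# Temporal discrepancy statistics.
#
# Three empirical views of the same process, all resampled to a
# standardized month of 30.4375 days:
#   * the cumulative discrepancy rate on the trial clock (t = 0 at first
#     patient in): discrepant patients so far / included patients so far;
#   * the distribution of discrepancies over the patient follow-up clock
#     (percent of all discrepancies falling in each follow-up interval);
#   * the discrete per-interval discrepancy probability (hazard):
#     discrepancies in the interval / patients evaluated and still
#     discrepancy-free in the interval.
# A model-based expected cumulative rate composes accrual, survival and the
# per-interval probability, in a literal ("naive") and a self-consistent
# ("hazard") mode.

.month_index <- function(days) ceiling(days / dr_month_days)

#' Assemble a trial time series for temporal analyses
#'
#' Combines per-patient inclusion times (days since first patient in),
#' follow-up durations (days since the patient's baseline) and per-KoD
#' determination days into the monthly-grid object consumed by the curve
#' estimators.
#'
#' @param inclusion_day Numeric vector, days since first patient in.
#' @param followup_day Numeric vector, last evaluable visit day per patient.
#' @param events Data frame (or named list) of per-patient determination
#'   days, one column per KoD, `NA` when the patient is not discrepant.
#' @param patient_id Optional identifiers.
#' @return Object of class `dr_series`.
#' @export
trial_series <- function(inclusion_day, followup_day, events,
                         patient_id = NULL) {
  n <- length(inclusion_day)
  events <- as.data.frame(events)
  stopifnot(length(followup_day) == n, nrow(events) == n)
  if (any(followup_day < 0, na.rm = TRUE)) stop("negative follow-up duration")
  if (is.null(patient_id)) patient_id <- as.character(seq_len(n))
  ev_ok <- vapply(events, function(d) all(is.na(d) | (d >= 0 & d <= followup_day + 1e-9)), TRUE)
  if (!all(ev_ok))
    stop("events fall outside the patient's on-study interval: ",
         paste(names(events)[!ev_ok], collapse = ", "))
  structure(list(
    patient_id = patient_id,
    inclusion_day = inclusion_day,
    followup_day = followup_day,
    inclusion_month = floor(inclusion_day / dr_month_days),
    fu_end_interval = pmax(1L, .month_index(followup_day)),
    event_fu_interval = lapply(events, .month_index),
    event_trial_month = lapply(events, function(d) .month_index(inclusion_day + d)),
    kods = names(events)
  ), class = "dr_series")
}

#' Build a `dr_series` from a per-patient KoD table
#'
#' @param kods Output of [kod_table()].
#' @param inclusion_day Days since first patient in, aligned with `kods`
#'   rows (or a named vector indexed by `patient_id`).
#' @return A [trial_series()] object with the four KoD event channels.
#' @export
series_from_kods <- function(kods, inclusion_day) {
  if (!is.null(names(inclusion_day)))
    inclusion_day <- inclusion_day[kods$patient_id]
  trial_series(
    inclusion_day = as.numeric(inclusion_day),
    followup_day = kods$followup_day,
    events = data.frame(PDD = kods$pdd_day, DOPD = kods$dopd_day,
                        BOR = kods$bor_day, DOFR = kods$dofr_day),
    patient_id = kods$patient_id
  )
}

.ci_cols <- function(x, n, level = 0.95) {
  lo <- hi <- numeric(length(x))
  for (i in seq_along(x)) {
    ci <- clopper_pearson(x[i], n[i], level)
    lo[i] <- ci$low; hi[i] <- ci$high
  }
  list(low = lo, high = hi)
}

#' Cumulative discrepancy rate on the trial clock
#'
#' For each trial month t: (number of patients whose discrepancy was
#' determinable by t) / (number of patients included by t), with exact
#' Clopper-Pearson intervals.  Months with zero denominator are omitted.
#'
#' @param series A [trial_series()] object.
#' @param kod_name Event channel to analyse.
#' @param level Confidence level, default 0.95.
#' @return Data frame of class `dr_rate_curve`: `month`, `n_discrepant`,
#'   `n_included`, `rate`, `low`, `high`.
#' @export
rate_over_time <- function(series, kod_name, level = 0.95) {
  kod_name <- match.arg(kod_name, series$kods)
  ev <- series$event_trial_month[[kod_name]]
  months <- 0:max(c(series$inclusion_month, series$fu_end_interval +
                    series$inclusion_month, ev), na.rm = TRUE)
  num <- vapply(months, function(t) sum(!is.na(ev) & ev <= t), 0L)
  den <- vapply(months, function(t) sum(series$inclusion_month <= t), 0L)
  keep <- den > 0
  if (!all(keep)) message(sum(!keep), " month(s) with zero denominator omitted")
  months <- months[keep]; num <- num[keep]; den <- den[keep]
  ci <- .ci_cols(num, den, level)
  out <- data.frame(month = months, n_discrepant = num, n_included = den,
                    rate = num / den, low = ci$low, high = ci$high)
  class(out) <- c("dr_rate_curve", "data.frame")
  out
}

#' Distribution of discrepancies over follow-up intervals
#'
#' Percent of all discrepancies (for one KoD) whose determination falls in
#' each follow-up interval; sums to 100 over intervals.
#'
#' @inheritParams rate_over_time
#' @param max_interval Optional last interval (defaults to the latest
#'   event interval).
#' @return Data frame: `interval`, `n`, `percent`; empty when there are no
#'   discrepancies.
#' @export
prop_disc_by_followup <- function(series, kod_name, max_interval = NULL) {
  kod_name <- match.arg(kod_name, series$kods)
  ev <- series$event_fu_interval[[kod_name]]
  ev <- ev[!is.na(ev)]
  if (!length(ev))
    return(data.frame(interval = integer(), n = integer(), percent = numeric()))
  if (is.null(max_interval)) max_interval <- max(ev)
  iv <- seq_len(max_interval)
  n <- vapply(iv, function(k) sum(ev == k), 0L)
  data.frame(interval = iv, n = n, percent = 100 * n / length(ev))
}

#' Per-interval discrepancy probability (discrete hazard) over follow-up
#'
#' For each follow-up interval: discrepancies determined in the interval
#' divided by patients evaluated during the interval and not yet discrepant
#' for this KoD, with Clopper-Pearson intervals.  Intervals with an empty
#' risk set are omitted.
#'
#' @inheritParams rate_over_time
#' @return Data frame of class `dr_hazard_curve`: `interval`, `n_event`,
#'   `n_at_risk`, `p_disc`, `low`, `high`.
#' @export
p_disc_by_followup <- function(series, kod_name, level = 0.95) {
  kod_name <- match.arg(kod_name, series$kods)
  ev <- series$event_fu_interval[[kod_name]]
  last <- series$fu_end_interval
  iv <- seq_len(max(last, na.rm = TRUE))
  n_event <- vapply(iv, function(k) sum(!is.na(ev) & ev == k), 0L)
  n_risk <- vapply(iv, function(k)
    sum(last >= k & (is.na(ev) | ev >= k)), 0L)
  keep <- n_risk > 0
  iv <- iv[keep]; n_event <- n_event[keep]; n_risk <- n_risk[keep]
  ci <- .ci_cols(n_event, n_risk, level)
  out <- data.frame(interval = iv, n_event = n_event, n_at_risk = n_risk,
                    p_disc = n_event / n_risk, low = ci$low, high = ci$high)
  class(out) <- c("dr_hazard_curve", "data.frame")
  out
}

#' Model-based expected cumulative discrepancy rate
#'
#' Composes a monthly accrual series `PatIncl`, a follow-up survival series
#' `Surv` (probability a patient is still evaluated in follow-up interval
#' k) and a per-interval discrepancy probability `PDisc` into the expected
#' cumulative rate on the trial clock.
#'
#' `mode = "naive"` evaluates the printed composition literally: each
#' cohort contributes `sum_k PDisc(k) * Surv(k)` over the intervals it has
#' been on study.  `mode = "hazard"` treats `PDisc` as the discrete hazard
#' of a first discrepancy and accumulates
#' `sum_k Surv(k) * PDisc(k) * prod_{j<k} (1 - PDisc(j))`,
#' the self-consistent form that matches empirical cumulative rates when
#' dropout is independent of the discrepancy process.  The two coincide
#' while `PDisc` is small; the naive form can exceed 1.
#'
#' @param accrual Numeric vector: patients first included in months
#'   `0, 1, ...` (index 1 = month 0).
#' @param surv Numeric vector over follow-up intervals `1..K`,
#'   non-increasing, starting at or below 1.
#' @param pdisc Numeric vector over the same intervals, values in `[0, 1]`.
#' @param mode `"hazard"` (default) or `"naive"`.
#' @return Data frame: `month`, `expected_rate`.
#' @export
expected_rate <- function(accrual, surv, pdisc, mode = c("hazard", "naive")) {
  mode <- match.arg(mode)
  K <- length(pdisc)
  surv <- rep_len(surv, K)
  if (any(diff(surv) > 1e-9)) stop("expected_rate: Surv must be non-increasing")
  if (any(pdisc < 0 | pdisc > 1)) stop("expected_rate: PDisc must lie in [0,1]")
  # cumulative per-cohort discrepancy probability after h intervals on study
  per_h <- if (mode == "naive") {
    cumsum(pdisc * surv)
  } else {
    cumsum(surv * pdisc * c(1, cumprod(1 - pdisc))[seq_len(K)])
  }
  months <- seq(0, length(accrual) - 1 + K)
  rate <- vapply(months, function(t) {
    m_idx <- 0:min(t, length(accrual) - 1)
    w <- accrual[m_idx + 1]
    if (sum(w) == 0) return(NA_real_)
    h <- pmin(t - m_idx, K)
    p <- ifelse(h <= 0, 0, per_h[pmax(h, 1)])
    sum(w * p) / sum(w)
  }, 1)
  out <- data.frame(month = months, expected_rate = rate)
  out[!is.na(out$expected_rate), ]
}

#' Empirical quantile of per-patient follow-up duration
#'
#' @param series A [trial_series()] object.
#' @param q Quantile in `[0, 1]` (default 0.95).
#' @return Follow-up duration in months (empirical inverse-CDF quantile,
#'   `type = 1`).
#' @export
followup_percentile <- function(series, q = 0.95) {
  quantile(series$followup_day / dr_month_days, q, type = 1, names = FALSE)
}

#' End-of-trial discrepancy rates with exact intervals
#'
#' Per cohort and per KoD: count, denominator, percentage (one decimal) and
#' the Clopper-Pearson 95% interval; cohorts are pooled by summing counts
#' over summed denominators.
#'
#' @param cohorts A single [kod_table()] data frame, or a named list of
#'   them (one per trial).
#' @param level Confidence level, default 0.95.
#' @return Data frame: `trial`, `kod`, `n_discrepant`, `n`, `percent`,
#'   `low`, `high` (bounds as fractions); includes a `"Pooled"` row set.
#' @export
end_of_trial_rates <- function(cohorts, level = 0.95) {
  if (is.data.frame(cohorts)) cohorts <- list(Trial = cohorts)
  if (is.null(names(cohorts)))
    names(cohorts) <- paste0("Trial", seq_along(cohorts))
  flag_col <- c(PDD = "pdd", DOPD = "dopd", BOR = "bor", DOFR = "dofr")
  one <- function(tab, trial) {
    do.call(rbind, lapply(names(flag_col), function(k) {
      x <- sum(tab[[flag_col[[k]]]]); n <- nrow(tab)
      ci <- clopper_pearson(x, n, level)
      data.frame(trial = trial, kod = k, n_discrepant = x, n = n,
                 percent = round(100 * x / n, 1), low = ci$low,
                 high = ci$high, stringsAsFactors = FALSE)
    }))
  }
  per <- do.call(rbind, Map(one, cohorts, names(cohorts)))
  pooled <- do.call(rbind, lapply(names(flag_col), function(k) {
    x <- sum(per$n_discrepant[per$kod == k])
    n <- sum(vapply(cohorts, nrow, 0L))
    ci <- clopper_pearson(x, n, level)
    data.frame(trial = "Pooled", kod = k, n_discrepant = x, n = n,
               percent = round(100 * x / n, 1), low = ci$low, high = ci$high,
               stringsAsFactors = FALSE)
  }))
  out <- rbind(per, pooled)
  rownames(out) <- NULL
  out
}

#' End-of-trial rates from printed per-trial counts
#'
#' Convenience for recomputing pooled rates from already-tabulated counts
#' (count of discrepant patients and cohort size per trial and KoD) rather
#' than patient-level tables.
#'
#' @param counts Data frame with columns `trial`, `kod`, `n_discrepant`, `n`.
#' @param level Confidence level.
#' @return Same layout as [end_of_trial_rates()].
#' @export
rates_from_counts <- function(counts, level = 0.95) {
  stopifnot(all(c("trial", "kod", "n_discrepant", "n") %in% names(counts)))
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    ci <- clopper_pearson(counts$n_discrepant[i], counts$n[i], level)
    data.frame(trial = counts$trial[i], kod = counts$kod[i],
               n_discrepant = counts$n_discrepant[i], n = counts$n[i],
               percent = round(100 * counts$n_discrepant[i] / counts$n[i], 1),
               low = ci$low, high = ci$high, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  pooled <- do.call(rbind, lapply(unique(counts$kod), function(k) {
    x <- sum(counts$n_discrepant[counts$kod == k])
    n <- sum(counts$n[counts$kod == k])
    ci <- clopper_pearson(x, n, level)
    data.frame(trial = "Pooled", kod = k, n_discrepant = x, n = n,
               percent = round(100 * x / n, 1), low = ci$low, high = ci$high,
               stringsAsFactors = FALSE)
  }))
  out <- rbind(per, pooled)
  rownames(out) <- NULL
  out
}
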