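# Postpartum time-to-dominance: record extraction, Kaplan-Meier estimation,
# landmarking, and Cox regression with time-dependent covariates.

#' Extract a dominance time-to-event record for one pregnancy
#'
#' A case is at risk when it is not dominated by the focal taxon (summed
#' member-ASV frequency > `threshold`) at its first postpartum sample and at
#' least one follow-up sample exists. The event is the first postpartum day
#' on which the taxon frequency exceeds the threshold; barring an event, the
#' case is censored at the last sampled day.
#'
#' @param counts Count matrix for the pregnancy's samples.
#' @param days day_vs_delivery per row (postpartum samples have day > 0).
#' @param taxonomy,taxon As in [taxon_frequency()].
#' @param threshold Dominance threshold (strict; default 0.7).
#' @param pregnancy_id Identifier copied into the record.
#' @return data.frame row: pregnancy_id, taxon, at_risk, reason,
#'   time_days, event. For not-at-risk cases time_days and event are NA and
#'   `reason` is "no_follow_up" or "dominated_at_entry".
#' @export
extract_dominance_record <- function(counts, days, taxonomy, taxon,
                                     threshold = 0.7, pregnancy_id = "preg") {
  stopifnot(nrow(counts) == length(days))
  post <- which(days > 0)
  rec <- function(at_risk, reason, time, event) {
    data.frame(pregnancy_id = pregnancy_id, taxon = taxon, at_risk = at_risk,
               reason = reason, time_days = time, event = event,
               stringsAsFactors = FALSE)
  }
  if (length(post) < 2) return(rec(FALSE, "no_follow_up", NA_real_, NA))
  post <- post[order(days[post])]
  freq <- relative_frequencies(counts[post, , drop = FALSE])
  f <- taxon_frequency(freq, taxonomy, taxon)
  pdays <- days[post]
  if (f[1] > threshold) return(rec(FALSE, "dominated_at_entry", NA_real_, NA))
  hit <- which(f > threshold)
  if (length(hit) > 0) {
    rec(TRUE, "at_risk", pdays[hit[1]], TRUE)
  } else {
    rec(TRUE, "at_risk", pdays[length(pdays)], FALSE)
  }
}

#' Dominance records for a whole cohort
#'
#' @param counts Full count matrix.
#' @param meta Sample metadata (`sample_id`, `pregnancy_id`,
#'   `day_vs_delivery`).
#' @inheritParams extract_dominance_record
#' @return data.frame of per-pregnancy records (all pregnancies, including
#'   not-at-risk ones, flagged by `at_risk`).
#' @export
cohort_dominance_records <- function(counts, meta, taxonomy, taxon,
                                     threshold = 0.7) {
  meta <- meta[match(rownames(counts), meta$sample_id), ]
  out <- lapply(split(seq_len(nrow(counts)), meta$pregnancy_id), function(idx) {
    extract_dominance_record(counts[idx, , drop = FALSE],
                             meta$day_vs_delivery[idx], taxonomy, taxon,
                             threshold, meta$pregnancy_id[idx[1]])
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Kaplan-Meier fit of time-to-dominance
#'
#' Product-limit estimator with Greenwood variance and a 95% CI computed on
#' the log-survival scale (clamped to \[0, 1\]); alternatives "plain" and
#' "log-log" are available.
#'
#' @param records data.frame with `time_days` and `event` (at-risk rows
#'   only are used; rows with `at_risk == FALSE` are dropped).
#' @param conf_type CI transformation passed to [survival::survfit()].
#' @return List of class `vag_km`: `time`, `survival`, `greenwood_se`,
#'   `ci_lower`, `ci_upper`, `n_risk`, `n_event`, `n_at_risk_cases`, plus the
#'   underlying `survfit` object as `fit`.
#' @export
km_fit <- function(records, conf_type = c("log", "plain", "log-log")) {
  conf_type <- match.arg(conf_type)
  if (!is.null(records$at_risk)) records <- records[records$at_risk %in% TRUE, ]
  if (nrow(records) < 1) stop("no at-risk records")
  fit <- survival::survfit(
    survival::Surv(records$time_days, records$event) ~ 1,
    conf.type = conf_type, conf.int = 0.95)
  s <- summary(fit, censored = TRUE)
  # survfit leaves the CI undefined once S hits 0; collapse it onto S there
  lower <- ifelse(is.na(s$lower), s$surv, s$lower)
  upper <- ifelse(is.na(s$upper), s$surv, s$upper)
  structure(list(time = s$time, survival = s$surv,
                 greenwood_se = s$std.err,
                 ci_lower = pmax(0, pmin(1, lower)),
                 ci_upper = pmax(0, pmin(1, upper)),
                 n_risk = s$n.risk, n_event = s$n.event,
                 n_at_risk_cases = nrow(records), fit = fit),
            class = "vag_km")
}

#' Cumulative incidence (1 - S) at a fixed horizon
#'
#' @param km A [km_fit()] result.
#' @param t Horizon in postpartum days (default 365).
#' @return List with `probability`, `ci_lower`, `ci_upper` (CI endpoints are
#'   the transformed survival CI, so ci_lower <= probability <= ci_upper).
#' @export
cumulative_incidence_at <- function(km, t = 365) {
  if (all(km$time > t)) return(list(probability = 0, ci_lower = 0, ci_upper = 0))
  s <- summary(km$fit, times = t, extend = TRUE)
  list(probability = 1 - s$surv,
       ci_lower = 1 - min(1, max(0, s$upper)),
       ci_upper = 1 - min(1, max(0, s$lower)))
}

#' Landmarked grouping of dominance records
#'
#' Cases with an event or censoring at or before the landmark are excluded;
#' the time origin is reset to the landmark; exposure is defined by covariate
#' onset at or before the landmark (cases with no onset are unexposed).
#'
#' @param records At-risk records (`pregnancy_id`, `time_days`, `event`).
#' @param onset_day Named numeric vector (names = pregnancy ids) of covariate
#'   onset days; NA or absent = never exposed.
#' @param landmark_day Landmark (default 90 days postpartum).
#' @return records with added `exposed` column and `time_days` shifted so the
#'   landmark is time 0.
#' @export
landmark_split <- function(records, onset_day, landmark_day = 90) {
  if (!is.null(records$at_risk)) records <- records[records$at_risk %in% TRUE, ]
  keep <- records$time_days > landmark_day
  if (!any(keep)) stop("no cases survive landmark")
  records <- records[keep, , drop = FALSE]
  onset <- onset_day[match(records$pregnancy_id, names(onset_day))]
  records$exposed <- !is.na(onset) & onset <= landmark_day
  records$time_days <- records$time_days - landmark_day
  records
}

#' Counting-process intervals for one time-dependent binary covariate
#'
#' @param records At-risk records (`pregnancy_id`, `time_days`, `event`).
#' @param onset_day Named numeric vector of onset days per pregnancy; the
#'   covariate steps from 0 to 1 at onset. Onsets at or after the record end
#'   (or absent) yield a single covariate-0 interval.
#' @return data.frame: pregnancy_id, start_day, stop_day, event_at_stop,
#'   covariate.
#' @export
counting_process_intervals <- function(records, onset_day) {
  if (!is.null(records$at_risk)) records <- records[records$at_risk %in% TRUE, ]
  rows <- lapply(seq_len(nrow(records)), function(i) {
    id <- records$pregnancy_id[i]
    stop_day <- records$time_days[i]
    ev <- isTRUE(records$event[i])
    onset <- onset_day[match(id, names(onset_day))]
    if (length(onset) == 0 || is.na(onset) || onset <= 0 || onset >= stop_day) {
      data.frame(pregnancy_id = id, start_day = 0, stop_day = stop_day,
                 event_at_stop = ev, covariate = 0L, stringsAsFactors = FALSE)
    } else {
      data.frame(pregnancy_id = rep(id, 2), start_day = c(0, onset),
                 stop_day = c(onset, stop_day),
                 event_at_stop = c(FALSE, ev), covariate = c(0L, 1L),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Univariate Cox regression on counting-process intervals
#'
#' Maximizes the counting-process partial likelihood (Efron tie correction)
#' and reports the hazard ratio with Wald 95% CI and p value. Monotone
#' likelihoods (complete separation) are flagged and give an unbounded CI.
#'
#' @param intervals Output of [counting_process_intervals()] (or a record
#'   set arranged as single intervals with columns start_day, stop_day,
#'   event_at_stop, covariate).
#' @return List of class `vag_cox`: `log_hr`, `hr`, `hr_ci_95`, `wald_p`,
#'   `n_intervals`, `n_events`, `separation`.
#' @export
cox_fit <- function(intervals) {
  if (sum(intervals$event_at_stop) < 1) stop("no events")
  if (length(unique(intervals$covariate)) < 2)
    stop("covariate constant across intervals")
  fit <- survival::coxph(
    survival::Surv(start_day, stop_day, event_at_stop) ~ covariate,
    data = intervals, ties = "efron")
  b <- unname(stats::coef(fit)[1])
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  separation <- !is.finite(se) || se > 50 || abs(b) > 15
  structure(list(log_hr = b, hr = exp(b),
                 hr_ci_95 = c(exp(b - 1.96 * se), exp(b + 1.96 * se)),
                 wald_p = 2 * stats::pnorm(-abs(b / se)),
                 n_intervals = nrow(intervals),
                 n_events = sum(intervals$event_at_stop),
                 separation = separation),
            class = "vag_cox")
}
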