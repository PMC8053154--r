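#' Success rate of an alert strategy
#'
#' An exacerbation counts as successfully identified when one or more
#' alerts fall in the `window` days before its onset (days
#' `onset - window` to `onset - 1`; day 0 itself does not count). The rate
#' is identified events over total events, computed after merging.
#'
#' @param alerts Alert tibble (`patient_id`, `day`, `alert`).
#' @param events Merged event tibble.
#' @param window Pre-onset window length in days (default 8).
#' @return A one-row tibble: `n_events`, `n_identified`, `rate`
#'   (`NA` when there are no events -- the rate is undefined, not zero).
#' @export
success_rate <- function(alerts, events, window = 8L) {
  window <- check_count(window, "window", min = 1L)
  id <- event_identified(alerts, events, window)
  n <- nrow(events)
  tibble(n_events = n, n_identified = sum(id),
         rate = if (n > 0) sum(id) / n else NA_real_)
}

event_identified <- function(alerts, events, window) {
  hits <- alerts[alerts$alert %in% TRUE, c("patient_id", "day")]
  vapply(seq_len(nrow(events)), function(i) {
    any(hits$patient_id == events$patient_id[i] &
          hits$day >= events$onset[i] - window &
          hits$day <= events$onset[i] - 1L)
  }, logical(1))
}

#' False alarm rate of an alert strategy
#'
#' Alerts raised on days not associated with any exacerbation (outside
#' every episode span extended by the pre/post margins) divided by the
#' number of such monitored days.
#'
#' @param alerts Alert tibble.
#' @param labels Day labels from [classify_days()].
#' @return A one-row tibble: `n_false`, `n_days`, `rate` (`NA` when there
#'   are no eligible days).
#' @export
false_alarm_rate <- function(alerts, labels) {
  joined <- left_join(labels, alerts[, c("patient_id", "day", "alert")],
                      by = c("patient_id", "day"))
  eligible <- joined$label == "non_associated"
  n_days <- sum(eligible)
  n_false <- sum(eligible & joined$alert %in% TRUE)
  tibble(n_false = n_false, n_days = n_days,
         rate = if (n_days > 0) n_false / n_days else NA_real_)
}

#' Lead times of identified exacerbations
#'
#' For each identified event, the number of days between the earliest
#' alert in the pre-onset window and onset (day 0); with multiple alerts
#' the earliest warning is taken. Unidentified events contribute nothing,
#' so every lead time lies in `[1, window]`.
#'
#' @inheritParams success_rate
#' @return Integer vector of lead times, one per identified event.
#' @export
lead_times <- function(alerts, events, window = 8L) {
  window <- check_count(window, "window", min = 1L)
  hits <- alerts[alerts$alert %in% TRUE, c("patient_id", "day")]
  out <- purrr::map_int(seq_len(nrow(events)), function(i) {
    d <- hits$day[hits$patient_id == events$patient_id[i] &
                    hits$day >= events$onset[i] - window &
                    hits$day <= events$onset[i] - 1L]
    if (!length(d)) return(NA_integer_)
    as.integer(events$onset[i] - min(d))
  })
  out[!is.na(out)]
}

#' Evaluate an alert strategy against exacerbation events
#'
#' Combines [success_rate()], [false_alarm_rate()] and [lead_times()] into
#' one report. The evaluator is a pure function of its inputs: alerts
#' raised on day 0 or during an episode neither identify the event nor
#' count as false alarms (they fall in the associated span).
#'
#' @param alerts Alert tibble from one strategy.
#' @param events Merged event tibble.
#' @param labels Day labels from [classify_days()] (use the monitored
#'   signal matching the strategy).
#' @param window Pre-onset success window (default 8 days).
#' @return An object of class `alert_evaluation` with fields `source`,
#'   `n_events`, `n_identified`, `success_rate`, `n_false`,
#'   `n_nonassociated_days`, `false_alarm_rate`, `lead_times`,
#'   `lead_time_mean`, `lead_time_sd`.
#' @export
evaluate_alerts <- function(alerts, events, labels, window = 8L) {
  sr <- success_rate(alerts, events, window)
  fa <- false_alarm_rate(alerts, labels)
  lt <- lead_times(alerts, events, window)
  stopifnot(all(lt >= 1), all(lt <= window))
  structure(list(
    source = if (nrow(alerts)) alerts$source[1] else NA_character_,
    n_events = sr$n_events, n_identified = sr$n_identified,
    success_rate = sr$rate,
    n_false = fa$n_false, n_nonassociated_days = fa$n_days,
    false_alarm_rate = fa$rate,
    lead_times = lt,
    lead_time_mean = if (length(lt)) mean(lt) else NA_real_,
    lead_time_sd = if (length(lt) > 1) sd(lt) else NA_real_),
    class = "alert_evaluation")
}

#' @export
print.alert_evaluation <- function(x, ...) {
  cat(sprintf("<alert_evaluation: %s>\n", x$source))
  cat(sprintf("  success rate     %s (%d/%d events identified)\n",
              fmt_rate(x$success_rate), x$n_identified, x$n_events))
  cat(sprintf("  false alarm rate %s (%d alerts / %d non-associated days)\n",
              fmt_rate(x$false_alarm_rate), x$n_false,
              x$n_nonassociated_days))
  cat(sprintf("  lead time        %s days (SD %s, n=%d)\n",
              fmt_rate(x$lead_time_mean), fmt_rate(x$lead_time_sd),
              length(x$lead_times)))
  invisible(x)
}

fmt_rate <- function(x) if (is.na(x)) "undefined" else sprintf("%.3f", x)

#' @describeIn evaluate_alerts one row per identified event's lead time.
#' @param x An `alert_evaluation`.
#' @param ... Unused.
#' @method tidy alert_evaluation
#' @export
tidy.alert_evaluation <- function(x, ...) {
  tibble(source = x$source,
         lead_time = if (length(x$lead_times)) x$lead_times else integer())
}

#' @describeIn evaluate_alerts one-row summary of all metrics.
#' @method glance alert_evaluation
#' @export
glance.alert_evaluation <- function(x, ...) {
  tibble(source = x$source, n_events = x$n_events,
         n_identified = x$n_identified, success_rate = x$success_rate,
         n_false = x$n_false,
         n_nonassociated_days = x$n_nonassociated_days,
         false_alarm_rate = x$false_alarm_rate,
         lead_time_mean = x$lead_time_mean, lead_time_sd = x$lead_time_sd,
         n_lead_times = length(x$lead_times))
}
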