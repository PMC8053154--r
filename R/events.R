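#' Detect treated exacerbation episodes
#'
#' An acute exacerbation (AE-COPD) is identified retrospectively from
#' treatment: a moderate episode requires oral corticosteroids and/or
#' antibiotics on two or more consecutive days without hospital
#' attendance; hospital attendance on any day of an episode makes it
#' severe. Onset (day 0) is the first self-reported treatment day or the
#' prescription date, whichever is earlier. Single-day treatment reports
#' are discarded, not grown: the case definition requires a run of at
#' least two days.
#'
#' @param records Daily-record tibble with `patient_id`, `day`, `steroid`,
#'   `antibiotic` and (optionally) `hospital` 0/1 columns; `NA` flags are
#'   treated as "no".
#' @param prescriptions Optional tibble of prescribing events with
#'   `patient_id` and `day`. A prescription inside (or overlapping) a
#'   self-reported run moves its onset earlier when the prescription
#'   predates it; a prescription with no self-report seeds an episode of
#'   `rx_course` days. Hospital admissions outside any treated run
#'   likewise seed a severe episode.
#' @param min_run Minimum run length of treatment days (default 2).
#' @param rx_course Assumed course length, in days, for episodes seeded by
#'   a prescription or admission alone (default 7).
#' @return An event tibble: `patient_id`, `onset`, `end`, `severity`
#'   (`"moderate"`/`"severe"`), `source` (`"self_report"`,
#'   `"prescription"`, `"hospital"`), sorted by patient and onset.
#' @export
detect_exacerbations <- function(records, prescriptions = NULL,
                                 min_run = 2L, rx_course = 7L) {
  check_records(records, c("patient_id", "day", "steroid", "antibiotic"))
  min_run <- check_count(min_run, "min_run", min = 1L)
  rx_course <- check_count(rx_course, "rx_course", min = 1L)
  if (!"hospital" %in% names(records)) records$hospital <- 0L
  per_patient <- function(df) {
    df <- df[order(df$day), , drop = FALSE]
    pid <- df$patient_id[1]
    treat_days <- df$day[which(df$steroid %in% 1 | df$antibiotic %in% 1)]
    hosp_days <- df$day[which(df$hospital %in% 1)]
    runs <- day_runs(treat_days)
    runs <- runs[runs$end - runs$onset + 1L >= min_run, , drop = FALSE]
    ev <- if (nrow(runs)) {
      tibble(patient_id = pid, onset = runs$onset, end = runs$end,
             source = "self_report")
    } else {
      tibble(patient_id = character(), onset = integer(), end = integer(),
             source = character())
    }
    rx <- if (is.null(prescriptions)) integer() else
      sort(prescriptions$day[prescriptions$patient_id == pid])
    for (d in rx) {
      span_end <- d + rx_course - 1L
      hit <- which(ev$onset <= span_end & ev$end >= d)
      if (length(hit)) {
        i <- hit[1]
        if (d < ev$onset[i]) {
          ev$onset[i] <- d
          ev$source[i] <- "prescription"
        }
      } else {
        ev <- bind_rows(ev, tibble(patient_id = pid, onset = as.integer(d),
                                   end = as.integer(span_end),
                                   source = "prescription"))
      }
    }
    for (d in hosp_days) {
      if (!any(ev$onset <= d & ev$end >= d))
        ev <- bind_rows(ev, tibble(patient_id = pid, onset = as.integer(d),
                                   end = as.integer(d + rx_course - 1L),
                                   source = "hospital"))
    }
    if (!nrow(ev)) return(empty_events())
    ev$severity <- vapply(seq_len(nrow(ev)), function(i) {
      if (any(hosp_days >= ev$onset[i] & hosp_days <= ev$end[i]))
        "severe" else "moderate"
    }, character(1))
    ev[order(ev$onset), c("patient_id", "onset", "end", "severity", "source")]
  }
  out <- records |>
    split(records$patient_id) |>
    purrr::map(per_patient) |>
    bind_rows()
  if (!nrow(out)) return(empty_events())
  arrange(out, .data$patient_id, .data$onset)
}

empty_events <- function() {
  tibble(patient_id = character(), onset = integer(), end = integer(),
         severity = character(), source = character())
}

# maximal runs of consecutive integers
day_runs <- function(days) {
  if (!length(days)) return(data.frame(onset = integer(), end = integer()))
  days <- sort(unique(as.integer(days)))
  brk <- c(0L, which(diff(days) > 1L), length(days))
  data.frame(onset = days[head(brk, -1L) + 1L], end = days[brk[-1L]])
}

#' Merge near-adjacent exacerbation episodes
#'
#' Episodes separated by fewer than `gap` clear days (next onset minus
#' previous end, strictly less than `gap`) are treated as a single event:
#' too little time has elapsed for recovery. The merged event spans from
#' the first onset to the last end; severity is the maximum of the parts.
#' The operation is idempotent.
#'
#' @param events Event tibble as returned by [detect_exacerbations()].
#' @param gap Merge threshold in days (default 8; the boundary is strict,
#'   a gap of exactly `gap` days keeps episodes separate).
#' @return Merged event tibble.
#' @export
merge_events <- function(events, gap = 8L) {
  gap <- check_count(gap, "gap", min = 1L)
  if (!nrow(events)) return(events)
  per_patient <- function(ev) {
    ev <- ev[order(ev$onset), , drop = FALSE]
    if (any(ev$onset[-1] <= ev$end[-nrow(ev)]))
      warn(sprintf("overlapping raw events for patient %s; merged.",
                   ev$patient_id[1]))
    keep <- ev[1, , drop = FALSE]
    for (i in seq_len(nrow(ev))[-1]) {
      j <- nrow(keep)
      if (ev$onset[i] - keep$end[j] < gap) {
        keep$end[j] <- max(keep$end[j], ev$end[i])
        if (ev$severity[i] == "severe") keep$severity[j] <- "severe"
      } else {
        keep <- bind_rows(keep, ev[i, ])
      }
    }
    keep
  }
  out <- events |> split(events$patient_id) |> purrr::map(per_patient) |>
    bind_rows()
  arrange(out, .data$patient_id, .data$onset)
}

#' Label each monitoring day relative to exacerbations
#'
#' Partitions every patient's horizon into `unmonitored` days (no usable
#' signal that day), `associated` days (from onset through `post` days
#' after episode end), `pre_window` days (the `pre` days before an onset,
#' where a successful alert may fall) and `non_associated` days (the false
#' alarm denominator). A day inside one event's episode span and another's
#' pre-window counts as `associated`.
#'
#' @param records Daily-record tibble (defines the horizon per patient).
#' @param events Merged event tibble.
#' @param pre,post Window margins in days (default 8 before onset, 8 after
#'   end).
#' @param signal_col Column whose non-missingness defines a monitored day
#'   (default `"cough_count"`). Use the score column for questionnaire
#'   strategies.
#' @return Tibble `patient_id`, `day`, `monitored` (logical), `label`.
#' @export
classify_days <- function(records, events, pre = 8L, post = 8L,
                          signal_col = "cough_count") {
  check_records(records, c("patient_id", "day", signal_col))
  pre <- check_count(pre, "pre"); post <- check_count(post, "post")
  out <- records |>
    select("patient_id", "day") |>
    mutate(monitored = !is.na(records[[signal_col]]),
           label = "non_associated")
  for (i in seq_len(nrow(events))) {
    sel_pre <- out$patient_id == events$patient_id[i] &
      out$day >= events$onset[i] - pre & out$day < events$onset[i]
    out$label[sel_pre & out$label == "non_associated"] <- "pre_window"
    sel_assoc <- out$patient_id == events$patient_id[i] &
      out$day >= events$onset[i] & out$day <= events$end[i] + post
    out$label[sel_assoc] <- "associated"
  }
  out$label[!out$monitored] <- "unmonitored"
  out
}

#' Select analyzable epochs around exacerbation onsets
#'
#' For the exacerbation-centred trend, each event contributes a candidate
#' 17-day epoch (8 days before onset to 8 days after). An epoch is
#' included only if all 17 days have cough counts and the window does not
#' intersect any other event's associated span (onset - `pre` to end +
#' `post`), so recurrent exacerbations and missing data cannot distort the
#' trend.
#'
#' @param events Merged event tibble.
#' @param records Daily-record tibble with `cough_count`.
#' @param pre,post Epoch half-widths around onset (default 8 and 8).
#' @return Tibble with one row per event: `patient_id`, `onset`, `end`,
#'   `severity`, `complete`, `overlapping`, `included`.
#' @export
select_epochs <- function(events, records, pre = 8L, post = 8L) {
  check_records(records, c("patient_id", "day", "cough_count"))
  pre <- check_count(pre, "pre"); post <- check_count(post, "post")
  if (!nrow(events))
    return(tibble(patient_id = character(), onset = integer(),
                  end = integer(), severity = character(),
                  complete = logical(), overlapping = logical(),
                  included = logical()))
  res <- purrr::map(seq_len(nrow(events)), function(i) {
    pid <- events$patient_id[i]
    win <- (events$onset[i] - pre):(events$onset[i] + post)
    rec <- records[records$patient_id == pid, , drop = FALSE]
    have <- rec$day[!is.na(rec$cough_count)]
    complete <- all(win %in% have)
    others <- events[events$patient_id == pid, , drop = FALSE]
    others <- others[others$onset != events$onset[i] |
                       others$end != events$end[i], , drop = FALSE]
    overlapping <- any(others$onset - pre <= max(win) &
                         others$end + post >= min(win))
    tibble(patient_id = pid, onset = events$onset[i], end = events$end[i],
           severity = events$severity[i], complete = complete,
           overlapping = overlapping,
           included = complete && !overlapping)
  })
  bind_rows(res)
}
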