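# small cohort configurations used across tests; kept tiny for speed
tiny_config <- function(...) {
  cohort_config(n_patients = 5L, horizon_days = 60L, seed = 11L, ...)
}

# daily-record grid for hand-built scenarios: one patient, all flags off
blank_records <- function(n_days, patient = "P001") {
  out <- tibble::tibble(patient_id = patient, day = 0:(n_days - 1L),
                        cough_count = 0L)
  for (j in 1:8) out[[paste0("q", j)]] <- 0L
  out$steroid <- 0L; out$antibiotic <- 0L; out$hospital <- 0L
  out
}

# alert tibble from explicit alert days
alerts_on <- function(days, n_days, patient = "P001", source = "cough") {
  tibble::tibble(patient_id = patient, day = 0:(n_days - 1L),
                 source = source, value = NA_real_,
                 alert = (0:(n_days - 1L)) %in% days)
}

# event tibble shorthand
events_tbl <- function(onset, end, patient = "P001",
                       severity = "moderate", source = "self_report") {
  tibble::tibble(patient_id = patient, onset = as.integer(onset),
                 end = as.integer(end), severity = severity,
                 source = source)
}

# brute-force oracle for the k-of-n run rule: enumerate every window
oracle_run_rule <- function(values, rule) {
  n_days <- length(values)
  observed <- !is.na(values)
  exceed <- observed & values > rule$threshold
  vapply(seq_len(n_days), function(t) {
    lo <- max(1L, t - rule$n + 1L)
    win <- lo:t
    sum(observed[win]) >= rule$min_observed &&
      sum(exceed[win]) >= rule$k &&
      (!rule$require_current || exceed[t])
  }, logical(1))
}
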