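test_that("success counts events with an alert in the 8 pre-onset days", {
  ev <- events_tbl(c(20, 50), c(24, 55))
  # alert 3 days before the first onset only
  al <- alerts_on(17, 90)
  s <- success_rate(al, ev)
  expect_equal(s$n_events, 2L)
  expect_equal(s$n_identified, 1L)
  expect_equal(s$rate, 0.5)
  # an alert on onset day 0 itself does not identify the event
  expect_equal(success_rate(alerts_on(50, 90), ev)$n_identified, 0L)
  # an alert 9 days ahead is outside the window
  expect_equal(success_rate(alerts_on(11, 90), ev)$n_identified, 0L)
  # no alerts at all -> rate 0; no events -> rate undefined, not 0
  expect_equal(success_rate(alerts_on(integer(), 90), ev)$rate, 0)
  expect_true(is.na(success_rate(al, ev[0, ])$rate))
})

test_that("false alarm rate counts alerts on non-associated monitored days", {
  rec <- blank_records(90)
  ev <- events_tbl(20, 25)
  labs <- classify_days(rec, ev)
  # alerts at day 5 (non-associated), day 15 (pre-window), day 22 (episode)
  fa <- false_alarm_rate(alerts_on(c(5, 15, 22), 90), labs)
  expect_equal(fa$n_false, 1L)
  expect_equal(fa$n_days, 90L - 22L)  # 8 + 6 + 8 associated-ish days removed
  expect_equal(fa$rate, 1 / 68)
  expect_equal(false_alarm_rate(alerts_on(integer(), 90), labs)$rate, 0)
  # zero denominator -> undefined
  labs_all <- classify_days(rec, events_tbl(0, 89))
  expect_true(is.na(false_alarm_rate(alerts_on(5, 90), labs_all)$rate))
})

test_that("lead time takes the earliest pre-onset alert", {
  ev <- events_tbl(50, 55)
  expect_equal(lead_times(alerts_on(c(45, 48), 90), ev), 5L)
  expect_equal(lead_times(alerts_on(49, 90), ev), 1L)
  expect_equal(lead_times(alerts_on(41, 90), ev), integer())  # onset-9: missed
  expect_equal(lead_times(alerts_on(42, 90), ev), 8L)
})

test_that("the evaluation report is internally consistent and replayable", {
  coh <- simulate_cohort(tiny_config())
  res1 <- suppressMessages(run_pipeline(coh$records))
  res2 <- suppressMessages(run_pipeline(coh$records))
  g1 <- glance(res1$evaluations$cough)
  expect_identical(g1, glance(res2$evaluations$cough))
  ev <- res1$evaluations$cough
  if (ev$n_events > 0)
    expect_equal(ev$success_rate, ev$n_identified / ev$n_events)
  expect_equal(ev$false_alarm_rate, ev$n_false / ev$n_nonassociated_days)
  expect_true(all(ev$lead_times >= 1 & ev$lead_times <= 8))
  expect_equal(nrow(tidy(ev)), length(ev$lead_times))
})

test_that("trend profile reduces to the epoch values in degenerate cases", {
  rec <- blank_records(60)
  rec$cough_count <- 10L
  rec$cough_count[31:36] <- 80L  # days 30..35
  rec <- add_bscale(rec)
  ev <- events_tbl(30, 35)
  tr <- exacerbation_trend(rec, ev)
  expect_s3_class(tr, "cough_trend")
  expect_equal(nrow(tr), 17L)
  expect_equal(tr$rel_day, -8:8)
  # single epoch: SEM 0 by convention, trend equals the centred values
  expect_true(all(tr$sem == 0))
  expect_equal(tr$n_epochs, rep(1L, 17))
  b_norm <- rec$b - mean(rec$b)
  expect_equal(tr$mean_b, b_norm[23:39])
  # two identical epochs in two patients: SEM still 0 everywhere
  rec2 <- rec; rec2$patient_id <- "P002"
  ev2 <- rbind(ev, events_tbl(30, 35, patient = "P002"))
  tr2 <- exacerbation_trend(rbind(rec, rec2), ev2)
  expect_equal(tr2$n_epochs, rep(2L, 17))
  expect_true(all(tr2$sem == 0))
  # no admissible epochs -> empty profile with a warning
  expect_warning(tr0 <- exacerbation_trend(rec, events_tbl(3, 6)),
                 "no complete")
  expect_equal(nrow(tr0), 0L)
})

test_that("simulated prodromes produce a rising pre-onset trend", {
  coh <- simulate_cohort(cohort_config(n_patients = 30, seed = 301,
                                       missing_day_prob = 0))
  rec <- add_bscale(coh$records)
  tr <- exacerbation_trend(rec, coh$episodes)
  expect_gt(tr$mean_b[tr$rel_day == -1], tr$mean_b[tr$rel_day == -8])
  expect_gt(tr$mean_b[tr$rel_day == 0], 2)  # elevation reaches >= 2 B units
})

test_that("point-biserial correlation matches the closed-form value", {
  rec <- blank_records(6)
  rec$cough_count <- c(10L, 20L, 15L, 40L, 80L, 60L)
  rec <- add_bscale(rec)
  # report "increased cough" exactly when B is above its median
  rec$q1 <- as.integer(rec$b > median(rec$b))
  res <- cough_report_correlation(rec, min_days = 5)
  # closed form: r = (m1 - m0) * sqrt(p*q) / sd_n(B) on 3-vs-3 split
  b <- rec$b
  m1 <- mean(b[4:6]); m0 <- mean(b[1:3])
  r_hand <- (m1 - m0) * sqrt(0.5 * 0.5) / (stats::sd(b) * sqrt(5 / 6))
  expect_equal(res$patients$r_bscale, r_hand, tolerance = 1e-12)
  expect_false(res$patients$excluded)
})

test_that("patients without variation are excluded and counted", {
  rec <- blank_records(20)
  rec$cough_count <- as.integer(round(50 + 10 * sin(1:20)))
  rec <- add_bscale(rec)
  rec$q1 <- 1L  # reports increased cough every single day
  res <- cough_report_correlation(rec)
  expect_true(res$patients$excluded)
  expect_equal(res$patients$reason, "zero_variance")
  expect_equal(res$summary$n_excluded, 1L)
  expect_true(is.na(res$summary$mean_r_bscale))
})

test_that("independent reports and counts give a null mean correlation", {
  coh <- simulate_cohort(cohort_config(
    n_patients = 200, horizon_days = 90, exacerbation_rate = 0,
    missing_day_prob = 0, item_sensitivity = 0.5, item_specificity = 0.5,
    always_yes_fraction = 0, seed = 404))
  rec <- add_bscale(coh$records)
  res <- cough_report_correlation(rec)
  s <- res$summary
  sem_b <- s$sd_r_bscale / sqrt(s$n_included)
  sem_c <- s$sd_r_change / sqrt(s$n_included)
  expect_lt(abs(s$mean_r_bscale), 3 * sem_b)
  expect_lt(abs(s$mean_r_change), 3 * sem_c)
})

test_that("random alerts on an event-free cohort calibrate the denominator", {
  coh <- simulate_cohort(cohort_config(n_patients = 40, horizon_days = 90,
                                       exacerbation_rate = 0,
                                       missing_day_prob = 0, seed = 505))
  rec <- coh$records
  p <- 0.1
  al <- withr::with_seed(99, tibble::tibble(
    patient_id = rec$patient_id, day = rec$day, source = "cough",
    value = NA_real_, alert = runif(nrow(rec)) < p))
  labs <- classify_days(rec, empty_ev <- events_tbl(1, 2)[0, ])
  fa <- false_alarm_rate(al, labs)
  expect_equal(fa$n_days, nrow(rec))
  sem <- sqrt(p * (1 - p) / fa$n_days)
  expect_lt(abs(fa$rate - p), 3 * sem)
})
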