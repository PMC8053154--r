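test_that("cohorts are reproducible for a seed and differ across seeds", {
  cfg <- tiny_config()
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  c_ <- simulate_cohort(cohort_config(n_patients = 5, horizon_days = 60,
                                      seed = 12))
  expect_false(identical(a$records$cough_count, c_$records$cough_count))
})

test_that("patient streams are stable under cohort-size changes", {
  small <- simulate_cohort(cohort_config(n_patients = 3, seed = 21))
  big <- simulate_cohort(cohort_config(n_patients = 6, seed = 21))
  expect_identical(small$records,
                   big$records[big$records$patient_id %in%
                                 unique(small$records$patient_id), ])
})

test_that("an event-free, fully observed cohort is exactly that", {
  coh <- simulate_cohort(tiny_config(exacerbation_rate = 0,
                                     missing_day_prob = 0))
  expect_equal(nrow(coh$episodes), 0L)
  expect_false(anyNA(coh$records$cough_count))
  expect_true(all(coh$records$steroid == 0L))
  expect_true(all(coh$records$hospital == 0L))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(cohort_config(missing_day_prob = 1.2), "missing_day_prob")
  expect_error(cohort_config(sd_slope = 0), "sd_slope")
  expect_error(cohort_config(prodrome_days = c(8, 4)), "prodrome_days")
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(baseline_mean_range = c(-5, 10)),
               "baseline_mean_range")
})

test_that("episode geometry respects the configuration", {
  coh <- simulate_cohort(cohort_config(n_patients = 40, seed = 31,
                                       exacerbation_rate = 2))
  ep <- coh$episodes
  expect_gt(nrow(ep), 10)
  expect_true(all(ep$prodrome_start < ep$onset))
  expect_true(all(ep$onset <= ep$end))
  expect_true(all(ep$end - ep$onset + 1L <= 14L))
  # episodes within a patient do not overlap
  by_pat <- split(ep, ep$patient_id)
  for (p in by_pat)
    if (nrow(p) > 1) {
      p <- p[order(p$onset), ]
      expect_true(all(p$onset[-1] > p$end[-nrow(p)]))
    }
  # medication flags cover exactly the episode spans
  rec <- coh$records
  for (i in seq_len(nrow(ep))) {
    span <- rec$patient_id == ep$patient_id[i] &
      rec$day >= ep$onset[i] & rec$day <= ep$end[i]
    expect_true(all(rec$steroid[span] == 1L | rec$antibiotic[span] == 1L))
  }
  # severe episodes carry a hospital marker at onset
  sev <- ep[ep$severity == "severe", ]
  for (i in seq_len(nrow(sev))) {
    expect_equal(rec$hospital[rec$patient_id == sev$patient_id[i] &
                                rec$day == sev$onset[i]], 1L)
  }
})

test_that("stable-period counts match the configured means and SD law", {
  # large cohort, long horizon: per-patient sample SD regressed on sample
  # mean recovers the generating slope within 15%
  cfg <- cohort_config(n_patients = 200, horizon_days = 365,
                       baseline_mean_range = c(5, 150),
                       exacerbation_rate = 0, missing_day_prob = 0,
                       seed = 61)
  coh <- simulate_cohort(cfg)
  per_pat <- coh$records |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(m = mean(cough_count), s = sd(cough_count))
  fit <- stats::lm(s ~ m, data = per_pat)
  expect_lt(abs(stats::coef(fit)[["m"]] / cfg$sd_slope - 1), 0.15)
  # per-patient means sit within 3 SEM of the configured baselines
  joined <- dplyr::left_join(per_pat, coh$patients, by = "patient_id")
  z <- (joined$m - joined$baseline_mean) /
    (joined$s / sqrt(cfg$horizon_days))
  expect_gt(mean(abs(z) <= 3), 0.97)
})

test_that("always-yes responders score the maximum every day", {
  coh <- simulate_cohort(tiny_config(always_yes_fraction = 1))
  scores <- questionnaire_score(coh$records[, paste0("q", 1:8)])
  expect_true(all(scores == 11L))
  expect_true(all(coh$patients$always_yes))
})

test_that("missingness modes hit the marginal rate", {
  cfg <- cohort_config(n_patients = 30, horizon_days = 365,
                       exacerbation_rate = 0, missing_day_prob = 0.1,
                       seed = 71)
  frac <- mean(is.na(simulate_cohort(cfg)$records$cough_count))
  expect_lt(abs(frac - 0.1), 0.02)
  cfg_b <- cohort_config(n_patients = 30, horizon_days = 365,
                         exacerbation_rate = 0, missing_day_prob = 0.1,
                         missing_mode = "burst", seed = 71)
  coh_b <- simulate_cohort(cfg_b)
  frac_b <- mean(is.na(coh_b$records$cough_count))
  expect_lt(abs(frac_b - 0.1), 0.03)
  # burst mode produces longer missing runs than independent drop-out
  run_lengths <- function(x) {
    r <- rle(x); r$lengths[r$values]
  }
  mean_run <- function(coh) {
    mean(unlist(purrr::map(split(is.na(coh$records$cough_count),
                                 coh$records$patient_id), run_lengths)))
  }
  expect_gt(mean_run(coh_b), 1.8)
})

test_that("questionnaire items track the exacerbation state", {
  coh <- simulate_cohort(cohort_config(n_patients = 60, seed = 81,
                                       always_yes_fraction = 0,
                                       exacerbation_rate = 2))
  rec <- coh$records
  rec$score <- questionnaire_score(rec[, paste0("q", 1:8)])
  in_state <- rep(FALSE, nrow(rec))
  ep <- coh$episodes
  for (i in seq_len(nrow(ep)))
    in_state <- in_state | (rec$patient_id == ep$patient_id[i] &
                              rec$day >= ep$prodrome_start[i] &
                              rec$day <= ep$end[i])
  # expected scores: 11 * sensitivity during episodes,
  # 11 * (1 - specificity) otherwise
  expect_equal(mean(rec$score[in_state]), 11 * 0.75, tolerance = 0.05)
  expect_equal(mean(rec$score[!in_state]), 11 * 0.2, tolerance = 0.05)
})
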