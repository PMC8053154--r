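test_that("treated exacerbations are detected from medication runs", {
  rec <- blank_records(40)
  expect_equal(nrow(detect_exacerbations(rec)), 0L)
  # steroids on days 10..16, no hospital -> one moderate event
  rec$steroid[11:17] <- 1L
  ev <- detect_exacerbations(rec)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset, 10L)
  expect_equal(ev$end, 16L)
  expect_equal(ev$severity, "moderate")
  expect_equal(ev$source, "self_report")
  # a single-day antibiotic report is not an exacerbation
  rec2 <- blank_records(40)
  rec2$antibiotic[21] <- 1L
  expect_equal(nrow(detect_exacerbations(rec2)), 0L)
  # steroids and antibiotics combine into one run
  rec3 <- blank_records(40)
  rec3$steroid[11:13] <- 1L
  rec3$antibiotic[14:15] <- 1L
  ev3 <- detect_exacerbations(rec3)
  expect_equal(c(ev3$onset, ev3$end), c(10L, 14L))
})

test_that("hospital attendance upgrades and can seed episodes", {
  rec <- blank_records(40)
  rec$steroid[11:17] <- 1L
  rec$hospital[14] <- 1L  # day 13, inside the run
  ev <- detect_exacerbations(rec)
  expect_equal(ev$severity, "severe")
  # admission with no treatment run seeds a severe episode
  rec2 <- blank_records(40)
  rec2$hospital[31] <- 1L
  ev2 <- detect_exacerbations(rec2, rx_course = 7)
  expect_equal(c(ev2$onset, ev2$end), c(30L, 36L))
  expect_equal(ev2$severity, "severe")
  expect_equal(ev2$source, "hospital")
})

test_that("prescription dates seed or advance episode onsets", {
  rec <- blank_records(40)
  rec$steroid[13:18] <- 1L  # self-report onset day 12
  rx <- tibble::tibble(patient_id = "P001", day = 10L)
  ev <- detect_exacerbations(rec, prescriptions = rx)
  expect_equal(ev$onset, 10L)  # the earlier of prescription and self-report
  expect_equal(ev$source, "prescription")
  # prescription with no self-report gets the default course length
  ev2 <- detect_exacerbations(blank_records(40), prescriptions = rx,
                              rx_course = 7)
  expect_equal(c(ev2$onset, ev2$end), c(10L, 16L))
})

test_that("events less than 8 days apart merge; a gap of exactly 8 does not", {
  e <- rbind(events_tbl(10, 14), events_tbl(19, 22))  # gap 5 < 8
  m <- merge_events(e)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$onset, m$end), c(10L, 22L))
  e2 <- rbind(events_tbl(10, 14), events_tbl(22, 25))  # gap exactly 8
  expect_equal(nrow(merge_events(e2)), 2L)
  expect_equal(merge_events(events_tbl(5, 9)), events_tbl(5, 9))
  # merged severity is the maximum of the parts
  e3 <- rbind(events_tbl(10, 14), events_tbl(19, 22, severity = "severe"))
  expect_equal(merge_events(e3)$severity, "severe")
})

test_that("merging is idempotent on random event lists", {
  withr::with_seed(13, {
    for (i in 1:50) {
      onsets <- sort(sample(0:80, sample(1:6, 1)))
      ev <- tibble::tibble(
        patient_id = sample(c("A", "B"), length(onsets), replace = TRUE),
        onset = onsets, end = onsets + sample(1:10, length(onsets),
                                              replace = TRUE),
        severity = sample(c("moderate", "severe"), length(onsets),
                          replace = TRUE),
        source = "self_report")
      m1 <- suppressWarnings(merge_events(ev))
      m2 <- suppressWarnings(merge_events(m1))
      expect_identical(m1, m2)
      # merged events are separated by at least the gap, per patient
      by_pat <- split(m1, m1$patient_id)
      for (p in by_pat)
        if (nrow(p) > 1) expect_true(all(p$onset[-1] - p$end[-nrow(p)] >= 8))
    }
  })
})

test_that("day labels partition the horizon around events", {
  rec <- blank_records(90)
  labs <- classify_days(rec, events_tbl(20, 25))
  expect_equal(labs$label[labs$day %in% 12:19], rep("pre_window", 8))
  expect_equal(labs$label[labs$day %in% 20:33], rep("associated", 14))
  expect_true(all(labs$label[labs$day < 12 | labs$day > 33] ==
                    "non_associated"))
  # no events -> every monitored day is non-associated
  labs0 <- classify_days(rec, events_tbl(1, 2)[0, ])
  expect_true(all(labs0$label == "non_associated"))
  # unmonitored days are labelled as such and excluded from denominators
  rec$cough_count[5] <- NA
  labs2 <- classify_days(rec, events_tbl(20, 25))
  expect_equal(labs2$label[labs2$day == 4], "unmonitored")
})

test_that("day labels match a brute-force membership test on random instances", {
  oracle_label <- function(day, ev, pre = 8, post = 8) {
    if (any(day >= ev$onset & day <= ev$end + post)) return("associated")
    if (any(day >= ev$onset - pre & day < ev$onset)) return("pre_window")
    "non_associated"
  }
  withr::with_seed(77, {
    for (i in 1:30) {
      onsets <- sort(sample(seq(0, 80, by = 12), sample(2:4, 1)))
      ev <- events_tbl(onsets, onsets + sample(1:6, length(onsets),
                                               replace = TRUE))
      rec <- blank_records(90)
      labs <- classify_days(rec, ev)
      want <- vapply(labs$day, oracle_label, character(1), ev = ev)
      expect_identical(labs$label, want)
      # partition: the three labels cover every monitored day exactly once
      expect_equal(sum(table(labs$label)), 90L)
    }
  })
})

test_that("epoch selection requires completeness and isolation", {
  rec <- blank_records(90)
  # early event: the window runs off the start of the record
  ep <- select_epochs(events_tbl(3, 8), rec)
  expect_false(ep$included)
  expect_false(ep$complete)
  # isolated event with complete data is included
  ep2 <- select_epochs(events_tbl(40, 45), rec)
  expect_true(ep2$included)
  # a missing count inside the 17-day window excludes the epoch
  rec2 <- blank_records(90)
  rec2$cough_count[34] <- NA  # day 33 = onset 40 - 7
  expect_false(select_epochs(events_tbl(40, 45), rec2)$complete)
  # two events 10 days apart invalidate each other's windows
  ep3 <- select_epochs(rbind(events_tbl(40, 43), events_tbl(50, 53)), rec)
  expect_equal(ep3$included, c(FALSE, FALSE))
  expect_equal(ep3$overlapping, c(TRUE, TRUE))
})
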