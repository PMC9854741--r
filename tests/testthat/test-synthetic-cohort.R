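test_that("degenerate config yields constant streams at the baseline", {
  cfg <- cohort_config(
    n_patients = 2,
    los = list(median_days = 1, sdlog = 0, min_days = 1),
    baseline = list(PR = c(median = 70, iqr = 0),
                    RR = c(median = 18, iqr = 0),
                    SPO2 = c(median = 95, iqr = 0)),
    noise_sd = c(PR = 0, RR = 0, SPO2 = 0),
    circadian_amplitude = c(PR = 0, RR = 0, SPO2 = 0),
    rates = c(PR = 2, SPO2 = 2, RR = 1),
    seed = 3
  )
  co <- generate_cohort(cfg)
  spo2 <- co$observations$value[co$observations$signal == "SPO2"]
  expect_true(length(spo2) > 0)
  expect_true(all(spo2 == 95))
  expect_true(all(co$observations$value[co$observations$signal == "PR"] == 70))
})

test_that("a fully adherent 24-h stay yields the device observation counts", {
  cfg <- cohort_config(
    n_patients = 1,
    los = list(median_days = 1, sdlog = 0, min_days = 1),
    adherence = list(target = 1, removals_per_day = 2, wear_median_h = 2,
                     spread = 0),
    seed = 11
  )
  co <- generate_cohort(cfg)
  counts <- table(co$observations$signal)
  expect_equal(unname(counts[["PR"]]), 43200)
  expect_equal(unname(counts[["SPO2"]]), 43200)
  expect_equal(unname(counts[["RR"]]), 21600)
})

test_that("observation counts per wear interval match rate x duration", {
  co <- generate_cohort(test_config(n_patients = 3, seed = 5))
  # recover wear intervals from gaps in the PR stream (rate 2/min -> 30 s)
  obs <- co$observations
  for (pid in unique(obs$patient_id)) {
    t <- as.numeric(obs$timestamp[obs$patient_id == pid &
                                    obs$signal == "PR"])
    breaks <- which(diff(t) > 31)
    seg_start <- c(1, breaks + 1)
    seg_end <- c(breaks, length(t))
    n_seg <- seg_end - seg_start + 1
    dur_min <- (t[seg_end] - t[seg_start]) / 60
    expect_true(all(abs(n_seg - (dur_min * 2 + 1)) <= 1))
  }
})

test_that("the same seed reproduces the cohort exactly, patient by patient", {
  a <- generate_cohort(test_config(n_patients = 3, seed = 9))
  b <- generate_cohort(test_config(n_patients = 3, seed = 9))
  expect_identical(a$observations, b$observations)
  expect_identical(a$facts, b$facts)
  expect_identical(a$patients, b$patients)

  # patient substreams do not depend on cohort size
  big <- generate_cohort(test_config(n_patients = 5, seed = 9))
  expect_identical(
    a$observations[a$observations$patient_id == "P002", ],
    big$observations[big$observations$patient_id == "P002", ])

  c2 <- generate_cohort(test_config(n_patients = 3, seed = 10))
  expect_false(identical(a$observations$value, c2$observations$value))
})

test_that("impossible adherence targets and empty cohorts are handled", {
  expect_error(cohort_config(adherence = list(target = 0.6,
                                              removals_per_day = 13,
                                              wear_median_h = 2,
                                              spread = 0.5)),
               "impossible")
  co <- generate_cohort(test_config(n_patients = 0))
  expect_equal(n_patients(co), 0)
  expect_equal(nrow(co$observations), 0)
})

test_that("an injected hypoxic episode is visible in the raw stream", {
  eps <- list(list(patient = 1, signal = "SPO2", onset_h = 6,
                   duration_h = 2, plateau = 85))
  co <- generate_cohort(test_config(n_patients = 1, seed = 21,
                                    episodes = eps,
                                    adherence = list(target = 1,
                                                     removals_per_day = 2,
                                                     wear_median_h = 2,
                                                     spread = 0)))
  spo2 <- co$observations[co$observations$signal == "SPO2", ]
  rel_h <- as.numeric(spo2$timestamp - co$patients$admit_timestamp[1],
                      units = "hours")
  inside <- rel_h > 6.5 & rel_h < 7.5
  expect_true(any(spo2$value[inside] < 90))
  outside <- rel_h < 5 | rel_h > 9
  expect_true(median(spo2$value[outside]) > 90)
})

test_that("cohort summaries report median (IQR) and mean +/- SD", {
  obs <- tibble::tibble(
    timestamp = T0 + (1:10) * 60,
    signal = "SPO2", value = rep(95, 10))
  co <- manual_cohort(obs = obs, los_days = 1)
  sm <- suppressWarnings(summarize_cohort(co, smooth = FALSE))
  row <- sm[sm$patient_id == "P001", ]
  expect_equal(row$median, 95)
  expect_equal(row$iqr, 0)
  expect_equal(row$mean, 95)

  # pooled median over two one-value patients by brute force
  obs2 <- vs_cohort(
    observations = tibble::tibble(
      patient_id = rep(c("A", "B"), each = 1),
      timestamp = T0 + c(60, 60), signal = "SPO2", value = c(90, 100)),
    patients = tibble::tibble(
      patient_id = c("A", "B"), admit_timestamp = T0,
      discharge_timestamp = T0 + 86400))
  pooled <- suppressWarnings(summarize_cohort(obs2, smooth = FALSE))
  expect_equal(pooled$median[pooled$patient_id == "(cohort)"], 95)
  expect_warning(summarize_cohort(obs2, smooth = FALSE), "PR")
})

test_that("generated cohorts recover the configured distribution targets", {
  # five seeds; medians must land within +/-10% of the configured values
  for (s in 1:5) {
    cfg <- cohort_config(n_patients = 100,
                         rates = c(PR = 0.2, SPO2 = 0.2, RR = 0.1),
                         seed = s)
    co <- generate_cohort(cfg)
    adh <- cohort_adherence(co)
    expect_gt(adh$cohort$median_adherence_pct, 64.6 * 0.9)
    expect_lt(adh$cohort$median_adherence_pct, 64.6 * 1.1)
    expect_gt(adh$cohort$median_removals_per_day, 2 * 0.9)
    expect_lt(adh$cohort$median_removals_per_day, 2 * 1.1)
    pooled <- summarize_cohort(co)
    pooled <- pooled[pooled$patient_id == "(cohort)", ]
    targets <- c(PR = 72.9, RR = 19.3, SPO2 = 95.4)
    for (sig in names(targets)) {
      m <- pooled$median[pooled$signal == sig]
      expect_gt(m, targets[[sig]] * 0.9)
      expect_lt(m, targets[[sig]] * 1.1)
    }
  }
})
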