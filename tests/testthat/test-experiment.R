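episode_config <- function(seed, n = 6) {
  eps <- lapply(1:2, function(i) {
    list(patient = i, signal = "SPO2", onset_h = 10, duration_h = 12,
         plateau = 88)
  })
  test_config(n_patients = n, seed = seed, episodes = c(
    eps,
    lapply(1:2, function(i) {
      list(patient = i, signal = "RR", onset_h = 10, duration_h = 12,
           plateau = 27)
    })
  ))
}

test_that("the default grid covers 3 rulesets x 8 conditions", {
  co <- generate_cohort(test_config(n_patients = 3, seed = 41,
                                    los_median = 1.2))
  g <- run_grid(co)
  expect_equal(nrow(g), 24)
  expect_equal(sort(unique(g$ruleset)), c("A1", "A2", "A3"))
  expect_equal(nrow(unique(g[, c("observation_rate", "aggregation_window")])),
               8)
  expect_true(all(g$W_AP <= g$included_windows))
  expect_true(all(is.na(g$patient_rate) | (g$patient_rate >= 0 &
                                             g$patient_rate <= 100)))
})

test_that("a breach-free cohort is silent across the whole grid", {
  cfg <- cohort_config(
    n_patients = 2, los = list(median_days = 1.2, sdlog = 0, min_days = 1),
    baseline = list(PR = c(median = 75, iqr = 0),
                    RR = c(median = 15, iqr = 0),
                    SPO2 = c(median = 97, iqr = 0)),
    noise_sd = c(PR = 0, RR = 0, SPO2 = 0),
    circadian_amplitude = c(PR = 0, RR = 0, SPO2 = 0),
    rates = c(PR = 2, SPO2 = 2, RR = 1), seed = 42)
  g <- run_grid(generate_cohort(cfg))
  expect_true(all(g$W_AP == 0))
})

test_that("positive windows are monotone across nested observation schedules", {
  co <- generate_cohort(episode_config(seed = 43))
  g <- run_grid(co)
  for (rs in c("A1", "A2", "A3")) {
    wap <- sapply(c("VS_12", "VS_4", "VS_1", "VS_15"), function(cond) {
      g$W_AP[g$ruleset == rs & g$observation_rate == cond]
    })
    expect_true(all(diff(wap) >= 0))
  }
})

test_that("per-window EDT under a fine schedule is never later than a coarse one", {
  co <- generate_cohort(episode_config(seed = 44, n = 4))
  ctx_adh <- cohort_adherence(co)
  sm <- smooth_cohort(co, 5)
  rs <- builtin_ruleset("A2")
  conds <- default_conditions()
  coarse <- downsample_cohort(sm, 240)
  fine <- downsample_cohort(sm, 15)
  for (pid in co$patients$patient_id) {
    row <- co$patients[co$patients$patient_id == pid, ]
    adh <- adherence_windows(row$admit_timestamp, row$discharge_timestamp,
                             co$facts$timestamp[co$facts$patient_id == pid])
    win <- build_assessment_windows(row$admit_timestamp,
                                    row$discharge_timestamp, adh)
    get_edt <- function(dcohort) {
      obs <- dcohort$observations
      streams <- sapply(c("PR", "SPO2", "RR"), function(sig) {
        obs[obs$patient_id == pid & obs$signal == sig,
            c("timestamp", "value")]
      }, simplify = FALSE)
      early_detection_time(assign_triggers(win,
                                           run_ruleset(rs, streams)$triggers))
    }
    e_coarse <- get_edt(coarse)
    e_fine <- get_edt(fine)
    both <- !is.na(e_coarse) & !is.na(e_fine)
    expect_true(all(e_fine[both] >= e_coarse[both]))
    # triggers present under the coarse schedule imply fine-schedule triggers
    expect_true(all(is.na(e_fine)[!is.na(e_coarse)] == FALSE))
  }
})

test_that("threshold sweeps are monotone with hand-computed percent deltas", {
  co <- generate_cohort(episode_config(seed = 45, n = 3))
  sw <- run_sweep(co, "SPO2", "lt", c(91, 92))
  expect_true(all(diff(sw$per_threshold$W_AP) >= 0))
  w <- sw$per_threshold$W_AP
  expect_equal(sw$deltas$W_AP_delta, w[2] - w[1])
  expect_equal(sw$deltas$W_AP_pct,
               if (w[1] > 0) 100 * (w[2] - w[1]) / w[1] else NA_real_)

  sw_rr <- run_sweep(co, "RR", "gt", c(20, 25))
  wr <- sw_rr$per_threshold
  expect_true(wr$W_AP[wr$threshold == 25] <= wr$W_AP[wr$threshold == 20])
})

test_that("patient scenarios attenuate alarms as the aggregation window grows", {
  # two clean 2-h hypoxic dips; no noise, so the attenuation of each
  # aggregation window is exactly the median-filter geometry
  eps <- list(list(patient = 1, signal = "SPO2", onset_h = 25,
                   duration_h = 2, plateau = 85),
              list(patient = 1, signal = "SPO2", onset_h = 49,
                   duration_h = 2, plateau = 85))
  cfg <- cohort_config(
    n_patients = 1, los = list(median_days = 3, sdlog = 0, min_days = 1),
    baseline = list(PR = c(median = 70, iqr = 0),
                    RR = c(median = 18, iqr = 0),
                    SPO2 = c(median = 95, iqr = 0)),
    noise_sd = c(PR = 0, RR = 0, SPO2 = 0),
    circadian_amplitude = c(PR = 0, RR = 0, SPO2 = 0),
    adherence = list(target = 1, removals_per_day = 2, wear_median_h = 2,
                     spread = 0),
    rates = c(PR = 2, SPO2 = 2, RR = 1), episodes = eps, seed = 46)
  co <- generate_cohort(cfg)
  rule <- alarm_rule("hypoxia", vital_condition("SPO2", "lt", 89))
  sc <- patient_scenario(co, "P001", rule)
  expect_equal(sc$aw_minutes, c(5, 15, 60, 240))
  expect_true(all(diff(sc$W_AP) <= 0))
  # a 4-h median cannot be dragged below threshold by a 2-h episode
  expect_lt(sc$W_AP[4], sc$W_AP[1])

  # a constant-breach fully adherent patient alarms in every window
  cfg2 <- cohort_config(
    n_patients = 1, los = list(median_days = 1, sdlog = 0, min_days = 1),
    baseline = list(PR = c(median = 70, iqr = 0),
                    RR = c(median = 18, iqr = 0),
                    SPO2 = c(median = 85, iqr = 0)),
    noise_sd = c(PR = 0, RR = 0, SPO2 = 0),
    circadian_amplitude = c(PR = 0, RR = 0, SPO2 = 0),
    adherence = list(target = 1, removals_per_day = 2, wear_median_h = 2,
                     spread = 0),
    rates = c(PR = 2, SPO2 = 2, RR = 1), seed = 47)
  co2 <- generate_cohort(cfg2)
  sc2 <- patient_scenario(co2, "P001", rule, aw_minutes = c(5, 60))
  expect_true(all(sc2$alarms_per_day_mean == 6))  # six 4-h windows per day

  # no data means no alarms, however low the configured vitals
  co3 <- manual_cohort(los_days = 2)
  expect_warning(sc3 <- patient_scenario(co3, "P001", rule), "no observation")
  expect_true(all(sc3$W_AP == 0))
})

test_that("identical cohorts and configs give byte-identical reports", {
  co1 <- generate_cohort(test_config(n_patients = 3, seed = 48))
  co2 <- generate_cohort(test_config(n_patients = 3, seed = 48))
  dir <- withr::local_tempdir()
  g1 <- run_grid(co1)
  g2 <- run_grid(co2)
  expect_identical(g1, g2)
  write_report(g1, file.path(dir, "r1"))
  write_report(g2, file.path(dir, "r2"))
  expect_identical(readLines(file.path(dir, "r1.json")),
                   readLines(file.path(dir, "r2.json")))
})
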