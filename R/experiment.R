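#' The default condition grid
#'
#' Eight pipeline conditions per ruleset, mirroring how continuous
#' monitoring is compared against spot-check practice:
#' * `VS_12`, `VS_4`, `VS_1`, `VS_15` — the 5-min smoothed stream
#'   downsampled to a 12-h/4-h/1-h/15-min schedule anchored at 06:00,
#'   evaluated with no further aggregation (min data points = 1).
#' * `VS_SD` — the 5-min smoothed stream at device rate.
#' * `AW_15`, `AW_1`, `AW_4` — the raw stream smoothed at 15 min/1 h/4 h,
#'   evaluated at device rate.
#'
#' @return Tibble with `label`, `kind` (`downsample`/`smooth`),
#'   `interval_min` (schedule interval for downsampled conditions),
#'   `aw_minutes` (aggregation window), `observation_rate` and
#'   `aggregation_window` report labels.
#' @export
default_conditions <- function() {
  tibble::tibble(
    label = c("VS_12", "VS_4", "VS_1", "VS_15", "VS_SD",
              "AW_15", "AW_1", "AW_4"),
    kind = c(rep("downsample", 4), rep("smooth", 4)),
    interval_min = c(720, 240, 60, 15, NA, NA, NA, NA),
    aw_minutes = c(5, 5, 5, 5, 5, 15, 60, 240),
    observation_rate = c("VS_12", "VS_4", "VS_1", "VS_15", "VS_SD",
                         "VS_OD", "VS_OD", "VS_OD"),
    aggregation_window = c("AW_0", "AW_0", "AW_0", "AW_0", "-",
                           "AW_15", "AW_1", "AW_4")
  )
}

# Prepare the evaluation cohort for one condition: smooth the raw stream
# at the condition's aggregation window, then (for spot-check conditions)
# downsample the 5-min smoothed stream onto the schedule.
prepare_condition <- function(cohort, condition, rates = DEVICE_RATES,
                              min_fraction = 0.2) {
  sm <- smooth_cohort(cohort, condition$aw_minutes,
                      min_fraction = min_fraction, rates = rates)
  if (condition$kind == "downsample") {
    downsample_cohort(sm, condition$interval_min)
  } else {
    sm
  }
}

split_streams <- function(cohort) {
  obs <- cohort$observations
  by_pid <- split(obs, obs$patient_id)
  out <- lapply(cohort$patients$patient_id, function(pid) {
    po <- by_pid[[pid]]
    sapply(SIGNALS, function(sig) {
      if (is.null(po)) {
        tibble::tibble(timestamp = as_time(numeric()), value = numeric())
      } else {
        po[po$signal == sig, c("timestamp", "value"), drop = FALSE]
      }
    }, simplify = FALSE)
  })
  names(out) <- cohort$patients$patient_id
  out
}

# Evaluate one ruleset over a prepared cohort and window the triggers.
evaluate_condition <- function(prepared, ruleset, adherence_grids,
                               assessment_windows, los, condition,
                               denominator = "contributing",
                               overlap_mode = "anchor",
                               keep_logs = FALSE) {
  streams <- split_streams(prepared)
  logs <- lapply(streams, function(s) run_ruleset(ruleset, s, overlap_mode))
  window_list <- lapply(names(logs), function(pid) {
    assign_triggers(assessment_windows[[pid]], logs[[pid]]$triggers)
  })
  names(window_list) <- names(logs)
  res <- condition_metrics(window_list, los,
                           ruleset_id = ruleset$ruleset_id,
                           observation_rate = condition$observation_rate,
                           aggregation_window = condition$aggregation_window,
                           denominator = denominator)
  if (keep_logs) attr(res, "trigger_logs") <- logs
  res
}

#' Run the full condition grid
#'
#' Executes every (ruleset, condition) cell: smooth, optionally
#' downsample, evaluate the ruleset per patient, group triggers into
#' 4-hour assessment windows, and compute the condition metrics. The
#' default grid is 3 rulesets x 8 conditions = 24 rows. Deterministic
#' given the cohort.
#'
#' @param cohort A [vs_cohort()] with raw device-rate observations.
#' @param rulesets List of [alarm_ruleset()]s (default the three built-in
#'   rulesets).
#' @param conditions Condition tibble (default [default_conditions()]).
#' @param rates Device rates per signal; defaults to the rates recorded in
#'   the cohort's generator config, falling back to the wearable rates.
#' @param denominator Patient-rate denominator, `"contributing"` or
#'   `"all"` (see [condition_metrics()]).
#' @param overlap_mode Combination-rule overlap semantics (see
#'   [evaluate_rule()]).
#' @param verbose Log per-condition progress and counts via `message()`.
#' @return Tibble of condition results, one row per cell.
#' @export
run_grid <- function(cohort,
                     rulesets = lapply(c("A1", "A2", "A3"), builtin_ruleset),
                     conditions = default_conditions(),
                     rates = cohort_rates(cohort),
                     denominator = "contributing",
                     overlap_mode = "anchor",
                     verbose = FALSE) {
  ctx <- grid_context(cohort)
  rows <- list()
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    t0 <- Sys.time()
    prepared <- prepare_condition(cohort, cond, rates = rates)
    for (rs in rulesets) {
      res <- evaluate_condition(prepared, rs, ctx$adherence,
                                ctx$assessment, ctx$los, cond,
                                denominator = denominator,
                                overlap_mode = overlap_mode)
      rows[[length(rows) + 1]] <- res
    }
    if (verbose) {
      message(sprintf("condition %s: %s obs in, %.1fs",
                      cond$label,
                      format(nrow(prepared$observations), big.mark = ","),
                      as.numeric(Sys.time() - t0, units = "secs")))
    }
  }
  dplyr::bind_rows(rows)
}

# Shared per-cohort context: adherence grids, assessment windows, LoS.
grid_context <- function(cohort) {
  facts_by_pid <- split(cohort$facts$timestamp, cohort$facts$patient_id)
  adherence <- lapply(seq_len(nrow(cohort$patients)), function(i) {
    row <- cohort$patients[i, ]
    adherence_windows(row$admit_timestamp, row$discharge_timestamp,
                      facts_by_pid[[row$patient_id]] %||% as_time(numeric()))
  })
  names(adherence) <- cohort$patients$patient_id
  assessment <- lapply(seq_len(nrow(cohort$patients)), function(i) {
    row <- cohort$patients[i, ]
    build_assessment_windows(row$admit_timestamp, row$discharge_timestamp,
                             adherence[[i]])
  })
  names(assessment) <- cohort$patients$patient_id
  list(adherence = adherence, assessment = assessment,
       los = length_of_stay(cohort))
}

#' Threshold-sensitivity sweep for a single rule
#'
#' Replays a one-condition pipeline with a family of single-signal rules
#' that differ only in their threshold, and reports positive alarm windows
#' and patient rate per threshold plus pairwise deltas. Because the
#' trigger sets of nested thresholds are contained in one another, the
#' metrics are monotone in the threshold.
#'
#' @param cohort A [vs_cohort()] with raw observations.
#' @param signal Signal to sweep.
#' @param op Comparison operator (`"lt"`, `"le"`, `"gt"`, `"ge"`).
#' @param thresholds Numeric vector of threshold values.
#' @param condition One row of [default_conditions()] (default `VS_SD`).
#' @param rates Device rates.
#' @return List with `per_threshold` (tibble: `threshold`, `W_AP`,
#'   `patient_rate`, `included_windows`) and `deltas` (tibble of pairwise
#'   absolute and percent differences in `W_AP` and `patient_rate`).
#' @export
run_sweep <- function(cohort, signal, op, thresholds,
                      condition = default_conditions()[5, ],
                      rates = cohort_rates(cohort)) {
  stopifnot(length(thresholds) >= 2)
  thresholds <- sort(thresholds)
  ctx <- grid_context(cohort)
  prepared <- prepare_condition(cohort, condition, rates = rates)
  rows <- lapply(thresholds, function(th) {
    rs <- alarm_ruleset(
      sprintf("%s_%s_%g", signal, op, th),
      list(alarm_rule("sweep-01", vital_condition(signal, op, th))))
    res <- evaluate_condition(prepared, rs, ctx$adherence, ctx$assessment,
                              ctx$los, condition)
    tibble::tibble(threshold = th, W_AP = res$W_AP,
                   patient_rate = res$patient_rate,
                   included_windows = res$included_windows)
  })
  per_threshold <- dplyr::bind_rows(rows)
  pairs <- utils::combn(seq_along(thresholds), 2)
  deltas <- dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    tibble::tibble(
      from = thresholds[i], to = thresholds[j],
      W_AP_delta = per_threshold$W_AP[j] - per_threshold$W_AP[i],
      W_AP_pct = if (per_threshold$W_AP[i] > 0)
        100 * (per_threshold$W_AP[j] - per_threshold$W_AP[i]) /
          per_threshold$W_AP[i] else NA_real_,
      patient_rate_delta = per_threshold$patient_rate[j] -
        per_threshold$patient_rate[i]
    )
  }))
  list(per_threshold = per_threshold, deltas = deltas)
}

#' Per-patient what-if scenario over aggregation windows
#'
#' For one patient and one rule (individual or combination), computes the
#' average alarms per day — positive 4-h assessment windows per 24-h slice
#' of the stay, reported as mean +/- SD across slices — for each candidate
#' aggregation window. Evaluation is at device rate. A patient with no
#' observation data generates zero alarms, whatever their vital-sign
#' values: data need to exist to alarm.
#'
#' @param cohort A [vs_cohort()].
#' @param patient_id Patient to analyse.
#' @param rule An [alarm_rule()].
#' @param aw_minutes Aggregation windows to compare (default
#'   `c(5, 15, 60, 240)`).
#' @param rates Device rates.
#' @return Tibble with `aw_minutes`, `alarms_per_day_mean`,
#'   `alarms_per_day_sd`, `W_AP`.
#' @export
patient_scenario <- function(cohort, patient_id, rule,
                             aw_minutes = c(5, 15, 60, 240),
                             rates = cohort_rates(cohort)) {
  pat <- cohort_patient(cohort, patient_id)
  if (!nrow(pat$observations)) {
    warning("patient ", patient_id, " has no observation data; ",
            "no alarms can be generated", call. = FALSE)
  }
  adh <- adherence_windows(pat$admit, pat$discharge, pat$facts$timestamp)
  aw_windows <- build_assessment_windows(pat$admit, pat$discharge, adh)
  rs <- alarm_ruleset("scenario", list(rule))
  sub <- vs_cohort(observations = pat$observations,
                   patients = cohort$patients[
                     cohort$patients$patient_id == patient_id, ],
                   facts = pat$facts)
  dplyr::bind_rows(lapply(aw_minutes, function(aw) {
    sm <- smooth_cohort(sub, aw, rates = rates)
    streams <- split_streams(sm)[[patient_id]]
    log <- run_ruleset(rs, streams)
    win <- assign_triggers(aw_windows, log$triggers)
    day <- floor(as.numeric(win$start - pat$admit, units = "secs") / 86400)
    per_day <- tapply(win$W_AP & win$included, day, sum)
    tibble::tibble(aw_minutes = aw,
                   alarms_per_day_mean = mean(per_day),
                   alarms_per_day_sd = if (length(per_day) > 1) sd(per_day)
                     else NA_real_,
                   W_AP = sum(win$W_AP & win$included))
  }))
}
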