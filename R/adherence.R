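#' Adherence on the 15-min window grid
#'
#' Divides one patient's stay `[T_a, T_d)` into consecutive 15-min windows
#' aligned to admission (a trailing partial window is included and judged
#' by the same rule) and marks a window adherent when at least one
#' wearable-on-arm fact falls inside it.
#'
#' @param admit,discharge Stay bounds (POSIXct).
#' @param fact_times POSIXct vector of wearable-on-arm facts.
#' @param window_min Window length in minutes (default 15).
#' @param align `"admission"` (windows counted from `T_a`, default) or
#'   `"clock"` (windows snapped to clock quarter-hours).
#' @return Tibble with `start`, `end`, `adherent` (logical); one row per
#'   window covering the stay with no gaps or overlaps.
#' @export
adherence_windows <- function(admit, discharge, fact_times,
                              window_min = 15,
                              align = c("admission", "clock")) {
  align <- match.arg(align)
  admit <- as_time(admit); discharge <- as_time(discharge)
  stopifnot(discharge > admit)
  step <- window_min * 60
  origin <- if (align == "admission") admit else {
    as.POSIXct(format(admit, "%Y-%m-%d"), tz = .tz) +
      floor(as.numeric(admit - as.POSIXct(format(admit, "%Y-%m-%d"),
                                          tz = .tz), units = "secs") /
              step) * step
  }
  total <- as.numeric(discharge - origin, units = "secs")
  n_win <- ceiling(total / step)
  starts <- origin + (seq_len(n_win) - 1) * step
  ends <- pmin(origin + seq_len(n_win) * step, discharge)
  ft <- as.numeric(fact_times)
  ft <- ft[ft >= as.numeric(admit) & ft < as.numeric(discharge)]
  idx <- floor((ft - as.numeric(origin)) / step) + 1
  idx <- idx[idx >= 1 & idx <= n_win]
  adherent <- tabulate(idx, nbins = n_win) > 0
  tibble::tibble(start = starts, end = ends, adherent = adherent)
}

#' Summarise one patient's wearable adherence
#'
#' Computes, from the 15-min grid: the adherent fraction; maximal runs of
#' adherent windows (windows of wear) and of non-adherent windows; the
#' removal count (wear-to-non-wear transitions, so wearing until discharge
#' is not a removal); daily adherence per 24-h slice of the stay (the
#' partial final day normalised by its actual duration); and the total
#' hours monitored (sum of wear-run durations).
#'
#' @param admit,discharge Stay bounds.
#' @param fact_times Wearable-on-arm fact times.
#' @param ... Passed to [adherence_windows()].
#' @return A list with `adherent_window_count`, `total_window_count`,
#'   `adherence_pct`, `daily_adherence` (tibble: `day`, `adherence_pct`),
#'   `wear_windows` and `nonwear_windows` (tibbles with `start`, `end`,
#'   `n_windows`, `hours`), `removal_count`, `hours_monitored`, and the
#'   window grid itself as `windows`.
#' @export
summarize_adherence <- function(admit, discharge, fact_times, ...) {
  win <- adherence_windows(admit, discharge, fact_times, ...)
  n_win <- nrow(win)
  n_adh <- sum(win$adherent)
  r <- rle(win$adherent)
  run_end_idx <- cumsum(r$lengths)
  run_start_idx <- run_end_idx - r$lengths + 1
  runs <- tibble::tibble(
    start = win$start[run_start_idx],
    end = win$end[run_end_idx],
    n_windows = r$lengths,
    adherent = r$values
  )
  runs$hours <- as.numeric(runs$end - runs$start, units = "hours")
  wear <- runs[runs$adherent, c("start", "end", "n_windows", "hours")]
  nonwear <- runs[!runs$adherent, c("start", "end", "n_windows", "hours")]
  n_wear_runs <- nrow(wear)
  ends_wearing <- n_win > 0 && win$adherent[n_win]
  removal_count <- if (n_wear_runs == 0) 0L else
    as.integer(n_wear_runs - as.integer(ends_wearing))

  # daily adherence over 24-h slices anchored at admission
  day_idx <- floor(as.numeric(win$start - as_time(admit), units = "secs") /
                     86400)
  day_tab <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(day = day_idx, adherent = win$adherent,
                                   dur = as.numeric(win$end - win$start,
                                                    units = "secs")),
                    .data$day),
    adherence_pct = 100 * sum(.data$dur[.data$adherent]) / sum(.data$dur),
    .groups = "drop"
  )

  list(
    adherent_window_count = n_adh,
    total_window_count = n_win,
    adherence_pct = 100 * n_adh / n_win,
    daily_adherence = day_tab,
    wear_windows = wear,
    nonwear_windows = nonwear,
    removal_count = removal_count,
    hours_monitored = sum(wear$hours),
    windows = win
  )
}

#' Cohort-level adherence summary
#'
#' Per-patient adherence summaries plus cohort aggregates: median (IQR)
#' adherence, removals per day, total hours monitored (the sum of all
#' patients' wear windows), each patient's contribution fraction (share of
#' the cohort's adherent windows), and a per-day median (IQR) adherence
#' table across the cohort.
#'
#' @param cohort A [vs_cohort()].
#' @param ... Passed to [adherence_windows()].
#' @return List with `patients` (tibble), `per_day` (tibble: `day`,
#'   `median`, `q1`, `q3`, `n`), and `cohort` (list of aggregates).
#' @export
cohort_adherence <- function(cohort, ...) {
  stopifnot(nrow(cohort$patients) > 0)
  facts_by_pid <- split(cohort$facts$timestamp, cohort$facts$patient_id)
  summaries <- lapply(seq_len(nrow(cohort$patients)), function(i) {
    row <- cohort$patients[i, ]
    ft <- facts_by_pid[[row$patient_id]] %||% as_time(numeric())
    summarize_adherence(row$admit_timestamp, row$discharge_timestamp, ft, ...)
  })
  los <- length_of_stay(cohort)
  per_patient <- tibble::tibble(
    patient_id = cohort$patients$patient_id,
    adherent_windows = vapply(summaries, `[[`, numeric(1),
                              "adherent_window_count"),
    total_windows = vapply(summaries, `[[`, numeric(1),
                           "total_window_count"),
    adherence_pct = vapply(summaries, `[[`, numeric(1), "adherence_pct"),
    removal_count = vapply(summaries, function(s)
      as.numeric(s$removal_count), numeric(1)),
    hours_monitored = vapply(summaries, `[[`, numeric(1), "hours_monitored"),
    los_days = los$los_days
  )
  per_patient$removals_per_day <- per_patient$removal_count /
    per_patient$los_days
  total_adherent <- sum(per_patient$adherent_windows)
  per_patient$contribution_pct <- if (total_adherent > 0) {
    100 * per_patient$adherent_windows / total_adherent
  } else rep(0, nrow(per_patient))

  day_all <- dplyr::bind_rows(lapply(seq_along(summaries), function(i) {
    d <- summaries[[i]]$daily_adherence
    d$patient_id <- per_patient$patient_id[i]
    d
  }))
  per_day <- dplyr::summarise(
    dplyr::group_by(day_all, .data$day),
    median = median(.data$adherence_pct),
    q1 = unname(quantile(.data$adherence_pct, 0.25)),
    q3 = unname(quantile(.data$adherence_pct, 0.75)),
    n = dplyr::n(),
    .groups = "drop"
  )

  list(
    patients = per_patient,
    per_day = per_day,
    cohort = list(
      median_adherence_pct = median(per_patient$adherence_pct),
      iqr_adherence_pct = unname(diff(quantile(per_patient$adherence_pct,
                                               c(0.25, 0.75)))),
      median_removals_per_day = median(per_patient$removals_per_day),
      total_hours_monitored = sum(per_patient$hours_monitored),
      total_adherent_windows = total_adherent
    )
  )
}
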