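#' Expected observation count for a signal over a duration
#'
#' The wearable emits pulse rate and SpO2 at 30 observations per minute and
#' respiratory rate at 15 per minute, so a fully adherent 24-hour day yields
#' 43,200 PR/SpO2 observations and 21,600 RR observations.
#'
#' @param rate Nominal device rate in observations per minute.
#' @param duration_min Duration in minutes (non-negative).
#' @return Integer count, `floor(rate * duration_min)`.
#' @export
expected_observation_count <- function(rate, duration_min) {
  stopifnot(rate > 0)
  if (any(duration_min < 0)) stop("duration must be non-negative", call. = FALSE)
  as.integer(floor(rate * duration_min))
}

#' Minimum observations required in an aggregation window
#'
#' The platform only emits a smoothed value when the window holds at least
#' 20% of the observations expected at the device rate; the count is the
#' ceiling of that fraction.
#'
#' @param rate Device rate (obs/min).
#' @param aw_minutes Aggregation window length in minutes.
#' @param min_fraction Required fraction of expected observations
#'   (default 0.2).
#' @return Integer minimum count (at least 1).
#' @export
min_observation_count <- function(rate, aw_minutes, min_fraction = 0.2) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  max(1L, as.integer(ceiling(min_fraction *
                               expected_observation_count(rate, aw_minutes))))
}

#' Time-windowed rolling median of a vital-sign stream
#'
#' Applies the platform's smoothing rule to one patient-signal stream: for
#' each observation time `t` the output is the median of all observations in
#' the trailing window `(t - AW, t]`, emitted only when the window holds at
#' least `min_fraction` of the observations expected at the device rate.
#' The window is causal (trailing) because the platform smooths live.
#'
#' @param stream Tibble with `timestamp` (POSIXct) and `value`, sorted or
#'   not (it is sorted internally), for a single patient and signal.
#' @param aw_minutes Aggregation window in minutes; `0` disables smoothing
#'   and returns the stream unchanged.
#' @param rate Device rate of the signal in obs/min, used for the
#'   minimum-observation rule.
#' @param min_fraction Fraction of expected observations required before a
#'   smoothed value is emitted (default 0.2). Windows below the minimum
#'   produce no output row.
#' @param min_count Override the minimum count directly (e.g. `1` to waive
#'   gating); when supplied, `min_fraction`/`rate` are not consulted.
#' @return Tibble with `timestamp` and `value` (the smoothed series);
#'   possibly fewer rows than the input where gating suppressed output.
#' @export
rolling_median <- function(stream, aw_minutes, rate = NULL,
                           min_fraction = 0.2, min_count = NULL) {
  stopifnot(aw_minutes >= 0)
  if (aw_minutes == 0) return(stream)
  if (is.null(min_count)) {
    if (is.null(rate)) stop("supply `rate` or `min_count`", call. = FALSE)
    min_count <- min_observation_count(rate, aw_minutes, min_fraction)
  }
  ord <- order(stream$timestamp)
  t <- as.numeric(stream$timestamp)[ord]
  x <- stream$value[ord]
  med <- roll_median_time(t, x, aw_minutes * 60, as.integer(min_count))
  keep <- !is.na(med)
  tibble::tibble(timestamp = as_time(stream$timestamp[ord][keep]),
                 value = med[keep])
}

#' Clinical observation-schedule ticks
#'
#' Spot-check schedules are anchored to 06:00 local clock time: ticks fall
#' at 06:00 plus integer multiples of the interval. The first tick is the
#' earliest anchored time at or after `from`; the last is the latest at or
#' before `to`. Because every interval divides 24 h, coarser schedules are
#' exact subsets of finer ones.
#'
#' @param from,to POSIXct bounds (typically admission and discharge).
#' @param interval_min Schedule interval in minutes (15, 60, 240, 720).
#' @param anchor Clock time of the daily anchor, `"HH:MM"` (default
#'   `"06:00"`).
#' @return POSIXct vector of tick times (possibly empty).
#' @export
schedule_ticks <- function(from, to, interval_min, anchor = "06:00") {
  from <- as_time(from); to <- as_time(to)
  stopifnot(interval_min > 0)
  hm <- as.integer(strsplit(anchor, ":", fixed = TRUE)[[1]])
  day0 <- as.POSIXct(format(from, "%Y-%m-%d"), tz = .tz)
  anchor0 <- day0 + (hm[1] * 60 + hm[2]) * 60 - 86400  # day before, for safety
  step <- interval_min * 60
  k0 <- ceiling(as.numeric(from - anchor0, units = "secs") / step)
  k1 <- floor(as.numeric(to - anchor0, units = "secs") / step)
  if (k1 < k0) return(as_time(numeric()))
  anchor0 + seq(k0, k1) * step
}

#' Downsample a smoothed stream to a clinical observation schedule
#'
#' Emulates in-person spot checks: at each schedule tick the observation at
#' the tick itself is used; failing that, the nearest observation within the
#' tolerance (30 min by default, e.g. a 06:05 value can stand in for the
#' 06:00 observation when nothing closer exists). Equidistant candidates
#' resolve to the earlier observation. Ticks with nothing inside the
#' tolerance produce no output. For schedules finer than twice the
#' tolerance, the tolerance is capped at half the interval so an
#' observation can satisfy at most one tick.
#'
#' @param stream Smoothed (5-min rolling median) stream tibble with
#'   `timestamp`, `value` for one patient-signal.
#' @param interval_min Schedule interval in minutes.
#' @param from,to Stay bounds delimiting the ticks.
#' @param tolerance_min Nearest-observation tolerance (default 30).
#' @param anchor Daily anchor clock time (default `"06:00"`).
#' @return Tibble with `timestamp` (the tick), `value` (the selected
#'   observation's value), and `source_timestamp`.
#' @export
downsample <- function(stream, interval_min, from, to,
                       tolerance_min = 30, anchor = "06:00") {
  ticks <- schedule_ticks(from, to, interval_min, anchor)
  tol <- min(tolerance_min, interval_min / 2) * 60
  if (!length(ticks) || !nrow(stream)) {
    return(tibble::tibble(timestamp = as_time(numeric()), value = numeric(),
                          source_timestamp = as_time(numeric())))
  }
  ord <- order(stream$timestamp)
  t <- as.numeric(stream$timestamp)[ord]
  v <- stream$value[ord]
  tk <- as.numeric(ticks)
  i_prev <- findInterval(tk, t)              # last obs at or before the tick
  half_exclusive <- tolerance_min * 60 > tol  # capped: right edge exclusive
  d_prev <- ifelse(i_prev >= 1, tk - t[pmax(i_prev, 1)], Inf)
  i_next <- i_prev + 1
  d_next <- ifelse(i_next <= length(t), t[pmin(i_next, length(t))] - tk, Inf)
  ok_prev <- d_prev <= tol
  ok_next <- if (half_exclusive) d_next < tol else d_next <= tol
  use_prev <- ok_prev & (d_prev <= d_next | !ok_next)  # tie -> earlier
  use_next <- !use_prev & ok_next
  sel <- ifelse(use_prev, i_prev, ifelse(use_next, i_next, NA_integer_))
  keep <- !is.na(sel)
  tibble::tibble(
    timestamp = as_time(ticks[keep]),
    value = v[sel[keep]],
    source_timestamp = as_time(t[sel[keep]])
  )
}

#' Ratio of scheduled observation counts between two schedules
#'
#' Under full adherence a 15-min schedule produces 48 times as many
#' observations as a 12-hour schedule over the same day.
#'
#' @param interval_a,interval_b Schedule intervals in minutes.
#' @param duration_min Common duration; both intervals must divide it.
#' @return `tick_count(a) / tick_count(b)`.
#' @export
observation_ratio <- function(interval_a, interval_b, duration_min) {
  stopifnot(interval_a > 0, interval_b > 0, duration_min > 0)
  if (duration_min %% interval_a != 0 || duration_min %% interval_b != 0) {
    stop("both intervals must divide the duration", call. = FALSE)
  }
  (duration_min / interval_a) / (duration_min / interval_b)
}

#' Smooth every patient-signal stream of a cohort
#'
#' Applies [rolling_median()] per (patient, signal) with the signal's device
#' rate driving the minimum-observation rule.
#'
#' @param cohort A [vs_cohort()].
#' @param aw_minutes Aggregation window in minutes (0 = pass-through).
#' @param min_fraction Minimum-observation fraction (default 0.2).
#' @param rates Named device rates per signal (obs/min).
#' @return A new cohort whose observations are the smoothed streams.
#' @export
smooth_cohort <- function(cohort, aw_minutes, min_fraction = 0.2,
                          rates = DEVICE_RATES) {
  if (aw_minutes == 0) return(cohort)
  obs <- cohort$observations
  if (!nrow(obs)) return(cohort)
  key <- paste(obs$patient_id, obs$signal, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(obs)), key), function(idx) {
    sig <- obs$signal[idx[1]]
    sm <- rolling_median(obs[idx, c("timestamp", "value")], aw_minutes,
                         rate = rates[[sig]], min_fraction = min_fraction)
    if (!nrow(sm)) return(NULL)
    tibble::tibble(patient_id = obs$patient_id[idx[1]],
                   timestamp = sm$timestamp, signal = sig, value = sm$value)
  })
  out <- dplyr::bind_rows(pieces)
  if (!nrow(out)) out <- empty_observations()
  vs_cohort(observations = out, patients = cohort$patients,
            facts = cohort$facts,
            metadata = c(cohort$metadata, list(aw_minutes = aw_minutes)))
}

#' Downsample every patient-signal stream of a cohort
#'
#' @param cohort A cohort whose observations are already smoothed (the
#'   5-min rolling-median stream feeds the schedules).
#' @param interval_min Schedule interval in minutes.
#' @param tolerance_min Nearest-observation tolerance (default 30).
#' @param anchor Daily anchor (default `"06:00"`).
#' @return A new cohort on the scheduled grid.
#' @export
downsample_cohort <- function(cohort, interval_min, tolerance_min = 30,
                              anchor = "06:00") {
  obs <- cohort$observations
  pat <- cohort$patients
  if (!nrow(obs)) return(cohort)
  key <- paste(obs$patient_id, obs$signal, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(obs)), key), function(idx) {
    pid <- obs$patient_id[idx[1]]
    row <- pat[pat$patient_id == pid, ]
    ds <- downsample(obs[idx, c("timestamp", "value")], interval_min,
                     from = row$admit_timestamp[1],
                     to = row$discharge_timestamp[1],
                     tolerance_min = tolerance_min, anchor = anchor)
    if (!nrow(ds)) return(NULL)
    tibble::tibble(patient_id = pid, timestamp = ds$timestamp,
                   signal = obs$signal[idx[1]], value = ds$value)
  })
  out <- dplyr::bind_rows(pieces)
  if (!nrow(out)) out <- empty_observations()
  vs_cohort(observations = out, patients = pat, facts = cohort$facts,
            metadata = c(cohort$metadata, list(interval_min = interval_min)))
}
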