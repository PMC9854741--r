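# Shared fixture builders and independent oracles.

T0 <- as.POSIXct("2021-05-01 00:00:00", tz = "UTC")

# A stream tibble from offsets in minutes relative to `origin`.
make_stream <- function(min_offsets, values, origin = T0) {
  tibble::tibble(timestamp = origin + min_offsets * 60, value = values)
}

# A one-patient cohort assembled by hand.
manual_cohort <- function(obs = NULL, facts_min = numeric(),
                          admit = T0, los_days = 1,
                          patient_id = "P001", rates = c(PR = 2, SPO2 = 2,
                                                         RR = 1)) {
  discharge <- admit + los_days * 86400
  observations <- if (is.null(obs)) NULL else {
    tibble::tibble(patient_id = patient_id, timestamp = obs$timestamp,
                   signal = obs$signal, value = obs$value)
  }
  co <- vs_cohort(
    observations = observations,
    facts = if (length(facts_min)) {
      tibble::tibble(patient_id = patient_id, timestamp = admit +
                       facts_min * 60)
    } else NULL,
    patients = tibble::tibble(patient_id = patient_id,
                              admit_timestamp = admit,
                              discharge_timestamp = discharge)
  )
  co$metadata$config <- list(rates = rates)
  co
}

# Brute-force trailing-window median oracle: a per-timestamp scan.
brute_rolling_median <- function(stream, aw_minutes, min_count = 1) {
  ord <- order(stream$timestamp)
  t <- as.numeric(stream$timestamp)[ord]
  x <- stream$value[ord]
  w <- aw_minutes * 60
  out_t <- numeric(0); out_v <- numeric(0)
  for (i in seq_along(t)) {
    in_win <- t > t[i] - w & t <= t[i]
    if (sum(in_win) >= min_count) {
      out_t <- c(out_t, t[i])
      out_v <- c(out_v, median(x[in_win]))
    }
  }
  tibble::tibble(timestamp = as.POSIXct(out_t, tz = "UTC",
                                        origin = "1970-01-01"),
                 value = out_v)
}

# Brute-force combination-rule oracle: double loop over observation pairs.
brute_rule_triggers <- function(rule, streams) {
  met <- function(cond, v) {
    switch(cond$op,
           lt = v < cond$value, le = v <= cond$value,
           gt = v > cond$value, ge = v >= cond$value,
           between = v >= cond$lower & v <= cond$upper)
  }
  conds <- rule$conditions
  s1 <- streams[[conds[[1]]$signal]]
  if (is.null(s1) || !nrow(s1)) return(numeric(0))
  anchor <- as.numeric(s1$timestamp)[met(conds[[1]], s1$value)]
  if (length(conds) == 1) return(sort(anchor))
  keep <- logical(length(anchor))
  for (k in seq_along(anchor)) {
    ok <- TRUE
    for (j in seq_along(conds)[-1]) {
      sj <- streams[[conds[[j]]$signal]]
      tj <- if (is.null(sj)) numeric(0) else
        as.numeric(sj$timestamp)[met(conds[[j]], sj$value)]
      if (!length(tj) || min(abs(tj - anchor[k])) > rule$overlap_s) {
        ok <- FALSE; break
      }
    }
    keep[k] <- ok
  }
  sort(anchor[keep])
}

# Random sparse stream for property tests.
random_stream <- function(n, span_min = 60, origin = T0) {
  make_stream(sort(runif(n, 0, span_min)), round(runif(n, 80, 100), 1),
              origin = origin)
}

# Small fast generator config for pipeline tests.
test_config <- function(n_patients = 6, seed = 1, los_median = 2,
                        episodes = NULL, ...) {
  cohort_config(
    n_patients = n_patients,
    los = list(median_days = los_median, sdlog = 0.3, min_days = 1.05),
    rates = c(PR = 2, SPO2 = 2, RR = 1),
    episodes = episodes,
    seed = seed,
    ...
  )
}
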