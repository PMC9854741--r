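---
title: "Methods: simulating vital-sign alarms under observation schedules and median filters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating vital-sign alarms under observation schedules and median filters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alarmsim)
```

## The problem this package models

Healthcare-at-home programmes replace bedside observation with a
continuous upper-arm wearable reporting pulse rate (PR) and oxygen
saturation (SpO₂) at 30 observations/min and respiratory rate (RR) at
15/min. Rule-based physiological track-and-trigger systems turn those
streams into alarms, and three design levers control the burden that
reaches the care team:

* the **observation rate** — whether rules see the continuous stream or
  spot-check samples every 15 min to 12 h;
* the **aggregation window (AW)** — the span of the rolling median applied
  before rules are evaluated;
* the **rules themselves** — thresholds, ranges, and whether several
  signals must breach together.

`alarmsim` implements this full pipeline plus a synthetic cohort
generator, so the interactions of these levers can be studied and
regression-tested without access to patient data.

## Smoothing

The platform's filter is a *trailing* time-windowed median: at each
observation time $t$ the output is the median of all observations in
$(t - AW,\, t]$. Trailing (causal) alignment is the package's design
choice: a live alarming system cannot use future samples, and the
carry-over behaviour users observe in practice (alarms at the start of
the assessment window *after* a deterioration ends) presupposes it. The
vendor's exact alignment is not public; a centred variant would shift,
not remove, the phenomena studied here.

A smoothed value is only emitted when the window holds at least 20% of
the observations expected at the device rate, i.e.
$\lceil 0.2 \cdot \text{rate} \cdot AW \rceil$ — ceiling because the rule
is a count ("minimum number of observations") and ceiling is the
conservative reading. For downsampled streams the minimum is 1, since
each scheduled time carries one observation. The kernel is implemented in
C++ (two balanced multisets, monotone window pointers, $O(n \log w)$) and
is property-tested against a brute-force per-timestamp scan.

## Observation schedules

Spot-check datasets are built from the 5-min smoothed stream by sampling
at clock times anchored at 06:00 and stepping by 15 min, 1 h, 4 h or
12 h. If no observation falls exactly on a scheduled minute, the nearest
observation within ±30 min substitutes; equidistant candidates resolve to
the *earlier* observation. That tie-break is an inference from how the
nearest-observation rule is conventionally stated (a 06:05 value is used
only in the absence of anything between 05:55 and 06:04); it matters only
for exactly-equidistant pairs. For the 15-min schedule a ±30-min
tolerance would span neighbouring scheduled times, so the tolerance is
capped at half the interval (±7.5 min), making each observation
assignable to at most one tick. Because all intervals divide 24 h and
share the anchor, tick sets are nested — the foundation of several exact
monotonicity guarantees below.

## Alarm rules and trigger logs

Rules are declarative: one condition per signal (strict or inclusive
threshold, or an inclusive range), one to three conditions per rule, and
a 30-s overlap window for combination rules. Boundary semantics are kept
exactly as written — `SpO2 <= 91` fires at 91.0 while `SpO2 < 92` fires
at 91.99 but not 92.0 — and values are compared unrounded.

Two decisions were genuinely open:

* **Trigger anchor.** A combination rule logs its trigger at the
  breaching observation of its *first-listed* signal, with every other
  condition breached within the overlap window of that anchor. Any
  consistent anchor choice yields the same positive-window counts except
  when a 4-h window boundary falls inside the 30-s overlap.
* **Three-signal overlap semantics.** "Within 30 s of one another" can
  mean pairwise-to-anchor (maximum spread 60 s) or a single shared 30-s
  span. Both are implemented (`overlap_mode = "anchor"` / `"span"`,
  default `"anchor"` as the literal per-evaluation reading); span-mode
  triggers are a subset of anchor-mode triggers, and a test asserts
  that containment.

No refractory period deduplicates consecutive triggers: the assessment
windows binarise alarm activity anyway, so dedup would not change any
reported metric.

## Adherence and assessment windows

The stay $[T_a, T_d)$ is divided into 15-min windows aligned to
admission (clock alignment is available by flag; admission alignment is
the default because the stay itself is what is being divided). A window
is adherent if it contains at least one wearable-on-arm fact. Maximal
runs of adherent windows are "windows of wear"; a *removal* is a
wear-to-non-wear transition, so a patient monitored until discharge is
not counted as removing the device at the end.

Assessment windows are consecutive 4-h slices from admission (a trailing
partial slice is dropped — the inclusion rule needs all sixteen 15-min
windows) and are *included* when ≥ 8 of 16 quarter-hours are adherent.
Triggers in excluded windows are discarded; whether the original
platform counted them anywhere is unknown, and discarding is the
conservative choice consistent with "assessment requires adherence".
Early detection time is the gap from a window's first trigger to its
end, in $[0, 4]$ h, with 4 h meaning detection at the window start.

Two denominators were open and are configurable:

* **alarm rate** divides by length of stay in days (not monitored
  hours) — stay length is the only per-patient duration the metric
  definitions reference directly;
* **patient rate** divides by patients contributing at least one
  included assessment window (per-condition cohort sizes naturally vary
  with data availability); `denominator = "all"` uses the full cohort.

EDT is pooled over all positive windows of a condition (one median/IQR
per condition), not averaged per patient first, because it is defined
per window.

## The synthetic cohort generator

The generator's defaults encode the cohort it emulates: 76 patients,
lognormal stays with median 10 days (sdlog 0.7, matching the reported
IQR of ~9.7 days), pooled vital-sign medians PR 72.9 (IQR 19.4)
beats/min, RR 19.3 (6.4) breaths/min, SpO₂ 95.4 (3.6)%, median adherence
64.6% with about two removals per day and a median 2-h wear window.

Per patient it simulates:

* **Admission** at a uniformly random clock time in a configurable
  window, so partial first days (and their low day-0 adherence) arise
  naturally rather than being forced.
* **Wear/non-wear alternation** from a two-state renewal process:
  lognormal wear intervals with the configured 2-h median, lognormal
  non-wear intervals with a 1-h median, per-patient means chosen so the
  long-run wear fraction matches that patient's adherence level.
  Patient adherence levels are drawn on the logit scale
  (spread 0.5 ≈ 20-point IQR). Two fixed calibration constants
  (a −0.20 logit offset and a 1.24 cycle-rate factor) compensate for
  15-min-grid quantisation: wear runs spill into partially covered
  windows, inflating grid-measured adherence, while non-wear gaps
  shorter than a window vanish, deflating measured removals. They were
  fixed by simulating the generator against its own configuration and
  are not user knobs. The real cohort's reported adherence IQR (63.5
  points, range 0–100%) is heavier-tailed than the default spread; the
  default prioritises reliable recovery of the configured medians,
  which is what the tests pre-register, and the spread is configurable
  for tail studies.
* **Vitals during wear** at the device rates:
  per-patient baseline + circadian swing + AR(1) noise (+ episode
  ramp). The between-patient baseline SD is derived from the pooled IQR
  target after subtracting the circadian (amplitude²/2) and noise
  variances, so the pooled quartiles come out near the configured IQRs
  without a separate knob. Noise is first-order autocorrelated with a
  10-min time constant — no within-patient dynamics are published, and
  AR(1) is the simplest process that gives the median filter realistic
  short-term structure to remove. SpO₂ is clipped to [40, 100] (the
  physiologic ceiling makes its pooled distribution left-skewed, as
  observed); PR/RR are floored at 1.
* **Wearable-on-arm facts** every 5 min of wear, guaranteeing every
  15-min window overlapping wear by ≥ 5 min registers as adherent.
* **Determinism**: one root seed; per-patient substreams are derived
  from the patient index, so patient $k$ is identical whatever the
  cohort size.

**What the generator does not emulate:** motion artifacts and
signal-quality dropout, demographic covariates, correlated multi-signal
deterioration dynamics beyond the injected episode ramps, and the
extreme non-adherence tail. Tests passing on synthetic cohorts therefore
demonstrate the *pipeline's* correctness and directional behaviour, not
clinical performance on real data.

## Problem sizes used in tests and the acceptance script

All distributional targets and directional grid results are invariant to
the device rate, so most simulation tests run at reduced rates (PR/SpO₂
2/min or 0.2/min, RR half that) and moderate cohort sizes — the
package's chosen desk-scale experiment sizes:

* distribution recovery: 100 patients × 5 seeds at 0.2/0.2/0.1 obs/min;
* grid directionality: `deterioration_scenario_config()` — 12 patients,
  median 2-day stays, rates 2/2/1 obs/min, a third of patients given a
  12-h combined deterioration (RR plateau 27 with SpO₂ plateau 88,
  overlapping) so combination rules have genuine events to find,
  5 seeds;
* the exact device-count checks (43,200/21,600 per 24 h) use the true
  30/30/15 rates on a single fully adherent 1-day stay.

The deterioration scenario's episode design was chosen once, from the
observation that combination rules need sustained multi-signal events to
fire at coarse schedules (a 12-h episode guarantees every 12-h schedule
sees at least one in-episode tick).

## Numerical choices and degenerate inputs

* Median of an even-sized window is the mean of the two central values
  (matching `stats::median`).
* EDT is computed as `(end − T_i)/3600` on epoch seconds *before*
  division, keeping sub-second triggers exact.
* Dirty observation rows (unparseable timestamps, non-positive values,
  SpO₂ > 100, unknown signals) are dropped and counted at read time, not
  fatal — mirroring upstream screening of export data.
* A patient with no observations has *undefined* (NA) length of wear,
  distinct from the zero of a single observation; a patient with no data
  generates zero alarms regardless of configured vitals.
* Empty cohorts, empty streams, sparse windows below the minimum count,
  and conditions with no included windows all return empty/NA results
  with warnings rather than errors.

## Exact invariants the implementation guarantees

Because coarser schedule tick sets are subsets of finer ones, on a fixed
smoothed stream: triggers(coarse) ⊆ triggers(fine); hence positive
windows, patient rate and alarm rate are monotone non-decreasing in the
observation rate, and per-window EDT is never later under a finer
schedule. Lowering a "less-than" threshold shrinks the trigger set;
combination-rule triggers are subsets of each member condition's own
triggers. Wear and non-wear runs partition the stay exactly, and
patient contribution fractions sum to 100%. All of these are asserted as
property-style tests, alongside the brute-force oracle equivalence of the
rolling median and of combination-rule evaluation.

## Known limitations

* The benchmark grid shipped in `inst/extdata/` is reference output of a
  published evaluation on a private 76-patient dataset; the package
  recomputes *comparisons between its cells* but cannot reproduce the
  cells themselves without that dataset.
* Aggregation-window attenuation is a statistical direction, not a
  theorem: a long median filter can *carry over* a sustained episode
  into the following assessment window and locally increase its count,
  which the per-patient scenario example in the README shows on purpose.
* Timestamps are timezone-naive local clock times; the 06:00 anchor and
  day boundaries are interpreted in that clock, and daylight-saving
  shifts are not modelled.
* NEWS2 aggregate scoring (summing band scores across signals) is out of
  scope; ruleset `A1` uses NEWS2 threshold *bands* as trigger rules
  only.
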