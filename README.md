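# alarmsim

Alarm-burden simulation for remote vital-sign monitoring in
healthcare-at-home (HaH) programmes.

When acute care moves into a patient's home, bedside observation is
replaced by a wearable that streams pulse rate (PR, 30 obs/min), oxygen
saturation (SpO₂, 30 obs/min) and respiratory rate (RR, 15 obs/min) — over
43,000 PR observations per patient-day instead of a handful of nurse spot
checks. Every alarm now costs a phone call or a home visit, so the choices
a clinical team makes — how often vitals are *assessed*, how much the
stream is *smoothed* before threshold rules run, which *thresholds* and
*rule combinations* fire — directly trade early detection against alarm
fatigue. `alarmsim` makes those trade-offs measurable: it replays
declarative track-and-trigger rulesets over continuous streams under a
grid of observation schedules and median-filter windows, and reports the
resulting alarm burden.

## The pipeline

1. **Smoothing.** Each patient-signal stream is filtered with a trailing
   rolling median over an aggregation window *AW* ∈ {5 min, 15 min, 1 h,
   4 h}; a smoothed value is emitted only when the window holds ≥ 20% of
   the observations expected at the device rate.
2. **Observation schedules.** The 5-min smoothed stream (*VS_SD*) is
   downsampled to spot-check schedules every 15 min, 1 h, 4 h and 12 h
   (*VS_15 … VS_12*), anchored at 06:00, taking the nearest observation
   within ±30 min of each scheduled time.
3. **Alarm rules.** Three built-in rulesets: `A1` (NEWS2-band subset, five
   single-signal plus five three-signal range rules), `A2` (five
   conventional single-signal thresholds, e.g. SpO₂ < 92, RR > 20) and
   `A3` (three combination rules plus PR < 45). Combination rules require
   all signals to breach within a 30-s overlap window. Custom rulesets
   load from JSON.
4. **Metrics.** The stay is divided into 4-h assessment windows, included
   when ≥ 8 of their 16 15-min windows contain a wearable-on-arm fact.
   Per condition the package reports: total positive alarm windows
   (*W_AP*), patient rate (% of patients with ≥ 1 positive window), alarm
   rate (mean ± SD positive windows per patient-day), and early detection
   time (EDT = hours from the first trigger to the window's end; 4 h
   means criteria were met at the window start).

A synthetic cohort generator reproduces the structure of a 76-patient HaH
cohort — lognormal stays (median 10 days), pooled medians PR 72.9 (19.4)
beats/min, RR 19.3 (6.4) breaths/min, SpO₂ 95.4 (3.6)%, median adherence
64.6% with ~2 wearable removals/day — so the whole pipeline is testable
without patient data. Deterioration episodes (ramped plateaus) can be
injected as ground truth.

## Worked example

```r
library(alarmsim)

co <- generate_cohort(deterioration_scenario_config(seed = 1))
co
#> <vs_cohort> 12 patients, 101,876 observations, 4,218 wear facts
#>   length of stay: median 1.89 days

grid <- run_grid(co)
as.data.frame(grid[grid$ruleset == "A3", c(1:6, 8)])
#>   ruleset observation_rate aggregation_window W_AP patient_rate alarm_rate EDT_median
#> 1      A3            VS_12               AW_0    2         16.7      0.136       2.55
#> 2      A3             VS_4               AW_0    8         41.7      0.452       2.55
#> 3      A3             VS_1               AW_0   16         50.0      0.839       3.26
#> 4      A3            VS_15               AW_0   19         58.3      0.949       3.38
#> 5      A3            VS_SD                  -   22         66.7      1.049       3.56
#> 6      A3            VS_OD              AW_15   20         58.3      0.985       3.49
#> 7      A3            VS_OD               AW_1   18         50.0      0.912       3.67
#> 8      A3            VS_OD               AW_4   14         41.7      0.761       3.68
```

Reading the table: under the combination-heavy ruleset `A3`, moving from
12-hourly spot checks (`VS_12`) to the continuous smoothed stream
(`VS_SD`) multiplies positive alarm windows elevenfold (2 → 22) and
raises the patient rate from 16.7% to 66.7%, but detection happens about
an hour earlier inside each window (EDT 2.55 → 3.56 h). Growing the
median-filter window from 5 min to 4 h at device rate (`AW_15`…`AW_4`)
walks the burden back down (22 → 14) while EDT *increases* — smoothing
discards brief excursions, not detection lead.

Per-patient what-if analysis uses a single rule:

```r
rule <- alarm_rule("hypoxia+tachypnea",
                   list(vital_condition("SPO2", "lt", 90),
                        vital_condition("RR", "gt", 25)))
patient_scenario(co, "P001", rule)
#>   aw_minutes alarms_per_day_mean alarms_per_day_sd W_AP
#> 1          5                 1.5               2.1    3
#> 2         15                 1.5               2.1    3
#> 3         60                 1.5               2.1    3
#> 4        240                 2.0               1.4    4
```

Patient P001 carries a sustained 12-h deterioration, so smoothing cannot
erase it; the 4-h window even adds a carry-over alarm in the assessment
window after the episode ends, because the long median keeps reporting
low values after the vitals recover.

Threshold sensitivity is a configuration sweep, not code:

```r
run_sweep(co, "SPO2", "lt", c(91, 92))$deltas
#>   from to W_AP_delta W_AP_pct patient_rate_delta
#> 1   91 92         11     73.3               16.7
```

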