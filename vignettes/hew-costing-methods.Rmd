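---
title: "Costing community health worker services: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costing community health worker services: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hewcost)
```

## The costing model

Ethiopia's Health Extension Program deploys salaried health extension
workers (HEWs) who deliver primary care at health posts and in households.
`hewcost` implements a time-driven activity-based costing (TDABC) model for
such a program: the cost of one service encounter is the worker's salary
cost per minute of *billable* time, multiplied by the average duration of an
encounter of that type, and grossed up for non-salary program costs. The
pipeline runs from two field inputs — a time-motion observation log and a
district (Woreda) salary survey — to a full-cost-recovery fee schedule per
setting.

The chain, per setting $s \in \{\text{urban}, \text{rural}\}$:

1. **Billable time.** Activities with an identifiable individual or
   community user are billable; enabling activities (travel, recordkeeping,
   receiving training/supervision, idle time) are not. The scope of
   practice differs by setting: 12 billable categories urban, 14 rural
   (rural adds voluntary HIV counseling & testing and TB services).
2. **Encounter statistics.** For each billable category, the mean and
   sample SD of encounter durations after excluding encounters longer than
   `mean + 3 SD` (statistics computed once on the full sample, single
   pass), plus each category's share of all kept billable encounters.
3. **Salary per billable minute.** $r = S / M$, with $S$ the average of
   Woreda salary-range midpoints and $M$ the billable minutes per
   worker-month (kept billable minutes scaled to a 30-day month and
   averaged over workers).
4. **Campaign uplift.** Workers lose a fraction $f$ of the year (default
   0.1742, about 9 weeks) to seasonal campaigns with no billable
   encounters; spreading annual salary over the remaining time gives
   $r_u = r / (1 - f)$. An explicit `rate_uplifted` override exists because
   published rates may embed a different uplift convention (see below).
5. **Fees.** Base salary cost per encounter $b = r_u \bar d$; total fee
   $b (1 + m)$ with $m = 0.82$ (management 33% + overhead 49% of salary)
   or $m = 2.70$ (adding supplies at 188%). Dollar columns divide by the
   exchange rate (22 birr/US$).

## Numerical conventions

**Decimal half-up rounding.** Money is reported half-up: birr to 1 decimal,
US$ to 2. Base R's banker's rounding fails on exact ties
(`56.5 * 3.7 = 209.05` must report 209.1, not 209.0), and binary floating
point misstores such ties (`124.5 * 3.7` evaluates to `460.6499…`), so
`round_half_up()` snaps to 9 decimals before the half-up decision.

**Unrounded propagation vs printed-cell chaining.**
`build_fee_schedule()` has two modes. `"unrounded"` carries full precision
through the chain and rounds only in report columns — the right default for
new data. `"chained"` rounds the base cell first and computes the scenario
columns from the rounded cell, which is how published tables that chain
printed cells behave; `base_override` additionally allows injecting printed
base cells directly when the unrounded source durations behind them are
unavailable. `reproduce_fee_schedules(mode = "chained")` reproduces every
money cell of the packaged reference tables exactly
(`fee_table_discrepant_cells = 0` out of 156); in unrounded mode the
largest fees differ by up to ~1.6 birr, the footprint of chaining from
rounded cells.

**Reported per-minute rates.** The published headline rates 0.94 birr
(rural, 1513/1600) and 1.57 birr (urban, 1419/900) are *truncations* of
0.9456 and 1.5767 at 2 decimals, not half-up roundings (which would give
0.95 and 1.58). `salary_per_minute()` therefore returns the unrounded
quotient, and only the headline report applies the truncation convention.

**Uplift inconsistencies.** The published uplifted rates (1.25 rural, 1.88
urban) are not reproducible from any single rule: 0.94→1.25 is +33%,
1.57→1.88 is +20%, the narrative says +31%, and $1/(1-0.1742) = 1.211$.
Similarly 9 weeks/year is 17.31%, not the printed 17.42%. We flag rather
than guess: the formula default is $1/(1-f)$, and reproduction runs inject
the printed rates through the override. The package never silently
reconciles these.

**Cost shares vs multipliers.** The national cost shares (salary 27%,
supplies 55%, management 9%, overhead 13%) sum to 104%, and 55/27 = 204%
differs from the published supplies multiplier of 188%. The explicit
multiplier set (188/33/49, totals 270/82) is internally consistent and is
canonical; `derive_multipliers()` supports the share route but
`cost_shares()` warns whenever shares do not sum to 1.

**Outlier rule.** One-sided by default: the rule drops only values above
`mean + 3 SD`. Durations are bounded at zero, so on right-skewed positive
data nothing can sit 3 SDs below a positive mean; a `two_sided` switch
exists for symmetric data. Sample SD (n−1) is the default, matching
reported-SD convention, with a population-SD switch. The rule is
deliberately single-pass (no re-estimation after removal) and therefore
idempotent with respect to the original statistics. Degenerate inputs: one
observation has SD 0 and is always kept; an empty vector is an error.

**Month standardization.** 21 observation days map to a month by the
factor 30/21. Thirty days is a modeling choice — nothing in the study
design fixes it — exposed as `days_per_month`.

## The synthetic-data generator

No observation-level field data are deposited anywhere, so
`generate_observation_log()` emulates the study design: 2 workers in each
of 22 Woredas (44 total, split 22 urban / 22 rural in this package's
default), observed 21 consecutive days; per-category duration targets and
the encounter mix default to the packaged reference tables; billable
workload targets 900 (urban) / 1600 (rural) minutes per worker-month;
`generate_salary_survey()` emulates the 7-Woreda salary survey with range
midpoints averaging 1419 / 1513 birr/month exactly (offsets are re-centered
after drawing).

Design choices, made once:

* **Log-normal durations.** Only means and SDs of the true duration
  distributions are known; durations are positive and right-skewed, so a
  moment-matched log-normal is the natural family. The family is a modeling
  choice and is explicit in the config.
* **Post-exclusion calibration.** The published duration statistics are
  *post-exclusion* values. A log-normal matched to them raw and then run
  through the 3-SD cut recovers means a few percent low, because the upper
  tail carries a disproportionate share of minutes. The generator therefore
  calibrates the raw parameters by fixed point so that the moments of the
  distribution truncated at `raw mean + 3 raw SD` equal the targets.
* **Multinomial category counts.** Encounter categories are drawn
  multinomially per worker rather than i.i.d. per encounter, keeping the
  realized mix tight around the target.
* **Outlier injection.** With probability `outlier_rate` (default 0.005,
  under the ~1% the exclusion rule is meant to absorb) an encounter's
  duration is replaced by a value 8–12 target SDs above the mean. Injected
  extremes inflate the sample SD and can *mask* natural tail values from
  exclusion — real behavior of any single-pass SD rule, visible in the
  tests.
* **Enabling time.** Three non-billable records (travel, recordkeeping,
  training received) per worker-day, totalling ~240 minutes, fill the
  observed day; they exercise classification and never enter billable
  statistics.

What the generator does **not** emulate: day-of-week and seasonal structure,
inter-observer recording variation, worker-level heterogeneity in activity
mix, correlation between consecutive events, or Woreda-level non-salary
budget lines. Passing recovery tests therefore show the *pipeline* is
correct under the stated statistical structure — not that real field data
meet that structure.

## Problem sizes used in the tests

Unit tests run on logs of tens to hundreds of records with brute-force
oracles re-deriving every statistic independently. The parameter-recovery
test uses a 128-worker rural configuration (~10,000 encounters), checking
per-category means within 3 standard errors, the encounter mix within 2
percentage points, and the salary-per-minute rate within 5%; it completes
in a few seconds. The single-category calibration test uses ~500 TB-service
encounters against a ±0.3 minute band, the scale at which standard error
(2.4/√500 ≈ 0.11) makes that band meaningful.

## Known limitations

* Supplies are costed as a uniform 188% of salary; supply-intensive
  services (e.g. HIV testing) are under-priced relative to true supply use,
  and supply-light education services over-priced.
* The campaign uplift treats campaign time as pure opportunity cost; it
  does not price the campaigns themselves.
* The fee schedule allocates program cost; it is not a billing system and
  carries no demand model — raising fees does not leave encounter volumes
  unchanged in reality.
* Published upstream inconsistencies (uplift, cost-share totals) mean a
  fully-unrounded end-to-end run cannot and should not match the reference
  tables cell-for-cell; the chained mode exists precisely to separate
  arithmetic verification from those upstream choices.
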