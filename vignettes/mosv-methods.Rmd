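---
title: "Measuring missed opportunities for simultaneous vaccination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring missed opportunities for simultaneous vaccination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosvkit)
```

## The problem

A missed opportunity for simultaneous vaccination (MOSV) occurs when a
child attends a vaccination visit, receives at least one dose, but not
every dose they were eligible for that day under the national schedule. A
child who gets DPT1 at six weeks but not the co-scheduled OPV1 has a MOSV
for OPV1; if OPV1 arrives at a later visit the MOSV was *corrected*, and
the gap in days is avoidable time at risk of disease. Household coverage
surveys (DHS, MICS, EPI cluster surveys) record the dates on a child's
home-based record ("card"), which is enough to reconstruct every
vaccination visit and, against a schedule, every dose that was due at it —
so MOSV frequency and its consequences can be estimated at population
level from archived survey microdata.

`mosvkit` implements that analysis for children aged 12–23 completed
months at the survey: cohort filtering and date cleaning, visit
reconstruction, MOSV detection under two dose-accounting rules, the
standard visit-based (VB) and child-based (CB) indicators, counterfactual
achievable coverage, and time-to-correction distributions, with optional
survey weighting and stratification. A synthetic cohort generator with a
known ground-truth event table ties the whole pipeline to testable truth.

## Schedules and eligibility

A schedule is a table of doses: series membership (DPT1–DPT3 form series
"DPT"), a minimum age in days, a minimum interval in days from the
previous dose of the same series, an optional maximum age, and a
`summarized` flag saying whether the dose enters MOSV summaries. The two
bundled profiles hold the classic EPI calendar: BCG and an OPV birth dose
from birth (the birth dose creditable only through 13 days of age),
three-dose OPV and DPT series from 42 days at 28-day intervals (minimum
ages 42/70/98 days), and a first measles-containing dose at 270 days
(`"nigeria"`) or 365 days (`"colombia"`). These constants live in the YAML
configuration, not in code: WHO summary tables are the source for any
given country and year, and users can (and should) supply their own file
when the national calendar differs. Pentavalent input columns alias onto
the DPT series, since in later survey rounds DPT-containing coverage is
reported through penta.

Eligibility at a visit requires: the dose not already counted as received;
age (in whole days, `visit_date - dob`) at least the minimum age, and no
more than the maximum age where one is set; and for the second or third
dose of a series, the previous dose counted as received *strictly before*
the visit with the minimum interval elapsed. Comparisons use `>=` on whole
days with no grace period. Only eight doses are summarized (BCG, OPV1–3,
DPT1–3, MCV1): the OPV birth dose defines visits but, with its narrow
13-day window, is not a dose whose omission we summarise as a missed
opportunity. A maximum age limits *eligibility* only — a documented dose
given past it still counts as received.

## Cleaning and cohort selection

Dates that cannot be correct would otherwise fabricate visits, so they are
demoted to tick marks — the child keeps credit for the dose, but the date
no longer exists. Two passes in fixed order: first absolute checks (date
before birth, date after the survey), then series ordering, scanning each
series in dose order and demoting any dose dated on or before the last
retained dose of that series (`OUT_OF_ORDER` / `DUPLICATE_DATE_IN_SERIES`),
with later doses re-checked against the last retained date. Demoting the
later-numbered dose keeps the maximal consistent prefix of the series.
Cleaning is total and idempotent, and never changes which doses have
evidence — only the evidence kind.

A missing day of birth is imputed from the earliest dated birth dose
(minimum age 0) that falls in the reported birth month and year, else as
the first day of the month. Restricting to same-month birth doses
guarantees the imputed birth date never lands after a retained
vaccination date. Children missing month or year of birth are excluded.

The analysis cohort is: card seen, resolvable date of birth, age 12–23
completed months (floor of the calendar-month difference, adjusting for
day of month) at the survey, and at least one vaccination date surviving
cleaning. Each excluded child is tallied against the first filter it
fails, in that order, so tallies partition the input. Excluded children
are dropped from all MOSV outputs — they are unobservable, not zero-MOSV.

## Crude and valid dose accounting

Two accountings of "received" are supported. Under **crude** accounting,
any dated dose counts as itself regardless of age or interval — this
matches how most immunization programmes actually operate, with no
mechanism to re-administer a mistimed dose. Under **valid** accounting, a
dose given too early or after too short an interval is invalid, and later
administrations may fill earlier slots: per series, administered dated
doses are scanned in date order, each filling the lowest open slot when it
meets the slot's minimum age and the minimum interval from the previously
counted dose — so if the documented DPT1 came at four weeks, the
documented DPT2 counts as DPT1 and DPT3 as DPT2. Standalone doses are
validated on age alone.

Eligibility at a visit respects the minimum interval in *both* modes: the
crude/valid distinction governs which received doses count, not when a
dose is due — otherwise crude accounting would flag schedule-compliant
visits as missed opportunities.

Tick marks and caregiver recall mean "received, date unknown". Such doses
are credited as received before all dated visits: they never generate
events, never define visits, and satisfy series prerequisites with the
interval taken as met. Under valid accounting a tick dose keeps credit for
its own slot. This is a deliberate benefit-of-the-doubt rule — the
alternative (ignoring undated evidence for prerequisites) would
manufacture spurious eligibility for later series doses; the sensitivity
of results to this rule is a known open question and worth checking on
real data by comparing runs with tick-rich and tick-poor strata.

## Detection and indicators

`detect_mosvs()` walks the reconstructed visits in date order. At each
visit the receipt history is everything counted strictly before that
date; every summarized dose that was eligible but not administered (valid
mode: not administered-and-counted, possibly via reallocation) at the
visit is a missed opportunity. One event per (child, dose) records the
first missed visit, how many visits missed it, and whether a counted
administration exists at a later date (corrected, with its delay in days).

* **VB1** — per dose: proportion of dose-eligible visits with a MOSV for
  it.
* **VB2** — proportion of visits eligible for at least one summarized
  dose with at least one MOSV.
* **VB3** — mean MOSVs per eligible visit; **1/VB3** is the expected
  number of vaccination visits between MOSVs (undefined at VB3 = 0).
* **CB1** — per dose: among children with at least one dose-eligible
  visit, the proportion with at least one MOSV for it, split
  corrected/uncorrected.
* **CB2** — proportion of children with at least one MOSV for any
  summarized dose, split by whether all, some or none of the child's
  MOSVs were corrected.

Splits sum to their headline proportion by construction. Weighted
variants multiply each child (and each of their visits) by the survey
weight; unweighted counts are always reported alongside, and with equal
weights the two coincide exactly. No variance estimation or design-effect
adjustment is attempted: these are descriptive point estimates, and the
package deliberately reports numerators and denominators so users can
judge stability.

**Potential coverage** asks what coverage would have been had no
opportunity been missed: walk each child's visits crediting every
summarized dose eligible under the counterfactual history (initialized
with tick/recall credit), assuming all previously eligible doses had also
been given, with the visit date as the counterfactual receipt date. The
reported potential receipt set is the union of counterfactual credits and
observed (mode-counted) receipt: a dose administered while formally
ineligible (an early dose under crude accounting) stays covered, so
potential coverage can never fall below observed coverage. Observed
coverage under crude accounting counts any evidence including ticks;
under valid accounting, counted valid doses.

**Time to correction** summarises corrected events per dose as an
unweighted empirical CDF of delay days with inverse-ECDF (type-1)
quantiles at the 25th/50th/75th/90th percentiles — the smallest observed
delay whose cumulative fraction reaches the percentile, a reproducible
rule on small discrete samples. Distributions with fewer than 25
corrected events are flagged `small_n` and should be masked in
presentation.

`stratified_run()` repeats everything per stratum and overall. A strata
specification can union raw strata into super-strata (north/south);
children in no super-stratum stay in the overall rows only, matching how
a central region can be nationally included but excluded from a
north–south comparison.

## The synthetic cohort generator

`generate_cohort()` emulates the structure the analysis assumes, with
known truth. Per child: a date of birth placing age at survey in [12, 24)
completed months; schedule-anchored visits at target ages 0, 42, 70, 98
and 273 days (the EPI contact pattern — a deliberate choice over a
Poisson process, since it makes eligible-visit denominators predictable)
with normal jitter (SD 7 days, truncated at ±21) and 8% per-visit
dropout; at each attended visit every due dose is administered unless a
per-dose miss probability fires (defaults 0.10–0.18 by dose), and
previously missed doses are retried with the correction probability
(default 0.5). Cards are available with probability 0.6 (between the
Colombian and Nigerian survey experiences); card-less children carry
recall evidence only and are excluded by the card filter, as in real
surveys. Weights are lognormal (SD 0.5 on the log scale) over two strata.
Date-recording errors (default 2% per recorded date, equal shares
before-birth / after-survey / swap-within-series) are injected into the
recorded card only, in a separate pass after the truth simulation so the
truth is identical at any error rate.

A visit at which every due dose was withheld leaves no dated card entry:
it is invisible to any card-based analysis, and the generator records no
truth events for it. One consequence, documented rather than hidden: with
timing jitter a visit can fall before a parallel series dose's interval
is met, so occasionally the only due dose is one whose miss fired — the
guaranteed-miss trial is censored and the raw per-visit miss rate is
estimated slightly low. The parameter-recovery test therefore runs with
exact visit timing and with the retry probability set so every eligible
visit is an independent Bernoulli trial; all other checks keep the
default jitter. A missed dose also blocks downstream series doses until
given — cascades are expected, not an artifact.

What the generator does *not* emulate: real card-availability selection
effects (card-less children are missing at random here, not by
health-seeking behaviour), digit-preference and transcription error
patterns beyond the three injected types, clustered sampling designs, or
catch-up campaigns. Passing tests therefore demonstrate correctness of
the accounting and estimation machinery under the stated data model, not
robustness to every pathology of real survey data.

## Numerical and design choices

* All date arithmetic is in whole days; month arithmetic only for the age
  filter (completed months).
* Exact-day boundaries are inclusive: a dose at exactly the minimum age
  or interval is eligible/valid.
* Zero denominators yield `NA` proportions with their zero counts
  reported.
* The analysis path is fully deterministic; all randomness is confined to
  the generator and governed by one integer seed.
* CSV outputs are sorted by (stratum, dose, mode) with proportions
  rounded to four decimals, so re-running a configuration byte-reproduces
  the files.
* Problem sizes in the test suite (500–2000 children, two to three seeds
  per property) were chosen so the full suite exercises every path at
  desk scale in a few minutes.

## Limitations

Only one-, two- and three-dose series are handled; booster schedules and
longer series would need slot logic beyond three. MOSVs at
non-vaccination (curative-care) contacts are invisible to card data, so
all rates here are lower bounds on missed opportunities generally.
Results describe card-holding children only; where cards are scarce the
cohort may be unrepresentative. Dates that are wrong but not impossible
pass cleaning undetected.
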