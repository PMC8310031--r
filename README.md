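# mosvkit

Missed opportunities for simultaneous vaccination (MOSV) from household
coverage surveys.

A MOSV occurs when a child attends a vaccination visit, receives at least
one dose, but not every dose they were eligible for that day under the
national immunization schedule. From child-level vaccination-date records
of the kind collected by DHS/MICS/EPI surveys, `mosvkit` reconstructs
vaccination visits, detects MOSVs, and quantifies their frequency and
consequences. It is aimed at immunization programme analysts and survey
epidemiologists working with card-based (home-based record) date data.

## What it computes

With eligible visits (visits at which the child was due a given dose, or
any summarized dose) as denominators:

- **VB1** — proportion of dose-eligible visits with a MOSV for that dose;
  **VB2** — proportion of visits with ≥1 MOSV for any dose;
  **VB3** — mean MOSVs per eligible visit, and **1/VB3**, the number of
  vaccination visits between MOSVs.
- **CB1** — proportion of children (among those with ≥1 dose-eligible
  visit) with ≥1 MOSV for the dose, split corrected/uncorrected;
  **CB2** — proportion with ≥1 MOSV for any dose, split by whether all,
  some or none were corrected by the survey.
- **Potential coverage** — the counterfactual coverage had every due dose
  been given at every attended visit, versus observed coverage.
- **Time to correction** — ECDF and 25/50/75/90th percentiles of the delay
  (days) from first missed opportunity to eventual receipt, flagged when
  n < 25.

Two dose accountings are supported: **crude** (any dated dose counts) and
**valid** (doses given too early or at too short an interval are invalid,
and later administrations may fill earlier series slots — a documented
DPT2 can count as DPT1). Estimates come weighted (child-level survey
weights) and unweighted, overall and per stratum, with super-strata
(e.g. north = union of regions) supported.

The pipeline: read CSV → impute missing birth day → demote impossible
dates (before birth, after survey, series out of order or duplicated) to
tick marks so the child keeps credit → select the 12–23-month card cohort
→ reconstruct visits from dated entries → detect events → aggregate.
Schedules (minimum ages, intervals, maximum ages, series, aliases) are
YAML/JSON configuration; two classic EPI profiles ship with the package.

A synthetic DHS-like cohort generator (`generate_cohort()`) with a known
ground-truth event table makes the full pipeline testable without
registration-gated survey microdata.

## Worked example

```r
library(mosvkit)
sched <- epi_schedule("nigeria")          # BCG+OPV0 at birth, OPV/DPT x3, MCV1 at 9 m
g     <- generate_cohort(synth_params(n_children = 500, seed = 42), sched)
co    <- clean_dates(impute_birth_day(g$cohort, sched), sched)
sel   <- select_cohort(co)
sel$counts
#>          included  excluded_no_card   excluded_no_dob      excluded_age excluded_no_dates
#>               306               194                 0                 0                 0

vb <- visit_based(sel$cohort, sched, "crude")
vb$overall[, c("n_eligible_visits", "vb2", "vb3", "vb3_inverse")]
#>  n_eligible_visits       vb2       vb3 vb3_inverse
#>               1110 0.2585586 0.2738739    3.651316
```

25.9% of the 1110 dose-eligible visits produced at least one MOSV; on
average 0.27 MOSVs per eligible visit, i.e. one MOSV every ~3.7
vaccination visits. Per child:

```r
cb <- child_based(sel$cohort, sched, "crude")
cb$overall[, c("n_children_eligible", "cb2", "cb2_all_corrected",
               "cb2_some_corrected", "cb2_none_corrected")]
#>  n_children_eligible       cb2 cb2_all_corrected cb2_some_corrected cb2_none_corrected
#>                  306 0.5915033         0.2156863           0.124183           0.251634
```

59.2% of children experienced at least one MOSV; for 25.2% of children
none of their missed doses had been given by the survey. Consequences:

```r
pc <- potential_coverage(sel$cohort, sched, "valid")
pc[pc$dose == "DPT3", c("observed_weighted", "potential_weighted", "difference_weighted")]
#>  observed_weighted potential_weighted difference_weighted
#>          0.4187058          0.6026013           0.1838955

ev <- detect_mosvs(sel$cohort, sched, "crude")
time_to_correction(ev, "DPT1")
#> <mosv_delay> DPT1: n=37
#> q25 q50 q75 q90
#>  22  32  60 218
```

Valid-dose DPT3 coverage would have been 18.4 percentage points higher
(60.3% instead of 41.9%) had no opportunity been missed; among the 37
corrected DPT1 misses the median delay was 32 days.

`run_analysis()` (or `mosvkit analyze`) runs the whole pipeline from a
config and writes tidy per-stratum CSVs plus a manifest;
`stratified_run()` does the same in-memory. See the methods vignette
(`vignettes/mosv-methods.Rmd`) for the model, assumptions and design
choices.

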