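---
title: "Needs-based planning of the oral health workforce with oralforce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Needs-based planning of the oral health workforce with oralforce}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oralforce)
```

## The planning problem

Workforce planning for dentistry has traditionally relied on crude
dentist-to-population ratios, which ignore the level of oral health need in
the population and how it changes. A needs-based approach instead sizes the
workforce from the services the population actually requires: demography
times health status times service use, converted into clinical time and then
into full-time-equivalent (FTE) practitioners. `oralforce` implements such a
simulation as two components compared year by year over a planning horizon:

* **Provider supply** — a stock-flow projection of the practitioner
  register, converted to FTE via participation and activity rates.
* **Provider requirement** — survey-estimated per-capita visit rates applied
  to population projections, weighted by per-visit service times and divided
  by the annual clinical capacity of one FTE.

The headline output is the ratio of FTE supply to FTE requirement per year,
under a baseline parameterisation and under named scenario overrides.

## Provider supply

The registered stock follows the annual recursion

$$ S_t = S_{t-1} + \mathrm{inflow}_t + \mathrm{graduates}_t -
\mathrm{outflow}_t, $$

where "stock at the end of year $t$" is identical to "stock at the start of
year $t+1$". Inflows cover foreign-trained registrants, domestically trained
registrants returning from abroad, and returns from a period of absence;
outflows cover emigration, absence and retirement/death. `project_stock()`
carries flow assumptions forward from the last specified year when a year is
missing — the minimal assumption when future flows are simply "based on"
current ones — and floors the stock at zero with a warning if outflows ever
exceed it. Headcounts are carried at full precision throughout; only the
reporting layer rounds.

Graduate output is the intake adjusted for non-progression to year 2,
attrition thereafter, and the share entering domestic employment:
`new_graduates(graduate_pipeline(100, 0.10, 0.05, 0.80))` gives 68.4. The
cohort entering in year $y$ joins the stock at the end of year
$y + \texttt{course\_length}$ (default 5). The pipeline is treated as
steady-state: cohorts are assumed to have entered in every year before the
horizon as well, so graduates arrive in every projection year. A pipeline
that starts cold would differ only in the first `course_length` years.

FTE supply adjusts headcount for who actually practises and for how much:

$$ \mathrm{FTE}_t = S_t \times \text{participation} \times \text{activity},
\qquad \text{activity} = (1 - q) + q\,h, $$

with part-time share $q$ and part-time hours fraction $h$. The defaults —
participation 0.95, $q = 0.30$, $h = 0.50$, hence activity 0.85 — reflect a
register that includes non-practising members and a substantial part-time
segment.

Where two register snapshots are available, `diff_registers()` estimates the
flows between them. Entries only in the later snapshot are inflows,
classified from qualification origin and year: a domestic registrant
qualified *after* the earlier snapshot year is a new graduate, other
domestic registrants are returning-domestic, foreign-qualified registrants
are foreign-trained. Entries only in the earlier snapshot are outflows;
their subtype is not identifiable from the register alone, so they are
reported as one unclassified count, optionally split by a
qualification-age heuristic (qualified at least 41 years before the later
snapshot, hence assumed at least 65 years old, is attributed to
retirement).

## Provider requirement

The requirement side is a chain of linear operations.

**Need rates.** Survey microdata supply, per respondent: sex, age, oral
health status (natural-teeth category, food/pain problem), whether they
visited a dentist in the last 12 months, how often, and the type of the last
visit (check-up/exam/cleaning, routine treatment, emergency treatment).
Respondents are grouped into eight strata — sex crossed with age bands
15–44, 45–64, 65–74 and 75+ (upper bounds inclusive) — and
`estimate_need_rates()` computes the per-capita annual visit rate as the
mean implied visit count, split across the three visit types.

Three modelling choices matter here:

* *Frequency mapping.* The survey instrument records an ordinal frequency
  category, not a count. The default mapping is once → 1, twice → 2,
  three-or-more → 3.5 visits/year; the open-ended top category needs a
  representative value and 3.5 is a conservative midpoint. Because results
  are sensitive to this choice the mapping is a first-class, validated
  parameter (`frequency_mapping()`), echoed into output metadata.
* *Visit-type attribution.* The survey records only the *most recent*
  visit's type, so the stratum-level distribution of last-visit types among
  visitors is applied to all of the stratum's visits. The three type rates
  therefore sum exactly to the stratum total by construction.
* *Weights.* Estimation is unweighted by default; design weights can be
  switched on (`use_weights = TRUE`), in which case estimates are invariant
  to uniform weight rescaling and the Kish effective sample size is
  reported.

Health-status stratification (`use_health_status = TRUE`) is available for
description, but the requirement calculation aggregates over it: population
projections carry no oral-health dimension, and health status is held
constant over the horizon anyway — a recognised simplification that likely
*overstates* future requirement, since oral health tends to improve across
cohorts. Strata with no respondents are flagged `defined = FALSE`, never
silently zero-filled; feeding an undefined rate to a populated stratum is an
error the caller must resolve explicitly.

`bootstrap_need_rates()` provides percentile intervals from a stratified
nonparametric bootstrap (whole respondent records resampled within
stratum), reproducible for a fixed seed.

**From rates to FTEs.** For year $t$ and stratum $s$,

$$ \mathrm{visits}_{s,k,t} = N_{s,t} \, r_{s,k}, \qquad
\mathrm{minutes}_t = \sum_{s,k} \mathrm{visits}_{s,k,t} \, m_k, \qquad
\mathrm{requirement}_t = \mathrm{minutes}_t / C, $$

with per-type service times $m_k$ (defaults 20/30/40 minutes for
check-up/routine/emergency) and annual capacity

$$ C = \text{weeks} \times \text{hours} \times \text{clinical fraction}
\times \text{adult-care share} \times 60 . $$

The default 45 weeks × 39 h × 0.90 gives 94 770 minutes, i.e. 1579.5 h,
displayed as 1580 h by the reporting layer. `adult_care_share` scales
capacity for time spent with patients outside the modelled 15+ population:
setting it to 0.8 (a dentist spending 20% of clinical time with children)
reduces weekly hours available to adults to 80% and hence multiplies the
requirement by exactly 1.25. Requirement is linear in population and in
every per-capita rate, additive across strata, and inversely proportional
to capacity — properties the test suite asserts directly.

Population years missing from the input table are linearly interpolated
between provided projection years; extrapolating beyond the table is an
error rather than a silent guess.

## Scenarios

A scenario (`scenario_spec()`) is a named partial override of the baseline
parameter set; `apply_overrides()` returns a modified copy (the baseline is
never mutated), rejects unknown paths by name and re-validates every touched
parameter group. `default_scenarios()` bundles the three standard
sensitivity analyses: longer service times (30/40/60 minutes), the
child-care capacity adjustment (`adult_care_share = 0.8`), and both
combined. `compare_scenarios()` emits a tidy `scenario × year` table;
`plot_supply_requirement_ratio()` charts the ratio paths.

Ratios are always computed from unrounded FTE values and only rounded (one
decimal) for display, so printed-rounding artefacts never compound.

## The synthetic-data generator

`synthetic_truth()` pins down a complete data-generating process so every
stage of the pipeline can be exercised against known parameters without any
external download: per-stratum visit participation (0.40–0.70), categorical
frequency and visit-type distributions (check-up-heavy), health-status
distributions, base population counts (~3.6 million adults) with faster
growth in the older bands, and planted register flows. The defaults sketch a
small European country but are arbitrary and carry no claim of matching any
real register or survey.

`gen_survey()`, `gen_population()` and `gen_register_pair()` are pure
functions of (truth, size, seed); each derives an independent RNG stream
from the seed, so regenerating one artefact never perturbs another.
`true_need_rates()` returns the analytic rates the estimator should recover.

What the generator deliberately does **not** emulate: the multistage sampling
design of a real interview survey (PSUs, post-stratification weights), item
non-response, correlation between health status and visit behaviour, and
age structure within the register (flows are planted counts, not hazards).
Passing tests therefore demonstrate the *estimators and accounting* are
correct, not that real survey estimates would be unbiased under a complex
design.

## Numerical choices and degenerate inputs

* All arithmetic is double precision, unrounded; reporting helpers
  (`report_fte()`, `report_hours()`, `report_ratio()`) round to integer
  FTEs/hours and one-decimal ratios.
* Stock-flow conservation is exact to machine precision and asserted to
  1e-9 over 30-year projections.
* Stock is floored at zero (with a warning) rather than allowed negative.
* Zero requirement yields an `NA` ratio plus a warning, never a division by
  zero.
* Under-15 respondents and records with missing core fields are dropped with
  logged counts, not imputed.
* Validation failures (probabilities outside [0, 1], non-monotone frequency
  mappings, unknown override paths, incomplete population grids) fail fast
  naming the offending field.

## Simulation sizes used by the test suite

The packaged checks run, by the package's own choice of problem size:
parameter recovery at n = 50 000 respondents (all eight stratum rates within
three standard errors of truth); estimator consistency across
n ∈ {500, 5000, 50 000}; bootstrap interval coverage over 30 replicates of
n = 2000 with B = 200 resamples (observed coverage ≥ 0.90 for nominal 95%
intervals); 30-year stock projections; and an end-to-end run whose FTE
requirement is compared with the analytic expectation
(truth rates × population × times / capacity) within a delta-method
Monte-Carlo bound.

## Known limitations

* Health status (and hence per-capita need) is held constant over the
  horizon; improving oral health would lower the true future requirement.
* The stock is a single aggregate — no age structure, so retirement waves
  cannot emerge endogenously; intra-year timing of flows is not modelled.
* Cosmetic demand, skill mix (hygienists, therapists) and economic costing
  are out of scope.
* Absolute published register figures are not derivable from register
  snapshots alone: exclusions (public dental service, specialists,
  academics) require auxiliary labels the register does not carry, which is
  why `practice_status` accepts an explicit `excluded` tag and outflow
  subtypes are reported as unclassified.
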