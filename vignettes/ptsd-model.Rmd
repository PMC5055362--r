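---
title: "A stock-and-flow model of PTSD in the military/veteran system: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stock-and-flow model of PTSD in the military/veteran system: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptsdflow)
```

## The model and its assumptions

`ptsdflow` treats PTSD in the US military and veteran populations as a
continuous-time compartmental system.  Seven stocks, in persons, are
connected by nine pathways plus a death outflow from every stock:

* **military**: `healthy_mil`, `ill_undiag_mil`, `ill_diag_mil`;
* **post-military**: `healthy_vet`, `ill_undiag_vet`, and the diagnosed
  veterans split into `ill_diag_vet_recent` (cases diagnosed from 2000
  onward, the Iraq/Afghanistan era) and `ill_diag_vet_pre2000` (the legacy
  cohort, which only decays through treatment and death).

Every flow is first-order in its source stock (a product of a fractional
annual rate and a population), which embodies three modelling assumptions:

1. **Exponential residence times.** Diagnosis and treatment delays are
   first-order ("exponential") delays.  Higher-order delay chains would
   sharpen the timing of the veteran peak but are out of scope.
2. **Incidence is deployment-driven.** New PTSD cases arise only among the
   deployed fraction of healthy personnel, at rate
   `trauma_exposure_rate * deployment(t) * p_ptsd_given_trauma`, linear in
   the deployment fraction.  Scenarios are therefore parameterised purely
   by the deployment trajectory.
3. **The military block is upstream.** Nothing flows from the veteran
   sector back into the military, so military dynamics are fully
   determined by the exogenous drivers.  This is what makes partial-model
   calibration clean (see below).

Recruitment enters mostly healthy; a small fraction
(`frac_recruit_ptsd_history`) enters the ill-undiagnosed military stock,
representing recruits with a pre-enlistment trauma history.  Those recruits
are booked as undiagnosed rather than diagnosed: a known, disclosed PTSD
diagnosis would typically bar enlistment, so what enters the system
unnoticed is undetected illness.

## Parameters

Rates are fractional annual rates (1/year), fractions are dimensionless in
[0, 1], costs are constant 2012 USD per diagnosed patient per year.  The
shipped defaults (`default_params()`, `inst/extdata/parameters.csv`) come
in two provenance classes, tagged per entry in the `source` column:

* **Literature-anchored**: `p_ptsd_given_trauma = 0.17`,
  `frac_reveal_mil = 0.043/yr`, `frac_treat_mil = 0.125/yr`,
  `cost_per_patient_mil = $4,500`, `cost_per_patient_va = $6,244`, and the
  scenario deployment levels (1%/2%/5%).
* **Package calibrations / synthetic placeholders**: everything else.
  `trauma_exposure_rate = 3.4/yr` (times 0.17, roughly a 58%/yr PTSD
  incidence among personnel deployed to intense/combat zones),
  `separation_rate_healthy = 0.10/yr` (a ~10-year mean career),
  `separation_rate_undiag = 0.13/yr` (undetected illness shortens
  careers), `discharge_rate_diag = 0.116/yr`,
  `frac_reveal_vet = 0.18/yr` (a ~5-year mean delay between separation
  and presenting at a clinic), `frac_treat_vet = 0.067/yr` (successful
  treatment is slower in the VA than in service), military death rates
  0.001/yr and veteran death rates 0.021–0.038/yr.  The 2000 initial
  stocks put ~2.1M persons in the military sector and ~4.1M in the
  modelled veteran sector (the VA-relevant population, not all living
  veterans), including a 1.18M-person undiagnosed-ill veteran reservoir
  from pre-2000 conflicts and 100k already-diagnosed legacy patients.

The calibrated values were chosen so that the base run reproduces the
historical pattern (a military diagnosis rate rising from ~1,700/yr in
2000 to ~17,900/yr around 2010 and declining after 2012) and the projected
2025 outcomes under the three deployment scenarios; the historical series
shipped in `inst/extdata/history.csv` are *synthetic reconstructions*
generated from that calibrated base run and rounded to three significant
digits, because the underlying agency tables are not redistributed with
the package.  The deployment trajectory is constructed to satisfy its
published summary constraints exactly: a 2001–2014 mean of 6.6%, a maximum
of 10.8% in 2008, and 1% by 2014.

## Numerical scheme

Integration is explicit Euler with `dt = 1/16` year, the common system
dynamics convention.  Two guards make the scheme robust in extreme
conditions:

* **Flow capping**: within each step, every stock's total outflow is
  scaled so that at most `stock/dt` can leave; because capping only ever
  *reduces* inflows elsewhere, one pass guarantees global non-negativity.
  Capped flows are what is recorded and what crosses the military/veteran
  boundary, so conservation is exact.
* **Rounding snap**: a capped stock lands on zero up to float rounding;
  residues below zero smaller than 1e-8 (relative) are snapped to zero,
  anything larger aborts as an internal error.

A refinement test (part of the test suite) checks that halving `dt`
changes the 2025 headline outputs by less than 0.5%.  Runs are
deterministic: identical inputs give bit-identical trajectories.

## Calibration

The payoff is a scaled weighted sum of squares,
`sum_s w_s sum_t ((model - data)/scale_s)^2` with `scale_s` the mean
absolute value of series *s*, making cases (10^4) and dollars (10^9)
commensurable.  `calibrate_partial()` minimises it with derivative-free
local searches — Brent's method for one free parameter, otherwise
Nelder-Mead on logit-transformed coordinates so box bounds are respected —
from `n_starts` Latin-hypercube start points under a fixed seed.

*Partial* calibration means fitting a block whose boundary inflows are
driven by data instead of the rest of the model: the military block is fit
with the observed deployment forcing (it has no other boundary inflows);
the veteran block is fit with the three separation flows supplied as
forcings (`drive`).  This mirrors the feed-forward structure and keeps the
two parameter groups from confounding each other.

`identifiability_report()` scans each estimate on a multiplicative grid
and reports the interval in which the payoff stays below twice its
minimum; parameters whose interval spans more than a factor of 10 are
flagged as weakly identified rather than silently reported.

## Scenarios, policies, and when they act

Scenarios splice a constant future deployment (1%, 2% or 5%) onto the
historical series from 2015.0 — the first year after the data period; the
data edge (2014, at 1%) makes scenario 1 seamless.  Policies multiply
`frac_reveal_mil`, `frac_treat_mil` and/or `p_ptsd_given_trauma` (capped
at 1).  In `run_grid()` the multipliers act from `policy_start` (default
2015.0): interventions are prospective what-ifs, so the replicated
2000–2014 history is identical in every grid cell.  Applying them from
2000 would retroactively rewrite the historical burden and roughly halve
the 2025 legacy under the prevention policy, which is not the question the
grid asks.

Total-system prevalence pools numerators and denominators across sectors
rather than averaging two prevalences.  The default prevalence definition
is `all_ill` (undiagnosed + diagnosed over the sector population): with a
~2.1M-person military sector this reproduces the observed ~6–7% military
prevalence scale in 2025, whereas `diagnosed_only` (28k diagnosed) would
imply ~1–2% under any plausible force size.  `diagnosed_only` remains
available as a toggle everywhere a prevalence is computed.

## The war-pulse counterfactual

`counterfactual_params()` freezes every exogenous driver: recruitment
constant, peacetime deployment zero, and PTSD-history recruitment switched
off.  The last point matters: with it on, the ill stocks have a nonzero
steady-state floor and "recovery to a fraction of the pulse peak" is
ill-defined.  The steady state is obtained by a 500-year burn-in and
verified (net flow below 1e-6 of each stock per year; re-simulation from
it stays constant).  The pulse steps deployment to 10% for war years 0–5
and back, and the response runs 80–120 years.

"PTSD-free" is operationalised as the veteran ill population (undiagnosed
plus diagnosed, recent cohort) falling below a threshold fraction of its
peak; since exponential tails never reach zero, the threshold is a
modelling choice, defaulting to 0.01 with
`recovery_threshold_scan()` documenting the sensitivity over
[0.005, 0.05].

A structural property of this calibration is worth stating plainly.
Holding ~500k diagnosed VA patients in 2025 — the scale implied by the
cost projections — requires veteran outflow poles no faster than
~0.09/yr, i.e. mean ill residence times beyond a decade.  Those same slow
poles govern the pulse decay, so the calibrated system recovers to 5% of
its veteran peak only ~55 years after the war starts (~74 years to 1%),
not the ~40–45 years sometimes quoted for post-war psychological
recovery.  Parameterisations that do recover within 45 years drain the
veteran sector so fast that the simulated VA caseload and costs fall ~40%
below their 2025 anchors.  We chose the parameterisation that honours the
caseload, cost and prevalence anchors and report the longer recovery
times as a finding about first-order stock-and-flow topologies at these
scales; the ~7-year lag of the veteran peak behind the war's end is
robust to this choice.

## The synthetic-history generator

`generate_synthetic_history()` runs the model, samples annual outputs and
multiplies them by mean-one lognormal noise with a requested coefficient
of variation (`sdlog = sqrt(log(1 + cv^2))`, mean-corrected), under a
fixed seed.  It emulates *observation* noise on an otherwise
perfectly-specified data-generating process.  It does **not** emulate the
features that make real calibration hard: structural misspecification,
correlated errors across years and between series, inconsistent
definitions across agencies, or revisions.  Passing parameter-recovery
tests (noise-free recovery of 0.043/yr and 0.125/yr to <1%, median
recovery within 5% under 5% noise across 20 replicates) therefore
demonstrates that the estimation machinery is correct and the parameters
are identifiable from these series — not that estimates from real agency
data would be unbiased.

## Problem sizes and runtime

The test suite and acceptance script use the model at its production
resolution: 25-year runs at `dt = 1/16` (401 grid points, ~10 ms each),
the full 3x8 policy grid, 120-year pulse responses, and multi-start
calibrations with 2–6 starts on 14-year windows.  The whole suite runs in
well under a minute on a single CPU; the acceptance script in a few
seconds.

## Known limitations

* Deployment is exogenous; there is no feedback from PTSD burden or costs
  to decisions about wars, and no macro-level drivers.
* No comorbidity, stigma or barrier-to-care feedbacks; treatment is a
  dichotomous cured/ill switch; no age or gender structure (first-order
  death rates stand in for cohort ageing, which is why very-long-horizon
  tails should not be over-interpreted).
* The veteran sector is the VA-relevant population, not all living US
  veterans; its 2000 composition is a calibrated reconstruction.
* Historical fixtures are model-generated reconstructions under printed
  constraints, suitable for testing and demonstration, not for empirical
  re-estimation.
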