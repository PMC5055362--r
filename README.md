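# ptsdflow

A system-dynamics (stock-and-flow) simulation of the population of US
military personnel and veterans affected by post-traumatic stress disorder
(PTSD), for health-policy analysts and simulation modellers who want to ask
*what-if* questions about future wars, screening, treatment and prevention
policies, and their long-run consequences for the military and the
Department of Veterans Affairs (VA) as one connected "system of systems".

## The model

Two sectors — military and post-military — each hold three stages:
healthy, ill-undiagnosed and ill-diagnosed, in persons.  The diagnosed
veteran population is split into a recent (Iraq/Afghanistan-era) cohort and
a pre-2000 cohort.  Nine pathways connect the stages; every stock also has
a death outflow.  Each stock evolves as the integral of inflows minus
outflows,

```
dS_i/dt  =  sum(inflows_i)  -  sum(outflows_i)
```

integrated with an explicit Euler scheme (dt = 1/16 year) with per-step
flow capping so no stock can be driven negative.  The key rate equations
are product-form first-order flows:

| pathway | flow (persons/year) |
|---|---|
| 1a/1b recruitment | `R(t) (1-h)` healthy, `R(t) h` with PTSD history |
| 2 onset | `tau * d(t) * p * healthy_mil` |
| 3 diagnosis (military) | `0.043 * ill_undiag_mil` |
| 4 treatment (military) | `0.125 * ill_diag_mil` |
| 5/6/7 separation, discharge | `rate * source stock` |
| 8 diagnosis (veterans) | `frac_reveal_vet * ill_undiag_vet` |
| 9 treatment (veterans) | `frac_treat_vet * ill_diag_vet` |

where `d(t)` is the exogenous fraction of personnel deployed to
intense/combat zones, `tau` the trauma-exposure rate among the deployed,
and `p = 0.17` the probability of developing PTSD after trauma.  Annual
healthcare costs apply constant 2012-dollar unit costs of $4,500 (military)
and $6,244 (VA) per diagnosed patient per year.

On top of the simulator the package provides

* **partial-model calibration** (`calibrate_partial()`): the military block
  is fit against observed series with deployment as forcing; the veteran
  block with observed separation flows as forcing; bounded multi-start
  simplex searches minimise a scaled sum-of-squares payoff, with an
  identifiability report from payoff curvature;
* **scenario x policy grids** (`run_grid()`): future deployment at 1%/2%/5%
  crossed with the base run and seven interventions (doubled screening,
  doubled treatment, halved post-trauma PTSD likelihood, and all
  combinations), reporting 2025 prevalence and costs per sector;
* a **steady-state war-pulse counterfactual** (`war_pulse()`,
  `recovery_time()`) measuring system inertia: peak heights, the lag of the
  veteran peak behind the war's end, and time to a near-PTSD-free veteran
  population;
* **fixtures and synthetic data** (`load_fixtures()`,
  `generate_synthetic_history()`): a calibrated parameter bundle with
  per-entry provenance, reconstructed 2000–2014 historical series, and a
  seeded noisy-history generator for parameter-recovery testing;
* a small **CLI** (`inst/scripts/ptsdflow`: `simulate`, `calibrate`,
  `grid`, `counterfactual`, `make-synthetic`).

## Worked example

```r
library(ptsdflow)
params <- default_params()
init   <- default_initial_state()

## minimum-deployment scenario (1% from 2015), 2000-2025
scen1 <- default_scenarios(params$deployment)[[1]]
tr <- simulate_ptsd(modify_params(params, deployment = scen1$deployment),
                    init, 2000, 2025)
tr
#> <ptsd_trajectory> 401 points over 2000-2025 (dt = 0.0625 yr, full, prevalence: all_ill)
#>   final: ill_diag_mil = 28131, ill_diag_vet_total = 515622, prevalence_mil = 0.064
```

By 2025 the diagnosed military population has declined to about 28,000
(annual cost $127M) while the VA still carries ~516,000 diagnosed patients
($3.2B/year) — the burden of a war outlives the war in the veteran sector.
The full policy grid (2025 military PTSD prevalence, %, all-ill
definition):

```r
grid <- run_grid(params, init)
round(100 * grid_to_wide(grid, "military", "prevalence"), 1)
#>      scenario_1 scenario_2 scenario_3
#> base        6.4        9.1       16.7
#> P1          5.9        8.6       15.9
#> P2          5.9        8.6       16.0
#> P3          5.0        6.5       10.6
#> P4          5.1        7.7       14.7
#> P5          4.6        6.0       10.0
#> P6          4.5        5.9        9.9
#> P7          3.8        5.1        9.0
```

Doubling screening (P1) or treatment (P2) alone barely moves prevalence;
every policy containing prevention (P3, P5–P7) cuts it substantially, and
the effect grows with war intensity.  The counterfactual 5-year, 10%-deployment
war pulse from a steady state shows the system's inertia:

```r
exp <- pulse_experiment()          # war years 0-5, 10% deployment
cf  <- counterfactual_params(params, exp)
recovery_time(war_pulse(cf, exp, horizon = 120))
#> <pulse_summary>
#>   veteran ill peak: 280394 persons at year 12.25 (lag 7.25 yr after war end)
#>   recovery to 0.01 of peak: 73.56 yr from war start (recovered)
```

The veteran ill population peaks about seven years *after* the war ends and
takes decades to fade — psychological consequences of a short war persist
for a generation.

## Limitations

The veteran-sector rates, separation/discharge rates, death rates and 2000
initial stocks are package calibrations (tagged in
`inst/extdata/parameters.csv`), not transcriptions of an official source;
the shipped "historical" series are synthetic reconstructions consistent
with the printed constraints on deployment and the model's base run.  See
the methods vignette (`vignettes/ptsd-model.Rmd`) for the full account of
assumptions, parameter choices and known limitations — including why the
calibrated system's pulse-recovery time is longer than the 40–45-year
figure sometimes quoted for post-war psychological recovery.
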