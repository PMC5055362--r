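## Minimal parameter sets and states used across the tests.  All fixtures
## are built in code; the shipped bundle is loaded where the calibrated
## model itself is under test.

zero_deaths <- function() stats::setNames(numeric(7), stock_names)

## a fully switched-off parameter set; override single pieces per test
toy_params <- function(...) {
  base <- ptsd_params(
    recruitment = 0,
    frac_recruit_ptsd_history = 0,
    deployment = 0,
    trauma_exposure_rate = 0,
    p_ptsd_given_trauma = 0.17,
    frac_reveal_mil = 0.043,
    frac_treat_mil = 0.125,
    frac_reveal_vet = 0,
    frac_treat_vet = 0,
    separation_rate_healthy = 0,
    separation_rate_undiag = 0,
    discharge_rate_diag = 0,
    death_rates = zero_deaths(),
    cost_per_patient_mil = 4500,
    cost_per_patient_va = 6244
  )
  modify_params(base, ...)
}

state_of <- function(...) {
  s <- stats::setNames(numeric(7), stock_names)
  over <- list(...)
  s[names(over)] <- unlist(over)
  s
}

## randomized non-negative parameter set for property tests
random_params <- function(seed, rate_max = 2) {
  set.seed(seed)
  r <- function(n = 1) stats::runif(n, 0, rate_max)
  toy_params(
    recruitment = stats::runif(1, 0, 5e5),
    frac_recruit_ptsd_history = stats::runif(1),
    deployment = stats::runif(1),
    trauma_exposure_rate = r(),
    p_ptsd_given_trauma = stats::runif(1),
    frac_reveal_mil = r(), frac_treat_mil = r(),
    frac_reveal_vet = r(), frac_treat_vet = r(),
    separation_rate_healthy = r(),
    separation_rate_undiag = r(),
    discharge_rate_diag = r(),
    death_rates = stats::setNames(r(7), stock_names)
  )
}

random_state <- function(seed) {
  set.seed(seed + 1000)
  stats::setNames(stats::runif(7, 0, 1e6), stock_names)
}
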