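## a small but dynamically interesting military system used throughout:
## constant recruitment and deployment, so every series is smooth and the
## fractional rates leave clear signatures in the outputs
calib_params <- function(...) {
  toy_params(recruitment = 50000, deployment = 0.08,
             trauma_exposure_rate = 1.5,
             separation_rate_healthy = 0.1,
             separation_rate_undiag = 0.1,
             discharge_rate_diag = 0.1, ...)
}
calib_init <- function() state_of(healthy_mil = 5e5)

test_that("payoff is zero iff the model matches the data", {
  p <- calib_params()
  tr <- simulate_ptsd(p, calib_init(), 0, 15)
  exact <- generate_synthetic_history(p, calib_init(),
                                      series = c("diagnosis_rate_mil",
                                                 "ill_diag_mil"),
                                      years = 1:14, noise_cv = 0,
                                      t_start = 0, t_end = 15)
  expect_equal(payoff(tr, exact), 0)
  off <- exact
  off[[1]]$values[3] <- off[[1]]$values[3] * 1.05
  expect_gt(payoff(tr, off), 0)
})

test_that("payoff matches its definition and is linear in the weights", {
  p <- calib_params()
  tr <- simulate_ptsd(p, calib_init(), 0, 10)
  m <- trajectory_value(tr, "ill_diag_mil", 5)
  ## single series, single year, model - data = scale  ->  weight * 1
  s1 <- observed_series("ill_diag_mil", 5, m / 2, weight = 3)
  expect_equal(payoff(tr, s1), 3)
  ## doubling every weight doubles the payoff
  s2 <- observed_series("diagnosis_rate_mil", c(2, 4, 8),
                        trajectory_value(tr, "diagnosis_rate_mil",
                                         c(2, 4, 8)) * 1.1)
  base <- payoff(tr, list(s1, s2))
  s1$weight <- 6; s2$weight <- 2
  expect_equal(payoff(tr, list(s1, s2)), 2 * base)
  expect_error(payoff(tr, observed_series("no_such_series", 1:3, 1:3)),
               "no_such_series")
})

test_that("noise-free military data recovers the generating rates", {
  p <- calib_params()  # true frac_reveal_mil 0.043, frac_treat_mil 0.125
  data <- generate_synthetic_history(p, calib_init(),
                                     series = c("diagnosis_rate_mil",
                                                "ill_diag_mil"),
                                     years = 1:14, noise_cv = 0,
                                     t_start = 0, t_end = 14)
  fit <- calibrate_partial(p, data,
                           free = list(frac_reveal_mil = c(0.005, 0.5),
                                       frac_treat_mil = c(0.01, 1)),
                           submodel = "military", init = calib_init(),
                           t_start = 0, t_end = 14, n_starts = 6, seed = 7)
  expect_lt(fit$payoff, 1e-6)
  expect_lt(abs(fit$estimates[["frac_reveal_mil"]] - 0.043) / 0.043, 0.01)
  expect_lt(abs(fit$estimates[["frac_treat_mil"]] - 0.125) / 0.125, 0.01)
  expect_true(fit$converged)
  ## identical seed reproduces the estimates exactly
  fit2 <- calibrate_partial(p, data,
                            free = list(frac_reveal_mil = c(0.005, 0.5),
                                        frac_treat_mil = c(0.01, 1)),
                            submodel = "military", init = calib_init(),
                            t_start = 0, t_end = 14, n_starts = 6, seed = 7)
  expect_identical(fit$estimates, fit2$estimates)
})

test_that("the veteran partial model is fit with driven boundary inflows", {
  fx <- load_fixtures()
  full <- simulate_ptsd(fx$params, fx$initial_state, 2000, 2014)
  drive <- list(
    separation_healthy = data.frame(year = full$time,
                                    value = full$separation_healthy),
    separation_undiag = data.frame(year = full$time,
                                   value = full$separation_undiag),
    discharge_diag = data.frame(year = full$time,
                                value = full$discharge_diag)
  )
  data <- list(observed_series("diagnosis_rate_vet", 2001:2014,
                               trajectory_value(full, "diagnosis_rate_vet",
                                                2001:2014)),
               observed_series("ill_diag_vet_total", 2001:2014,
                               trajectory_value(full, "ill_diag_vet_total",
                                                2001:2014)))
  fit <- calibrate_partial(fx$params, data,
                           free = list(frac_reveal_vet = c(0.02, 0.6)),
                           submodel = "veterans", init = fx$initial_state,
                           t_start = 2000, t_end = 2014, drive = drive,
                           n_starts = 3, seed = 11)
  expect_lt(abs(fit$estimates[["frac_reveal_vet"]] -
                  fx$params$frac_reveal_vet) /
              fx$params$frac_reveal_vet, 0.01)
  expect_error(
    calibrate_partial(fx$params, data,
                      free = list(frac_reveal_vet = c(0.02, 0.6)),
                      submodel = "veterans", init = fx$initial_state,
                      t_start = 2000, t_end = 2014, n_starts = 1, seed = 1),
    "drive")
})

test_that("noisy data recovers the treatment rate in the median", {
  p <- calib_params()
  ests <- vapply(1:20, function(rep) {
    data <- generate_synthetic_history(p, calib_init(),
                                       series = "ill_diag_mil",
                                       years = 1:14, noise_cv = 0.05,
                                       seed = 100 + rep,
                                       t_start = 0, t_end = 14)
    fit <- calibrate_partial(p, data,
                             free = list(frac_treat_mil = c(0.01, 1)),
                             submodel = "military", init = calib_init(),
                             t_start = 0, t_end = 14, n_starts = 1,
                             seed = rep)
    fit$estimates[["frac_treat_mil"]]
  }, numeric(1))
  expect_lt(abs(stats::median(ests) - 0.125) / 0.125, 0.05)
})

test_that("series too short for fitting and bad bounds are rejected", {
  p <- calib_params()
  tiny <- observed_series("ill_diag_mil", c(1, 2), c(10, 20))
  expect_error(
    calibrate_partial(p, tiny, free = list(frac_treat_mil = c(0.01, 1)),
                      submodel = "military", init = calib_init(),
                      t_start = 0, t_end = 5),
    "fewer than 3")
  ok <- observed_series("ill_diag_mil", 1:3, c(10, 20, 30))
  expect_error(
    calibrate_partial(p, ok, free = list(frac_treat_mil = c(1, 0.5)),
                      submodel = "military", init = calib_init(),
                      t_start = 0, t_end = 5),
    "bounds")
  expect_error(
    calibrate_partial(p, ok, free = list(no_such = c(0, 1)),
                      submodel = "military", init = calib_init(),
                      t_start = 0, t_end = 5),
    "no_such")
})

test_that("the identifiability report brackets the optimum", {
  p <- calib_params()
  data <- generate_synthetic_history(p, calib_init(),
                                     series = c("diagnosis_rate_mil",
                                                "ill_diag_mil"),
                                     years = 1:14, noise_cv = 0,
                                     t_start = 0, t_end = 14)
  fit <- calibrate_partial(p, data,
                           free = list(frac_reveal_mil = c(0.005, 0.5)),
                           submodel = "military", init = calib_init(),
                           t_start = 0, t_end = 14, n_starts = 2, seed = 3)
  rep <- identifiability_report(fit, n_grid = 41)
  expect_equal(rep$parameter, "frac_reveal_mil")
  expect_lte(rep$lower, rep$estimate)
  expect_gte(rep$upper, rep$estimate)
  ## the diagnosis rate pins this parameter sharply: far from weakly
  ## identified
  expect_false(rep$flagged)
  expect_lt(rep$interval_ratio, 2)
})
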