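test_that("pathway flows follow the product-form rate equations", {
  p <- toy_params(recruitment = 1000, frac_recruit_ptsd_history = 0.1,
                  deployment = 0.5, trauma_exposure_rate = 2,
                  frac_reveal_vet = 0.05, frac_treat_vet = 0.05)
  s <- state_of(healthy_mil = 1e5, ill_undiag_mil = 10000,
                ill_diag_mil = 8000, ill_undiag_vet = 2000,
                ill_diag_vet_recent = 3000, ill_diag_vet_pre2000 = 500)
  fl <- compute_flows(s, p, t = 2005)
  expect_equal(fl[["diagnosis_mil"]], 0.043 * 10000)    # 430 persons/yr
  expect_equal(fl[["treatment_mil"]], 0.125 * 8000)     # 1000 persons/yr
  expect_equal(fl[["onset_mil"]], 2 * 0.5 * 0.17 * 1e5)
  expect_equal(fl[["recruit_healthy"]], 900)
  expect_equal(fl[["recruit_history"]], 100)
  expect_equal(fl[["diagnosis_vet"]], 0.05 * 2000)
  expect_equal(fl[["treatment_vet_recent"]], 0.05 * 3000)
  expect_equal(fl[["treatment_vet_pre2000"]], 0.05 * 500)
})

test_that("an empty system produces only recruitment flows", {
  p <- toy_params(recruitment = 5000, frac_recruit_ptsd_history = 0.02,
                  deployment = 1, trauma_exposure_rate = 5)
  fl <- compute_flows(state_of(), p, t = 2000)
  expect_equal(fl[["recruit_healthy"]], 4900)
  expect_equal(fl[["recruit_history"]], 100)
  expect_equal(unname(fl[setdiff(names(fl), c("recruit_healthy",
                                              "recruit_history"))]),
               numeric(16))
})

test_that("invalid states and arguments are rejected by name", {
  p <- toy_params()
  s <- state_of(); s["ill_diag_mil"] <- -5
  expect_error(compute_flows(s, p, 2000), "ill_diag_mil")
  expect_error(euler_step(state_of(), p, 2000, dt = 0), "dt")
  expect_error(euler_step(state_of(), p, 2000, dt = -1), "dt")
  expect_error(simulate_ptsd(p, state_of(), 2010, 2005), "t_end")
  expect_error(prevalence(state_of(), "military"), "military")
})

test_that("the Euler update adds exactly dt times the net flow", {
  p <- toy_params(recruitment = 430)
  s0 <- state_of(healthy_mil = 100)
  s1 <- euler_step(s0, p, t = 0, dt = 0.25)
  expect_equal(s1[["healthy_mil"]], 100 + 0.25 * 430)
  expect_equal(s1[setdiff(stock_names, "healthy_mil")],
               s0[setdiff(stock_names, "healthy_mil")])
  ## all flows zero: state unchanged for any dt
  expect_identical(euler_step(s0, toy_params(), 0, dt = 2), s0)
})

test_that("a single linear stock reaches the closed-form r/k equilibrium", {
  ## constant inflow r = 430/yr, fractional outflow k = 0.125/yr via the
  ## healthy-separation pathway: equilibrium r/k = 3440, and the transient
  ## decays as exp(-k t), so 10 time constants reach 0.1% easily
  p <- toy_params(recruitment = 430, separation_rate_healthy = 0.125)
  tr <- simulate_ptsd(p, state_of(), 0, 10 / 0.125, dt = 1 / 16)
  expect_equal(tr$healthy_mil[nrow(tr)], 430 / 0.125,
               tolerance = 1e-3)
  ## the same people accumulate as healthy veterans: mass is conserved
  total_in <- 430 * 80
  expect_equal(tr$healthy_mil[nrow(tr)] + tr$healthy_vet[nrow(tr)],
               total_in, tolerance = 1e-9)
})

test_that("simulation conserves mass and is bit-identical on repeat", {
  fx <- load_fixtures()
  tr1 <- simulate_ptsd(fx$params, fx$initial_state, 2000, 2010)
  tr2 <- simulate_ptsd(fx$params, fx$initial_state, 2000, 2010)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
  expect_lt(check_mass_balance(tr1), 1e-9)
})

test_that("mass balance and non-negativity hold for randomized systems", {
  for (seed in 1:8) {
    p <- random_params(seed, rate_max = if (seed %% 2) 2 else 30)
    tr <- simulate_ptsd(p, random_state(seed), 0, 10, dt = 1 / 16)
    expect_lt(check_mass_balance(tr), 1e-9)
    expect_true(all(as.matrix(tr[, stock_names]) >= 0))
  }
})

test_that("military-to-veteran coupling is conserved cumulatively", {
  fx <- load_fixtures()
  tr <- simulate_ptsd(fx$params, fx$initial_state, 2000, 2015)
  h <- diff(tr$time)
  n <- nrow(tr)
  ## veteran-sector change must equal integrated boundary inflows
  ## (pathways 5-7) minus veteran deaths and nothing else
  vet <- rowSums(tr[, c("healthy_vet", "ill_undiag_vet",
                        "ill_diag_vet_recent", "ill_diag_vet_pre2000")])
  inflow <- tr$separation_healthy + tr$separation_undiag +
    tr$discharge_diag
  outflow <- tr$death_healthy_vet + tr$death_ill_undiag_vet +
    tr$death_ill_diag_vet_recent + tr$death_ill_diag_vet_pre2000
  lhs <- vet[n] - vet[1]
  rhs <- sum(h * (inflow - outflow)[-n])
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("flow capping prevents negative stocks at extreme rates", {
  p <- toy_params(frac_reveal_mil = 40, separation_rate_undiag = 40)
  s <- state_of(ill_undiag_mil = 100)
  s1 <- euler_step(s, p, 0, dt = 1 / 4)
  expect_gte(s1[["ill_undiag_mil"]], 0)
  ## the capped outflow is rerouted consistently: people are conserved
  expect_equal(sum(s1), sum(s))
})

test_that("zero-rate systems with nonzero stocks stay constant", {
  s <- state_of(healthy_mil = 10, ill_diag_vet_recent = 5)
  tr <- simulate_ptsd(toy_params(frac_reveal_mil = 0, frac_treat_mil = 0),
                      s, 0, 20, dt = 1 / 8)
  expect_true(all(tr$healthy_mil == 10))
  expect_true(all(tr$ill_diag_vet_recent == 5))
})

test_that("prevalence definitions and pooling behave as documented", {
  s <- state_of(healthy_mil = 1000, ill_undiag_mil = 600,
                ill_diag_mil = 400, healthy_vet = 9000,
                ill_diag_vet_recent = 600, ill_diag_vet_pre2000 = 400)
  expect_equal(prevalence(s, "military", "all_ill"), 0.5)
  expect_equal(prevalence(s, "military", "diagnosed_only"), 0.2)
  expect_equal(prevalence(s, "veterans", "all_ill"), 0.1)
  ## pooled, not averaged
  expect_equal(prevalence(s, "total", "all_ill"),
               (1000 + 1000) / (2000 + 10000))
  expect_equal(prevalence(state_of(healthy_mil = 10), "military"), 0)
})

test_that("annual costs are the per-patient cost times diagnosed stocks", {
  p <- toy_params()
  s <- state_of(healthy_mil = 1, ill_diag_mil = 28000, healthy_vet = 1,
                ill_diag_vet_recent = 300000,
                ill_diag_vet_pre2000 = 172453)
  tr <- simulate_ptsd(p, s, 0, 1, dt = 1)
  costs <- annual_costs(tr)
  expect_equal(costs$cost_mil[1], 28000 * 4500)  # $1.26e8/yr
  expect_equal(costs$cost_va[1], 472453 * 6244)
  zero <- annual_costs(simulate_ptsd(p, state_of(healthy_mil = 1), 0, 1,
                                     dt = 1))
  expect_equal(zero$cost_mil, c(0, 0))
  expect_equal(zero$cost_va, c(0, 0))
})

test_that("halving the integration step barely changes the trajectory", {
  fx <- load_fixtures()
  f <- sapply(c(1 / 16, 1 / 32), function(dt) {
    tr <- simulate_ptsd(fx$params, fx$initial_state, 2000, 2010, dt = dt)
    unlist(tr[nrow(tr), stock_names])
  })
  expect_true(all(abs(f[, 2] - f[, 1]) / pmax(f[, 1], 1) < 0.005))
})

test_that("trajectory CSV export is tidy and unit-labelled", {
  tr <- simulate_ptsd(toy_params(recruitment = 10),
                      state_of(healthy_mil = 5), 0, 2, dt = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  out <- read.csv(path)
  expect_setequal(names(out), c("time", "series", "value", "units"))
  expect_true(all(c("healthy_mil", "cost_va", "prevalence_total") %in%
                    out$series))
  expect_equal(unique(out$units[out$series == "cost_mil"]), "USD/year")
})
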