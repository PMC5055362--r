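#' Stock names of the military/post-military PTSD model
#'
#' The model tracks seven population stocks, in persons: three military
#' stages (healthy, ill-undiagnosed, ill-diagnosed), and four post-military
#' stocks (healthy veterans, ill-undiagnosed veterans, and the ill-diagnosed
#' veteran population split into the recent -- Iraq/Afghanistan era -- cohort
#' and the pre-2000 cohort).
#'
#' @format character vector of length 7.
#' @export
stock_names <- c(
  "healthy_mil", "ill_undiag_mil", "ill_diag_mil",
  "healthy_vet", "ill_undiag_vet",
  "ill_diag_vet_recent", "ill_diag_vet_pre2000"
)

## Internal flow bookkeeping.
##
## The flow vector has 18 entries: 11 pathway flows followed by 7 death
## flows (one per stock).  Pathway numbering follows the model diagram:
##   1a recruit_healthy        boundary -> healthy_mil
##   1b recruit_history        boundary -> ill_undiag_mil
##   2  onset_mil              healthy_mil -> ill_undiag_mil
##   3  diagnosis_mil          ill_undiag_mil -> ill_diag_mil
##   4  treatment_mil          ill_diag_mil -> healthy_mil
##   5  separation_healthy     healthy_mil -> healthy_vet
##   6  separation_undiag      ill_undiag_mil -> ill_undiag_vet
##   7  discharge_diag         ill_diag_mil -> ill_diag_vet_recent
##   8  diagnosis_vet          ill_undiag_vet -> ill_diag_vet_recent
##   9r treatment_vet_recent   ill_diag_vet_recent -> healthy_vet
##   9p treatment_vet_pre2000  ill_diag_vet_pre2000 -> healthy_vet
## All post-2000 diagnosed-veteran inflows (pathways 7 and 8) enter the
## recent cohort; the pre-2000 cohort only decays (treatment and death).

flow_names <- c(
  "recruit_healthy", "recruit_history", "onset_mil", "diagnosis_mil",
  "treatment_mil", "separation_healthy", "separation_undiag",
  "discharge_diag", "diagnosis_vet", "treatment_vet_recent",
  "treatment_vet_pre2000",
  paste0("death_", stock_names)
)

## outflow / inflow index sets per stock (into the 18-long flow vector)
.out_idx <- list(
  c(3L, 6L, 12L),   # healthy_mil: onset, healthy separation, death
  c(4L, 7L, 13L),   # ill_undiag_mil: diagnosis, separation, death
  c(5L, 8L, 14L),   # ill_diag_mil: treatment, discharge, death
  15L,              # healthy_vet: death
  c(9L, 16L),       # ill_undiag_vet: diagnosis, death
  c(10L, 17L),      # ill_diag_vet_recent: treatment, death
  c(11L, 18L)       # ill_diag_vet_pre2000: treatment, death
)
.in_idx <- list(
  c(1L, 5L),        # healthy_mil: recruitment 1a, treatment
  c(2L, 3L),        # ill_undiag_mil: recruitment 1b, onset
  4L,               # ill_diag_mil: diagnosis
  c(6L, 10L, 11L),  # healthy_vet: healthy separation, treatments 9
  7L,               # ill_undiag_vet: separation with unknown illness
  c(8L, 9L),        # ill_diag_vet_recent: discharge, veteran diagnosis
  integer(0)        # ill_diag_vet_pre2000: decays only
)

## Raw (uncapped) flows given the state, scalar parameters and the
## pre-evaluated forcings at time t.  `s` is the unnamed 7-long stock vector.
.raw_flows <- function(s, p, recruit, deploy) {
  fl <- numeric(18L)
  fl[1L] <- recruit * (1 - p$frac_recruit_ptsd_history)
  fl[2L] <- recruit * p$frac_recruit_ptsd_history
  fl[3L] <- p$trauma_exposure_rate * deploy * p$p_ptsd_given_trauma * s[1L]
  fl[4L] <- p$frac_reveal_mil * s[2L]
  fl[5L] <- p$frac_treat_mil * s[3L]
  fl[6L] <- p$separation_rate_healthy * s[1L]
  fl[7L] <- p$separation_rate_undiag * s[2L]
  fl[8L] <- p$discharge_rate_diag * s[3L]
  fl[9L] <- p$frac_reveal_vet * s[5L]
  fl[10L] <- p$frac_treat_vet * s[6L]
  fl[11L] <- p$frac_treat_vet * s[7L]
  fl[12:18] <- p$death_rates_vec * s
  fl
}

## Cap outflows so no stock can be driven below zero within one Euler step
## of size dt: each stock's outflows are scaled by stock / (dt * total
## outflow) when needed.  Capping a flow reduces only inflows elsewhere, so
## one pass guarantees non-negativity everywhere.
.cap_flows <- function(fl, s, dt) {
  for (i in 1:7) {
    idx <- .out_idx[[i]]
    tot <- sum(fl[idx])
    if (tot > 0 && dt * tot > s[i]) {
      fl[idx] <- fl[idx] * (s[i] / (dt * tot))
    }
  }
  fl
}

.net_change <- function(fl) {
  vapply(1:7, function(i) sum(fl[.in_idx[[i]]]) - sum(fl[.out_idx[[i]]]),
         numeric(1))
}

## normalise/complete a parameter list for the inner loop
.prep_params <- function(params) {
  validate_params(params)
  p <- unclass(params)
  p$death_rates_vec <- unname(p$death_rates[stock_names])
  p
}

.check_state <- function(state) {
  if (is.data.frame(state)) state <- unlist(state[1, stock_names])
  if (is.null(names(state))) {
    if (length(state) != 7L) {
      stop("a stock state needs 7 values (see `stock_names`)", call. = FALSE)
    }
    names(state) <- stock_names
  }
  if (!all(stock_names %in% names(state))) {
    stop("state must name all stocks: ",
         paste(setdiff(stock_names, names(state)), collapse = ", "),
         call. = FALSE)
  }
  state <- state[stock_names]
  if (anyNA(state) || any(!is.finite(state))) {
    bad <- stock_names[which(!is.finite(state))[1]]
    stop(sprintf("invalid state: stock '%s' is not finite", bad),
         call. = FALSE)
  }
  if (any(state < 0)) {
    bad <- stock_names[which(state < 0)[1]]
    stop(sprintf("invalid state: stock '%s' is negative (%g)",
                 bad, state[bad]), call. = FALSE)
  }
  state
}

#' Pathway and death flows at a time point
#'
#' Evaluates every pathway flow and death flow (persons/year) for a given
#' stock state.  The diagnosis flow (pathway 3) is the product of the
#' fractional symptom-revealing rate and the ill-undiagnosed military
#' population; the treatment flow (pathway 4) is the product of the
#' fractional treatment rate and the ill-diagnosed military population;
#' veteran diagnosis and treatment (pathways 8 and 9) are analogous.  PTSD
#' onset (pathway 2) applies the trauma-exposure rate and the conditional
#' PTSD probability to the currently deployed fraction of healthy
#' personnel.  Separation and discharge (pathways 5-7) are first-order
#' rates on the corresponding military stocks.
#'
#' @param state named numeric vector of the seven stocks (persons); see
#'   [stock_names].
#' @param params a [ptsd_params()] object.
#' @param t calendar year at which the exogenous forcings are evaluated.
#' @param dt optional step length (years); when given, outflows are capped
#'   so that no stock can be driven negative within one Euler step of that
#'   length.
#' @return named numeric vector of 11 pathway flows and 7 death flows,
#'   persons/year.
#' @examples
#' \dontrun{
#' p <- default_params()
#' s <- default_initial_state()
#' compute_flows(s, p, t = 2000)
#' }
#' @export
compute_flows <- function(state, params, t, dt = NULL) {
  state <- .check_state(state)
  p <- .prep_params(params)
  recruit <- forcing_value(params$recruitment, t)
  deploy <- forcing_value(params$deployment, t)
  if (!is.finite(recruit) || !is.finite(deploy)) {
    stop(sprintf("exogenous forcing undefined at year %g", t), call. = FALSE)
  }
  fl <- .raw_flows(unname(state), p, recruit, deploy)
  if (!is.null(dt)) {
    if (dt <= 0) stop("'dt' must be > 0", call. = FALSE)
    fl <- .cap_flows(fl, unname(state), dt)
  }
  names(fl) <- flow_names
  fl
}

#' Advance the state by one Euler step
#'
#' Each stock is updated by the explicit Euler rule
#' `stock + dt * (inflows - outflows)`, with outflows capped so the stock
#' cannot be driven below zero.  Flows across the military/post-military
#' boundary are conserved: the separation and discharge outflows (pathways
#' 5-7) are the identical quantities added to the veteran stocks.
#'
#' @inheritParams compute_flows
#' @param dt step length in years; must be > 0.
#' @return named numeric vector: the state at `t + dt`.
#' @export
euler_step <- function(state, params, t, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("'dt' must be a single number > 0", call. = FALSE)
  }
  fl <- compute_flows(state, params, t, dt = dt)
  s <- .check_state(state)
  s <- s + dt * .net_change(fl)
  ## capping leaves at most float-rounding residue below zero
  pmax(s, 0)
}

#' Simulate the model forward in time
#'
#' Integrates the stock-and-flow model with the explicit Euler scheme from
#' `t_start` to `t_end` with step `dt` (default 1/16 year, the usual system
#' dynamics convention).  The run is fully deterministic: identical inputs
#' give bit-identical trajectories.
#'
#' The returned trajectory holds, at every grid point, the seven stocks, the
#' (capped) pathway and death flows actually applied over the following
#' step, and derived series: the military and veteran diagnosis rates (new
#' cases/year, pathways 3 and 8), PTSD prevalence per sector, annual costs,
#' and the pooled diagnosed-veteran stock.
#'
#' @param params a [ptsd_params()] object.
#' @param init named numeric vector of initial stocks (persons).
#' @param t_start,t_end simulation window in calendar years; `t_end` must
#'   exceed `t_start`.
#' @param dt Euler step, years.
#' @param prevalence_def prevalence definition used for the derived
#'   prevalence columns: `"all_ill"` (undiagnosed + diagnosed; default) or
#'   `"diagnosed_only"`.
#' @param sector `"full"` integrates all seven stocks. `"military"`
#'   integrates only the three military stocks (the military block is
#'   upstream of the veteran block, so this is the military partial model
#'   driven by the observed deployment forcing).  `"veterans"` integrates
#'   only the veteran stocks, with the boundary inflows (pathways 5-7)
#'   driven by the forcings in `drive`.
#' @param drive for `sector = "veterans"`: a named list with elements
#'   `separation_healthy`, `separation_undiag`, `discharge_diag`, each a
#'   forcing in persons/year.
#' @return a `ptsd_trajectory`: a data.frame with one row per grid point
#'   and attributes `params`, `dt`.
#' @examples
#' \dontrun{
#' p <- default_params()
#' tr <- simulate_ptsd(p, default_initial_state(), 2000, 2025)
#' tail(tr[, c("time", "ill_diag_mil", "ill_diag_vet_total")])
#' }
#' @export
simulate_ptsd <- function(params, init, t_start, t_end, dt = 1 / 16,
                          prevalence_def = c("all_ill", "diagnosed_only"),
                          sector = c("full", "military", "veterans"),
                          drive = NULL) {
  prevalence_def <- match.arg(prevalence_def)
  sector <- match.arg(sector)
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  if (t_end <= t_start) stop("'t_end' must exceed 't_start'", call. = FALSE)
  s <- unname(.check_state(init))
  p <- .prep_params(params)

  n <- ceiling((t_end - t_start) / dt - 1e-9)
  times <- t_start + dt * seq_len(n + 1L) - dt
  times[n + 1L] <- t_end
  steps <- diff(times)

  recruit <- forcing_value(params$recruitment, times)
  deploy <- forcing_value(params$deployment, times)
  if (anyNA(recruit) || anyNA(deploy)) {
    stop(sprintf("exogenous forcing undefined at year %g",
                 times[which(is.na(recruit) | is.na(deploy))[1]]),
         call. = FALSE)
  }

  drv <- NULL
  if (sector == "veterans") {
    need <- c("separation_healthy", "separation_undiag", "discharge_diag")
    if (is.null(drive) || !all(need %in% names(drive))) {
      stop("the veteran partial model needs `drive` forcings for: ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    drv <- lapply(drive[need], function(f) forcing_value(as_forcing(f), times))
    if (any(vapply(drv, function(v) any(v < 0), logical(1)))) {
      stop("driven separation flows must be >= 0", call. = FALSE)
    }
  }

  states <- matrix(NA_real_, n + 1L, 7L)
  flows <- matrix(NA_real_, n + 1L, 18L)

  for (k in seq_len(n + 1L)) {
    fl <- .raw_flows(s, p, recruit[k], deploy[k])
    if (sector == "military") {
      fl[6:11] <- c(fl[6:8], 0, 0, 0)  # separations leave the submodel
      fl[15:18] <- 0
    } else if (sector == "veterans") {
      fl[1:5] <- 0
      fl[12:14] <- 0
      fl[6L] <- drv$separation_healthy[k]
      fl[7L] <- drv$separation_undiag[k]
      fl[8L] <- drv$discharge_diag[k]
    }
    h <- if (k <= n) steps[k] else dt
    fl <- .cap_flows(fl, s, h)
    states[k, ] <- s
    flows[k, ] <- fl
    if (k <= n) {
      s <- s + steps[k] * .net_change(fl)
      if (sector == "military") s[4:7] <- states[k, 4:7]
      if (sector == "veterans") s[1:3] <- states[k, 1:3]
      ## flow capping guarantees non-negativity up to float rounding;
      ## snap the rounding residue (never a real deficit) back to zero
      neg <- s < 0
      if (any(neg)) {
        if (any(s[neg] < -1e-8 * max(1, abs(s)))) {
          stop(sprintf("internal error: stock '%s' went negative at year %.4f",
                       stock_names[which(s < 0)[1]], times[k + 1L]),
               call. = FALSE)
        }
        s[neg] <- 0
      }
      if (any(!is.finite(s))) {
        stop(sprintf("non-finite state at year %.4f (stock '%s'); aborting",
                     times[k + 1L], stock_names[which(!is.finite(s))[1]]),
             call. = FALSE)
      }
    }
  }

  colnames(states) <- stock_names
  colnames(flows) <- flow_names
  traj <- data.frame(time = times, states, flows, check.names = FALSE)

  traj$ill_diag_vet_total <- traj$ill_diag_vet_recent +
    traj$ill_diag_vet_pre2000
  traj$diagnosis_rate_mil <- traj$diagnosis_mil
  traj$diagnosis_rate_vet <- traj$diagnosis_vet
  traj$cost_mil <- params$cost_per_patient_mil * traj$ill_diag_mil
  traj$cost_va <- params$cost_per_patient_va * traj$ill_diag_vet_total

  mil_pop <- traj$healthy_mil + traj$ill_undiag_mil + traj$ill_diag_mil
  vet_pop <- traj$healthy_vet + traj$ill_undiag_vet + traj$ill_diag_vet_total
  if (prevalence_def == "all_ill") {
    mil_ill <- traj$ill_undiag_mil + traj$ill_diag_mil
    vet_ill <- traj$ill_undiag_vet + traj$ill_diag_vet_total
  } else {
    mil_ill <- traj$ill_diag_mil
    vet_ill <- traj$ill_diag_vet_total
  }
  traj$prevalence_mil <- ifelse(mil_pop > 0, mil_ill / mil_pop, NA_real_)
  traj$prevalence_vet <- ifelse(vet_pop > 0, vet_ill / vet_pop, NA_real_)
  traj$prevalence_total <- ifelse(mil_pop + vet_pop > 0,
                                  (mil_ill + vet_ill) / (mil_pop + vet_pop),
                                  NA_real_)

  attr(traj, "params") <- params
  attr(traj, "dt") <- dt
  attr(traj, "prevalence_def") <- prevalence_def
  attr(traj, "sector") <- sector
  class(traj) <- c("ptsd_trajectory", "data.frame")
  traj
}

#' PTSD prevalence of a stock state
#'
#' Fraction of a sector's living population that is ill.  Under the default
#' `all_ill` definition the numerator counts undiagnosed plus diagnosed
#' cases; under `diagnosed_only` it counts diagnosed cases only.  The
#' denominator is the sector's whole living population.  `"total"` pools
#' numerators and denominators across both sectors (not the mean of the two
#' prevalences).
#'
#' @param state named numeric stock vector, or a `ptsd_trajectory` row.
#' @param sector `"military"`, `"veterans"` or `"total"`.
#' @param definition `"all_ill"` or `"diagnosed_only"`.
#' @return prevalence in \[0, 1\].
#' @export
prevalence <- function(state, sector = c("military", "veterans", "total"),
                       definition = c("all_ill", "diagnosed_only")) {
  sector <- match.arg(sector)
  definition <- match.arg(definition)
  s <- .check_state(state)
  mil_pop <- s[["healthy_mil"]] + s[["ill_undiag_mil"]] + s[["ill_diag_mil"]]
  vet_pop <- s[["healthy_vet"]] + s[["ill_undiag_vet"]] +
    s[["ill_diag_vet_recent"]] + s[["ill_diag_vet_pre2000"]]
  if (definition == "all_ill") {
    mil_ill <- s[["ill_undiag_mil"]] + s[["ill_diag_mil"]]
    vet_ill <- s[["ill_undiag_vet"]] + s[["ill_diag_vet_recent"]] +
      s[["ill_diag_vet_pre2000"]]
  } else {
    mil_ill <- s[["ill_diag_mil"]]
    vet_ill <- s[["ill_diag_vet_recent"]] + s[["ill_diag_vet_pre2000"]]
  }
  num <- switch(sector, military = mil_ill, veterans = vet_ill,
                total = mil_ill + vet_ill)
  den <- switch(sector, military = mil_pop, veterans = vet_pop,
                total = mil_pop + vet_pop)
  if (den <= 0) {
    stop(sprintf("prevalence undefined: %s population is zero", sector),
         call. = FALSE)
  }
  unname(num / den)
}

#' Annual healthcare costs along a trajectory
#'
#' Direct annual PTSD healthcare costs under the constant cost-per-patient
#' assumption: `cost_mil = cost_per_patient_mil * ill_diag_mil` and
#' `cost_va = cost_per_patient_va * (diagnosed veterans, both cohorts)`,
#' in constant 2012 US dollars per year.
#'
#' @param traj a `ptsd_trajectory`.
#' @param params a [ptsd_params()] object; defaults to the trajectory's own.
#' @return data.frame with columns `time`, `cost_mil`, `cost_va` (USD/year).
#' @export
annual_costs <- function(traj, params = attr(traj, "params")) {
  stopifnot(inherits(traj, "ptsd_trajectory"))
  if (params$cost_per_patient_mil < 0 || params$cost_per_patient_va < 0) {
    stop("cost parameters must be >= 0", call. = FALSE)
  }
  data.frame(
    time = traj$time,
    cost_mil = params$cost_per_patient_mil * traj$ill_diag_mil,
    cost_va = params$cost_per_patient_va *
      (traj$ill_diag_vet_recent + traj$ill_diag_vet_pre2000)
  )
}

#' Sample a trajectory at given years
#'
#' Linear interpolation of one trajectory column onto arbitrary years
#' (exact at grid points).
#'
#' @param traj a `ptsd_trajectory`.
#' @param series a column name of the trajectory.
#' @param years numeric vector of years inside the simulated window.
#' @export
trajectory_value <- function(traj, series, years) {
  stopifnot(inherits(traj, "ptsd_trajectory"))
  if (!series %in% names(traj)) {
    stop(sprintf("series '%s' is not a trajectory output", series),
         call. = FALSE)
  }
  if (any(years < min(traj$time) - 1e-9 | years > max(traj$time) + 1e-9)) {
    stop("requested years fall outside the simulated window", call. = FALSE)
  }
  stats::approx(traj$time, traj[[series]], xout = years,
                ties = "ordered")$y
}

#' Mass-balance check of a trajectory
#'
#' Verifies, step by step, that the change in total population equals the
#' integral of recruitment minus total deaths (the system is closed
#' otherwise).  Returns the largest per-step discrepancy relative to the
#' total population.
#'
#' @param traj a full-model `ptsd_trajectory`.
#' @return maximum relative per-step mass-balance error (dimensionless).
#' @export
check_mass_balance <- function(traj) {
  stopifnot(inherits(traj, "ptsd_trajectory"))
  stocks <- as.matrix(traj[, stock_names])
  total <- rowSums(stocks)
  n <- length(total)
  h <- diff(traj$time)
  boundary <- traj$recruit_healthy + traj$recruit_history -
    rowSums(as.matrix(traj[, paste0("death_", stock_names)]))
  err <- abs(diff(total) - h * boundary[-n])
  max(err / pmax(total[-n], 1))
}

#' @export
print.ptsd_trajectory <- function(x, ...) {
  cat(sprintf("<ptsd_trajectory> %d points over %.4g-%.4g (dt = %g yr, %s, prevalence: %s)\n",
              nrow(x), min(x$time), max(x$time), attr(x, "dt"),
              attr(x, "sector"), attr(x, "prevalence_def")))
  last <- x[nrow(x), ]
  cat(sprintf("  final: ill_diag_mil = %.0f, ill_diag_vet_total = %.0f, prevalence_mil = %.3f\n",
              last$ill_diag_mil, last$ill_diag_vet_total,
              last$prevalence_mil))
  invisible(x)
}

#' @export
plot.ptsd_trajectory <- function(x, series = "ill_diag_mil", ...) {
  graphics::plot(x$time, x[[series]], type = "l", xlab = "year",
                 ylab = series, ...)
}

#' Write a trajectory as tidy CSV
#'
#' Long format with columns `time`, `series`, `value`, `units`.
#'
#' @param traj a `ptsd_trajectory`.
#' @param path output file path.
#' @param series columns to export (default: stocks and derived series).
#' @export
write_trajectory_csv <- function(traj, path,
                                 series = c(stock_names,
                                            "diagnosis_rate_mil",
                                            "diagnosis_rate_vet",
                                            "ill_diag_vet_total",
                                            "prevalence_mil",
                                            "prevalence_vet",
                                            "prevalence_total",
                                            "cost_mil", "cost_va")) {
  stopifnot(inherits(traj, "ptsd_trajectory"))
  units <- function(nm) {
    if (nm %in% stock_names || nm == "ill_diag_vet_total") "persons"
    else if (grepl("^diagnosis_rate", nm)) "persons/year"
    else if (grepl("^prevalence", nm)) "dimensionless"
    else if (grepl("^cost", nm)) "USD/year"
    else "persons/year"
  }
  out <- do.call(rbind, lapply(series, function(nm) {
    data.frame(time = traj$time, series = nm, value = traj[[nm]],
               units = units(nm))
  }))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
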