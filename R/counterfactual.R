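#' War-pulse experiment definition
#'
#' A counterfactual experiment measuring system inertia: from a steady
#' state, deployment is stepped up to a war level for the duration of a
#' hypothetical war and back to the peacetime level afterwards.  The
#' standard experiment is a 5-year war with 10% troop deployment (around
#' the maximum Iraq-era deployment) and zero peacetime deployment, which
#' isolates the war's effect from all other exogenous drivers.
#'
#' @param war_start,war_end war interval in simulation years
#'   (`war_end > war_start`).
#' @param war_deployment_frac deployment fraction during the war, \[0, 1\].
#' @param peacetime_deployment_frac deployment outside the war, \[0, 1\].
#' @param recovery_threshold fraction of the veteran ill peak below which
#'   the population counts as recovered ("PTSD-free"), in (0, 1).
#' @return an object of class `pulse_experiment`.
#' @export
pulse_experiment <- function(war_start = 0, war_end = 5,
                             war_deployment_frac = 0.10,
                             peacetime_deployment_frac = 0,
                             recovery_threshold = 0.01) {
  if (war_end <= war_start) {
    stop("'war_end' must exceed 'war_start'", call. = FALSE)
  }
  for (d in c(war_deployment_frac, peacetime_deployment_frac)) {
    if (!is.finite(d) || d < 0 || d > 1) {
      stop("deployment fractions must lie in [0, 1]", call. = FALSE)
    }
  }
  if (recovery_threshold <= 0 || recovery_threshold >= 1) {
    stop("'recovery_threshold' must lie in (0, 1)", call. = FALSE)
  }
  structure(list(war_start = war_start, war_end = war_end,
                 war_deployment_frac = war_deployment_frac,
                 peacetime_deployment_frac = peacetime_deployment_frac,
                 recovery_threshold = recovery_threshold),
            class = "pulse_experiment")
}

#' Parameter set for the counterfactual
#'
#' Freezes every exogenous driver of a calibrated parameter set to a
#' constant: recruitment is held at a constant level, peacetime deployment
#' at `peacetime_deployment_frac`, and the recruitment of people with a
#' pre-enlistment PTSD history is switched off, so that in peacetime the
#' ill stocks relax to zero and the war pulse is the only source of new
#' cases.
#'
#' @param params calibrated [ptsd_params()].
#' @param exp a [pulse_experiment()].
#' @param recruitment constant recruitment level (persons/year); defaults
#'   to the last value of the calibrated recruitment trajectory.
#' @export
counterfactual_params <- function(params, exp = pulse_experiment(),
                                  recruitment = NULL) {
  stopifnot(inherits(params, "ptsd_params"),
            inherits(exp, "pulse_experiment"))
  if (is.null(recruitment)) {
    recruitment <- params$recruitment$value[length(params$recruitment$value)]
  }
  modify_params(params,
                recruitment = recruitment,
                deployment = exp$peacetime_deployment_frac,
                frac_recruit_ptsd_history = 0)
}

#' Steady state under constant exogenous inputs
#'
#' Burns the model in over a long horizon under constant forcings and
#' returns a state where every stock's net flow is numerically zero.
#' Re-simulating from the returned state under unchanged inputs stays
#' constant.
#'
#' @param params a [ptsd_params()] with constant forcings (see
#'   [counterfactual_params()]).
#' @param init optional starting state for the burn-in (default: empty
#'   system filled by recruitment).
#' @param burn_in burn-in horizon, years (default 500).
#' @param dt Euler step, years.
#' @param tol convergence tolerance: largest |net flow| relative to the
#'   stock magnitude (floor 1 person), per year.
#' @return named stock vector at steady state.
#' @export
steady_state <- function(params, init = NULL, burn_in = 500, dt = 1 / 16,
                         tol = 1e-6) {
  if (is.null(init)) {
    init <- stats::setNames(numeric(7), stock_names)
  }
  tr <- simulate_ptsd(params, init, 0, burn_in, dt = dt)
  s <- unlist(tr[nrow(tr), stock_names])
  fl <- compute_flows(s, params, burn_in)
  drift <- .net_change(unname(fl))
  rel <- abs(drift) / pmax(s, 1)
  if (any(rel > tol)) {
    bad <- order(rel, decreasing = TRUE)[1:3]
    stop("no steady state within the burn-in horizon; largest drifts: ",
         paste(sprintf("%s: %.3g/yr (stock %.3g)", stock_names[bad],
                       drift[bad], s[bad]), collapse = ", "),
         call. = FALSE)
  }
  s
}

#' Simulate the war pulse
#'
#' Starting from the steady state of `params`, deployment is stepped to
#' the war level on `[war_start, war_end)` and back to the peacetime level
#' afterwards; the trajectory is run for `horizon` years after the war
#' starts.
#'
#' @param params constant-input [ptsd_params()] (see
#'   [counterfactual_params()]).
#' @param exp a [pulse_experiment()].
#' @param horizon years simulated after `war_start` (default 80).
#' @param dt Euler step, years.
#' @param init optional pre-computed steady state (skips the burn-in).
#' @return a `ptsd_trajectory` with attribute `experiment`.
#' @export
war_pulse <- function(params, exp = pulse_experiment(), horizon = 80,
                      dt = 1 / 16, init = NULL) {
  stopifnot(inherits(exp, "pulse_experiment"))
  if (is.null(init)) init <- steady_state(params, dt = dt)
  pulse <- as_forcing(
    data.frame(year = c(exp$war_start, exp$war_end),
               value = c(exp$war_deployment_frac,
                         exp$peacetime_deployment_frac)),
    method = "constant"
  )
  p <- modify_params(params, deployment = pulse)
  tr <- simulate_ptsd(p, init, exp$war_start, exp$war_start + horizon,
                      dt = dt)
  attr(tr, "experiment") <- exp
  tr
}

#' Recovery time and peak lag of the pulse response
#'
#' From a war-pulse trajectory, finds the peak of the veteran ill
#' population (undiagnosed plus diagnosed, recent cohort) and returns the
#' first time after the peak at which that population falls below
#' `recovery_threshold` times its peak, measured from the war start, plus
#' the lag of the veteran peak behind the war's end.
#'
#' @param traj a trajectory from [war_pulse()].
#' @param exp the [pulse_experiment()] (default: the trajectory's own).
#' @return list of class `pulse_summary`: `recovery_time` (years from war
#'   start), `recovered` (logical; FALSE if the threshold is never reached
#'   within the horizon), `not_applicable` (TRUE for a zero-amplitude
#'   pulse), `peak_time`, `peak_value`, `peak_lag` (veteran peak time minus
#'   war end), `military_peak_time`, `threshold`.
#' @export
recovery_time <- function(traj, exp = attr(traj, "experiment")) {
  stopifnot(inherits(traj, "ptsd_trajectory"),
            inherits(exp, "pulse_experiment"))
  v <- traj$ill_undiag_vet + traj$ill_diag_vet_recent
  m <- traj$ill_undiag_mil + traj$ill_diag_mil
  baseline <- v[1]
  peak_i <- which.max(v)
  peak <- v[peak_i]
  if (peak - baseline <= 1e-9 * max(peak, 1)) {
    return(structure(list(recovery_time = 0, recovered = NA,
                          not_applicable = TRUE, peak_time = NA_real_,
                          peak_value = peak, peak_lag = NA_real_,
                          military_peak_time = NA_real_,
                          threshold = exp$recovery_threshold),
                     class = "pulse_summary"))
  }
  thresh <- exp$recovery_threshold * peak
  after <- which(traj$time > traj$time[peak_i] & v < thresh)
  if (length(after)) {
    rec_t <- traj$time[after[1]] - exp$war_start
    recovered <- TRUE
  } else {
    rec_t <- max(traj$time) - exp$war_start
    recovered <- FALSE
  }
  structure(list(recovery_time = rec_t, recovered = recovered,
                 not_applicable = FALSE,
                 peak_time = traj$time[peak_i], peak_value = peak,
                 peak_lag = traj$time[peak_i] - exp$war_end,
                 military_peak_time = traj$time[which.max(m)],
                 threshold = exp$recovery_threshold),
            class = "pulse_summary")
}

#' @export
print.pulse_summary <- function(x, ...) {
  cat("<pulse_summary>\n")
  if (isTRUE(x$not_applicable)) {
    cat("  zero-amplitude pulse: recovery not applicable\n")
    return(invisible(x))
  }
  cat(sprintf("  veteran ill peak: %.0f persons at year %.2f (lag %.2f yr after war end)\n",
              x$peak_value, x$peak_time, x$peak_lag))
  cat(sprintf("  recovery to %.3g of peak: %.2f yr from war start (%s)\n",
              x$threshold, x$recovery_time,
              if (isTRUE(x$recovered)) "recovered" else "not reached"))
  invisible(x)
}

#' Recovery time across a range of thresholds
#'
#' The "PTSD-free" criterion is a modelling choice (exponential tails
#' never reach exactly zero); this helper documents how the recovery time
#' depends on it over a threshold range, rather than guessing a single
#' value.
#'
#' @param traj a [war_pulse()] trajectory.
#' @param thresholds vector of threshold fractions in (0, 1).
#' @param exp the [pulse_experiment()] (default: the trajectory's own).
#' @return data.frame with columns `threshold`, `recovery_time`,
#'   `recovered`.
#' @export
recovery_threshold_scan <- function(traj,
                                    thresholds = c(0.005, 0.01, 0.02,
                                                   0.03, 0.04, 0.05),
                                    exp = attr(traj, "experiment")) {
  rows <- lapply(thresholds, function(th) {
    e <- exp
    e$recovery_threshold <- th
    r <- recovery_time(traj, e)
    data.frame(threshold = th, recovery_time = r$recovery_time,
               recovered = isTRUE(r$recovered))
  })
  do.call(rbind, rows)
}
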