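#' War scenarios
#'
#' A scenario is an exogenous future-deployment assumption: the fraction of
#' military personnel deployed to intense/combat zones, by year.  The three
#' standard scenarios hold deployment constant from 2015 through the
#' horizon at 1% (scenario 1, the 2014 status quo), 2% (scenario 2) and 5%
#' (scenario 3), spliced onto the historical deployment series.
#'
#' @param name scenario label.
#' @param deployment deployment-fraction forcing (anything [as_forcing()]
#'   accepts); values must lie in \[0, 1\].
#' @return an object of class `ptsd_scenario`.
#' @export
scenario <- function(name, deployment) {
  deployment <- as_forcing(deployment)
  if (any(deployment$value < 0 | deployment$value > 1)) {
    stop(sprintf("scenario '%s': deployment fraction must lie in [0, 1]",
                 name), call. = FALSE)
  }
  structure(list(name = name, deployment = deployment),
            class = "ptsd_scenario")
}

#' @rdname scenario
#' @param historical historical deployment forcing (default: the shipped
#'   2000-2014 series) onto which the constant future levels are spliced.
#' @param levels future deployment fractions of the three scenarios.
#' @param from first year of the future level (default 2015).
#' @param to last year covered (default 2030).
#' @export
default_scenarios <- function(historical = default_params()$deployment,
                              levels = c(0.01, 0.02, 0.05),
                              from = 2015, to = 2030) {
  historical <- as_forcing(historical)
  hist_df <- as.data.frame(historical)
  hist_df <- hist_df[hist_df$year < from, , drop = FALSE]
  mapply(function(lv, i) {
    scenario(paste0("scenario_", i),
             rbind(hist_df, data.frame(year = c(from, to),
                                       value = c(lv, lv))))
  }, levels, seq_along(levels), SIMPLIFY = FALSE)
}

#' Policy interventions
#'
#' A policy is a set of multipliers on three controllable parameters:
#' `screening_mult` scales the fractional symptom-revealing rate in the
#' military (`frac_reveal_mil`), `treatment_mult` scales the fractional
#' treatment rate in the military (`frac_treat_mil`), and
#' `resilience_mult` scales the probability of developing PTSD after
#' trauma (`p_ptsd_given_trauma`; doubling resilience halves that
#' probability).  The base policy leaves all three at 1.
#'
#' @param name policy label.
#' @param screening_mult,treatment_mult non-negative multipliers.
#' @param resilience_mult multiplier in (0, 1\].
#' @return an object of class `ptsd_policy`.
#' @export
policy <- function(name, screening_mult = 1, treatment_mult = 1,
                   resilience_mult = 1) {
  for (m in c(screening_mult, treatment_mult, resilience_mult)) {
    if (!is.finite(m) || m < 0) {
      stop("policy multipliers must be non-negative numbers", call. = FALSE)
    }
  }
  if (resilience_mult > 1 || resilience_mult <= 0) {
    stop("'resilience_mult' must lie in (0, 1]", call. = FALSE)
  }
  structure(list(name = name, screening_mult = screening_mult,
                 treatment_mult = treatment_mult,
                 resilience_mult = resilience_mult),
            class = "ptsd_policy")
}

#' @rdname policy
#' @details [default_policies()] returns the base run plus the seven
#'   standard interventions: P1 doubles screening, P2 doubles treatment,
#'   P3 halves the chance of developing PTSD after trauma (doubled
#'   resilience), and P4-P7 are all combinations of the three.
#' @export
default_policies <- function() {
  list(
    policy("base"),
    policy("P1", screening_mult = 2),
    policy("P2", treatment_mult = 2),
    policy("P3", resilience_mult = 0.5),
    policy("P4", screening_mult = 2, treatment_mult = 2),
    policy("P5", screening_mult = 2, resilience_mult = 0.5),
    policy("P6", treatment_mult = 2, resilience_mult = 0.5),
    policy("P7", screening_mult = 2, treatment_mult = 2,
           resilience_mult = 0.5)
  )
}

#' Apply a policy to a parameter set
#'
#' Returns a new parameter set with the three targeted parameters scaled by
#' the policy multipliers; everything else is untouched.  The post-trauma
#' PTSD probability is capped at 1.
#'
#' @param params a [ptsd_params()] object.
#' @param pol a [policy()] object.
#' @export
apply_policy <- function(params, pol) {
  stopifnot(inherits(params, "ptsd_params"), inherits(pol, "ptsd_policy"))
  modify_params(
    params,
    frac_reveal_mil = params$frac_reveal_mil * pol$screening_mult,
    frac_treat_mil = params$frac_treat_mil * pol$treatment_mult,
    p_ptsd_given_trauma = min(1, params$p_ptsd_given_trauma *
                                pol$resilience_mult)
  )
}

## Historical run to `switch_year` under base parameters, then continuation
## to `horizon` with the policy applied and the scenario deployment in
## force throughout.  Returns the spliced trajectory.
.run_scenario_policy <- function(params, init, scen, pol, t_start,
                                 switch_year, horizon, dt,
                                 prevalence_def) {
  p_scen <- modify_params(params, deployment = scen$deployment)
  tr1 <- simulate_ptsd(p_scen, init, t_start, switch_year, dt = dt,
                       prevalence_def = prevalence_def)
  s_switch <- unlist(tr1[nrow(tr1), stock_names])
  p_pol <- apply_policy(p_scen, pol)
  tr2 <- simulate_ptsd(p_pol, s_switch, switch_year, horizon, dt = dt,
                       prevalence_def = prevalence_def)
  out <- rbind(as.data.frame(tr1)[-nrow(tr1), ], as.data.frame(tr2))
  attributes(out)$params <- p_pol
  attr(out, "dt") <- dt
  attr(out, "prevalence_def") <- prevalence_def
  attr(out, "sector") <- "full"
  class(out) <- c("ptsd_trajectory", "data.frame")
  out
}

#' Run the scenario-by-policy grid
#'
#' Simulates every combination of war scenario and policy intervention and
#' reports, for each sector (military, veterans, total system), PTSD
#' prevalence and annual healthcare costs at the horizon year.  With the 3
#' standard scenarios and the base run plus 7 policies this is 24 cells
#' per sector per measure.  The historical period up to `policy_start`
#' runs under base parameters; policy multipliers act from `policy_start`
#' onward (interventions are future what-ifs, the replicated history is
#' common to all cells).
#'
#' Total-system prevalence pools numerators and denominators across both
#' sectors; sector costs are `cost_mil`, `cost_va` and their sum.
#'
#' @param params calibrated base [ptsd_params()].
#' @param init initial stocks at `t_start`.
#' @param scenarios list of [scenario()]s (default [default_scenarios()]).
#' @param policies list of [policy()]s (default [default_policies()]).
#' @param horizon_year year at which the measures are reported.
#' @param t_start start of the historical run.
#' @param policy_start year from which policy multipliers act.
#' @param dt Euler step, years.
#' @param prevalence_def prevalence definition (see [prevalence()]).
#' @return a `data.frame` (class `ptsd_grid`) with one row per (scenario,
#'   policy, sector): columns `scenario`, `policy`, `sector`,
#'   `prevalence`, `cost`, `diagnosed`, `ok`.  Failed cells carry NA
#'   measures and `ok = FALSE`; the grid is still returned.
#' @export
run_grid <- function(params, init,
                     scenarios = default_scenarios(params$deployment),
                     policies = default_policies(),
                     horizon_year = 2025, t_start = 2000,
                     policy_start = 2015, dt = 1 / 16,
                     prevalence_def = c("all_ill", "diagnosed_only")) {
  prevalence_def <- match.arg(prevalence_def)
  rows <- list()
  for (scen in scenarios) {
    for (pol in policies) {
      cell <- tryCatch({
        tr <- .run_scenario_policy(params, init, scen, pol, t_start,
                                   policy_start, horizon_year, dt,
                                   prevalence_def)
        last <- tr[nrow(tr), ]
        s <- unlist(last[stock_names])
        data.frame(
          scenario = scen$name, policy = pol$name,
          sector = c("military", "veterans", "total"),
          prevalence = c(prevalence(s, "military", prevalence_def),
                         prevalence(s, "veterans", prevalence_def),
                         prevalence(s, "total", prevalence_def)),
          cost = c(last$cost_mil, last$cost_va,
                   last$cost_mil + last$cost_va),
          diagnosed = c(last$ill_diag_mil, last$ill_diag_vet_total,
                        last$ill_diag_mil + last$ill_diag_vet_total),
          ok = TRUE
        )
      }, error = function(e) {
        data.frame(scenario = scen$name, policy = pol$name,
                   sector = c("military", "veterans", "total"),
                   prevalence = NA_real_, cost = NA_real_,
                   diagnosed = NA_real_, ok = FALSE)
      })
      rows[[length(rows) + 1L]] <- cell
    }
  }
  grid <- do.call(rbind, rows)
  attr(grid, "horizon_year") <- horizon_year
  attr(grid, "prevalence_def") <- prevalence_def
  class(grid) <- c("ptsd_grid", "data.frame")
  grid
}

#' Reshape a grid to the policy-by-scenario layout
#'
#' Rows are the base run and policies P1-P7, columns the scenarios, for
#' one sector and one measure.
#'
#' @param grid a `ptsd_grid` from [run_grid()].
#' @param sector `"military"`, `"veterans"` or `"total"`.
#' @param measure `"prevalence"`, `"cost"` or `"diagnosed"`.
#' @export
grid_to_wide <- function(grid, sector = "military",
                         measure = c("prevalence", "cost", "diagnosed")) {
  measure <- match.arg(measure)
  stopifnot(inherits(grid, "ptsd_grid"))
  g <- grid[grid$sector == sector, ]
  pol_order <- unique(g$policy)
  scen_order <- unique(g$scenario)
  wide <- sapply(scen_order, function(sc) {
    g[[measure]][match(paste(pol_order, sc),
                       paste(g$policy, g$scenario))]
  })
  wide <- matrix(wide, nrow = length(pol_order),
                 dimnames = list(pol_order, scen_order))
  as.data.frame(wide)
}

#' Latin-hypercube sensitivity sweep
#'
#' Samples the named parameters within their ranges by a seeded Latin
#' hypercube, re-simulates, and reports the spread (min/median/max) of the
#' horizon-year prevalence and costs per sector.
#'
#' @param params base [ptsd_params()].
#' @param init initial stocks.
#' @param ranges named list of `c(low, high)` ranges (low <= high).
#' @param n_samples number of hypercube samples (>= 2).
#' @param seed integer seed.
#' @param t_start,horizon_year,dt simulation window and step.
#' @param prevalence_def prevalence definition.
#' @return data.frame with columns `measure`, `min`, `median`, `max`;
#'   attribute `samples` holds the sampled parameter matrix.
#' @export
sensitivity_sweep <- function(params, init, ranges, n_samples, seed = 1,
                              t_start = 2000, horizon_year = 2025,
                              dt = 1 / 16,
                              prevalence_def = c("all_ill",
                                                 "diagnosed_only")) {
  prevalence_def <- match.arg(prevalence_def)
  if (n_samples < 2) stop("'n_samples' must be >= 2", call. = FALSE)
  if (!is.list(ranges) || is.null(names(ranges))) {
    stop("'ranges' must be a named list of c(low, high)", call. = FALSE)
  }
  lo <- vapply(ranges, `[`, numeric(1), 1L)
  hi <- vapply(ranges, `[`, numeric(1), 2L)
  if (any(lo < 0) || any(hi < lo)) {
    stop("ranges must satisfy 0 <= low <= high", call. = FALSE)
  }
  k <- length(ranges)
  set.seed(seed)
  u <- lhs::randomLHS(n_samples, k)
  samples <- sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(samples) <- names(ranges)

  measures <- c("prevalence_mil", "prevalence_vet", "prevalence_total",
                "cost_mil", "cost_va")
  vals <- matrix(NA_real_, n_samples, length(measures),
                 dimnames = list(NULL, measures))
  for (i in seq_len(n_samples)) {
    pp <- do.call(modify_params, c(list(params),
                                   as.list(samples[i, , drop = TRUE])))
    tr <- simulate_ptsd(pp, init, t_start, horizon_year, dt = dt,
                        prevalence_def = prevalence_def)
    last <- tr[nrow(tr), ]
    vals[i, ] <- c(last$prevalence_mil, last$prevalence_vet,
                   last$prevalence_total, last$cost_mil, last$cost_va)
  }
  out <- data.frame(
    measure = measures,
    min = apply(vals, 2, min),
    median = apply(vals, 2, stats::median),
    max = apply(vals, 2, max),
    row.names = NULL
  )
  attr(out, "samples") <- samples
  attr(out, "seed") <- seed
  out
}
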