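#' An observed historical series
#'
#' A named data series used for calibration.  The name must match a
#' trajectory output column (e.g. `ill_diag_mil`, `diagnosis_rate_mil`,
#' `ill_diag_vet_total`, `cost_va`); values carry the units of that output.
#'
#' @param name identifier matching a trajectory output.
#' @param years calendar years, strictly increasing.
#' @param values observed values, finite.
#' @param weight non-negative calibration weight (default 1).
#' @return an object of class `observed_series`.
#' @export
observed_series <- function(name, years, values, weight = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  years <- as.numeric(years); values <- as.numeric(values)
  if (length(years) != length(values) || length(years) < 1L) {
    stop("'years' and 'values' must have equal, positive length",
         call. = FALSE)
  }
  if (is.unsorted(years, strictly = TRUE)) {
    stop(sprintf("years of series '%s' must be strictly increasing", name),
         call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop(sprintf("series '%s' contains non-finite values", name),
         call. = FALSE)
  }
  if (!is.finite(weight) || weight < 0) {
    stop("'weight' must be a non-negative number", call. = FALSE)
  }
  structure(list(name = name, years = years, values = values,
                 weight = weight),
            class = "observed_series")
}

#' @export
print.observed_series <- function(x, ...) {
  cat(sprintf("<observed_series> %s: %d points over %g-%g (weight %g)\n",
              x$name, length(x$years), min(x$years), max(x$years),
              x$weight))
  invisible(x)
}

.as_series_list <- function(data) {
  if (inherits(data, "observed_series")) data <- list(data)
  if (!is.list(data) ||
      !all(vapply(data, inherits, logical(1), "observed_series"))) {
    stop("'data' must be an observed_series or a list of them",
         call. = FALSE)
  }
  data
}

#' Calibration payoff
#'
#' Weighted sum of squared scaled residuals between a simulated trajectory
#' and a collection of observed series:
#' `sum_series w * sum_years ((model - data) / scale)^2`, where `scale` is
#' the mean absolute value of the series' data.  Scaling makes series of
#' very different magnitude (cases vs. billions of dollars) commensurable.
#' The payoff is zero if and only if the model matches the data at every
#' fitted point (for positive weights).
#'
#' @param traj a `ptsd_trajectory`.
#' @param data an `observed_series` or list of them.
#' @return non-negative dimensionless scalar.
#' @export
payoff <- function(traj, data) {
  stopifnot(inherits(traj, "ptsd_trajectory"))
  data <- .as_series_list(data)
  total <- 0
  for (s in data) {
    if (!s$name %in% names(traj)) {
      stop(sprintf("series '%s' does not map to any trajectory output",
                   s$name), call. = FALSE)
    }
    m <- trajectory_value(traj, s$name, s$years)
    scale <- mean(abs(s$values))
    if (scale == 0) scale <- 1
    total <- total + s$weight * sum(((m - s$values) / scale)^2)
  }
  total
}

## logit transform of x within [lo, hi] and back; keeps the simplex search
## unconstrained while respecting bounds
.to_unconstrained <- function(x, lo, hi) {
  u <- (x - lo) / (hi - lo)
  u <- pmin(pmax(u, 1e-10), 1 - 1e-10)
  log(u / (1 - u))
}
.from_unconstrained <- function(z, lo, hi) lo + (hi - lo) * stats::plogis(z)

#' Partial-model calibration
#'
#' Estimates free parameters by minimising [payoff()] over seeded
#' multi-start derivative-free local searches (Nelder-Mead simplex on
#' logit-transformed parameters; Brent's method for a single parameter).
#' Partial calibration fits a subsystem whose boundary inflows are driven
#' directly by data rather than by the rest of the model: the military
#' block is fit with the observed deployment trajectory as forcing
#' (`submodel = "military"`; the block is upstream of the veteran block, so
#' no other boundary flows exist), and the veteran block is fit with
#' observed separation flows as forcing (`submodel = "veterans"`, via
#' `drive`).
#'
#' @param params baseline [ptsd_params()]; non-free parameters keep these
#'   values.
#' @param data observed series (list of [observed_series()]), each with at
#'   least 3 points.
#' @param free named list: for each free parameter name, a numeric
#'   `c(lower, upper)` bound pair (finite, lower >= 0).
#' @param submodel `"military"`, `"veterans"` or `"full"`.
#' @param init initial stock state for the fitted simulations.
#' @param t_start,t_end,dt simulation window and step.
#' @param drive boundary forcings for the veteran submodel (see
#'   [simulate_ptsd()]).
#' @param n_starts number of multi-start points (default 10).
#' @param seed integer seed making the multi-start reproducible.
#' @param maxit maximum simplex iterations per start.
#' @return a `ptsd_calibration`: list with `estimates`, `payoff`,
#'   `converged`, `per_series` residual summaries, `free` bounds, `seed`,
#'   `n_evals`, and the `objective` function (payoff as a function of a
#'   named parameter vector) for downstream diagnostics.
#' @export
calibrate_partial <- function(params, data, free,
                              submodel = c("military", "veterans", "full"),
                              init, t_start, t_end, dt = 1 / 16,
                              drive = NULL, n_starts = 10, seed = 1,
                              maxit = 500) {
  submodel <- match.arg(submodel)
  data <- .as_series_list(data)
  short <- vapply(data, function(s) length(s$years) < 3L, logical(1))
  if (any(short)) {
    stop(sprintf("series '%s' has fewer than 3 points; at least 3 are needed for fitting",
                 data[[which(short)[1]]]$name), call. = FALSE)
  }
  if (!is.list(free) || is.null(names(free)) || length(free) == 0L) {
    stop("'free' must be a named list of c(lower, upper) bounds",
         call. = FALSE)
  }
  unknown <- setdiff(names(free), .scalar_param_names)
  if (length(unknown)) {
    stop("free parameter(s) not in the parameter set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  lo <- vapply(free, `[`, numeric(1), 1L)
  hi <- vapply(free, `[`, numeric(1), 2L)
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo < 0) ||
      any(hi <= lo)) {
    stop("bounds must be finite with 0 <= lower < upper", call. = FALSE)
  }
  sector <- if (submodel == "full") "full" else submodel

  n_evals <- 0L
  objective <- function(x) {
    n_evals <<- n_evals + 1L
    pp <- do.call(modify_params, c(list(params), as.list(x)))
    tr <- simulate_ptsd(pp, init, t_start, t_end, dt = dt,
                        sector = sector, drive = drive)
    payoff(tr, data)
  }

  k <- length(free)
  set.seed(seed)
  starts <- lhs::randomLHS(n_starts, k)
  best <- NULL
  for (i in seq_len(n_starts)) {
    x0 <- lo + (hi - lo) * starts[i, ]
    if (k == 1L) {
      fit <- stats::optim(x0, function(v) {
        names(v) <- names(free); objective(v)
      }, method = "Brent", lower = lo, upper = hi,
      control = list(maxit = maxit))
      est <- stats::setNames(fit$par, names(free))
    } else {
      fit <- stats::optim(
        .to_unconstrained(x0, lo, hi),
        function(z) {
          v <- .from_unconstrained(z, lo, hi)
          names(v) <- names(free)
          objective(v)
        },
        method = "Nelder-Mead",
        control = list(maxit = maxit, reltol = 1e-12)
      )
      est <- stats::setNames(.from_unconstrained(fit$par, lo, hi),
                             names(free))
    }
    if (is.null(best) || fit$value < best$value) {
      best <- list(value = fit$value, estimates = est,
                   converged = fit$convergence == 0L)
    }
  }

  p_best <- do.call(modify_params, c(list(params), as.list(best$estimates)))
  tr <- simulate_ptsd(p_best, init, t_start, t_end, dt = dt,
                      sector = sector, drive = drive)
  per_series <- do.call(rbind, lapply(data, function(s) {
    m <- trajectory_value(tr, s$name, s$years)
    data.frame(series = s$name, n = length(s$years),
               rmse = sqrt(mean((m - s$values)^2)),
               scale = mean(abs(s$values)), weight = s$weight)
  }))

  structure(list(estimates = best$estimates, payoff = best$value,
                 converged = best$converged, per_series = per_series,
                 free = free, seed = seed, n_starts = n_starts,
                 n_evals = n_evals, submodel = submodel,
                 objective = objective),
            class = "ptsd_calibration")
}

#' @export
print.ptsd_calibration <- function(x, ...) {
  cat(sprintf("<ptsd_calibration> %s submodel, payoff %.4g (%sconverged, seed %d, %d evals)\n",
              x$submodel, x$payoff, if (x$converged) "" else "NOT ",
              x$seed, x$n_evals))
  for (nm in names(x$estimates)) {
    cat(sprintf("  %-22s %.6g  in [%g, %g]\n", nm, x$estimates[[nm]],
                x$free[[nm]][1], x$free[[nm]][2]))
  }
  invisible(x)
}

#' Identifiability report from payoff curvature
#'
#' Scans each estimated parameter over a multiplicative grid (other
#' parameters held at their estimates) and reports the interval inside
#' which the payoff stays below twice its minimum (with a small absolute
#' floor for near-perfect fits).  A parameter whose interval spans more
#' than a factor of 10 is flagged as weakly identified.
#'
#' @param fit a `ptsd_calibration` result.
#' @param span half-width of the multiplicative scan, as a factor
#'   (default 20: the scan covers estimate/20 to estimate*20, clipped to
#'   the bounds).
#' @param n_grid grid points per parameter.
#' @return data.frame with columns `parameter`, `estimate`, `lower`,
#'   `upper`, `interval_ratio`, `flagged`.
#' @export
identifiability_report <- function(fit, span = 20, n_grid = 61) {
  stopifnot(inherits(fit, "ptsd_calibration"))
  threshold <- max(2 * fit$payoff, fit$payoff + 1e-8)
  out <- lapply(names(fit$estimates), function(nm) {
    est <- fit$estimates[[nm]]
    b <- fit$free[[nm]]
    base <- if (est > 0) est else (b[1] + b[2]) / 2
    grid <- sort(unique(pmin(pmax(
      base * exp(seq(-log(span), log(span), length.out = n_grid)),
      b[1]), b[2])))
    vals <- vapply(grid, function(g) {
      x <- fit$estimates
      x[nm] <- g
      fit$objective(x)
    }, numeric(1))
    i0 <- which.min(abs(grid - est))
    ok <- vals <= threshold
    lo_i <- i0
    while (lo_i > 1L && ok[lo_i - 1L]) lo_i <- lo_i - 1L
    hi_i <- i0
    while (hi_i < length(grid) && ok[hi_i + 1L]) hi_i <- hi_i + 1L
    lower <- grid[lo_i]; upper <- grid[hi_i]
    ratio <- if (lower > 0) upper / lower else Inf
    data.frame(parameter = nm, estimate = est, lower = lower,
               upper = upper, interval_ratio = ratio,
               flagged = ratio > 10)
  })
  do.call(rbind, out)
}

#' Serialize a calibration result
#'
#' Writes estimates, bounds, payoff, convergence flag, seed and per-series
#' residual summaries as JSON.
#'
#' @param fit a `ptsd_calibration`.
#' @param path output path.
#' @export
write_calibration_json <- function(fit, path) {
  stopifnot(inherits(fit, "ptsd_calibration"))
  jsonlite::write_json(list(
    submodel = fit$submodel,
    estimates = as.list(fit$estimates),
    bounds = fit$free,
    payoff = fit$payoff,
    converged = fit$converged,
    seed = fit$seed,
    n_starts = fit$n_starts,
    n_evals = fit$n_evals,
    per_series = fit$per_series
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
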