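.fixture_files <- c(params = "parameters.csv",
                    exogenous = "exogenous.csv",
                    initial = "initial_state.csv",
                    history = "history.csv")

#' Load the packaged fixture bundle
#'
#' Reads the versioned fixture files (parameter table with per-entry source
#' tags, exogenous trajectories, 2000 initial stocks, and the historical
#' 2000-2014 observed series) and returns a validated bundle.  The shipped
#' historical series are synthetic reconstructions: the underlying agency
#' tables are not redistributed, so the series are generated from the
#' calibrated base run under the published summary constraints (see the
#' provenance column and the methods vignette).
#'
#' @param path directory holding the fixture CSV files; defaults to the
#'   files shipped with the package.
#' @return an object of class `ptsd_fixtures`: a list with elements
#'   `params` (a [ptsd_params()]), `initial_state` (named stock vector),
#'   `history` (list of [observed_series()]), and `provenance`
#'   (data.frame of every parameter entry with its source tag).
#' @export
load_fixtures <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", package = "ptsdflow")
  }
  files <- file.path(path, .fixture_files)
  names(files) <- names(.fixture_files)
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop("fixture file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  par_tab <- utils::read.csv(files[["params"]], stringsAsFactors = FALSE)
  exo <- utils::read.csv(files[["exogenous"]], stringsAsFactors = FALSE)
  ini <- utils::read.csv(files[["initial"]], stringsAsFactors = FALSE)
  hist <- utils::read.csv(files[["history"]], stringsAsFactors = FALSE)

  for (col in c("name", "value", "units", "source")) {
    if (!col %in% names(par_tab)) {
      stop(sprintf("parameters.csv lacks column '%s'", col), call. = FALSE)
    }
  }
  if (is.null(par_tab$name) || anyNA(par_tab$value)) {
    stop("parameters.csv has missing values", call. = FALSE)
  }
  vals <- stats::setNames(par_tab$value, par_tab$name)
  death_names <- paste0("death_rate_", stock_names)
  need <- c(.scalar_param_names, death_names)
  absent <- setdiff(need, names(vals))
  if (length(absent)) {
    stop("parameters.csv lacks entries: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }

  exo_need <- c("recruitment", "deployment_frac")
  if (!all(exo_need %in% exo$series)) {
    stop("exogenous.csv must provide series: ",
         paste(exo_need, collapse = ", "), call. = FALSE)
  }
  forcing_of <- function(nm) {
    d <- exo[exo$series == nm, c("year", "value")]
    as_forcing(d)
  }

  params <- ptsd_params(
    recruitment = forcing_of("recruitment"),
    frac_recruit_ptsd_history = vals[["frac_recruit_ptsd_history"]],
    deployment = forcing_of("deployment_frac"),
    trauma_exposure_rate = vals[["trauma_exposure_rate"]],
    p_ptsd_given_trauma = vals[["p_ptsd_given_trauma"]],
    frac_reveal_mil = vals[["frac_reveal_mil"]],
    frac_treat_mil = vals[["frac_treat_mil"]],
    frac_reveal_vet = vals[["frac_reveal_vet"]],
    frac_treat_vet = vals[["frac_treat_vet"]],
    separation_rate_healthy = vals[["separation_rate_healthy"]],
    separation_rate_undiag = vals[["separation_rate_undiag"]],
    discharge_rate_diag = vals[["discharge_rate_diag"]],
    death_rates = stats::setNames(vals[death_names], stock_names),
    cost_per_patient_mil = vals[["cost_per_patient_mil"]],
    cost_per_patient_va = vals[["cost_per_patient_va"]]
  )

  if (!all(stock_names %in% ini$stock)) {
    stop("initial_state.csv must provide every stock in `stock_names`",
         call. = FALSE)
  }
  init <- stats::setNames(ini$value, ini$stock)[stock_names]
  if (anyNA(init) || any(init < 0)) {
    bad <- stock_names[which(is.na(init) | init < 0)[1]]
    stop(sprintf("initial stock '%s' must be a non-negative number", bad),
         call. = FALSE)
  }

  history <- lapply(split(hist, hist$series), function(d) {
    d <- d[order(d$year), ]
    w <- if ("weight" %in% names(d)) d$weight[1] else 1
    observed_series(d$series[1], d$year, d$value, weight = w)
  })

  structure(list(params = params, initial_state = init, history = history,
                 provenance = par_tab[, c("name", "value", "units",
                                          "source")],
                 path = path),
            class = "ptsd_fixtures")
}

#' Save a fixture bundle
#'
#' Writes the four fixture CSV files so that [load_fixtures()] on the
#' target directory round-trips the bundle.
#'
#' @param bundle a `ptsd_fixtures` object.
#' @param dir output directory (created if needed).
#' @export
save_fixtures <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ptsd_fixtures"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$provenance,
                   file.path(dir, .fixture_files[["params"]]),
                   row.names = FALSE)
  p <- bundle$params
  exo <- rbind(
    data.frame(series = "recruitment", year = p$recruitment$year,
               value = p$recruitment$value),
    data.frame(series = "deployment_frac", year = p$deployment$year,
               value = p$deployment$value)
  )
  utils::write.csv(exo, file.path(dir, .fixture_files[["exogenous"]]),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(stock = stock_names,
               value = unname(bundle$initial_state[stock_names]),
               units = "persons",
               source = "synthetic reconstruction (calibrated)"),
    file.path(dir, .fixture_files[["initial"]]), row.names = FALSE)
  hist <- do.call(rbind, lapply(bundle$history, function(s) {
    data.frame(series = s$name, year = s$years, value = s$values,
               weight = s$weight)
  }))
  utils::write.csv(hist, file.path(dir, .fixture_files[["history"]]),
                   row.names = FALSE)
  invisible(dir)
}

#' @export
print.ptsd_fixtures <- function(x, ...) {
  cat(sprintf("<ptsd_fixtures> %d parameters, %d historical series, initial year stocks for %d compartments\n",
              nrow(x$provenance), length(x$history),
              length(x$initial_state)))
  invisible(x)
}

#' Placeholder / synthetic provenance report
#'
#' Lists every fixture parameter whose value is a synthetic placeholder or
#' package calibration rather than a figure printed in the source
#' literature.
#'
#' @param bundle a `ptsd_fixtures` bundle.
#' @return data.frame subset of the provenance table.
#' @export
fixture_placeholders <- function(bundle) {
  stopifnot(inherits(bundle, "ptsd_fixtures"))
  prov <- bundle$provenance
  prov[grepl("synthetic|placeholder|calibrat", prov$source,
             ignore.case = TRUE), ]
}

#' Default calibrated parameter set and initial state
#'
#' Convenience accessors for the shipped fixture bundle.
#' @return [default_params()]: a [ptsd_params()];
#'   [default_initial_state()]: named stock vector for the year 2000.
#' @export
default_params <- function() load_fixtures()$params

#' @rdname default_params
#' @export
default_initial_state <- function() load_fixtures()$initial_state

#' Generate a synthetic observed history
#'
#' Runs the model and samples annual outputs, optionally multiplied by
#' mean-one lognormal observation noise with a given coefficient of
#' variation.  With `noise_cv = 0` the series reproduce the model outputs
#' exactly; a fixed seed makes the noise reproducible.  Used for
#' parameter-recovery testing of the calibration machinery.
#'
#' @param params a [ptsd_params()].
#' @param init initial stocks.
#' @param series character vector of trajectory output names to sample.
#' @param years sampling years.
#' @param noise_cv coefficient of variation of the multiplicative
#'   observation noise (>= 0).
#' @param seed integer seed.
#' @param t_start,t_end,dt simulation window and step (default: the span
#'   of `years`).
#' @param sector,drive passed to [simulate_ptsd()].
#' @return list of [observed_series()].
#' @export
generate_synthetic_history <- function(params, init,
                                       series = c("diagnosis_rate_mil",
                                                  "ill_diag_mil"),
                                       years = 2000:2014,
                                       noise_cv = 0, seed = 1,
                                       t_start = min(years),
                                       t_end = max(years), dt = 1 / 16,
                                       sector = "full", drive = NULL) {
  if (noise_cv < 0) stop("'noise_cv' must be >= 0", call. = FALSE)
  tr <- simulate_ptsd(params, init, t_start, t_end, dt = dt,
                      sector = sector, drive = drive)
  set.seed(seed)
  lapply(series, function(nm) {
    v <- trajectory_value(tr, nm, years)
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      v <- v * stats::rlnorm(length(v), meanlog = -sdlog^2 / 2,
                             sdlog = sdlog)
    }
    observed_series(nm, years, v)
  })
}
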