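.scalar_param_names <- c(
  "frac_recruit_ptsd_history", "trauma_exposure_rate",
  "p_ptsd_given_trauma", "frac_reveal_mil", "frac_treat_mil",
  "frac_reveal_vet", "frac_treat_vet",
  "separation_rate_healthy", "separation_rate_undiag",
  "discharge_rate_diag",
  "cost_per_patient_mil", "cost_per_patient_va"
)

#' Model parameter set
#'
#' Collects every rate constant, fraction, exogenous driver and unit cost of
#' the model.  Rates are fractional rates per year (first-order outflow
#' coefficients); fractions are dimensionless in \[0, 1\]; costs are constant
#' 2012 US dollars per patient per year.
#'
#' @param recruitment recruitment into the military, persons/year
#'   (number, table or [as_forcing()] object).
#' @param frac_recruit_ptsd_history fraction of recruits entering with a
#'   pre-enlistment history of PTSD (pathway 1b), in \[0, 1\].
#' @param deployment fraction of military personnel deployed to
#'   intense/combat zones, in \[0, 1\] (forcing).
#' @param trauma_exposure_rate trauma exposures per deployed person-year
#'   (1/year); applies only to the deployed fraction of healthy personnel.
#' @param p_ptsd_given_trauma probability of developing PTSD after a trauma
#'   exposure (dimensionless; base value 0.17).
#' @param frac_reveal_mil fractional annual rate at which ill-undiagnosed
#'   military personnel reveal symptoms and are diagnosed (pathway 3;
#'   1/year; base value 0.043).
#' @param frac_treat_mil fractional annual rate of successful treatment of
#'   ill-diagnosed military personnel (pathway 4; 1/year; base value 0.125).
#' @param frac_reveal_vet fractional annual rate of diagnosis among
#'   ill-undiagnosed veterans (pathway 8; 1/year).
#' @param frac_treat_vet fractional annual rate of successful treatment of
#'   ill-diagnosed veterans (pathway 9; 1/year).
#' @param separation_rate_healthy fractional annual rate of healthy
#'   separation from the military (pathway 5; 1/year).
#' @param separation_rate_undiag fractional annual separation rate of
#'   ill-undiagnosed personnel (pathway 6; 1/year).
#' @param discharge_rate_diag fractional annual separation/discharge rate of
#'   ill-diagnosed personnel (pathway 7; 1/year).
#' @param death_rates named numeric vector of fractional death rates
#'   (1/year), one per stock in [stock_names].
#' @param cost_per_patient_mil annual healthcare cost per diagnosed PTSD
#'   patient in the military (2012 USD/person/year; base value 4500).
#' @param cost_per_patient_va annual healthcare cost per diagnosed PTSD
#'   patient in the VA (2012 USD/person/year; base value 6244).
#' @return an object of class `ptsd_params`.
#' @seealso [default_params()] for the calibrated shipped parameterisation,
#'   [modify_params()] for derived sets, [apply_policy()] for intervention
#'   multipliers.
#' @export
ptsd_params <- function(recruitment,
                        frac_recruit_ptsd_history,
                        deployment,
                        trauma_exposure_rate,
                        p_ptsd_given_trauma,
                        frac_reveal_mil,
                        frac_treat_mil,
                        frac_reveal_vet,
                        frac_treat_vet,
                        separation_rate_healthy,
                        separation_rate_undiag,
                        discharge_rate_diag,
                        death_rates,
                        cost_per_patient_mil,
                        cost_per_patient_va) {
  p <- list(
    recruitment = as_forcing(recruitment),
    frac_recruit_ptsd_history = as.numeric(frac_recruit_ptsd_history),
    deployment = as_forcing(deployment),
    trauma_exposure_rate = as.numeric(trauma_exposure_rate),
    p_ptsd_given_trauma = as.numeric(p_ptsd_given_trauma),
    frac_reveal_mil = as.numeric(frac_reveal_mil),
    frac_treat_mil = as.numeric(frac_treat_mil),
    frac_reveal_vet = as.numeric(frac_reveal_vet),
    frac_treat_vet = as.numeric(frac_treat_vet),
    separation_rate_healthy = as.numeric(separation_rate_healthy),
    separation_rate_undiag = as.numeric(separation_rate_undiag),
    discharge_rate_diag = as.numeric(discharge_rate_diag),
    death_rates = death_rates,
    cost_per_patient_mil = as.numeric(cost_per_patient_mil),
    cost_per_patient_va = as.numeric(cost_per_patient_va)
  )
  class(p) <- "ptsd_params"
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks the invariants of the parameter set: every rate and cost is
#' non-negative and finite, every fraction lies in \[0, 1\] (including the
#' whole deployment trajectory), and the death-rate vector names every
#' stock.  Invisibly returns the validated object; stops with a message
#' naming the offending quantity otherwise.
#'
#' @param params a `ptsd_params` object.
#' @export
validate_params <- function(params) {
  if (!inherits(params, "ptsd_params")) {
    stop("not a 'ptsd_params' object", call. = FALSE)
  }
  for (nm in .scalar_param_names) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("parameter '%s' must be a single finite number", nm),
           call. = FALSE)
    }
    if (v < 0) {
      stop(sprintf("parameter '%s' is negative (%g); rates, fractions and costs must be >= 0",
                   nm, v), call. = FALSE)
    }
  }
  for (nm in c("frac_recruit_ptsd_history", "p_ptsd_given_trauma")) {
    if (params[[nm]] > 1) {
      stop(sprintf("parameter '%s' is a fraction and must lie in [0, 1], got %g",
                   nm, params[[nm]]), call. = FALSE)
    }
  }
  dep <- params$deployment
  if (any(dep$value < 0 | dep$value > 1)) {
    stop(sprintf("parameter 'deployment' must lie in [0, 1]; found value %g",
                 dep$value[which(dep$value < 0 | dep$value > 1)[1]]),
         call. = FALSE)
  }
  if (any(params$recruitment$value < 0)) {
    stop("parameter 'recruitment' must be >= 0", call. = FALSE)
  }
  dr <- params$death_rates
  if (!is.numeric(dr) || length(dr) != length(stock_names) ||
      is.null(names(dr)) || !setequal(names(dr), stock_names)) {
    stop("'death_rates' must be a numeric vector named after all seven stocks",
         call. = FALSE)
  }
  if (anyNA(dr) || any(dr < 0) || any(!is.finite(dr))) {
    bad <- names(dr)[which(is.na(dr) | dr < 0 | !is.finite(dr))[1]]
    stop(sprintf("death rate for stock '%s' must be finite and >= 0", bad),
         call. = FALSE)
  }
  invisible(params)
}

#' Derive a modified parameter set
#'
#' Returns a copy of `params` with the named fields replaced, re-validated.
#' Forcings (`recruitment`, `deployment`) may be given as numbers or tables.
#'
#' @param params a `ptsd_params` object.
#' @param ... named replacement values.
#' @export
modify_params <- function(params, ...) {
  stopifnot(inherits(params, "ptsd_params"))
  repl <- list(...)
  if (length(repl) == 0L) return(params)
  if (is.null(names(repl)) || any(names(repl) == "")) {
    stop("all replacements must be named", call. = FALSE)
  }
  unknown <- setdiff(names(repl), names(unclass(params)))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(repl)) {
    v <- repl[[nm]]
    if (nm %in% c("recruitment", "deployment")) v <- as_forcing(v)
    params[[nm]] <- v
  }
  validate_params(params)
  params
}

#' @export
print.ptsd_params <- function(x, ...) {
  cat("<ptsd_params>\n")
  for (nm in .scalar_param_names) {
    cat(sprintf("  %-26s %g\n", nm, x[[nm]]))
  }
  cat("  death_rates:", paste(sprintf("%s=%g", names(x$death_rates),
                                      x$death_rates), collapse = " "), "\n")
  cat("  recruitment: "); print(x$recruitment)
  cat("  deployment:  "); print(x$deployment)
  invisible(x)
}
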