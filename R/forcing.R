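#' Exogenous forcing trajectories
#'
#' A forcing is a time-varying exogenous input to the model (recruitment in
#' persons/year, or the fraction of military personnel deployed to
#' intense/combat zones).  It is stored as a table of (year, value) pairs.
#' Between listed years the value is linearly interpolated (or held constant
#' from the left for `method = "constant"`, which is appropriate for stepwise
#' experiments such as the war pulse); outside the listed range the nearest
#' listed value is used (last-value extrapolation).
#'
#' @param x a single number (constant forcing), a two-column `data.frame`
#'   with columns `year` and `value`, or an existing `ptsd_forcing`.
#' @param method interpolation between listed years: `"linear"` (default) or
#'   `"constant"` (left-continuous step function).
#' @return an object of class `ptsd_forcing`.
#' @examples
#' dep <- as_forcing(data.frame(year = c(2000, 2008), value = c(0.01, 0.108)))
#' forcing_value(dep, 2004)   # midpoint, linearly interpolated
#' forcing_value(dep, 2030)   # beyond the table: last value
#' @export
as_forcing <- function(x, method = c("linear", "constant")) {
  method <- match.arg(method)
  if (inherits(x, "ptsd_forcing")) {
    return(x)
  }
  if (is.numeric(x) && length(x) == 1L && is.null(dim(x))) {
    x <- data.frame(year = 0, value = as.numeric(x))
  }
  if (!is.data.frame(x) || !all(c("year", "value") %in% names(x))) {
    stop("a forcing must be a single number or a data.frame with columns ",
         "'year' and 'value'", call. = FALSE)
  }
  x <- x[order(x$year), c("year", "value"), drop = FALSE]
  if (anyNA(x$year) || anyNA(x$value)) {
    stop("forcing table contains missing values", call. = FALSE)
  }
  if (anyDuplicated(x$year)) {
    stop("forcing table has duplicated years", call. = FALSE)
  }
  structure(list(year = as.numeric(x$year), value = as.numeric(x$value),
                 method = method),
            class = "ptsd_forcing")
}

#' Evaluate a forcing at given times
#'
#' @param f a `ptsd_forcing` (or anything [as_forcing()] accepts).
#' @param t numeric vector of calendar years.
#' @return numeric vector of forcing values at `t`.
#' @export
forcing_value <- function(f, t) {
  f <- as_forcing(f)
  if (anyNA(t)) {
    stop("forcing evaluated at an undefined time (NA)", call. = FALSE)
  }
  if (length(f$year) == 1L) {
    return(rep(f$value, length(t)))
  }
  stats::approx(f$year, f$value, xout = t, method = f$method,
                rule = 2, f = 0, ties = "ordered")$y
}

#' @export
print.ptsd_forcing <- function(x, ...) {
  if (length(x$year) == 1L) {
    cat(sprintf("<ptsd_forcing> constant %.6g\n", x$value))
  } else {
    cat(sprintf("<ptsd_forcing> %d points, %s interpolation, %.6g-%.6g over %s-%s\n",
                length(x$year), x$method, min(x$value), max(x$value),
                format(min(x$year)), format(max(x$year))))
  }
  invisible(x)
}

#' @export
as.data.frame.ptsd_forcing <- function(x, ...) {
  data.frame(year = x$year, value = x$value)
}
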