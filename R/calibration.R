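#' Gas calibration constants for a MOS sensor
#'
#' A `gas_calibration` holds the two constants of the power-law sensitivity
#' model \eqn{R_s = A \, C^{\alpha}} relating gas concentration \eqn{C} (ppm)
#' to the sensing-element resistivity \eqn{R_s} (dimensionless sensor units,
#' as published in Figaro datasheet sensitivity plots). Datasheet entries that
#' are not published for a model are represented with `available = FALSE`
#' rather than zeros, so they can never silently propagate into features.
#'
#' @param gas_name one of `"methane"`, `"isobutane"`, `"hydrogen"`,
#'   `"propane"`, `"ethanol"`, `"air"`, `"CO"`.
#' @param A resistivity scale, strictly positive when available.
#' @param alpha power-law exponent; `alpha = 0` gives a concentration-independent
#'   response (valid forward, non-invertible).
#' @param available logical; `FALSE` marks a gas/model pair with no published
#'   sensitivity curve.
#' @return an object of class `gas_calibration`.
#' @seealso [resistivity_from_concentration()], [concentration_from_resistivity()],
#'   [fit_power_law()], [sensor_models()]
#' @export
gas_calibration <- function(gas_name, A = NA_real_, alpha = NA_real_,
                            available = TRUE) {
  gas_name <- match.arg(gas_name, enose_gases())
  if (available) {
    stopifnot(is.numeric(A), length(A) == 1L, is.finite(A), A > 0,
              is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  } else {
    A <- NA_real_
    alpha <- NA_real_
  }
  structure(list(gas_name = gas_name, A = as.numeric(A),
                 alpha = as.numeric(alpha), available = isTRUE(available)),
            class = "gas_calibration")
}

#' @export
print.gas_calibration <- function(x, ...) {
  if (x$available) {
    cat(sprintf("<gas_calibration> %s: Rs = %.10g * C^%.10g\n",
                x$gas_name, x$A, x$alpha))
  } else {
    cat(sprintf("<gas_calibration> %s: not available\n", x$gas_name))
  }
  invisible(x)
}

#' The seven gases a sensor model is calibrated against
#' @return character vector of the gas names, in the frozen feature order.
#' @export
enose_gases <- function() {
  c("methane", "isobutane", "hydrogen", "propane", "ethanol", "air", "CO")
}

#' The four sensor models of the 32-socket array
#' @return character vector of model identifiers; position defines the
#'   model ordinal (0-based) used by [encode_identifier()].
#' @export
enose_sensor_models <- function() {
  c("TGS-2611E00", "TGS-2611C00", "TGS-2610C00", "TGS-2620")
}

#' Load the shipped (or a user-supplied) sensor calibration table
#'
#' Reads the versioned JSON calibration resource mapping sensor model to
#' per-gas power-law constants. Every model carries exactly seven gas entries;
#' gases whose sensitivity curve is not published for a model are stored as
#' unavailable.
#'
#' @param file path to a calibration JSON; defaults to the resource shipped
#'   with the package.
#' @return a named list of `sensor_model` objects, one per model; each has
#'   `$model_id`, `$ordinal` (0-based) and `$calibrations` (named list of
#'   [gas_calibration()] objects covering all seven gases).
#' @export
sensor_models <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "figaro_calibrations.json",
                        package = "enosedx", mustWork = TRUE)
  }
  raw <- jsonlite::read_json(file)
  if (is.null(raw$models)) stop("calibration file has no 'models' entry: ", file)
  models <- lapply(seq_along(raw$models), function(i) {
    model_id <- names(raw$models)[i]
    entries <- raw$models[[i]]
    missing <- setdiff(enose_gases(), names(entries))
    if (length(missing)) {
      stop("model ", model_id, " is missing gas entries: ",
           paste(missing, collapse = ", "))
    }
    cals <- lapply(enose_gases(), function(g) {
      e <- entries[[g]]
      if (isTRUE(e$available)) {
        gas_calibration(g, A = e$A, alpha = e$alpha, available = TRUE)
      } else {
        gas_calibration(g, available = FALSE)
      }
    })
    names(cals) <- enose_gases()
    structure(list(model_id = model_id, ordinal = i - 1L, calibrations = cals),
              class = "sensor_model")
  })
  names(models) <- names(raw$models)
  models
}

#' @export
print.sensor_model <- function(x, ...) {
  cat(sprintf("<sensor_model> %s (ordinal %d)\n", x$model_id, x$ordinal))
  for (cal in x$calibrations) print(cal)
  invisible(x)
}

#' Forward power-law model: resistivity at a gas concentration
#'
#' Evaluates \eqn{R_s = A \, C^{\alpha}} for one calibrated gas.
#'
#' @param cal a [gas_calibration()].
#' @param c gas concentration in ppm, strictly positive (vectorised).
#' @return predicted resistivity in sensor units.
#' @export
resistivity_from_concentration <- function(cal, c) {
  stopifnot(inherits(cal, "gas_calibration"))
  if (!cal$available) {
    stop("no-calibration: ", cal$gas_name, " has no published constants",
         call. = FALSE)
  }
  if (!is.numeric(c) || any(!is.finite(c)) || any(c <= 0)) {
    stop("concentration must be strictly positive (ppm)", call. = FALSE)
  }
  cal$A * c^cal$alpha
}

#' Inverse power-law model: ppm estimate from an observed resistivity
#'
#' Inverts \eqn{R_s = A \, C^{\alpha}} to \eqn{C = (R_s/A)^{1/\alpha}}.
#' Round-trips with [resistivity_from_concentration()] to better than 1e-9
#' relative for any available calibration with `alpha != 0`.
#'
#' @param cal a [gas_calibration()].
#' @param rs observed resistivity, strictly positive (vectorised).
#' @return estimated concentration in ppm.
#' @export
concentration_from_resistivity <- function(cal, rs) {
  stopifnot(inherits(cal, "gas_calibration"))
  if (!cal$available) {
    stop("no-calibration: ", cal$gas_name, " has no published constants",
         call. = FALSE)
  }
  if (cal$alpha == 0) {
    stop("non-invertible: alpha = 0 makes Rs independent of concentration",
         call. = FALSE)
  }
  if (!is.numeric(rs) || any(!is.finite(rs)) || any(rs <= 0)) {
    stop("resistivity must be strictly positive", call. = FALSE)
  }
  (rs / cal$A)^(1 / cal$alpha)
}

#' Fit the power-law sensitivity model by log-log regression
#'
#' Ordinary least squares of \eqn{\ln R_s} on \eqn{\ln C} — the straight-line
#' trendline a spreadsheet fits to a datasheet sensitivity plot on log axes.
#' `A = exp(intercept)`, `alpha = slope`. On noiseless power-law data the
#' generating constants are recovered exactly (to floating-point).
#'
#' @param concentration ppm values, all strictly positive, length >= 2.
#' @param resistivity matching resistivity values, all strictly positive.
#' @param gas_name gas label attached to the returned calibration.
#' @return a [gas_calibration()] with extra fields `fit` (the underlying
#'   `lm` object) and `n` (points used); also of class `power_law_fit`.
#' @examples
#' cal <- fit_power_law(c(1, 10, 100, 1000), 50 * c(1, 10, 100, 1000)^-0.4)
#' cal$A      # 50
#' cal$alpha  # -0.4
#' @export
fit_power_law <- function(concentration, resistivity, gas_name = "methane") {
  if (length(concentration) != length(resistivity)) {
    stop("concentration and resistivity must have equal length", call. = FALSE)
  }
  if (length(concentration) < 2L) {
    stop("at least 2 points are required", call. = FALSE)
  }
  if (any(!is.finite(concentration)) || any(concentration <= 0) ||
      any(!is.finite(resistivity)) || any(resistivity <= 0)) {
    stop("all concentrations and resistivities must be strictly positive",
         call. = FALSE)
  }
  fit <- stats::lm(log(resistivity) ~ log(concentration))
  cf <- stats::coef(fit)
  out <- gas_calibration(gas_name, A = exp(unname(cf[1L])),
                         alpha = unname(cf[2L]), available = TRUE)
  out$fit <- fit
  out$n <- length(concentration)
  class(out) <- c("power_law_fit", class(out))
  out
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit (log-log OLS, n = %d):\n", x$n))
  cat(sprintf("  Rs = %.10g * C^%.10g  [%s]\n", x$A, x$alpha, x$gas_name))
  invisible(x)
}

#' @param object a `power_law_fit`.
#' @param newdata optional list/data.frame with a `concentration` element;
#'   defaults to the training concentrations.
#' @param ... unused.
#' @rdname fit_power_law
#' @export
predict.power_law_fit <- function(object, newdata = NULL, ...) {
  c <- if (is.null(newdata)) exp(object$fit$model[["log(concentration)"]])
       else newdata$concentration
  resistivity_from_concentration(object, c)
}

#' Load-divider measurement circuit
#'
#' A MOS sensing element is read through a series load resistor: the board
#' digitises the voltage across the load, from which the element resistance
#' follows. Supply voltage and load resistance default to conventional Figaro
#' test-circuit values; both feed the run metadata because ppm features
#' depend on them.
#'
#' @param supply_voltage supply rail in volts (default 5).
#' @param load_resistance load resistor in ohms (default 10000).
#' @param reference_resistance reference resistance in ohms dividing the
#'   ohmic element resistance into the dimensionless sensor units of the
#'   calibration tables (default 1000).
#' @return an object of class `divider_circuit`.
#' @export
divider_circuit <- function(supply_voltage = 5, load_resistance = 10000,
                            reference_resistance = 1000) {
  stopifnot(supply_voltage > 0, load_resistance > 0, reference_resistance > 0)
  structure(list(supply_voltage = supply_voltage,
                 load_resistance = load_resistance,
                 reference_resistance = reference_resistance),
            class = "divider_circuit")
}

#' Element resistance from the measured divider voltage
#'
#' Standard load-divider inversion
#' \eqn{R_s = R_L (V_{cc} - V_{out}) / V_{out}}; monotone decreasing in
#' `v_out`, with `Rs = RL` at the midpoint `v_out = Vcc/2`.
#'
#' @param v_out measured voltage across the load, strictly inside
#'   `(0, supply_voltage)` (vectorised).
#' @param circuit a [divider_circuit()].
#' @return element resistance in ohms.
#' @export
resistance_from_voltage <- function(v_out, circuit = divider_circuit()) {
  stopifnot(inherits(circuit, "divider_circuit"))
  if (!is.numeric(v_out) || any(!is.finite(v_out)) ||
      any(v_out <= 0) || any(v_out >= circuit$supply_voltage)) {
    stop("v_out must lie strictly inside (0, supply_voltage)", call. = FALSE)
  }
  circuit$load_resistance * (circuit$supply_voltage - v_out) / v_out
}
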