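#' Concentration calibration curves
#'
#' Fits signal-vs-concentration series either linearly
#' (`signal = a c + b`) or with an extended Langmuir binding isotherm
#' `signal = I_max (K c)^n / (1 + (K c)^n)` (n = 1 by default, the classical
#' Langmuir form that surface adsorption on the sensor follows at low
#' coverage).
#'
#' @param series Data frame with columns `concentration` (>= 0) and `signal`.
#' @param model `"linear"` or `"langmuir_ext"`.
#' @param n_exponent Langmuir exponent n (fixed, not fitted).
#' @param weights Optional per-point weights.
#' @return A list of class `calibration_fit`: `model`, `parameters` (named),
#'   `residuals`, `fitted`, `data`, `units`.
#' @param units Concentration units label (e.g. `"ng uL-1"`, `"nM"`).
#' @examples
#' d <- tibble::tibble(concentration = 0:5, signal = 0.01 * (0:5))
#' calibration_fit(d)$parameters
#' @export
calibration_fit <- function(series, model = c("linear", "langmuir_ext"),
                            n_exponent = 1, weights = NULL,
                            units = "ng uL-1") {
  model <- match.arg(model)
  if (!all(c("concentration", "signal") %in% names(series))) {
    abort("`series` needs `concentration` and `signal` columns.")
  }
  conc <- series$concentration
  sig <- series$signal
  if (length(conc) < 3) abort("Need at least 3 calibration points.")
  if (any(conc < 0)) abort("Concentrations must be non-negative.")
  if (length(unique(conc)) < 2) {
    abort("Rank-deficient design: all concentrations identical.")
  }
  w <- weights %||% rep(1, length(conc))
  if (model == "linear") {
    fit <- lm(sig ~ conc, weights = w)
    pars <- c(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
    fitted_vals <- unname(fitted(fit))
  } else {
    i0 <- max(sig) * 1.2
    k0 <- 1 / max(median(conc[conc > 0]), .Machine$double.eps)
    fit <- minpack.lm::nlsLM(
      sig ~ imax * (k * conc)^n_exponent / (1 + (k * conc)^n_exponent),
      start = list(imax = i0, k = k0), weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- coef(fit)
    if (cf[["imax"]] <= 0 || cf[["k"]] <= 0) {
      abort("Langmuir fit returned non-positive I_max or K.")
    }
    pars <- c(i_max = unname(cf[["imax"]]), k = unname(cf[["k"]]),
              n = n_exponent)
    fitted_vals <- unname(fitted(fit))
  }
  structure(list(model = model, parameters = pars,
                 fitted = fitted_vals, residuals = sig - fitted_vals,
                 data = tibble(concentration = conc, signal = sig),
                 units = units, fit = fit),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> model = %s (%d points, conc in %s)\n",
              x$model, nrow(x$data), x$units))
  print(round(x$parameters, 6))
  invisible(x)
}

#' @export
tidy.calibration_fit <- function(x, ...) {
  tibble(term = names(x$parameters), estimate = unname(x$parameters))
}

#' @export
glance.calibration_fit <- function(x, ...) {
  tibble(model = x$model, rmse = sqrt(mean(x$residuals^2)),
         nobs = nrow(x$data),
         slope_at_origin = slope_at_origin(x))
}

slope_at_origin <- function(calibration) {
  p <- calibration$parameters
  if (calibration$model == "linear") return(unname(p[["slope"]]))
  n <- p[["n"]]
  if (n > 1) return(0)       # (Kc)^n has zero derivative at c = 0 for n > 1
  if (n < 1) return(Inf)
  unname(p[["i_max"]] * p[["k"]])
}

#' 3-sigma limit of detection
#'
#' The limit of detection is the concentration whose expected signal equals
#' three times the blank noise standard deviation:
#' `LOD = 3 sigma_blank / slope_at_origin`, with the slope at zero
#' concentration taken from the calibration model (linear slope, or
#' `I_max K` for the Langmuir form with n = 1).
#'
#' @param calibration A [calibration_fit()].
#' @param sigma_blank Blank noise standard deviation, signal units (>= 0).
#' @return A list of class `lod_report`: `sigma_blank`, `slope_at_origin`,
#'   `lod` (concentration units of the calibration).
#' @examples
#' d <- tibble::tibble(concentration = 0:5, signal = 0.01 * (0:5))
#' lod_3sigma(calibration_fit(d), sigma_blank = 0.3)$lod  # 90
#' @export
lod_3sigma <- function(calibration, sigma_blank) {
  if (sigma_blank < 0) abort("`sigma_blank` must be >= 0.")
  slope <- slope_at_origin(calibration)
  if (!is.finite(slope) || slope <= 0) {
    abort("Calibration slope at the origin must be positive and finite for a 3-sigma LOD.")
  }
  structure(list(sigma_blank = sigma_blank, slope_at_origin = slope,
                 lod = 3 * sigma_blank / slope, units = calibration$units),
            class = "lod_report")
}

#' @export
print.lod_report <- function(x, ...) {
  cat(sprintf("<lod_report> LOD = %.4g %s (3 x %.4g / %.4g)\n",
              x$lod, x$units, x$sigma_blank, x$slope_at_origin))
  invisible(x)
}
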