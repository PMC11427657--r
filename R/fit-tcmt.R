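#' Invert TCMT parameters from an absorption spectrum
#'
#' Nonlinear least squares of the coupled-mode dispersion against a measured
#' or synthetic absorbance spectrum, with multi-start initialization.
#' Positive rates are fitted on the log scale. With `n_oscillators = 0` the
#' bare Lorentzian `4 gr ga / ((gr + ga)^2 + (w - w0)^2)` only determines
#' (w0, gr + ga, gr * ga); the gr <-> ga swap is resolved by `regime_prior`
#' (an amplitude-only bare spectrum cannot distinguish f from 1/f).
#' `regime_prior = "auto"` needs at least one molecular line and uses the
#' sign of the residual enhanced signal at that line (positive -> OC,
#' negative -> UC); with no oscillator it raises an ambiguity error.
#'
#' The fitted loaded-device resonance `omega01` (the absorption maximum of
#' the coupled system, red-shifted from the bare `omega0`) is reported
#' alongside the bare parameters.
#'
#' @param spectrum An absorbance-kind [seira_spectrum()].
#' @param n_oscillators Number of molecular lines to fit (>= 0).
#' @param regime_prior `"OC"`, `"UC"` or `"auto"`.
#' @param seed Integer seed for the multi-start jitter.
#' @param osc_positions Optional numeric vector of initial line positions
#'   (cm^-1), e.g. the declared fingerprint bands; when `NULL`, lines are
#'   seeded at the largest residual peaks of a bare pre-fit.
#' @param n_starts Number of seeded starts.
#' @return A list of class `tcmt_fit`: `resonator`, `oscillators`, `omega01`,
#'   `residual_rms`, `regime`, `coupling_label`, `uncertainties` (tibble),
#'   `converged`, plus the data and fitted values.
#' @examples
#' sys <- coupled_system(resonator(1730, 400, 40),
#'                       molecular_oscillator(1730, 10, 25))
#' sp <- absorption_spectrum(sys, seq(800, 4000, length.out = 1687))
#' fit <- fit_tcmt(sp, n_oscillators = 1, regime_prior = "OC", seed = 1)
#' glance(fit)
#' @export
fit_tcmt <- function(spectrum, n_oscillators = 0,
                     regime_prior = c("auto", "OC", "UC"),
                     seed = 1, osc_positions = NULL, n_starts = 5) {
  regime_prior <- match.arg(regime_prior)
  spectrum <- as_spectrum_like(spectrum)
  if (spectrum_kind(spectrum) != "absorbance") {
    abort("`fit_tcmt()` expects an absorbance-kind spectrum.")
  }
  if (n_oscillators == 0 && regime_prior == "auto") {
    abort(paste0("With no molecular line the gamma_r <-> gamma_a swap is not ",
                 "identifiable from an amplitude spectrum: supply ",
                 "`regime_prior` = \"OC\" or \"UC\"."))
  }
  wn <- spectrum$wavenumber
  y <- spectrum$value
  init <- bare_init(wn, y)
  if (regime_prior == "auto") {
    # bare pre-fit (swap-invariant), then the sign of the residual at the
    # strongest candidate line decides the regime
    pre <- run_tcmt_ls(wn, y, pack_theta(init$omega0, init$gr_oc, init$ga_oc,
                                         NULL), 0)
    resid <- y - pre$fitted
    pos <- osc_positions %||% residual_line_positions(wn, resid, n_oscillators)
    s <- resid[which.min(abs(wn - pos[1]))]
    regime_prior <- if (s >= 0) "OC" else "UC"
  }
  if (regime_prior == "OC") {
    gr0 <- init$gr_oc; ga0 <- init$ga_oc
  } else {
    gr0 <- init$ga_oc; ga0 <- init$gr_oc
  }
  if (n_oscillators > 0) {
    pre <- run_tcmt_ls(wn, y, pack_theta(init$omega0, gr0, ga0, NULL), 0)
    resid <- y - pre$fitted
    pos <- osc_positions %||% residual_line_positions(wn, resid, n_oscillators)
    if (length(pos) < n_oscillators) {
      pos <- c(pos, seq(min(wn), max(wn),
                        length.out = n_oscillators - length(pos) + 2)[-c(1, n_oscillators - length(pos) + 2)])
    }
    gm0 <- rep(max((gr0 + ga0) / 40, 2 * grid_step(spectrum)), n_oscillators)
    mu0 <- gm0
  } else {
    pos <- numeric(0); gm0 <- numeric(0); mu0 <- numeric(0)
  }
  theta0 <- pack_theta(init$omega0, gr0, ga0,
                       list(pos = pos[seq_len(n_oscillators)],
                            gm = gm0, mu = mu0))
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    th <- theta0
    if (s > 1) {
      jit <- rnorm(length(th), 0, 0.15)
      # jitter frequencies additively on the rate scale, rates on log scale
      th <- th + jit * ifelse(grepl("^omega", names(th)), (gr0 + ga0) / 20, 1)
    }
    cand <- tryCatch(run_tcmt_ls(wn, y, th, n_oscillators),
                     error = function(e) NULL)
    if (!is.null(cand) && (is.null(best) || cand$deviance < best$deviance)) {
      best <- cand
    }
  }
  if (is.null(best)) {
    abort("TCMT fit failed to converge from any start.")
  }
  finish_tcmt_fit(best, wn, y, spectrum, regime_prior)
}

pack_theta <- function(omega0, gr, ga, osc) {
  th <- c(omega0 = omega0, log_gr = log(gr), log_ga = log(ga))
  if (!is.null(osc) && length(osc$pos) > 0) {
    for (k in seq_along(osc$pos)) {
      th <- c(th, setNames(c(osc$pos[k], log(osc$gm[k]), log(max(osc$mu[k], 1e-8))),
                           paste0(c("omega_m", "log_gm", "log_mu"), k)))
    }
  }
  th
}

unpack_theta <- function(theta) {
  n_osc <- (length(theta) - 3) / 3
  res <- resonator(theta[["omega0"]], exp(theta[["log_gr"]]),
                   exp(theta[["log_ga"]]))
  osc <- lapply(seq_len(n_osc), function(k) {
    molecular_oscillator(theta[[paste0("omega_m", k)]],
                         exp(theta[[paste0("log_gm", k)]]),
                         exp(theta[[paste0("log_mu", k)]]))
  })
  coupled_system(res, osc)
}

tcmt_model_values <- function(theta, wn) {
  sys <- unpack_theta(theta)
  1 - Mod(tcmt_r(sys, wn))^2
}

run_tcmt_ls <- function(wn, y, theta, n_oscillators) {
  fit <- minpack.lm::nls.lm(
    par = theta,
    fn = function(p) tcmt_model_values(p, wn) - y,
    control = minpack.lm::nls.lm.control(maxiter = 300))
  list(par = fit$par, deviance = fit$deviance,
       fitted = tcmt_model_values(fit$par, wn), fit = fit)
}

bare_init <- function(wn, y) {
  imax <- which.max(y)
  omega0 <- wn[imax]
  amax <- min(max(y[imax], 1e-6), 0.999)
  half <- amax / 2
  above <- y >= half
  lo <- imax; hi <- imax
  while (lo > 1 && above[lo - 1]) lo <- lo - 1
  while (hi < length(y) && above[hi + 1]) hi <- hi + 1
  gam <- max((wn[hi] - wn[lo]) / 2, 2 * (wn[2] - wn[1]))  # HWHM ~ gr + ga
  q <- amax * gam^2 / 4
  disc <- sqrt(max(gam^2 - 4 * q, 0))
  list(omega0 = omega0, gr_oc = (gam + disc) / 2, ga_oc = (gam - disc) / 2)
}

residual_line_positions <- function(wn, resid, n) {
  sp <- seira_spectrum(wn, abs(resid), kind = "difference")
  pk <- find_peaks(sp, min_prominence = 0.05 * max(abs(resid)))
  if (nrow(pk) == 0) return(wn[which.max(abs(resid))])
  head(pk$position, n)
}

finish_tcmt_fit <- function(best, wn, y, spectrum, regime_prior) {
  sys <- unpack_theta(best$par)
  n <- length(y); p <- length(best$par)
  resid <- best$fitted - y
  rms <- sqrt(mean(resid^2))
  se <- rep(NA_real_, p)
  hess <- best$fit$hessian
  if (!is.null(hess)) {
    cv <- tryCatch(solve(hess / 2) * best$deviance / max(n - p, 1),
                   error = function(e) NULL)
    if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0))
  }
  est_nat <- natural_parameters(best$par)
  se_nat <- se * ifelse(grepl("^log_", names(best$par)), est_nat, 1)
  fine <- seq(min(wn), max(wn), length.out = 8 * length(wn))
  afine <- 1 - Mod(tcmt_r(sys, fine))^2
  omega01 <- fine[which.max(afine)]
  label <- if (length(sys$oscillators) == 0) "weak" else {
    rep <- tryCatch(detect_loops(sample_trajectory(sys)),
                    error = function(e) NULL)
    if (is.null(rep)) {
      if (any(vapply(sys$oscillators, function(o) o$xi, numeric(1)) > 1))
        "strong" else "weak"
    } else rep$coupling_label
  }
  structure(list(
    resonator = sys$resonator,
    oscillators = sys$oscillators,
    system = sys,
    omega01 = omega01,
    residual_rms = rms,
    regime = classify_regime(sys$resonator),
    regime_prior = regime_prior,
    coupling_label = label,
    uncertainties = tibble(term = names(est_nat), estimate = unname(est_nat),
                           std.error = unname(se_nat)),
    converged = best$fit$info %in% 1:4,
    data = tibble(wavenumber = wn, value = y, fitted = best$fitted)),
    class = "tcmt_fit")
}

natural_parameters <- function(theta) {
  out <- theta
  lg <- grepl("^log_", names(theta))
  out[lg] <- exp(theta[lg])
  names(out) <- sub("^log_", "", names(out))
  out
}

#' @export
print.tcmt_fit <- function(x, ...) {
  r <- x$resonator
  cat(sprintf(
    "<tcmt_fit> %s (%s coupling), residual rms %.3g\n  omega0 = %.6g, omega01 = %.6g, gamma_r = %.4g, gamma_a = %.4g (f = %.3g)\n",
    x$regime, x$coupling_label, x$residual_rms, r$omega0, x$omega01,
    r$gamma_r, r$gamma_a, r$f))
  for (o in x$oscillators) {
    cat(sprintf("  line %.6g cm-1: gamma_m = %.4g, mu = %.4g (xi = %.3g)\n",
                o$omega_m, o$gamma_m, o$mu, o$xi))
  }
  invisible(x)
}

#' @rdname fit_tcmt
#' @param fit A `tcmt_fit`.
#' @param grid Wavenumber grid; defaults to the fitted data grid.
#' @return `predict_from_fit()`: an absorbance-kind [seira_spectrum()].
#' @export
predict_from_fit <- function(fit, grid = NULL) {
  grid <- grid %||% fit$data$wavenumber
  absorption_spectrum(fit$system, grid)
}

#' @export
tidy.tcmt_fit <- function(x, ...) {
  x$uncertainties
}

#' @export
glance.tcmt_fit <- function(x, ...) {
  tibble(residual_rms = x$residual_rms, regime = x$regime,
         coupling_label = x$coupling_label, omega01 = x$omega01,
         f = x$resonator$f, n_oscillators = length(x$oscillators),
         converged = x$converged, nobs = nrow(x$data))
}

#' Detuning dependence of the enhanced signal
#'
#' Tabulates the sensitivity statistic against spectral detuning
#' `detuning = omega_m - omega01` for a series of systems (specified or
#' fitted), where `omega01` is the loaded-device resonance (absorption
#' maximum of the coupled system). The theoretical curve comes directly from
#' the coupled-mode dispersion.
#'
#' @param systems A list of [coupled_system()] and/or `tcmt_fit` objects.
#' @param oscillator_index Which line to evaluate at.
#' @return Tibble with `omega01`, `detuning`, `i_seira`.
#' @export
detuning_response <- function(systems, oscillator_index = 1) {
  if (inherits(systems, c("coupled_system", "tcmt_fit"))) systems <- list(systems)
  purrr::map_dfr(systems, function(s) {
    sys <- if (inherits(s, "tcmt_fit")) s$system else s
    w01 <- if (inherits(s, "tcmt_fit")) s$omega01 else loaded_resonance(sys)
    wm <- sys$oscillators[[oscillator_index]]$omega_m
    tibble(omega01 = w01, detuning = wm - w01,
           i_seira = seira_sensitivity(sys, oscillator_index))
  })
}

loaded_resonance <- function(sys) {
  r <- sys$resonator
  span <- 5 * (r$gamma_r + r$gamma_a)
  fine <- seq(max(r$omega0 - span, 1e-9), r$omega0 + span, length.out = 4001)
  a <- 1 - Mod(tcmt_r(sys, fine))^2
  fine[which.max(a)]
}
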