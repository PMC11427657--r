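#' Resonator, molecular oscillators and coupled systems
#'
#' The temporal coupled-mode description of a metamaterial absorber (MA) has a
#' single bright mode at `omega0` with a radiative loss rate `gamma_r` (the
#' channel through which light couples in and out; input coupling
#' kappa = sqrt(2 gamma_r)) and an absorptive loss rate `gamma_a` (ohmic
#' dissipation). The loss ratio f = gamma_r / gamma_a sets the coupling
#' regime: undercoupled (f < 1), critically coupled (f = 1, perfect
#' on-resonance absorption) or overcoupled (f > 1). All rates and frequencies
#' are expressed on the wavenumber axis (cm^-1) and are half-width-type rates:
#' the bare absorption line has FWHM = 2 (gamma_r + gamma_a).
#'
#' @param omega0 Bare resonance position, cm^-1 (> 0).
#' @param gamma_r Radiative loss rate, cm^-1 (> 0).
#' @param gamma_a Absorptive loss rate, cm^-1 (> 0).
#' @return `resonator()` returns a list of class `resonator` with fields
#'   `omega0`, `gamma_r`, `gamma_a` and derived `f` (loss ratio) and `kappa`
#'   (input coupling, kappa^2 = 2 gamma_r).
#' @examples
#' res <- resonator(1730, gamma_r = 400, gamma_a = 40)
#' res$f
#' classify_regime(res)
#' @export
resonator <- function(omega0, gamma_r, gamma_a) {
  stop_unless_positive(omega0 = omega0, gamma_r = gamma_r, gamma_a = gamma_a)
  structure(
    list(omega0 = omega0, gamma_r = gamma_r, gamma_a = gamma_a,
         f = gamma_r / gamma_a, kappa = sqrt(2 * gamma_r)),
    class = "resonator"
  )
}

#' @rdname resonator
#' @param omega_m Vibrational line position, cm^-1 (> 0).
#' @param gamma_m Molecular absorption loss rate, cm^-1 (> 0). A zero rate
#'   puts a pole on the real frequency axis and is rejected.
#' @param mu Resonator-oscillator coupling coefficient, cm^-1 (>= 0).
#' @return `molecular_oscillator()` returns a list of class
#'   `molecular_oscillator` with the derived coupling ratio `xi = mu/gamma_m`.
#' @export
molecular_oscillator <- function(omega_m, gamma_m, mu) {
  stop_unless_positive(omega_m = omega_m, gamma_m = gamma_m)
  if (!is.finite(mu) || mu < 0) {
    abort("`mu` must be finite and >= 0.")
  }
  structure(
    list(omega_m = omega_m, gamma_m = gamma_m, mu = mu, xi = mu / gamma_m),
    class = "molecular_oscillator"
  )
}

#' @rdname resonator
#' @param res A `resonator`.
#' @param oscillators List of `molecular_oscillator` objects (possibly empty);
#'   an empty list reproduces the bare absorber (mu = 0 limit).
#' @return `coupled_system()` returns a list of class `coupled_system`.
#' @export
coupled_system <- function(res, oscillators = list()) {
  if (!inherits(res, "resonator")) abort("`res` must be a resonator().")
  if (inherits(oscillators, "molecular_oscillator")) {
    oscillators <- list(oscillators)
  }
  ok <- vapply(oscillators, inherits, logical(1), "molecular_oscillator")
  if (!all(ok)) abort("`oscillators` must be molecular_oscillator() objects.")
  structure(list(resonator = res, oscillators = oscillators),
            class = "coupled_system")
}

stop_unless_positive <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort(sprintf("`%s` must be a single finite positive number.", nm))
    }
  }
  invisible(NULL)
}

#' @export
print.coupled_system <- function(x, ...) {
  r <- x$resonator
  cat(sprintf(
    "<coupled_system> omega0 = %.6g, gamma_r = %.4g, gamma_a = %.4g (f = %.3g), %d oscillator(s)\n",
    r$omega0, r$gamma_r, r$gamma_a, r$f, length(x$oscillators)))
  for (o in x$oscillators) {
    cat(sprintf("  line %.6g cm-1: gamma_m = %.4g, mu = %.4g (xi = %.3g)\n",
                o$omega_m, o$gamma_m, o$mu, o$xi))
  }
  invisible(x)
}

# Denominator D(w) = j(w - w0) + (gr + ga) + sum_i mu_i^2 / (j(w - wm_i) + gm_i)
tcmt_denominator <- function(system, omega) {
  res <- system$resonator
  d <- 1i * (omega - res$omega0) + (res$gamma_r + res$gamma_a)
  for (osc in system$oscillators) {
    d <- d + osc$mu^2 / (1i * (omega - osc$omega_m) + osc$gamma_m)
  }
  d
}

tcmt_r <- function(system, omega) {
  2 * system$resonator$gamma_r / tcmt_denominator(system, omega) - 1
}

check_grid <- function(grid) {
  grid <- as.numeric(grid)
  if (length(grid) < 2 || anyNA(grid)) abort("`grid` must have >= 2 finite values.")
  if (any(grid <= 0)) abort("`grid` must be positive (wavenumbers, cm^-1).")
  if (any(diff(grid) <= 0)) abort("`grid` must be strictly increasing.")
  grid
}

#' TCMT forward model: reflection, absorption and enhanced-signal spectra
#'
#' The complex amplitude reflection of the molecule-loaded absorber is
#' `r(w) = kappa^2 / D(w) - 1` with
#' `D(w) = j(w - omega0) + (gamma_r + gamma_a) + sum_i mu_i^2 / (j(w - omega_m_i) + gamma_m_i)`
#' and `kappa^2 = 2 gamma_r`. With zero transmission the absorbance is
#' `A(w) = 1 - |r(w)|^2`; without oscillators this is the bare Lorentzian
#' `4 gamma_r gamma_a / ((gamma_r + gamma_a)^2 + (w - omega0)^2)`. The
#' enhanced signal is `deltaA = A - A|mu = 0` (same resonator, all couplings
#' switched off), and the sensitivity statistic is deltaA evaluated at the
#' molecular line.
#'
#' Multiple oscillators enter the denominator additively (independent dark
#' modes), which reduces literally to the single-oscillator dispersion when
#' one line is present.
#'
#' @param system A [coupled_system()].
#' @param grid Strictly increasing positive wavenumber grid, cm^-1.
#' @return `reflection()`: a tibble of class `complex_trajectory` with columns
#'   `wavenumber` and complex `r`. `absorption_spectrum()`,
#'   `delta_spectrum()`: a [seira_spectrum()]. `seira_sensitivity()`: a signed
#'   scalar.
#' @examples
#' sys <- coupled_system(resonator(1730, 10, 1),
#'                       molecular_oscillator(1730, 1, 2))
#' a <- absorption_spectrum(sys, seq(1600, 1860, 0.5))
#' seira_sensitivity(sys)
#' @export
reflection <- function(system, grid) {
  grid <- check_grid(grid)
  out <- tibble(wavenumber = grid, r = tcmt_r(system, grid))
  class(out) <- c("complex_trajectory", class(out))
  attr(out, "system") <- system
  out
}

#' @rdname reflection
#' @export
absorption_spectrum <- function(system, grid) {
  grid <- check_grid(grid)
  a <- 1 - Mod(tcmt_r(system, grid))^2
  seira_spectrum(grid, a, kind = "absorbance",
                 meta = list(parameters = system_parameters(system)))
}

#' @rdname reflection
#' @export
delta_spectrum <- function(system, grid) {
  if (length(system$oscillators) == 0) {
    abort("`delta_spectrum()` needs a system with at least one oscillator.")
  }
  grid <- check_grid(grid)
  a <- 1 - Mod(tcmt_r(system, grid))^2
  a0 <- 1 - Mod(tcmt_r(bare_system(system), grid))^2
  seira_spectrum(grid, a - a0, kind = "difference",
                 meta = list(parameters = system_parameters(system)))
}

bare_system <- function(system) {
  osc0 <- lapply(system$oscillators, function(o) {
    molecular_oscillator(o$omega_m, o$gamma_m, 0)
  })
  coupled_system(system$resonator, osc0)
}

system_parameters <- function(system) {
  r <- system$resonator
  list(omega0 = r$omega0, gamma_r = r$gamma_r, gamma_a = r$gamma_a,
       oscillators = lapply(system$oscillators, function(o) {
         list(omega_m = o$omega_m, gamma_m = o$gamma_m, mu = o$mu)
       }))
}

#' @rdname reflection
#' @param oscillator_index Which oscillator's line position to evaluate at.
#' @export
seira_sensitivity <- function(system, oscillator_index = 1) {
  n <- length(system$oscillators)
  if (oscillator_index < 1 || oscillator_index > n) {
    abort(sprintf("`oscillator_index` out of range (system has %d oscillator(s)).", n))
  }
  wm <- system$oscillators[[oscillator_index]]$omega_m
  a <- 1 - Mod(tcmt_r(system, wm))^2
  a0 <- 1 - Mod(tcmt_r(bare_system(system), wm))^2
  unname(a - a0)
}

#' Coupling-regime classification and bare linewidth
#'
#' A resonator is overcoupled (OC) when f = gamma_r/gamma_a > 1, undercoupled
#' (UC) when f < 1 and critically coupled at f = 1 (perfect on-resonance
#' absorption). `tol` widens the critical band; the exact boundary is
#' labelled critical.
#'
#' @param res A [resonator()].
#' @param tol Non-negative tolerance on f around 1.
#' @return `classify_regime()`: one of `"UC"`, `"critical"`, `"OC"`.
#' @examples
#' classify_regime(resonator(1730, 10, 1))  # "OC"
#' @export
classify_regime <- function(res, tol = 1e-9) {
  if (!is.numeric(tol) || tol < 0) abort("`tol` must be >= 0.")
  f <- res$gamma_r / res$gamma_a
  if (f > 1 + tol) "OC" else if (f < 1 - tol) "UC" else "critical"
}

#' @rdname classify_regime
#' @return `resonator_fwhm()`: the full width at half maximum of the bare
#'   absorption Lorentzian, `2 (gamma_r + gamma_a)`, cm^-1.
#' @export
resonator_fwhm <- function(res) {
  2 * (res$gamma_r + res$gamma_a)
}

#' Reduced-coordinate sensitivity
#'
#' Evaluates the enhanced-signal statistic for a single co-oscillator system
#' described by the three channels (f, xi, detuning): loss ratio
#' f = gamma_r/gamma_a, coupling ratio xi = mu/gamma_m, and spectral detuning
#' `detuning = omega0 - omega_m`. Reference scales fix the absolute rates:
#' gamma_a = `gamma_a_ref`, gamma_r = f * gamma_a, gamma_m = `gamma_m_ref`,
#' mu = xi * gamma_m. Vectorised over the three channels (recycled).
#'
#' @param f Loss ratio(s), >= 0.
#' @param xi Coupling ratio(s), >= 0.
#' @param detuning Detuning(s) omega0 - omega_m, in rate units of
#'   `gamma_m_ref`'s axis.
#' @param gamma_a_ref,gamma_m_ref Reference scales (rate units).
#' @return Signed numeric vector of sensitivities.
#' @examples
#' sensitivity_value(f = 10, xi = 1, detuning = 0)  # 0.225
#' @export
sensitivity_value <- function(f, xi, detuning = 0,
                              gamma_a_ref = 1, gamma_m_ref = 1) {
  n <- max(length(f), length(xi), length(detuning))
  f <- rep_len(f, n); xi <- rep_len(xi, n); dw <- rep_len(detuning, n)
  ga <- gamma_a_ref
  gr <- f * ga
  gm <- gamma_m_ref
  mu <- xi * gm
  gam <- gr + ga
  # evaluate at w = omega_m, i.e. w - omega0 = -detuning
  d <- -1i * dw + gam + mu^2 / gm
  a <- 1 - Mod(2 * gr / d - 1)^2
  a0 <- 1 - Mod(2 * gr / (-1i * dw + gam) - 1)^2
  a - a0
}
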