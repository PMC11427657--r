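#' Asymmetric least squares (AsLS) baseline extraction
#'
#' Estimates the broad resonator envelope under narrow molecular features by
#' the Eilers-Boelens penalized scheme: the baseline z minimizes
#' `sum_i w_i (y_i - z_i)^2 + lambda sum (d2 z)^2` with asymmetric weights
#' `w_i = p` where `y_i > z_i` and `1 - p` otherwise, iterated until the
#' relative change of z drops below `convergence_tol`. A small `p` keeps the
#' baseline below upward features, which is the overcoupled-device case where
#' molecular signatures are positive peaks; for undercoupled devices the
#' signatures are dips and the asymmetry is flipped (p -> 1 - p) by
#' [extract_difference()].
#'
#' @param smoothness Penalty weight lambda (> 0). The default 1e3 is tuned to
#'   the default 1.9 cm^-1 measurement grid: stiff on the scale of
#'   vibrational lines (tens of cm^-1) yet flexible enough to track the
#'   resonator envelope (hundreds of cm^-1) to better than 1 percent.
#'   Lambda scales roughly with the fourth power of the grid step, so a
#'   4 cm^-1 grid wants a correspondingly larger value.
#' @param asymmetry Asymmetry weight p in (0, 1).
#' @param max_iterations Maximum reweighting sweeps.
#' @param convergence_tol Relative-change threshold on the baseline.
#' @return `asls_config()`: a list of class `asls_config`.
#' @examples
#' cfg <- asls_config()
#' @export
asls_config <- function(smoothness = 1e3, asymmetry = 0.001,
                        max_iterations = 30, convergence_tol = 1e-6) {
  if (smoothness <= 0) abort("`smoothness` (lambda) must be > 0.")
  if (asymmetry <= 0 || asymmetry >= 1) abort("`asymmetry` (p) must be in (0, 1).")
  if (max_iterations < 1) abort("`max_iterations` must be >= 1.")
  structure(list(smoothness = smoothness, asymmetry = asymmetry,
                 max_iterations = max_iterations,
                 convergence_tol = convergence_tol),
            class = "asls_config")
}

#' @rdname asls_config
#' @param spectrum An absorbance-kind [seira_spectrum()].
#' @param config An [asls_config()].
#' @return `asls_baseline()`: a baseline-kind [seira_spectrum()] whose meta
#'   records iterations used and final relative change.
#' @export
asls_baseline <- function(spectrum, config = asls_config()) {
  spectrum <- as_spectrum_like(spectrum)
  if (spectrum_kind(spectrum) != "absorbance") {
    abort("`asls_baseline()` expects an absorbance-kind spectrum.")
  }
  y <- spectrum$value
  m <- length(y)
  if (m < 5) abort("Spectrum too short for a second-difference penalty.")
  lambda <- config$smoothness
  p <- config$asymmetry
  d2 <- Matrix::diff(Matrix::Diagonal(m), differences = 2)
  pen <- lambda * Matrix::crossprod(d2)
  w <- rep(1, m)
  z <- y
  converged <- FALSE
  rel <- NA_real_
  for (it in seq_len(config$max_iterations)) {
    wmat <- Matrix::Diagonal(x = w)
    z_new <- as.numeric(Matrix::solve(wmat + pen, w * y))
    rel <- sqrt(sum((z_new - z)^2)) / max(sqrt(sum(z_new^2)), .Machine$double.eps)
    z <- z_new
    w_new <- ifelse(y > z, p, 1 - p)
    if (it > 1 && rel < config$convergence_tol) { converged <- TRUE; break }
    w <- w_new
  }
  if (!converged) {
    abort(sprintf(
      "AsLS baseline did not converge in %d iterations (last relative change %.3g, lambda = %.3g, p = %.3g).",
      config$max_iterations, rel, lambda, p))
  }
  seira_spectrum(spectrum$wavenumber, z, kind = "baseline",
                 meta = c(spectrum_meta(spectrum),
                          list(asls = list(lambda = lambda, p = p,
                                           iterations = it,
                                           relative_change = rel))))
}

#' Difference-spectrum extraction from a measured absorption spectrum
#'
#' Subtracts the AsLS baseline from an absorbance spectrum to recover the
#' enhanced molecular signal deltaA. For overcoupled devices the molecular
#' signatures ride on top of the envelope, so the baseline hugs the spectrum
#' from below (small p); for undercoupled devices they are dips and the
#' asymmetry is flipped automatically when `regime = "UC"`.
#'
#' @inheritParams asls_config
#' @param spectrum An absorbance-kind [seira_spectrum()].
#' @param config An [asls_config()].
#' @param regime `"OC"` (features are peaks) or `"UC"` (features are dips).
#' @return A difference-kind [seira_spectrum()].
#' @export
extract_difference <- function(spectrum, config = asls_config(),
                               regime = c("OC", "UC")) {
  regime <- match.arg(regime)
  spectrum <- as_spectrum_like(spectrum)
  if (regime == "UC") {
    config <- asls_config(smoothness = config$smoothness,
                          asymmetry = 1 - config$asymmetry,
                          max_iterations = config$max_iterations,
                          convergence_tol = config$convergence_tol)
  }
  base <- asls_baseline(spectrum, config)
  seira_spectrum(spectrum$wavenumber, spectrum$value - base$value,
                 kind = "difference",
                 meta = c(spectrum_meta(spectrum),
                          list(baseline = spectrum_meta(base)$asls,
                               regime = regime)))
}
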