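#' Wavelength / wavenumber conversion
#'
#' Infrared band positions convert between wavelength (micrometres) and
#' wavenumber (cm^-1) by `wavenumber = 10000 / wavelength`; the map is its
#' own inverse up to the unit swap. `band_width_wavenumber()` gives the width
#' in cm^-1 of a wavelength band, e.g. the 3-10 um mid-infrared fingerprint
#' window spans 3333.33 - 1000 = 2333.33 cm^-1.
#'
#' @param wavelength_um Wavelength(s), micrometres (> 0).
#' @return Wavenumber(s), cm^-1.
#' @examples
#' wavelength_to_wavenumber(3)    # 3333.33 cm-1
#' wavenumber_to_wavelength(1000) # 10 um
#' band_width_wavenumber(3, 10)   # 2333.33 cm-1
#' @export
wavelength_to_wavenumber <- function(wavelength_um) {
  if (any(!is.finite(wavelength_um)) || any(wavelength_um <= 0)) {
    abort("Wavelength must be positive.")
  }
  10000 / wavelength_um
}

#' @rdname wavelength_to_wavenumber
#' @param wavenumber_cm1 Wavenumber(s), cm^-1 (> 0).
#' @export
wavenumber_to_wavelength <- function(wavenumber_cm1) {
  if (any(!is.finite(wavenumber_cm1)) || any(wavenumber_cm1 <= 0)) {
    abort("Wavenumber must be positive.")
  }
  10000 / wavenumber_cm1
}

#' @rdname wavelength_to_wavenumber
#' @param lambda_lo_um,lambda_hi_um Band edges in micrometres (lo < hi).
#' @export
band_width_wavenumber <- function(lambda_lo_um, lambda_hi_um) {
  if (lambda_lo_um >= lambda_hi_um) abort("Band edges must satisfy lo < hi.")
  wavelength_to_wavenumber(lambda_lo_um) - wavelength_to_wavenumber(lambda_hi_um)
}

#' Film-thickness-normalized sensitivity
#'
#' A peak enhanced-signal contrast measured on a film of known thickness,
#' expressed per nanometre: e.g. a 58 percent contrast over an 8 nm film is
#' 7.25 percent nm^-1.
#'
#' @param contrast_percent Peak difference-spectrum contrast, percent.
#' @param thickness_nm Film thickness, nm (> 0).
#' @return Sensitivity in percent per nm.
#' @examples
#' unit_sensitivity(58, 8)  # 7.25
#' @export
unit_sensitivity <- function(contrast_percent, thickness_nm) {
  if (any(thickness_nm <= 0)) abort("`thickness_nm` must be > 0.")
  contrast_percent / thickness_nm
}

#' Savitzky-Golay derivative spectra
#'
#' First- and second-derivative spectra of the enhanced signal sharpen
#' overlapping vibrational bands; second-derivative minima locate Amide-I
#' sub-bands used for protein secondary-structure analysis. Derivatives are
#' computed with a Savitzky-Golay filter and scaled by the grid spacing so
#' values are per cm^-1 (order 1) or per cm^-2 (order 2). The grid must be
#' uniform; non-uniform grids are linearly resampled with a warning.
#'
#' @param window_points Odd filter window length (>= poly_order + 2).
#' @param poly_order Local polynomial degree.
#' @param order Derivative order, 1 or 2. Defaults (11-point window, cubic)
#'   suit 4 cm^-1-class FTIR grids.
#' @return `derivative_config()`: a list of class `derivative_config`.
#' @export
derivative_config <- function(window_points = 11, poly_order = 3,
                              order = 2) {
  if (!order %in% c(1, 2)) abort("`order` must be 1 or 2.")
  if (order > poly_order) abort("`order` must be <= `poly_order`.")
  if (window_points %% 2 != 1 || window_points < poly_order + 2) {
    abort("`window_points` must be odd and >= poly_order + 2.")
  }
  structure(list(window_points = window_points, poly_order = poly_order,
                 order = order),
            class = "derivative_config")
}

#' @rdname derivative_config
#' @param spectrum A [seira_spectrum()].
#' @param config A [derivative_config()].
#' @return `derivative_spectrum()`: a derivative-kind [seira_spectrum()].
#' @examples
#' s <- seira_spectrum(seq(1500, 1900, 2), dnorm(seq(1500, 1900, 2), 1730, 15),
#'                     kind = "difference")
#' d2 <- derivative_spectrum(s, derivative_config(order = 2))
#' @export
derivative_spectrum <- function(spectrum, config = derivative_config()) {
  spectrum <- as_spectrum_like(spectrum)
  if (config$window_points > nrow(spectrum)) {
    abort("Savitzky-Golay window larger than the spectrum.")
  }
  wn <- spectrum$wavenumber
  y <- spectrum$value
  if (!is_uniform_grid(wn)) {
    warn("Non-uniform grid: resampling linearly before differentiation.")
    wn_u <- seq(min(wn), max(wn), length.out = length(wn))
    y <- approx(wn, y, xout = wn_u)$y
    wn <- wn_u
  }
  h <- mean(diff(wn))
  dy <- signal::sgolayfilt(y, p = config$poly_order, n = config$window_points,
                           m = config$order, ts = h)
  seira_spectrum(wn, dy,
                 kind = paste0("derivative", config$order),
                 meta = c(spectrum_meta(spectrum),
                          list(derivative = unclass(config))))
}

#' Peak finding with prominence
#'
#' Local maxima above a prominence floor. Prominence of a peak is its height
#' above the higher of the two lowest points separating it from higher
#' terrain on either side (or from the spectrum edge). Positions are refined
#' by a 3-point parabolic fit.
#'
#' @param spectrum A [seira_spectrum()] (any kind).
#' @param min_prominence Minimum prominence; peaks below are dropped.
#' @return Tibble with `position` (cm^-1), `height`, `prominence`; zero rows
#'   when nothing qualifies.
#' @export
find_peaks <- function(spectrum, min_prominence = 0) {
  spectrum <- as_spectrum_like(spectrum)
  wn <- spectrum$wavenumber
  y <- spectrum$value
  n <- length(y)
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  # keep only the leftmost point of flat-topped peaks
  cand <- cand[y[cand] > y[pmax(cand - 1, 1)] & y[cand] >= y[pmin(cand + 1, n)]]
  if (length(cand) == 0) {
    return(tibble(position = numeric(0), height = numeric(0),
                  prominence = numeric(0)))
  }
  prom <- vapply(cand, function(i) {
    h <- y[i]
    left_min <- h; j <- i
    while (j > 1) {
      j <- j - 1
      if (y[j] > h) break
      left_min <- min(left_min, y[j])
      if (j == 1) break
    }
    left_base <- if (y[j] > h) left_min else min(left_min, y[1])
    right_min <- h; j <- i
    while (j < n) {
      j <- j + 1
      if (y[j] > h) break
      right_min <- min(right_min, y[j])
      if (j == n) break
    }
    right_base <- if (y[j] > h) right_min else min(right_min, y[n])
    h - max(left_base, right_base)
  }, numeric(1))
  keep <- prom >= min_prominence & prom > 0
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) == 0) {
    return(tibble(position = numeric(0), height = numeric(0),
                  prominence = numeric(0)))
  }
  pos <- vapply(cand, function(i) {
    if (i == 1 || i == n) return(wn[i])
    y0 <- y[i - 1]; y1 <- y[i]; y2 <- y[i + 1]
    den <- y0 - 2 * y1 + y2
    if (den == 0) return(wn[i])
    d <- 0.5 * (y0 - y2) / den
    d <- max(min(d, 0.5), -0.5)
    wn[i] + d * (wn[min(i + 1, n)] - wn[i])
  }, numeric(1))
  tibble(position = pos, height = y[cand], prominence = prom) %>%
    dplyr::arrange(dplyr::desc(.data$prominence))
}
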