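#' Spectra as tibbles
#'
#' A spectrum is a two-column tibble (`wavenumber`, `value`) carrying two
#' attributes: `kind`, one of `"absorbance"`, `"difference"`, `"baseline"`,
#' `"derivative1"`, `"derivative2"`; and `meta`, a free-form provenance list.
#' The wavenumber grid is in cm^-1, strictly increasing; values are
#' dimensionless (absorbance fraction, its difference, or its derivative per
#' cm^-1 / cm^-2).
#'
#' Absorbance-kind values must lie in \[0, 1\] up to the additive noise
#' tolerance declared in `meta$noise_tol` (default 0.1), since for a
#' metal-backed absorber with zero transmission A = 1 - R and both A and R
#' are energy fractions.
#'
#' @param wavenumber Strictly increasing numeric grid, cm^-1.
#' @param value Numeric values, same length as `wavenumber`.
#' @param kind Spectrum kind (see Details).
#' @param meta Named list of provenance (generator parameters, seed, ...).
#' @return A tibble of class `seira_spectrum`.
#' @examples
#' s <- seira_spectrum(seq(1000, 2000, 10), rep(0.5, 101), "absorbance")
#' spectrum_kind(s)
#' @export
seira_spectrum <- function(wavenumber, value,
                           kind = c("absorbance", "difference", "baseline",
                                    "derivative1", "derivative2"),
                           meta = list()) {
  kind <- match.arg(kind)
  wavenumber <- as.numeric(wavenumber)
  value <- as.numeric(value)
  if (length(wavenumber) != length(value)) {
    abort("`wavenumber` and `value` must have equal length.")
  }
  if (length(wavenumber) < 2) {
    abort("A spectrum needs at least 2 points.")
  }
  if (anyNA(wavenumber) || anyNA(value)) {
    abort("Spectra may not contain missing values.")
  }
  if (any(diff(wavenumber) <= 0)) {
    abort("`wavenumber` must be strictly increasing.")
  }
  if (kind == "absorbance") {
    tol <- meta$noise_tol %||% 0.1
    if (min(value) < -tol || max(value) > 1 + tol) {
      abort(paste0("Absorbance values outside [0, 1] beyond the declared ",
                   "noise tolerance (", format(tol), ")."))
    }
  }
  out <- tibble(wavenumber = wavenumber, value = value)
  class(out) <- c("seira_spectrum", class(out))
  attr(out, "kind") <- kind
  attr(out, "meta") <- meta
  out
}

#' @rdname seira_spectrum
#' @param x A `seira_spectrum`.
#' @export
spectrum_kind <- function(x) attr(x, "kind") %||% "absorbance"

#' @rdname seira_spectrum
#' @export
spectrum_meta <- function(x) attr(x, "meta") %||% list()

as_spectrum_like <- function(x) {
  # accept any data frame with wavenumber/value-like first two columns
  if (inherits(x, "seira_spectrum")) return(x)
  if (!is.data.frame(x) || ncol(x) < 2) {
    abort("Expected a spectrum: a data frame with wavenumber and value columns.")
  }
  nm <- names(x)
  wn <- if ("wavenumber" %in% nm) x[["wavenumber"]] else x[[1]]
  va <- if ("value" %in% nm) x[["value"]] else x[[2]]
  seira_spectrum(wn, va, kind = attr(x, "kind") %||% "absorbance",
                 meta = attr(x, "meta") %||% list())
}

grid_step <- function(spectrum) {
  d <- diff(spectrum$wavenumber)
  if (diff(range(d)) > 1e-6 * mean(d)) return(stats::median(d))
  mean(d)
}

is_uniform_grid <- function(wavenumber, rel_tol = 1e-6) {
  d <- diff(wavenumber)
  diff(range(d)) <= rel_tol * mean(d)
}

#' @export
print.seira_spectrum <- function(x, ...) {
  cat(sprintf("<seira_spectrum> kind = %s, %d points, %.6g - %.6g cm-1\n",
              spectrum_kind(x), nrow(x), min(x$wavenumber), max(x$wavenumber)))
  NextMethod()
}
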