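#' Secondary-loop (strong-coupling) detection on complex reflection
#'
#' The complex reflection r(w) of the bare absorber traces a single loop in
#' the complex plane. When the resonator-oscillator coupling ratio
#' xi = mu/gamma_m exceeds 1 the trajectory develops a self-intersection — a
#' secondary loop — which marks the weak-to-strong coupling transition. For
#' the single-oscillator, zero-detuning model the self-intersection exists
#' iff mu^2 > gamma_m^2, at frequencies omega_m +/- sqrt(mu^2 - gamma_m^2),
#' where r takes the real value kappa^2/(gamma_r + gamma_a + gamma_m) - 1.
#'
#' `detect_loops()` finds self-intersections of the sampled polyline.
#' Consecutive segments must be shorter than `max_seg_frac` times the
#' trajectory diameter, otherwise a resolution error is raised (a coarse
#' polyline can silently miss a small loop). Intersections closer than
#' `tol_frac` times the diameter to a shared vertex are ignored as numerical
#' coincidences.
#'
#' @param trajectory A `complex_trajectory` from [reflection()] (or any data
#'   frame with `wavenumber` and complex `r` columns).
#' @param max_seg_frac Maximum allowed segment length as a fraction of the
#'   trajectory diameter.
#' @param tol_frac Intersection tolerance as a fraction of the diameter.
#' @return A list of class `loop_report`: `has_secondary_loop`,
#'   `crossing_frequencies` (numeric, length 0 or 2 per crossing),
#'   `crossing_point` (complex, or NULL), `coupling_label` ("weak"/"strong").
#' @examples
#' sys <- coupled_system(resonator(1730, 10, 1),
#'                       molecular_oscillator(1730, 1, 2))
#' tr <- sample_trajectory(sys)
#' detect_loops(tr)$has_secondary_loop
#' @export
detect_loops <- function(trajectory, max_seg_frac = 0.05, tol_frac = 1e-6) {
  if (!all(c("wavenumber", "r") %in% names(trajectory))) {
    abort("`trajectory` needs `wavenumber` and `r` columns.")
  }
  w <- trajectory$wavenumber
  z <- trajectory$r
  n <- length(z)
  if (n < 4) abort("Trajectory too short for loop analysis.")
  x <- Re(z); y <- Im(z)
  diam <- sqrt(diff(range(x))^2 + diff(range(y))^2)
  if (diam == 0) {
    return(new_loop_report(FALSE, numeric(0), NULL))
  }
  seg_len <- sqrt(diff(x)^2 + diff(y)^2)
  if (max(seg_len) > max_seg_frac * diam) {
    abort(paste0(
      "Trajectory sampled too coarsely for loop detection: longest segment ",
      "is ", format(max(seg_len) / diam, digits = 3), " of the diameter ",
      "(limit ", format(max_seg_frac), "). Refine the grid (see ",
      "sample_trajectory())."))
  }
  hits <- polyline_self_intersections(x, y, tol = tol_frac * diam)
  if (nrow(hits) == 0) {
    return(new_loop_report(FALSE, numeric(0), NULL))
  }
  # interpolate crossing frequencies along each of the two segments
  wa <- w[hits$i] + hits$ti * (w[hits$i + 1] - w[hits$i])
  wb <- w[hits$j] + hits$tj * (w[hits$j + 1] - w[hits$j])
  pt <- complex(real = hits$px[1], imaginary = hits$py[1])
  new_loop_report(TRUE, sort(c(wa[1], wb[1])), pt,
                  all_crossings = tibble(
                    omega_a = wa, omega_b = wb,
                    point = complex(real = hits$px, imaginary = hits$py)))
}

new_loop_report <- function(has, freqs, point, all_crossings = NULL) {
  structure(
    list(has_secondary_loop = has,
         crossing_frequencies = freqs,
         crossing_point = point,
         coupling_label = if (has) "strong" else "weak",
         crossings = all_crossings),
    class = "loop_report")
}

#' @export
print.loop_report <- function(x, ...) {
  cat(sprintf("<loop_report> %s coupling: secondary loop %s\n",
              x$coupling_label,
              if (x$has_secondary_loop) "present" else "absent"))
  if (x$has_secondary_loop) {
    cat(sprintf("  crossing at %.6g / %.6g cm-1, r = %.4g %+.4gi\n",
                x$crossing_frequencies[1], x$crossing_frequencies[2],
                Re(x$crossing_point), Im(x$crossing_point)))
  }
  invisible(x)
}

# All transversal self-intersections of the open polyline (x, y).
# Bounding-box prefilter on all non-adjacent segment pairs, then exact
# parametric intersection. Returns segment indices, parameters and points.
polyline_self_intersections <- function(x, y, tol) {
  n <- length(x) - 1L
  x1 <- x[1:n]; y1 <- y[1:n]; x2 <- x[2:(n + 1)]; y2 <- y[2:(n + 1)]
  bxmin <- pmin(x1, x2) - tol; bxmax <- pmax(x1, x2) + tol
  bymin <- pmin(y1, y2) - tol; bymax <- pmax(y1, y2) + tol
  cand <- which(
    outer(bxmin, bxmax, "<=") & outer(bxmax, bxmin, ">=") &
    outer(bymin, bymax, "<=") & outer(bymax, bymin, ">="),
    arr.ind = TRUE)
  cand <- cand[cand[, 2] > cand[, 1] + 1L, , drop = FALSE]  # skip adjacent
  if (nrow(cand) == 0) {
    return(tibble(i = integer(0), j = integer(0), ti = numeric(0),
                  tj = numeric(0), px = numeric(0), py = numeric(0)))
  }
  i <- cand[, 1]; j <- cand[, 2]
  dxi <- x2[i] - x1[i]; dyi <- y2[i] - y1[i]
  dxj <- x2[j] - x1[j]; dyj <- y2[j] - y1[j]
  den <- dxi * dyj - dyi * dxj
  rx <- x1[j] - x1[i]; ry <- y1[j] - y1[i]
  ti <- (rx * dyj - ry * dxj) / den
  tj <- (rx * dyi - ry * dxi) / den
  eps <- 1e-12
  ok <- is.finite(ti) & is.finite(tj) &
    ti > -eps & ti < 1 + eps & tj > -eps & tj < 1 + eps & abs(den) > 0
  # drop near-vertex touches (numerical, not a genuine loop)
  vtx <- (ti < 1e-9 | ti > 1 - 1e-9) & (tj < 1e-9 | tj > 1 - 1e-9)
  ok <- ok & !vtx
  if (!any(ok)) {
    return(tibble(i = integer(0), j = integer(0), ti = numeric(0),
                  tj = numeric(0), px = numeric(0), py = numeric(0)))
  }
  i <- i[ok]; j <- j[ok]; ti <- ti[ok]; tj <- tj[ok]
  tibble(i = i, j = j, ti = ti, tj = tj,
         px = x1[i] + ti * (x2[i] - x1[i]),
         py = y1[i] + ti * (y2[i] - y1[i]))
}

#' Adaptive trajectory sampling
#'
#' Samples r(w) over a span of at least `span_factor` half-widths
#' (gamma_r + gamma_a) either side of the resonance, plus a fine window
#' around each molecular line, then subdivides in w until every polyline
#' segment is shorter than `seg_frac` of the trajectory diameter. This keeps
#' small secondary loops (near the xi = 1 threshold) resolved without a huge
#' uniform grid.
#'
#' @param system A [coupled_system()].
#' @param span_factor Half-span in units of (gamma_r + gamma_a); at least 10.
#' @param n0 Initial number of samples.
#' @param seg_frac Target maximum segment length / trajectory diameter.
#' @param max_pass Maximum subdivision passes.
#' @return A `complex_trajectory` tibble.
#' @export
sample_trajectory <- function(system, span_factor = 10, n0 = 601,
                              seg_frac = 0.01, max_pass = 8) {
  res <- system$resonator
  span <- max(10, span_factor) * (res$gamma_r + res$gamma_a)
  w <- seq(max(res$omega0 - span, 1e-9), res$omega0 + span, length.out = n0)
  for (osc in system$oscillators) {
    fine <- seq(osc$omega_m - 5 * osc$gamma_m, osc$omega_m + 5 * osc$gamma_m,
                length.out = 201)
    w <- c(w, fine[fine > 0])
  }
  w <- sort(unique(w))
  z <- tcmt_r(system, w)
  for (pass in seq_len(max_pass)) {
    x <- Re(z); y <- Im(z)
    diam <- sqrt(diff(range(x))^2 + diff(range(y))^2)
    dx <- diff(x); dy <- diff(y)
    seg <- sqrt(dx^2 + dy^2)
    long <- which(seg > seg_frac * diam)
    # high-curvature refinement: split around sharp polyline turns so small
    # secondary loops (xi just above 1) stay resolved
    ns <- length(seg)
    cosang <- (dx[-ns] * dx[-1] + dy[-ns] * dy[-1]) /
      pmax(seg[-ns] * seg[-1], .Machine$double.xmin)
    sharp <- which(cosang < cos(0.2) & pmax(seg[-ns], seg[-1]) > 1e-7 * diam)
    split <- sort(unique(c(long, sharp, sharp + 1L)))
    split <- split[split >= 1 & split <= ns]
    if (length(split) == 0) break
    mid <- (w[split] + w[split + 1]) / 2
    w2 <- sort(unique(c(w, mid)))
    if (length(w2) == length(w)) break
    w <- w2
    z <- tcmt_r(system, w)
  }
  out <- tibble(wavenumber = w, r = z)
  class(out) <- c("complex_trajectory", class(out))
  attr(out, "system") <- system
  out
}

#' Strong-coupling threshold scan
#'
#' Sweeps the coupling ratio xi = mu/gamma_m and reports, for each loss ratio
#' f, the smallest xi at which the complex reflection trajectory develops a
#' secondary loop. For the co-resonant single-oscillator model the analytic
#' threshold is xi = 1 (crossings at omega_m +/- sqrt(mu^2 - gamma_m^2)).
#'
#' @param f_values Loss ratios to scan.
#' @param xi_values Increasing grid of coupling ratios.
#' @param gamma_a,gamma_m Reference rates (gamma_r = f * gamma_a,
#'   mu = xi * gamma_m), rate units.
#' @param omega0 Resonance position for both resonator and oscillator
#'   (co-resonant scan), cm^-1.
#' @return Tibble with columns `f`, `xi_threshold`.
#' @examples
#' loop_threshold(f_values = 10, xi_values = seq(0.8, 1.2, 0.05))
#' @export
loop_threshold <- function(f_values = c(0.4, 1, 10),
                           xi_values = seq(0.5, 3, by = 0.01),
                           gamma_a = 1, gamma_m = 1, omega0 = 1730) {
  purrr::map_dfr(f_values, function(f) {
    thr <- NA_real_
    for (xi in xi_values) {
      sys <- coupled_system(
        resonator(omega0, f * gamma_a, gamma_a),
        molecular_oscillator(omega0, gamma_m, xi * gamma_m))
      rep <- detect_loops(sample_trajectory(sys))
      if (rep$has_secondary_loop) { thr <- xi; break }
    }
    tibble(f = f, xi_threshold = thr)
  })
}
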