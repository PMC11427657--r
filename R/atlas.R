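#' Sensitivity maps over the three coupling channels
#'
#' The sensitivity of the absorber is controlled through three channels: the
#' radiation-loss channel f = gamma_r/gamma_a, the resonator-oscillator
#' coupling channel xi = mu/gamma_m, and the frequency-detuning channel
#' detuning = omega0 - omega_m. `channel_grid()` fixes the reduced
#' coordinates plus the reference scales that close the parametrization
#' (gamma_a = `gamma_a_ref`, gamma_r = f gamma_a, gamma_m = `gamma_m_ref`,
#' mu = xi gamma_m). `sensitivity_map()` evaluates the enhanced-signal
#' statistic on the plane spanned by the two free channels.
#'
#' Default grids mirror the usual presentation: f log-spaced on \[0.1, 20\],
#' xi on \[0.5, 3\], detuning on \[-25, 25\] gamma_m units.
#'
#' @param f_values,xi_values,detuning_values Strictly increasing channel
#'   grids (f, xi >= 0).
#' @param gamma_a_ref,gamma_m_ref Reference rate scales.
#' @return `channel_grid()`: a list of class `channel_grid`.
#' @examples
#' g <- channel_grid(f_values = c(0.4, 1, 10), xi_values = c(0.5, 1),
#'                   detuning_values = seq(-5, 5, 0.5))
#' m <- sensitivity_map(g, fixed_channel = "xi", fixed_value = 1)
#' @export
channel_grid <- function(f_values = exp(seq(log(0.1), log(20), length.out = 200)),
                         xi_values = c(0.5, 1, 1.5, 2, 2.5, 3),
                         detuning_values = seq(-25, 25, length.out = 501),
                         gamma_a_ref = 1, gamma_m_ref = 1) {
  for (nm in c("f_values", "xi_values", "detuning_values")) {
    v <- get(nm)
    if (length(v) < 1 || anyNA(v)) abort(sprintf("`%s` must be non-empty.", nm))
    if (length(v) > 1 && any(diff(v) <= 0)) {
      abort(sprintf("`%s` must be strictly increasing.", nm))
    }
  }
  if (any(f_values < 0) || any(xi_values < 0)) {
    abort("`f_values` and `xi_values` must be >= 0.")
  }
  stop_unless_positive(gamma_a_ref = gamma_a_ref, gamma_m_ref = gamma_m_ref)
  structure(list(f_values = f_values, xi_values = xi_values,
                 detuning_values = detuning_values,
                 gamma_a_ref = gamma_a_ref, gamma_m_ref = gamma_m_ref),
            class = "channel_grid")
}

#' @rdname channel_grid
#' @param grid A [channel_grid()].
#' @param fixed_channel Which channel to hold fixed: `"f"`, `"xi"` or
#'   `"detuning"`.
#' @param fixed_value Value of the fixed channel.
#' @return `sensitivity_map()`: a long tibble of class `sensitivity_map` with
#'   the two free channel columns and `i_seira` (signed).
#' @export
sensitivity_map <- function(grid, fixed_channel = c("xi", "f", "detuning"),
                            fixed_value = NULL) {
  if (!inherits(grid, "channel_grid")) abort("`grid` must be a channel_grid().")
  fixed_channel <- match.arg(fixed_channel)
  axes <- setdiff(c("f", "xi", "detuning"), fixed_channel)
  vals <- list(f = grid$f_values, xi = grid$xi_values,
               detuning = grid$detuning_values)
  if (is.null(fixed_value)) fixed_value <- vals[[fixed_channel]][1]
  cells <- tidyr::expand_grid(!!axes[1] := vals[[axes[1]]],
                              !!axes[2] := vals[[axes[2]]])
  ch <- as.list(cells)
  ch[[fixed_channel]] <- fixed_value
  cells$i_seira <- sensitivity_value(
    f = ch$f, xi = ch$xi, detuning = ch$detuning,
    gamma_a_ref = grid$gamma_a_ref, gamma_m_ref = grid$gamma_m_ref)
  class(cells) <- c("sensitivity_map", class(cells))
  attr(cells, "axes") <- axes
  attr(cells, "fixed") <- setNames(fixed_value, fixed_channel)
  attr(cells, "refs") <- c(gamma_a_ref = grid$gamma_a_ref,
                           gamma_m_ref = grid$gamma_m_ref)
  cells
}

#' Detuning of maximum sensitivity
#'
#' Finds the detuning maximising |sensitivity| at a given (f, xi), from a
#' precomputed map containing a detuning axis. Ties are broken toward zero
#' detuning, then toward the non-negative member of a symmetric tie.
#'
#' @param map A `sensitivity_map` with a `detuning` column.
#' @param f,xi Channel values; the nearest grid slice is used for whichever
#'   of the two is an axis of the map.
#' @return Optimal detuning (rate units of the map).
#' @export
optimal_detuning <- function(map, f = NULL, xi = NULL) {
  if (!"detuning" %in% names(map)) {
    abort("`map` must contain a `detuning` axis.")
  }
  sl <- map
  for (ch in c("f", "xi")) {
    want <- switch(ch, f = f, xi = xi)
    if (ch %in% names(sl) && !is.null(want)) {
      g <- unique(sl[[ch]])
      pick <- g[which.min(abs(g - want))]
      sl <- sl[sl[[ch]] == pick, ]
    }
  }
  s <- abs(sl$i_seira)
  if (diff(range(s)) == 0) {
    abort("Flat sensitivity slice: the detuning argmax is degenerate.")
  }
  best <- which(s >= max(s) - .Machine$double.eps * max(s) * 4)
  d <- sl$detuning[best]
  d <- d[order(abs(d), -sign(d))]  # toward 0, prefer non-negative on ties
  d[1]
}

#' Enhancement bandwidth over detuning
#'
#' The contiguous detuning interval, containing the sensitivity maximum, on
#' which |sensitivity| stays at or above `floor_fraction` of its maximum.
#' Reported in rate units of `gamma_m_ref`.
#'
#' @param f,xi Channel values.
#' @param floor_fraction Fraction of max |sensitivity| defining the floor
#'   (0 < floor_fraction < 1).
#' @param detuning_values Detuning scan grid.
#' @inheritParams channel_grid
#' @return One-row tibble: `lower`, `upper`, `width` (width 0 with NA bounds
#'   when xi = 0, i.e. no coupling).
#' @examples
#' enhancement_bandwidth(f = 10, xi = 1)$width
#' @export
enhancement_bandwidth <- function(f, xi, floor_fraction = 0.1,
                                  detuning_values = seq(-200, 200, 0.25),
                                  gamma_a_ref = 1, gamma_m_ref = 1) {
  if (floor_fraction <= 0 || floor_fraction >= 1) {
    abort("`floor_fraction` must be in (0, 1).")
  }
  if (xi == 0) {
    return(tibble(lower = NA_real_, upper = NA_real_, width = 0))
  }
  s <- abs(sensitivity_value(f, xi, detuning_values,
                             gamma_a_ref = gamma_a_ref,
                             gamma_m_ref = gamma_m_ref))
  imax <- which.max(s)
  keep <- s >= floor_fraction * s[imax]
  lo <- imax; hi <- imax
  while (lo > 1 && keep[lo - 1]) lo <- lo - 1
  while (hi < length(s) && keep[hi + 1]) hi <- hi + 1
  tibble(lower = detuning_values[lo], upper = detuning_values[hi],
         width = detuning_values[hi] - detuning_values[lo])
}

#' Anticrossing diagnostic
#'
#' Sweeps the resonator position omega0 through the molecular line and traces
#' the prominent extrema of the enhanced-signal spectrum deltaA(w). In an
#' undercoupled strong-coupling system the two polariton branches avoid
#' crossing (positive minimum branch separation and a gap around the line);
#' in the overcoupled regime the dominant feature stays pinned at the
#' molecular line for every resonator position.
#'
#' @param f,xi Channel values.
#' @param sweep_range Range of omega0 around the line, rate units; must
#'   cover the line.
#' @param omega_m Molecular line position, cm^-1.
#' @param n_sweep Number of resonator positions.
#' @param gamma_a_ref,gamma_m_ref Reference rates.
#' @param min_prominence_frac Prominence floor for branch extrema, as a
#'   fraction of the global max |deltaA|.
#' @return A list of class `anticrossing_trace`: `branches` (tibble: `omega0`,
#'   `position`, `depth`, `rank`), `dominant` (tibble: `omega0`, `position`),
#'   `min_branch_separation` (cm^-1), `max_dominant_offset` (cm^-1),
#'   `grid_step`.
#' @export
anticrossing_diagnostic <- function(f, xi, sweep_range = c(-60, 60),
                                    omega_m = 1730, n_sweep = 41,
                                    gamma_a_ref = 1, gamma_m_ref = 1,
                                    min_prominence_frac = 0.01) {
  if (sweep_range[1] > 0 || sweep_range[2] < 0) {
    abort("`sweep_range` must cover the molecular line (contain 0).")
  }
  ga <- gamma_a_ref; gr <- f * ga; gm <- gamma_m_ref; mu <- xi * gm
  sweep <- omega_m + seq(sweep_range[1], sweep_range[2], length.out = n_sweep)
  span <- 6 * (gr + ga) + max(abs(sweep_range))
  wgrid <- seq(max(omega_m - span, 1e-9), omega_m + span,
               by = max(gm / 8, (gr + ga) / 2000))
  step <- wgrid[2] - wgrid[1]
  all_max <- 0
  per <- purrr::map(sweep, function(w0) {
    sys <- coupled_system(resonator(w0, gr, ga),
                          molecular_oscillator(omega_m, gm, mu))
    ds <- delta_spectrum(sys, wgrid)
    ds$value
  })
  all_max <- max(vapply(per, function(v) max(abs(v)), numeric(1)))
  if (all_max == 0) {
    return(structure(list(
      branches = tibble(omega0 = numeric(0), position = numeric(0),
                        depth = numeric(0), rank = integer(0)),
      dominant = tibble(omega0 = numeric(0), position = numeric(0)),
      min_branch_separation = 0, max_dominant_offset = 0, grid_step = step),
      class = "anticrossing_trace"))
  }
  prom_floor <- min_prominence_frac * all_max
  branches <- purrr::map2_dfr(sweep, per, function(w0, v) {
    sp <- seira_spectrum(wgrid, abs(v), kind = "difference")
    pk <- find_peaks(sp, min_prominence = prom_floor)
    if (nrow(pk) == 0) return(tibble())
    pk <- dplyr::arrange(pk, dplyr::desc(.data$prominence))
    tibble(omega0 = w0, position = pk$position, depth = pk$height,
           rank = seq_len(nrow(pk)))
  })
  if (nrow(branches) == 0) {
    abort("No resolved extrema in the anticrossing sweep; refine the grid.")
  }
  seps <- branches %>%
    dplyr::group_by(.data$omega0) %>%
    dplyr::filter(dplyr::n() >= 2) %>%
    dplyr::summarise(
      sep = {
        p <- .data$position[order(-.data$depth)][1:2]
        abs(diff(p))
      }, .groups = "drop")
  min_sep <- if (nrow(seps) == 0) 0 else min(seps$sep)
  dominant <- branches %>%
    dplyr::filter(.data$rank == 1) %>%
    dplyr::select("omega0", "position")
  structure(list(
    branches = branches,
    dominant = dominant,
    min_branch_separation = min_sep,
    max_dominant_offset = max(abs(dominant$position - omega_m)),
    grid_step = step),
    class = "anticrossing_trace")
}

#' @export
print.anticrossing_trace <- function(x, ...) {
  cat(sprintf(
    "<anticrossing_trace> %d sweep points; min branch separation %.4g cm-1; max dominant offset %.4g cm-1 (grid step %.4g)\n",
    length(unique(x$branches$omega0)), x$min_branch_separation,
    x$max_dominant_offset, x$grid_step))
  invisible(x)
}
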