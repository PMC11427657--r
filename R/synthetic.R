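#' Device and molecule presets
#'
#' Three device presets span the study conditions: a traditional overcoupled
#' absorber (`"OC"`, f = 10, weak molecular coupling), its high-coupling
#' variant (`"OC-Hmu"`, same losses, small antenna gap giving xi about 2.5 at
#' unit coverage) and an undercoupled high-coupling device (`"UC-Hmu"`,
#' f = 0.4). Rates are in cm^-1 and were chosen to reproduce the qualitative
#' regimes (loss ratio, coupling ratio, mid-infrared linewidths); they are
#' synthetic stand-ins, not fitted values of any fabricated device.
#'
#' Molecule presets give Lorentzian line tables (position, width, relative
#' strength). The PMMA carbonyl line at 1730 cm^-1 and the protein Amide
#' I/II bands near 1657/1540 cm^-1 anchor the tables; remaining positions
#' are literature-informed fingerprints, flagged as such in the metadata.
#'
#' @param name Preset name.
#' @return `device_preset()`: list of class `device_preset` with `name`,
#'   `omega0`, `gamma_r`, `gamma_a`, `coupling_scale` (base mu per unit
#'   surface coverage, cm^-1).
#' @examples
#' device_preset("OC-Hmu")$gamma_r
#' molecule_preset("PMMA")$lines
#' @export
device_preset <- function(name = c("OC-Hmu", "OC", "UC-Hmu")) {
  name <- match.arg(name)
  p <- switch(name,
    "OC-Hmu" = list(gamma_r = 400, gamma_a = 40, coupling_scale = 25),
    "OC"     = list(gamma_r = 400, gamma_a = 40, coupling_scale = 6),
    "UC-Hmu" = list(gamma_r = 40, gamma_a = 100, coupling_scale = 25))
  structure(c(list(name = name, omega0 = 1730), p), class = "device_preset")
}

#' @rdname device_preset
#' @return `molecule_preset()`: list of class `molecule_preset` with `name`,
#'   `lines` (tibble: `omega_m`, `gamma_m`, `strength`), `c_half`
#'   (half-saturation concentration of the Langmuir coverage map, in the
#'   molecule's working units), `molar_mass_kda` (proteins; literature
#'   values), `anchored` (which line positions are study-anchored vs
#'   literature-informed).
#' @export
molecule_preset <- function(name = c("PMMA", "BSA", "BLG", "urea",
                                     "lactic_acid", "glucose", "spike")) {
  name <- match.arg(name)
  ln <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    tibble(omega_m = m[, 1], gamma_m = m[, 2], strength = m[, 3])
  }
  p <- switch(name,
    PMMA = list(lines = ln(1150, 12, 0.50, 1193, 12, 0.45, 1270, 12, 0.30,
                           1450, 12, 0.25, 1730, 10, 1.00, 2950, 20, 0.30),
                c_half = 30, molar_mass_kda = NA_real_,
                anchored = "1730 (C=O)"),
    BSA = list(lines = ln(1300, 25, 0.20, 1540, 25, 0.70, 1657, 25, 1.00),
               c_half = 50, molar_mass_kda = 66.4,
               anchored = "1657 (Amide I), 1540 (Amide II)"),
    BLG = list(lines = ln(1300, 25, 0.20, 1540, 25, 0.65, 1632, 22, 0.80,
                          1657, 25, 0.45, 1680, 20, 0.25),
               c_half = 50, molar_mass_kda = 18.4,
               anchored = "Amide I/II identities"),
    urea = list(lines = ln(1465, 18, 1.00, 1590, 20, 0.80, 1682, 18, 0.90),
                c_half = 30, molar_mass_kda = NA_real_,
                anchored = "none (literature fingerprints)"),
    lactic_acid = list(lines = ln(1125, 15, 0.60, 1220, 15, 0.40,
                                  1455, 15, 0.30, 1730, 14, 1.00),
                       c_half = 3, molar_mass_kda = NA_real_,
                       anchored = "none (literature fingerprints)"),
    glucose = list(lines = ln(1030, 15, 1.00, 1080, 15, 0.80,
                              1150, 15, 0.50, 1365, 15, 0.30),
                   c_half = 30, molar_mass_kda = NA_real_,
                   anchored = "none (literature fingerprints)"),
    spike = list(lines = ln(1240, 25, 0.25, 1545, 25, 0.70, 1657, 25, 1.00),
                 c_half = 50, molar_mass_kda = NA_real_,
                 anchored = "Amide I/II identities"))
  structure(c(list(name = name), p), class = "molecule_preset")
}

#' Assemble a coupled system from presets
#'
#' Couples a device preset to a molecule preset at a given surface coverage.
#' Coupling energy scales with molecule number, so the per-line coupling is
#' `mu_i = coupling_scale * sqrt(coverage) * sqrt(strength_i)`: quadrupling
#' the coverage doubles every mu.
#'
#' @param device A [device_preset()] (or its name).
#' @param molecule A [molecule_preset()] (or its name).
#' @param coverage Surface coverage, >= 0 (1 = the study's working load).
#' @return A [coupled_system()].
#' @examples
#' sys <- make_system("OC-Hmu", "PMMA")
#' @export
make_system <- function(device, molecule, coverage = 1) {
  if (is.character(device)) device <- device_preset(device)
  if (is.character(molecule)) molecule <- molecule_preset(molecule)
  if (!is.numeric(coverage) || coverage < 0) abort("`coverage` must be >= 0.")
  res <- resonator(device$omega0, device$gamma_r, device$gamma_a)
  osc <- purrr::pmap(molecule$lines, function(omega_m, gamma_m, strength) {
    molecular_oscillator(omega_m, gamma_m,
                         device$coupling_scale * sqrt(coverage) * sqrt(strength))
  })
  coupled_system(res, osc)
}

#' Noise model for simulated FTIR measurements
#'
#' Additive Gaussian noise plus a slow cubic-polynomial baseline drift
#' (amplitude-bounded), both drawn from a seeded stream so identical seeds
#' give identical realizations.
#'
#' @param sigma Gaussian standard deviation, absorbance units (>= 0).
#' @param baseline_drift Maximum drift amplitude, absorbance units (>= 0).
#' @param seed Integer seed.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(sigma = 0.005, baseline_drift = 0.01, seed = 0) {
  if (sigma < 0 || baseline_drift < 0) {
    abort("`sigma` and `baseline_drift` must be >= 0.")
  }
  structure(list(sigma = sigma, baseline_drift = baseline_drift,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Default measurement grid
#'
#' 1687 points over 800-4000 cm^-1, matching a 4 cm^-1-class FTIR
#' acquisition after interpolation.
#'
#' @export
default_grid <- function() seq(800, 4000, length.out = 1687)

#' Simulate a noisy FTIR absorbance measurement
#'
#' Forward TCMT absorbance plus seeded drift and Gaussian noise, clipped to
#' \[0, 1\]. With `sigma = 0` and `baseline_drift = 0` the output equals
#' [absorption_spectrum()] exactly. All generation parameters and the seed
#' are recorded in the spectrum meta.
#'
#' @param system A [coupled_system()].
#' @param grid Wavenumber grid (default [default_grid()]).
#' @param noise A [noise_model()].
#' @return An absorbance-kind [seira_spectrum()].
#' @export
simulate_measurement <- function(system, grid = default_grid(),
                                 noise = noise_model()) {
  grid <- check_grid(grid)
  clean <- 1 - Mod(tcmt_r(system, grid))^2
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(noise$seed)
  drift <- rep(0, length(grid))
  if (noise$baseline_drift > 0) {
    u <- 2 * (grid - min(grid)) / diff(range(grid)) - 1
    cf <- runif(4, -1, 1)
    raw <- cf[1] + cf[2] * u + cf[3] * u^2 + cf[4] * u^3
    drift <- noise$baseline_drift * raw / max(abs(raw))
  }
  eps <- if (noise$sigma > 0) rnorm(length(grid), 0, noise$sigma) else 0
  y <- pmin(pmax(clean + drift + eps, 0), 1)
  seira_spectrum(grid, y, kind = "absorbance",
                 meta = list(parameters = system_parameters(system),
                             noise = unclass(noise),
                             noise_tol = max(0.1, 5 * noise$sigma)))
}

#' Simulated labelled datasets
#'
#' `simulate_classification_dataset()` builds the molecule-identification
#' set: `n_per_class` noisy absorbance spectra per molecule on one device
#' (defaults: 5 molecules x 50 spectra on the high-coupling overcoupled
#' preset, 1687-point grid). `simulate_titration_dataset()` builds BSA/BLG
#' mixtures: line strengths are weight-summed before coupling and labels
#' carry both concentrations (percent of total protein).
#' `simulate_concentration_series()` simulates a dilution series for one
#' molecule and extracts the peak enhanced signal per concentration through
#' the baseline pipeline.
#'
#' Every function is a pure function of (presets, parameters, seed): per-row
#' noise seeds are derived from `noise$seed` so the whole dataset is
#' reproducible.
#'
#' @param device Device preset or name.
#' @param molecules Character vector of molecule preset names.
#' @param n_per_class Spectra per molecule (>= 2).
#' @param noise A [noise_model()]; its seed anchors the per-row streams.
#' @param grid Wavenumber grid.
#' @param coverage Surface coverage for each molecule.
#' @return A wide spectra tibble (see [spectra_matrix()]) with label columns.
#' @export
simulate_classification_dataset <- function(device = "OC-Hmu",
                                            molecules = c("urea", "lactic_acid",
                                                          "glucose", "BSA", "BLG"),
                                            n_per_class = 50,
                                            noise = noise_model(sigma = 0.01),
                                            grid = default_grid(),
                                            coverage = 1) {
  if (n_per_class < 2) abort("`n_per_class` must be >= 2.")
  rows <- purrr::imap_dfr(setNames(molecules, molecules), function(mol, nm) {
    sys <- make_system(device, mol, coverage)
    which_mol <- match(mol, molecules)
    purrr::map_dfr(seq_len(n_per_class), function(i) {
      nm_i <- noise_model(noise$sigma, noise$baseline_drift,
                          seed = noise$seed + 1000L * which_mol + i)
      sp <- simulate_measurement(sys, grid, nm_i)
      dplyr::bind_cols(tibble(molecule = mol),
                       spectra_matrix(matrix(sp$value, 1), grid))
    })
  })
  rows
}

#' @rdname simulate_classification_dataset
#' @param ratios Data frame or matrix with columns `bsa`, `blg` (relative
#'   concentrations, sum-normalizable, >= 0); default the 7-step titration
#'   100:0 ... 0:100.
#' @param n_per_ratio Spectra per mixture ratio.
#' @export
simulate_titration_dataset <- function(ratios = default_titration_ratios(),
                                       n_per_ratio = 50,
                                       noise = noise_model(sigma = 0.01),
                                       device = "OC-Hmu",
                                       grid = default_grid(),
                                       coverage = 1) {
  ratios <- as.data.frame(ratios)
  if (!all(c("bsa", "blg") %in% names(ratios))) {
    abort("`ratios` needs `bsa` and `blg` columns.")
  }
  if (any(ratios$bsa < 0 | ratios$blg < 0)) abort("Ratios must be >= 0.")
  if (any(ratios$bsa + ratios$blg <= 0)) abort("Each ratio must have positive total.")
  purrr::map_dfr(seq_len(nrow(ratios)), function(k) {
    wb <- ratios$bsa[k] / (ratios$bsa[k] + ratios$blg[k])
    sys <- make_mixture_system(device, wb, coverage)
    purrr::map_dfr(seq_len(n_per_ratio), function(i) {
      nm_i <- noise_model(noise$sigma, noise$baseline_drift,
                          seed = noise$seed + 1000L * k + i)
      sp <- simulate_measurement(sys, grid, nm_i)
      dplyr::bind_cols(tibble(conc_bsa = 100 * wb, conc_blg = 100 * (1 - wb)),
                       spectra_matrix(matrix(sp$value, 1), grid))
    })
  })
}

#' @rdname simulate_classification_dataset
#' @param weight_bsa BSA weight fraction in \[0, 1\] (BLG gets 1 - weight).
#' @export
make_mixture_system <- function(device = "OC-Hmu", weight_bsa, coverage = 1) {
  if (weight_bsa < 0 || weight_bsa > 1) abort("`weight_bsa` must be in [0, 1].")
  bsa <- molecule_preset("BSA")$lines
  blg <- molecule_preset("BLG")$lines
  bsa$strength <- bsa$strength * weight_bsa
  blg$strength <- blg$strength * (1 - weight_bsa)
  lines <- dplyr::bind_rows(bsa, blg) %>%
    dplyr::group_by(.data$omega_m, .data$gamma_m) %>%
    dplyr::summarise(strength = sum(.data$strength), .groups = "drop") %>%
    dplyr::filter(.data$strength > 0)
  mol <- structure(list(name = sprintf("BSA%.0f:BLG%.0f", 100 * weight_bsa,
                                       100 * (1 - weight_bsa)),
                        lines = lines, c_half = 50),
                   class = "molecule_preset")
  make_system(device, mol, coverage)
}

#' @rdname simulate_classification_dataset
#' @export
default_titration_ratios <- function() {
  tibble(bsa = c(100, 80, 60, 50, 40, 20, 0),
         blg = c(0, 20, 40, 50, 60, 80, 100))
}

#' @rdname simulate_classification_dataset
#' @param molecule Molecule preset or name.
#' @param concentrations Non-negative concentrations in the molecule's
#'   working units; coverage follows the Langmuir adsorption map
#'   `coverage = c / (c + c_half)`.
#' @param signal_at Line position (cm^-1) at which the enhanced signal is
#'   read; defaults to the molecule's strongest line.
#' @return `simulate_concentration_series()`: tibble with `concentration`,
#'   `signal` (enhanced-signal value at the line after baseline extraction).
#' @export
simulate_concentration_series <- function(device = "OC-Hmu", molecule = "BSA",
                                          concentrations = c(0, 10, 25, 50,
                                                             100, 150, 250),
                                          noise = noise_model(sigma = 0.002),
                                          grid = default_grid(),
                                          signal_at = NULL) {
  if (any(concentrations < 0)) abort("Concentrations must be >= 0.")
  if (is.character(molecule)) molecule <- molecule_preset(molecule)
  if (is.null(signal_at)) {
    signal_at <- molecule$lines$omega_m[which.max(molecule$lines$strength)]
  }
  purrr::imap_dfr(concentrations, function(conc, i) {
    coverage <- conc / (conc + molecule$c_half)
    sys <- make_system(device, molecule, coverage)
    nm_i <- noise_model(noise$sigma, noise$baseline_drift,
                        seed = noise$seed + i)
    sp <- simulate_measurement(sys, grid, nm_i)
    da <- extract_difference(sp)
    sig <- approx(da$wavenumber, da$value, xout = signal_at)$y
    tibble(concentration = conc, signal = sig)
  })
}
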