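test_that("device presets sit in their intended regimes", {
  expect_identical(classify_regime(resonator(
    device_preset("OC-Hmu")$omega0, device_preset("OC-Hmu")$gamma_r,
    device_preset("OC-Hmu")$gamma_a)), "OC")
  expect_identical(classify_regime(resonator(
    1730, device_preset("UC-Hmu")$gamma_r,
    device_preset("UC-Hmu")$gamma_a)), "UC")
  expect_gt(device_preset("OC-Hmu")$coupling_scale,
            device_preset("OC")$coupling_scale)
  expect_error(device_preset("nope"))
})

test_that("molecule presets carry the anchored fingerprint lines", {
  expect_true(1730 %in% molecule_preset("PMMA")$lines$omega_m)
  for (prot in c("BSA", "BLG", "spike")) {
    lines <- molecule_preset(prot)$lines$omega_m
    expect_true(any(abs(lines - 1657) < 30))  # Amide I
    expect_true(any(abs(lines - 1540) < 10))  # Amide II
  }
})

test_that("coupling scales with sqrt(coverage) and preset arithmetic holds", {
  s0 <- make_system("OC-Hmu", "PMMA", coverage = 0)
  expect_true(all(vapply(s0$oscillators, function(o) o$mu, numeric(1)) == 0))
  s1 <- make_system("OC-Hmu", "PMMA", coverage = 1)
  s4 <- make_system("OC-Hmu", "PMMA", coverage = 4)
  mu1 <- vapply(s1$oscillators, function(o) o$mu, numeric(1))
  mu4 <- vapply(s4$oscillators, function(o) o$mu, numeric(1))
  expect_equal(mu4, 2 * mu1, tolerance = 1e-12)
  # the carbonyl line of the high-coupling preset is strongly coupled
  xi_co <- vapply(s1$oscillators, function(o) o$xi, numeric(1))[
    which(vapply(s1$oscillators, function(o) o$omega_m, numeric(1)) == 1730)]
  expect_gt(xi_co, 1)
  # and the traditional OC preset stays weakly coupled at the same line
  oc <- make_system("OC", "PMMA", coverage = 1)
  xi_oc <- max(vapply(oc$oscillators, function(o) o$xi, numeric(1)))
  expect_lt(xi_oc, 1)
})

test_that("loop topology of the presets mirrors the device taxonomy", {
  expect_true(detect_loops(sample_trajectory(
    make_system("OC-Hmu", "PMMA")))$has_secondary_loop)
  expect_false(detect_loops(sample_trajectory(
    make_system("OC", "PMMA")))$has_secondary_loop)
})

test_that("simulated measurements are clean in the zero-noise limit", {
  sys <- make_system("OC-Hmu", "PMMA")
  grid <- default_grid()
  sp <- simulate_measurement(sys, grid, noise_model(0, 0, 5))
  expect_equal(sp$value, absorption_spectrum(sys, grid)$value,
               tolerance = 1e-14)
  expect_length(sp$value, 1687)
})

test_that("noise realization has the declared scale and is seed-reproducible", {
  sys <- make_system("OC-Hmu", "PMMA")
  grid <- default_grid()
  clean <- absorption_spectrum(sys, grid)$value
  sp1 <- simulate_measurement(sys, grid, noise_model(0.01, 0, 11))
  sp2 <- simulate_measurement(sys, grid, noise_model(0.01, 0, 11))
  expect_identical(sp1$value, sp2$value)
  resid <- (sp1$value - clean)[clean > 0.05 & clean < 0.95]  # avoid clipping
  expect_gt(sd(resid), 0.009)
  expect_lt(sd(resid), 0.011)
  sp3 <- simulate_measurement(sys, grid, noise_model(0.01, 0, 12))
  expect_false(identical(sp1$value, sp3$value))
})

test_that("classification dataset has the study shape and is pure in seed", {
  d <- simulate_classification_dataset(n_per_class = 3,
                                       noise = noise_model(0.01, 0.01, 0))
  expect_equal(nrow(d), 15)
  expect_equal(length(spectra_grid(d)), 1687)
  expect_equal(sort(unique(d$molecule)),
               sort(c("urea", "lactic_acid", "glucose", "BSA", "BLG")))
  d2 <- simulate_classification_dataset(n_per_class = 3,
                                        noise = noise_model(0.01, 0.01, 0))
  expect_identical(spectra_values(d), spectra_values(d2))
  expect_error(simulate_classification_dataset(n_per_class = 1), ">= 2")
  # zero noise -> identical rows within class
  d0 <- simulate_classification_dataset(n_per_class = 2,
                                        noise = noise_model(0, 0, 0),
                                        molecules = c("urea", "BSA"))
  v <- spectra_values(d0)
  expect_identical(v[1, ], v[2, ])
})

test_that("titration endpoints reduce to the single-protein simulations", {
  grid <- default_grid()
  pure <- simulate_titration_dataset(
    ratios = tibble::tibble(bsa = 1, blg = 0), n_per_ratio = 1,
    noise = noise_model(0, 0, 0))
  direct <- simulate_measurement(make_system("OC-Hmu", "BSA"), grid,
                                 noise_model(0, 0, 0))
  expect_equal(unname(spectra_values(pure)[1, ]), direct$value,
               tolerance = 1e-12)
  d <- simulate_titration_dataset(n_per_ratio = 2,
                                  noise = noise_model(0.01, 0, 0))
  expect_equal(nrow(d), 14)
  expect_error(simulate_titration_dataset(
    ratios = tibble::tibble(bsa = -1, blg = 2)), ">= 0")
})

test_that("concentration series rises monotonically and saturates", {
  ser <- simulate_concentration_series(noise = noise_model(0, 0, 1))
  expect_true(all(diff(ser$signal) >= 0))
  # residual baseline-extraction error at zero coverage is well below the
  # smallest real signal in the series
  expect_lt(abs(ser$signal[ser$concentration == 0]), 0.005)
  # saturation: increments shrink at high concentration
  inc <- diff(ser$signal) / diff(ser$concentration)
  expect_lt(tail(inc, 1), head(inc[inc > 0], 1))
})

test_that("series + calibration + 3-sigma closure recovers the implied LOD", {
  concs <- c(0, 5, 10, 25, 50, 100, 200)
  sigma <- 0.002
  ser <- simulate_concentration_series(concentrations = concs,
                                       noise = noise_model(sigma, 0, 1))
  cal <- calibration_fit(ser, model = "langmuir_ext")
  blanks <- vapply(1:20, function(s) {
    simulate_concentration_series(concentrations = 0,
                                  noise = noise_model(sigma, 0, s))$signal
  }, numeric(1))
  lod <- lod_3sigma(cal, sigma_blank = sd(blanks))$lod
  # reference: the same model fitted to the noiseless response gives the
  # generator-implied origin slope
  ser0 <- simulate_concentration_series(concentrations = concs,
                                        noise = noise_model(0, 0, 1))
  cal0 <- calibration_fit(ser0, model = "langmuir_ext")
  lod_ref <- lod_3sigma(cal0, sigma_blank = sd(blanks))$lod
  expect_lt(abs(lod - lod_ref) / lod_ref, 0.2)
})
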