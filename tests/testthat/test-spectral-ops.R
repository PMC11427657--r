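test_that("wavelength/wavenumber conversion matches 10000/x and is involutive", {
  expect_equal(wavelength_to_wavenumber(3), 3333.333, tolerance = 1e-6)
  expect_equal(wavelength_to_wavenumber(10), 1000)
  expect_equal(wavenumber_to_wavelength(wavelength_to_wavenumber(1730)), 1730)
  expect_equal(band_width_wavenumber(3, 10), 10000 / 3 - 1000)
  expect_error(wavelength_to_wavenumber(-2), "positive")
  expect_equal(unit_sensitivity(58, 8), 7.25)
})

test_that("AsLS baseline tracks a broad envelope and recovers a narrow peak", {
  grid <- default_grid()
  broad <- absorption_spectrum(coupled_system(resonator(1730, 400, 40)), grid)
  base <- asls_baseline(broad)
  interior <- grid > 1000 & grid < 3800
  expect_lt(max(abs(base$value - broad$value)[interior]),
            0.01 * max(broad$value))
  # broad resonance + narrow upward peak of height h
  h <- 0.2
  peaky <- seira_spectrum(grid,
                          broad$value + h * exp(-((grid - 1730) / 15)^2),
                          kind = "absorbance")
  da <- extract_difference(peaky)
  expect_equal(max(da$value), h, tolerance = 0.1)
  # flat zero spectrum -> zero baseline
  flat <- seira_spectrum(grid, rep(0, length(grid)), kind = "absorbance")
  expect_true(all(abs(asls_baseline(flat)$value) < 1e-12))
})

test_that("AsLS is idempotent: re-extracting baseline + baseline is stable", {
  grid <- default_grid()
  sys <- make_system("OC-Hmu", "PMMA")
  sp <- simulate_measurement(sys, grid, noise_model(0, 0, 1))
  b1 <- asls_baseline(sp)
  again <- seira_spectrum(grid, b1$value, kind = "absorbance")
  b2 <- asls_baseline(again)
  # the asymmetric pull-down on an already-smooth input stays within a few
  # percent of the envelope height
  expect_lt(max(abs(b2$value - b1$value)), 0.05 * max(b1$value))
})

test_that("extraction locates molecular lines and respects the regime flag", {
  grid <- default_grid()
  step <- diff(grid[1:2])
  sp <- simulate_measurement(make_system("OC-Hmu", "PMMA"), grid,
                             noise_model(0, 0, 1))
  da <- extract_difference(sp)
  pk <- find_peaks(da, min_prominence = 0.2 * max(da$value))
  expect_lt(abs(pk$position[1] - 1730), step)
  # nothing to extract without coupling
  sp0 <- simulate_measurement(make_system("OC-Hmu", "PMMA", coverage = 0),
                              grid, noise_model(0, 0, 1))
  da0 <- extract_difference(sp0)
  expect_lt(max(abs(da0$value)), 0.01 * max(sp0$value))
  # detuned UC extraction is dispersive: sign change across the line
  dev <- device_preset("UC-Hmu"); dev$omega0 <- 1780
  spu <- simulate_measurement(make_system(dev, "PMMA"), grid,
                              noise_model(0, 0, 1))
  dau <- extract_difference(spu, regime = "UC")
  near <- dau$value[grid > 1700 & grid < 1760]
  expect_true(min(near) < 0 && max(near) > 0)
})

test_that("Savitzky-Golay derivatives are exact on polynomials and linear", {
  grid <- seq(1000, 1200, 2)
  q <- seira_spectrum(grid, (grid - 1100)^2, kind = "difference")
  d2 <- derivative_spectrum(q, derivative_config(order = 2))
  inner <- seq(10, length(grid) - 10)
  expect_equal(d2$value[inner], rep(2, length(inner)), tolerance = 1e-9)
  ramp <- seira_spectrum(grid, 3 * grid, kind = "difference")
  d1 <- derivative_spectrum(ramp, derivative_config(order = 1))
  expect_equal(d1$value[inner], rep(3, length(inner)), tolerance = 1e-9)
  expect_true(all(abs(derivative_spectrum(ramp,
    derivative_config(order = 2))$value[inner]) < 1e-9))
  # linearity of the operator
  y1 <- sin(grid / 20); y2 <- cos(grid / 30)
  lin <- derivative_spectrum(seira_spectrum(grid, 2 * y1 - 5 * y2, "difference"),
                             derivative_config(order = 1))
  d1a <- derivative_spectrum(seira_spectrum(grid, y1, "difference"),
                             derivative_config(order = 1))
  d1b <- derivative_spectrum(seira_spectrum(grid, y2, "difference"),
                             derivative_config(order = 1))
  expect_equal(lin$value, 2 * d1a$value - 5 * d1b$value, tolerance = 1e-12)
})

test_that("second derivative of a Lorentzian dips at the line position", {
  grid <- seq(1600, 1860, 2)
  lor <- seira_spectrum(grid, 1 / (1 + ((grid - 1730) / 12)^2), "difference")
  d2 <- derivative_spectrum(lor, derivative_config(order = 2))
  expect_lt(abs(grid[which.min(d2$value)] - 1730), 2.1)
  expect_error(derivative_spectrum(
    seira_spectrum(grid[1:5], rep(0, 5), "difference"),
    derivative_config(window_points = 11)), "window")
})

test_that("peak finder reports Amide anchors and handles degenerate input", {
  grid <- seq(1400, 1800, 2)
  y <- exp(-((grid - 1657) / 12)^2) + 0.7 * exp(-((grid - 1540) / 14)^2)
  pk <- find_peaks(seira_spectrum(grid, y, "difference"), min_prominence = 0.1)
  expect_equal(nrow(pk), 2)
  expect_equal(sort(pk$position), c(1540, 1657), tolerance = 0.5)
  mono <- seira_spectrum(grid, seq_along(grid) * 0.001, "difference")
  expect_equal(nrow(find_peaks(mono)), 0)
  expect_equal(nrow(find_peaks(seira_spectrum(grid, y, "difference"),
                               min_prominence = 10)), 0)
})

test_that("CSV round trip preserves spectra and malformed input errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  sp <- simulate_measurement(make_system("OC-Hmu", "BSA"),
                             noise = noise_model(0.01, 0.01, 7))
  write_spectrum(sp, f)
  back <- read_spectrum(f)
  expect_equal(back$wavenumber, sp$wavenumber, tolerance = 1e-9)
  expect_equal(back$value, sp$value, tolerance = 1e-9)
  expect_identical(spectrum_kind(back), "absorbance")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "3,4"), bad)
  expect_error(read_spectrum(bad), "header")
})

test_that("JCAMP subset reads and reorders a descending abscissa", {
  f <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c(
    "##TITLE=synthetic descending fixture",
    "##JCAMP-DX=4.24",
    "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
    "##XFACTOR=1", "##YFACTOR=0.001",
    "##DELTAX=-2",
    "##XYDATA=(X++(Y..Y))",
    "2000 10 20 30 40",
    "1992 50 60 70 80",
    "##END="), f)
  sp <- read_spectrum(f)
  expect_equal(sp$wavenumber, seq(1986, 2000, 2))
  expect_equal(sp$value, rev(c(10, 20, 30, 40, 50, 60, 70, 80)) * 0.001)
})
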