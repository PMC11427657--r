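test_that("constructors enforce parameter domains and derived quantities", {
  res <- resonator(1730, 10, 1)
  expect_equal(res$f, 10)
  expect_equal(res$kappa^2, 2 * res$gamma_r)
  expect_error(resonator(1730, -1, 1), "positive")
  expect_error(resonator(1730, 10, 0), "positive")
  expect_error(molecular_oscillator(1730, 0, 1), "positive")  # gm = 0 pole
  osc <- molecular_oscillator(1730, 2, 1)
  expect_equal(osc$xi, 0.5)
  expect_error(molecular_oscillator(1730, 1, -0.1), "mu")
  expect_error(coupled_system(list()), "resonator")
})

test_that("critical coupling gives r = 0 and perfect absorption on resonance", {
  sys <- coupled_system(resonator(1730, 3, 3))
  tr <- reflection(sys, c(1729, 1730, 1731))
  expect_equal(Mod(tr$r[2]), 0, tolerance = 1e-12)
  a <- absorption_spectrum(sys, c(1729, 1730, 1731))
  expect_equal(a$value[2], 1, tolerance = 1e-12)
})

test_that("overcoupled bare absorber matches the 4f/(1+f)^2 closed form", {
  sys <- coupled_system(resonator(1730, 10, 1))
  a <- absorption_spectrum(sys, c(1700, 1730, 1760))
  expect_equal(a$value[2], 40 / 121, tolerance = 1e-12)
  # off resonance the bare Lorentzian form holds
  expect_equal(a$value[1], 4 * 10 * 1 / (11^2 + 30^2), tolerance = 1e-12)
})

test_that("vanishing radiative loss sends r to -1 (no input coupling)", {
  sys <- coupled_system(resonator(1730, 1e-12, 1))
  tr <- reflection(sys, seq(1720, 1740, 1))
  expect_true(all(Mod(tr$r + 1) < 1e-5))
})

test_that("coupled on-resonance absorption follows the gamma_eff closed form", {
  sys <- oc_system(xi = 1)
  a <- absorption_spectrum(sys, c(1729, 1730, 1731))
  expect_equal(a$value[2], 80 / 144, tolerance = 1e-12)
  expect_equal(a$value[2], closed_form_peak(10, 1, 1, 1), tolerance = 1e-12)
})

test_that("delta spectrum is the difference against the decoupled absorber", {
  sys <- oc_system(xi = 1)
  grid <- seq(1700, 1760, 0.25)
  ds <- delta_spectrum(sys, grid)
  expect_spectrum(ds)
  i0 <- which(grid == 1730)
  expect_equal(ds$value[i0], 80 / 144 - 40 / 121, tolerance = 1e-12)
  # all couplings zero -> identically zero
  sys0 <- coupled_system(resonator(1730, 10, 1),
                         molecular_oscillator(1730, 1, 0))
  expect_true(all(abs(delta_spectrum(sys0, grid)$value) < 1e-15))
  expect_error(delta_spectrum(coupled_system(resonator(1730, 10, 1)), grid),
               "oscillator")
})

test_that("sensitivity statistic is signed and flips between OC and UC", {
  expect_equal(seira_sensitivity(oc_system(xi = 1)), 80 / 144 - 40 / 121,
               tolerance = 1e-12)
  uc <- coupled_system(resonator(1730, 0.4, 1),
                       molecular_oscillator(1730, 1, 0.5))
  expect_equal(seira_sensitivity(uc),
               closed_form_peak(0.4, 1, 1, 0.5) - closed_form_peak(0.4, 1),
               tolerance = 1e-12)
  expect_lt(seira_sensitivity(uc), 0)
  expect_equal(seira_sensitivity(coupled_system(
    resonator(1730, 10, 1), molecular_oscillator(1730, 1, 0))), 0)
  expect_error(seira_sensitivity(oc_system(), 2), "out of range")
})

test_that("regime classification respects the tolerance band", {
  expect_identical(classify_regime(resonator(1730, 10, 1)), "OC")
  expect_identical(classify_regime(resonator(1730, 0.4, 1)), "UC")
  expect_identical(classify_regime(resonator(1730, 1, 1)), "critical")
  expect_identical(classify_regime(resonator(1730, 1.05, 1), tol = 0.1),
                   "critical")
  expect_error(classify_regime(resonator(1730, 1, 1), tol = -1), "tol")
})

test_that("bare linewidth is 2(gamma_r + gamma_a) and scales linearly", {
  expect_equal(resonator_fwhm(resonator(1730, 1, 1)), 4)
  expect_equal(resonator_fwhm(resonator(1730, 10, 10)), 40)
  # numeric half-maximum search agrees with the closed form
  res <- resonator(1730, 7, 3)
  grid <- seq(1600, 1860, 0.05)
  a <- absorption_spectrum(coupled_system(res), grid)$value
  above <- grid[a >= max(a) / 2]
  expect_equal(max(above) - min(above), resonator_fwhm(res),
               tolerance = 0.1 / resonator_fwhm(res))
})

test_that("A = 1 - |r|^2 pointwise and the energy bound holds", {
  grid <- seq(1500, 2000, 0.5)
  for (sys in list(oc_system(2.5), uc_system(2.5),
                   coupled_system(resonator(1700, 3, 5)))) {
    tr <- reflection(sys, grid)
    a <- absorption_spectrum(sys, grid)
    expect_equal(a$value, 1 - Mod(tr$r)^2, tolerance = 1e-14)
    expect_true(all(Mod(tr$r) <= 1 + 1e-12))
    expect_true(all(a$value >= -1e-12 & a$value <= 1 + 1e-12))
  }
})

test_that("zero-detuning closed form holds for multiple co-resonant lines", {
  sys <- coupled_system(
    resonator(1730, 8, 2),
    list(molecular_oscillator(1730, 1, 1.5),
         molecular_oscillator(1730, 2, 1)))
  a <- absorption_spectrum(sys, c(1729.5, 1730, 1730.5))
  expect_equal(a$value[2], closed_form_peak(8, 2, c(1, 2), c(1.5, 1)),
               tolerance = 1e-12)
})

test_that("sign law at zero detuning: positive iff gamma_eff within (ga, gr^2/ga)", {
  # with ga = gm = 1, gamma_eff = 1 + xi^2; the statistic is positive
  # exactly when 1 < gamma_eff < f^2
  for (f in c(0.4, 2, 10)) {
    for (xi in c(0.1, 0.5, 1, 2, 5, 12)) {
      s <- sensitivity_value(f, xi, 0)
      geff <- 1 + xi^2
      if (geff < f^2) expect_gt(s, 0) else expect_lt(s, 0)
    }
  }
})

test_that("sensitivity is invariant under loss scaling at fixed f and xi'", {
  # scaling gr, ga by s and mu by sqrt(s) (gm fixed at 1/s of the scale)
  # keeps f and mu^2/(ga gm) fixed; the statistic is unchanged
  base <- sensitivity_value(10, 1, 0)
  for (s in c(0.1, 1, 10)) {
    sys <- coupled_system(resonator(1730, 10 * s, 1 * s),
                          molecular_oscillator(1730, 1, sqrt(s)))
    expect_equal(seira_sensitivity(sys), base, tolerance = 1e-12)
  }
})

test_that("grid validation rejects bad inputs", {
  sys <- oc_system()
  expect_error(reflection(sys, c(2, 1)), "increasing")
  expect_error(reflection(sys, c(-1, 1)), "positive")
  expect_error(reflection(sys, 5), "2 finite")
})
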