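# Shared fixtures: small coupled systems in reduced units and cm^-1 scale.

oc_system <- function(xi = 1, f = 10, detuning = 0, gamma_a = 1, gamma_m = 1,
                      omega_m = 1730) {
  coupled_system(
    resonator(omega_m + detuning, f * gamma_a, gamma_a),
    molecular_oscillator(omega_m, gamma_m, xi * gamma_m))
}

uc_system <- function(xi = 1, detuning = 0) {
  oc_system(xi = xi, f = 0.4, detuning = detuning)
}

# closed form at the line for co-resonant oscillators:
# A(wm) = 4 gr geff / (gr + geff)^2, geff = ga + sum mu^2/gm
closed_form_peak <- function(gr, ga, gm = NULL, mu = NULL) {
  geff <- ga + sum(if (is.null(gm)) 0 else mu^2 / gm)
  4 * gr * geff / (gr + geff)^2
}

expect_spectrum <- function(x) {
  expect_s3_class(x, "seira_spectrum")
  expect_true(all(diff(x$wavenumber) > 0))
}
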