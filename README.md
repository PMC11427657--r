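# seiratcmt

Temporal coupled-mode theory (TCMT) tools for surface-enhanced infrared
absorption (SEIRA) sensing with overcoupled metamaterial absorbers.

Label-free infrared biosensing reads molecular fingerprint vibrations off
the reflection spectrum of a metal-insulator-metal absorber. Because the
bottom mirror blocks transmission, absorbance is `A = 1 - R`, and the whole
device-molecule system is captured by a handful of rates: the absorber's
radiative and ohmic losses (γ_r, γ_a), each molecular line's position,
width and coupling (ω_m, γ_m, μ). This package is for people designing or
analysing such sensors: it implements the coupled-mode dispersion

    r(ω) = κ² / D(ω) − 1,   κ² = 2 γ_r,
    D(ω) = j(ω − ω₀) + (γ_r + γ_a) + Σᵢ μᵢ² / (j(ω − ω_mᵢ) + γ_mᵢ),
    A(ω) = 1 − |r(ω)|²,     ΔA = A − A|μ=0,

and everything the associated measurement workflow needs:

* **Forward model & diagnostics** — absorption/difference spectra, the
  sensitivity statistic `I_SEIRA = ΔA(ω_m)`, coupling-regime
  classification (undercoupled f = γ_r/γ_a < 1 vs overcoupled f > 1), and
  complex-reflection trajectories with secondary-loop detection: the
  trajectory self-intersects exactly when μ/γ_m > 1, the weak-to-strong
  coupling transition.
* **Sensitivity atlas** — maps of `I_SEIRA` over the three control
  channels (f, ξ = μ/γ_m, detuning ω₀ − ω_m), optimal detuning,
  enhancement bandwidth, anticrossing diagnostics.
* **Spectral operations** — asymmetric-least-squares baseline extraction,
  Savitzky–Golay derivative spectra, peak finding, µm↔cm⁻¹ conversion,
  CSV and JCAMP-DX (subset) I/O.
* **Inversion & calibration** — nonlinear least-squares recovery of all
  TCMT parameters from a spectrum, linear / Langmuir concentration
  calibrations, 3σ limits of detection.
* **Chemometrics** — PCA, one-vs-rest linear SVM molecule classification,
  non-negative spectral unmixing, a dense-network concentration regressor,
  Amide-I secondary-structure summaries.
* **Synthetic data** — seeded generators for all of the above: device
  presets (OC, OC-Hµ, UC-Hµ), molecule line tables (PMMA, BSA, BLG, urea,
  lactic acid, glucose, spike protein), noise + drift models, labelled
  classification/titration/concentration datasets.

## Worked example

Build the high-coupling overcoupled device with a single carbonyl-like
line, check its regime and coupling topology, then recover the parameters
from a noisy simulated measurement:

```r
library(seiratcmt)

sys <- coupled_system(resonator(1730, 400, 40),          # f = 10: overcoupled
                      molecular_oscillator(1730, 10, 25)) # xi = 2.5: strong

seira_sensitivity(sys)
#> [1] 0.3189

detect_loops(sample_trajectory(sys))
#> <loop_report> strong coupling: secondary loop present
#>   crossing at 1707.09 / 1752.91 cm-1, r = 0.7778 +2.168e-19i

sp  <- simulate_measurement(sys, noise = noise_model(sigma = 0.005, seed = 42))
fit <- fit_tcmt(sp, n_oscillators = 1, regime_prior = "OC", seed = 1)
fit
#> <tcmt_fit> OC (strong coupling), residual rms 0.00681
#>   omega0 = 1737.13, omega01 = 1730, gamma_r = 407.7, gamma_a = 40.68 (f = 10)
#>   line 1730.14 cm-1: gamma_m = 10.11, mu = 25.48 (xi = 2.52)
```

The sensitivity 0.319 means the carbonyl line adds 32 percentage points of
absorption contrast on top of the bare absorber. The crossing frequencies
sit at ω_m ± √(μ² − γ_m²) = 1730 ± 22.9 cm⁻¹ and the self-intersection
value κ²/(γ_r + γ_a + γ_m) − 1 = 0.7778, both exactly as the dispersion
predicts; the fit recovers all six generating parameters within a few
percent at σ = 0.005 noise (the drift in the simulated baseline accounts
for the small ω₀ offset). `tidy()` and `glance()` return the fit as
tibbles, and `autoplot()` works on spectra, trajectories, maps and
calibrations.

A command-line front end over the same functions lives in
`inst/cli/seiratcmt.R` (subcommands `simulate`, `atlas`, `baseline`,
`derivative`, `fit`, `lod`, `classify`, `unmix`, `synth`).

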