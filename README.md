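# paracest

Simulation and quantification toolkit for **dual-agent paraCEST MRI
cell tracking** in R.

Chemical exchange saturation transfer (CEST) MRI detects agents through
the exchangeable protons they carry: selective RF saturation at the
proton's resonance transfers signal loss to bulk water, producing a dip
in the *z-spectrum* (normalized water signal S/S0 versus saturation
offset). Paramagnetic lanthanide chelates shift their exchangeable
protons far from water — Eu-HPDO3A resonates at **+18 ppm**, Yb-HPDO3A
at **+69/+97 ppm** — so two cell populations labeled with the two
agents can be imaged *simultaneously and distinguishably* in the same
voxel, e.g. neural stem cells (Eu) co-implanted with endothelial cells
(Yb) into a stroke cavity.

The package is aimed at researchers developing or validating such
dual-label protocols. It provides, end to end:

- **Bloch-McConnell simulation** (`simulate_zspectrum()`): multi-pool
  z-spectra under a continuous rectangular pulse, solved exactly per
  offset by matrix exponentiation of the coupled system

  dM/dt = A(Δ, ω₁) M + b,

  with a semisolid magnetization-transfer (MT) pool handled as a
  longitudinal pool saturated at W = π ω₁² g(Δ), where g is the
  super-Lorentzian lineshape (`super_lorentzian()`).
- **Quantification** (`mtr_asymmetry()`, `auc_contrast()`): MTR
  asymmetry, MTRasym = [S(−Δ) − S(+Δ)]/S0, and its band average over
  ±16..20 ppm (Eu) / ±95..99 ppm (Yb); linear concentration
  calibration with detection-threshold inversion
  (`fit_calibration()`, `detection_threshold()`).
- **QUESP exchange-rate estimation** (`quesp_fit()`): Hanes-Woolf
  linearization ω₁²/MTR ~ ω₁², giving the exchange rate k and proton
  fraction f_b from a saturation-power series.
- **WASSR B0 mapping** (`field_map()`, `max_symmetry_center()`):
  per-voxel water-center offsets from low-power water saturation shift
  referencing spectra via the maximum-symmetry algorithm, and
  z-spectrum recentring (`apply_b0_correction()`).
- **Dual-channel mapping** (`dual_channel_maps()`, `roi_compare()`,
  `threshold_overlay()`): B0-corrected Eu and uncorrected Yb AUC maps,
  Welch ROI statistics, colour overlays on T2-weighted images.
- **Digital phantoms** (`tube_phantom()`, `lesion_phantom()`,
  `simulate_study()`): fully simulated, seeded, ground-truthed
  acquisitions of agar tube grids and lesion-slice implants at
  realistic concentrations, noise and B0 inhomogeneity.

## Worked example

Simulate a 4 mM Eu-HPDO3A solution acquisition (1.5 s, 15 uT pulse at
9.4 T), quantify it, and invert the published calibration line:

```r
library(paracest)

sys <- build_system(agent_preset("Eu-HPDO3A", 4), "solution")
z   <- simulate_zspectrum(sys, pulse_preset("eu_solution"),
                          acquisition_protocol(c(-20:-16, 16:20)))
auc_contrast(z, eu_band())
#> [1] 6.250071

# published calibration lines (% asymmetry vs mM)
eu <- calibration_line(4.739, -0.4127)
detection_threshold(eu, 5)      # concentration for a 5% signal change
#> [1] 1.142161

# exchange-rate estimation from a saturation-power series
w1  <- uT_to_rad_s(c(5, 10, 15, 20, 25))
mtr <- quesp_mtr_model(5000, 3.6e-5, 3.0, w1)
quesp_fit(w1, mtr, t1w = 3.0)
#> <quesp_fit> k = 5000 /s, fb = 3.6e-05, r^2 = 1.00000
```

A full synthetic study — dual-labeled implant in a lesion slice,
WASSR field map, channel maps, ROI statistics, overlay — runs as:

```r
report <- run_pipeline(study_config(seed = 3))
report$roi_stats$yb$mean_diff_pct
#> [1] 1.511525
```

A thin command-line wrapper with `simulate`, `quantify`, `quesp`,
`wassr`, `map`, `phantom` and `run` subcommands lives at
`inst/cli/paracest.R` (after installation:
`system.file("cli/paracest.R", package = "paracest")`).

## Vignette

`vignettes/paracest-methods.Rmd` documents the model, its parameters
and defaults, the phantom generator's scope, and the numerical and
design choices.
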