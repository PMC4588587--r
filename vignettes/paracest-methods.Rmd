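---
title: "Models and methods behind paracest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind paracest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paracest)
```

`paracest` simulates and quantifies dual-agent paraCEST MRI
experiments: Eu-HPDO3A-labeled and Yb-HPDO3A-labeled cell populations
imaged simultaneously through their well-separated exchange sites
(+18 ppm for Eu; +69 and +97 ppm for Yb). This vignette documents the
underlying models, the tunable parameters and their defaults, what the
synthetic phantoms do and do not emulate, and the numerical and design
choices made where the design was genuinely open.

## The spin model

A voxel is modeled as a set of exchanging proton pools. Free water
(fraction 1, shift 0) and each agent exchange site are Bloch pools
with full transverse and longitudinal magnetization; in tissue an
additional *semisolid* pool represents macromolecule-bound water.
Under a continuous rectangular saturation pulse of amplitude
$\omega_1 = \gamma B_1$ applied at offset $\Delta$, the coupled
Bloch-McConnell equations form a constant-coefficient linear system

$$\frac{d\mathbf{M}}{dt} = A(\Delta, \omega_1)\,\mathbf{M} + \mathbf{b},$$

with exchange between water and each solute at rate $k_b$
(solute→water) and $f_b k_b$ (water→solute), where $f_b$ is the solute
proton fraction. Because the pulse is rectangular, the system is
propagated *exactly* over the saturation time by a single matrix
exponential of the augmented generator (`Matrix::expm`), rather than
by time stepping. The z-spectrum value is the water longitudinal
magnetization at the end of saturation, normalized by the same readout
with $\omega_1 = 0$.

The test suite validates this propagation against two independent
routes on the same physics: an adaptive fine-step integration
(`deSolve::lsoda`) of an independently assembled right-hand side, and
an eigendecomposition solution of the linear system. The fine-step
route runs at the full 1.5 s pulse for representative offsets and at
0.3 s for ensembles of random systems — direct integration of the
rotating-frame oscillations (hundreds of kHz at the outer offsets) is
exact but slow, and these problem sizes probe every term of the model
while keeping the default test run at desk scale.

### The semisolid (MT) pool

The semisolid pool has a microsecond-scale T2, so it has no
Bloch-representable transverse line; it is modeled as a single
longitudinal component saturated at the lineshape-derived rate
$W = \pi \omega_1^2 g(\Delta)$, with $g$ the super-Lorentzian
absorption lineshape

$$g(\Delta) = \sqrt{\tfrac{2}{\pi}} \int_0^{\pi/2} \sin\theta\,
  \frac{T_{2b}}{|3\cos^2\theta - 1|}
  \exp\!\left[-2\left(\frac{2\pi\Delta T_{2b}}{3\cos^2\theta-1}\right)^2\right]
  d\theta .$$

$g$ diverges on resonance; values for $|\Delta|$ below a 1 kHz cutoff
are obtained by natural-spline interpolation through flanking points
at 1–3× the cutoff, the standard remedy. Off-cutoff values use
adaptive quadrature; the tests pin them against an independent
fine-grid trapezoid quadrature at 1e-6 relative tolerance.

This broad, symmetric MT saturation is what differentiates solution
from tissue behaviour: it widens the water saturation response and
attenuates CEST contrast much more severely at 18 ppm (close to
water) than at 97 ppm — the reason the Yb channel is the more robust
one in vivo, which the attenuation-ordering test reproduces
qualitatively.

### Pool inventories and parameters

Named presets carry the agents' published exchange properties: Eu has
one site (+18 ppm, 5000 s⁻¹); Yb has two (+69 ppm, 10 000 s⁻¹ and
+97 ppm, 15 000 s⁻¹). Proton bookkeeping assumes one exchangeable
proton per complex against 111 000 mM water protons, so
$f_b = n_H c / 111000$; for Yb the proton population is split equally
between the two sites. The Yb "3-pool" description is ambiguous about
whether both sites enter the simulation; we simulate both (water + 2
sites, + semisolid in tissue = 4 pools), since dropping the 69 ppm
site would silently delete its direct-saturation shoulder.

Defaults (all overridable via `build_system(..., overrides = )`):

| parameter | solution | tissue | basis |
|---|---|---|---|
| water T1 | 3.0 s | 1.8 s | typical 9.4 T values |
| water T2 | 1.5 s | 40 ms | tissue value is protocol-fixed |
| semisolid T2 | — | 9.2 µs | protocol-fixed |
| semisolid fraction | — | 0.10 | typical brain MT fraction |
| semisolid k | — | 40 s⁻¹ | typical brain MT rate |
| solute T1 / T2 | 1 s / 10 ms | same | typical bound-proton values |

Only the tissue water T2 and the semisolid T2 are fixed by the study's
protocol; the remaining values are field-typical choices, which is why
absolute in-tissue contrast values (e.g. the published 31%→1.1%
Eu attenuation) are not reproduction targets — the ordering and
direction of the MT effect are.

## Quantification

MTR asymmetry is $100\,[S(-\Delta) - S(+\Delta)]/S_0$ (solute sites at
positive ppm, so agents give positive asymmetry). The AUC contrast of
a band (±16..20 ppm for Eu, ±95..99 ppm for Yb) is defined as the
*mean* asymmetry over the band's mirrored pairs: for the unit-spaced
bands used here, the trapezoidal area divided by the band width
differs from the mean only by a constant, and the mean keeps AUC on
the same percent scale as single-offset asymmetry and the calibration
lines.

Normalization prefers the −300 ppm far-offset reference, averaging
with +300 ppm when both exist; the 0 ppm acquisition is never used as
a reference because it is fully saturated. The source protocols are
not uniform about the reference convention (−120 ppm in the
solution-phantom figure, ±300 ppm in the imaging protocol), so the
policy is a configurable argument with `far_offset` as default.

Concentration calibration is ordinary least squares of percent
asymmetry on mM, and the detection threshold is its exact inverse
$(t - b)/m$. Inverting the published Yb line (slope 2.171, intercept
−0.9877) at a 5% target gives 2.7580 mM — quoted as 2.75 in print;
the package reports the computed value.

## QUESP exchange-rate estimation

The closed-form QUESP model
$\mathrm{MTR} = f_b k T_{1w} \omega_1^2 / [\omega_1^2 (1 + f_b k T_{1w}) + k^2]$
is linearized by the Hanes-Woolf transformation: regressing
$\omega_1^2/\mathrm{MTR}$ on $\omega_1^2$ (unweighted least squares,
matching the cited linear-QUESP formulation) yields
$A = 1/(s-1)$, $k = \sqrt{iA}$, $f_b = A/(kT_{1w})$ from slope $s$ and
intercept $i$. A saturation-independent (constant) MTR series gives a
zero intercept — no rate information — and is rejected, as is
$s \le 1$. Fitting series generated by the full Bloch-McConnell
simulator recovers the generating rate within 15%: the closed form
neglects direct water saturation, so exact agreement is not expected,
and rate differences below ~500 s⁻¹ produce no visible spectral change
anyway.

## WASSR B0 mapping

The low-power WASSR scan samples ±0.3 ppm in 0.04 ppm steps; its
direct-saturation dip is symmetric about the voxel's true water
frequency. `max_symmetry_center()` fits a spline through the sampled
dip, then finds the shift $\delta_0$ minimizing the mirror cost
$\sum_\Delta [C(\delta_0+\Delta) - C(\delta_0-\Delta)]^2$ over the
overlap region, by a 0.001 ppm grid scan with parabolic refinement.
Two numerical choices matter:

- the symmetry search is restricted to a ±0.08 ppm window around the
  dip minimum. Without this, candidates near the grid edge — whose
  mirror overlap is almost empty — achieve noise-level cost and can
  win under noise;
- mirror offsets are spaced at 0.002 ppm so that dips within ~0.02 ppm
  of the grid edge still retain at least three usable mirror pairs;
  with the coarser 0.01 ppm spacing those voxels lose their true
  candidate entirely and bias inward.

The acquisition protocol prints a WASSR pulse of "0.1 µT for 1 ms"; a
1 ms pulse at 0.1 µT produces no measurable dip (the nutation angle is
of order 10⁻⁵ rad), so the package's default WASSR preset uses 1 s at
0.1 µT, with the printed duration kept available as `wassr_short`.

Correction resamples the spline-fitted spectrum at offsets shifted by
$\delta_0$. Disjoint sampled segments (the two sides of an imaging
band) are fitted separately — a single spline across the ±16 ppm gap
would bridge the water dip. Following the source protocols, the
pipeline applies the correction to the Eu (18 ppm) channel only: at
97 ppm the spectrum is locally flat and shifts of ±0.3 ppm are
immaterial, while at 18 ppm the tissue MT background slopes steeply
through the band and an uncorrected 0.2 ppm shift visibly biases the
band asymmetry. (In pure solution spectra the correction is actually
counterproductive — the band mean is already shift-robust there and
1 ppm-sampled spline resampling adds more error than the shift — which
is consistent with applying it only where MT makes it necessary.)

## Dual-channel mapping and statistics

Channel maps normalize each voxel by its −300 ppm reference and
average asymmetry over the channel band; the whole map is invariant
under global intensity scaling. ROI comparison uses a Welch two-sample
t-test on voxel values (no test is named in the source reporting;
unequal variances between lesion and control tissue are expected),
with voxels treated as independent — spatial autocorrelation is not
modeled, a documented limitation. The two channels are two planned
comparisons and are reported raw, without multiplicity correction.
Zero-variance ROIs are handled explicitly (equal constants give p = 1,
different constants p = 0). Lesion masks can be derived from
T2-weighted images by thresholding 1 SD above the contralateral mean.
The supra-threshold level for overlays is a configuration parameter
with no protocol-fixed value.

## The synthetic phantoms

The generator emulates two experiment classes:

- **Tube phantoms**: circular solution compartments (Eu-only, Yb-only,
  mixed) in a 2% agar cylinder, no semisolid pool, used for
  calibration and channel-selectivity checks.
- **Lesion phantoms**: a 64×64 brain slice (matching the 64×64 CEST
  matrix) with healthy tissue (MT pool on), a fluid-filled lesion
  cavity containing unlabeled cells, and an implant region carrying
  the mixture plan's voxel concentrations. The `patched` pattern
  splits the implant into an Eu-rich and a Yb-rich blob (seeded random
  field, median split) while conserving each agent's total amount —
  emulating the regional heterogeneity seen after implantation of a
  homogeneous mixture.

The mixture plan splits 200 000 cells/µL 4:1 into 160 000 NSCs and
40 000 ECs and converts intracellular loads (6.8 mM Eu, 9.5 mM Yb) to
voxel concentrations via each population's share of the cell volume
times a cell volume fraction of 0.83. That fraction was chosen once so
that the 4:1 plan reproduces the reported voxel concentrations
(≈4.5 / 1.6 mM) under equal per-cell volume — the source does not
state its derivation, and this is one consistent reading.

`simulate_study()` quantizes the smooth polynomial B0 field to
0.01 ppm, simulates each (compartment × field level) z-spectrum at the
protocol offsets shifted by the local offset, assigns spectra to
voxels, and adds seeded Gaussian noise of SD `noise_sigma`·S0 per
acquisition average before merging (`noise_sigma` 0.02 = SNR 50, the
high-SNR magnitude regime; Rician noise is out of scope). Everything
is bit-reproducible from (spec, protocols, seed). The default
end-to-end study conditions — 4.5/1.6 mM implant voxels, SNR 50,
10 averages — mirror the in vivo protocol.

What the phantoms deliberately do **not** model: anatomically
realistic geometry, partial-volume mixing at compartment borders, B1
inhomogeneity, relaxation during readout, diffusion/perfusion, and
motion. Passing the end-to-end tests therefore demonstrates that the
*analysis chain* is correct and sensitive at realistic contrast and
noise levels, not that real-animal variability is captured.

## Known limitations

- Absolute tissue contrast depends on semisolid parameters that are
  field-typical defaults, not measured values; only MT ordering and
  direction are asserted.
- On-resonance values of long-T2 solution systems retain coherent
  nutation (a rectangular CW pulse leaves an oscillatory Mz), so
  simulated S/S0 can transiently undershoot zero at 0 ppm by ~1e-4;
  off-resonance values are bounded in [0, 1] to solver tolerance. The
  0 ppm acquisition is never used quantitatively.
- The Hanes-Woolf fit inherits the closed-form model's neglect of
  direct saturation; at high B1 the recovered rate is biased (kept
  within the documented 15% at the Eu operating point).
- ROI inference treats voxels as independent samples.
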