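---
title: "Quantifying Cas9 RNP delivery: FCS, axial offsets and dosimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Cas9 RNP delivery: FCS, axial offsets and dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnpquant)
```

This vignette documents the models behind `rnpquant`, the assumptions they
make, the tunable parameters and their defaults, what the synthetic-data
generators do and do not emulate, and the numerical choices made where the
design was open.

## The correlation model

FCS extracts diffusion properties from the fluctuations of the fluorescence
collected from a femtoliter-scale confocal volume. For a 3D Gaussian
detection profile and free diffusion, the normalized fluctuation
autocorrelation of a species with diffusion correlation time $t_D$ is
$(1+t/t_D)^{-1}(1+t/(\omega^2 t_D))^{-1/2}$, with $\omega$ the axial/radial
aspect ratio of the detection volume. `model_correlation()` evaluates the
two-component version with a triplet factor and baseline:

$$G(t) = \frac{1}{N}\left[R\,g_1(t) + (1-R)\,g_2(t)\right]
\left(1 + A_T e^{-t/t_T}\right) + b_0 .$$

Two diffusion components are the physically motivated minimum whenever a
labeled protein is measured in the presence of residual free dye: component
1 is conventionally the fast species (free dye), component 2 the slow one
(the protein or its complexes). Assumptions: free 3D diffusion (no
anomalous exponents), a Gaussian detection profile, and triplet blinking
much faster than diffusion. The triplet factor multiplies the whole
two-component sum as $(1+A_T e^{-t/t_T})$; the $(1-A_T)$-normalized variant
seen elsewhere in the FCS literature is *not* used, so fitted $A_T$ values
are comparable only within this convention.

All internal units are SI (seconds, meters, kelvin, pascal-seconds);
µs/µm/nm/cP appear only at I/O boundaries and in printed summaries. This
removes an entire class of unit bugs and makes the printed-value
comparisons a pure formatting step.

### Parameters

| symbol | field | meaning | default |
|---|---|---|---|
| $N$ | `n_molecules` | mean focal-volume occupancy | free |
| $t_{D,1}, t_{D,2}$ | `t_d1`, `t_d2` | diffusion correlation times (s) | component 1 often fixed to the dye |
| $R$ | `fraction_1` | weight of component 1 | free or fixed |
| $\omega$ | `aspect_ratio` | axial/radial extent | fixed at 5 |
| $A_T, t_T$ | `triplet_amplitude`, `triplet_lifetime` | triplet term | 0 / 5 µs |
| $b_0$ | `baseline` | long-lag offset | free, near 0 |

$\omega$ is fixed during fitting because $\omega$ and $t_D$ are strongly
covariant on single curves; 5 is a typical value for a confocal FCS setup
and can be replaced by a calibrated value when one exists. Because the
effective focal volume $V = \pi^{3/2} W_{xy}^2(\omega W_{xy})$ depends on
$\omega$, `focal_volume()` always reports the aspect ratio it used — the
volume is meaningful only conditional on it.

## Calibration and physical conversions

The beam waist is not measured directly; it is calibrated from a reference
dye of known diffusion coefficient via $D = W_{xy}^2/(4 t_D)$
(`beam_waist_from_reference()`, `focal_volume_calibration()`). Sample
diffusion times then convert through the same relation
(`diffusion_from_time()`), and `hydrodynamic_radius()` applies
Stokes–Einstein, $R_H = k_B T/(6\pi\eta D)$, with the CODATA $k_B$ and
defaults of 298.15 K and 0.89 cP (water at 25 °C). The calibration
roundtrip (dye analyzed against its own calibration) is an exact identity
and is tested as such.

## The correlator

`autocorrelate()` computes the fluctuation estimator
$G(\tau) = \langle\delta I(t)\,\delta I(t+\tau)\rangle/\langle I\rangle^2$
with **symmetric normalization**: at each lag the means are taken over the
two overlapping segments of the trace. This removes the long-lag bias of
the plain estimator, so curves decay to 0 for uncorrelated data and the
fitted $b_0$ stays near zero, matching the model's separate baseline term.
Lag 0 is excluded: it is dominated by shot noise and the model is fit on
$\tau > 0$.

The default scheme is the standard multi-tau layout with 16 lags per
octave: the first 16 lags at the native bin width, then the trace is
coarsened by summing adjacent bin pairs and the next 8 lags are evaluated
at the doubled width, repeating while the coarsened trace remains long
enough. This covers µs-to-s lags at near-linear cost. The direct
$O(n\,\tau_{max})$ estimator is kept as the reference implementation; on
uncorrelated seeded traces the two agree to within $10^{-3}$ absolute on
shared lags (the residual difference is purely statistical and shrinks
with the trace mean). The default initial bin width of 1 µs resolves
triplet dynamics while keeping traces desk-scale.

## Fitting

`fit_curve()` minimizes the residual between the measured curve and the
model by Levenberg–Marquardt (`minpack.lm::nls.lm`) under box bounds, with
optional $1/\sigma$ weighting when the curve carries per-lag standard
errors. Starting values come from the data: $N$ from $1/G$ at the first
lag, the slow diffusion time from the half-decay lag; if the first attempt
does not converge, three seeded multiplicative jitters of the start are
tried and the best deviance kept, so fits are deterministic given the
config and seed. Non-convergence is reported as a flag, not an exception.

Two conventions remove ambiguity:

* **Component ordering** — when both diffusion times are free, the result
  is relabeled so $t_{D,1} \le t_{D,2}$ (swapping $R \leftrightarrow 1-R$).
* **Free-dye workflow** — the recommended configuration for labeled-protein
  samples fixes $t_{D,1}$ to the calibration dye's diffusion time and
  reports the slow component as the protein, mirroring the physical reason
  a second component is needed at all.

Parameter uncertainties are taken from the covariance of the linearized
problem at the optimum (inverse approximate Hessian scaled by the reduced
chi-square) — standard, cheap, and adequate at this scale; they are not
profile or bootstrap intervals. On noiseless self-generated curves the fit
reproduces the generating parameters to $10^{-4}$ relative with reduced
chi-square below $10^{-8}$; at 0.5 % noise the median relative error of
each free parameter stays below 10 % over 20 seeded replicates (both are
part of the test suite).

## The Brownian-dynamics simulator

`simulate_fcs_stream()` provides ground-truth photon streams: particles
take independent Gaussian steps ($\sigma = \sqrt{2D\,\Delta t}$ per
coordinate) in a periodic box, the detection profile is
$\exp(-2(x^2+y^2)/W_{xy}^2 - 2z^2/(\omega W_{xy})^2)$, per-step photon
counts are Poisson with mean $\Delta t\,(\text{background} + \sum_i B_i
W(\mathbf{r}_i))$, and timestamps are uniform within the step. Periodic
boundaries keep the mean occupancy constant without particle injection
bookkeeping. Triplet blinking is a per-particle two-state telegraph
process (bright→dark at `on_rate`, dark→bright at `off_rate`), the minimal
mechanism that produces the $(1+A_T e^{-t/t_T})$ signature with
$A_T = F/(1-F)$, $t_T = 1/(on+off)$, $F$ the stationary dark fraction.

Default box: half-widths of five focal radii **per axis**,
$5\,(W_{xy}, W_{xy}, \omega W_{xy})$. An isotropic box of half-width
$5\,\omega W_{xy}$ would be ~125× larger in volume at $\omega = 5$ and
would require thousands of particles for a usable occupancy; the per-axis
choice is the smallest box at which wrap-around artifacts are negligible,
and the analytic expectations in `fcs_sim_truth()` (count rate, occupancy
$N_\mathrm{eff} = M\,V_\mathrm{eff}/V_\mathrm{box}$, amplitude
$1/N_\mathrm{eff}$) ignore only the $<10^{-5}$ Gaussian tail truncation.
The constructor enforces a time step well below the focal transit time
$W_{xy}^2/(4D)$.

What the simulator does **not** emulate: a real (non-Gaussian, aberrated)
PSF, detector dead time and afterpulsing, photobleaching, refractive-index
mismatch, and optical saturation. Passing the end-to-end tests therefore
shows the *analysis chain* is correct and self-consistent — it does not
certify accuracy on data whose detection profile departs from Gaussian.

Problem sizes: the validation runs use a single species with
$D = 3.6\times10^{-10}\,\mathrm{m^2\,s^{-1}}$, $W_{xy} = 0.3$ µm,
$\omega = 5$ (transit time 62.5 µs), 40 particles, 3 s of stream at a 2 µs
step and ~16 kHz count rate — about 48,000 focal transits, which
comfortably supports the 20 % recovery checks on the transit time and the
$1/N_\mathrm{eff}$ amplitude while running in well under a minute.

## Axial-offset quantification

For two-channel z-stacks split into single-channel stacks, `z_profile()`
computes the per-slice ROI mean (the same quantity Fiji's *Plot Z-axis
Profile* reports), `peak_slice()` takes the argmax (ties broken toward the
smaller index; a flat profile returns 0 with a flatness flag), and
`axial_offsets()` reports the per-ROI signed offset
$\Delta z = \mathrm{peak}(ch_2) - \mathrm{peak}(ch_1)$ with channel 2
conventionally the deeper (protein) channel. Because the sign convention
is not always recoverable from published summaries, the absolute-value
summary is always emitted alongside the signed one. Slice indices are
0-based internally; reports also carry 1-based indices matching Fiji.

Pixel values are treated as intensities regardless of bit depth, and no
background subtraction or chromatic-aberration correction is applied —
the procedure quantifies the apparent offset of the recorded stacks.
Peak detection is integer-valued: on generator output the recovery test
demands *exact* per-ROI offsets at up to 5 % noise, which holds provided
blobs are separated by a few lateral widths (overlapping structures
contaminate each other's ROI profiles — a property of the scene, not of
the estimator; the bundled layouts use a 4×3 grid with ≥16 px spacing and
11×11 ROIs).

## Dosimetry

All dose computations are full precision; rounding to the printed style (2
significant figures for per-cell doses) lives only in `format_dose()`,
which rounds halves away from zero — the convention that matches reported
figures such as 0.013 ng/cell from 50 µL × 25 ng/µL over 100,000 cells.
Molecular-weight defaults (`MW_CAS9` 160 kDa, `MW_SGRNA_100NT` 32 kDa,
`MW_RNP` their sum) are conventional round values and always overridable.
BCA calibration is ordinary least squares of absorbance on concentration;
inversion flags below-blank readings instead of clamping them. The
immobilization balance is exact by construction
(`bound + unbound = loaded`).

## Numerical choices and degenerate inputs

* Validation errors name the offending field; readers report the offending
  line or byte range.
* An all-zero intensity trace is rejected (undefined normalization); a
  constant nonzero trace returns an all-zero curve.
* A constant correlation curve is rejected by the fitter; a curve with
  fewer points than free parameters likewise.
* Default fit bounds are broad physical boxes (e.g. diffusion times in
  $[10^{-9}, 10]$ s, $R \in [0,1]$); tighten them per experiment when prior
  knowledge exists.
* The binary photon format stores nanosecond-integer timestamps (exact
  below $2^{53}$ ns ≈ 104 days); curve CSVs store 15 significant digits so
  fits are reproducible from files.
* 16-bit TIFF round-trips are bit exact for integer stacks in
  $[0, 65535]$.

## Known limitations

Single-curve fitting only (no global multi-curve analysis, maximum-entropy
$t_D$ distributions or Bayesian posteriors); no anomalous-diffusion, 2D
membrane or cross-correlation models; no sub-slice (interpolated) peak
localization or chromatic registration; no vendor TCSPC or AVI readers —
convert to the documented CSV/binary/TIFF formats first.
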