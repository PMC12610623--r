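# rnpquant

Quantitative analysis for CRISPR ribonucleoprotein (RNP) delivery
experiments in cultured cells. When Cas9–sgRNA complexes are delivered by
electroporation, lipid nanoparticles (LNPs) or magnetofection, three
quantitative readouts decide how the methods compare, and this package
implements all three:

1. **Fluorescence correlation spectroscopy (FCS)** of the labeled Cas9 —
   from raw photon-arrival streams to hydrodynamic radii. Intensity
   fluctuations of fluorophores transiting a confocal detection volume are
   autocorrelated and fitted with a two-component diffusion model with a
   triplet term,

   G(t) = (1/N) · [ R (1 + t/t_D1)⁻¹ (1 + t/(ω² t_D1))^(−1/2)
                  + (1−R)(1 + t/t_D2)⁻¹ (1 + t/(ω² t_D2))^(−1/2) ]
          · (1 + A_T e^(−t/t_T)) + b₀,

   where N is the mean occupancy of the focal volume, t_D1 and t_D2 the
   diffusion correlation times of the two species (free dye and labeled
   protein) weighted by R, ω the axial/radial aspect ratio, A_T and t_T
   the triplet amplitude and lifetime, and b₀ the baseline. The focal
   volume is calibrated against reference dyes via D = W²ₓᵧ/(4 t_D), and
   diffusion coefficients convert to hydrodynamic radii through
   Stokes–Einstein, R_H = k_B T / (6π η D). An enlarged R_H relative to
   free Cas9 (~6 nm) flags aggregation of the delivered protein.

2. **Confocal two-channel axial-offset quantification** — for z-stacks in
   which carrier (e.g. LNP) and cargo (Cas9) are labeled separately, the
   per-ROI z-profile (mean intensity per slice) is computed for each
   channel, the peak slice located, and the per-ROI axial offset
   Δz = peak(ch2) − peak(ch1) summarized (mean, sd, median, range). A
   nonzero Δz indicates axial separation of carrier and cargo.

3. **Reagent dosimetry** — per-cell dose arithmetic
   (volume × concentration / cells), molar→mass conversion for RNPs, BCA
   linear calibration (absorbance at 562 nm vs µg/mL, ordinary least
   squares, with inversion), and the immobilization mass balance of
   nanoparticle bioconjugation (bound + unbound = loaded, efficiency =
   100·bound/loaded).

Because raw instrument acquisitions are rarely shareable, the package also
ships first-class synthetic-data generators with known ground truth: a
Brownian-dynamics simulator that emits photon streams from particles
diffusing through a 3D Gaussian focal volume (optional triplet blinking and
background), and a two-channel Gaussian-blob z-stack generator with
prescribed peak slices. Every stochastic stage of the pipeline is validated
against these generators.

## Worked example

Calibrate the focal volume from the Cy5 reference dye, simulate a dye-like
species diffusing through it, and run the full chain (bin → autocorrelate →
fit → diffusion properties):

```r
library(rnpquant)

# focal-volume calibration: Cy5, literature D = 3.6e-10 m^2/s, fitted
# diffusion time 271 us
cal <- focal_volume_calibration(3.6e-10, 271e-6)
cal
#> Focal-volume calibration
#>   reference D  = 3.6e-10 m^2/s, t_D = 0.000271 s
#>   beam waist   = 6.25e-07 m (0.62 um), omega = 5

# simulate 3 s of photon arrivals: 40 particles, D = 3.6e-10 m^2/s,
# Wxy = 0.3 um, omega = 5 (expected transit time Wxy^2/(4D) = 62.5 us)
cfg <- fcs_sim_config(3.6e-10, 40, 2e5, 0.3e-6, aspect_ratio = 5,
                      duration = 3, time_step = 2e-6, seed = 7)
res <- run_fcs_pipeline(cfg, seed = 7)
res$properties
#> Diffusion properties
#>   t_D (component 2) = 5.989e-05 s
#>   D  = 3.757e-10 m^2/s (3.76 x 10^-10 m^2/s)
#>   RH = 6.531e-10 m (0.653 nm) at T = 298.15 K, eta = 0.00089 Pa s
```

The fitted transit time (59.9 µs) recovers the configured 62.5 µs within
4%, and the derived R_H of 0.65 nm is what a free small dye should give —
delivered Cas9 under real conditions shows 11.9 nm (electroporation
medium) to 22 nm (LNP buffer), the enlargement indicating
aggregation/complexation.

Dosimetry is plain arithmetic with validation and printed-style rounding:

```r
format_dose(dose_per_cell(75, 25, 20000))   # 75 uL x 25 ng/uL, 20k cells
#> [1] 0.094
immobilization_balance(100, 42.90)
#> Mass balance: 100.00 ug loaded, 42.90 ug bound (42.90%), 57.10 ug unbound
```

See `vignettes/rnp-delivery-quantification.Rmd` for the model details,
simulator assumptions and numerical choices.

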