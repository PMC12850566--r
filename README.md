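# metalsim

Simulation of MRI near metallic implants at arbitrary field strength.

Orthopedic implants (hip/knee replacements, spinal hardware) have magnetic
susceptibilities far from tissue — titanium ≈ 182 ppm, cobalt-chromium ≈
900 ppm versus ≈ −9 ppm for water — and induce strong off-resonance fields
Δf around them. In Cartesian spin-echo imaging this displaces signal by
Δf/BW pixels along the frequency-encode axis and by Δf·THK/rf_bw through the
slice, producing the familiar signal voids and pile-up artifacts.
Multi-spectral techniques (VAT, SEMAC, MAVRIC, MAVRIC-SL) recover much of
this signal. Choosing a protocol — field strength, RF and readout
bandwidths, number of spectral encodings, implant material — is exactly the
kind of question better answered in simulation than by scanning volunteers
with implants.

`metalsim` implements the full chain:

1. **Phantoms** — voxelized label volumes from geometric primitives (sphere
   head, cylinder stem, spherical-cap acetabular cups), watertight triangle
   meshes (ray-parity voxelization), or NIfTI body models; per-voxel maps of
   ρ, T1, T2, χ from a material table (field-dependent T1 via a power law
   T1 = A·B0^B fitted in log–log space).
2. **Field map** — Fourier-domain dipole convolution
   Δf = γ̄·B0·IFT{D(k)·FT(χ)} with D(k) = 1/3 − k_b²/|k|², D(0) = 0,
   zero-padded to suppress wrap-around; validated against the closed-form
   field of a susceptibility sphere.
3. **Acquisition** — displacement-based multi-spectral spin-echo simulation
   (TSE, VAT, SEMAC, MAVRIC, MAVRIC-SL) with
   S = ρ(1 − e^(−TR/T1))e^(−TE/T2), configurable RF spectral profiles,
   VAT shear compensation, SEMAC z-encodes with spectral aliasing, unitary
   FFT to k-space.
4. **Noise** — complex Gaussian with σ ∝ B0·(1/V)·√BW·√(1/NEX) and signal
   ∝ B0² (body-noise dominance), seed-reproducible.
5. **Reconstruction** — per-bin unitary inverse FFT and root-sum-of-squares
   combination.
6. **Metrics** — signal-void area and RL/SI extents from tissue-matched
   difference images, Rayleigh-corrected SNR, per-bin signal fractions near
   the implant.

MAVRIC and MAVRIC-SL are implemented but unvalidated; no quantitative
claims are attached to them.

## Worked example

Simulate the bundled hip-implant-in-water-bath phantom with SEMAC-12 at
0.55 T and 3 T, and quantify the susceptibility artifact by the
tissue-matched difference method:

```r
library(metalsim)

cfg <- list(
  phantom  = list(type = "water_bath", args = list(grid_spacing_mm = 1)),
  b0       = 0.55,
  fieldmap = list(pad_factor = 2),
  sequence = list(seq_type = "SEMAC", tr_ms = 2000, te_ms = 34,
                  fov_mm = c(96, 96), matrix = c(96, 96),
                  slice_thickness_mm = 3, n_slices = 12,
                  readout_bw_hz_per_px = 400, rf_bw_hz = 1000,
                  vat_fraction = 1, n_bins = 12, rf_profile = "rect",
                  slice_center_offset_mm = 16),
  noise    = NULL,
  metrics  = list(threshold_fraction = 0.5))

tab <- sweep_configs(lapply(c(0.55, 3), function(b) {
  cfg$b0 <- b; cfg
}), axis = "b0")
print(tab[, 1:4])
```

```
  axis_value area_mm2 extent_rl_mm extent_si_mm
1       0.55        8            1            8
2       3.00     2156           54           54
```

At 0.55 T, SEMAC with 12 spectral encodings recovers signal essentially up
to the implant surface — the residual void beyond the implant is a few mm².
At 3 T the same protocol leaves a void of ≈ 2200 mm² extending ≈ 54 mm in
both in-plane directions: the artifact grows strongly with field strength,
which is the central argument for imaging near metal at low field. With
noise enabled (`noise = list(sigma_ref = 0.024)`), the same pipeline
reports Rayleigh-corrected SNR, which scales as B0·V·√(NEX/BW) (ratio
≈ 5.45 between 3 T and 0.55 T at fixed protocol).

A thin command-line interface over the same functions is installed at
`inst/cli/metalsim.R` (subcommands `phantom-make-demo`, `fieldmap`,
`simulate`, `metrics`, `sweep`).

## Package layout

- `R/` — grid/materials, phantom primitives and meshes, relaxometry,
  dipole field map, sequence simulation, noise, reconstruction, metrics,
  fixtures, pipeline/config, NIfTI/YAML I/O.
- `vignettes/metalsim-methods.Rmd` — the models, their assumptions,
  numerical conventions and limitations.
- `tests/testthat/` — unit and property tests per module plus end-to-end
  acceptance properties.
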