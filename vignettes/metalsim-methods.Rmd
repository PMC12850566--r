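---
title: "Simulating MRI near metallic implants: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating MRI near metallic implants: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalsim)
```

# The problem

Orthopedic implants (hip and knee replacements, spinal hardware) are made of
materials whose magnetic susceptibility differs from tissue by two to five
orders of magnitude: titanium alloys around 182 ppm, cobalt-chromium around
900 ppm, against roughly −9 ppm for water and soft tissue. Placed in the
scanner's static field B0, this contrast induces a strong, rapidly varying
off-resonance field around the implant. In spin-echo imaging the off-resonance
displaces signal along the frequency-encode direction (by Δf / BW pixels) and
through the slice (by Δf · THK / rf_bw), producing signal voids, ripples and
pile-up artifacts. Multi-spectral techniques — view-angle tilting (VAT), slice
encoding for metal artifact correction (SEMAC), and the MAVRIC family —
recover much of this signal at the cost of scan time.

`metalsim` simulates this whole chain at arbitrary field strength so that
protocols (field, RF and readout bandwidths, number of spectral encodings,
implant material) can be compared computationally before committing scanner
time. The pipeline is: digital phantom → per-voxel parameter maps → dipole
field map → multi-spectral spin-echo k-space → noise → per-bin reconstruction
→ root-sum-of-squares combination → artifact/SNR metrics.

# Phantoms and parameter maps

Phantoms are integer label volumes on a regular fine grid (`voxel_grid`),
built from geometric primitives (`make_sphere_mask`, `make_cylinder_mask`,
`make_cap_shell_mask` for acetabular cups), from watertight triangle meshes
(`voxelize_mesh`, a deterministic ray-parity inside test with a fixed
sub-voxel ray perturbation to avoid grazing hits), or loaded from NIfTI.
Voxel membership is decided by the voxel center alone; sub-voxel accuracy
comes from simulating on a grid finer than the imaging resolution, not from
partial-volume fractions. The bundled anatomy is deliberately synthetic
(layered fat/muscle/bone boxes and a water bath): it exercises every
mechanism of the simulator — dipole patterns, through-plane displacement,
spectral aliasing — but does not represent human anatomy, organ
heterogeneity, or any scanned implant geometry.

Material properties live in a `material_table`: susceptibility χ (ppm),
relative proton density, T2 (ms, treated as field-constant), a T1 model, and
a no-signal flag for metals and signal-free solids (ceramic, polyethylene at
the echo times of interest). The shipped χ values are the standard ones
(Ti 182, CoCr 900, ceramic 2, PE 9, tissue/water −9.05, cortical bone −8.86,
fat −5.55, air 0.36 ppm). Proton density, T1 and T2 defaults are
representative values chosen once from literature ranges and are explicitly
user-overridable; no claim is made that they match any specific published
fit.

T1 lengthens with field strength. We model this as a power law
T1(B0) = A · B0^B and fit A, B by ordinary least squares in log–log space
(`fit_t1_dispersion`): a multiplicative error model matches the
heterogeneity of literature values and makes noiseless recovery exact, which
the tests exploit.

# The dipole field map

For a susceptibility distribution χ(r) the induced fractional field shift is
the convolution of χ with the unit dipole response, computed in k-space:

  Δf = γ̄ · B0 · IFT{ D(k) · FT(χ) },  D(k) = 1/3 − k_b² / |k|²,

with k_b the component along B0 and γ̄ = 42.5775 MHz/T. Numerical choices,
each testable:

* **D(0) := 0.** Demodulation at the bulk frequency; bin frequencies are
  reported relative to scanner center. A spatially uniform χ therefore maps
  to Δf ≡ 0 exactly.
* **Analytic kernel at the discrete frequencies** rather than the FFT of a
  discretized dipole — this is what makes the Lorentz-sphere oracle agree to
  a few percent.
* **Zero-padding factor 2 per axis** (configurable), padding filled with the
  dominant boundary susceptibility, to suppress circular-convolution
  wrap-around. The closed-form external field of a sphere,
  Δf = γ̄B0(Δχ/3)(a/r)³(3cos²θ − 1), is the arbiter: at 128³ with pad 2 the
  external RMS relative error is ≈ 2.3% and the interior field is ≈ 0.5% of
  the surface maximum, and the error falls monotonically as the pad factor
  grows.

Susceptibility is assumed linear in B0 for all materials; saturating
materials such as stainless steel are out of scope.

# The acquisition model

The simulator uses a displacement-based encoding model rather than a full
Bloch simulation: eddy currents, concomitant fields, gradient nonlinearity
and non-Cartesian readouts are excluded, which matches the regime where
susceptibility displacement dominates and keeps every step verifiable
against a brute-force discrete-Fourier oracle.

Each fine-grid spin carries the spin-echo signal
S = ρ(1 − e^(−TR/T1))e^(−TE/T2). For each excitation — slice s for 2D
multislice (TSE, VAT, SEMAC), spectral bin b for the MAVRIC family,
slice-and-bin for MAVRIC-SL — the excitation weight is the RF spectral
profile (ideal rect, Hann-windowed sinc computed numerically with
time-bandwidth product 4, or Gaussian with FWHM = rf_bw) evaluated at the
spin's effective offset Δf − f_b + (z − z_s)·rf_bw/THK. The slice-select
term is the standard displaced-excitation model: the gradient strength
implied by bandwidth over thickness.

Excited spins are then displaced and gridded:

* **Frequency encode:** x_app = x + (1 − v)·Δf/BW_px pixels, where v is the
  VAT fraction. VAT (v = 1) exactly cancels the in-plane shift; an optional
  boxcar of width v·rf_bw/BW_px pixels models the associated readout blur
  (off by default, so the core displacement law stays exactly testable).
* **Phase encode:** never displaced (Cartesian spin echo).
* **SEMAC z-encode:** the z phase encode resolves the through-plane
  displacement Δf/rf_bw in slice units. The continuous encode index is
  split linearly between the two nearest encodes and wrapped modulo the
  z-encode field of view (n_bins slices), which reproduces spectral
  aliasing. Per-slice reassembly places encode k of excitation s into
  reconstructed slice s − k — the spin's true slab. (A literal reading of
  "encode the apparent position relative to the excited slab" would pin all
  energy to the central encode and forbid aliasing, contradicting both the
  physics and the observable artifact; the displacement-resolving rule is
  the consistent one, and with it an on-resonance object puts exactly all
  energy in the central encode while an offset of 1.5·rf_bw splits 50/50
  between adjacent encodes.)

Spins are accumulated onto the image grid by box-averaging with linear
splitting of sub-pixel positions, scaled by the fine-to-image voxel volume
ratio so that a uniform object reproduces its box-averaged signal exactly.
Each accumulated bin image is transformed to k-space by a **unitary** 2D FFT
— one normalization convention used everywhere, so Parseval holds exactly
and k-space and image-domain noise sigmas coincide. MAVRIC bins are Gaussian
profiles at uniform spacing (default = rf_bw) about center frequency;
MAVRIC-SL adds the slab-selective term. Both are provided as implemented
but unvalidated sequences: no quantitative claims are attached to them.

# Noise

Complex bivariate Gaussian noise is added independently per k-space sample
with standard deviation

  σ = σ_ref (B0/B0_ref)¹ (V_ref/V) √(BW/BW_ref) √(NEX_ref/NEX),

while signal scales as (B0/B0_ref)². This is the body-noise-dominated
scaling, giving SNR ∝ B0 · V · √(NEX/BW); both exponents are
config-overridable. The default σ_ref = 0.024 is a calibration placeholder
chosen once so that water imaged with the baseline protocol (1×1×3 mm
voxels, 400 Hz/px, NEX 1) has SNR ≈ 20 at 0.55 T; absolute SNR values
therefore track this choice, while every SNR *ratio* (across B0, bandwidth,
averaging) is independent of it.

# Metrics

Artifact quantification follows the tissue-matched difference protocol: the
pipeline is run twice with identical parameters and seed, the second time
with every metal's χ set to the tissue value (−9.05 ppm), and the artifact
is measured on the magnitude difference of the final images. Where the
original procedure traced the void outline manually, `measure_artifact`
substitutes a reproducible rule: threshold at a stated fraction (default
0.5) of the median reference signal over signal-bearing tissue, keep the
largest connected component touching the implant neighborhood, and fill
enclosed holes — the implant's own signal-free interior, where the
difference is near zero but which a manual outline would enclose. Area is
pixel count times pixel area; RL/SI extents are bounding-box extents along
the declared axes. The threshold is exposed because no automated rule can
claim to reproduce a particular manual tracing.

SNR is mean(signal ROI) divided by the background noise sigma recovered
from the Rayleigh-distributed magnitude background:
σ̂ = sd(background)/√(2 − π/2). Per-bin signal fractions within a band
(default 30 mm) of the implant boundary are computed with an FFT ball-kernel
dilation and always sum to 100%.

# Problem sizes and defaults

The bundled studies run at desk scale, chosen once: the water-bath fixture
is a 96 mm bath with a 14 mm CoCr head and tilted Ti stem on a 1 mm fine
grid (108³ voxels), imaged at 1×1 mm in-plane with 3 mm slices and the
stack centered on the head; a SEMAC study of 12 slices simulates in about a
second per factor, and a full metal-vs-reference artifact measurement in
under 20 s. The demonstration configurations mirror the standard sweep
protocol (TR 2000 ms, TE 34 ms, 400 Hz/px, 1 kHz RF bandwidth; B0 from 0.05
to 5 T; SEMAC factors 4–24; RF bandwidths 0.5–1.5 kHz; readout bandwidths
100–800 Hz/px TSE vs VAT). Fine grids at 0.5 mm or below are preferable for
production use — 1 mm under-resolves the field at implant edges — but the
qualitative behavior (artifact growth with B0, correction with SEMAC
factor, the VAT shift law) is already stable at the bundled sizes.

# What passing tests do and do not show

The test suite verifies the *mechanisms*: the dipole operator against a
closed form, the encoding against a brute-force DFT, displacement laws,
SEMAC encode algebra including aliasing, noise scaling in distribution, and
metric recovery on synthetic truths. Because the bundled phantoms are
geometric stand-ins and the relaxometry defaults are representative rather
than fitted, quantitative outputs (artifact areas in mm², absolute SNR) are
properties of those choices, not predictions for any real implant or
patient. Realistic use requires a voxelized body model, a scanned or CAD
implant mesh, measured relaxation values, and a noise calibration against
scanner data — all of which plug into the same interfaces
(`read_labels_nifti`, `voxelize_mesh`, `material_table`, `noise_model`).

# Known limitations

Single receive channel; no eddy currents, gradient nonlinearity or
concomitant fields; Cartesian sampling only; no chemical shift of fat; no
T2* mechanism beyond the intra-voxel frequency spread captured by the fine
grid; susceptibility linear in B0; MAVRIC/MAVRIC-SL unvalidated; 2D
multislice geometry without slice gaps or crosstalk; circular (wrap-around)
behavior of the band dilation near volume edges.
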