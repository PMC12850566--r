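Package: metalsim
Title: Simulation of MRI Near Metallic Implants at Arbitrary Field Strength
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Simulates magnetic resonance imaging near metallic implants
    across main field strengths. Builds voxelized digital phantoms from
    geometric primitives or triangle meshes, computes susceptibility-induced
    off-resonance maps by Fourier-domain dipole convolution, simulates
    multi-spectral spin-echo acquisitions (TSE, VAT, SEMAC, MAVRIC,
    MAVRIC-SL) with a displacement-based encoding model, adds field-,
    bandwidth-, voxel-volume- and averaging-scaled complex Gaussian noise,
    reconstructs and combines spectral bins by root sum-of-squares, and
    quantifies metal artifacts (signal-void area and extents) and SNR with
    Rayleigh-corrected noise statistics.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
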