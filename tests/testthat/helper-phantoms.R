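# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  got <- .fixture_cache[[key]]
  if (is.null(got)) {
    got <- build()
    .fixture_cache[[key]] <- got
  }
  got
}

# uniform water volume with parameter maps at a given field
uniform_water_maps <- function(shape = c(16, 16, 24), spacing = 1,
                               b0 = 0.55) {
  g <- voxel_grid(shape, spacing)
  lv <- label_volume(g, array(1L, dim = shape))
  assign_parameters(lv, default_materials(), b0)
}

# a field-shift map holding a constant value (or any array)
const_dfmap <- function(maps, value) {
  structure(list(grid = maps$grid,
                 delta_f_hz = array(value, dim = maps$grid$shape),
                 b0 = maps$b0),
            class = "field_shift_map")
}

# water-bath fixture with maps + dipole field map at a field strength
bath_study <- function(b0) {
  cached(sprintf("bath_%g", b0), function() {
    fx <- make_water_bath_phantom(grid_spacing_mm = 1)
    maps <- assign_parameters(fx$labels, fx$materials, b0)
    dfmap <- susceptibility_to_fieldshift(maps, b0 = b0)
    list(fx = fx, maps = maps, dfmap = dfmap)
  })
}

# standard SEMAC protocol on the bath fixture (stack centered on the head)
bath_semac_params <- function(n_bins, rf_bw_hz = 1000) {
  sequence_params("SEMAC", tr_ms = 2000, te_ms = 34, fov_mm = c(96, 96),
                  matrix = c(96, 96), slice_thickness_mm = 3, n_slices = 12,
                  readout_bw_hz_per_px = 400, rf_bw_hz = rf_bw_hz,
                  vat_fraction = 1, n_bins = n_bins, rf_profile = "rect",
                  slice_center_offset_mm = 16)
}

# pipeline configuration for the bath fixture
bath_config <- function(b0, n_bins = 12, seq_type = "SEMAC",
                        readout_bw = 400, vat_fraction = 1,
                        noise = NULL) {
  list(
    phantom = list(type = "water_bath", args = list(grid_spacing_mm = 1)),
    b0 = b0,
    fieldmap = list(pad_factor = 2),
    sequence = list(seq_type = seq_type, tr_ms = 2000, te_ms = 34,
                    fov_mm = c(96, 96), matrix = c(96, 96),
                    slice_thickness_mm = 3, n_slices = 12,
                    readout_bw_hz_per_px = readout_bw, rf_bw_hz = 1000,
                    vat_fraction = vat_fraction,
                    n_bins = if (seq_type == "SEMAC") n_bins else 1L,
                    rf_profile = "rect", slice_center_offset_mm = 16),
    noise = noise,
    metrics = list(threshold_fraction = 0.5))
}

# small TSE protocol on a water box smaller than the FOV, so the image has a
# noise-only background; used for SNR scaling studies
snr_study_kspace <- function(b0, readout_bw = 400) {
  cached(sprintf("snr_%g_%g", b0, readout_bw), function() {
    shape <- c(32, 32, 16)
    g <- voxel_grid(shape, 2)
    cc_x <- abs(grid_axis_coords(g, 1)) <= 20
    cc_y <- abs(grid_axis_coords(g, 2)) <= 20
    lab <- array(0L, dim = shape)
    lab[cc_x, cc_y, ] <- 1L  # water box 40 mm in a 64 mm FOV
    maps <- assign_parameters(label_volume(g, lab), default_materials(), b0)
    dfmap <- const_dfmap(maps, 0)
    p <- sequence_params("TSE", tr_ms = 2000, te_ms = 34,
                         fov_mm = c(64, 64), matrix = c(32, 32),
                         slice_thickness_mm = 4, n_slices = 4,
                         readout_bw_hz_per_px = readout_bw, rf_bw_hz = 1000,
                         rf_profile = "rect")
    simulate_acquisition(maps, dfmap, p)
  })
}

snr_rois <- function() {
  sig <- array(FALSE, dim = c(32, 32)); sig[13:20, 13:20] <- TRUE
  bg <- array(FALSE, dim = c(32, 32))
  bg[c(1:3, 30:32), ] <- TRUE; bg[, c(1:3, 30:32)] <- TRUE
  list(signal = sig, background = bg)
}

snr_of_realization <- function(kstack, model, b0, seed) {
  noisy <- add_noise(kstack, model, b0, seed = seed)
  img <- combine_rsos(reconstruct_bins(noisy))[, , 2]
  r <- snr_rois()
  measure_snr(img, r$signal, r$background)
}
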