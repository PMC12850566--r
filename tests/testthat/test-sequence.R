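test_that("spin-echo signal equation evaluates its limits and values", {
  expect_equal(spin_echo_signal(0, 1000, 80, 2000, 34), 0)
  expect_equal(spin_echo_signal(1, 10, 80, 1e6, 0), 1, tolerance = 1e-12)
  expect_equal(spin_echo_signal(1, 1000, 80, 2000, 34),
               (1 - exp(-2)) * exp(-0.425), tolerance = 1e-9)
  expect_equal(spin_echo_signal(1, 1000, 80, 2000, 34), 0.56529,
               tolerance = 1e-4)
  expect_error(spin_echo_signal(1, 1000, 80, -1, 34), "non-negative")
  expect_error(spin_echo_signal(1, -5, 80, 2000, 34), "T1")
})

test_that("RF spectral weights obey their profile definitions", {
  for (prof in c("rect", "windowed_sinc", "gaussian"))
    expect_equal(rf_spectral_weight(prof, 1000, 0), 1, tolerance = 1e-9)
  expect_equal(rf_spectral_weight("rect", 1000, 750), 0)
  expect_equal(rf_spectral_weight("rect", 1000, c(-499, 499)), c(1, 1))
  expect_equal(rf_spectral_weight("gaussian", 1000, 500), 0.5,
               tolerance = 1e-9)
  expect_error(rf_spectral_weight("rect", -1, 0), "bw")
  expect_error(rf_spectral_weight("boxcar", 1000, 0), "arg")
  # windowed sinc: monotone falloff into the stopband, small far tail
  w <- rf_spectral_weight("windowed_sinc", 1000, c(0, 400, 900, 2500))
  expect_true(all(diff(w) < 0))
  expect_lt(w[4], 0.05)
})

test_that("TSE on a uniform object reproduces the box-averaged maps", {
  maps <- uniform_water_maps(shape = c(32, 32, 24), spacing = 1, b0 = 0.55)
  dfm <- const_dfmap(maps, 0)
  p <- sequence_params("TSE", tr_ms = 2000, te_ms = 34, fov_mm = c(16, 16),
                       matrix = c(16, 16), slice_thickness_mm = 4,
                       n_slices = 4, readout_bw_hz_per_px = 400,
                       rf_bw_hz = 1000, rf_profile = "rect")
  img <- combine_rsos(reconstruct_bins(simulate_acquisition(maps, dfm, p)))
  s <- spin_echo_signal(1, 3000, 2000, 2000, 34)
  expect_lt(max(abs(img - s)) / s, 1e-6)
})

test_that("constant off-resonance displaces by (1 - v) * df / BW pixels", {
  g <- voxel_grid(c(48, 24, 24), 1)
  lab <- array(0L, dim = c(48, 24, 24))
  lab[abs(grid_axis_coords(g, 1)) <= 6, , ] <- 1L
  maps <- assign_parameters(label_volume(g, lab), default_materials(), 0.55)
  centroid <- function(img) {
    pr <- rowSums(img[, , 1])
    sum(seq_along(pr) * pr) / sum(pr)
  }
  for (v in c(0, 0.5, 1)) {
    p <- sequence_params(if (v == 0) "TSE" else "VAT", tr_ms = 2000,
                         te_ms = 34, fov_mm = c(48, 24), matrix = c(48, 24),
                         slice_thickness_mm = 4, n_slices = 2,
                         readout_bw_hz_per_px = 400, rf_bw_hz = 1000,
                         vat_fraction = v, rf_profile = "rect")
    img0 <- combine_rsos(reconstruct_bins(
      simulate_acquisition(maps, const_dfmap(maps, 0), p)))
    img1 <- combine_rsos(reconstruct_bins(
      simulate_acquisition(maps, const_dfmap(maps, 3 * 400), p)))
    expect_equal(centroid(img1) - centroid(img0), (1 - v) * 3,
                 tolerance = 0.25)
  }
})

test_that("FFT-path k-space equals brute-force DFT of the gridded spins", {
  # 16 x 16 x 4 fine grid, two off-resonance regions, rect excitation
  g <- voxel_grid(c(16, 16, 4), c(1, 1, 1))
  lab <- array(1L, dim = c(16, 16, 4))
  maps <- assign_parameters(label_volume(g, lab), default_materials(), 0.55)
  df <- array(0, dim = c(16, 16, 4))
  df[5:8, , ] <- 130          # fractional-pixel displacement
  df[13:16, 9:16, ] <- -340
  dfm <- const_dfmap(maps, df)
  p <- sequence_params("TSE", tr_ms = 2000, te_ms = 34, fov_mm = c(16, 16),
                       matrix = c(16, 16), slice_thickness_mm = 4,
                       n_slices = 1, readout_bw_hz_per_px = 400,
                       rf_bw_hz = 1000, rf_profile = "rect")
  kfft <- simulate_acquisition(maps, dfm, p)$data[, , 1, 1]
  # independent path: grid the displaced, weighted spins with explicit loops,
  # then direct DFT by matrix multiplication
  s <- spin_echo_signal(1, 3000, 2000, 2000, 34)
  vol_ratio <- 1 / (1 * 1 * 4)
  img <- matrix(0, 16, 16)
  for (i in 1:16) for (j in 1:16) for (k in 1:4) {
    z <- grid_axis_coords(g, 3)[k]
    if (abs(df[i, j, k] + z * 1000 / 4) > 500) next
    gx <- i + df[i, j, k] / 400
    i0 <- floor(gx); w <- 1 - (gx - i0)
    if (i0 >= 1 && i0 <= 16) img[i0, j] <- img[i0, j] + s * vol_ratio * w
    if (i0 + 1 >= 1 && i0 + 1 <= 16)
      img[i0 + 1, j] <- img[i0 + 1, j] + s * vol_ratio * (1 - w)
  }
  W <- function(n) exp(-2i * pi * outer(0:(n - 1), 0:(n - 1)) / n)
  kdft <- (W(16) %*% img %*% W(16)) / 16
  expect_lt(max(Mod(kfft - kdft)), 1e-9 * max(Mod(kfft)))
})

test_that("SEMAC z-encodes capture displacement, splitting and aliasing", {
  maps <- uniform_water_maps(shape = c(16, 16, 24), spacing = 1, b0 = 0.55)
  p <- sequence_params("SEMAC", tr_ms = 2000, te_ms = 34, fov_mm = c(16, 16),
                       matrix = c(16, 16), slice_thickness_mm = 4,
                       n_slices = 4, readout_bw_hz_per_px = 400,
                       rf_bw_hz = 1000, n_bins = 6, rf_profile = "rect")
  energy_by_bin <- function(df_hz) {
    st <- simulate_acquisition(maps, const_dfmap(maps, df_hz), p)
    e <- apply(Mod(st$data)^2, 4, sum)
    e / sum(e)
  }
  centers <- c(-3000, -2000, -1000, 0, 1000, 2000)
  e0 <- energy_by_bin(0)
  expect_equal(unname(e0[centers == 0]), 1)
  expect_true(all(e0[centers != 0] == 0))
  # constant offset of 1.5 x rf_bw: equal split between the +1 and +2 encodes
  e15 <- energy_by_bin(1500)
  expect_equal(unname(e15[c(5, 6)]), c(0.5, 0.5), tolerance = 1e-9)
  # offset beyond n_bins/2 x rf_bw wraps to the opposite encode
  e4 <- energy_by_bin(4000)
  expect_equal(unname(e4[2]), 1, tolerance = 1e-9)  # center -2000 Hz
})

test_that("SEMAC combined image conserves energy vs TSE when on-resonance", {
  maps <- uniform_water_maps(shape = c(16, 16, 24), spacing = 1, b0 = 0.55)
  dfm <- const_dfmap(maps, 0)
  ps <- sequence_params("SEMAC", tr_ms = 2000, te_ms = 34, fov_mm = c(16, 16),
                        matrix = c(16, 16), slice_thickness_mm = 4,
                        n_slices = 4, readout_bw_hz_per_px = 400,
                        rf_bw_hz = 1000, n_bins = 6, rf_profile = "rect")
  pt <- sequence_params("TSE", tr_ms = 2000, te_ms = 34, fov_mm = c(16, 16),
                        matrix = c(16, 16), slice_thickness_mm = 4,
                        n_slices = 4, readout_bw_hz_per_px = 400,
                        rf_bw_hz = 1000, rf_profile = "rect")
  sem <- combine_rsos(reconstruct_bins(simulate_semac_study(maps, dfm, ps)))
  tse <- combine_rsos(reconstruct_bins(simulate_acquisition(maps, dfm, pt)))
  expect_lt(abs(sum(sem) - sum(tse)) / sum(tse), 1e-6)
})

test_that("no displacement ever occurs along the phase-encode axis", {
  g <- voxel_grid(c(24, 24, 16), 1)
  lab <- array(0L, dim = c(24, 24, 16))
  # block bounded along the frequency axis so the imposed shift stays in FOV
  lab[abs(grid_axis_coords(g, 1)) <= 5,
      abs(grid_axis_coords(g, 2)) <= 5, ] <- 1L
  maps <- assign_parameters(label_volume(g, lab), default_materials(), 0.55)
  p <- sequence_params("TSE", tr_ms = 2000, te_ms = 34, fov_mm = c(24, 24),
                       matrix = c(24, 24), slice_thickness_mm = 4,
                       n_slices = 2, readout_bw_hz_per_px = 400,
                       rf_bw_hz = 1e7,  # keep all spins excited at any offset
                       rf_profile = "rect")
  prof <- function(df) {
    img <- combine_rsos(reconstruct_bins(
      simulate_acquisition(maps, const_dfmap(maps, df), p)))
    colSums(img[, , 1])
  }
  expect_equal(prof(2000), prof(0), tolerance = 1e-9)
})

test_that("the noiseless simulation is deterministic", {
  maps <- uniform_water_maps(shape = c(16, 16, 16), spacing = 1, b0 = 0.55)
  dfm <- const_dfmap(maps, 123)
  p <- sequence_params("VAT", tr_ms = 2000, te_ms = 34, fov_mm = c(16, 16),
                       matrix = c(16, 16), slice_thickness_mm = 4,
                       n_slices = 2, readout_bw_hz_per_px = 400,
                       rf_bw_hz = 1000, vat_fraction = 0.5,
                       rf_profile = "windowed_sinc")
  a <- simulate_acquisition(maps, dfm, p)
  b <- simulate_acquisition(maps, dfm, p)
  expect_identical(a$data, b$data)
})

test_that("sequence parameter validation enforces the schema", {
  mk <- function(...) sequence_params(...)
  expect_error(mk("TSE", 2000, 34, c(16, 16), c(16, 16), 4, 1, 400, 1000,
                  n_bins = 6), "n_bins")
  expect_error(mk("SEMAC", 2000, 34, c(16, 16), c(16, 16), 4, 1, -400, 1000),
               "bandwidth")
  expect_error(mk("VAT", 2000, 34, c(16, 16), c(16, 16), 4, 1, 400, 1000,
                  vat_fraction = 1.5), "vat_fraction")
  expect_error(mk("TSE", 2000, 34, c(16, 16), c(16, 16), 4, 1, 400, 1000,
                  freq_axis = 2, phase_axis = 2), "permutation")
})
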