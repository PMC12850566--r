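test_that("Rayleigh correction recovers the underlying Gaussian sigma", {
  set.seed(5)
  n <- 1e5
  mag <- Mod(complex(real = rnorm(n), imaginary = rnorm(n)))
  img <- c(rep(20, 100), mag)
  sig_roi <- c(rep(TRUE, 100), rep(FALSE, n))
  bg_roi <- !sig_roi
  snr <- measure_snr(img, sig_roi, bg_roi)
  # sigma = 1, so SNR should recover the signal mean
  expect_lt(abs(snr / 20 - 1), 0.02)
  # doubling the signal intensity doubles SNR exactly
  img2 <- img; img2[sig_roi] <- 2 * img2[sig_roi]
  expect_equal(measure_snr(img2, sig_roi, bg_roi), 2 * snr,
               tolerance = 1e-12)
  expect_error(measure_snr(img, sig_roi, sig_roi), "disjoint")
  expect_error(measure_snr(img, rep(FALSE, n + 100), bg_roi), "empty")
  expect_error(measure_snr(rep(1, 10), c(TRUE, rep(FALSE, 9)),
                           c(FALSE, rep(TRUE, 9))), "variance")
})

test_that("high-SNR magnitude measurement approaches the complex SNR", {
  set.seed(6)
  n <- 4e4
  noise <- complex(real = rnorm(n), imaginary = rnorm(n))
  img <- c(Mod(20 + noise[1:(n / 2)]), Mod(noise[(n / 2 + 1):n]))
  sig_roi <- c(rep(TRUE, n / 2), rep(FALSE, n / 2))
  expect_lt(abs(measure_snr(img, sig_roi, !sig_roi) / 20 - 1), 0.05)
})

test_that("a painted disc void is measured to pixel accuracy", {
  nx <- 80
  ref <- matrix(1, nx, nx)
  xy <- expand.grid(x = 1:nx - 40.5, y = 1:nx - 40.5)
  disc <- matrix(sqrt(xy$x^2 + xy$y^2) <= 15, nx, nx)
  diffimg <- matrix(0, nx, nx); diffimg[disc] <- 1
  am <- measure_artifact(diffimg, ref, c(1, 1))
  ring <- pi * ((15 + 1)^2 - 15^2)        # one pixel-ring tolerance
  expect_lt(abs(am$area_mm2 - pi * 15^2), ring)
  expect_lt(abs(am$extent_rl_mm - 30), 1.01)
  expect_lt(abs(am$extent_si_mm - 30), 1.01)
  # zero difference: empty measure
  am0 <- measure_artifact(matrix(0, nx, nx), ref, c(1, 1))
  expect_equal(am0$area_mm2, 0)
  expect_equal(am0$extent_rl_mm, 0)
  expect_error(measure_artifact(diffimg, ref * 0, c(1, 1)), "zero")
})

test_that("only the void connected to the implant neighborhood is measured", {
  nx <- 80
  ref <- matrix(1, nx, nx)
  diffimg <- matrix(0, nx, nx)
  diffimg[30:40, 30:40] <- 1    # near the implant
  diffimg[70:78, 70:78] <- 1    # disjoint, far away
  implant <- matrix(FALSE, nx, nx); implant[33:37, 33:37] <- TRUE
  am <- measure_artifact(diffimg, ref, c(1, 1), implant_mask = implant)
  expect_equal(am$area_mm2, 11 * 11)
})

test_that("artifact area is monotone non-increasing in the threshold", {
  set.seed(7)
  nx <- 60
  ref <- matrix(1, nx, nx)
  xy <- expand.grid(x = 1:nx - 30.5, y = 1:nx - 30.5)
  # smooth blob: difference decays from the center
  diffimg <- matrix(exp(-(xy$x^2 + xy$y^2) / 200), nx, nx)
  areas <- sapply(c(0.2, 0.4, 0.6, 0.8), function(tf)
    measure_artifact(diffimg, ref, c(1, 1), threshold_fraction = tf)$area_mm2)
  expect_true(all(diff(areas) <= 0))
})

test_that("per-bin signal fractions sum to 100 and isolate single bins", {
  p <- sequence_params("SEMAC", tr_ms = 2000, te_ms = 34, fov_mm = c(32, 32),
                       matrix = c(32, 32), slice_thickness_mm = 4,
                       n_slices = 2, readout_bw_hz_per_px = 400,
                       rf_bw_hz = 1000, n_bins = 4)
  set.seed(8)
  dat <- array(complex(real = abs(rnorm(32 * 32 * 2 * 4))),
               dim = c(32, 32, 2, 4))
  st <- bin_stack(dat, bin_offsets_hz <- c(-2, -1, 0, 1) * 1000, "image", p,
                  meta = list(px_mm = c(1, 1), slice_thickness_mm = 4))
  implant <- array(FALSE, dim = c(32, 32, 2)); implant[14:18, 14:18, ] <- TRUE
  fr <- bin_signal_fraction(st, implant, band_mm = 8)
  expect_equal(sum(fr), 100, tolerance = 1e-9)
  # all signal in one bin
  one <- dat * 0; one[, , , 2] <- 1
  st1 <- bin_stack(one, c(-2, -1, 0, 1) * 1000, "image", p,
                   meta = list(px_mm = c(1, 1), slice_thickness_mm = 4))
  expect_equal(bin_signal_fraction(st1, implant, band_mm = 8),
               c(0, 100, 0, 0))
  expect_error(bin_signal_fraction(st, implant, band_mm = -1), "band_mm")
})

test_that("metric dilation respects the metric radius", {
  m <- array(FALSE, dim = c(21, 21))
  m[11, 11] <- TRUE
  d <- dilate_mask_mm(m, c(1, 1), 5)
  xy <- expand.grid(x = 1:21 - 11, y = 1:21 - 11)
  expect_equal(as.vector(d), sqrt(xy$x^2 + xy$y^2) <= 5 + 1e-9)
  # anisotropic spacing shrinks the reach in coarse directions
  d2 <- dilate_mask_mm(m, c(2, 1), 5)
  expect_false(d2[11 + 3, 11])  # 6 mm away along x
  expect_true(d2[11, 11 + 5])
})
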