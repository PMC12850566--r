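test_that("sphere mask volume matches the analytic volume", {
  g <- voxel_grid(c(64, 64, 64), 0.5)
  expect_false(any(make_sphere_mask(g, c(0, 0, 0), 0)))
  vol <- sum(make_sphere_mask(g, c(0, 0, 0), 10)) * 0.5^3
  expect_lt(abs(vol - 4188.79) / 4188.79, 0.01)
  # center far outside the grid: disjoint support
  expect_false(any(make_sphere_mask(g, c(100, 0, 0), 10)))
  expect_error(make_sphere_mask(g, c(0, 0, 0), -1), "radius")
})

test_that("cylinder mask volume matches pi r^2 L and rejects a degenerate axis", {
  g <- voxel_grid(c(40, 40, 120), 0.5)
  vol <- sum(make_cylinder_mask(g, c(0, 0, -25), c(0, 0, 25), 5)) * 0.5^3
  expect_lt(abs(vol - 3926.99) / 3926.99, 0.015)
  expect_false(any(make_cylinder_mask(g, c(0, 0, -25), c(0, 0, 25), 0)))
  expect_error(make_cylinder_mask(g, c(1, 2, 3), c(1, 2, 3), 5), "degenerate")
})

test_that("cap shell mask reproduces shell and hemisphere volumes", {
  g <- voxel_grid(c(80, 80, 80), 0.5)
  full <- make_cap_shell_mask(g, c(0, 0, 0), 15, 10, c(0, 0, 1), 180)
  vol_true <- 4 / 3 * pi * (15^3 - 10^3)
  expect_lt(abs(sum(full) * 0.125 - vol_true) / vol_true, 0.02)
  half <- make_cap_shell_mask(g, c(0, 0, 0), 15, 10, c(0, 0, 1), 90)
  expect_lt(abs(sum(half) / sum(full) - 0.5), 0.02)
  expect_error(make_cap_shell_mask(g, c(0, 0, 0), 10, 10), "r_inner")
  expect_error(make_cap_shell_mask(g, c(0, 0, 0), 15, 10, cap_angle = 0),
               "cap_angle")
})

test_that("voxelized volumes converge to the analytic volume as spacing shrinks", {
  err <- sapply(c(1, 0.5, 0.25), function(h) {
    g <- voxel_grid(round(c(30, 30, 30) / h), h)
    abs(sum(make_sphere_mask(g, c(0, 0, 0), 10)) * h^3 - 4188.79)
  })
  expect_true(all(diff(err) < 0))
})

test_that("merge_masks applies declared precedence and is idempotent", {
  g <- voxel_grid(c(20, 20, 20), 1)
  tb <- default_materials()
  anatomy <- label_volume(g, array(2L, dim = c(20, 20, 20)))  # muscle
  head <- make_sphere_mask(g, c(0, 0, 2), 5)
  stem <- make_cylinder_mask(g, c(0, 0, 2), c(0, 0, -8), 2)
  merged <- merge_masks(anatomy, list(
    list(mask = head, material = "cocr"),
    list(mask = stem, material = "titanium")), tb)
  lab_ti <- tb$label[tb$material == "titanium"]
  lab_co <- tb$label[tb$material == "cocr"]
  # overlap gets the later-listed material
  expect_true(all(merged$labels[head & stem] == lab_ti))
  expect_true(all(merged$labels[head & !stem] == lab_co))
  expect_equal(sum(merged$labels %in% c(lab_ti, lab_co)), sum(head | stem))
  # anatomy preserved outside implant support; idempotent
  expect_true(all(merged$labels[!(head | stem)] == 2L))
  merged2 <- merge_masks(merged, list(
    list(mask = head, material = "cocr"),
    list(mask = stem, material = "titanium")), tb)
  expect_identical(merged2$labels, merged$labels)
  # empty implant list is the identity
  expect_identical(merge_masks(anatomy, list(), tb)$labels, anatomy$labels)
  # grid mismatch
  g2 <- voxel_grid(c(10, 10, 10), 1)
  expect_error(merge_masks(anatomy,
                           list(list(mask = array(TRUE, dim = c(10, 10, 10)),
                                     material = "cocr")), tb), "mismatch")
})

test_that("assign_parameters is a pure per-voxel lookup with metal handling", {
  g <- voxel_grid(c(6, 6, 6), 1)
  tb <- default_materials()
  lab <- array(1L, dim = c(6, 6, 6))
  lab[1, 1, 1] <- tb$label[tb$material == "titanium"]
  maps <- assign_parameters(label_volume(g, lab), tb, 0.55)
  expect_equal(maps$chi_ppm[1, 1, 1], 182)
  expect_equal(maps$rho[1, 1, 1], 0)
  expect_true(all(maps$rho[-1] == 1))
  expect_true(all(maps$chi_ppm[-1] == -9.05))
  # single-material volume: constant maps
  m2 <- assign_parameters(label_volume(g, array(2L, dim = c(6, 6, 6))), tb, 1.5)
  expect_equal(length(unique(as.vector(m2$t1_ms))), 1L)
  # power-law field dependence of muscle T1
  m3 <- assign_parameters(label_volume(g, array(2L, dim = c(6, 6, 6))), tb, 3)
  m05 <- assign_parameters(label_volume(g, array(2L, dim = c(6, 6, 6))), tb, 0.55)
  B <- tb$t1_b[tb$material == "muscle"]
  expect_equal(m3$t1_ms[1] / m05$t1_ms[1], (3 / 0.55)^B, tolerance = 1e-12)
  # unknown label names the label
  lab_bad <- lab; lab_bad[2, 2, 2] <- 99L
  expect_error(assign_parameters(label_volume(g, lab_bad), tb, 1), "99")
  # permutation equivariance
  perm <- sample(length(lab))
  lab_p <- array(as.vector(lab)[perm], dim = dim(lab))
  maps_p <- assign_parameters(label_volume(g, lab_p), tb, 0.55)
  expect_equal(as.vector(maps_p$chi_ppm), as.vector(maps$chi_ppm)[perm])
  expect_equal(as.vector(maps_p$t1_ms), as.vector(maps$t1_ms)[perm])
})
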