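# Susceptibility chain: Laplacian unwrapping, V-SHARP background
# removal, TKD dipole inversion, multi-echo field mapping.

test_that("unwrapping returns smooth unwrapped input up to a constant", {
  d <- c(32, 32, 8)
  g <- histomri:::expand_grid_3d(d)
  phi <- 0.8 * sin(2 * pi * g$x / d[1]) * cos(2 * pi * g$y / d[2])
  psi <- laplacian_unwrap(phi)
  dev <- psi - phi
  dev <- dev - mean(dev)
  expect_lt(max(abs(dev)), 1e-3)
  expect_error(laplacian_unwrap(matrix(0, 4, 4)), "3-D")
})

test_that("unwrapping recovers a wrapped linear ramp", {
  d <- c(128, 16, 8)
  g <- histomri:::expand_grid_3d(d)
  phi <- 6 * pi * g$x / (d[1] - 1)
  psi <- laplacian_unwrap(wrap_phase(phi))
  interior <- g$x >= 4 & g$x <= d[1] - 5
  dev <- psi - phi
  dev <- dev - mean(dev[interior])
  expect_lt(max(abs(dev[interior])), 0.05)
  # harmonic consistency: wrap(psi + c) matches wrap(phi) in the interior
  delta <- wrap_phase(phi - psi)
  const <- atan2(mean(sin(delta)), mean(cos(delta)))
  expect_lt(max(abs(wrap_phase(psi + const - phi))[interior]), 1e-2)
})

test_that("V-SHARP removes purely external (harmonic) background fields", {
  d <- c(48, 48, 48)
  g <- histomri:::expand_grid_3d(d)
  r2 <- (g$x - 23.5)^2 + (g$y - 23.5)^2 + (g$z - 23.5)^2
  mask <- r2 < 19^2
  chi_ext <- array(0, d); chi_ext[4, 4, 4] <- 50; chi_ext[44, 8, 40] <- -30
  bg <- histomri:::dipole_forward_field(chi_ext)
  vs <- vsharp_filter(bg, mask, radii = 5:1)
  ratio <- sqrt(mean(vs$tissue_field[vs$mask]^2)) / sqrt(mean(bg[mask]^2))
  expect_lt(ratio, 0.01)
  # zero field -> zero output
  vs0 <- vsharp_filter(array(0, d), mask, radii = 5:1)
  expect_equal(max(abs(vs0$tissue_field)), 0)
  expect_error(vsharp_filter(bg, mask, radii = 1:5), "decreasing")
})

test_that("V-SHARP preserves the internal tissue field", {
  d <- c(48, 48, 48)
  g <- histomri:::expand_grid_3d(d)
  r2 <- (g$x - 23.5)^2 + (g$y - 23.5)^2 + (g$z - 23.5)^2
  mask <- r2 < 19^2
  set.seed(1)
  chi_t <- array(0.02 * smooth_noise_field(d, 5, 3), d)
  chi_t[!mask] <- 0
  chi_t[r2 < 6^2] <- chi_t[r2 < 6^2] + 0.1
  ft <- histomri:::dipole_forward_field(chi_t)
  chi_b <- array(0, d); chi_b[4, 4, 4] <- 50
  fb <- histomri:::dipole_forward_field(chi_b)
  vs <- vsharp_filter(ft + fb, mask, radii = 5:1)
  expect_gt(stats::cor(vs$tissue_field[vs$mask], ft[vs$mask]), 0.98)
})

test_that("dipole inversion is linear and exact for uniform fields", {
  d <- c(24, 24, 24)
  mask <- array(TRUE, d)
  chi0 <- dipole_invert(array(0, d), mask)
  expect_equal(max(abs(chi0$values)), 0)
  set.seed(2)
  f <- array(smooth_noise_field(d, 3, 4) * 0.01, d)
  c1 <- dipole_invert(f, mask)
  c2 <- dipole_invert(2 * f, mask)
  expect_equal(c2$values, 2 * c1$values, tolerance = 1e-10)
  expect_error(dipole_invert(f, mask, threshold = 0.7), "threshold")
})

test_that("forward-inverse sphere round trip recovers susceptibility", {
  d <- c(48, 48, 48)
  g <- histomri:::expand_grid_3d(d)
  r2 <- (g$x - 23.5)^2 + (g$y - 23.5)^2 + (g$z - 23.5)^2
  chi <- array(0, d); chi[r2 < 8^2] <- 0.1
  mask <- array(r2 < 20^2, d)
  f <- histomri:::dipole_forward_field(chi)
  rec <- dipole_invert(f, mask)
  med <- stats::median(rec$values[chi > 0.05 & mask])
  expect_lt(abs(med - 0.1) / 0.1, 0.15)
})

test_that("multi-echo field map fit is exact on noiseless phase", {
  d <- c(8, 8, 4)
  te <- c(2, 8.6, 15.2, 21.8, 28.4, 35)
  ph <- lapply(te, function(t) array(wrap_phase(2 * pi * 10 * t / 1000), d))
  fm <- fieldmap_from_multiecho(acq_series(ph, te, "qsm_phase"))
  expect_equal(fm$df_hz$values, array(10, d), tolerance = 1e-9)
  # adding a constant phase leaves the frequency unchanged
  ph2 <- lapply(ph, function(p) wrap_phase(p + 0.7))
  fm2 <- fieldmap_from_multiecho(acq_series(ph2, te, "qsm_phase"))
  expect_equal(fm2$df_hz$values, fm$df_hz$values, tolerance = 1e-9)
  expect_equal(fm2$phi0$values, fm$phi0$values + 0.7, tolerance = 1e-9)
  # phantom round trip
  st <- make_signal_stack(9, "me_t2star", dims = c(6, 6, 2))
  fm3 <- fieldmap_from_multiecho(st$phase_series)
  expect_lt(max(abs(fm3$df_hz$values - st$ground_truth$df_hz)), 1e-6)
  expect_error(fieldmap_from_multiecho(acq_series(ph[1:2][1],
    te[1], "qsm_phase")), "volumes|echoes")
})
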