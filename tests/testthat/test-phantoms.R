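# Generator contracts: determinism, construction round trips, and the
# forward models used as ground truth by the fitting tests.

test_that("slice-pair phantom satisfies its construction invariants", {
  sp <- make_slice_pair(1)
  expect_equal(sp$true_pose$angle, 0)
  # identity pose: block is an exact integer-offset crop of the intact photo
  off <- sp$block_to_slice$translation
  expect_equal(off, round(off))
  bh <- dim(sp$block_photo)[1]; bw <- dim(sp$block_photo)[2]
  crop <- sp$intact_photo[(1:bh) + off[1], (1:bw) + off[2], , drop = FALSE]
  expect_equal(sp$block_photo, crop)
  # hole strictly inside the foreground
  expect_true(all(sp$foreground_mask[sp$hole_mask]))

  sp2 <- make_slice_pair(1, pose = rigid2d(7, c(5, 3)))
  # resampling the intact scene on the posed block grid reproduces the
  # block exactly (noiseless construction round trip)
  bg <- pixel_grid(56, 56)
  src <- apply_transform(sp2$block_to_slice,
                         cbind(as.vector(bg$r), as.vector(bg$c)))
  for (k in 1:3)
    expect_equal(matrix(bilinear_sample(sp2$intact_photo[, , k], src), 56),
                 sp2$block_photo[, , k])
})

test_that("slice-pair generation is bit-reproducible and rejects bad poses", {
  a <- make_slice_pair(3, pose = rigid2d(5, c(2, -1)))
  b <- make_slice_pair(3, pose = rigid2d(5, c(2, -1)))
  expect_identical(a$intact_photo, b$intact_photo)
  expect_identical(a$block_photo, b$block_photo)
  expect_error(make_slice_pair(3, pose = rigid2d(0, c(500, 0))),
               "invalid-pose")
})

test_that("histology phantom obeys Beer-Lambert structure", {
  hp <- make_histology_phantom(2)
  # zero amplitude -> zero deformation field
  expect_true(all(hp$true_deformation$r == 0))
  # zero-concentration pixels equal the white reference
  bgpix <- !hp$tissue_mask
  for (k in 1:3)
    expect_equal(hp$rgb_image[, , k][bgpix],
                 rep(hp$stains$white_reference[k], sum(bgpix)))
  # single stain: every foreground OD pixel parallel to the stain vector
  sv <- stain_vector_set(list(c(0.65, 0.70, 0.29), c(0.27, 0.57, 0.78)),
                         c("a", "b"))
  conc <- list(a = matrix(0.7, 8, 8), b = matrix(0, 8, 8))
  rgb <- histomri:::render_stains(conc, sv)
  od <- rgb_to_od(rgb)
  odm <- cbind(as.vector(od[, , 1]), as.vector(od[, , 2]),
               as.vector(od[, , 3]))
  cosang <- odm %*% sv$vectors[, 1] / sqrt(rowSums(odm^2))
  expect_true(all(abs(cosang - 1) < 1e-12))
})

test_that("histology deformation keeps a positive Jacobian determinant", {
  hp <- make_histology_phantom(9, deformation_amplitude = 6)
  expect_gt(hp$min_jacobian, 0)
  expect_gt(max(sqrt(hp$true_deformation$r^2 + hp$true_deformation$c^2)), 3)
})

test_that("inversion-recovery forward model nulls near T1 log(2)", {
  ti <- seq(1, 2000, by = 1)
  s <- abs(1000 - 2000 * exp(-ti / 700))
  expect_lt(abs(ti[which.min(s)] - 700 * log(2)), 1)
})

test_that("spin-echo stack is exactly log-linear in TE", {
  st <- make_signal_stack(4, "me_t2", dims = c(6, 6, 1))
  te <- st$series$params
  v <- st$series$volumes
  i <- 17  # arbitrary voxel
  y <- log(vapply(v, function(x) x[i], numeric(1)))
  slope <- stats::coef(stats::lm(y ~ te))[2]
  expect_equal(unname(slope), -1 / st$ground_truth$T2[i], tolerance = 1e-10)
})

test_that("uniform zero susceptibility produces zero tissue phase", {
  st <- make_signal_stack(5, "qsm", dims = c(16, 16, 16))
  chi0 <- array(0, c(16, 16, 16))
  f <- histomri:::dipole_forward_field(chi0)
  expect_equal(max(abs(f)), 0)
})

test_that("signal stacks are bit-reproducible for a fixed seed", {
  a <- make_signal_stack(8, "dwi", noise_sd = 5)
  b <- make_signal_stack(8, "dwi", noise_sd = 5)
  expect_identical(a$series$volumes, b$series$volumes)
  expect_identical(a$ground_truth$FA, b$ground_truth$FA)
})

test_that("registration phantom landmarks are consistent across frames", {
  ph <- make_registration_phantom(21, dims = c(96L, 96L, 16L),
                                  block_dims = c(40L, 40L),
                                  n_landmarks = 8)
  lm <- ph$landmarks
  # photo frame -> grid frame via the true pose
  expect_equal(apply_transform(ph$photo_to_grid, lm$photo), lm$grid,
               tolerance = 1e-12)
  # grid -> 3-D via the true surface
  expect_equal(histomri:::surface_points(ph$surface, lm$grid[, 1],
                                         lm$grid[, 2]),
               lm$mr, tolerance = 1e-12)
  # hist-sub -> hist-full scaling
  expect_equal(lm$hist_sub * ph$hist_factor + (ph$hist_factor - 1) / 2,
               lm$hist_full, tolerance = 1e-12)
})
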