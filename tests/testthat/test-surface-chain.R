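# Curvilinear resampling, boundary-based registration, and transform
# chain composition.

test_that("curvilinear resampling reduces to planar extraction", {
  set.seed(3)
  vol <- array(runif(40 * 40 * 10), c(40, 40, 10))
  surf <- curvilinear_surface(c(0, 0, 4), c(1, 0, 0), c(0, 1, 0),
                              c(0, 0, 1), 40, 40)
  rs <- resample_along_surface(vol, surf)
  expect_equal(rs$raster, vol[, , 5], tolerance = 1e-12)
  expect_true(all(rs$inside))
  # constant volume -> constant raster under any offsets
  volc <- array(0.4, c(20, 20, 8))
  offs <- matrix(seq(-2, 2, length.out = 400), 20, 20)
  surf2 <- curvilinear_surface(c(0, 0, 4), c(1, 0, 0), c(0, 1, 0),
                               c(0, 0, 1), 20, 20, offs)
  expect_equal(resample_along_surface(volc, surf2)$raster,
               matrix(0.4, 20, 20))
  # linear ramp volume: raster equals the ramp at the surface heights
  g <- histomri:::expand_grid_3d(c(20, 20, 8))
  ramp <- array(2 * g$z + 1, c(20, 20, 8))
  rs3 <- resample_along_surface(ramp, surf2)
  expect_equal(rs3$raster, 2 * (4 + offs) + 1, tolerance = 1e-12)
})

test_that("surface offsets are bounded and validated", {
  expect_error(curvilinear_surface(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                   c(0, 0, 1), 4, 4,
                                   matrix(10, 4, 4), max_offset = 5),
               "max_offset")
})

test_that("BBR finds a local maximum at the true pose", {
  vp <- make_mr_volume_phantom(13, dims = c(96L, 96L, 16L))
  seg <- segment_tissue(vp$slice_raster, mask = vp$foreground)
  shift <- rigid2d(0, c(3, -2), c(47.5, 47.5))
  shifted <- warp_image(vp$slice_raster, shift, pad = 0.05)
  br <- bbr_register(seg$boundary, shifted)
  expect_lt(max(abs(br$transform$translation - c(3, -2))), 0.5)
  # init at truth: no +/-2 px grid perturbation improves the cost
  bnd <- histomri:::boundary_samples(seg$boundary)
  cost_at <- function(dr, dc) histomri:::bbr_cost(
    shifted, bnd, rigid2d(br$transform$angle,
                          br$transform$translation + c(dr, dc),
                          br$transform$centre))
  c0 <- cost_at(0, 0)
  for (dr in c(-2, 0, 2)) for (dc in c(-2, 0, 2))
    expect_lte(cost_at(dr, dc), c0 + 1e-9)
  # reversed boundary orientation with flipped polarity: same optimum
  rev_bnd <- lapply(seg$boundary, function(p) p[rev(seq_len(nrow(p))), ])
  br2 <- bbr_register(rev_bnd, shifted, polarity = -1)
  expect_lt(max(abs(br2$transform$translation -
                      br$transform$translation)), 0.5)
  expect_error(bbr_register(seg$boundary, matrix(1, 96, 96)), "flat")
})

test_that("planar-limit surface fit keeps offsets near zero", {
  vp <- make_mr_volume_phantom(17, dims = c(96L, 96L, 16L),
                               surface_amplitude = 0)
  seg <- segment_tissue(vp$slice_raster, mask = vp$foreground)
  d <- dim(vp$volume)
  init <- curvilinear_surface(c(0, 0, floor(d[3] / 2)), c(1, 0, 0),
                              c(0, 1, 0), c(0, 0, 1), d[1], d[2],
                              max_offset = 5)
  sf <- fit_curvilinear_surface(vp$volume, seg$boundary, init,
                                nodes = c(4, 4), outer_iterations = 1)
  expect_lt(max(abs(sf$surface$offsets[vp$foreground])), 0.5)
})

test_that("chain steps compose, invert, and report landmark errors", {
  s1 <- chain_step_subsample("sub", 4)
  s2 <- chain_step_linear("rigid", rigid2d(10, c(3, -2), c(10, 10)))
  u <- helper_smooth_disp(c(60, 60), 2, 9)
  s3 <- chain_step_displacement("warp", u)
  chain <- compose_chain(list(s1, s2, s3))
  set.seed(4)
  pts <- cbind(runif(20, 60, 120), runif(20, 60, 120))
  fwd <- chain_map(chain, pts, to_3d = FALSE)
  back <- chain_map(chain, fwd, direction = "inverse")
  expect_lt(max(sqrt(rowSums((back - pts)^2))), 0.1)
  # stepwise equals composite
  p1 <- s3$forward(s2$forward(s1$forward(pts)))
  expect_lt(max(abs(p1 - fwd)), 0.05)
  # TRE utilities
  tre0 <- target_registration_error(chain, pts, fwd)
  expect_equal(tre0$mean, 0)
  off <- fwd + 2
  tre2 <- target_registration_error(chain, pts, off)
  expect_equal(tre2$mean, sqrt(8), tolerance = 1e-9)
  expect_error(compose_chain(list("x")), "chain_step")
})

test_that("identity chains return the subsampled histology unchanged", {
  img <- helper_texture(5)
  chain <- compose_chain(list(chain_step_linear("id", rigid2d())))
  out <- map_histology_to_mr(chain, img, dims = dim(img))
  expect_equal(out$raster, img, tolerance = 1e-12)
})
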