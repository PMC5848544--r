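# Quantitative map fitting: RMS combination, T2/T2* log-linear fits,
# inversion-recovery T1, diffusion tensor.

test_that("RMS combination is exact on analytic cases", {
  v <- array(runif(32), c(4, 4, 2))
  s <- acq_series(list(v, v), c(0, 180), "phase_cycled")
  expect_equal(trufi_rms_combine(s), v)
  a <- array(3, c(2, 2, 1)); b <- array(4, c(2, 2, 1))
  expect_equal(trufi_rms_combine(acq_series(list(a, b), c(0, 180),
                                            "phase_cycled"))[1],
               sqrt(12.5))
  expect_error(acq_series(list(a, array(0, c(3, 3, 1))), c(0, 180), "x"),
               "grid mismatch")
})

test_that("RMS combination suppresses phase-cycle banding", {
  pc <- make_phase_cycled_stack(5)
  comb <- trufi_rms_combine(pc)
  cv <- function(x) stats::sd(x) / mean(x)
  expect_true(all(cv(comb) < vapply(pc$volumes, cv, numeric(1))))
})

test_that("log-linear T2 fit recovers noiseless ground truth", {
  st <- make_signal_stack(3, "me_t2")
  f <- fit_t2_loglinear(st$series)
  expect_lt(max(abs(f$t2$values - st$ground_truth$T2) /
                  st$ground_truth$T2), 1e-9)
  expect_lt(max(abs(f$s0$values - st$ground_truth$S0) /
                  st$ground_truth$S0), 1e-9)
  # two echoes: exact interpolation, zero residual
  s2 <- acq_series(list(array(100, c(2, 2, 1)), array(50, c(2, 2, 1))),
                   c(20, 40), "me_t2")
  f2 <- fit_t2_loglinear(s2)
  expect_equal(f2$t2$values[1, 1, 1], 20 / log(2), tolerance = 1e-12)
  expect_lt(max(f2$t2$diagnostics$residual_rms), 1e-12)
  # weighting is irrelevant at zero residual
  fn <- fit_t2_loglinear(st$series, weighting = "none")
  expect_equal(f$t2$values, fn$t2$values, tolerance = 1e-10)
  expect_error(fit_t2_loglinear(acq_series(list(array(1, c(1, 1, 1)),
    array(1, c(1, 1, 1))), c(30, 30), "me_t2")), "distinct")
})

test_that("T2* fit recovers truth and reports the reciprocal R2* map", {
  st <- make_signal_stack(7, "me_t2star", dims = c(8, 8, 1))
  f <- fit_t2star_map(st$series)
  expect_lt(max(abs(f$t2star$values - st$ground_truth$T2star) /
                  st$ground_truth$T2star), 1e-6)
  expect_equal(f$r2star$values[f$r2star$mask],
               1 / f$t2star$values[f$t2star$mask], tolerance = 1e-12)
})

test_that("T2* estimator has small median bias under Rician noise", {
  set.seed(7)
  te <- c(2, 8.6, 15.2, 21.8, 28.4, 35)
  t2s <- 50; s0 <- 1000; sdn <- 20  # SNR 50
  n <- 500                          # seeded replicates, one per voxel
  vols <- lapply(te, function(t) {
    s <- rep(s0 * exp(-t / t2s), n)
    array(sqrt((s + rnorm(n, 0, sdn))^2 + rnorm(n, 0, sdn)^2), c(n, 1, 1))
  })
  f <- fit_t2star_map(acq_series(vols, te, "me_t2star"))
  bias <- (stats::median(f$t2star$values, na.rm = TRUE) - t2s) / t2s
  expect_lt(abs(bias), 0.05)
})

test_that("inversion-recovery T1 fit recovers truth within 0.1%", {
  ti <- c(60, 120, 240, 480, 935)
  t1 <- c(450, 700, 820)
  vols <- lapply(ti, function(t)
    array(abs(1000 - 2000 * exp(-t / t1)), c(3, 1, 1)))
  f <- fit_t1_ir(acq_series(vols, ti, "ir_t1"))
  expect_lt(max(abs(f$t1$values - t1) / t1), 1e-3)
  expect_equal(as.vector(f$a$values), rep(1000, 3), tolerance = 1e-4)
})

test_that("T1 fit flags degenerate voxels and is scale invariant", {
  ti <- c(60, 120, 240, 480, 935)
  vols <- lapply(ti, function(t) array(c(500, abs(1000 - 2000 * exp(-t / 700))),
                                       c(2, 1, 1)))
  f <- fit_t1_ir(acq_series(vols, ti, "ir_t1"))
  expect_false(f$t1$mask[1, 1, 1])   # constant signal -> invalid
  expect_true(f$t1$mask[2, 1, 1])
  vols5 <- lapply(vols, function(v) 5 * v)
  f5 <- fit_t1_ir(acq_series(vols5, ti, "ir_t1"))
  expect_equal(f5$t1$values[2, 1, 1], f$t1$values[2, 1, 1],
               tolerance = 1e-6)
})

test_that("tensor fit is exact for isotropic and prolate tensors", {
  dirs <- histomri:::default_dwi_dirs()
  p <- data.frame(b = c(0, rep(1000, 6)),
                  gx = c(0, dirs[, 1]), gy = c(0, dirs[, 2]),
                  gz = c(0, dirs[, 3]))
  # isotropic: FA 0, MD d
  d0 <- 7e-4
  vols <- lapply(seq_len(nrow(p)), function(i)
    array(1000 * exp(-p$b[i] * d0), c(2, 2, 1)))
  f <- fit_dti_loglinear(acq_series(vols, p, "dwi"))
  expect_lt(max(abs(f$fa$values)), 1e-9)
  expect_equal(f$md$values[1, 1, 1], d0, tolerance = 1e-12)
  # prolate lambda = (1.7, 0.2, 0.2) x 1e-3 along x
  lam <- c(1.7e-3, 2e-4, 2e-4)
  D <- diag(lam)
  vols2 <- lapply(seq_len(nrow(p)), function(i) {
    g <- c(p$gx[i], p$gy[i], p$gz[i])
    array(1000 * exp(-p$b[i] * (g %*% D %*% g)[1]), c(1, 1, 1))
  })
  f2 <- fit_dti_loglinear(acq_series(vols2, p, "dwi"))
  md_true <- mean(lam)
  fa_true <- sqrt(1.5 * sum((lam - md_true)^2) / sum(lam^2))
  expect_equal(f2$md$values[1, 1, 1], md_true, tolerance = 1e-10)
  expect_equal(f2$fa$values[1, 1, 1], fa_true, tolerance = 1e-8)
  expect_equal(abs(f2$e1[1, 1]), 1, tolerance = 1e-8)
})

test_that("tensor fit is equivariant under joint rotation", {
  th <- 35 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  lam <- c(1.7e-3, 2e-4, 2e-4)
  D <- diag(lam)
  Drot <- R %*% D %*% t(R)
  dirs <- histomri:::default_dwi_dirs()
  make_fit <- function(Dm, G) {
    p <- data.frame(b = c(0, rep(1000, nrow(G))),
                    gx = c(0, G[, 1]), gy = c(0, G[, 2]), gz = c(0, G[, 3]))
    vols <- lapply(seq_len(nrow(p)), function(i) {
      g <- c(p$gx[i], p$gy[i], p$gz[i])
      array(1000 * exp(-p$b[i] * (g %*% Dm %*% g)[1]), c(1, 1, 1))
    })
    fit_dti_loglinear(acq_series(vols, p, "dwi"))
  }
  f1 <- make_fit(D, dirs)
  f2 <- make_fit(Drot, dirs %*% t(R))  # rotate tensor and gradients jointly
  expect_equal(f1$fa$values, f2$fa$values, tolerance = 1e-8)
  expect_equal(f1$md$values, f2$md$values, tolerance = 1e-10)
  # principal direction of the rotated-tensor fit (on the original
  # gradient set) follows the rotation
  f3 <- make_fit(Drot, dirs)
  e_expect <- (R %*% c(1, 0, 0))[, 1]
  if (e_expect[3] < 0 || (e_expect[3] == 0 && e_expect[2] < 0))
    e_expect <- -e_expect
  expect_equal(as.vector(f3$e1[1, ]), e_expect, tolerance = 1e-6)
  expect_error(make_fit(D, dirs[c(1, 1, 1, 1, 1, 1), ]), "rank|collinear")
})

test_that("fits are invariant to global positive magnitude scaling", {
  st <- make_signal_stack(3, "me_t2", dims = c(4, 4, 1))
  f1 <- fit_t2_loglinear(st$series)
  s2 <- acq_series(lapply(st$series$volumes, function(v) 3.7 * v),
                   st$series$params, "me_t2")
  f2 <- fit_t2_loglinear(s2)
  expect_equal(f1$t2$values, f2$t2$values, tolerance = 1e-9)
})
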