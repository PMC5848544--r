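# Registration building blocks: keying, NMI, MIND, block insertion,
# subsampling, affine and deformable recovery, tissue segmentation.

test_that("background keying recovers the phantom foreground", {
  sp <- make_slice_pair(11)
  fg <- segment_background(sp$intact_photo)
  expect_gt(mean(fg == sp$foreground_mask), 0.995)
  # idempotence: keying the masked photo returns the same mask
  masked <- sp$intact_photo
  for (k in 1:3) {
    ch <- masked[, , k]
    ch[!fg] <- phantom_background_blue()[k]
    masked[, , k] <- ch
  }
  expect_identical(segment_background(masked), fg)
  # pure background -> error
  bgimg <- array(0, c(8, 8, 3))
  for (k in 1:3) bgimg[, , k] <- phantom_background_blue()[k]
  expect_error(segment_background(bgimg), "foreground")
})

test_that("NMI behaves as an information-theoretic similarity", {
  set.seed(2)
  a <- matrix(runif(120 * 120), 120)
  b <- matrix(runif(120 * 120), 120)
  expect_equal(nmi(a, a, 64), 2, tolerance = 1e-12)
  expect_lt(abs(nmi(a, b, 64) - 1), 0.05)
  expect_equal(nmi(a, b, 64), nmi(b, a, 64), tolerance = 1e-12)
  expect_error(nmi(a, b[1:10, 1:10]), "dimensions")
})

test_that("MIND descriptors are self-consistent and intensity invariant", {
  img <- helper_texture(11)
  m1 <- compute_mind(img)
  expect_equal(mind_distance(m1, m1), 0)
  expect_true(all(m1$descriptors > 0 & m1$descriptors <= 1))
  # constant image: variance floor keeps descriptors defined and uniform
  mc <- compute_mind(matrix(0.5, 20, 20))
  expect_true(all(is.finite(mc$descriptors)))
  expect_equal(max(mc$descriptors) - min(mc$descriptors), 0)
  # invariance to global affine intensity rescaling
  m2 <- compute_mind(3.1 * img + 0.4)
  expect_lt(sqrt(mind_distance(m1, m2)), 1e-6)
  # cross-modality robustness: MIND distance between an image and its
  # inversion is far below the normalised raw-intensity distance
  inv <- max(img) - img
  d_mind <- mind_distance(m1, compute_mind(inv))
  d_raw <- mean(((img - mean(img)) / stats::sd(img) -
                   (inv - mean(inv)) / stats::sd(inv))^2)
  expect_lt(d_mind, d_raw / 10)
})

test_that("block insertion recovers the identity and scores the argmax", {
  sp <- make_slice_pair(1)  # identity pose: block is an exact crop
  ins <- insert_block_face(sp$block_photo, sp$intact_photo,
                           sp$cutout_photo, rotations = seq(-20, 20, 2))
  expect_lt(abs(ins$pose$angle), 1)
  expect_lt(max(abs(ins$pose$translation - sp$block_to_slice$translation)), 1)
  # the refined score is at least the best coarse-grid score
  expect_gte(ins$score + 1e-9, ins$coarse_score)
  expect_gt(ins$score, 1.95)  # essentially exact match
})

test_that("whole-slice fallback warns when the cut-out gives no hole", {
  sp <- make_slice_pair(1)
  expect_warning(
    insert_block_face(sp$block_photo, sp$intact_photo,
                      cutout = sp$intact_photo,   # nothing excised
                      rotations = c(0)),
    "whole-slice")
})

test_that("histology subsampling is anti-aliased and mean preserving", {
  const <- matrix(0.7, 40, 40)
  expect_equal(subsample_histology(const, 4), matrix(0.7, 10, 10))
  checker <- outer(1:100, 1:100, function(i, j) (i + j) %% 2)
  down <- subsample_histology(checker, 100)
  expect_equal(dim(down), c(1L, 1L))
  expect_equal(down[1, 1], 0.5, tolerance = 1e-6)
  img <- helper_texture(3)
  d4 <- subsample_histology(img, 4)
  expect_lt(abs(mean(d4) - mean(img)) / mean(img), 0.005)
  expect_error(subsample_histology(img, 0.5), "upsampling")
})

test_that("affine registration is stable at the identity and under remaps", {
  img <- helper_texture(11)
  reg <- register_affine(img, img)
  # identity recovery: displacement effect under 0.1 px over the image
  g <- pixel_grid(nrow(img), ncol(img))
  pts <- cbind(as.vector(g$r), as.vector(g$c))
  moved <- apply_transform(reg$transform, pts)
  expect_lt(max(sqrt(rowSums((moved - pts)^2))), 0.1)
  # recovery unchanged under a monotone intensity remap of both images
  fg <- make_slice_pair(11, dims = c(96L, 96L),
                        block_dims = c(32L, 32L))$foreground_mask
  remap <- function(x) x^1.7 + 0.1 * x
  ctr <- c((nrow(img) - 1) / 2, (ncol(img) - 1) / 2)
  truth <- affine2d(0.93 * diag(2), ctr * 0.07)
  moving <- warp_image(img, truth)
  r1 <- register_affine(moving, img, mask = fg)
  r2 <- register_affine(remap(moving), remap(img), mask = fg)
  expect_lt(max(abs(r1$transform$A - r2$transform$A)), 0.01)
  expect_equal(sqrt(det(r1$transform$A)), 0.93, tolerance = 0.01)
})

test_that("deformable registration recovers a known smooth warp", {
  img <- helper_texture(11)
  u <- helper_smooth_disp(dim(img), 5, 77)
  fixed <- displace_image(img, u$r, u$c)
  def <- register_deformable(img, fixed)
  fg <- helper_erode(segment_background(
    make_slice_pair(11, dims = c(96L, 96L), block_dims = c(32L, 32L))$intact_photo), 6)
  err <- sqrt((def$disp$r - u$r)^2 + (def$disp$c - u$c)^2)
  expect_lt(mean(err[fg]), 1)
  expect_lt(stats::quantile(err[fg], 0.95), 2)
  expect_gt(def$min_jacobian, 0)
  # moving = fixed: near-zero field
  def0 <- register_deformable(img, img, levels = 1, iterations = 5)
  expect_lt(sqrt(mean(def0$disp$r^2 + def0$disp$c^2)), 0.1)
})

test_that("displacement inversion composes to the identity", {
  u <- helper_smooth_disp(c(64, 64), 4, 5)
  v <- invert_displacement(u)
  g <- pixel_grid(64, 64)
  # (id+u) o (id+v): forward-then-inverse within 0.1 px in the interior
  pr <- g$r + u$r + matrix(bilinear_sample(v$r, cbind(as.vector(g$r + u$r),
    as.vector(g$c + u$c))), 64)
  pc <- g$c + u$c + matrix(bilinear_sample(v$c, cbind(as.vector(g$r + u$r),
    as.vector(g$c + u$c))), 64)
  interior <- matrix(FALSE, 64, 64); interior[9:56, 9:56] <- TRUE
  expect_lt(max(abs(pr - g$r)[interior]), 0.1)
  expect_lt(max(abs(pc - g$c)[interior]), 0.1)
})

test_that("tissue segmentation separates classes and extracts boundaries", {
  # clean bimodal GM/WM phantom, classes separated by >> 3 sigma
  set.seed(13)
  g <- histomri:::pixel_grid(80, 80)
  fg <- ((g$r - 39.5)^2 + (g$c - 39.5)^2) < 36^2
  truth_wm <- fg & (((g$r - 39.5)^2 + (g$c - 39.5)^2) < 20^2)
  sl <- matrix(0.05, 80, 80)
  sl[fg] <- 0.45; sl[truth_wm] <- 0.85
  sl <- sl + matrix(rnorm(6400, 0, 0.02), 80)
  seg <- segment_tissue(sl, mask = fg)
  acc <- mean((seg$labels == 2L)[fg] == truth_wm[fg])
  expect_gt(acc, 0.99)
  expect_gt(length(seg$boundary), 0)
  # inverted contrast with swapped priors gives the same boundary set
  seg_inv <- segment_tissue(max(sl) - sl, mask = fg, wm_bright = FALSE)
  expect_equal(length(seg_inv$boundary), length(seg$boundary))
  b1 <- do.call(rbind, seg$boundary)
  b2 <- do.call(rbind, seg_inv$boundary)
  expect_equal(dim(b1), dim(b2))
  expect_lt(max(abs(sort(b1[, 1]) - sort(b2[, 1]))), 1e-6)
  # unimodal Gaussian noise cannot be split into tissue classes
  expect_error(segment_tissue(matrix(rnorm(400, 0.5, 0.01), 20)),
               "unimodal")
  # boundaries are closed or terminate on the foreground edge
  for (p in seg$boundary) {
    closed <- sqrt(sum((p[1, ] - p[nrow(p), ])^2)) < 1.5
    ends_on_edge <- !fg[cbind(pmin(pmax(round(p[c(1, nrow(p)), 1]), 0),
                                   79) + 1,
                              pmin(pmax(round(p[c(1, nrow(p)), 2]), 0),
                                   79) + 1)]
    expect_true(closed || all(ends_on_edge) ||
                  any(p[c(1, nrow(p)), ] <= 0.5) ||
                  any(p[c(1, nrow(p)), ] >= 78.5))
  }
})
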