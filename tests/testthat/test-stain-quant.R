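# Colour deconvolution and positive-pixel quantification.

test_that("optical density transform and its inverse are exact", {
  img <- array(0, c(2, 2, 3))
  img[, , 1] <- 1; img[, , 2] <- 1; img[, , 3] <- 1
  expect_equal(rgb_to_od(img), array(0, c(2, 2, 3)))
  img2 <- array(0.1, c(2, 2, 3))
  expect_equal(rgb_to_od(img2), array(1, c(2, 2, 3)))
  set.seed(1)
  x <- array(runif(4 * 5 * 3, 0.02, 1), c(4, 5, 3))
  expect_equal(od_to_rgb(rgb_to_od(x)), x, tolerance = 1e-12)
  expect_error(rgb_to_od(img, white_reference = c(0, 1, 1)), "positive")
})

test_that("stain vector calibration recovers generating directions", {
  v <- c(0.65, 0.704, 0.286); v <- v / sqrt(sum(v^2))
  set.seed(2)
  conc <- matrix(runif(100, 0.2, 1.2), 10, 10)
  od <- array(0, c(10, 10, 3))
  for (k in 1:3) od[, , k] <- conc * v[k]
  cal <- calibrate_stain_vectors(list(od), "s1")
  expect_equal(cal$vectors[, 1], v, tolerance = 1e-6)
  # permuting sample order permutes output identically
  w <- c(0.27, 0.57, 0.78); w <- w / sqrt(sum(w^2))
  od2 <- array(0, c(10, 10, 3))
  for (k in 1:3) od2[, , k] <- conc * w[k]
  c1 <- calibrate_stain_vectors(list(od, od2), c("s1", "s2"))
  c2 <- calibrate_stain_vectors(list(od2, od), c("s2", "s1"))
  expect_equal(c1$vectors[, 1], c2$vectors[, 2], tolerance = 1e-12)
  expect_error(calibrate_stain_vectors(list(od * 0), "s1"), "calibration")
})

test_that("deconvolution matches the exact matrix-inverse oracle", {
  sv <- stain_vectors_hdab()
  hp <- make_histology_phantom(6, stains = sv)
  od <- rgb_to_od(hp$rgb_image, sv$white_reference)
  dc <- deconvolve(od, sv)
  # oracle: solve the 3x3 mixing system per pixel
  Vi <- solve(sv$vectors)
  M <- cbind(as.vector(od[, , 1]), as.vector(od[, , 2]),
             as.vector(od[, , 3]))
  Cor <- M %*% t(Vi)
  expect_lt(max(abs(as.vector(dc$concentrations[[1]]) - Cor[, 1])), 1e-10)
  # phantom round trip: recovers generating concentration fields
  rel <- abs(dc$concentrations$haematoxylin -
               hp$concentration_fields$haematoxylin) /
    pmax(hp$concentration_fields$haematoxylin, 1)
  expect_lt(max(rel), 1e-6)
  rel2 <- abs(dc$concentrations$dab - hp$concentration_fields$dab) /
    pmax(hp$concentration_fields$dab, 1)
  expect_lt(max(rel2), 1e-6)
  # 50/50 mixture of calibrated pure stains gives equal concentrations
  odm <- array(0, c(4, 4, 3))
  for (k in 1:3) odm[, , k] <- 0.5 * sv$vectors[k, 1] + 0.5 * sv$vectors[k, 2]
  dm <- deconvolve(odm, sv)
  expect_equal(dm$concentrations[[1]], dm$concentrations[[2]],
               tolerance = 1e-10)
  # OD = 0 pixel -> all concentrations 0; pure pixel -> own channel only
  od0 <- array(0, c(1, 1, 3))
  d0 <- deconvolve(od0, sv)
  expect_true(all(vapply(d0$concentrations, max, numeric(1)) == 0))
  odp <- array(sv$vectors[, 2] * 0.8, c(1, 1, 3))
  dp <- deconvolve(aperm(array(odp, c(3, 1, 1)), c(2, 3, 1)), sv)
  expect_equal(dp$concentrations$dab[1, 1], 0.8, tolerance = 1e-10)
  expect_lt(abs(dp$concentrations$haematoxylin[1, 1]), 1e-10)
})

test_that("two-stain sets complete an orthogonal residual vector", {
  sv <- stain_vectors_hdab()
  expect_equal(ncol(sv$vectors), 3)
  expect_lt(abs(sum(sv$vectors[, 1] * sv$vectors[, 3])), 1e-10)
  expect_lt(abs(sum(sv$vectors[, 2] * sv$vectors[, 3])), 1e-10)
  expect_error(stain_vector_set(list(c(1, 0, 0), c(1, 0, 0)), c("a", "b")),
               "dependent")
})

test_that("pixel classification uses half-open lower-inclusive bins", {
  th <- positive_pixel_thresholds(0.2, 0.5, 0.8, background_cutoff = 0.01)
  conc <- list(dab = matrix(c(0.1999, 0.2, 0.5, 0.8), 1),
               haem = matrix(0, 1, 4))
  mk <- classify_pixels(conc, thresholds = th)
  expect_equal(as.vector(mk$labels), c(3L, 4L, 5L, 6L))  # neg/weak/med/strong
  expect_error(positive_pixel_thresholds(0.5, 0.2, 0.8), "thresholds")
})

test_that("stained area fraction matches direct-count ground truth", {
  set.seed(4)
  conc <- matrix(runif(60 * 60), 60, 60)
  th <- positive_pixel_thresholds(stats::quantile(conc, 0.7), 2, 3,
                                  background_cutoff = 0)
  mk <- classify_pixels(list(dab = conc), thresholds = th)
  f <- stained_area_fraction(mk)
  truth <- mean(conc >= th$t_weak)
  expect_equal(f$stained_area_fraction, truth, tolerance = 1e-12)
  expect_equal(sum(f$counts), f$analysed_pixels)
  # all-weak and all-negative limits
  allw <- classify_pixels(list(dab = matrix(0.5, 3, 3)),
                          thresholds = positive_pixel_thresholds(0.1, 0.9, 1))
  expect_equal(stained_area_fraction(allw)$stained_area_fraction, 1)
  alln <- classify_pixels(list(dab = matrix(0.05, 3, 3)),
                          thresholds = positive_pixel_thresholds(0.1, 0.9, 1,
                            background_cutoff = 0.01))
  expect_equal(stained_area_fraction(alln)$stained_area_fraction, 0)
})

test_that("raising thresholds never increases the stained fraction", {
  set.seed(5)
  conc <- list(dab = matrix(runif(900), 30, 30))
  fr <- vapply(c(0.2, 0.4, 0.6, 0.8), function(tw) {
    th <- positive_pixel_thresholds(tw, 0.9, 0.95, background_cutoff = 0)
    stained_area_fraction(classify_pixels(conc,
      thresholds = th))$stained_area_fraction
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("polygon annotations gate the analysis and exclusions win", {
  sq <- function(r0, c0, r1, c1)
    rbind(c(r0, c0), c(r0, c1), c(r1, c1), c(r1, c0))
  ann <- region_annotation(list(sq(2, 2, 17, 17)), list(sq(5, 5, 9, 9)))
  m <- annotation_mask(ann, c(20, 20))
  expect_true(m[4, 4] && !m[7, 7] && !m[1, 1])
  conc <- list(dab = matrix(1, 20, 20))
  th <- positive_pixel_thresholds(0.5, 2, 3, background_cutoff = 0)
  mk <- classify_pixels(conc, thresholds = th, annotation = ann)
  f <- stained_area_fraction(mk)
  expect_equal(f$analysed_pixels, sum(m))
  expect_error(classify_pixels(conc, thresholds = th,
    annotation = region_annotation(list(sq(100, 100, 110, 110)))),
    "empty analysis mask")
})

test_that("classification is invariant to joint rotation of image and mask", {
  set.seed(6)
  conc <- matrix(runif(400), 20, 20)
  th <- positive_pixel_thresholds(0.3, 0.6, 0.9, background_cutoff = 0.05)
  rot <- function(m) t(m)[, nrow(m):1]  # 90 degrees
  m1 <- classify_pixels(list(dab = conc), thresholds = th)
  m2 <- classify_pixels(list(dab = rot(conc)), thresholds = th)
  expect_identical(rot(m1$labels), m2$labels)
})

test_that("markup rendering uses the fixed class palette", {
  th <- positive_pixel_thresholds(0.2, 0.5, 0.8, background_cutoff = 0.01)
  conc <- list(dab = matrix(c(0, 0.1, 0.3, 0.6, 0.9, 0.9), 2, 3))
  mk <- classify_pixels(conc, thresholds = th)
  img <- render_markup(mk)
  expect_equal(img[1, 1, ], c(1, 1, 1))       # unstained white
  expect_equal(img[2, 1, ], c(0, 0, 1))       # negative blue
  expect_equal(img[1, 2, ], c(1, 1, 0))       # weak yellow
  expect_equal(img[2, 2, ], c(1, 0.5, 0))     # medium orange
  expect_equal(img[1, 3, ], c(1, 0, 0))       # strong red
})

test_that("threshold stability reports per-region fractions", {
  hp <- make_histology_phantom(8)
  sv <- hp$stains
  od <- rgb_to_od(hp$rgb_image, sv$white_reference)
  dc <- deconvolve(od, sv)
  sq <- function(r0, c0, r1, c1)
    rbind(c(r0, c0), c(r0, c1), c(r1, c1), c(r1, c0))
  regions <- list(region_annotation(list(sq(30, 30, 60, 60))),
                  region_annotation(list(sq(60, 60, 95, 95))))
  th <- positive_pixel_thresholds(0.1, 0.4, 0.8, background_cutoff = 0.02)
  st <- threshold_stability(dc, od, th, regions)
  expect_equal(nrow(st), 2)
  expect_true(all(st$stained_area_fraction >= 0 &
                    st$stained_area_fraction <= 1))
  expect_false(is.null(attr(st, "cv")))
})
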