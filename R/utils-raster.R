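# Shared raster utilities: interpolation, separable Gaussian smoothing,
# seeded smooth random fields.
#
# Conventions (kept bit-stable across the package):
#  * 2-D images are numeric matrices indexed [row, col]; RGB images are
#    [row, col, 3] arrays with channels in [0, 1].
#  * Continuous pixel coordinates are 0-based, pixel-centre: the centre of
#    matrix element [1, 1] is (0, 0). Points are n x 2 matrices (row, col).
#  * 3-D volumes are [i, j, k] arrays with 0-based voxel-centre coordinates.

#' Bilinear interpolation of a 2-D image
#'
#' Samples `img` at continuous, 0-based pixel-centre coordinates. Queries
#' outside the image domain are clamped to the edge unless a constant
#' `pad` value is given.
#'
#' @param img numeric matrix.
#' @param pts n x 2 matrix of (row, col) coordinates, 0-based.
#' @param pad optional constant value for out-of-domain queries; default
#'   edge clamping.
#' @return numeric vector of length n.
#' @export
bilinear_sample <- function(img, pts, pad = NULL) {
  stopifnot(is.matrix(img), ncol(pts) == 2)
  nr <- nrow(img); nc <- ncol(img)
  r <- pts[, 1]; c <- pts[, 2]
  outside <- r < 0 | r > nr - 1 | c < 0 | c > nc - 1
  rc <- pmin(pmax(r, 0), nr - 1)
  cc <- pmin(pmax(c, 0), nc - 1)
  r0 <- pmin(floor(rc), nr - 2); c0 <- pmin(floor(cc), nc - 2)
  if (nr == 1) r0 <- rep(0, length(rc))
  if (nc == 1) c0 <- rep(0, length(cc))
  fr <- rc - r0; fc <- cc - c0
  i00 <- (c0) * nr + r0 + 1
  v00 <- img[i00]
  v10 <- if (nr > 1) img[i00 + 1] else v00
  v01 <- if (nc > 1) img[i00 + nr] else v00
  v11 <- if (nr > 1 && nc > 1) img[i00 + nr + 1] else v00
  out <- (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
  if (!is.null(pad)) out[outside] <- pad
  out
}

#' Trilinear interpolation of a 3-D volume
#'
#' @param vol 3-D numeric array.
#' @param pts n x 3 matrix of (i, j, k) coordinates, 0-based voxel-centre.
#' @param pad optional constant for out-of-domain queries (default edge
#'   clamping).
#' @return numeric vector of length n.
#' @export
trilinear_sample <- function(vol, pts, pad = NULL) {
  stopifnot(length(dim(vol)) == 3, ncol(pts) == 3)
  d <- dim(vol)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  outside <- x < 0 | x > d[1] - 1 | y < 0 | y > d[2] - 1 | z < 0 | z > d[3] - 1
  x <- pmin(pmax(x, 0), d[1] - 1)
  y <- pmin(pmax(y, 0), d[2] - 1)
  z <- pmin(pmax(z, 0), d[3] - 1)
  x0 <- pmin(floor(x), max(d[1] - 2, 0))
  y0 <- pmin(floor(y), max(d[2] - 2, 0))
  z0 <- pmin(floor(z), max(d[3] - 2, 0))
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  sx <- 1L; sy <- d[1]; sz <- d[1] * d[2]
  i000 <- x0 + y0 * sy + z0 * sz + 1
  gx <- as.integer(d[1] > 1); gy <- as.integer(d[2] > 1); gz <- as.integer(d[3] > 1)
  v <- function(dx, dy, dz) vol[i000 + dx * gx * sx + dy * gy * sy + dz * gz * sz]
  out <-
    (1 - fx) * (1 - fy) * (1 - fz) * v(0, 0, 0) +
    fx       * (1 - fy) * (1 - fz) * v(1, 0, 0) +
    (1 - fx) * fy       * (1 - fz) * v(0, 1, 0) +
    fx       * fy       * (1 - fz) * v(1, 1, 0) +
    (1 - fx) * (1 - fy) * fz       * v(0, 0, 1) +
    fx       * (1 - fy) * fz       * v(1, 0, 1) +
    (1 - fx) * fy       * fz       * v(0, 1, 1) +
    fx       * fy       * fz       * v(1, 1, 1)
  if (!is.null(pad)) out[outside] <- pad
  out
}

# Discrete Gaussian kernel, truncated at 3 sigma (minimum half-width 1).
gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  hw <- max(1L, ceiling(3 * sigma))
  x <- seq(-hw, hw)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# 1-D convolution along matrix rows with edge replication.
conv_cols <- function(m, k) {
  hw <- (length(k) - 1L) / 2L
  if (hw == 0) return(m * k)
  nr <- nrow(m)
  idx <- c(rep(1L, hw), seq_len(nr), rep(nr, hw))
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, nr, ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + nr - 1L), , drop = FALSE]
  out
}

#' Separable Gaussian smoothing of a matrix or 3-D array
#'
#' Edge-replicated boundary handling; truncation at three standard
#' deviations. `sigma` is in pixels/voxels and may be a scalar or one
#' value per dimension.
#'
#' @param x numeric matrix or 3-D array.
#' @param sigma Gaussian standard deviation(s), pixels.
#' @return smoothed array, same shape as `x`.
#' @export
gauss_smooth <- function(x, sigma) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2) {
    sigma <- rep(sigma, length.out = 2)
    m <- conv_cols(as.matrix(x), gaussian_kernel_1d(sigma[1]))
    t(conv_cols(t(m), gaussian_kernel_1d(sigma[2])))
  } else if (length(d) == 3) {
    sigma <- rep(sigma, length.out = 3)
    out <- x
    for (ax in 1:3) {
      k <- gaussian_kernel_1d(sigma[ax])
      if (length(k) == 1) next
      perm <- c(ax, setdiff(1:3, ax))
      m <- aperm(out, perm)
      dm <- dim(m)
      m2 <- conv_cols(matrix(m, dm[1], dm[2] * dm[3]), k)
      out <- aperm(array(m2, dm), order(perm))
    }
    out
  } else stop("gauss_smooth: x must be 2-D or 3-D")
}

#' Seeded smooth random field
#'
#' White Gaussian noise smoothed with a Gaussian kernel and rescaled to
#' zero mean, unit standard deviation. Deterministic for a fixed seed.
#'
#' @param dims integer vector of length 2 or 3.
#' @param sigma smoothing bandwidth in pixels.
#' @param seed integer seed.
#' @return array of the requested dimensions.
#' @export
smooth_noise_field <- function(dims, sigma, seed) {
  set.seed(as.integer(seed))
  x <- array(stats::rnorm(prod(dims)), dim = dims)
  x <- gauss_smooth(x, sigma)
  (x - mean(x)) / stats::sd(x)
}

# Meshgrid of 0-based (row, col) coordinates for an nr x nc image,
# returned as a list of two matrices.
pixel_grid <- function(nr, nc) {
  list(r = matrix(rep(0:(nr - 1), nc), nr, nc),
       c = matrix(rep(0:(nc - 1), each = nr), nr, nc))
}

# Clamp helper.
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
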