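# 2-D rigid and affine transforms and image warping.
#
# A transform maps points forward from its source frame to its target
# frame. Image resampling is always a pull-back: the warped image on the
# target grid is obtained by mapping target coordinates through the
# *inverse* transform and interpolating the source once.

#' Construct a 2-D rigid transform
#'
#' Rotation (degrees, anticlockwise in (row, col) coordinates) about
#' `centre`, followed by a translation in pixels.
#'
#' @param angle rotation in degrees.
#' @param translation length-2 numeric, (row, col) shift in pixels.
#' @param centre length-2 numeric, centre of rotation (0-based pixels).
#' @return object of class `rigid2d`.
#' @export
rigid2d <- function(angle = 0, translation = c(0, 0), centre = c(0, 0)) {
  structure(list(angle = angle, translation = as.numeric(translation),
                 centre = as.numeric(centre)),
            class = "rigid2d")
}

#' @export
print.rigid2d <- function(x, ...) {
  cat(sprintf("rigid2d: %.3f deg, t = (%.3f, %.3f) px, centre (%.2f, %.2f)\n",
              x$angle, x$translation[1], x$translation[2],
              x$centre[1], x$centre[2]))
  invisible(x)
}

# Rotation matrix acting on (row, col) column vectors.
rot2 <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' Apply a 2-D transform to points
#'
#' @param tf a `rigid2d`, `affine2d`, or any object with an
#'   `apply_transform` method.
#' @param pts n x 2 matrix of (row, col) points.
#' @return n x 2 matrix of mapped points.
#' @export
apply_transform <- function(tf, pts) UseMethod("apply_transform")

#' @export
apply_transform.rigid2d <- function(tf, pts) {
  pts <- rbind(pts)
  R <- rot2(tf$angle)
  out <- sweep(pts, 2, tf$centre) %*% t(R)
  sweep(out, 2, tf$centre + tf$translation, `+`)
}

#' Invert a transform
#' @param tf transform object.
#' @return transform of the same class mapping target to source.
#' @export
invert_transform <- function(tf) UseMethod("invert_transform")

#' @export
invert_transform.rigid2d <- function(tf) {
  # p' = R (p - c) + c + t  =>  p = R^-1 (p' - (c + t)) + (c + t) - t
  rigid2d(angle = -tf$angle,
          translation = -tf$translation,
          centre = tf$centre + tf$translation)
}

#' Construct a 2-D affine transform
#'
#' @param A 2 x 2 linear part (acting on (row, col) vectors); must have
#'   positive determinant (no reflection).
#' @param b length-2 offset in pixels.
#' @return object of class `affine2d`.
#' @export
affine2d <- function(A = diag(2), b = c(0, 0)) {
  A <- matrix(as.numeric(A), 2, 2)
  if (det(A) <= 0) stop("affine2d: linear part must have positive determinant")
  structure(list(A = A, b = as.numeric(b)), class = "affine2d")
}

#' @export
apply_transform.affine2d <- function(tf, pts) {
  sweep(rbind(pts) %*% t(tf$A), 2, tf$b, `+`)
}

#' @export
invert_transform.affine2d <- function(tf) {
  Ai <- solve(tf$A)
  affine2d(Ai, -(Ai %*% tf$b)[, 1])
}

#' @export
print.affine2d <- function(x, ...) {
  cat("affine2d:\n"); print(cbind(x$A, x$b)); invisible(x)
}

# rigid -> equivalent affine (about the origin).
as_affine2d <- function(tf) {
  if (inherits(tf, "affine2d")) return(tf)
  R <- rot2(tf$angle)
  affine2d(R, tf$centre + tf$translation - (R %*% tf$centre)[, 1])
}

#' Warp an image through a transform
#'
#' Resamples `img` onto a target grid of size `dims` such that
#' `out[p] = img[inverse(tf)(p)]` — i.e. `tf` maps source coordinates into
#' the target frame.
#'
#' @param img numeric matrix (or `[nr, nc, k]` array, warped per channel).
#' @param tf forward transform from image frame to target frame.
#' @param dims target dimensions (default those of `img`).
#' @param pad out-of-domain fill value (default 0).
#' @return warped image.
#' @export
warp_image <- function(img, tf, dims = NULL, pad = 0) {
  d <- dim(img)
  if (is.null(dims)) dims <- d[1:2]
  g <- pixel_grid(dims[1], dims[2])
  src <- apply_transform(invert_transform(tf), cbind(as.vector(g$r), as.vector(g$c)))
  if (length(d) == 2) {
    matrix(bilinear_sample(img, src, pad = pad), dims[1], dims[2])
  } else {
    out <- array(0, c(dims[1], dims[2], d[3]))
    for (k in seq_len(d[3]))
      out[, , k] <- matrix(bilinear_sample(img[, , k], src, pad = pad),
                           dims[1], dims[2])
    out
  }
}

#' Displace an image by a dense field
#'
#' Pull-back warp: `out[p] = img[p + disp[p]]`, the convention used by the
#' deformable registration (the field stores, per target pixel, where to
#' sample the source).
#'
#' @param img numeric matrix.
#' @param disp_r,disp_c displacement components (matrices, pixels).
#' @param pad fill value outside the source domain (default edge clamp).
#' @return warped matrix of the same size.
#' @export
displace_image <- function(img, disp_r, disp_c, pad = NULL) {
  g <- pixel_grid(nrow(img), ncol(img))
  pts <- cbind(as.vector(g$r + disp_r), as.vector(g$c + disp_c))
  matrix(bilinear_sample(img, pts, pad = pad), nrow(img), ncol(img))
}

# Minimum Jacobian determinant of the mapping p -> p + disp(p),
# central differences in the interior.
min_jacobian_det <- function(disp_r, disp_c) {
  nr <- nrow(disp_r); nc <- ncol(disp_r)
  if (nr < 3 || nc < 3) return(1)
  ddr_dr <- (disp_r[3:nr, ] - disp_r[1:(nr - 2), ]) / 2
  ddr_dc <- (disp_r[, 3:nc] - disp_r[, 1:(nc - 2)]) / 2
  ddc_dr <- (disp_c[3:nr, ] - disp_c[1:(nr - 2), ]) / 2
  ddc_dc <- (disp_c[, 3:nc] - disp_c[, 1:(nc - 2)]) / 2
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  jac <- (1 + ddr_dr[, j]) * (1 + ddc_dc[i, ]) - ddr_dc[i, ] * ddc_dr[, j]
  min(jac)
}
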