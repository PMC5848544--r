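# Photograph phantoms: a coronal-slice scene on a blue background, the
# same scene with one tissue block excised, and the photographed block
# itself under a known rigid pose. These drive the block-insertion and
# background-keying stages with exact ground truth.

#' Background colour used by the photograph phantoms
#'
#' A saturated blue, emulating slice photography on a blue board so that
#' chroma keying separates tissue from background.
#' @return length-3 RGB vector in [0, 1].
#' @export
phantom_background_blue <- function() c(0.08, 0.16, 0.85)

# Textured tissue scene: foreground ellipse with a grey-matter band and a
# white-matter core, plus seeded smooth texture. Returns the RGB photo,
# the foreground mask and the white-matter label mask.
render_slice_scene <- function(seed, dims, texture, background) {
  nr <- dims[1]; nc <- dims[2]
  g <- pixel_grid(nr, nc)
  cr <- (nr - 1) / 2; cc <- (nc - 1) / 2
  n1 <- smooth_noise_field(dims, sigma = nr / 16, seed = seed)
  n2 <- smooth_noise_field(dims, sigma = nr / 40, seed = seed + 1000L)
  rad2 <- ((g$r - cr) / (0.42 * nr))^2 + ((g$c - cc) / (0.44 * nc))^2
  fg <- (rad2 + 0.18 * n1) < 1
  core2 <- ((g$r - cr) / (0.26 * nr))^2 + ((g$c - cc) / (0.30 * nc))^2
  wm <- fg & ((core2 + 0.25 * n1) < 1)
  if (texture == "blobs") wm <- fg & (n1 > 0.15)
  base <- ifelse(wm, 0.82, 0.55) + 0.08 * n2
  base <- clamp(base, 0, 1)
  rgb <- array(0, c(nr, nc, 3))
  tint <- c(1.00, 0.88, 0.80)  # pale pinkish tissue
  for (k in 1:3)
    rgb[, , k] <- ifelse(fg, clamp(base * tint[k], 0, 1), background[k])
  list(rgb = rgb, fg = fg, wm = wm)
}

#' Generate a slice / excised-block photograph phantom
#'
#' Builds an intact-slice photograph, the same slice with one block region
#' replaced by background colour (the cut-out slice), and the photograph
#' of the excised block under a known rigid pose. The block photograph is
#' the intact scene resampled on the posed block grid, so resampling the
#' intact photograph at the posed grid reproduces the block exactly
#' (noiselessly); with an identity pose the block is an integer-offset
#' crop.
#'
#' @param seed integer seed; output is bit-identical for a fixed seed.
#' @param texture `"layered"` (grey-matter band / white-matter core,
#'   default) or `"blobs"`.
#' @param pose [rigid2d()] perturbation of the block placement about the
#'   block centre (rotation degrees, translation px). Identity by default.
#' @param dims photograph dimensions (rows, cols).
#' @param block_dims block photograph dimensions.
#' @param background RGB background triple.
#' @return a list of class `phantom_slice_pair` with elements
#'   `intact_photo`, `cutout_photo`, `block_photo`, `true_pose`,
#'   `block_to_slice` (the full block-to-intact rigid map),
#'   `background_color`, `foreground_mask`, `hole_mask`, `wm_mask`.
#' @export
make_slice_pair <- function(seed, texture = c("layered", "blobs"),
                            pose = rigid2d(), dims = c(192L, 192L),
                            block_dims = c(56L, 56L),
                            background = phantom_background_blue()) {
  texture <- match.arg(texture)
  scene <- render_slice_scene(seed, dims, texture, background)
  nr <- dims[1]; nc <- dims[2]
  bh <- block_dims[1]; bw <- block_dims[2]
  # Base placement: block centred on the white-matter core (integer
  # offset so identity pose is an exact crop).
  wm_idx <- which(scene$wm, arr.ind = TRUE)
  ctr <- if (nrow(wm_idx)) round(colMeans(wm_idx)) else round(c(nr, nc) / 2)
  off <- c(ctr[1] - 1 - floor(bh / 2), ctr[2] - 1 - floor(bw / 2))
  block_to_slice <- rigid2d(
    angle = pose$angle,
    translation = off + pose$translation,
    centre = c((bh - 1) / 2, (bw - 1) / 2))

  corners <- rbind(c(0, 0), c(bh - 1, 0), c(0, bw - 1), c(bh - 1, bw - 1))
  mapped <- apply_transform(block_to_slice, corners)
  inside <- mapped[, 1] > 1 & mapped[, 1] < nr - 2 &
    mapped[, 2] > 1 & mapped[, 2] < nc - 2
  fg_at <- bilinear_sample(scene$fg * 1, mapped, pad = 0) > 0.999
  if (!all(inside) || !all(fg_at))
    stop("invalid-pose: block placement leaves the slice foreground")

  # Block photo: intact scene resampled on the posed block grid.
  bg <- pixel_grid(bh, bw)
  src <- apply_transform(block_to_slice, cbind(as.vector(bg$r), as.vector(bg$c)))
  block_photo <- array(0, c(bh, bw, 3))
  for (k in 1:3)
    block_photo[, , k] <- matrix(bilinear_sample(scene$rgb[, , k], src), bh, bw)

  # Hole: footprint of the posed block interior in the intact frame.
  ig <- pixel_grid(nr, nc)
  back <- apply_transform(invert_transform(block_to_slice),
                          cbind(as.vector(ig$r), as.vector(ig$c)))
  hole <- matrix(back[, 1] >= 0.5 & back[, 1] <= bh - 1.5 &
                   back[, 2] >= 0.5 & back[, 2] <= bw - 1.5, nr, nc)
  if (any(hole & !scene$fg))
    stop("invalid-pose: excision hole crosses the background")
  cutout <- scene$rgb
  for (k in 1:3) {
    ch <- cutout[, , k]
    ch[hole] <- background[k]
    cutout[, , k] <- ch
  }

  structure(list(intact_photo = scene$rgb, cutout_photo = cutout,
                 block_photo = block_photo, true_pose = pose,
                 block_to_slice = block_to_slice,
                 background_color = background,
                 foreground_mask = scene$fg, hole_mask = hole,
                 wm_mask = scene$wm, seed = seed),
            class = "phantom_slice_pair")
}

#' @export
print.phantom_slice_pair <- function(x, ...) {
  cat(sprintf("phantom_slice_pair: %d x %d photo, %d x %d block, pose %.1f deg (%.1f, %.1f) px\n",
              nrow(x$foreground_mask), ncol(x$foreground_mask),
              dim(x$block_photo)[1], dim(x$block_photo)[2],
              x$true_pose$angle, x$true_pose$translation[1],
              x$true_pose$translation[2]))
  invisible(x)
}
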