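# Volume-level phantom for the photograph-mediated registration chain: a
# 3-D MR-like volume with white-matter structures whose in-plane
# geometry changes with depth, cut along a known curvilinear surface to
# produce the slice photograph; an excised block under a known rigid
# pose; and a histology section derived from the block under a known
# affine shrinkage plus smooth deformation and a monotone
# contrast remap. Every stage of the chain has exact ground truth.

#' Generate the MR volume phantom with a known cutting surface
#'
#' The volume contains several cone-like white-matter structures inside
#' a grey-matter ellipse; their in-plane boundaries move with depth, so
#' boundary-based costs constrain the cutting surface everywhere in the
#' tissue. The true cut is a quadratic height field over the mid-plane.
#'
#' @param seed integer seed.
#' @param dims volume dimensions (default c(144, 144, 24)).
#' @param surface_amplitude peak-to-centre offset of the true cut,
#'   voxels (default 2.5).
#' @param n_structures white-matter cones (default 4).
#' @return list of class `volume_phantom`: `volume`, `surface`
#'   ([curvilinear_surface()] of the true cut), `slice_raster` (truth
#'   resample along it), `foreground` (in-plane tissue mask),
#'   `gm_value`, `wm_value`.
#' @export
make_mr_volume_phantom <- function(seed, dims = c(144L, 144L, 24L),
                                   surface_amplitude = 2.5,
                                   n_structures = 4) {
  set.seed(as.integer(seed))
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  z0 <- floor(nz / 2)
  g <- expand_grid_3d(dims)
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  rfg <- sqrt(((g$x - cx) / (0.40 * nx))^2 + ((g$y - cy) / (0.42 * ny))^2)
  fg3 <- rfg < 1
  vol <- ifelse(fg3, 0.45, 0.05)
  # cone-like WM structures: centre, base radius, radial growth per z
  ang <- stats::runif(n_structures, 0, 2 * pi)
  rad <- stats::runif(n_structures, 0.16, 0.30) * nx / 2
  ctr_r <- stats::runif(n_structures, 0.25, 0.6)
  slope <- stats::runif(n_structures, 0.6, 1.2) *
    sample(c(-1, 1), n_structures, replace = TRUE)
  for (i in seq_len(n_structures)) {
    bx <- cx + ctr_r[i] * 0.40 * nx * cos(ang[i])
    by <- cy + ctr_r[i] * 0.42 * ny * sin(ang[i])
    rr <- sqrt((g$x - bx)^2 + (g$y - by)^2)
    wm <- fg3 & (rr < rad[i] + slope[i] * (g$z - z0))
    vol[wm] <- 0.85
  }
  vol <- vol + 0.02 * smooth_noise_field(dims, 3, seed + 7L)
  vol <- gauss_smooth(vol, 0.8)

  gu <- pixel_grid(nx, ny)
  h <- surface_amplitude *
    (((gu$r - cx) / cx)^2 + ((gu$c - cy) / cy)^2 - 0.6)
  h <- clamp(h, -surface_amplitude, surface_amplitude)
  surf <- curvilinear_surface(c(0, 0, z0), c(1, 0, 0), c(0, 1, 0),
                              c(0, 0, 1), nx, ny, h,
                              max_offset = max(5, surface_amplitude))
  rs <- resample_along_surface(vol, surf)
  fg2 <- matrix(rfg[, , z0 + 1] < 1, nx, ny)
  structure(list(volume = vol, surface = surf, slice_raster = rs$raster,
                 foreground = fg2, gm_value = 0.45, wm_value = 0.85,
                 seed = seed),
            class = "volume_phantom")
}

# Luminance raster -> tissue-tinted RGB photo on a blue background.
raster_to_photo <- function(raster, foreground,
                            background = phantom_background_blue()) {
  tint <- c(1.00, 0.88, 0.80)
  out <- array(0, c(dim(raster), 3))
  for (k in 1:3)
    out[, , k] <- ifelse(foreground, clamp(raster * tint[k], 0, 1),
                         background[k])
  out
}

#' Generate the full registration-chain phantom
#'
#' Chains every stage with ground truth: the MR volume and true cutting
#' surface from [make_mr_volume_phantom()]; the slice photograph (the
#' true resampled slice, tissue-tinted on blue, under a known small
#' in-plane rigid offset `photo_pose`); cut-out and block photographs
#' under a known insertion pose; and a histology image at
#' `hist_factor`-times photograph resolution, derived from the block
#' face by a known affine shrinkage, a known smooth deformation and a
#' monotone contrast inversion. Seeded landmarks in the block frame
#' carry their true positions in every frame.
#'
#' @param seed integer seed.
#' @param dims volume dimensions.
#' @param block_dims block photograph size, px.
#' @param pose block insertion perturbation ([rigid2d()], about the
#'   block centre).
#' @param photo_pose true photo-to-slice-grid rigid offset.
#' @param shrink histology affine scale (default 0.9, paraffin
#'   shrinkage).
#' @param warp_amplitude histology deformation, px (default 3).
#' @param hist_factor histology-to-photo resolution ratio (default 4).
#' @param n_landmarks seeded evaluation landmarks (default 25).
#' @return list of class `registration_phantom` with the volume phantom
#'   fields plus `intact_photo`, `cutout_photo`, `block_photo`,
#'   `block_to_photo` (truth pose), `photo_to_grid` (truth rigid),
#'   `histology` (full-resolution image), `hist_affine` (truth
#'   block -> hist-sub affine), `hist_disp` (truth pull-back field on
#'   the hist-sub grid), `landmarks` (list with per-frame truth
#'   coordinates), `hist_factor`.
#' @export
make_registration_phantom <- function(seed, dims = c(144L, 144L, 24L),
                                      block_dims = c(56L, 56L),
                                      pose = rigid2d(7, c(5, 3)),
                                      photo_pose = rigid2d(1.5, c(3, -2)),
                                      shrink = 0.9, warp_amplitude = 3,
                                      hist_factor = 4L,
                                      n_landmarks = 25) {
  vp <- make_mr_volume_phantom(seed, dims)
  nr <- dims[1]; nc <- dims[2]
  # Photograph: true slice raster under the inverse photo pose, so the
  # true map photo px -> slice grid px equals photo_pose.
  photo_lum <- warp_image(vp$slice_raster, invert_transform(photo_pose),
                          pad = 0.05)
  photo_fg <- warp_image(vp$foreground * 1, invert_transform(photo_pose),
                         pad = 0) > 0.5
  intact <- raster_to_photo(photo_lum, photo_fg)

  # Block placement inside the photo foreground (centred on the largest
  # WM structure visible in the photo).
  bh <- block_dims[1]; bw <- block_dims[2]
  wm2 <- photo_fg & (photo_lum > 0.65)
  wmi <- which(wm2, arr.ind = TRUE)
  ctr <- if (nrow(wmi)) round(colMeans(wmi)) else round(c(nr, nc) / 2)
  off <- c(ctr[1] - 1 - floor(bh / 2), ctr[2] - 1 - floor(bw / 2))
  block_to_photo <- rigid2d(pose$angle, off + pose$translation,
                            centre = c((bh - 1) / 2, (bw - 1) / 2))
  bg <- pixel_grid(bh, bw)
  src <- apply_transform(block_to_photo,
                         cbind(as.vector(bg$r), as.vector(bg$c)))
  block_photo <- array(0, c(bh, bw, 3))
  for (k in 1:3)
    block_photo[, , k] <- matrix(bilinear_sample(intact[, , k], src), bh, bw)
  ig <- pixel_grid(nr, nc)
  back <- apply_transform(invert_transform(block_to_photo),
                          cbind(as.vector(ig$r), as.vector(ig$c)))
  hole <- matrix(back[, 1] >= 0.5 & back[, 1] <= bh - 1.5 &
                   back[, 2] >= 0.5 & back[, 2] <= bw - 1.5, nr, nc)
  cutout <- intact
  bgc <- phantom_background_blue()
  for (k in 1:3) {
    ch <- cutout[, , k]; ch[hole] <- bgc[k]; cutout[, , k] <- ch
  }

  # Histology: block luminance -> affine shrink -> smooth deformation ->
  # monotone contrast inversion; generated at hist-sub resolution then
  # carried to full resolution.
  block_lum <- luminance(block_photo)
  bctr <- c((bh - 1) / 2, (bw - 1) / 2)
  S <- affine2d(shrink * diag(2), bctr * (1 - shrink))  # block -> hist-sub
  histo_aff <- warp_image(block_lum, S, pad = block_lum[1, 1])
  if (warp_amplitude > 0) {
    vr <- smooth_noise_field(block_dims, bh / 9, seed + 301L)
    vc <- smooth_noise_field(block_dims, bh / 9, seed + 402L)
    mx <- max(sqrt(vr^2 + vc^2))
    vr <- vr * warp_amplitude / mx; vc <- vc * warp_amplitude / mx
    while (min_jacobian_det(vr, vc) <= 0.05) { vr <- vr * 0.8; vc <- vc * 0.8 }
  } else {
    vr <- matrix(0, bh, bw); vc <- matrix(0, bh, bw)
  }
  hist_sub <- displace_image(histo_aff, vr, vc)
  hist_sub <- clamp(0.95 - 0.78 * hist_sub^1.1, 0, 1)   # modality remap
  f <- as.integer(hist_factor)
  hg <- pixel_grid(bh * f, bw * f)
  hist_full <- matrix(bilinear_sample(
    hist_sub, cbind((as.vector(hg$r) - (f - 1) / 2) / f,
                    (as.vector(hg$c) - (f - 1) / 2) / f)), bh * f, bw * f)

  # Landmarks in the block-frame interior with truth in every frame.
  set.seed(as.integer(seed) + 77L)
  lb <- cbind(stats::runif(n_landmarks, bh * 0.2, bh * 0.8),
              stats::runif(n_landmarks, bw * 0.2, bw * 0.8))
  vinv <- invert_displacement(list(r = vr, c = vc))
  # forward block -> hist-sub: y = (id + v)^-1 (S(p))
  sp <- apply_transform(S, lb)
  l_hist_sub <- sp + cbind(bilinear_sample(vinv$r, sp),
                           bilinear_sample(vinv$c, sp))
  l_hist_full <- l_hist_sub * f + (f - 1) / 2
  l_photo <- apply_transform(block_to_photo, lb)
  l_grid <- apply_transform(photo_pose, l_photo)
  l_mr <- surface_points(vp$surface, l_grid[, 1], l_grid[, 2])

  structure(c(unclass(vp),
              list(intact_photo = intact, cutout_photo = cutout,
                   block_photo = block_photo,
                   block_to_photo = block_to_photo,
                   photo_to_grid = photo_pose,
                   photo_foreground = photo_fg,
                   histology = hist_full,
                   hist_affine = S,
                   hist_disp = list(r = vr, c = vc),
                   hist_factor = f,
                   landmarks = list(block = lb, hist_sub = l_hist_sub,
                                    hist_full = l_hist_full,
                                    photo = l_photo, grid = l_grid,
                                    mr = l_mr))),
            class = "registration_phantom")
}
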