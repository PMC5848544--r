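# Quantitative susceptibility mapping chain: Laplacian phase unwrapping,
# V-SHARP background-field removal, and thresholded k-space dipole
# inversion (TKD), plus the multi-echo field-map fit feeding it.
#
# All spectral operations use the FFT with B0 along the volume's third
# axis; the dipole kernel's k = 0 term is set to 0.

# Unit dipole kernel in k-space on the array's own grid:
# D(k) = 1/3 - kz^2/|k|^2, D(0) = 0.
dipole_kernel <- function(dims) {
  f <- function(n) {
    k <- 0:(n - 1)
    ifelse(k > n / 2, k - n, k) / n
  }
  kx <- f(dims[1]); ky <- f(dims[2]); kz <- f(dims[3])
  KX2 <- array(rep(kx^2, times = dims[2] * dims[3]), dims)
  KY2 <- array(rep(rep(ky^2, each = dims[1]), times = dims[3]), dims)
  KZ2 <- array(rep(kz^2, each = dims[1] * dims[2]), dims)
  k2 <- KX2 + KY2 + KZ2
  D <- 1 / 3 - KZ2 / k2
  D[k2 == 0] <- 0
  D
}

fft3 <- function(x) stats::fft(x)
ifft3 <- function(x) Re(stats::fft(x, inverse = TRUE)) / length(x)

# Forward field (same units as chi) of a susceptibility distribution.
dipole_forward_field <- function(chi) {
  D <- dipole_kernel(dim(chi))
  ifft3(fft3(chi) * D)
}

# Even (mirror) extension of a 3-D array to twice the size per axis, so
# a periodic FFT Poisson solve satisfies Neumann conditions.
mirror_extend <- function(x) {
  d <- dim(x)
  out <- array(0, 2 * d)
  ix <- c(seq_len(d[1]), rev(seq_len(d[1])))
  iy <- c(seq_len(d[2]), rev(seq_len(d[2])))
  iz <- c(seq_len(d[3]), rev(seq_len(d[3])))
  out[] <- x[ix, iy, iz]
  out
}

# Spectral Laplacian symbol -(2 pi k / n)^2 summed over axes, on a grid
# of dims d (periodic; applied on the mirrored domain where periodic =
# Neumann).
laplace_symbol <- function(d) {
  e <- function(n) {
    k <- 0:(n - 1)
    k <- ifelse(k > n / 2, k - n, k)
    -(2 * pi * k / n)^2
  }
  ex <- array(rep(e(d[1]), times = d[2] * d[3]), d)
  ey <- array(rep(rep(e(d[2]), each = d[1]), times = d[3]), d)
  ez <- array(rep(e(d[3]), each = d[1] * d[2]), d)
  ex + ey + ez
}

spectral_laplacian <- function(x) {
  lam <- laplace_symbol(dim(x))
  ifft3(fft3(x) * lam)
}

#' Laplacian phase unwrapping
#'
#' Solves `lap psi = cos(phi) lap sin(phi) - sin(phi) lap cos(phi)` with
#' an FFT Poisson solve (mirror extension, hence Neumann boundaries).
#' The result is harmonically consistent with the input: away from the
#' boundary, `wrap(psi)` matches `wrap(phi)`. The unwrapped phase is
#' defined up to an additive constant; the mean over the volume is
#' removed.
#'
#' @param wrapped_phase 3-D array of phase in (-pi, pi].
#' @return 3-D array of unwrapped phase (zero mean).
#' @export
laplacian_unwrap <- function(wrapped_phase) {
  if (length(dim(wrapped_phase)) != 3) stop("laplacian_unwrap needs a 3-D array")
  s <- mirror_extend(sin(wrapped_phase))
  c <- mirror_extend(cos(wrapped_phase))
  rhs <- c * spectral_laplacian(s) - s * spectral_laplacian(c)
  lam <- laplace_symbol(dim(rhs))
  F <- fft3(rhs) / ifelse(lam == 0, 1, lam)
  F[lam == 0] <- 0
  psi_ext <- ifft3(F)
  d <- dim(wrapped_phase)
  psi <- psi_ext[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]
  psi - mean(psi)
}

# Normalised spherical kernel of radius r (voxels) and its k-space
# transform, centred for FFT convolution.
smv_kernel_fft <- function(dims, radius) {
  g <- expand_grid_3d(dims)
  f <- function(x, n) ifelse(x > n / 2, x - n, x)
  dx <- f(g$x, dims[1]); dy <- f(g$y, dims[2]); dz <- f(g$z, dims[3])
  k <- (dx^2 + dy^2 + dz^2) <= radius^2
  k <- k / sum(k)
  fft3(k)
}

# Binary erosion of a mask by a spherical structuring element (FFT
# convolution with the sphere; kept where the sphere fits entirely).
erode_sphere <- function(mask, radius) {
  K <- smv_kernel_fft(dim(mask), radius)
  conv <- ifft3(fft3(mask * 1) * K)
  conv > 1 - 1e-9
}

#' V-SHARP background-field removal
#'
#' Variable-radius sophisticated harmonic artefact reduction: the
#' spherical-mean-value (SMV) high-pass `(delta - S_r) * field` removes
#' any component harmonic inside the mask; toward the mask edge the
#' radius shrinks through `radii` so less brain is lost. The remaining
#' deconvolution `1/(1 - S)` is inverted with the largest-radius kernel
#' (the one applied over the mask interior) under a truncated-SVD
#' threshold. Returns the tissue field inside the mask eroded by the
#' largest radius.
#'
#' @param unwrapped 3-D array, unwrapped field (any linear unit).
#' @param mask logical 3-D array of the reliable-phase region.
#' @param radii decreasing kernel radii, voxels (default `6:1`).
#' @param tsvd_threshold truncation threshold for the deconvolution
#'   (default 0.05).
#' @return list: `tissue_field` (masked array), `mask` (eroded mask).
#' @export
vsharp_filter <- function(unwrapped, mask, radii = 6:1,
                          tsvd_threshold = 0.05) {
  if (is.unsorted(rev(radii))) stop("radii must be decreasing")
  if (!any(mask)) stop("empty mask")
  d <- dim(unwrapped)
  er_max <- erode_sphere(mask, max(radii))
  if (!any(er_max)) stop("mask smaller than the largest SMV kernel")
  Ffield <- fft3(unwrapped * mask)
  filtered <- array(0, d)
  assigned <- array(FALSE, d)
  K_large <- NULL
  for (r in radii) {
    K <- smv_kernel_fft(d, r)
    if (is.null(K_large)) K_large <- K   # first = largest radius
    er <- erode_sphere(mask, r)
    hp <- unwrapped - ifft3(Ffield * K)
    sel <- er & !assigned
    filtered[sel] <- hp[sel]
    assigned <- assigned | er
  }
  # Deconvolve the (1 - SMV) operation with the interior (largest) kernel.
  denom <- 1 - Re(K_large)
  Ff <- fft3(filtered * assigned)
  inv <- ifelse(abs(denom) > tsvd_threshold, 1 / denom, 0)
  tissue <- ifft3(Ff * inv)
  tissue[!er_max] <- 0
  list(tissue_field = tissue, mask = er_max)
}

#' Thresholded k-space dipole inversion (TKD)
#'
#' Inverts the dipole convolution `field = D * chi` by k-space division
#' with the kernel magnitude floored at `threshold`:
#' `chi(k) = F(field)/D` where `|D| > threshold`, else
#' `sign(D) F(field)/threshold`. The result is referenced to zero mean
#' over the mask. Plain TKD systematically underestimates
#' susceptibility (modes near the dipole zero cone are attenuated); by
#' default the standard point-spread amplitude correction is applied:
#' the map is scaled by the reciprocal of the mean of `D * D_inv` over
#' k-space, the central value of the reconstruction point-spread
#' function. The default threshold of 0.19 is the usual compromise.
#'
#' @param tissue_field 3-D array, background-free field in ppm.
#' @param mask logical 3-D array; the susceptibility reference region.
#' @param threshold kernel floor, in (0, 2/3).
#' @param correct_underestimation apply the PSF amplitude correction
#'   (default TRUE).
#' @return [parameter_map()] of susceptibility (ppm) inside `mask`;
#'   diagnostics carry the correction factor used.
#' @export
dipole_invert <- function(tissue_field, mask, threshold = 0.19,
                          correct_underestimation = TRUE) {
  if (!(threshold > 0 && threshold < 2 / 3))
    stop("threshold must lie in (0, 2/3)")
  D <- dipole_kernel(dim(tissue_field))
  sgn <- ifelse(D >= 0, 1, -1)
  Dinv <- ifelse(abs(D) > threshold, 1 / D, sgn / threshold)
  Dinv[D == 0] <- 1 / threshold
  chi <- ifft3(fft3(tissue_field) * Dinv)
  fac <- if (correct_underestimation) 1 / mean(D * Dinv) else 1
  chi <- chi * fac
  chi <- chi - mean(chi[mask])
  parameter_map(chi, mask, "ppm",
                diagnostics = list(psf_correction = fac))
}

#' Field map from multi-echo phase
#'
#' Unwraps each echo's phase (Laplacian method for 3-D input; the
#' 2-pi-consistent temporal ramp is then resolved per voxel) and fits a
#' weighted straight line of phase against TE; the slope over 2 pi is
#' the off-resonance frequency in kHz for TE in ms, returned in Hz.
#'
#' @param phase_series [acq_series()] of wrapped phase volumes (TE ms).
#' @param weights optional per-echo weights (default equal).
#' @param unwrap `"temporal"` (default; per-voxel unwrapping along TE,
#'   exact when inter-echo phase steps stay below pi) or `"laplacian"`
#'   for spatial unwrapping of each echo, with the additive constant
#'   restored by circular-mean matching against the wrapped input.
#' @return list: `df_hz` [parameter_map()], `phi0` map (radians).
#' @export
fieldmap_from_multiecho <- function(phase_series, weights = NULL,
                                    unwrap = c("temporal", "laplacian")) {
  unwrap <- match.arg(unwrap)
  stopifnot(inherits(phase_series, "acq_series"))
  te <- as.numeric(phase_series$params)
  if (length(te) < 2) stop("need >= 2 echoes")
  d <- phase_series$dims
  n <- prod(d)
  P <- vapply(phase_series$volumes, as.vector, numeric(n))
  if (unwrap == "laplacian" && length(d) == 3 && d[3] > 2) {
    P <- vapply(phase_series$volumes, function(v) {
      psi <- laplacian_unwrap(v)
      delta <- v - psi
      psi <- psi + atan2(mean(sin(delta)), mean(cos(delta)))
      as.vector(psi)
    }, numeric(n))
    # resolve any residual global 2 pi offset between adjacent echoes
    for (j in seq_along(te)[-1]) {
      k <- round(stats::median(
        P[, j] - P[, j - 1] - wrap_phase(P[, j] - P[, j - 1])) / (2 * pi))
      P[, j] <- P[, j] - 2 * pi * k
    }
  } else {
    # temporal unwrap relative to the first echo
    for (j in seq_along(te)[-1])
      P[, j] <- P[, j - 1] + as.vector(wrap_phase(P[, j] - P[, j - 1]))
  }
  w <- if (is.null(weights)) rep(1, length(te)) else weights
  sw <- sum(w); swx <- sum(w * te); swx2 <- sum(w * te^2)
  swy <- P %*% w
  swxy <- P %*% (w * te)
  denom <- sw * swx2 - swx^2
  slope <- (sw * swxy - swx * swy) / denom       # rad per ms
  phi0 <- (swy - slope * swx) / sw
  df <- array(as.vector(slope) / (2 * pi) * 1000, d)   # Hz
  list(df_hz = parameter_map(df, array(TRUE, d), "Hz"),
       phi0 = parameter_map(array(as.vector(phi0), d), array(TRUE, d), "rad"))
}

#' Full QSM chain: unwrap, V-SHARP, dipole inversion
#'
#' Convenience composition for multi-echo phase input: field map via
#' [fieldmap_from_multiecho()], conversion from Hz to ppm with the given
#' scanner constant, [vsharp_filter()] background removal and
#' [dipole_invert()].
#'
#' @param phase_series wrapped multi-echo phase [acq_series()] (TE ms).
#' @param mask logical 3-D array of reliable phase.
#' @param hz_per_ppm field scaling (42.576 * B0 in tesla; default 7 T).
#' @param radii,tsvd_threshold passed to [vsharp_filter()].
#' @param threshold passed to [dipole_invert()].
#' @return list: `chi` [parameter_map()] (ppm), `tissue_field_ppm`,
#'   `eroded_mask`, `df_hz`.
#' @export
qsm_chain <- function(phase_series, mask, hz_per_ppm = 42.576 * 7,
                      radii = 6:1, tsvd_threshold = 0.05,
                      threshold = 0.19, unwrap = "temporal") {
  fm <- fieldmap_from_multiecho(phase_series, unwrap = unwrap)
  field_ppm <- fm$df_hz$values / hz_per_ppm
  field_ppm[!is.finite(field_ppm)] <- 0
  vs <- vsharp_filter(field_ppm, mask, radii = radii,
                      tsvd_threshold = tsvd_threshold)
  chi <- dipole_invert(vs$tissue_field, vs$mask, threshold = threshold)
  list(chi = chi, tissue_field_ppm = vs$tissue_field,
       eroded_mask = vs$mask, df_hz = fm$df_hz)
}
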