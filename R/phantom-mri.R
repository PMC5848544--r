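# MR signal-stack phantoms: known parameter maps pushed through the
# forward signal models (inversion recovery, multi-echo spin echo,
# multi-echo gradient echo with off-resonance phase, diffusion tensor,
# and a susceptibility phantom with dipole-convolved field), optionally
# with Rician noise (Gaussian on real/imaginary channels).

#' Wrap phase into (-pi, pi]
#' @param x phase values (radians).
#' @return wrapped phase.
#' @export
wrap_phase <- function(x) {
  out <- atan2(sin(x), cos(x))
  out[out <= -pi] <- pi
  out
}

# Default acquisition parameter lists (7 T post mortem protocol values).
default_ti_list <- function() c(60, 120, 240, 480, 935)            # ms
default_te_t2 <- function() c(25, 38, 50, 63, 76)                  # ms
default_te_t2star <- function() c(2, 8.6, 15.2, 21.8, 28.4, 35)    # ms

# Six non-collinear unit gradient directions (classic dual-gradient set).
default_dwi_dirs <- function() {
  s <- 1 / sqrt(2)
  rbind(c(s, s, 0), c(s, -s, 0), c(0, s, s),
        c(0, s, -s), c(s, 0, s), c(-s, 0, s))
}

#' An acquisition series of co-registered volumes
#'
#' @param volumes list of numeric arrays on a common grid.
#' @param params per-volume acquisition parameter: numeric vector (TI or
#'   TE in ms) or, for DWI, a data.frame with columns `b` (s/mm^2) and
#'   `gx`, `gy`, `gz`.
#' @param kind tag: one of `ir_t1`, `me_t2`, `me_t2star`, `dwi`,
#'   `phase_cycled`, `qsm_phase`.
#' @param voxel_size voxel dimensions, mm.
#' @return object of class `acq_series`.
#' @export
acq_series <- function(volumes, params, kind, voxel_size = c(1, 1, 1)) {
  if (length(volumes) < 2) stop("an acquisition series needs >= 2 volumes")
  d1 <- dim(volumes[[1]])
  if (!all(vapply(volumes, function(v) identical(dim(v), d1), TRUE)))
    stop("grid mismatch: all volumes must share one grid")
  np <- if (is.data.frame(params)) nrow(params) else length(params)
  if (np != length(volumes)) stop("one parameter per volume required")
  structure(list(volumes = volumes, params = params, kind = kind,
                 voxel_size = voxel_size, dims = d1),
            class = "acq_series")
}

#' @export
print.acq_series <- function(x, ...) {
  cat(sprintf("acq_series '%s': %d volumes of %s\n", x$kind,
              length(x$volumes), paste(x$dims, collapse = " x ")))
  invisible(x)
}

# Smooth seeded parameter field in [lo, hi] over given dims.
param_field <- function(dims, lo, hi, seed, sigma_frac = 1 / 8) {
  n <- smooth_noise_field(dims, sigma = max(dims) * sigma_frac, seed = seed)
  n <- (n - min(n)) / (max(n) - min(n))
  lo + (hi - lo) * n
}

rician <- function(signal, sd) {
  if (sd <= 0) return(signal)
  sqrt((signal + stats::rnorm(length(signal), 0, sd))^2 +
         stats::rnorm(length(signal), 0, sd)^2)
}

#' Generate an MR signal-stack phantom
#'
#' Draws smooth seeded ground-truth parameter maps and evaluates the
#' noiseless forward model at the requested acquisition parameters;
#' optional Rician noise (Gaussian on real/imaginary channels) is added
#' on magnitude data. Forward models:
#' \itemize{
#' \item `ir_t1`: `S(TI) = |a + b exp(-TI/T1)|` with `a = S0`,
#'   `b = -2 S0`;
#' \item `me_t2`: `S(TE) = S0 exp(-TE/T2)`;
#' \item `me_t2star`: `S0 exp(-TE/T2*)` plus phase
#'   `phi(TE) = phi0 + 2 pi df TE`, wrapped;
#' \item `dwi`: `S = S0 exp(-b g' D g)` for a smooth prolate tensor
#'   field;
#' \item `qsm`: susceptibility map convolved with the unit dipole kernel
#'   (B0 along the third axis) to a field in ppm, scaled to Hz at 7 T,
#'   then multi-echo wrapped phase plus `T2*` magnitude decay.
#' }
#'
#' @param seed integer seed (bit-reproducible output).
#' @param kind one of `"ir_t1"`, `"me_t2"`, `"me_t2star"`, `"dwi"`,
#'   `"qsm"`.
#' @param params acquisition list: TI/TE vector (ms) or DWI data.frame
#'   (`b`, `gx`, `gy`, `gz`); defaults are the protocol lists above.
#' @param dims grid dimensions (length 2 or 3; promoted to 3-D).
#' @param noise_sd Rician channel noise SD (0 = noiseless, default).
#' @return list of class `signal_stack`: `series` ([acq_series()]),
#'   `ground_truth` (named list of parameter arrays), `mask`, and for
#'   `qsm` also `phase_series`, `field_ppm`, `b0_t` etc.
#' @export
make_signal_stack <- function(seed, kind = c("ir_t1", "me_t2", "me_t2star",
                                             "dwi", "qsm"),
                              params = NULL, dims = c(24L, 24L, 4L),
                              noise_sd = 0) {
  kind <- match.arg(kind)
  if (length(dims) == 2) dims <- c(dims, 1L)
  set.seed(as.integer(seed))
  gt <- list()
  gt$S0 <- param_field(dims, 800, 1200, seed + 10L)
  mask <- array(TRUE, dims)
  out <- switch(kind,
    ir_t1 = {
      p <- if (is.null(params)) default_ti_list() else params
      if (!length(p) || any(p <= 0)) stop("TI list must be non-empty and positive")
      gt$T1 <- param_field(dims, 400, 900, seed + 11L)
      gt$a <- gt$S0; gt$b <- -2 * gt$S0
      vols <- lapply(p, function(ti)
        rician(abs(gt$a + gt$b * exp(-ti / gt$T1)), noise_sd))
      list(series = acq_series(vols, p, "ir_t1"), ground_truth = gt)
    },
    me_t2 = {
      p <- if (is.null(params)) default_te_t2() else params
      if (!length(p) || any(p <= 0)) stop("TE list must be non-empty and positive")
      gt$T2 <- param_field(dims, 20, 80, seed + 11L)
      vols <- lapply(p, function(te) rician(gt$S0 * exp(-te / gt$T2), noise_sd))
      list(series = acq_series(vols, p, "me_t2"), ground_truth = gt)
    },
    me_t2star = {
      p <- if (is.null(params)) default_te_t2star() else params
      if (!length(p) || any(p <= 0)) stop("TE list must be non-empty and positive")
      gt$T2star <- param_field(dims, 15, 60, seed + 11L)
      gt$df_hz <- param_field(dims, -20, 20, seed + 12L)
      gt$phi0 <- param_field(dims, -1, 1, seed + 13L)
      vols <- lapply(p, function(te)
        rician(gt$S0 * exp(-te / gt$T2star), noise_sd))
      ph <- lapply(p, function(te)
        wrap_phase(gt$phi0 + 2 * pi * gt$df_hz * te / 1000))
      list(series = acq_series(vols, p, "me_t2star"),
           phase_series = acq_series(ph, p, "qsm_phase"), ground_truth = gt)
    },
    dwi = {
      p <- params
      if (is.null(p)) {
        dirs <- default_dwi_dirs()
        p <- data.frame(b = c(0, rep(1000, nrow(dirs))),
                        gx = c(0, dirs[, 1]), gy = c(0, dirs[, 2]),
                        gz = c(0, dirs[, 3]))
      }
      if (any(p$b < 0)) stop("b-values must be non-negative")
      # Smooth prolate tensor field: orientation varies smoothly in-plane.
      th <- param_field(dims, 0, pi / 2, seed + 11L)
      l1 <- param_field(dims, 1.2e-3, 1.8e-3, seed + 12L)
      l23 <- param_field(dims, 1.5e-4, 3.5e-4, seed + 13L)
      n <- prod(dims)
      Dt <- matrix(0, n, 6)  # xx, yy, zz, xy, xz, yz
      ct <- cos(as.vector(th)); st <- sin(as.vector(th))
      e1 <- cbind(ct, st, 0)
      l1v <- as.vector(l1); l23v <- as.vector(l23)
      Dt[, 1] <- l23v + (l1v - l23v) * e1[, 1]^2
      Dt[, 2] <- l23v + (l1v - l23v) * e1[, 2]^2
      Dt[, 3] <- l23v
      Dt[, 4] <- (l1v - l23v) * e1[, 1] * e1[, 2]
      gt$tensor <- Dt; gt$e1 <- e1
      gt$MD <- array((Dt[, 1] + Dt[, 2] + Dt[, 3]) / 3, dims)
      lam <- cbind(l1v, l23v, l23v)
      gt$FA <- array(fa_from_eigenvalues(lam), dims)
      vols <- lapply(seq_len(nrow(p)), function(i) {
        gvec <- c(p$gx[i], p$gy[i], p$gz[i])
        q <- Dt[, 1] * gvec[1]^2 + Dt[, 2] * gvec[2]^2 + Dt[, 3] * gvec[3]^2 +
          2 * (Dt[, 4] * gvec[1] * gvec[2] + Dt[, 5] * gvec[1] * gvec[3] +
                 Dt[, 6] * gvec[2] * gvec[3])
        array(rician(as.vector(gt$S0) * exp(-p$b[i] * q), noise_sd), dims)
      })
      list(series = acq_series(vols, p, "dwi"), ground_truth = gt)
    },
    qsm = {
      p <- if (is.null(params)) default_te_t2star() else params
      if (length(dims) != 3 || any(dims < 8)) stop("qsm phantom needs a 3-D grid")
      g <- expand_grid_3d(dims)
      ctr <- (dims - 1) / 2
      r2 <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2
      chi <- array(0, dims)
      chi[r2 < (min(dims) * 0.16)^2] <- 0.1           # ppm sphere
      mask <- array(r2 < (min(dims) * 0.42)^2, dims)  # tissue mask
      gt$chi <- chi
      field <- dipole_forward_field(chi)              # ppm, B0 along 3rd axis
      gt$field_ppm <- field
      hz_per_ppm <- 42.576 * 7                        # 1e6*gamma/2pi*B0*1e-6
      gt$T2star <- param_field(dims, 15, 60, seed + 11L)
      gt$phi0 <- param_field(dims, -1, 1, seed + 13L)
      mag <- lapply(p, function(te)
        array(rician(as.vector(gt$S0 * exp(-te / gt$T2star)), noise_sd), dims))
      ph <- lapply(p, function(te)
        wrap_phase(gt$phi0 + 2 * pi * hz_per_ppm * field * te / 1000))
      list(series = acq_series(mag, p, "me_t2star"),
           phase_series = acq_series(ph, p, "qsm_phase"),
           ground_truth = gt, hz_per_ppm = hz_per_ppm)
    })
  out$mask <- mask
  out$kind <- kind
  out$noise_sd <- noise_sd
  out$seed <- seed
  class(out) <- "signal_stack"
  out
}

#' @export
print.signal_stack <- function(x, ...) {
  cat(sprintf("signal_stack '%s': %d volumes, grid %s, noise sd %.3g\n",
              x$kind, length(x$series$volumes),
              paste(x$series$dims, collapse = " x "), x$noise_sd))
  invisible(x)
}

#' Generate a phase-cycled structural series with banding
#'
#' Balanced-SSFP-like phantom: a common anatomy modulated by a slowly
#' varying banding pattern whose phase differs per cycle, used to test
#' root-mean-square combination.
#'
#' @param seed integer seed.
#' @param cycles phase-cycling increments in degrees.
#' @param dims grid dimensions.
#' @return [acq_series()] of kind `phase_cycled` with attribute
#'   `anatomy` (the banding-free truth).
#' @export
make_phase_cycled_stack <- function(seed, cycles = c(0, 90, 180, 270),
                                    dims = c(48L, 48L, 1L)) {
  if (length(dims) == 2) dims <- c(dims, 1L)
  anatomy <- param_field(dims, 400, 1000, seed)
  g <- expand_grid_3d(dims)
  offres <- 2 * pi * 1.5 * g$x / dims[1]   # slowly varying off-resonance
  vols <- lapply(cycles, function(pc)
    anatomy * abs(sin((offres + pc * pi / 180) / 2) * 0.9 + 0.1))
  s <- acq_series(vols, cycles, "phase_cycled")
  attr(s, "anatomy") <- anatomy
  s
}

# 0-based voxel coordinate grids for a 3-D array.
expand_grid_3d <- function(dims) {
  list(x = array(rep(0:(dims[1] - 1), times = dims[2] * dims[3]), dims),
       y = array(rep(rep(0:(dims[2] - 1), each = dims[1]), times = dims[3]), dims),
       z = array(rep(0:(dims[3] - 1), each = dims[1] * dims[2]), dims))
}
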