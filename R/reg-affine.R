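# MIND-driven affine registration of the (sub-sampled) histology image
# to the block-face photograph: addresses tissue shrinkage and
# large-scale distortion before deformable refinement.

# Block-mean 2x downsample (for registration pyramids).
pyr_down <- function(m) {
  nr <- (nrow(m) %/% 2) * 2; nc <- (ncol(m) %/% 2) * 2
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  0.25 * (m[seq(1, nr, 2), seq(1, nc, 2)] + m[seq(2, nr, 2), seq(1, nc, 2)] +
            m[seq(1, nr, 2), seq(2, nc, 2)] + m[seq(2, nr, 2), seq(2, nc, 2)])
}

# Affine parameter vector (angle deg, log-scale r, log-scale c, shear,
# t_r, t_c) about a centre -> affine2d (maps fixed px -> moving px).
params_to_affine <- function(p, centre) {
  R <- rot2(p[1])
  S <- matrix(c(exp(p[2]), 0, p[4], exp(p[3])), 2, 2)
  A <- R %*% S
  affine2d(A, centre + p[5:6] - (A %*% centre)[, 1])
}

affine_to_params <- function(tf, centre) {
  A <- tf$A
  # QR-like decomposition: rotation x (scale + shear)
  ang <- atan2(A[2, 1], A[1, 1]) * 180 / pi
  R <- rot2(ang)
  S <- solve(R, A)
  c(ang, log(S[1, 1]), log(S[2, 2]), S[1, 2],
    (tf$b + (A %*% centre)[, 1]) - centre)
}

# Mean squared MIND distance between fixed and warped moving at one
# pyramid level; tf maps fixed px -> moving px.
affine_mind_cost <- function(p, centre, moving, fixed_mind, mask, mind_args) {
  tf <- tryCatch(params_to_affine(p, centre), error = function(e) NULL)
  if (is.null(tf)) return(1e6)
  warped <- warp_image(moving, invert_transform(tf), dims = dim(fixed_mind$descriptors)[1:2])
  wm <- do.call(compute_mind, c(list(warped), mind_args))
  mind_distance(fixed_mind, wm, mask = mask)
}

#' Affine registration on MIND descriptors
#'
#' Estimates the 6-parameter affine map from the fixed frame to the
#' moving frame (the pull-back used for resampling: positive scale
#' < 1 means the moving image is a shrunken copy of the fixed scene)
#' by minimising the mean squared MIND descriptor distance, coarse to
#' fine over an image pyramid with Nelder-Mead at each level. The
#' determinant is kept positive by construction (no reflections).
#'
#' @param moving,fixed numeric matrices (intensity images; descriptors
#'   are recomputed from the warped moving image at every evaluation).
#' @param init optional [rigid2d()] or [affine2d()] initial fixed->
#'   moving map (identity default).
#' @param levels pyramid levels, coarsest first (default 2: half and
#'   full resolution).
#' @param mask optional logical matrix on the fixed grid.
#' @param patch_radius,sigma MIND parameters (see [compute_mind()]).
#' @param maxit Nelder-Mead iteration cap per level.
#' @return list of class `affine_registration`: `transform`
#'   ([affine2d()], fixed px -> moving px), `cost`, `converged`.
#' @export
register_affine <- function(moving, fixed, init = NULL, levels = 2,
                            mask = NULL, patch_radius = 1, sigma = 0.5,
                            maxit = 300) {
  centre_full <- c((nrow(fixed) - 1) / 2, (ncol(fixed) - 1) / 2)
  tf0 <- if (is.null(init)) affine2d() else as_affine2d(init)
  p <- affine_to_params(tf0, centre_full)
  mind_args <- list(patch_radius = patch_radius, sigma = sigma)
  pyr_m <- list(moving); pyr_f <- list(fixed); pyr_k <- list(mask)
  for (l in seq_len(levels - 1)) {
    pyr_m <- c(list(pyr_down(pyr_m[[1]])), pyr_m)
    pyr_f <- c(list(pyr_down(pyr_f[[1]])), pyr_f)
    pyr_k <- c(list(if (is.null(mask)) NULL else
      pyr_down(pyr_k[[1]] * 1) > 0.5), pyr_k)
  }
  converged <- TRUE
  for (l in seq_len(levels)) {
    sc <- 2^(levels - l)
    mv <- pyr_m[[l]]; fx <- pyr_f[[l]]; mk <- pyr_k[[l]]
    ctr <- centre_full / sc
    fm <- do.call(compute_mind, c(list(fx), mind_args))
    # translations live in level pixels: scale them down/up
    pl <- p; pl[5:6] <- p[5:6] / sc
    cost_fn <- function(q) affine_mind_cost(q, ctr, mv, fm, mk, mind_args)
    op <- stats::optim(pl, cost_fn, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-9))
    # restart: Nelder-Mead simplexes collapse prematurely on plateaued
    # descriptor costs; a fresh simplex at the optimum recovers precision
    op <- stats::optim(op$par, cost_fn, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-9))
    if (op$convergence != 0) converged <- FALSE
    p <- op$par; p[5:6] <- p[5:6] * sc
  }
  list(transform = params_to_affine(p, centre_full), cost = op$value,
       converged = converged)
}
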