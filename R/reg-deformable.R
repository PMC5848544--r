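# Deformable registration on MIND descriptors: multichannel demons-style
# updates with Gaussian fluid (update) and diffusion (field) smoothing,
# coarse-to-fine over a pyramid, gradually compensating small-scale
# section distortions after affine pre-alignment.

# Central-difference gradients of a matrix (edge replicated).
grad2d <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gr <- (shift_edge(m, 1, 0) - shift_edge(m, -1, 0)) / 2
  gc <- (shift_edge(m, 0, 1) - shift_edge(m, 0, -1)) / 2
  list(r = gr, c = gc)
}

#' Deformable registration on MIND descriptors
#'
#' Estimates a dense displacement field `u` mapping the fixed frame into
#' the moving frame (pull-back: the registered moving image is
#' `moving[p + u(p)]`). Demons-style iterations: at each step the moving
#' image is warped by the current field, MIND descriptors of the warped
#' image are recomputed, and a force field is accumulated over
#' descriptor channels as `sum_k (F_k - M_k) grad M_k` normalised by
#' `sum_k |grad M_k|^2 + alpha^2 (F_k - M_k)^2`. The update is smoothed
#' with `sigma_update` (fluid regularisation), added, and the field
#' smoothed with `sigma_field` (diffusion regularisation). Runs coarse
#' to fine over a pyramid; iteration stops early when the descriptor
#' distance increases on three consecutive outer iterations (the best
#' field seen is returned).
#'
#' @param moving,fixed numeric matrices on a common grid.
#' @param init optional initial displacement (list `r`, `c`).
#' @param levels pyramid depth (default 3).
#' @param iterations outer iterations per level (default 30).
#' @param sigma_update,sigma_field Gaussian regularisation, px
#'   (defaults 2 and 1).
#' @param alpha demons normalisation constant (default 0.1).
#' @param step maximum per-iteration displacement, px (default 1.5).
#' @param patch_radius,sigma MIND parameters.
#' @param mask optional logical matrix (fixed frame) over which the
#'   distance is scored.
#' @return list of class `deformation_field`: `disp` (list `r`, `c`),
#'   `distance` (final mean MIND distance), `min_jacobian`,
#'   `diverged` flag.
#' @export
register_deformable <- function(moving, fixed, init = NULL, levels = 3,
                                iterations = 30, sigma_update = 2,
                                sigma_field = 1, alpha = 0.1, step = 1.5,
                                patch_radius = 1, sigma = 0.5,
                                mask = NULL) {
  mind_args <- list(patch_radius = patch_radius, sigma = sigma)
  pyr_m <- list(moving); pyr_f <- list(fixed); pyr_k <- list(mask)
  for (l in seq_len(levels - 1)) {
    if (min(dim(pyr_m[[1]])) < 32) break
    pyr_m <- c(list(pyr_down(pyr_m[[1]])), pyr_m)
    pyr_f <- c(list(pyr_down(pyr_f[[1]])), pyr_f)
    pyr_k <- c(list(if (is.null(mask)) NULL else
      pyr_down(pyr_k[[1]] * 1) > 0.5), pyr_k)
  }
  ur <- uc <- NULL
  diverged <- FALSE
  for (l in seq_along(pyr_m)) {
    mv <- pyr_m[[l]]; fx <- pyr_f[[l]]; mk <- pyr_k[[l]]
    d <- dim(fx)
    if (is.null(ur)) {
      ur <- matrix(0, d[1], d[2]); uc <- matrix(0, d[1], d[2])
    } else {
      # upsample previous level's field (displacements double)
      g <- pixel_grid(d[1], d[2])
      pts <- cbind(as.vector(g$r) / 2, as.vector(g$c) / 2)
      ur <- matrix(bilinear_sample(ur, pts) * 2, d[1], d[2])
      uc <- matrix(bilinear_sample(uc, pts) * 2, d[1], d[2])
    }
    fm <- do.call(compute_mind, c(list(fx), mind_args))$descriptors
    nch <- dim(fm)[3]
    best <- list(dist = Inf, ur = ur, uc = uc)
    rises <- 0
    for (it in seq_len(iterations)) {
      warped <- displace_image(mv, ur, uc)
      wm <- do.call(compute_mind, c(list(warped), mind_args))$descriptors
      dist <- if (is.null(mk)) mean((fm - wm)^2) else
        sum((fm - wm)^2 * array(mk, dim(fm))) / (sum(mk) * nch)
      if (dist < best$dist) {
        best <- list(dist = dist, ur = ur, uc = uc)
        rises <- 0
      } else {
        rises <- rises + 1
        if (rises >= 3) { diverged <- TRUE; break }
      }
      num_r <- num_c <- den <- matrix(0, d[1], d[2])
      for (k in seq_len(nch)) {
        dif <- fm[, , k] - wm[, , k]
        g <- grad2d(wm[, , k])
        num_r <- num_r + dif * g$r
        num_c <- num_c + dif * g$c
        den <- den + g$r^2 + g$c^2 + alpha^2 * dif^2
      }
      vr <- num_r / (den + 1e-12)
      vc <- num_c / (den + 1e-12)
      vr <- gauss_smooth(vr, sigma_update)
      vc <- gauss_smooth(vc, sigma_update)
      # cap the largest update at `step` pixels per iteration
      mx <- max(sqrt(vr^2 + vc^2))
      if (mx > step) { vr <- vr * (step / mx); vc <- vc * (step / mx) }
      ur <- gauss_smooth(ur + vr, sigma_field)
      uc <- gauss_smooth(uc + vc, sigma_field)
    }
    ur <- best$ur; uc <- best$uc
  }
  structure(list(disp = list(r = ur, c = uc), distance = best$dist,
                 min_jacobian = min_jacobian_det(ur, uc),
                 diverged = diverged,
                 sigma_update = sigma_update, sigma_field = sigma_field),
            class = "deformation_field")
}

#' Numerically invert a displacement field
#'
#' Fixed-point iteration for the field `v` with
#' `(id + v) o (id + u) = id` (both pull-back convention).
#'
#' @param disp list with `r`, `c` matrices.
#' @param iterations fixed-point iterations (default 20).
#' @return list with `r`, `c` of the inverse field.
#' @export
invert_displacement <- function(disp, iterations = 20) {
  ur <- disp$r; uc <- disp$c
  vr <- -ur; vc <- -uc
  for (i in seq_len(iterations)) {
    # v(p) = -u(p + v(p))
    vr_new <- -displace_image(ur, vr, vc)
    vc_new <- -displace_image(uc, vr, vc)
    vr <- vr_new; vc <- vc_new
  }
  list(r = vr, c = vc)
}
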