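# Histology section phantom: known per-stain concentration fields
# rendered through Beer-Lambert optical-density mixing, optionally after
# a known smooth deformation (section distortion) with simulated tears.

#' Generate a stained-section phantom
#'
#' Builds non-negative per-stain concentration fields (a broad nuclear
#' counterstain plus a patchy positive stain), renders them to RGB via
#' `OD = sum_s c_s v_s`, `I = I0 * 10^(-OD)`, and optionally applies a
#' known smooth deformation before rendering, emulating the distortions
#' of cutting sections from a block.
#'
#' The returned `rgb_image` is the deformed render: `rgb_image(x)`
#' renders `concentration(x + u(x))` where `u = true_deformation`
#' (pull-back convention). `reference_rgb` is the undeformed render, so
#' registering `reference_rgb` (moving) to `rgb_image` (fixed) should
#' recover `u`. The deformation always has strictly positive Jacobian
#' determinant (amplitude is reduced if the seeded field would fold).
#'
#' @param seed integer seed.
#' @param stains a [stain_vector_set()]; default published H-DAB vectors.
#' @param deformation_amplitude maximum displacement magnitude, px (>= 0).
#' @param dims image dimensions.
#' @param tear_fraction approximate fraction of tissue removed by
#'   simulated tears (0 disables, default).
#' @return list of class `histology_phantom`: `concentration_fields`
#'   (named list, undeformed truth), `rgb_image`, `reference_rgb`,
#'   `true_deformation` (list `r`, `c` displacement matrices),
#'   `tear_mask`, `tissue_mask`, `stains`, `min_jacobian`.
#' @export
make_histology_phantom <- function(seed, stains = stain_vectors_hdab(),
                                   deformation_amplitude = 0,
                                   dims = c(128L, 128L),
                                   tear_fraction = 0) {
  if (deformation_amplitude < 0) stop("deformation_amplitude must be >= 0")
  stopifnot(inherits(stains, "stain_vector_set"))
  nr <- dims[1]; nc <- dims[2]
  g <- pixel_grid(nr, nc)
  cr <- (nr - 1) / 2; cc <- (nc - 1) / 2
  n1 <- smooth_noise_field(dims, sigma = nr / 14, seed = seed)
  n2 <- smooth_noise_field(dims, sigma = nr / 32, seed = seed + 1L)
  tissue <- (((g$r - cr) / (0.46 * nr))^2 + ((g$c - cc) / (0.46 * nc))^2 +
               0.15 * n1) < 1
  # Counterstain: broad, gently varying; positive stain: patchy blobs.
  haem <- ifelse(tissue, clamp(0.45 + 0.18 * n1 + 0.08 * n2, 0, 2), 0)
  pos <- ifelse(tissue, clamp(0.9 * (n2 - 0.25), 0, 2)^1 +
                  0.6 * clamp(n1 - 0.6, 0, 2), 0)
  conc <- list(haem, pos)
  names(conc) <- stains$names[1:2]
  if (stains$n_stains == 3) {
    conc[[stains$names[3]]] <- matrix(0, nr, nc)
  }

  # Deformation: seeded smooth field scaled to the requested amplitude,
  # shrunk if necessary so min Jacobian determinant stays positive.
  if (deformation_amplitude > 0) {
    ur <- smooth_noise_field(dims, sigma = nr / 10, seed = seed + 101L)
    uc <- smooth_noise_field(dims, sigma = nr / 10, seed = seed + 202L)
    sc <- deformation_amplitude / max(sqrt(ur^2 + uc^2))
    ur <- ur * sc; uc <- uc * sc
    while (min_jacobian_det(ur, uc) <= 0.05) { ur <- ur * 0.8; uc <- uc * 0.8 }
  } else {
    ur <- matrix(0, nr, nc); uc <- matrix(0, nr, nc)
  }

  deform <- function(m) if (deformation_amplitude > 0)
    displace_image(m, ur, uc) else m
  conc_def <- lapply(conc, deform)

  tear <- matrix(FALSE, nr, nc)
  if (tear_fraction > 0) {
    set.seed(as.integer(seed) + 999L)
    target <- tear_fraction * sum(tissue)
    while (sum(tear) < target) {
      tr <- stats::runif(1, 0.2, 0.8) * nr
      tc <- stats::runif(1, 0.2, 0.8) * nc
      a <- stats::runif(1, 2, 0.06 * nr); b <- stats::runif(1, 2, 0.06 * nc)
      tear <- tear | (((g$r - tr) / a)^2 + ((g$c - tc) / b)^2 < 1)
    }
    tear <- tear & tissue
    conc_def <- lapply(conc_def, function(m) { m[tear] <- 0; m })
  }

  rgb <- render_stains(conc_def, stains)
  structure(list(concentration_fields = conc, rgb_image = rgb,
                 reference_rgb = render_stains(conc, stains),
                 true_deformation = list(r = ur, c = uc),
                 tear_mask = tear, tissue_mask = tissue, stains = stains,
                 min_jacobian = min_jacobian_det(ur, uc), seed = seed),
            class = "histology_phantom")
}

#' @export
print.histology_phantom <- function(x, ...) {
  cat(sprintf("histology_phantom: %d x %d px, stains %s, max |u| = %.2f px\n",
              nrow(x$rgb_image), ncol(x$rgb_image),
              paste(names(x$concentration_fields), collapse = "/"),
              max(sqrt(x$true_deformation$r^2 + x$true_deformation$c^2))))
  invisible(x)
}
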