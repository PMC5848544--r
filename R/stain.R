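# Colour deconvolution: Beer-Lambert optical densities and unmixing of an
# RGB brightfield image into per-stain concentration maps via calibrated
# stain vectors.

#' Construct a stain vector set
#'
#' Each stain is a unit-norm, non-negative optical-density direction in
#' RGB space. When two stains are given, a residual third vector is
#' completed orthogonally (cross product, flipped non-negative) so the
#' 3 x 3 unmixing system is invertible.
#'
#' @param vectors 3 x n matrix (columns = stains, rows = R, G, B optical
#'   densities) or a list of length-3 vectors.
#' @param names stain labels, one per column.
#' @param white_reference RGB triple of the unstained background
#'   intensity, strictly positive; default `c(1, 1, 1)` for images scaled
#'   to [0, 1].
#' @return object of class `stain_vector_set` with elements `names`,
#'   `vectors` (3 x 3, residual column completed and flagged),
#'   `n_stains`, `white_reference`.
#' @export
stain_vector_set <- function(vectors, names, white_reference = c(1, 1, 1)) {
  if (is.list(vectors)) vectors <- do.call(cbind, vectors)
  vectors <- matrix(as.numeric(vectors), nrow = 3)
  n <- ncol(vectors)
  if (n < 1 || n > 3) stop("need 1 to 3 stain vectors")
  if (length(names) != n) stop("one name per stain vector")
  if (any(vectors < -1e-12)) stop("calibration error: stain vectors must be non-negative")
  nrm <- sqrt(colSums(vectors^2))
  if (any(nrm < 1e-8)) stop("calibration error: near-zero stain vector")
  V <- sweep(vectors, 2, nrm, `/`)
  if (n == 3 && abs(det(V)) < 1e-8)
    stop("calibration error: stain vectors are linearly dependent")
  if (n == 2) {
    r <- c(V[2, 1] * V[3, 2] - V[3, 1] * V[2, 2],
           V[3, 1] * V[1, 2] - V[1, 1] * V[3, 2],
           V[1, 1] * V[2, 2] - V[2, 1] * V[1, 2])
    if (sqrt(sum(r^2)) < 1e-8)
      stop("calibration error: stain vectors are linearly dependent")
    r <- r / sqrt(sum(r^2))
    if (sum(r) < 0) r <- -r
    V <- cbind(V, r)
    names <- c(names, "residual")
  }
  if (n == 1) {
    # orthonormal completion of the single stain direction
    Q <- qr.Q(qr(cbind(V, diag(3))))[, 2:3]
    for (j in 1:2) if (sum(Q[, j]) < 0) Q[, j] <- -Q[, j]
    V <- cbind(V, Q)
    names <- c(names, "residual1", "residual2")
  }
  if (any(white_reference <= 0)) stop("white reference must be strictly positive")
  structure(list(names = names, vectors = V, n_stains = n,
                 white_reference = as.numeric(white_reference)),
            class = "stain_vector_set")
}

#' Ruifrok-Johnston haematoxylin / DAB stain vectors
#'
#' The published H-DAB optical-density directions, the standard default
#' when no slide-specific calibration is available.
#' @param white_reference RGB white point (default unit).
#' @return a [stain_vector_set()] with stains `haematoxylin` and `dab`.
#' @export
stain_vectors_hdab <- function(white_reference = c(1, 1, 1)) {
  stain_vector_set(
    vectors = cbind(c(0.650, 0.704, 0.286), c(0.269, 0.568, 0.778)),
    names = c("haematoxylin", "dab"),
    white_reference = white_reference)
}

#' @export
print.stain_vector_set <- function(x, ...) {
  cat(sprintf("stain_vector_set: %d calibrated stain(s)\n", x$n_stains))
  m <- x$vectors; colnames(m) <- x$names; rownames(m) <- c("R", "G", "B")
  print(round(m, 4))
  invisible(x)
}

#' RGB image to optical densities
#'
#' Beer-Lambert transform `OD_c = -log10(I_c / I0_c)` per channel.
#' Intensities are clipped below at `I0 / 10^od_cap` before the log so OD
#' is finite and bounded.
#'
#' @param image RGB array `[nr, nc, 3]`.
#' @param white_reference RGB triple, strictly positive.
#' @param od_cap maximum representable OD (default 3, i.e. intensities
#'   clipped at `I0/1000`).
#' @return `[nr, nc, 3]` array of optical densities (>= 0).
#' @export
rgb_to_od <- function(image, white_reference = c(1, 1, 1), od_cap = 3) {
  if (any(white_reference <= 0)) stop("white reference must be strictly positive")
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("image must be an [nr, nc, 3] RGB array")
  od <- array(0, dim(image))
  for (k in 1:3) {
    i <- pmax(image[, , k], white_reference[k] * 10^(-od_cap))
    od[, , k] <- pmax(-log10(i / white_reference[k]), 0)
  }
  od
}

#' Optical densities back to RGB
#'
#' Inverse of [rgb_to_od()]: `I_c = I0_c * 10^(-OD_c)`.
#' @param od `[nr, nc, 3]` OD array.
#' @param white_reference RGB white point.
#' @return RGB array.
#' @export
od_to_rgb <- function(od, white_reference = c(1, 1, 1)) {
  out <- array(0, dim(od))
  for (k in 1:3) out[, , k] <- white_reference[k] * 10^(-od[, , k])
  out
}

#' Calibrate stain vectors from single-stain samples
#'
#' For each sample image dominated by one stain, takes the principal
#' direction of its OD pixels (first right singular vector, flipped
#' non-negative) as that stain's colour vector.
#'
#' @param samples list of OD arrays (`[nr, nc, 3]`), one per stain.
#' @param names stain labels in the same order.
#' @param white_reference white point recorded in the returned set.
#' @param min_od pixels with total OD below this are ignored as
#'   background (default 0.05).
#' @return a [stain_vector_set()] in sample order.
#' @export
calibrate_stain_vectors <- function(samples, names,
                                    white_reference = c(1, 1, 1),
                                    min_od = 0.05) {
  stopifnot(length(samples) == length(names))
  vecs <- vapply(samples, function(od) {
    m <- cbind(as.vector(od[, , 1]), as.vector(od[, , 2]), as.vector(od[, , 3]))
    m <- m[rowSums(m) > min_od, , drop = FALSE]
    if (nrow(m) < 3) stop("calibration error: sample has no stained pixels above min_od")
    sv <- svd(m, nu = 0, nv = 1)
    v <- sv$v[, 1]
    if (sum(v) < 0) v <- -v
    if (any(v < -1e-6)) stop("calibration error: principal OD direction not non-negative")
    pmax(v, 0)
  }, numeric(3))
  stain_vector_set(vecs, names, white_reference = white_reference)
}

#' Unmix optical densities into per-stain concentrations
#'
#' Per pixel solves `OD = V c` with the inverse of the completed 3 x 3
#' stain matrix. Negative concentrations are clamped to zero and the
#' clamped fraction reported.
#'
#' @param od `[nr, nc, 3]` OD array (see [rgb_to_od()]).
#' @param stains a [stain_vector_set()].
#' @return list of class `stain_concentrations`: `concentrations` (named
#'   list of matrices, one per stain incl. any residual channel),
#'   `clamp_fraction` (fraction of pixel-channels clamped at 0).
#' @export
deconvolve <- function(od, stains) {
  stopifnot(inherits(stains, "stain_vector_set"))
  V <- stains$vectors
  if (abs(det(V)) < 1e-10) stop("singular stain matrix")
  Vi <- solve(V)
  nr <- dim(od)[1]; nc <- dim(od)[2]
  M <- cbind(as.vector(od[, , 1]), as.vector(od[, , 2]), as.vector(od[, , 3]))
  C <- M %*% t(Vi)
  clamp_fraction <- mean(C < -1e-12)
  C[C < 0] <- 0
  conc <- lapply(seq_len(ncol(V)), function(j) matrix(C[, j], nr, nc))
  names(conc) <- colnames(stains$vectors) <- NULL
  names(conc) <- stains$names
  structure(list(concentrations = conc, clamp_fraction = clamp_fraction,
                 stains = stains$names[seq_len(stains$n_stains)]),
            class = "stain_concentrations")
}

# Forward Beer-Lambert render: concentrations (named list of matrices,
# order matching the stain set) -> RGB image.
render_stains <- function(concentrations, stains) {
  V <- stains$vectors
  nr <- nrow(concentrations[[1]]); nc <- ncol(concentrations[[1]])
  od <- array(0, c(nr, nc, 3))
  for (j in seq_along(concentrations)) {
    cj <- concentrations[[j]]
    for (k in 1:3) od[, , k] <- od[, , k] + cj * V[k, j]
  }
  od_to_rgb(od, stains$white_reference)
}
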