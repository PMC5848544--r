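# Similarity measures for the registration chain: foreground keying,
# normalised mutual information, and the modality-independent
# neighbourhood self-similarity descriptor (MIND).

#' Separate tissue foreground from a keyed background
#'
#' Chroma-distance keying against the (blue) background colour model:
#' pixels far from the key colour in RGB are foreground. The raw mask is
#' cleaned by morphological closing and reduced to its largest connected
#' component (holes are allowed and preserved).
#'
#' @param photo `[nr, nc, 3]` RGB array in [0, 1].
#' @param key background RGB triple (default the phantom blue).
#' @param threshold chroma distance above which a pixel is foreground
#'   (default 0.25).
#' @param closing_radius disc radius for morphological closing, px.
#' @return logical foreground mask.
#' @export
segment_background <- function(photo, key = phantom_background_blue(),
                               threshold = 0.25, closing_radius = 3) {
  if (length(dim(photo)) != 3) stop("photo must be an RGB array")
  d2 <- (photo[, , 1] - key[1])^2 + (photo[, , 2] - key[2])^2 +
    (photo[, , 3] - key[3])^2
  fg <- sqrt(d2) > threshold
  if (!any(fg)) stop("empty foreground: image matches the background key")
  if (closing_radius > 0) {
    brush <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
    fg <- EBImage::closing(fg, brush) > 0
  }
  lab <- EBImage::bwlabel(fg)
  if (max(lab) > 1) {
    sizes <- tabulate(lab[lab > 0])
    fg <- lab == which.max(sizes)
  }
  fg
}

#' Normalised mutual information of two rasters
#'
#' `NMI = (H(A) + H(B)) / H(A, B)` over the joint histogram of the
#' pixels selected by `mask` (foreground-only by convention). Each
#' raster is binned into `bins` equal-width bins over its own range.
#' Symmetric in its arguments; 2 for identical non-constant rasters
#' (up to binning), about 1 for independent ones.
#'
#' @param a,b numeric matrices of identical dimensions.
#' @param bins number of histogram bins (>= 2, default 64).
#' @param mask optional logical matrix restricting the evaluation.
#' @return scalar NMI score.
#' @export
nmi <- function(a, b, bins = 64, mask = NULL) {
  if (!identical(dim(a), dim(b))) stop("rasters must share dimensions")
  if (bins < 2) stop("bins must be >= 2")
  av <- as.vector(a); bv <- as.vector(b)
  if (!is.null(mask)) { av <- av[mask]; bv <- bv[mask] }
  if (!length(av)) stop("empty overlap")
  bin <- function(x) {
    r <- range(x)
    if (r[2] <= r[1]) return(rep(1L, length(x)))
    pmin(pmax(floor((x - r[1]) / (r[2] - r[1]) * bins) + 1L, 1L), bins)
  }
  ia <- bin(av); ib <- bin(bv)
  joint <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins)
  p <- joint[joint > 0] / length(ia)
  hab <- -sum(p * log(p))
  ent <- function(i) {
    t <- tabulate(i, nbins = bins)
    q <- t[t > 0] / length(i)
    -sum(q * log(q))
  }
  ha <- ent(ia); hb <- ent(ib)
  if (hab <= 0) return(2)  # both constant: degenerate, identical histograms
  (ha + hb) / hab
}

# Shift a matrix by integer (dr, dc) with edge replication.
shift_edge <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- clamp(seq_len(nr) + dr, 1, nr)
  ci <- clamp(seq_len(nc) + dc, 1, nc)
  m[ri, ci, drop = FALSE]
}

# Default MIND offset neighbourhood: 4-connected plus two diagonals.
mind_offsets <- function() {
  rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, 1), c(1, -1))
}

#' Modality-independent neighbourhood descriptor (MIND) field
#'
#' Per pixel and offset r, `D(x, r) = exp(-SSD(x, x + r) / V(x))`, where
#' SSD is the Gaussian-weighted patch distance between the patch at x
#' and the patch displaced by r, and V is the local variance estimate
#' (mean of the four axial patch distances, floored to avoid
#' divide-by-zero in constant regions). Each pixel's descriptor is
#' normalised to maximum 1, making it invariant to global affine
#' intensity rescaling; identical images get identical descriptors.
#'
#' @param image numeric matrix.
#' @param patch_radius Gaussian patch radius, px (default 1: 3 x 3).
#' @param offsets k x 2 integer matrix of descriptor offsets (default
#'   the 6-neighbourhood above).
#' @param sigma Gaussian patch weight SD, px (default 0.5).
#' @param variance_floor_frac variance floor as a fraction of the
#'   squared dynamic range (default 1e-6).
#' @return object of class `mind_field`: `descriptors` `[nr, nc, k]`
#'   array with components in (0, 1], plus the parameters used.
#' @export
compute_mind <- function(image, patch_radius = 1, offsets = mind_offsets(),
                         sigma = 0.5, variance_floor_frac = 1e-6) {
  if (min(dim(image)) < 2 * patch_radius + 1)
    stop("image smaller than the descriptor patch")
  dr <- diff(range(image))
  floor_v <- variance_floor_frac * max(dr, .Machine$double.eps)^2
  k <- nrow(offsets)
  nr <- nrow(image); nc <- ncol(image)
  ssd <- array(0, c(nr, nc, k))
  for (i in seq_len(k)) {
    dif <- (image - shift_edge(image, offsets[i, 1], offsets[i, 2]))^2
    ssd[, , i] <- gauss_smooth(dif, sigma)
  }
  # Variance estimate: mean axial patch distance (first four offsets are
  # the 4-neighbourhood by construction of the default; for custom
  # offset sets use all of them).
  vidx <- if (k >= 4) 1:4 else seq_len(k)
  V <- pmax(apply(ssd[, , vidx, drop = FALSE], c(1, 2), mean), floor_v)
  desc <- array(0, c(nr, nc, k))
  for (i in seq_len(k)) desc[, , i] <- exp(-ssd[, , i] / V)
  mx <- apply(desc, c(1, 2), max)
  for (i in seq_len(k)) desc[, , i] <- desc[, , i] / mx
  structure(list(descriptors = desc, patch_radius = patch_radius,
                 offsets = offsets, sigma = sigma),
            class = "mind_field")
}

#' Mean squared MIND distance between two descriptor fields
#'
#' @param a,b `mind_field` objects (or raw descriptor arrays) on the
#'   same grid.
#' @param mask optional logical matrix.
#' @return scalar mean squared descriptor difference.
#' @export
mind_distance <- function(a, b, mask = NULL) {
  da <- if (inherits(a, "mind_field")) a$descriptors else a
  db <- if (inherits(b, "mind_field")) b$descriptors else b
  if (!identical(dim(da), dim(db))) stop("descriptor grids differ")
  d2 <- (da - db)^2
  if (is.null(mask)) mean(d2) else {
    k <- dim(da)[3]
    sum(d2 * array(mask, dim(da))) / (sum(mask) * k)
  }
}
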