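# Block-face insertion: rigid placement of the excised-block photograph
# into the intact-slice photograph, informed by the cut-out slice
# photograph, with NMI as the cost.

#' Luminance of an RGB image
#' @param rgb `[nr, nc, 3]` array.
#' @return numeric matrix (Rec. 601 weights).
#' @export
luminance <- function(rgb) {
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

# NMI of the block placed at a candidate pose (block -> intact map),
# evaluated over the block's own grid.
insertion_score <- function(block_lum, block_mask, intact_lum, pose, bins) {
  bg <- pixel_grid(nrow(block_lum), ncol(block_lum))
  src <- apply_transform(pose, cbind(as.vector(bg$r), as.vector(bg$c)))
  vals <- bilinear_sample(intact_lum, src, pad = NA)
  sel <- as.vector(block_mask) & !is.na(vals)
  if (sum(sel) < 32) return(-Inf)
  nmi(matrix(vals[sel]), matrix(block_lum[as.vector(block_mask) & !is.na(vals)]),
      bins = bins, mask = NULL)
}

#' Insert a block-face photograph into the intact-slice photograph
#'
#' Rigid-body registration of the block photograph to the intact slice
#' using normalised mutual information. The cut-out slice photograph
#' informs the search: candidate block-centre translations are
#' restricted to the (dilated) region present in the intact foreground
#' but missing from the cut-out foreground — the excision hole — which
#' avoids erroneous insertions elsewhere in the slice. An exhaustive
#' coarse grid over rotation x translation is refined by local
#' Nelder-Mead optimisation of NMI.
#'
#' @param block RGB array of the block-face photograph.
#' @param intact RGB array of the intact-slice photograph.
#' @param cutout RGB array of the cut-out-slice photograph (NULL to
#'   search the whole slice).
#' @param block_mask,intact_mask,cutout_mask optional foreground masks
#'   (computed by [segment_background()] when omitted).
#' @param key background colour for mask computation.
#' @param rotations coarse rotation grid, degrees (default -180..180 in
#'   2 degree steps; flips are excluded — blocks are photographed
#'   face-up).
#' @param translation_stride coarse translation stride, px (default 4).
#' @param hole_dilate dilation of the candidate region, px (default 6).
#' @param bins NMI histogram bins.
#' @return list of class `block_insertion`: `pose` ([rigid2d()] mapping
#'   block px into intact px, centre at the block centre), `score`
#'   (NMI at the optimum), `searched_whole_slice` flag.
#' @export
insert_block_face <- function(block, intact, cutout = NULL,
                              block_mask = NULL, intact_mask = NULL,
                              cutout_mask = NULL,
                              key = phantom_background_blue(),
                              rotations = seq(-180, 178, by = 2),
                              translation_stride = 4, hole_dilate = 6,
                              bins = 64) {
  if (is.null(block_mask)) block_mask <- segment_background(block, key)
  if (is.null(intact_mask)) intact_mask <- segment_background(intact, key)
  if (!any(block_mask) || !any(intact_mask)) stop("empty foreground mask")
  bl <- luminance(block); il <- luminance(intact)
  bh <- nrow(bl); bw <- ncol(bl)
  ctr <- c((bh - 1) / 2, (bw - 1) / 2)

  searched_whole <- FALSE
  cand <- NULL
  if (!is.null(cutout)) {
    if (is.null(cutout_mask)) cutout_mask <- segment_background(cutout, key)
    hole <- intact_mask & !cutout_mask
    if (any(hole)) {
      brush <- EBImage::makeBrush(2 * hole_dilate + 1, shape = "disc")
      cand <- EBImage::dilate(hole, brush) > 0
    }
  }
  if (is.null(cand) || !any(cand)) {
    warning("empty candidate region; falling back to whole-slice search")
    searched_whole <- TRUE
    cand <- intact_mask
  }
  ci <- which(cand, arr.ind = TRUE) - 1L   # 0-based centre candidates
  keep <- (ci[, 1] %% translation_stride == 0) &
    (ci[, 2] %% translation_stride == 0)
  ci <- ci[keep, , drop = FALSE]
  if (!nrow(ci)) ci <- which(cand, arr.ind = TRUE) - 1L

  # Coarse exhaustive search on a decimated block grid: per rotation the
  # rotated grid is precomputed and shifted per candidate centre.
  dec <- seq(1, bh, by = 2)
  decc <- seq(1, bw, by = 2)
  q <- cbind(as.vector(outer(dec - 1, rep(1, length(decc)))),
             as.vector(outer(rep(1, length(dec)), decc - 1)))
  bm_dec <- as.vector(block_mask[dec, decc])
  bv_dec <- as.vector(bl[dec, decc])
  best <- list(score = -Inf, pose = NULL)
  for (ang in rotations) {
    base <- sweep(sweep(q, 2, ctr) %*% t(rot2(ang)), 2, ctr, `+`)
    for (i in seq_len(nrow(ci))) {
      t_i <- ci[i, ] - ctr
      src <- cbind(base[, 1] + t_i[1], base[, 2] + t_i[2])
      vals <- bilinear_sample(il, src, pad = NA)
      sel <- bm_dec & !is.na(vals)
      if (sum(sel) < 32) next
      s <- nmi(matrix(vals[sel], ncol = 1), matrix(bv_dec[sel], ncol = 1),
               bins = bins)
      if (s > best$score)
        best <- list(score = s, pose = rigid2d(ang, t_i, centre = ctr))
    }
  }
  if (is.null(best$pose)) stop("block insertion failed: no valid placement")

  # Local refinement of (angle, translation) by Nelder-Mead on NMI.
  p0 <- c(best$pose$angle, best$pose$translation)
  op <- stats::optim(p0, function(p) {
    -insertion_score(bl, block_mask, il,
                     rigid2d(p[1], p[2:3], centre = ctr), bins)
  }, method = "Nelder-Mead",
  control = list(maxit = 400, reltol = 1e-10))
  refined <- rigid2d(op$par[1], op$par[2:3], centre = ctr)
  structure(list(pose = refined, score = -op$value,
                 coarse_pose = best$pose, coarse_score = best$score,
                 searched_whole_slice = searched_whole),
            class = "block_insertion")
}

#' @export
print.block_insertion <- function(x, ...) {
  cat(sprintf("block_insertion: %.2f deg, t = (%.2f, %.2f) px, NMI = %.4f\n",
              x$pose$angle, x$pose$translation[1], x$pose$translation[2],
              x$score))
  invisible(x)
}

#' Anti-aliased histology subsampling
#'
#' Gaussian pre-filter followed by block-mean downsampling by the
#' integer ratio of source to target pixel size, bridging the
#' resolution gap between digitised sections and slice photographs.
#' Preserves mean intensity.
#'
#' @param image numeric matrix or RGB array.
#' @param factor integer downsampling factor (> 1), or computed from
#'   `src_px_size` / `target_px_size`.
#' @param src_px_size,target_px_size physical pixel sizes (same units);
#'   used when `factor` is missing.
#' @return downsampled image.
#' @export
subsample_histology <- function(image, factor = NULL, src_px_size = NULL,
                                target_px_size = NULL) {
  if (is.null(factor)) {
    if (is.null(src_px_size) || is.null(target_px_size))
      stop("give either factor or both pixel sizes")
    factor <- round(target_px_size / src_px_size)
  }
  if (factor < 1) stop("upsampling requested: target must be coarser than source")
  factor <- as.integer(factor)
  if (factor == 1) return(image)
  down1 <- function(m) {
    sm <- gauss_smooth(m, sigma = factor / 3)
    nr <- (nrow(sm) %/% factor) * factor
    nc <- (ncol(sm) %/% factor) * factor
    sm <- sm[seq_len(nr), seq_len(nc), drop = FALSE]
    blk <- array(sm, c(factor, nr %/% factor, factor, nc %/% factor))
    apply(blk, c(2, 4), mean)
  }
  d <- dim(image)
  if (length(d) == 2) down1(image)
  else {
    out <- NULL
    for (k in seq_len(d[3])) {
      ch <- down1(image[, , k])
      if (is.null(out)) out <- array(0, c(dim(ch), d[3]))
      out[, , k] <- ch
    }
    out
  }
}
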