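# Positive-pixel classification of deconvolved stain concentrations and
# stained-area-fraction summaries, with polygonal include/exclude
# annotations for artefact removal.

#' Positive-pixel intensity thresholds
#'
#' Cutoffs (in OD units of the positive-channel concentration) separating
#' negative, weak, medium and strong staining, plus a background cutoff
#' below which a pixel counts as unstained. Bins are half-open and
#' lower-inclusive: weak = [t_weak, t_medium), medium = [t_medium,
#' t_strong), strong = [t_strong, Inf).
#'
#' @param t_weak,t_medium,t_strong increasing positive cutoffs.
#' @param background_cutoff total-OD (or positive-channel, see
#'   [classify_pixels()]) level below which a pixel is unstained.
#' @param positive_channel label of the stain quantified as positive.
#' @return object of class `positive_pixel_thresholds`.
#' @export
positive_pixel_thresholds <- function(t_weak, t_medium, t_strong,
                                      background_cutoff = 0.05,
                                      positive_channel = "dab") {
  if (!(background_cutoff >= 0)) stop("background_cutoff must be >= 0")
  if (!(0 < t_weak && t_weak < t_medium && t_medium < t_strong))
    stop("thresholds must satisfy 0 < t_weak < t_medium < t_strong")
  structure(list(positive_channel = positive_channel, t_weak = t_weak,
                 t_medium = t_medium, t_strong = t_strong,
                 background_cutoff = background_cutoff),
            class = "positive_pixel_thresholds")
}

#' Region annotation from include / exclude polygons
#'
#' The analysis mask is the union of the include polygons minus the union
#' of the exclude polygons (artefacts: folds, tears, debris). Polygons
#' are closed lists of (row, col) vertices in 0-based pixel coordinates;
#' rasterisation uses even-odd fill with pixel-centre inclusion.
#'
#' @param include_polygons list of n x 2 vertex matrices.
#' @param exclude_polygons list of n x 2 vertex matrices (may be empty).
#' @return object of class `region_annotation`.
#' @export
region_annotation <- function(include_polygons, exclude_polygons = list()) {
  chk <- function(p) is.matrix(p) && ncol(p) == 2 && nrow(p) >= 3
  if (!length(include_polygons) || !all(vapply(include_polygons, chk, TRUE)))
    stop("include_polygons must be a non-empty list of n x 2 vertex matrices")
  if (length(exclude_polygons) && !all(vapply(exclude_polygons, chk, TRUE)))
    stop("exclude_polygons must be n x 2 vertex matrices")
  structure(list(include_polygons = include_polygons,
                 exclude_polygons = exclude_polygons),
            class = "region_annotation")
}

# Even-odd polygon rasterisation on the 0-based pixel grid; a pixel is
# inside when its centre is (crossing-number parity per scanline).
rasterize_polygon <- function(poly, nr, nc) {
  out <- matrix(FALSE, nr, nc)
  py <- poly[, 1]; px <- poly[, 2]
  n <- length(py)
  jseq <- c(n, seq_len(n - 1))
  for (row in 0:(nr - 1)) {
    xs <- numeric(0)
    for (i in seq_len(n)) {
      j <- jseq[i]
      y1 <- py[i]; y2 <- py[j]
      if ((y1 <= row && y2 > row) || (y2 <= row && y1 > row)) {
        t <- (row - y1) / (y2 - y1)
        xs <- c(xs, px[i] + t * (px[j] - px[i]))
      }
    }
    if (length(xs)) {
      xs <- sort(xs)
      for (k in seq(1, length(xs) - 1, by = 2)) {
        cols <- seq.int(ceiling(xs[k]), floor(xs[k + 1]))
        cols <- cols[xs[k + 1] > cols | abs(xs[k + 1] - cols) < 1e-12]
        cols <- cols[cols >= 0 & cols <= nc - 1]
        if (length(cols)) out[row + 1, cols + 1] <- TRUE
      }
    }
  }
  out
}

#' Rasterise a region annotation to an analysis mask
#'
#' @param annotation a [region_annotation()].
#' @param dims image dimensions (rows, cols).
#' @return logical matrix; TRUE inside the analysed region.
#' @export
annotation_mask <- function(annotation, dims) {
  nr <- dims[1]; nc <- dims[2]
  inc <- matrix(FALSE, nr, nc)
  for (p in annotation$include_polygons) inc <- inc | rasterize_polygon(p, nr, nc)
  for (p in annotation$exclude_polygons) inc <- inc & !rasterize_polygon(p, nr, nc)
  inc
}

CLASS_LEVELS <- c("excluded", "unstained", "negative", "weak", "medium", "strong")

#' Classify pixels by staining intensity
#'
#' Inside the analysis mask, a pixel is `unstained` when its background
#' measure (total OD by default `mode = "total_od"`, or the positive
#' channel alone with `mode = "positive"`) falls below
#' `background_cutoff`; otherwise it is binned on the positive-channel
#' concentration into negative / weak / medium / strong (half-open,
#' lower-inclusive bins). Pixels outside the mask are `excluded` and
#' never counted.
#'
#' @param concentrations a `stain_concentrations` object from
#'   [deconvolve()], or a named list of concentration matrices.
#' @param od the `[nr, nc, 3]` OD array (needed for the total-OD
#'   background measure; may be NULL when `mode = "positive"`).
#' @param thresholds a [positive_pixel_thresholds()].
#' @param annotation a [region_annotation()], or NULL to analyse the full
#'   image.
#' @param mode background measure: `"positive"` (positive channel only,
#'   default) or `"total_od"`.
#' @return object of class `markup_classification`: `labels` (factor
#'   matrix stored as integer codes of `CLASS_LEVELS`), `dims`,
#'   `thresholds`, `mode`.
#' @export
classify_pixels <- function(concentrations, od = NULL, thresholds,
                            annotation = NULL,
                            mode = c("positive", "total_od")) {
  mode <- match.arg(mode)
  conc <- if (inherits(concentrations, "stain_concentrations"))
    concentrations$concentrations else concentrations
  pos <- conc[[thresholds$positive_channel]]
  if (is.null(pos)) stop("positive channel '", thresholds$positive_channel,
                         "' not found among concentrations")
  nr <- nrow(pos); nc <- ncol(pos)
  mask <- if (is.null(annotation)) matrix(TRUE, nr, nc)
    else annotation_mask(annotation, c(nr, nc))
  if (!any(mask)) stop("empty analysis mask")
  bgmeas <- if (mode == "total_od") {
    if (is.null(od)) stop("mode 'total_od' needs the OD array")
    od[, , 1] + od[, , 2] + od[, , 3]
  } else pos
  lab <- matrix(1L, nr, nc)                      # excluded
  lab[mask] <- 2L                                # unstained
  stained <- mask & (bgmeas >= thresholds$background_cutoff)
  lab[stained] <- 3L                             # negative
  lab[stained & pos >= thresholds$t_weak]   <- 4L
  lab[stained & pos >= thresholds$t_medium] <- 5L
  lab[stained & pos >= thresholds$t_strong] <- 6L
  structure(list(labels = lab, dims = c(nr, nc), thresholds = thresholds,
                 mode = mode, levels = CLASS_LEVELS),
            class = "markup_classification")
}

#' Stained area fraction of a markup classification
#'
#' Fraction of analysed pixels that are weak, medium or strong positive —
#' the area of positive staining over the total analysis area. Excluded
#' pixels never enter numerator or denominator.
#'
#' @param markup a `markup_classification`.
#' @return object of class `area_fraction_result`: per-class pixel
#'   `counts`, `analysed_pixels`, `stained_area_fraction`.
#' @export
stained_area_fraction <- function(markup) {
  stopifnot(inherits(markup, "markup_classification"))
  counts <- tabulate(markup$labels, nbins = 6L)
  names(counts) <- CLASS_LEVELS
  analysed <- sum(counts[-1])
  if (analysed == 0) stop("markup has no analysed pixels")
  frac <- sum(counts[c("weak", "medium", "strong")]) / analysed
  structure(list(counts = counts[-1], analysed_pixels = analysed,
                 stained_area_fraction = frac),
            class = "area_fraction_result")
}

#' @export
print.area_fraction_result <- function(x, ...) {
  cat(sprintf("stained area fraction: %.4f over %d analysed px\n",
              x$stained_area_fraction, x$analysed_pixels))
  print(x$counts)
  invisible(x)
}

#' Render a markup classification as an RGB image
#'
#' Fixed palette matching conventional positive-pixel markups: unstained
#' white, negative blue, weak yellow, medium orange, strong red; excluded
#' pixels mid-grey.
#'
#' @param markup a `markup_classification`.
#' @return `[nr, nc, 3]` RGB array in [0, 1].
#' @export
render_markup <- function(markup) {
  pal <- rbind(excluded = c(0.5, 0.5, 0.5),
               unstained = c(1, 1, 1),
               negative = c(0, 0, 1),
               weak = c(1, 1, 0),
               medium = c(1, 0.5, 0),
               strong = c(1, 0, 0))
  out <- array(0, c(markup$dims, 3))
  for (k in 1:3) out[, , k] <- matrix(pal[markup$labels, k], markup$dims[1])
  out
}

#' Threshold stability across calibration regions
#'
#' Supports calibrating a single threshold set on several structurally
#' distinct regions: computes the stained area fraction per region at the
#' candidate thresholds and reports the spread, so a threshold can be
#' chosen that yields robust results across regions.
#'
#' @param concentrations `stain_concentrations` (or named list).
#' @param od OD array (or NULL for positive-channel mode).
#' @param thresholds candidate [positive_pixel_thresholds()].
#' @param regions list of [region_annotation()] objects.
#' @param mode background measure passed to [classify_pixels()].
#' @return data.frame with one row per region (fraction, analysed pixels)
#'   plus attributes `mean`, `sd`, `cv`.
#' @export
threshold_stability <- function(concentrations, od = NULL, thresholds,
                                regions, mode = "positive") {
  fr <- vapply(regions, function(rg) {
    m <- classify_pixels(concentrations, od, thresholds, rg, mode = mode)
    stained_area_fraction(m)$stained_area_fraction
  }, numeric(1))
  out <- data.frame(region = seq_along(regions), stained_area_fraction = fr)
  attr(out, "mean") <- mean(fr)
  attr(out, "sd") <- stats::sd(fr)
  attr(out, "cv") <- stats::sd(fr) / max(mean(fr), .Machine$double.eps)
  out
}
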