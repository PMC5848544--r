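# ROI-level comparison of quantitative MR maps and histology stained
# area fractions: per-voxel summaries, two-sample t tests (Welch or
# pooled), and the combined region-comparison report.

#' Extract ROI values from a parameter map
#'
#' @param map a [parameter_map()] (or bare numeric array).
#' @param mask logical array/matrix within the map domain.
#' @param roi name of the region.
#' @param voxel_area in-plane voxel area, mm^2 (for the cross-sectional
#'   area field; default 1).
#' @param modality label and `units` for reporting.
#' @param units unit string.
#' @return object of class `roi_sample`: `roi`, `modality`, `units`,
#'   `n`, `mean`, `sd` (n-1 denominator), `area_mm2`, `values`.
#' @export
extract_roi_values <- function(map, mask, roi = "roi",
                               modality = "map", units = NULL,
                               voxel_area = 1) {
  if (inherits(map, "parameter_map")) {
    if (is.null(units)) units <- map$units
    sel <- mask & map$mask
    vals <- map$values[sel]
  } else {
    vals <- map[mask]
  }
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("empty intersection of mask and valid voxels")
  structure(list(roi = roi, modality = modality,
                 units = units %||% "", n = length(vals),
                 mean = mean(vals), sd = stats::sd(vals),
                 area_mm2 = length(vals) * voxel_area, values = vals),
            class = "roi_sample")
}

#' Construct an ROI sample from printed summary statistics
#'
#' For comparisons where only mean, SD and voxel count are available
#' (e.g. a published table).
#'
#' @param mean,sd,n summary statistics (SD with n-1 denominator).
#' @param roi,modality,units labels.
#' @param area_mm2 optional cross-sectional area.
#' @return `roi_sample` with `values = NULL`.
#' @export
roi_summary <- function(mean, sd, n, roi = "roi", modality = "map",
                        units = "", area_mm2 = NA_real_) {
  if (n < 2) stop("n must be >= 2")
  if (sd < 0) stop("sd must be >= 0")
  structure(list(roi = roi, modality = modality, units = units, n = n,
                 mean = mean, sd = sd, area_mm2 = area_mm2, values = NULL),
            class = "roi_sample")
}

#' @export
print.roi_sample <- function(x, ...) {
  cat(sprintf("roi_sample '%s' [%s]: %.4g +/- %.4g %s (n = %d)\n",
              x$roi, x$modality, x$mean, x$sd, x$units, x$n))
  invisible(x)
}

#' Two-sample t test from ROI samples
#'
#' Standard two-tailed two-sample t test computed from the samples'
#' (mean, SD, n) — identical whether the sample carries raw values or
#' only summaries. Welch (default) uses the Welch-Satterthwaite degrees
#' of freedom; pooled assumes equal variances.
#'
#' @param a,b `roi_sample` objects (n >= 2 each, not both zero SD).
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return list of class `roi_ttest`: `t`, `df`, `p` (two-tailed),
#'   `variant`, `mean_diff`.
#' @export
two_sample_ttest <- function(a, b, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (a$n < 2 || b$n < 2) stop("both samples need n >= 2")
  if (a$sd == 0 && b$sd == 0) stop("zero variance in both samples")
  va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
  if (variant == "welch") {
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  } else {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  }
  t <- (a$mean - b$mean) / se
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  structure(list(t = t, df = df, p = p, variant = variant,
                 mean_diff = a$mean - b$mean),
            class = "roi_ttest")
}

#' @export
print.roi_ttest <- function(x, ...) {
  cat(sprintf("t = %.3f, df = %.1f, two-tailed p = %.3g (%s)\n",
              x$t, x$df, x$p, x$variant))
  invisible(x)
}

#' Build a region-comparison report
#'
#' One row per MR modality comparing two ROIs with a two-tailed t test,
#' plus one row per histology stain carrying the stained area fractions
#' of both regions with no test (a single section per stain admits no
#' inference; the inference columns are NA).
#'
#' @param mr_samples list of `roi_sample` pairs: each element a list
#'   `list(a = , b = )` for one modality (labels taken from the
#'   samples).
#' @param histology_fractions optional list: each element
#'   `list(stain = , a = , b = )` where `a`, `b` are
#'   [stained_area_fraction()] results (or bare fractions).
#' @param variant t-test variant.
#' @return data.frame of class `region_comparison_report` with columns
#'   modality, roi_a_mean, roi_a_sd, roi_a_n, roi_b_mean, roi_b_sd,
#'   roi_b_n, t, df, p.
#' @export
build_comparison_report <- function(mr_samples, histology_fractions = list(),
                                    variant = "welch") {
  frac_of <- function(x) if (inherits(x, "area_fraction_result"))
    x$stained_area_fraction else as.numeric(x)
  rows <- lapply(mr_samples, function(pair) {
    if (!identical(pair$a$modality, pair$b$modality))
      stop("modality label mismatch: ", pair$a$modality, " vs ",
           pair$b$modality)
    tt <- two_sample_ttest(pair$a, pair$b, variant = variant)
    data.frame(modality = pair$a$modality, kind = "mri",
               roi_a_mean = pair$a$mean, roi_a_sd = pair$a$sd,
               roi_a_n = pair$a$n, roi_b_mean = pair$b$mean,
               roi_b_sd = pair$b$sd, roi_b_n = pair$b$n,
               t = tt$t, df = tt$df, p = tt$p)
  })
  hrows <- lapply(histology_fractions, function(h) {
    data.frame(modality = h$stain, kind = "histology",
               roi_a_mean = frac_of(h$a), roi_a_sd = NA_real_,
               roi_a_n = NA_integer_, roi_b_mean = frac_of(h$b),
               roi_b_sd = NA_real_, roi_b_n = NA_integer_,
               t = NA_real_, df = NA_real_, p = NA_real_)
  })
  out <- do.call(rbind, c(rows, hrows))
  rownames(out) <- NULL
  class(out) <- c("region_comparison_report", "data.frame")
  out
}
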