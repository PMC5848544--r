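# Voxel-wise quantitative MR parameter-map estimation: RMS combination of
# phase-cycled structural scans, signal-weighted log-linear T2/T2*
# fitting, non-linear magnitude inversion-recovery T1 fitting, and a
# log-linear diffusion-tensor fit with FA/MD/principal-direction maps.

#' A quantitative parameter map with validity mask
#'
#' @param values numeric array (map values).
#' @param mask logical array, TRUE where the fit is valid.
#' @param units unit string (`"ms"`, `"ppm"`, `"Hz"`, `"mm^2/s"`, `""`).
#' @param diagnostics optional list (residual norm field, failure counts).
#' @return object of class `parameter_map`.
#' @export
parameter_map <- function(values, mask = NULL, units = "", diagnostics = list()) {
  if (is.null(mask)) mask <- array(TRUE, dim(values) %||% length(values))
  v <- values
  v[!mask] <- NA_real_
  structure(list(values = v, mask = mask, units = units,
                 diagnostics = diagnostics),
            class = "parameter_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.parameter_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("parameter_map [%s]: %s, %d valid voxels, median %.4g\n",
              x$units, paste(dim(x$values) %||% length(x$values), collapse = " x "),
              sum(x$mask), stats::median(v)))
  invisible(x)
}

#' Root-mean-square combination of phase-cycled scans
#'
#' Voxel-wise `sqrt(mean(S_i^2))` across the phase-cycled volumes,
#' suppressing balanced-SSFP banding in the combined structural image.
#'
#' @param series [acq_series()] with >= 2 phase cycles.
#' @return numeric array on the common grid.
#' @export
trufi_rms_combine <- function(series) {
  stopifnot(inherits(series, "acq_series"))
  if (length(series$volumes) < 2) stop("need >= 2 phase cycles")
  acc <- 0
  for (v in series$volumes) acc <- acc + v^2
  sqrt(acc / length(series$volumes))
}

# Shared weighted log-linear mono-exponential decay fit.
# Returns list(rate, lnS0, resid_rms, valid) as vectors over voxels.
loglin_decay_fit <- function(series, weighting) {
  te <- as.numeric(series$params)
  if (length(unique(te)) < 2) stop("need >= 2 distinct echo times")
  n <- prod(series$dims)
  S <- matrix(vapply(series$volumes, as.vector, numeric(n)),
              nrow = n)                                # n x nTE
  pos <- rowSums(S <= 0) == 0
  Sc <- pmax(S, .Machine$double.xmin)
  Y <- log(Sc)
  W <- if (weighting == "signal") Sc else matrix(1, nrow(S), ncol(S))
  # Weighted straight-line fit y = b0 + b1*te per voxel, closed form.
  sw <- rowSums(W)
  swx <- W %*% te
  swx2 <- W %*% te^2
  swy <- rowSums(W * Y)
  swxy <- rowSums(W * sweep(Y, 2, te, `*`))
  denom <- sw * swx2 - swx^2
  b1 <- (sw * swxy - swx * swy) / denom
  b0 <- (swy - b1 * swx) / sw
  fit <- outer(as.vector(b0), rep(1, length(te))) +
    outer(as.vector(b1), te)
  resid_rms <- sqrt(rowMeans((Y - fit)^2))
  list(rate = as.vector(b1), lnS0 = as.vector(b0), resid_rms = resid_rms,
       valid = pos & as.vector(b1) < 0 & is.finite(b1))
}

#' Log-linear T2 map fit
#'
#' Solves `ln S = ln S0 - TE/T2` per voxel by (signal-weighted) least
#' squares — the pseudoinverse of the linearised temporal signal
#' evolution, with the measured magnitude as weight compensating the
#' log-transform variance. Voxels with non-positive signal or
#' non-negative slope are masked invalid.
#'
#' @param series [acq_series()] of multi-TE magnitude volumes (TE in ms).
#' @param weighting `"signal"` (default) or `"none"`.
#' @return list with `t2` and `s0` [parameter_map()]s.
#' @export
fit_t2_loglinear <- function(series, weighting = c("signal", "none")) {
  weighting <- match.arg(weighting)
  f <- loglin_decay_fit(series, weighting)
  d <- series$dims
  t2 <- array(-1 / f$rate, d)
  mask <- array(f$valid, d)
  list(t2 = parameter_map(t2, mask, "ms",
                          list(residual_rms = array(f$resid_rms, d))),
       s0 = parameter_map(array(exp(f$lnS0), d), mask, ""))
}

#' Log-linear T2* map fit with R2* companion map
#'
#' Identical estimator to [fit_t2_loglinear()] applied to multi-echo
#' gradient-echo magnitudes; additionally returns `R2* = 1/T2*` (kHz
#' when TE is in ms; reported per ms).
#'
#' @inheritParams fit_t2_loglinear
#' @return list with `t2star`, `r2star` and `s0` [parameter_map()]s.
#' @export
fit_t2star_map <- function(series, weighting = c("signal", "none")) {
  weighting <- match.arg(weighting)
  f <- fit_t2_loglinear(series, weighting)
  r2 <- parameter_map(1 / f$t2$values, f$t2$mask, "1/ms")
  list(t2star = f$t2, r2star = r2, s0 = f$s0)
}

# Magnitude inversion-recovery fit for one voxel. Separable NLLS: for a
# candidate polarity restoration (first k samples negated) the model
# a + b exp(-TI/T1) is linear in (a, b) given T1, so T1 is found by 1-D
# golden-section search and the best polarity wins on residual.
fit_ir_voxel <- function(s, ti, t1_range) {
  o <- order(ti)
  ti <- ti[o]; s <- s[o]
  n <- length(s)
  best <- list(sse = Inf)
  sse_given_t1 <- function(t1, y) {
    X <- cbind(1, exp(-ti / t1))
    cf <- tryCatch(qr.solve(X, y), error = function(e) NULL)
    if (is.null(cf)) return(list(sse = Inf))
    r <- y - X %*% cf
    list(sse = sum(r^2), a = cf[1], b = cf[2])
  }
  for (k in 0:n) {
    y <- s
    if (k > 0) y[1:k] <- -y[1:k]
    op <- stats::optimize(function(t1) sse_given_t1(t1, y)$sse,
                          interval = t1_range, tol = 1e-4)
    if (op$objective < best$sse) {
      fit <- sse_given_t1(op$minimum, y)
      best <- list(sse = op$objective, t1 = op$minimum,
                   a = fit$a, b = fit$b, k = k)
    }
  }
  best
}

#' Non-linear inversion-recovery T1 fit
#'
#' Per voxel fits the 3-parameter magnitude model
#' `S(TI) = |a + b exp(-TI/T1)|` by separable non-linear least squares
#' with a multi-start over the polarity ambiguity at the zero-crossing
#' (every candidate sign-restoration of the early samples is tried and
#' the lowest residual wins). T1 is bounded to (0, 10000] ms; degenerate
#' voxels (constant signal, non-convergence) are masked invalid.
#'
#' @param series [acq_series()] of >= 3 inversion-recovery magnitudes
#'   (TI in ms).
#' @param t1_range search interval for T1, ms.
#' @return list with `t1`, `a`, `b` [parameter_map()]s; diagnostics carry
#'   the invalid-voxel count.
#' @export
fit_t1_ir <- function(series, t1_range = c(1, 10000)) {
  stopifnot(inherits(series, "acq_series"))
  ti <- as.numeric(series$params)
  if (length(unique(ti)) < 3) stop("need >= 3 distinct inversion times")
  d <- series$dims
  n <- prod(d)
  S <- matrix(vapply(series$volumes, as.vector, numeric(n)), nrow = n)
  t1 <- a <- b <- rep(NA_real_, n)
  resid <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  for (i in seq_len(n)) {
    s <- S[i, ]
    if (diff(range(s)) < 1e-9 * max(abs(s), 1)) next
    f <- fit_ir_voxel(s, ti, t1_range)
    if (is.finite(f$sse)) {
      t1[i] <- f$t1; a[i] <- f$a; b[i] <- f$b
      resid[i] <- sqrt(f$sse / length(s))
      valid[i] <- is.finite(f$t1) && f$t1 > 0
    }
  }
  diag <- list(residual_rms = array(resid, d), n_invalid = sum(!valid))
  list(t1 = parameter_map(array(t1, d), array(valid, d), "ms", diag),
       a = parameter_map(array(a, d), array(valid, d), ""),
       b = parameter_map(array(b, d), array(valid, d), ""))
}

# FA from per-voxel eigenvalue triples (matrix n x 3).
fa_from_eigenvalues <- function(lam) {
  md <- rowMeans(lam)
  num <- (lam[, 1] - md)^2 + (lam[, 2] - md)^2 + (lam[, 3] - md)^2
  den <- lam[, 1]^2 + lam[, 2]^2 + lam[, 3]^2
  fa <- sqrt(1.5 * num / pmax(den, .Machine$double.xmin))
  fa[den <= 0] <- 0
  pmin(fa, 1)
}

#' Log-linear diffusion tensor fit
#'
#' Ordinary least squares on `ln(S/S0) = -b g' D g` per voxel, yielding
#' the symmetric tensor, FA, MD and the principal eigenvector
#' (descending eigenvalues; sign convention: non-negative third
#' component, ties broken on the second). Negative eigenvalues are
#' clamped to zero for FA/MD with a diagnostic count.
#'
#' @param series [acq_series()] with params data.frame (`b`, `gx`, `gy`,
#'   `gz`); needs >= 1 b = 0 volume and >= 6 non-collinear directions.
#' @return list of class `tensor_field`: `tensor` (n x 6: xx, yy, zz,
#'   xy, xz, yz), `fa`, `md` [parameter_map()]s, `e1` (n x 3 principal
#'   directions), `dims`, `n_clamped`.
#' @export
fit_dti_loglinear <- function(series) {
  stopifnot(inherits(series, "acq_series"))
  p <- series$params
  if (!is.data.frame(p)) stop("DWI series needs a data.frame of b and directions")
  b0 <- p$b <= 0
  if (!any(b0)) stop("need at least one b = 0 volume")
  if (sum(!b0) < 6) stop("need >= 6 diffusion-weighted directions")
  d <- series$dims
  n <- prod(d)
  S <- matrix(vapply(series$volumes, as.vector, numeric(n)), nrow = n)
  s0 <- if (sum(b0) == 1) S[, b0] else rowMeans(S[, b0, drop = FALSE])
  dw <- which(!b0)
  G <- as.matrix(p[dw, c("gx", "gy", "gz")])
  bv <- p$b[dw]
  # Design matrix for (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
  X <- -bv * cbind(G[, 1]^2, G[, 2]^2, G[, 3]^2,
                   2 * G[, 1] * G[, 2], 2 * G[, 1] * G[, 3],
                   2 * G[, 2] * G[, 3])
  if (qr(X)$rank < 6) stop("collinear gradient directions: design rank < 6")
  Y <- log(pmax(S[, dw, drop = FALSE], .Machine$double.xmin) /
             pmax(s0, .Machine$double.xmin))
  Dt <- t(qr.solve(X, t(Y)))                      # n x 6
  fa <- md <- numeric(n)
  e1 <- matrix(0, n, 3)
  n_clamped <- 0L
  for (i in seq_len(n)) {
    M <- matrix(c(Dt[i, 1], Dt[i, 4], Dt[i, 5],
                  Dt[i, 4], Dt[i, 2], Dt[i, 6],
                  Dt[i, 5], Dt[i, 6], Dt[i, 3]), 3, 3)
    ev <- eigen(M, symmetric = TRUE)
    lam <- ev$values                              # descending
    if (any(lam < 0)) n_clamped <- n_clamped + 1L
    lamc <- pmax(lam, 0)
    md[i] <- mean(lamc)
    fa[i] <- fa_from_eigenvalues(matrix(lamc, 1))
    v <- ev$vectors[, 1]
    tol <- 1e-10
    if (v[3] < -tol || (abs(v[3]) <= tol && v[2] < 0)) v <- -v
    e1[i, ] <- v
  }
  mask <- array(is.finite(md), d)
  structure(list(tensor = Dt,
                 fa = parameter_map(array(fa, d), mask, ""),
                 md = parameter_map(array(md, d), mask, "mm^2/s"),
                 e1 = e1, dims = d, n_clamped = n_clamped),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("tensor_field: %s grid, median FA %.3f, median MD %.3g mm^2/s\n",
              paste(x$dims, collapse = " x "),
              stats::median(x$fa$values[x$fa$mask]),
              stats::median(x$md$values[x$md$mask])))
  invisible(x)
}
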