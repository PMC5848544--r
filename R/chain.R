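# Transform chains: ordered composition of the registration stages
# mapping histology pixel coordinates into MR voxel coordinates, with
# single-interpolation resampling and landmark-error evaluation.

#' Construct a chain step
#'
#' @param name step label.
#' @param forward function mapping an n x 2 point matrix source -> target.
#' @param inverse function mapping target -> source (NULL when
#'   unavailable; such steps block inverse evaluation of the chain).
#' @return object of class `chain_step`.
#' @export
chain_step <- function(name, forward, inverse = NULL) {
  structure(list(name = name, forward = forward, inverse = inverse),
            class = "chain_step")
}

# Step constructors -----------------------------------------------------

#' @rdname chain_step
#' @param tf a [rigid2d()] or [affine2d()] mapping source -> target.
#' @export
chain_step_linear <- function(name, tf) {
  inv <- invert_transform(tf)
  chain_step(name,
             forward = function(p) apply_transform(tf, p),
             inverse = function(p) apply_transform(inv, p))
}

#' @rdname chain_step
#' @param factor integer subsampling factor; forward maps full-resolution
#'   pixel centres to subsampled pixel centres.
#' @export
chain_step_subsample <- function(name, factor) {
  f <- as.numeric(factor)
  chain_step(name,
             forward = function(p) (p - (f - 1) / 2) / f,
             inverse = function(p) p * f + (f - 1) / 2)
}

#' @rdname chain_step
#' @param disp pull-back displacement field (list `r`, `c`): the step's
#'   *inverse* samples source at `p + disp(p)`; the forward map is the
#'   numerical inverse.
#' @export
chain_step_displacement <- function(name, disp) {
  dinv <- invert_displacement(disp)
  samp <- function(field, p) cbind(
    p[, 1] + bilinear_sample(field$r, p),
    p[, 2] + bilinear_sample(field$c, p))
  chain_step(name,
             forward = function(p) samp(dinv, p),
             inverse = function(p) samp(disp, p))
}

#' Compose registration stages into a transform chain
#'
#' @param steps list of [chain_step()]s in forward (histology -> MR)
#'   order, 2-D throughout.
#' @param surface optional terminal [curvilinear_surface()] lifting
#'   slice-grid coordinates to 3-D MR voxel coordinates.
#' @return object of class `transform_chain`.
#' @export
compose_chain <- function(steps, surface = NULL) {
  if (!length(steps) || !all(vapply(steps, inherits, TRUE, "chain_step")))
    stop("steps must be chain_step objects")
  structure(list(steps = steps, surface = surface), class = "transform_chain")
}

#' @export
print.transform_chain <- function(x, ...) {
  cat("transform_chain:", paste(vapply(x$steps, `[[`, "", "name"),
                                collapse = " -> "))
  if (!is.null(x$surface)) cat(" -> surface")
  cat("\n")
  invisible(x)
}

#' Map points through a chain
#'
#' @param chain a [compose_chain()] result.
#' @param pts n x 2 points in the first step's source frame (forward) or
#'   the last 2-D frame (inverse).
#' @param direction `"forward"` (default) or `"inverse"`; inverse stops
#'   before the surface step.
#' @param to_3d lift the final slice-grid coordinates through the
#'   surface (forward only; default TRUE when a surface is present).
#' @return n x 2 (or n x 3) matrix of mapped coordinates.
#' @export
chain_map <- function(chain, pts, direction = c("forward", "inverse"),
                      to_3d = !is.null(chain$surface)) {
  direction <- match.arg(direction)
  p <- rbind(pts)
  if (direction == "forward") {
    for (s in chain$steps) p <- s$forward(p)
    if (to_3d) {
      if (is.null(chain$surface)) stop("chain has no surface step")
      p <- surface_points(chain$surface, p[, 1], p[, 2])
    }
  } else {
    for (s in rev(chain$steps)) {
      if (is.null(s$inverse)) stop("step '", s$name, "' has no inverse")
      p <- s$inverse(p)
    }
  }
  p
}

#' Resample a histology image into the MR slice frame
#'
#' Pull-back through the whole chain with a single interpolation: every
#' slice-grid pixel is mapped back to histology coordinates through the
#' inverses of all 2-D steps and the histology image is sampled once.
#'
#' @param chain a [compose_chain()] result whose first frame is the
#'   histology image frame.
#' @param histology numeric matrix (or RGB array).
#' @param dims slice-grid dimensions (defaults to the surface grid).
#' @param pad fill value outside the histology domain.
#' @return list: `raster` (resampled histology on the slice grid),
#'   `coords_3d` (n x 3 voxel coordinates of the grid pixels, when a
#'   surface is present).
#' @export
map_histology_to_mr <- function(chain, histology, dims = NULL, pad = NA) {
  if (is.null(dims)) {
    if (is.null(chain$surface)) stop("give dims or a chain with a surface")
    dims <- c(chain$surface$nu, chain$surface$nv)
  }
  g <- pixel_grid(dims[1], dims[2])
  grid_pts <- cbind(as.vector(g$r), as.vector(g$c))
  src <- chain_map(chain, grid_pts, direction = "inverse")
  d <- dim(histology)
  raster <- if (length(d) == 2) {
    matrix(bilinear_sample(histology, src, pad = pad), dims[1], dims[2])
  } else {
    out <- array(0, c(dims, d[3]))
    for (k in seq_len(d[3]))
      out[, , k] <- matrix(bilinear_sample(histology[, , k], src, pad = pad),
                           dims[1], dims[2])
    out
  }
  coords <- if (!is.null(chain$surface))
    surface_points(chain$surface, grid_pts[, 1], grid_pts[, 2]) else NULL
  list(raster = raster, coords_3d = coords)
}

#' Target registration error of a chain at landmark pairs
#'
#' Maps landmarks given in the chain's source (histology) frame forward
#' and compares with their true target coordinates.
#'
#' @param chain a [compose_chain()] result.
#' @param source_pts n x 2 landmark coordinates in the histology frame.
#' @param target_pts n x 2 or n x 3 true coordinates in the chain's
#'   target frame.
#' @return list: `errors` (per-landmark Euclidean distances), `mean`,
#'   `max`, `rms`, `n`.
#' @export
target_registration_error <- function(chain, source_pts, target_pts) {
  target_pts <- rbind(target_pts)
  mapped <- chain_map(chain, source_pts, to_3d = ncol(target_pts) == 3)
  if (!all(dim(mapped) == dim(target_pts)))
    stop("landmark dimensionality mismatch")
  e <- sqrt(rowSums((mapped - target_pts)^2))
  list(errors = e, mean = mean(e), max = max(e),
       rms = sqrt(mean(e^2)), n = length(e))
}
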