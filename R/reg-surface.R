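# Slice-photo to MR-volume stage: tissue-type segmentation of the
# photograph, extraction of a slightly curved (curvilinear) cutting
# surface through the MR volume, resampling along it, and boundary-based
# rigid registration (BBR) driven by the grey/white-matter interface.

# Deterministic 1-D 3-class k-means (quantile init, Lloyd iterations).
kmeans_1d_3 <- function(x, iterations = 50) {
  ctr <- stats::quantile(x, c(0.1, 0.5, 0.9), names = FALSE)
  for (i in seq_len(iterations)) {
    d <- outer(x, ctr, function(a, b) (a - b)^2)
    assign <- max.col(-d, ties.method = "first")
    new_ctr <- vapply(1:3, function(k)
      if (any(assign == k)) mean(x[assign == k]) else ctr[k], numeric(1))
    if (max(abs(new_ctr - ctr)) < 1e-12) { ctr <- new_ctr; break }
    ctr <- new_ctr
  }
  list(assign = assign, centers = ctr)
}

#' Tissue-type segmentation of a masked slice image
#'
#' Three-class intensity clustering (background / grey matter / white
#' matter) with spatial smoothing of the class indicators, followed by
#' extraction of the grey-white interface as contour polylines at the
#' 0.5 level of the smoothed white-matter indicator.
#'
#' @param slice numeric matrix, background at (or near) the lowest
#'   intensity.
#' @param mask optional logical foreground mask; intensities outside it
#'   are treated as background.
#' @param wm_bright TRUE (default) when white matter is the brightest
#'   class; FALSE inverts the class order (contrast-inverted images give
#'   the identical boundary set).
#' @param smooth_sigma spatial smoothing of class indicators, px.
#' @param min_separation minimum cluster-centre gap in units of the
#'   pooled within-class standard deviation; below it the histogram is
#'   considered unimodal and an error is raised (default 3).
#' @return list of class `tissue_segmentation`: `labels` (matrix, 0 =
#'   background, 1 = GM, 2 = WM), `boundary` (list of n x 2 polylines,
#'   0-based px, GM/WM interface), `centers`.
#' @export
segment_tissue <- function(slice, mask = NULL, wm_bright = TRUE,
                           smooth_sigma = 1, min_separation = 3) {
  if (is.null(mask)) mask <- slice > min(slice) + 1e-12
  if (!any(mask)) stop("empty foreground")
  # cluster over the whole slice so the background mode anchors the
  # darkest class even when the mask removes it from the labelling
  x <- as.vector(slice)
  km <- kmeans_1d_3(x)
  ord <- order(km$centers)
  within_sd <- sqrt(mean(vapply(1:3, function(k) {
    xi <- x[km$assign == k]
    if (length(xi) > 1) stats::var(xi) else 0
  }, numeric(1))))
  if (diff(range(x)) <= 0 ||
      min(diff(km$centers[ord])) < min_separation *
        max(within_sd, .Machine$double.eps))
    stop("unimodal intensity histogram: cannot separate tissue classes")
  # rank 1..3 from dark to bright; map to classes inside the mask
  rank_of <- match(seq_len(3), ord)
  cls <- matrix(rank_of[km$assign], nrow(slice))  # 1 dark, 2 mid, 3 bright
  labels <- matrix(0L, nrow(slice), ncol(slice))
  if (wm_bright) {
    labels[mask] <- ifelse(cls[mask] == 3, 2L,
                           ifelse(cls[mask] == 2, 1L, 0L))
  } else {
    labels[mask] <- ifelse(cls[mask] == 1, 2L,
                           ifelse(cls[mask] == 2, 1L, 0L))
  }
  # smooth the WM indicator and re-threshold for spatial regularity
  wmi <- gauss_smooth((labels == 2L) * 1, smooth_sigma)
  gmi <- gauss_smooth((labels >= 1L) * 1, smooth_sigma)
  labels[mask] <- 0L
  labels[mask & gmi > 0.5] <- 1L
  labels[mask & wmi > 0.5] <- 2L
  # GM/WM interface: 0.5-contour of the smoothed WM indicator, kept
  # where GM is present on the other side.
  nr <- nrow(slice); nc <- ncol(slice)
  cl <- grDevices::contourLines(x = 0:(nr - 1), y = 0:(nc - 1), z = wmi,
                                levels = 0.5)
  boundary <- lapply(cl, function(s) cbind(s$x, s$y))
  boundary <- Filter(function(p) nrow(p) >= 5, boundary)
  # Orient each polyline so segment normals (-t2, t1) point toward the
  # white-matter side; BBR contrast signs are then consistent.
  boundary <- lapply(boundary, function(p) {
    seg <- diff(p)
    len <- pmax(sqrt(rowSums(seg^2)), 1e-12)
    mid <- (p[-1, , drop = FALSE] + p[-nrow(p), , drop = FALSE]) / 2
    n <- cbind(-seg[, 2], seg[, 1]) / len
    into_wm <- bilinear_sample(wmi, mid + 1.5 * n) -
      bilinear_sample(wmi, mid - 1.5 * n)
    if (mean(into_wm) < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p
  })
  structure(list(labels = labels, boundary = boundary,
                 centers = sort(km$centers), wm_indicator = wmi),
            class = "tissue_segmentation")
}

#' Construct a curvilinear resampling surface
#'
#' A base plane through the MR volume (origin plus two in-plane unit
#' axes and a normal, all in 0-based voxel coordinates) carrying a
#' single-valued height-field of normal offsets per in-plane sample.
#'
#' @param origin length-3 voxel coordinates of in-plane sample (0, 0).
#' @param u_axis,v_axis orthonormal in-plane direction vectors (voxel
#'   step per in-plane pixel).
#' @param normal unit normal vector.
#' @param nu,nv in-plane sample counts.
#' @param offsets nu x nv matrix of normal offsets, voxels (default 0).
#' @param max_offset bound on |offsets| (default 5 voxels).
#' @return object of class `curvilinear_surface`.
#' @export
curvilinear_surface <- function(origin, u_axis, v_axis, normal, nu, nv,
                                offsets = NULL, max_offset = 5) {
  if (is.null(offsets)) offsets <- matrix(0, nu, nv)
  if (any(abs(offsets) > max_offset + 1e-9))
    stop("offsets exceed max_offset")
  structure(list(origin = as.numeric(origin), u_axis = as.numeric(u_axis),
                 v_axis = as.numeric(v_axis), normal = as.numeric(normal),
                 nu = nu, nv = nv, offsets = offsets,
                 max_offset = max_offset),
            class = "curvilinear_surface")
}

# 3-D voxel coordinates of surface samples at in-plane (u, v) points
# (matrices or vectors, 0-based in-plane px).
surface_points <- function(surface, up, vp, offsets = surface$offsets) {
  h <- matrix(bilinear_sample(offsets, cbind(as.vector(up), as.vector(vp))),
              length(up))
  cbind(surface$origin[1] + as.vector(up) * surface$u_axis[1] +
          as.vector(vp) * surface$v_axis[1] + as.vector(h) * surface$normal[1],
        surface$origin[2] + as.vector(up) * surface$u_axis[2] +
          as.vector(vp) * surface$v_axis[2] + as.vector(h) * surface$normal[2],
        surface$origin[3] + as.vector(up) * surface$u_axis[3] +
          as.vector(vp) * surface$v_axis[3] + as.vector(h) * surface$normal[3])
}

#' Resample an MR volume along a curvilinear surface
#'
#' Trilinear interpolation of the volume at the surface sample points;
#' with zero offsets and an axis-aligned base plane this reduces to
#' direct slice extraction. Samples outside the volume are edge-padded
#' and flagged in the returned mask.
#'
#' @param volume 3-D array.
#' @param surface a [curvilinear_surface()].
#' @return list: `raster` (nu x nv matrix), `inside` (logical matrix).
#' @export
resample_along_surface <- function(volume, surface) {
  g <- pixel_grid(surface$nu, surface$nv)
  pts <- surface_points(surface, g$r, g$c)
  d <- dim(volume)
  inside <- pts[, 1] >= 0 & pts[, 1] <= d[1] - 1 &
    pts[, 2] >= 0 & pts[, 2] <= d[2] - 1 &
    pts[, 3] >= 0 & pts[, 3] <= d[3] - 1
  vals <- trilinear_sample(volume, pts)
  list(raster = matrix(vals, surface$nu, surface$nv),
       inside = matrix(inside, surface$nu, surface$nv))
}

# Resample boundary polylines: points and outward normals in the slice
# frame, concatenated over polylines with arc-length spacing ~1 px.
boundary_samples <- function(boundary, spacing = 1) {
  pts <- NULL; nrm <- NULL
  for (p in boundary) {
    if (nrow(p) < 2) next
    seg <- diff(p)
    len <- sqrt(rowSums(seg^2))
    cum <- c(0, cumsum(len))
    s <- seq(0, cum[length(cum)], by = spacing)
    idx <- findInterval(s, cum, rightmost.closed = TRUE)
    idx <- pmin(idx, nrow(seg))
    t <- (s - cum[idx]) / pmax(len[idx], 1e-12)
    q <- p[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * t
    tang <- seg[idx, , drop = FALSE] / pmax(len[idx], 1e-12)
    n <- cbind(-tang[, 2], tang[, 1])
    pts <- rbind(pts, q); nrm <- rbind(nrm, n)
  }
  if (is.null(pts)) stop("empty boundary")
  list(points = pts, normals = nrm)
}

# BBR cost: mean tanh-saturated signed contrast of the raster sampled at
# +/- `offset` px along boundary normals, after mapping boundary points
# through `tf` (boundary frame -> raster frame). Positive polarity
# expects brighter tissue on the -normal side.
bbr_cost <- function(raster, bnd, tf = NULL, offset = 1, polarity = 1,
                     scale = NULL) {
  p <- bnd$points; n <- bnd$normals
  if (!is.null(tf)) {
    p2 <- apply_transform(tf, p)
    R <- if (inherits(tf, "rigid2d")) rot2(tf$angle) else tf$A
    n2 <- n %*% t(R)
    n2 <- n2 / pmax(sqrt(rowSums(n2^2)), 1e-12)
  } else { p2 <- p; n2 <- n }
  if (is.null(scale)) {
    scale <- stats::mad(raster[raster != 0], constant = 1)
    if (!is.finite(scale) || scale <= 0) scale <- stats::sd(raster)
    if (!is.finite(scale) || scale <= 0) stop("flat raster: BBR undefined")
  }
  a <- bilinear_sample(raster, p2 + offset * n2, pad = NA)
  b <- bilinear_sample(raster, p2 - offset * n2, pad = NA)
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 8) return(-Inf)
  mean(tanh(polarity * (a[ok] - b[ok]) / scale))
}

#' Boundary-based rigid registration
#'
#' Maximises the mean signed intensity contrast of `mr_slice` sampled at
#' a fixed offset either side of the projected tissue boundary, over
#' in-plane rigid parameters. A small coarse grid around `init` guards
#' against local maxima before Nelder-Mead refinement.
#'
#' @param photo_boundary list of n x 2 polylines (0-based px, from
#'   [segment_tissue()]).
#' @param mr_slice numeric matrix (e.g. from
#'   [resample_along_surface()]).
#' @param init [rigid2d()] initial boundary-to-slice map (identity
#'   default).
#' @param offset normal sampling offset, px (default 1).
#' @param polarity +1 (default) when the +normal side should be
#'   brighter; -1 for the opposite contrast.
#' @param grid_radius coarse translation search radius, px.
#' @return list of class `bbr_registration`: `transform` ([rigid2d()]),
#'   `cost`.
#' @export
bbr_register <- function(photo_boundary, mr_slice, init = rigid2d(),
                         offset = 1, polarity = 1, grid_radius = 4) {
  if (stats::sd(mr_slice) < 1e-12) stop("flat raster: BBR undefined")
  bnd <- boundary_samples(photo_boundary)
  ctr <- c((nrow(mr_slice) - 1) / 2, (ncol(mr_slice) - 1) / 2)
  scale <- stats::mad(mr_slice[mr_slice != 0], constant = 1)
  if (!is.finite(scale) || scale <= 0) scale <- stats::sd(mr_slice)
  best <- list(cost = -Inf, par = c(init$angle, init$translation))
  for (dr in seq(-grid_radius, grid_radius, by = 2))
    for (dc in seq(-grid_radius, grid_radius, by = 2)) {
      par <- c(init$angle, init$translation + c(dr, dc))
      cst <- bbr_cost(mr_slice, bnd, rigid2d(par[1], par[2:3], ctr),
                      offset, polarity, scale)
      if (cst > best$cost) best <- list(cost = cst, par = par)
    }
  op <- stats::optim(best$par, function(p)
    -bbr_cost(mr_slice, bnd, rigid2d(p[1], p[2:3], ctr),
              offset, polarity, scale),
    method = "Nelder-Mead", control = list(maxit = 500, reltol = 1e-10))
  structure(list(transform = rigid2d(op$par[1], op$par[2:3], ctr),
                 cost = -op$value),
            class = "bbr_registration")
}

#' Fit a curvilinear surface to match photographed anatomy
#'
#' Optimises per-node normal offsets of the resampling surface
#' (bilinearly interpolated over the in-plane grid, smoothness
#' penalised) to maximise the BBR agreement between the photograph's
#' tissue boundary and the resampled MR slice. Optionally alternates
#' with in-plane [bbr_register()] refinement of the boundary pose.
#'
#' @param volume 3-D MR array.
#' @param photo_boundary boundary polylines in the slice frame.
#' @param init_surface [curvilinear_surface()] defining the base plane
#'   and sampling grid (offsets ignored).
#' @param nodes node-grid size for the height field (default c(5, 5)).
#' @param max_offset offset bound, voxels (default the surface's).
#' @param smoothness penalty weight on squared node differences.
#' @param outer_iterations alternations of surface fit and in-plane BBR
#'   (default 2).
#' @param offset,polarity BBR sampling parameters.
#' @return list of class `surface_fit`: `surface` (with fitted
#'   offsets), `pose` (in-plane boundary pose), `cost`.
#' @export
fit_curvilinear_surface <- function(volume, photo_boundary, init_surface,
                                    nodes = c(5, 5), max_offset = NULL,
                                    smoothness = 0.5,
                                    outer_iterations = 2,
                                    offset = 1, polarity = 1) {
  surf <- init_surface
  if (is.null(max_offset)) max_offset <- surf$max_offset
  bnd <- boundary_samples(photo_boundary)
  nu <- surf$nu; nv <- surf$nv
  node_r <- seq(0, nu - 1, length.out = nodes[1])
  node_c <- seq(0, nv - 1, length.out = nodes[2])
  expand_nodes <- function(h) {
    hn <- matrix(h, nodes[1], nodes[2])
    g <- pixel_grid(nu, nv)
    # map full-grid coords into node-grid coords
    ur <- as.vector(g$r) / (nu - 1) * (nodes[1] - 1)
    vc <- as.vector(g$c) / (nv - 1) * (nodes[2] - 1)
    matrix(bilinear_sample(hn, cbind(ur, vc)), nu, nv)
  }
  pose <- rigid2d()
  h <- rep(0, prod(nodes))
  cost_h <- function(h) {
    hb <- clamp(h, -max_offset, max_offset)
    offs <- expand_nodes(hb)
    rs <- resample_along_surface(volume,
      curvilinear_surface(surf$origin, surf$u_axis, surf$v_axis,
                          surf$normal, nu, nv, offs, max_offset))
    hm <- matrix(hb, nodes[1], nodes[2])
    pen <- smoothness * (sum(diff(hm)^2) + sum(t(diff(t(hm)))^2)) /
      prod(nodes)
    cst <- bbr_cost(rs$raster, bnd, pose, offset, polarity)
    if (!is.finite(cst)) return(1e6)
    -cst + pen
  }
  for (it in seq_len(outer_iterations)) {
    op <- stats::optim(h, cost_h, method = "BFGS",
                       control = list(maxit = 60, reltol = 1e-8))
    h <- clamp(op$par, -max_offset, max_offset)
    offs <- expand_nodes(h)
    surf <- curvilinear_surface(surf$origin, surf$u_axis, surf$v_axis,
                                surf$normal, nu, nv, offs, max_offset)
    rs <- resample_along_surface(volume, surf)
    br <- tryCatch(bbr_register(photo_boundary, rs$raster, init = pose,
                                offset = offset, polarity = polarity,
                                grid_radius = 2),
                   error = function(e) NULL)
    if (!is.null(br)) pose <- br$transform
  }
  structure(list(surface = surf, pose = pose, cost = -op$value),
            class = "surface_fit")
}
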