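# File I/O: NIfTI volumes, PNG/TIFF photographs, JSON polygon
# annotations and transforms, YAML run configuration. All round trips
# are lossless for the artefact types the pipeline exchanges.

#' Load / save an MR volume (NIfTI)
#'
#' @param path file path (`.nii` / `.nii.gz`).
#' @return numeric array with attribute `pixdim` (voxel sizes, mm).
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "pixdim") <- RNifti::pixdim(img)
  out
}

#' @rdname load_volume
#' @param volume numeric array.
#' @param pixdim voxel sizes, mm.
#' @export
save_volume <- function(volume, path, pixdim = c(1, 1, 1)) {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- pixdim[seq_len(length(dim(volume)))]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Load / save a photograph or markup image
#'
#' PNG (8/16-bit) via the png package; TIFF via the tiff package when
#' installed. Values are in [0, 1].
#'
#' @param path image path (`.png`, `.tif`, `.tiff`).
#' @return matrix (grey) or `[nr, nc, channels]` array.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") return(png::readPNG(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the tiff package")
    return(tiff::readTIFF(path))
  }
  stop("unsupported image format: .", ext)
}

#' @rdname load_image
#' @param image matrix or array in [0, 1].
#' @export
save_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  image <- clamp(image, 0, 1)
  if (ext == "png") png::writePNG(image, path)
  else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("writing TIFF requires the tiff package")
    tiff::writeTIFF(image, path, bits.per.sample = 16L)
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

#' Load / save ROI polygon annotations (JSON)
#'
#' The JSON schema is a list of named ROIs, each with `include` and
#' `exclude` polygon lists; every polygon is a list of [row, col]
#' vertices (0-based pixels). Coordinates round-trip exactly.
#'
#' @param path JSON file path.
#' @return named list of [region_annotation()] objects.
#' @export
load_rois <- function(path) {
  if (!file.exists(path)) stop("ROI file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!length(raw)) stop("malformed ROI file ", path, ": no rois")
  lapply(raw, function(r) {
    to_mats <- function(polys) lapply(polys, function(p) {
      m <- do.call(rbind, lapply(p, function(v) as.numeric(unlist(v))))
      if (ncol(m) != 2) stop("malformed ROI file ", path,
                             ": polygon vertices must be [row, col]")
      m
    })
    region_annotation(include_polygons = to_mats(r$include),
                      exclude_polygons = to_mats(r$exclude %||% list()))
  })
}

#' @rdname load_rois
#' @param rois named list of [region_annotation()] objects.
#' @export
save_rois <- function(rois, path) {
  out <- lapply(rois, function(r) list(
    include = lapply(r$include_polygons, function(m) unname(m)),
    exclude = lapply(r$exclude_polygons, function(m) unname(m))))
  jsonlite::write_json(out, path, digits = NA)
  invisible(path)
}

#' Load / save a transform (JSON)
#'
#' Serialises [rigid2d()], [affine2d()], displacement fields (dense
#' `r`/`c` bands) and [curvilinear_surface()] objects as typed JSON.
#'
#' @param path JSON file path.
#' @return the transform object.
#' @export
load_transform <- function(path) {
  if (!file.exists(path)) stop("transform file not found: ", path)
  j <- jsonlite::fromJSON(path)
  if (is.null(j$type)) stop("malformed transform file ", path,
                            ": missing 'type'")
  switch(j$type,
    rigid2d = rigid2d(j$angle, j$translation, j$centre),
    affine2d = affine2d(matrix(j$A, 2, 2), j$b),
    displacement = list(r = matrix(j$r, j$dims[1], j$dims[2]),
                        c = matrix(j$c, j$dims[1], j$dims[2])),
    curvilinear_surface = curvilinear_surface(
      j$origin, j$u_axis, j$v_axis, j$normal, j$nu, j$nv,
      matrix(j$offsets, j$nu, j$nv), j$max_offset),
    stop("malformed transform file ", path, ": unknown type '", j$type, "'"))
}

#' @rdname load_transform
#' @param tf transform object.
#' @export
save_transform <- function(tf, path) {
  j <- if (inherits(tf, "rigid2d")) {
    list(type = "rigid2d", angle = tf$angle, translation = tf$translation,
         centre = tf$centre)
  } else if (inherits(tf, "affine2d")) {
    list(type = "affine2d", A = as.vector(tf$A), b = tf$b)
  } else if (inherits(tf, "curvilinear_surface")) {
    list(type = "curvilinear_surface", origin = tf$origin,
         u_axis = tf$u_axis, v_axis = tf$v_axis, normal = tf$normal,
         nu = tf$nu, nv = tf$nv, offsets = as.vector(tf$offsets),
         max_offset = tf$max_offset)
  } else if (is.list(tf) && !is.null(tf$r) && !is.null(tf$c)) {
    list(type = "displacement", dims = dim(tf$r),
         r = as.vector(tf$r), c = as.vector(tf$c))
  } else stop("unsupported transform object")
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Known configuration keys per stage (unknown keys are rejected).
config_schema <- function() list(
  seed = "integer",
  stain = c("t_weak", "t_medium", "t_strong", "background_cutoff",
            "positive_channel", "mode"),
  insertion = c("rotation_step", "translation_stride", "hole_dilate",
                "bins"),
  registration = c("levels", "iterations", "sigma_update", "sigma_field"),
  surface = c("nodes", "max_offset", "smoothness"),
  qsm = c("radii", "tsvd_threshold", "threshold", "hz_per_ppm"),
  paths = c("volume", "intact_photo", "cutout_photo", "block_photo",
            "histology", "rois", "output_dir"))

#' Load and validate a run configuration (YAML)
#'
#' Unknown stages or keys are rejected with a structured error naming
#' the offending field. A `seed` entry is required so every stochastic
#' stage is explicitly seeded.
#'
#' @param path YAML file path.
#' @return named list of configuration blocks.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  schema <- config_schema()
  for (stage in names(cfg)) {
    if (!stage %in% names(schema))
      stop("config error in ", path, ": unknown stage '", stage, "'")
    if (stage == "seed") next
    bad <- setdiff(names(cfg[[stage]]), schema[[stage]])
    if (length(bad))
      stop("config error in ", path, ": unknown key '", bad[1],
           "' in stage '", stage, "'")
  }
  if (is.null(cfg$seed))
    stop("config error in ", path, ": 'seed' is required")
  cfg
}
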