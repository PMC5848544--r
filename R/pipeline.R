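# End-to-end pipeline: runs every estimation stage of the registration
# chain on a (phantom or real) dataset and assembles the composite
# histology-to-MR transform, with landmark evaluation and provenance.

#' Run the full registration chain
#'
#' Executes the staged co-registration on a [make_registration_phantom()]
#' dataset (or a list with the same fields): background keying of all
#' photographs, NMI block-face insertion informed by the cut-out slice,
#' histology subsampling, MIND affine and deformable registration of the
#' histology to the block face, tissue segmentation of the slice
#' photograph, curvilinear-surface fitting with boundary-based rigid
#' registration into the MR volume, and composition into a single
#' [compose_chain()] transform. When landmark ground truth is present
#' the target registration error is evaluated.
#'
#' @param data a `registration_phantom` (or compatible list).
#' @param rotations coarse rotation grid for the insertion search.
#' @param surface_nodes node grid for the surface fit.
#' @param verbose print stage progress.
#' @return list of class `chain_fit`: `chain`, per-stage estimates
#'   (`insertion`, `affine`, `deformable`, `surface_fit`), `tre`
#'   (landmark statistics or NULL), `timings` (seconds per stage).
#' @export
run_registration_chain <- function(data,
                                   rotations = seq(-180, 178, by = 2),
                                   surface_nodes = c(5, 5),
                                   verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  tic <- function() Sys.time()
  timings <- list()

  # Stage 1: foreground separation.
  t0 <- tic()
  fg_intact <- segment_background(data$intact_photo)
  fg_block <- segment_background(data$block_photo)
  fg_cut <- segment_background(data$cutout_photo)
  timings$segmentation <- as.numeric(tic() - t0, units = "secs")
  say("stage 1: foreground masks (%.1fs)", timings$segmentation)

  # Stage 2: block-face insertion.
  t0 <- tic()
  ins <- insert_block_face(data$block_photo, data$intact_photo,
                           data$cutout_photo,
                           block_mask = fg_block, intact_mask = fg_intact,
                           cutout_mask = fg_cut, rotations = rotations)
  timings$insertion <- as.numeric(tic() - t0, units = "secs")
  say("stage 2: insertion %.2f deg (%.1fs)", ins$pose$angle,
      timings$insertion)

  # Stage 3: histology -> block face (subsample, affine, deformable).
  t0 <- tic()
  hist_sub <- subsample_histology(data$histology, factor = data$hist_factor)
  block_lum <- luminance(data$block_photo)
  aff <- register_affine(hist_sub, block_lum)
  warped <- warp_image(hist_sub, invert_transform(aff$transform),
                       dims = dim(block_lum))
  def <- register_deformable(warped, block_lum, levels = 2)
  timings$histology <- as.numeric(tic() - t0, units = "secs")
  say("stage 3: affine scale %.3f, deformable dist %.2e (%.1fs)",
      sqrt(det(aff$transform$A)), def$distance, timings$histology)

  # Stage 4: slice photo -> MR volume (segmentation, surface fit, BBR).
  t0 <- tic()
  photo_lum <- luminance(data$intact_photo)
  seg <- segment_tissue(photo_lum, mask = fg_intact)
  d <- dim(data$volume)
  init_surf <- curvilinear_surface(c(0, 0, floor(d[3] / 2)),
                                   c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                                   d[1], d[2],
                                   max_offset = data$surface$max_offset)
  sf <- fit_curvilinear_surface(data$volume, seg$boundary, init_surf,
                                nodes = surface_nodes)
  timings$surface <- as.numeric(tic() - t0, units = "secs")
  say("stage 4: surface fit cost %.3f, pose %.2f deg (%.1fs)",
      sf$cost, sf$pose$angle, timings$surface)

  # Stage 5: composition. The histology->block step inverts the fitted
  # (affine o deformation) pull-back map.
  steps <- list(
    chain_step_subsample("hist_subsample", data$hist_factor),
    local({
      tf <- aff$transform           # block -> hist-sub (pull-back)
      dsp <- def$disp               # block -> residual (pull-back)
      dinv <- invert_displacement(dsp)
      fwd <- function(p) {          # hist-sub -> block
        q <- apply_transform(invert_transform(tf), p)
        cbind(q[, 1] + bilinear_sample(dinv$r, q),
              q[, 2] + bilinear_sample(dinv$c, q))
      }
      inv <- function(p) {          # block -> hist-sub
        q <- cbind(p[, 1] + bilinear_sample(dsp$r, p),
                   p[, 2] + bilinear_sample(dsp$c, p))
        apply_transform(tf, q)
      }
      chain_step("hist_to_block", fwd, inv)
    }),
    chain_step_linear("block_insertion", ins$pose),
    chain_step_linear("photo_to_grid", sf$pose))
  chain <- compose_chain(steps, surface = sf$surface)

  tre <- NULL
  if (!is.null(data$landmarks))
    tre <- target_registration_error(chain, data$landmarks$hist_full,
                                     data$landmarks$mr)
  structure(list(chain = chain, insertion = ins, affine = aff,
                 deformable = def, surface_fit = sf, segmentation = seg,
                 tre = tre, timings = timings),
            class = "chain_fit")
}

#' @export
print.chain_fit <- function(x, ...) {
  cat("chain_fit:\n")
  cat(sprintf("  insertion: %.2f deg, t=(%.2f, %.2f), NMI %.3f\n",
              x$insertion$pose$angle, x$insertion$pose$translation[1],
              x$insertion$pose$translation[2], x$insertion$score))
  cat(sprintf("  affine scale: %.4f\n", sqrt(det(x$affine$transform$A))))
  cat(sprintf("  deformable: min Jacobian %.3f\n", x$deformable$min_jacobian))
  if (!is.null(x$tre))
    cat(sprintf("  landmark TRE: mean %.3f, max %.3f voxels (n=%d)\n",
                x$tre$mean, x$tre$max, x$tre$n))
  invisible(x)
}

#' Provenance record for a pipeline run
#'
#' @param config list of the parameters used.
#' @param inputs named list or character vector of input files (hashed
#'   when they exist on disk).
#' @param timings named list of stage timings, seconds.
#' @param warnings character vector of warnings raised.
#' @return list of class `provenance_record`.
#' @export
provenance_record <- function(config = list(), inputs = character(),
                              timings = list(), warnings = character()) {
  hash_file <- function(f) if (file.exists(f))
    as.character(tools::md5sum(f)) else NA_character_
  structure(list(
    tool = "histomri",
    version = as.character(utils::packageVersion("histomri")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = substr(digest_config(config), 1, 16),
    inputs = if (length(inputs))
      stats::setNames(vapply(inputs, hash_file, ""), inputs) else list(),
    timings = timings, warnings = warnings),
    class = "provenance_record")
}

# Stable hash of a config list via its canonical JSON serialisation.
digest_config <- function(config) {
  js <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(js, tf)
  as.character(tools::md5sum(tf))
}
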