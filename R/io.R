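# File formats: multi-page TIFF stacks with JSON sidecar calibration,
# ground-truth CSVs and scene manifests.

#' Write a field image as a multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered channel-major (all nuclei slices, then all VWF
#' slices), stored as 32-bit float after scaling into `[0, 1]` by a global
#' intensity scale recorded in the sidecar. The sidecar
#' (`<path>.json`) carries pixel size, z-step, page layout and identifiers,
#' playing the role of OME metadata.
#'
#' @param field a [field_image()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path) {
  stopifnot(inherits(field, "field_image"))
  Z <- dim(field$nuclei_channel)[3]
  scale <- max(field$nuclei_channel, field$vwf_channel, 1e-12)
  pages <- c(lapply(seq_len(Z), function(s) field$nuclei_channel[, , s] / scale),
             lapply(seq_len(Z), function(s) field$vwf_channel[, , s] / scale))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(dimension_order = "CZYX", channels = c("nuclei", "vwf"),
               n_slices = Z, size_y = dim(field$nuclei_channel)[1],
               size_x = dim(field$nuclei_channel)[2],
               pixel_size_um = field$pixel_size_um,
               z_step_um = field$z_step_um, intensity_scale = scale,
               field_id = field$field_id, slide_id = field$slide_id,
               condition_id = field$condition_id)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a field image written by [write_field_tiff()]
#'
#' @param path TIFF path (expects the `<path>.json` sidecar next to it; if
#'   absent, `pixel_size_um`, `z_step_um` and `n_slices` must be given).
#' @param pixel_size_um,z_step_um,n_slices fallback calibration when no
#'   sidecar exists.
#' @return a [field_image()].
#' @export
read_field_tiff <- function(path, pixel_size_um = NULL, z_step_um = NULL,
                            n_slices = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list()
  px <- meta$pixel_size_um %||% pixel_size_um %||%
    stop("pixel_size_um not found in sidecar and not supplied")
  zs <- meta$z_step_um %||% z_step_um %||%
    stop("z_step_um not found in sidecar and not supplied")
  Z <- meta$n_slices %||% n_slices %||% (length(pages) %/% 2L)
  if (length(pages) != 2L * Z)
    stop(sprintf("expected %d pages (2 channels x %d slices), found %d",
                 2L * Z, Z, length(pages)))
  scale <- meta$intensity_scale %||% 1
  stack_of <- function(idx) {
    a <- array(0, c(dim(pages[[idx[1]]]), Z))
    for (k in seq_along(idx)) a[, , k] <- pages[[idx[k]]] * scale
    a
  }
  field_image(stack_of(seq_len(Z)), stack_of(Z + seq_len(Z)),
              pixel_size_um = px, z_step_um = zs,
              field_id = meta$field_id %||% basename(path),
              slide_id = meta$slide_id %||% NA_character_,
              condition_id = meta$condition_id %||% NA_character_)
}

#' Write ground truth as a flat CSV
#'
#' One row per object: type (nucleus / wpb / immature), centroid x/y (pixel,
#' 0-based), z_center (slice), two size parameters in pixels (semi-axes for
#' nuclei, length/width for WPBs, radius for vesicles) and orientation.
#'
#' @param truth a `ground_truth` from [render_field()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_csv <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  rows <- list()
  if (nrow(truth$nuclei)) {
    rows$nuc <- data.frame(type = "nucleus", x_px = truth$nuclei$x_px,
                           y_px = truth$nuclei$y_px,
                           z_center = truth$nuclei$z_center,
                           size1_px = truth$nuclei$a_px,
                           size2_px = truth$nuclei$b_px,
                           orientation_rad = truth$nuclei$orientation_rad)
  }
  if (nrow(truth$wpbs)) {
    rows$wpb <- data.frame(type = "wpb", x_px = truth$wpbs$x_px,
                           y_px = truth$wpbs$y_px,
                           z_center = truth$wpbs$z_center,
                           size1_px = truth$wpbs$length_px,
                           size2_px = truth$wpbs$width_px,
                           orientation_rad = truth$wpbs$orientation_rad)
  }
  if (nrow(truth$immature)) {
    rows$imm <- data.frame(type = "immature", x_px = truth$immature$x_px,
                           y_px = truth$immature$y_px,
                           z_center = truth$immature$z_center,
                           size1_px = truth$immature$radius_px,
                           size2_px = NA_real_, orientation_rad = NA_real_)
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(type = character(0), x_px = numeric(0), y_px = numeric(0),
               z_center = numeric(0), size1_px = numeric(0),
               size2_px = numeric(0), orientation_rad = numeric(0))
  }
  rownames(out) <- NULL
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a scene specification as a JSON manifest
#' @param spec a [scene_spec()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_scene_json <- function(spec, path) {
  stopifnot(inherits(spec, "scene_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a scene specification manifest
#' @param path JSON path written by [write_scene_json()] (or a YAML scene
#'   config with the same keys).
#' @return a [scene_spec()].
#' @export
read_scene_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(scene_spec, vals)
}
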