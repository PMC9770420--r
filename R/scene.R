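#' Specify a synthetic imaging scene
#'
#' A scene describes one imaged field: geometry (field size, pixel size,
#' z-stack), object inventory (elliptical nuclei, rod-shaped WPBs rendered as
#' capsules, small round immature vesicles) and acquisition physics
#' (background, Gaussian noise, lateral/axial blur). Defaults follow typical
#' spinning-disc confocal imaging of endothelial monolayers at 60X: 23
#' z-slices at 0.3 um steps, 0.11 um/px lateral sampling, WPBs 1-5 um long
#' and 0.1-0.3 um wide, immature vesicles below 0.5 um radius.
#'
#' Object intensity is peak-normalized: every object's in-focus peak is ~1.0
#' after the lateral blur model, so the scene's signal-to-noise ratio is
#' simply `1 / noise_sd`.
#'
#' @param field_width_px,field_height_px field size in pixels.
#' @param pixel_size_um lateral calibration, um per pixel (> 0).
#' @param n_slices number of z-slices.
#' @param z_step_um z-step between slices in um.
#' @param nucleus_count,wpb_count,immature_count object counts (>= 0).
#' @param nucleus_radius_um (min, max) of nucleus ellipse semi-axes, um.
#' @param wpb_length_um,wpb_width_um (min, max) WPB length and diameter, um.
#' @param immature_radius_um (min, max) immature vesicle radius, um.
#' @param background_level additive background intensity.
#' @param noise_sd per-slice Gaussian noise standard deviation.
#' @param psf_sigma_um lateral Gaussian blur sigma, um (0 = hard edges).
#' @param z_sigma_um axial Gaussian fall-off sigma for WPBs/vesicles, um.
#' @param nucleus_z_sigma_um axial fall-off sigma for nuclei, um.
#' @param min_separation_um minimum surface-to-surface clearance enforced
#'   between VWF-channel objects (non-overlapping placement).
#' @param nucleus_separation_um minimum clearance between nuclei.
#' @param max_place_retries rejection-sampling retries per object before the
#'   scene is rejected as over-dense.
#' @param seed mandatory integer seed; rendering is deterministic given the
#'   spec.
#' @return an object of class `scene_spec`.
#' @seealso [render_field()]
#' @export
scene_spec <- function(field_width_px = 1024L, field_height_px = 1024L,
                       pixel_size_um = 0.11, n_slices = 23L, z_step_um = 0.3,
                       nucleus_count = 0L, nucleus_radius_um = c(4, 8),
                       wpb_count = 0L, wpb_length_um = c(1, 5),
                       wpb_width_um = c(0.1, 0.3),
                       immature_count = 0L, immature_radius_um = c(0.25, 0.45),
                       background_level = 0.1, noise_sd = 0.1,
                       psf_sigma_um = 0.15, z_sigma_um = 0.5,
                       nucleus_z_sigma_um = 1.5,
                       min_separation_um = 0.4, nucleus_separation_um = 1,
                       max_place_retries = 100L, seed) {
  if (missing(seed)) stop("scene_spec: 'seed' is mandatory")
  spec <- list(
    field_width_px = assert_count(field_width_px, "field_width_px", 1L),
    field_height_px = assert_count(field_height_px, "field_height_px", 1L),
    pixel_size_um = assert_scalar(pixel_size_um, "pixel_size_um", 0, TRUE),
    n_slices = assert_count(n_slices, "n_slices", 1L),
    z_step_um = assert_scalar(z_step_um, "z_step_um", 0, TRUE),
    nucleus_count = assert_count(nucleus_count, "nucleus_count"),
    nucleus_radius_um = assert_pair(nucleus_radius_um, "nucleus_radius_um"),
    wpb_count = assert_count(wpb_count, "wpb_count"),
    wpb_length_um = assert_pair(wpb_length_um, "wpb_length_um"),
    wpb_width_um = assert_pair(wpb_width_um, "wpb_width_um"),
    immature_count = assert_count(immature_count, "immature_count"),
    immature_radius_um = assert_pair(immature_radius_um, "immature_radius_um"),
    background_level = assert_scalar(background_level, "background_level", 0),
    noise_sd = assert_scalar(noise_sd, "noise_sd", 0),
    psf_sigma_um = assert_scalar(psf_sigma_um, "psf_sigma_um", 0),
    z_sigma_um = assert_scalar(z_sigma_um, "z_sigma_um", 0, TRUE),
    nucleus_z_sigma_um = assert_scalar(nucleus_z_sigma_um,
                                       "nucleus_z_sigma_um", 0, TRUE),
    min_separation_um = assert_scalar(min_separation_um,
                                      "min_separation_um", 0),
    nucleus_separation_um = assert_scalar(nucleus_separation_um,
                                          "nucleus_separation_um", 0),
    max_place_retries = assert_count(max_place_retries, "max_place_retries", 1L),
    seed = assert_count(seed, "seed"))
  if (spec$field_width_px * spec$field_height_px <= 0)
    stop("scene_spec: zero-area field")
  class(spec) <- "scene_spec"
  spec
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(
    "<scene_spec> %d x %d px @ %.3g um/px, %d z-slices @ %.3g um\n",
    x$field_width_px, x$field_height_px, x$pixel_size_um, x$n_slices,
    x$z_step_um))
  cat(sprintf("  nuclei: %d, WPBs: %d, immature: %d, noise_sd: %.3g, seed: %d\n",
              x$nucleus_count, x$wpb_count, x$immature_count, x$noise_sd,
              x$seed))
  invisible(x)
}

#' Parametric WPB-per-cell curve
#'
#' The expected number of WPBs per cell as a function of local cell density
#' (cells per field). The `logistic` form rises monotonically from `floor`
#' to `ceiling` around `midpoint` with slope `steepness`; `constant` returns
#' `value` everywhere. Curves are stored as parameter lists so that a run
#' manifest remains fully serializable.
#'
#' @param type `"logistic"` or `"constant"`.
#' @param floor,ceiling,midpoint,steepness logistic parameters (ceiling >=
#'   floor, steepness >= 0 for a monotone non-decreasing curve).
#' @param value constant value for `type = "constant"`.
#' @return an object of class `wpb_curve`.
#' @export
wpb_curve <- function(type = c("logistic", "constant"),
                      floor = 50, ceiling = 64, midpoint = 40,
                      steepness = 0.15, value = 60) {
  type <- match.arg(type)
  cv <- if (type == "constant") {
    list(type = "constant", value = assert_scalar(value, "value", 0))
  } else {
    if (ceiling < floor) stop("wpb_curve: ceiling must be >= floor")
    list(type = "logistic",
         floor = assert_scalar(floor, "floor", 0),
         ceiling = assert_scalar(ceiling, "ceiling", 0),
         midpoint = assert_scalar(midpoint, "midpoint"),
         steepness = assert_scalar(steepness, "steepness", 0))
  }
  class(cv) <- "wpb_curve"
  cv
}

#' Evaluate a WPB-per-cell curve at a local density
#'
#' @param curve a [wpb_curve()] (or a bare parameter list from a manifest).
#' @param density cells per field (numeric vector).
#' @return expected WPBs per cell at each density.
#' @export
eval_wpb_curve <- function(curve, density) {
  if (is.null(curve$type)) stop("not a wpb_curve")
  switch(curve$type,
    constant = rep(curve$value, length(density)),
    logistic = curve$floor + (curve$ceiling - curve$floor) /
      (1 + exp(-curve$steepness * (density - curve$midpoint))),
    stop("unknown wpb_curve type: ", curve$type))
}

# default confluency cutoffs (cells/field at 60X) per cell type
.default_cutoffs <- c(HUVEC = 51, ECFC = 75)

#' Specify a simulated WPB experiment
#'
#' An experiment design mirrors the two standard culture strategies for
#' reaching endothelial confluence: `constant_density` seeds at a fixed
#' 30,000 cells/cm^2 and varies incubation time (default 24/48/72/96 h);
#' `constant_time` incubates for a fixed 96 h and varies seeding density
#' (default 5,000/10,000/30,000 cells/cm^2). Each condition is imaged as
#' `slides_per_condition` slides x `fields_per_slide` fields, replicated over
#' `n_experiments` independent experiments.
#'
#' Expected cells per field grow exponentially with doubling time
#' `growth_doubling_time_hr` from the seeded surface density scaled to the
#' field area, and are capped at `carrying_capacity_cells` (contact
#' inhibition). The expected WPB count per cell follows `wpb_per_cell_curve`
#' evaluated at the field's realized cell count.
#'
#' The scene template for experiments defaults to 1024 px fields at 0.25
#' um/px (a ~256 um field of view, consistent with confluent monolayers
#' averaging tens of cells per field); see the package vignette.
#'
#' @param method `"constant_density"` (vary time) or `"constant_time"`
#'   (vary seeding density).
#' @param cell_type `"HUVEC"` or `"ECFC"` (sets doubling time, capacity and
#'   WPB-curve defaults).
#' @param seeding_densities cells/cm^2 (constant_density designs fix this at
#'   30,000).
#' @param time_points_hr incubation times in hours (constant_time designs fix
#'   this at 96).
#' @param slides_per_condition slides (biological replicates) per condition;
#'   fewer than 5 triggers a warning.
#' @param fields_per_slide imaged locations per slide (default 9).
#' @param n_experiments independent experiment replicates.
#' @param growth_doubling_time_hr population doubling time (default 33 h
#'   HUVEC, 26 h ECFC).
#' @param carrying_capacity_cells maximum expected cells per field (default
#'   1.25x the cell type's confluency cutoff).
#' @param wpb_per_cell_curve a [wpb_curve()]; default is a logistic rise with
#'   density (50 to 64 WPB/cell for HUVEC, 85 to 95 for ECFC).
#' @param immature_fraction immature vesicles as a fraction of the WPB count.
#' @param scene named list of [scene_spec()] overrides for rendered fields.
#' @param seed mandatory master seed.
#' @return an object of class `experiment_design`.
#' @seealso [simulate_experiment()]
#' @export
experiment_design <- function(method = c("constant_density", "constant_time"),
                              cell_type = c("HUVEC", "ECFC"),
                              seeding_densities = NULL, time_points_hr = NULL,
                              slides_per_condition = 5L, fields_per_slide = 9L,
                              n_experiments = 3L,
                              growth_doubling_time_hr = NULL,
                              carrying_capacity_cells = NULL,
                              wpb_per_cell_curve = NULL,
                              immature_fraction = 0.15,
                              scene = list(), seed) {
  method <- match.arg(method)
  cell_type <- match.arg(cell_type)
  if (missing(seed)) stop("experiment_design: 'seed' is mandatory")

  if (method == "constant_density") {
    seeding_densities <- seeding_densities %||% 30000
    if (length(seeding_densities) != 1L)
      stop("constant_density designs use a single seeding density")
    time_points_hr <- time_points_hr %||% c(24, 48, 72, 96)
  } else {
    time_points_hr <- time_points_hr %||% 96
    if (length(time_points_hr) != 1L)
      stop("constant_time designs use a single time point")
    seeding_densities <- seeding_densities %||% c(5000, 10000, 30000)
  }
  stopifnot(all(seeding_densities > 0), all(time_points_hr > 0))

  slides_per_condition <- assert_count(slides_per_condition,
                                       "slides_per_condition", 1L)
  if (slides_per_condition < 5L)
    warning("fewer than 5 slides per condition; the standard design images ",
            "at least 5 biological replicates")

  cutoff <- .default_cutoffs[[cell_type]]
  dt_default <- if (cell_type == "HUVEC") 33 else 26
  curve_default <- if (cell_type == "HUVEC") {
    wpb_curve("logistic", floor = 50, ceiling = 64, midpoint = 40,
              steepness = 0.15)
  } else {
    wpb_curve("logistic", floor = 85, ceiling = 95, midpoint = 55,
              steepness = 0.12)
  }

  design <- list(
    method = method, cell_type = cell_type,
    seeding_densities = as.numeric(seeding_densities),
    time_points_hr = as.numeric(time_points_hr),
    slides_per_condition = slides_per_condition,
    fields_per_slide = assert_count(fields_per_slide, "fields_per_slide", 1L),
    n_experiments = assert_count(n_experiments, "n_experiments", 1L),
    growth_doubling_time_hr = assert_scalar(
      growth_doubling_time_hr %||% dt_default, "growth_doubling_time_hr",
      0, TRUE),
    carrying_capacity_cells = assert_scalar(
      carrying_capacity_cells %||% ceiling(1.25 * cutoff),
      "carrying_capacity_cells", 0, TRUE),
    wpb_per_cell_curve = if (is.null(wpb_per_cell_curve)) curve_default else {
      if (is.null(wpb_per_cell_curve$type)) stop("wpb_per_cell_curve must be a wpb_curve")
      wpb_per_cell_curve
    },
    immature_fraction = assert_scalar(immature_fraction, "immature_fraction", 0),
    scene = scene,
    seed = assert_count(seed, "seed"))
  class(design) <- "experiment_design"
  design
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("<experiment_design> %s, %s\n", x$cell_type, x$method))
  cat(sprintf("  densities: %s cells/cm^2; times: %s hr\n",
              paste(x$seeding_densities, collapse = "/"),
              paste(x$time_points_hr, collapse = "/")))
  cat(sprintf("  %d slides x %d fields x %d experiments; DT %.3g hr; seed %d\n",
              x$slides_per_condition, x$fields_per_slide, x$n_experiments,
              x$growth_doubling_time_hr, x$seed))
  invisible(x)
}

# scene template used for simulated experiments: same stack geometry, wider
# field of view (0.25 um/px at 1024 px ~ 256 um) so that cells-per-field
# trajectories are on the scale of the 51/75 cells-per-field confluency
# cutoffs
experiment_scene_defaults <- function() {
  list(field_width_px = 1024L, field_height_px = 1024L, pixel_size_um = 0.25,
       n_slices = 23L, z_step_um = 0.3, background_level = 0.1,
       noise_sd = 0.1, psf_sigma_um = 0.15)
}
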