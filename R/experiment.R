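# Whole-experiment simulation: growth model -> per-field object counts ->
# rendered fields, with the replication structure slides x fields x
# experiments.

#' Simulate a whole imaging experiment
#'
#' For every condition (seeding density x time point), expected cells per
#' field follow exponential growth from the seeded density scaled to the
#' field area, capped at the design's carrying capacity (contact
#' inhibition); each field draws its realized nucleus count from a Poisson
#' around that expectation, and its WPB count from a Poisson with mean
#' `cells x wpb_per_cell_curve(cells)`. Each field is rendered with
#' [render_field()] under a seed derived deterministically from the design
#' seed, so two runs of the same design are identical.
#'
#' Holding every rendered stack of a large design in memory is impractical;
#' pass `field_fun` (e.g. a wrapper around [count_field()]) to map each
#' field to a lightweight result as it is generated. With `field_fun =
#' NULL` the rendered image and ground truth are kept.
#'
#' @param design an [experiment_design()].
#' @param field_fun optional `function(image, truth)` applied to each field;
#'   its return value is stored in place of the field.
#' @return an object of class `simulated_experiment`: `design`, `fields`
#'   (data frame: condition_id, cell_type, method, seeding_density, time_hr,
#'   experiment, slide_id, field_index, seed, true object counts), and
#'   `results` (list parallel to the rows of `fields`).
#' @examples
#' des <- experiment_design("constant_density", "HUVEC",
#'                          time_points_hr = 96, slides_per_condition = 5,
#'                          n_experiments = 1,
#'                          wpb_per_cell_curve = wpb_curve("constant",
#'                                                         value = 5),
#'                          scene = list(field_width_px = 96,
#'                                       field_height_px = 96,
#'                                       pixel_size_um = 0.25,
#'                                       n_slices = 5),
#'                          seed = 11)
#' sim <- simulate_experiment(des, field_fun = function(img, truth) NULL)
#' nrow(sim$fields)  # 5 slides x 9 fields
#' @export
simulate_experiment <- function(design, field_fun = NULL) {
  stopifnot(inherits(design, "experiment_design"))
  scn <- utils::modifyList(experiment_scene_defaults(), design$scene)
  px <- scn$pixel_size_um %||% stop("scene template lacks pixel_size_um")
  field_area_cm2 <- (scn$field_width_px * px * 1e-4) *
    (scn$field_height_px * px * 1e-4)

  conds <- expand.grid(seeding_density = design$seeding_densities,
                       time_hr = design$time_points_hr)
  S <- design$slides_per_condition
  FPS <- design$fields_per_slide
  E <- design$n_experiments
  n_fields <- nrow(conds) * S * FPS * E

  rows <- vector("list", n_fields)
  results <- vector("list", n_fields)
  i <- 0L
  for (e in seq_len(E)) {
    for (ci in seq_len(nrow(conds))) {
      dens <- conds$seeding_density[ci]
      t_hr <- conds$time_hr[ci]
      cond_id <- sprintf("d%g_t%g", dens, t_hr)
      lambda_cells <- min(design$carrying_capacity_cells,
                          dens * field_area_cm2 *
                            2^(t_hr / design$growth_doubling_time_hr))
      for (s in seq_len(S)) {
        slide_id <- sprintf("e%d_%s_s%d", e, cond_id, s)
        for (f in seq_len(FPS)) {
          i <- i + 1L
          idx <- i - 1L
          draw_seed <- derive_seed(design$seed, 2L * idx)
          spec_seed <- derive_seed(design$seed, 2L * idx + 1L)
          nn <- withr::with_seed(draw_seed, {
            n_nuc <- rpois(1L, lambda_cells)
            rate <- eval_wpb_curve(design$wpb_per_cell_curve, n_nuc)
            n_wpb <- rpois(1L, n_nuc * rate)
            n_imm <- rpois(1L, design$immature_fraction * n_nuc * rate)
            c(n_nuc, n_wpb, n_imm)
          })
          spec <- do.call(scene_spec,
                          c(scn, list(nucleus_count = nn[1],
                                      wpb_count = nn[2],
                                      immature_count = nn[3],
                                      seed = spec_seed)))
          fld <- tryCatch(
            render_field(spec, field_id = sprintf("%s_f%d", slide_id, f),
                         slide_id = slide_id, condition_id = cond_id),
            error = function(err) {
              stop(sprintf("condition %s (slide %s, field %d): %s", cond_id,
                           slide_id, f, conditionMessage(err)), call. = FALSE)
            })
          results[[i]] <- if (is.null(field_fun)) fld else {
            field_fun(fld$image, fld$truth)
          }
          rows[[i]] <- data.frame(
            condition_id = cond_id, cell_type = design$cell_type,
            method = design$method, seeding_density = dens, time_hr = t_hr,
            experiment = e, slide_id = slide_id, field_index = f,
            seed = spec_seed, n_nuclei_true = nn[1], n_wpb_true = nn[2],
            n_immature_true = nn[3], stringsAsFactors = FALSE)
        }
      }
    }
  }
  fields <- do.call(rbind, rows)
  rownames(fields) <- NULL
  structure(list(design = design, fields = fields, results = results),
            class = "simulated_experiment")
}

#' @export
print.simulated_experiment <- function(x, ...) {
  cat(sprintf("<simulated_experiment> %s %s: %d fields across %d condition(s)\n",
              x$design$cell_type, x$design$method, nrow(x$fields),
              length(unique(x$fields$condition_id))))
  invisible(x)
}

#' Count every field of a simulated experiment
#'
#' Convenience helper: simulates the experiment with [count_field()] as the
#' streaming per-field function and returns the per-field counts table with
#' design metadata attached, ready for [summarize_slides()].
#'
#' @param design an [experiment_design()].
#' @param params a [pipeline_params()].
#' @return a data frame of per-field counts plus metadata and true counts.
#' @export
count_experiment <- function(design, params = pipeline_params()) {
  sim <- simulate_experiment(design, field_fun = function(img, truth) {
    count_field(img, params)$counts
  })
  counts <- do.call(rbind, sim$results)
  cbind(counts,
        sim$fields[, c("cell_type", "method", "seeding_density", "time_hr",
                       "experiment", "n_nuclei_true", "n_wpb_true",
                       "n_immature_true")])
}
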