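# End-to-end orchestration: config -> simulate -> quantify -> cohort ->
# stats, with a manifest that reproduces the run bit-for-bit.

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  config
}

validate_run_config <- function(config) {
  if (is.null(config$design))
    stop("config validation: 'design' section is required")
  if (is.null(config$design$seed))
    stop("config validation: design$seed is required (runs must be seeded)")
  scn <- utils::modifyList(experiment_scene_defaults(),
                           config$design$scene %||% list())
  if (is.null(scn$pixel_size_um))
    stop("config validation: scene pixel_size_um is required")
  if (is.null(scn$z_step_um))
    stop("config validation: scene z_step_um is required")
  invisible(config)
}

# canonical, fully serializable form of the configuration: this is the run
# manifest, and feeding it back to run_pipeline() reproduces every output
# file identically
canonical_config <- function(config, design, params) {
  list(design = list(
         method = design$method, cell_type = design$cell_type,
         seeding_densities = design$seeding_densities,
         time_points_hr = design$time_points_hr,
         slides_per_condition = design$slides_per_condition,
         fields_per_slide = design$fields_per_slide,
         n_experiments = design$n_experiments,
         growth_doubling_time_hr = design$growth_doubling_time_hr,
         carrying_capacity_cells = design$carrying_capacity_cells,
         wpb_per_cell_curve = unclass(design$wpb_per_cell_curve),
         immature_fraction = design$immature_fraction,
         scene = design$scene, seed = design$seed),
       pipeline = unclass(params),
       cutoff = config$cutoff %||% list(cell_type = design$cell_type),
       groupings = config$groupings %||% c("by_confluency", "by_time"),
       growth = config$growth,
       save_images = isTRUE(config$save_images),
       package_version = as.character(packageVersion("wpbquant")))
}

build_design <- function(dcfg) {
  args <- dcfg[intersect(names(dcfg),
                         names(formals(experiment_design)))]
  do.call(experiment_design, args)
}

build_params <- function(pcfg) {
  args <- (pcfg %||% list())[intersect(names(pcfg %||% list()),
                                       names(formals(pipeline_params)))]
  do.call(pipeline_params, args)
}

stage_msg <- function(stage, t0) {
  message(sprintf("[%s] done in %.1f s", stage,
                  as.numeric(proc.time()[3] - t0)))
}

#' Run the full simulate -> quantify -> cohort -> stats pipeline
#'
#' Validates the configuration, simulates the experiment design, counts
#' every field, aggregates per-slide WPB/nuclei statistics, assembles
#' cohort comparisons, and writes a reproducible report bundle to
#' `out_dir`: `counts.csv` (per field), `slides.csv`, `cohorts.csv`,
#' `stats.json`, `summary.txt` and `manifest.json`. Rerunning with the
#' saved manifest regenerates every file identically (all randomness is
#' derived from the seeds the manifest records; no timestamps are written).
#'
#' @param config a configuration list, or a path to a YAML/JSON config. See
#'   the package vignette and `inst/extdata/demo_run.yaml` for the schema
#'   (sections: design, pipeline, cutoff, groupings, growth, save_images).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the output paths and the key tables.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- read_run_config(config)
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  design <- build_design(config$design)
  params <- build_params(config$pipeline)
  manifest <- canonical_config(config, design, params)

  cutcfg <- manifest$cutoff
  cutoff <- confluency_cutoff(cutcfg$cell_type %||% design$cell_type,
                              cutcfg$cells_per_field_cutoff)

  t0 <- proc.time()[3]
  save_dir <- file.path(out_dir, "fields")
  if (manifest$save_images) dir.create(save_dir, showWarnings = FALSE)
  sim <- simulate_experiment(design, field_fun = function(img, truth) {
    if (manifest$save_images) {
      write_field_tiff(img, file.path(save_dir, paste0(img$field_id, ".tif")))
      write_ground_truth_csv(truth, file.path(save_dir,
                                              paste0(img$field_id, ".csv")))
    }
    count_field(img, params)$counts
  })
  counts <- cbind(do.call(rbind, sim$results),
                  sim$fields[, c("cell_type", "method", "seeding_density",
                                 "time_hr", "experiment", "n_nuclei_true",
                                 "n_wpb_true", "n_immature_true")])
  stage_msg("simulate+count", t0)

  t0 <- proc.time()[3]
  slides <- summarize_slides(counts, cutoff)
  cohorts <- do.call(rbind, lapply(manifest$groupings, function(g) {
    assign_cohorts(slides, g)
  }))
  stage_msg("quantify", t0)

  t0 <- proc.time()[3]
  stats <- list()
  for (g in manifest$groupings) {
    tab <- cohorts[cohorts$grouping == g, , drop = FALSE]
    groups <- split(tab$wpb_per_nuclei, tab$group)
    entry <- list(groups = lapply(groups, function(v) {
      list(n = length(v), mean = mean(v), sd = if (length(v) > 1) sd(v) else NA)
    }))
    if (length(groups) >= 2L && all(vapply(groups, length, integer(1)) >= 2L)) {
      an <- one_way_anova(groups)
      entry$one_way_anova <- list(f_statistic = an$f_statistic,
                                  df_between = an$df_between,
                                  df_within = an$df_within,
                                  p_value = an$p_value)
    } else {
      entry$one_way_anova <- "not testable (need >= 2 groups with >= 2 slides)"
    }
    stats[[g]] <- entry
  }

  if (!is.null(manifest$growth)) {
    gcfg <- manifest$growth
    gstats <- list()
    series <- list()
    dts <- gcfg$doubling_times_hr %||%
      setNames(list(design$growth_doubling_time_hr), design$cell_type)
    for (ct in names(dts)) {
      s <- simulate_growth_counts(
        gcfg$seed_density %||% 100, dts[[ct]],
        gcfg$times_hr %||% c(4, 24, 48, 72, 96),
        noise = gcfg$noise %||% "poisson",
        seed = derive_seed(gcfg$seed %||% design$seed, match(ct, names(dts))),
        cell_type = ct)
      series[[ct]] <- s
      reg <- fit_growth_regression(s)
      gstats[[ct]] <- list(
        mean_doubling_time_hr = suppressWarnings(mean_doubling_time(s)),
        regression = list(slope = reg$slope, r_squared = reg$r_squared,
                          p_value = reg$p_value))
    }
    if (length(series) == 2L) {
      st <- slopes_equal_test(series[[1]], series[[2]])
      gstats$slopes_equal <- list(f_statistic = st$f_statistic,
                                  p_value = st$p_value)
    }
    stats$growth <- gstats
  }
  stage_msg("stats", t0)

  paths <- list(counts = file.path(out_dir, "counts.csv"),
                slides = file.path(out_dir, "slides.csv"),
                cohorts = file.path(out_dir, "cohorts.csv"),
                stats = file.path(out_dir, "stats.json"),
                summary = file.path(out_dir, "summary.txt"),
                manifest = file.path(out_dir, "manifest.json"))
  write.csv(counts, paths$counts, row.names = FALSE)
  write.csv(slides, paths$slides, row.names = FALSE)
  write.csv(cohorts, paths$cohorts, row.names = FALSE)
  jsonlite::write_json(stats, paths$stats, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  lines <- c(
    sprintf("wpbquant run: %s, %s", design$cell_type, design$method),
    sprintf("fields: %d (%d slides x %d fields x %d experiments per condition)",
            nrow(counts), design$slides_per_condition,
            design$fields_per_slide, design$n_experiments),
    sprintf("conditions: %s",
            paste(unique(counts$condition_id), collapse = ", ")),
    sprintf("confluency cutoff: %.3g cells/field (%s)",
            cutoff$cells_per_field_cutoff, cutoff$cell_type),
    "",
    "per-slide WPB/nuclei:",
    sprintf("  %s [%s]: %.2f (mean cells/field %.1f)", slides$slide_id,
            slides$confluency, slides$wpb_per_nuclei,
            slides$mean_cells_per_field))
  for (g in manifest$groupings) {
    an <- stats[[g]]$one_way_anova
    lines <- c(lines, "", sprintf("grouping %s:", g))
    for (nm in names(stats[[g]]$groups)) {
      gr <- stats[[g]]$groups[[nm]]
      lines <- c(lines, sprintf("  %s: mean %.2f (n = %d)", nm, gr$mean, gr$n))
    }
    if (is.list(an))
      lines <- c(lines, sprintf("  one-way ANOVA: F = %.4g, p = %.4g",
                                an$f_statistic, an$p_value))
  }
  writeLines(lines, paths$summary)

  invisible(list(paths = paths, counts = counts, slides = slides,
                 cohorts = cohorts, stats = stats, manifest = manifest))
}
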