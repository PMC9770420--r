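# Per-slide aggregation of field counts and confluency cohorting.

#' Confluency cutoff for a cell type
#'
#' Confluence (a cohesive monolayer covering ~80% of the culture surface) is
#' operationalized as a mean cells-per-field cutoff at 60X: 51 cells/field
#' for HUVECs and 75 for ECFCs by default. The comparison is inclusive: a
#' slide averaging exactly the cutoff is classified confluent.
#'
#' @param cell_type `"HUVEC"` or `"ECFC"`.
#' @param cells_per_field_cutoff override for the default cutoff (> 0).
#' @param surface_coverage_definition documented coverage fraction the
#'   cutoff stands for (not used computationally).
#' @return an object of class `confluency_cutoff`.
#' @export
confluency_cutoff <- function(cell_type = c("HUVEC", "ECFC"),
                              cells_per_field_cutoff = NULL,
                              surface_coverage_definition = 0.80) {
  cell_type <- match.arg(cell_type)
  cutoff <- cells_per_field_cutoff %||% .default_cutoffs[[cell_type]]
  assert_scalar(cutoff, "cells_per_field_cutoff", 0, TRUE)
  structure(list(cell_type = cell_type, cells_per_field_cutoff = cutoff,
                 surface_coverage_definition = surface_coverage_definition),
            class = "confluency_cutoff")
}

#' Summarize one slide's field counts
#'
#' Pools the slide's fields into the central statistic WPB/nuclei =
#' total WPBs / total nuclei (the pooled ratio is robust to low-count
#' fields; `ratio = "mean_of_fields"` instead averages per-field ratios).
#' The slide is classified `confluent` when its mean cells per field is at
#' or above the cutoff, `sub_confluent` otherwise. A slide with zero total
#' nuclei is flagged invalid (with a warning) so cohort assembly can exclude
#' it.
#'
#' @param field_counts data frame of per-field counts (columns
#'   `nuclei_count`, `wpb_count`, and a single `slide_id`).
#' @param cutoff a [confluency_cutoff()].
#' @param ratio `"pooled"` (default) or `"mean_of_fields"`.
#' @return a one-row data frame (class `slide_result`): slide_id,
#'   condition_id, n_fields, total_nuclei, total_wpb, wpb_per_nuclei,
#'   mean_cells_per_field, confluency, valid.
#' @examples
#' fc <- data.frame(field_id = c("f1", "f2"), slide_id = "s1",
#'                  condition_id = "c1", nuclei_count = c(10, 10),
#'                  wpb_count = c(500, 760))
#' summarize_slide(fc, confluency_cutoff("HUVEC"))$wpb_per_nuclei  # 63
#' @export
summarize_slide <- function(field_counts, cutoff = confluency_cutoff("HUVEC"),
                            ratio = c("pooled", "mean_of_fields")) {
  ratio <- match.arg(ratio)
  stopifnot(is.data.frame(field_counts), nrow(field_counts) >= 1L,
            all(c("nuclei_count", "wpb_count") %in% names(field_counts)),
            inherits(cutoff, "confluency_cutoff"))
  sid <- unique(field_counts$slide_id %||% "slide1")
  if (length(sid) != 1L)
    stop("field_counts must come from a single slide; got: ",
         paste(sid, collapse = ", "))
  total_nuclei <- sum(field_counts$nuclei_count)
  total_wpb <- sum(field_counts$wpb_count)
  n_fields <- nrow(field_counts)
  mean_cells <- total_nuclei / n_fields
  valid <- total_nuclei > 0
  wpn <- if (!valid) {
    warning(sprintf("slide %s has zero nuclei; flagged invalid", sid))
    NA_real_
  } else if (ratio == "pooled") {
    total_wpb / total_nuclei
  } else {
    ok <- field_counts$nuclei_count > 0
    mean(field_counts$wpb_count[ok] / field_counts$nuclei_count[ok])
  }
  out <- data.frame(
    slide_id = sid,
    condition_id = unique(field_counts$condition_id %||% NA_character_)[1],
    n_fields = n_fields, total_nuclei = total_nuclei, total_wpb = total_wpb,
    wpb_per_nuclei = wpn, mean_cells_per_field = mean_cells,
    confluency = if (mean_cells >= cutoff$cells_per_field_cutoff)
      "confluent" else "sub_confluent",
    valid = valid, stringsAsFactors = FALSE)
  class(out) <- c("slide_result", class(out))
  out
}

#' Summarize every slide in a counts table
#'
#' Convenience wrapper applying [summarize_slide()] per `slide_id` and
#' carrying slide-level metadata columns (cell_type, method,
#' seeding_density, time_hr) through when present and constant per slide.
#'
#' @param counts data frame of per-field counts with a `slide_id` column.
#' @param cutoff a [confluency_cutoff()].
#' @param ratio see [summarize_slide()].
#' @return a data frame with one row per slide.
#' @export
summarize_slides <- function(counts, cutoff = confluency_cutoff("HUVEC"),
                             ratio = "pooled") {
  stopifnot("slide_id" %in% names(counts))
  meta_cols <- intersect(c("cell_type", "method", "seeding_density",
                           "time_hr", "experiment"), names(counts))
  rows <- lapply(split(counts, counts$slide_id), function(fc) {
    sr <- summarize_slide(fc, cutoff, ratio)
    for (mc in meta_cols) {
      v <- unique(fc[[mc]])
      sr[[mc]] <- if (length(v) == 1L) v else NA
    }
    sr
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

cohort_group_col <- function(grouping) {
  switch(grouping,
         by_confluency = "confluency",
         by_method = "method",
         by_time = "time_hr",
         by_density = "seeding_density",
         stop("unknown grouping: ", grouping))
}

#' Assign slides to comparison cohorts
#'
#' Partitions slide-level results into disjoint, exhaustive groups for one
#' grouping variable: `by_confluency` (sub-confluent vs confluent),
#' `by_method` (constant-density vs constant-time culture design),
#' `by_time`, or `by_density`. Invalid slides (zero nuclei) are dropped with
#' a message; missing metadata raises an error naming the slide.
#'
#' @param slides data frame from [summarize_slides()].
#' @param grouping one of `"by_confluency"`, `"by_method"`, `"by_time"`,
#'   `"by_density"`.
#' @return a data frame (class `cohort_table`) with columns cell_type,
#'   grouping, group, slide_id, wpb_per_nuclei.
#' @export
assign_cohorts <- function(slides,
                           grouping = c("by_confluency", "by_method",
                                        "by_time", "by_density")) {
  grouping <- match.arg(grouping)
  if (nrow(slides) == 0L) {
    out <- data.frame(cell_type = character(0), grouping = character(0),
                      group = character(0), slide_id = character(0),
                      wpb_per_nuclei = numeric(0))
    class(out) <- c("cohort_table", class(out))
    return(out)
  }
  col <- cohort_group_col(grouping)
  if (!col %in% names(slides))
    stop(sprintf("grouping '%s' needs column '%s' in the slide table",
                 grouping, col))
  if ("valid" %in% names(slides) && any(!slides$valid)) {
    message(sprintf("excluding %d invalid slide(s): %s", sum(!slides$valid),
                    paste(slides$slide_id[!slides$valid], collapse = ", ")))
    slides <- slides[slides$valid, , drop = FALSE]
  }
  bad <- is.na(slides[[col]])
  if (any(bad))
    stop(sprintf("slide(s) missing '%s' metadata: %s", col,
                 paste(slides$slide_id[bad], collapse = ", ")))
  out <- data.frame(
    cell_type = if ("cell_type" %in% names(slides)) slides$cell_type
                else NA_character_,
    grouping = grouping,
    group = as.character(slides[[col]]),
    slide_id = slides$slide_id,
    wpb_per_nuclei = slides$wpb_per_nuclei,
    stringsAsFactors = FALSE)
  sizes <- table(out$group)
  message(sprintf("cohorts (%s): %s", grouping,
                  paste(sprintf("%s = %d", names(sizes), sizes),
                        collapse = ", ")))
  class(out) <- c("cohort_table", class(out))
  out
}

#' Keep only slides at a design's confluency endpoint
#'
#' When two culture designs are compared at their confluent endpoints, a
#' constant-density design contributes its final time point (default 96 h)
#' and a constant-time design contributes its highest seeding density
#' (default 30,000 cells/cm^2). Slides from other conditions are dropped.
#'
#' @param slides slide-level data frame with `method` plus `time_hr` /
#'   `seeding_density` columns.
#' @param endpoint_time_hr,endpoint_density endpoint condition values.
#' @return the filtered slide data frame (with a warning if empty).
#' @export
method_endpoint_filter <- function(slides, endpoint_time_hr = 96,
                                   endpoint_density = 30000) {
  stopifnot("method" %in% names(slides))
  keep <- rep(FALSE, nrow(slides))
  cd <- slides$method == "constant_density"
  if (any(cd)) keep[cd] <- slides$time_hr[cd] == endpoint_time_hr
  ct <- slides$method == "constant_time"
  if (any(ct)) keep[ct] <- slides$seeding_density[ct] == endpoint_density
  out <- slides[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("no slides match the confluency endpoints")
  rownames(out) <- NULL
  out
}
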