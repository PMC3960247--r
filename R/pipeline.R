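# End-to-end orchestration: scan -> grid -> mask -> crop -> threshold ->
# consistency check -> invert -> measure, with optional sub-region
# reanalysis and QC artifacts. The stage order is fixed; every stage error
# carries the stage name and, where applicable, the well id.

#' Assemble an analysis configuration
#'
#' Defaults mirror the method's standard constants: 5% concentric crop,
#' cross-well consistency check with the wells rescaled to maximum intensity
#' 200 and tolerance 50 scaled units.
#'
#' @param input A file path (TIFF/PNG) or a [plate_image()].
#' @param layout A [plate_layout()] or a built-in name (`"6"`, `"12"`, `"24"`).
#' @param roi Selection rectangle `c(x0, y0, x1, y1)` enclosing the wells.
#' @param wells Well ids to analyse (vector or `"A1:C4"` range); default all.
#' @param crop_fraction Concentric crop (fraction of diameter), default 0.05.
#' @param tolerance Consistency-check tolerance in scaled units, default 50.
#' @param harmonize Run the cross-well consistency check (default `TRUE`).
#' @param manual_thresholds `NULL`, a single intensity, or a named per-well
#'   map; when given, automatic detection is bypassed.
#' @param min_cell_area Passed to [detect_threshold()].
#' @param subregion Optional rectangle `c(col0, row0, col1, row1)` in
#'   well-image coordinates for sub-region reanalysis.
#' @param subregion_wells Wells to reanalyse with `subregion`; default all.
#' @param dpi_override Resolution override for [read_scan()].
#' @param out_csv,out_montage,out_threshold_log Optional output paths; when
#'   `NULL` the corresponding artifact is not written.
#' @param csv_digits Decimal places for percentages in the results CSV.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(input, layout = "12", roi, wells = NULL,
                            crop_fraction = 0.05, tolerance = 50,
                            harmonize = TRUE, manual_thresholds = NULL,
                            min_cell_area = 0, subregion = NULL,
                            subregion_wells = NULL, dpi_override = NULL,
                            out_csv = NULL, out_montage = NULL,
                            out_threshold_log = NULL, csv_digits = 4) {
  if (!inherits(layout, "plate_layout")) layout <- plate_layout(layout)
  structure(list(input = input, layout = layout, roi = roi, wells = wells,
                 crop_fraction = crop_fraction, tolerance = tolerance,
                 harmonize = harmonize, manual_thresholds = manual_thresholds,
                 min_cell_area = min_cell_area, subregion = subregion,
                 subregion_wells = subregion_wells,
                 dpi_override = dpi_override, out_csv = out_csv,
                 out_montage = out_montage,
                 out_threshold_log = out_threshold_log,
                 csv_digits = csv_digits),
            class = "analysis_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    e$message <- sprintf("[stage %s] %s", name, conditionMessage(e))
    stop(e)
  })
}

#' Run the full colony-quantification pipeline
#'
#' @param config An [analysis_config()].
#' @return An object of class `plate_analysis`: `measurements` (results
#'   table, see [measure_stack()]), `thresholds` (per-well threshold log),
#'   `subregion_measurements` (if configured), `wells`, `inverted` (the
#'   cropped and the thresholded stacks), and `summary` (flag counts).
#' @export
run_analysis <- function(config) {
  if (!inherits(config, "analysis_config")) {
    stop_validation("'config' must be an analysis_config")
  }
  image <- stage("read", {
    if (inherits(config$input, "plate_image")) config$input
    else read_scan(config$input, dpi_override = config$dpi_override)
  })
  grid <- stage("grid", grid_from_selection(config$roi, config$layout,
                                            selected_wells = config$wells,
                                            image = image))
  masked <- stage("mask", mask_interwell(image, grid))
  wells <- stage("crop", crop_well_stack(masked, grid,
                                         crop_fraction = config$crop_fraction))

  if (is.null(config$manual_thresholds)) {
    results <- stage("threshold", lapply(wells, function(w) {
      detect_threshold(area_threshold_curve(w),
                       min_cell_area = config$min_cell_area)
    }))
    if (isTRUE(config$harmonize) && length(wells) >= 2L) {
      results <- stage("harmonize",
                       harmonize_thresholds(wells, results,
                                            tolerance = config$tolerance,
                                            min_cell_area = config$min_cell_area))
    }
    inverted <- stage("invert", mapply(function(w, r) {
      apply_threshold_invert(w, min(r$threshold, 254L), method = r$method,
                             flagged = r$flagged)
    }, wells, results, SIMPLIFY = FALSE))
  } else {
    inverted <- stage("threshold", manual_threshold(wells, config$manual_thresholds))
    results <- mapply(function(w, tw) {
      threshold_result(tw$threshold, max(w$pixels[w$mask]), method = "manual")
    }, wells, inverted, SIMPLIFY = FALSE)
  }

  threshold_log <- data.frame(
    well_id = vapply(wells, function(w) w$well_id, character(1)),
    threshold = vapply(results, function(r) r$threshold, integer(1)),
    scaled_threshold = vapply(results, function(r) r$scaled_threshold, integer(1)),
    max_intensity = vapply(results, function(r) r$max_intensity, integer(1)),
    method = vapply(results, function(r) r$method, character(1)),
    flagged = vapply(results, function(r) r$flagged, logical(1)),
    stringsAsFactors = FALSE
  )

  measurements <- stage("measure", measure_stack(inverted))

  subregion_measurements <- NULL
  if (!is.null(config$subregion)) {
    subregion_measurements <- stage("subregion",
      measure_stack(inverted, region = config$subregion,
                    subset = config$subregion_wells))
  }

  if (!is.null(config$out_csv)) {
    write_measurements(measurements, config$out_csv, digits = config$csv_digits)
  }
  if (!is.null(config$out_threshold_log)) {
    utils::write.csv(threshold_log, config$out_threshold_log, row.names = FALSE,
                     quote = FALSE)
  }
  if (!is.null(config$out_montage)) {
    write_well_montage(wells, inverted, config$out_montage)
  }

  structure(list(
    measurements = measurements,
    thresholds = threshold_log,
    subregion_measurements = subregion_measurements,
    wells = wells,
    inverted = inverted,
    summary = list(n_wells = length(wells),
                   n_flagged = sum(threshold_log$flagged),
                   n_no_colonies = sum(threshold_log$method == "no_colonies"))
  ), class = "plate_analysis")
}

#' @export
print.plate_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<plate_analysis> %d wells (%d flagged, %d without colonies)\n",
              s$n_wells, s$n_flagged, s$n_no_colonies))
  print(x$measurements[, c("well_id", "area_pct", "intensity_pct",
                           "threshold", "threshold_method", "flags")],
        digits = 4)
  invisible(x)
}
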