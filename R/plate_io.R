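# Image input and tabular/QC output.
#
# Scans of crystal-violet-stained plates arrive as TIFF or PNG, greyscale or
# RGB, 8- or 16-bit. Everything downstream operates on 8-bit greyscale
# integer matrices (0 = black, 255 = white), the representation the analysis
# was designed around.

#' Construct a plate image
#'
#' A `plate_image` is an 8-bit greyscale raster of a whole scanned plate plus
#' the scan resolution. Pixels are stored as an integer matrix indexed
#' `[y, x]` (row 1 is the top scan line), values in 0--255.
#'
#' @param pixels Integer or numeric matrix with values in 0--255.
#' @param dpi Scan resolution in dots per inch (positive number). Links the
#'   plate's millimetre geometry to pixel coordinates.
#' @param source Provenance string (file path or generator description).
#' @return An object of class `plate_image` with fields `pixels`, `dpi`,
#'   `source`.
#' @export
plate_image <- function(pixels, dpi, source = "<memory>") {
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop_validation("'pixels' must be a matrix with at least one pixel")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop_validation("pixel values must lie in [0, 255] with no missing values")
  }
  if (!is_scalar_number(dpi) || dpi <= 0) {
    stop_validation("'dpi' must be a single positive number")
  }
  pixels <- matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels))
  structure(list(pixels = pixels, dpi = dpi, source = as.character(source)),
            class = "plate_image")
}

#' @export
print.plate_image <- function(x, ...) {
  cat(sprintf("<plate_image> %d x %d px, %g dpi, source: %s\n",
              ncol(x$pixels), nrow(x$pixels), x$dpi, x$source))
  invisible(x)
}

#' @export
dim.plate_image <- function(x) dim(x$pixels)

#' Read a plate scan from TIFF or PNG
#'
#' Decodes the file, converts colour images to 8-bit greyscale (see
#' [to_grayscale_8bit()]) and linearly rescales 16-bit samples to 0--255 by
#' min--max. Resolution is taken from the file metadata where present; files
#' without resolution metadata require `dpi_override`.
#'
#' @param path Path to a TIFF or PNG file.
#' @param dpi_override Optional positive number; replaces (or supplies) the
#'   scan resolution.
#' @param gray_method Passed to [to_grayscale_8bit()] for colour inputs.
#' @return A [plate_image()].
#' @export
read_scan <- function(path, dpi_override = NULL, gray_method = c("mean", "luma")) {
  gray_method <- match.arg(gray_method)
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_format("file not found: %s", path)
  }
  magic <- readBin(path, "raw", n = 4L)
  is_png <- length(magic) >= 4L &&
    identical(magic, as.raw(c(0x89, 0x50, 0x4e, 0x47)))
  is_tiff <- length(magic) >= 4L &&
    (identical(magic[1:2], as.raw(c(0x49, 0x49))) ||
     identical(magic[1:2], as.raw(c(0x4d, 0x4d))))
  if (!is_png && !is_tiff) {
    stop_format("unsupported image format (expected TIFF or PNG): %s", path)
  }

  dpi <- NULL
  if (is_tiff) {
    img <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
                    error = function(e) stop_format("cannot decode TIFF %s: %s",
                                                    path, conditionMessage(e)))
    bits <- attr(img, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
    xres <- attr(img, "x.resolution")
    unit <- attr(img, "resolution.unit")
    if (!is.null(xres) && is.finite(xres) && xres > 0) {
      dpi <- if (identical(unit, "cm")) xres * 2.54 else xres
    }
    samples <- img
    # some encodings come back as 0-1 doubles even with as.is = TRUE
    if (is.double(samples) && max(samples) <= 1 && bits > 1L) {
      samples <- samples * (2^bits - 1)
    }
  } else {
    img <- tryCatch(png::readPNG(path, info = TRUE),
                    error = function(e) stop_format("cannot decode PNG %s: %s",
                                                    path, conditionMessage(e)))
    info <- attr(img, "info")
    bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    if (!is.null(info$dpi) && all(is.finite(info$dpi)) && info$dpi[1] > 0) {
      dpi <- round(info$dpi[1])
    }
    # readPNG returns [0, 1]; restore integer sample values
    samples <- img * (2^bits - 1)
  }

  # drop an alpha channel if present (flat scans carry no transparency)
  if (length(dim(samples)) == 3L && dim(samples)[3] %in% c(2L, 4L)) {
    samples <- samples[, , -dim(samples)[3], drop = FALSE]
    if (dim(samples)[3] == 1L) samples <- samples[, , 1L]
  }

  if (bits > 8L) {
    rng <- range(samples)
    samples <- if (rng[2] > rng[1]) {
      (samples - rng[1]) / (rng[2] - rng[1]) * 255
    } else {
      samples / (2^bits - 1) * 255
    }
  }

  if (length(dim(samples)) == 3L) {
    pixels <- gray_from_channels(samples, gray_method)
  } else {
    pixels <- round_half_up(as.matrix(samples))
  }

  if (!is.null(dpi_override)) {
    if (!is_scalar_number(dpi_override) || dpi_override <= 0) {
      stop_validation("'dpi_override' must be a single positive number")
    }
    dpi <- dpi_override
  }
  if (is.null(dpi)) {
    stop_validation(
      "%s carries no resolution metadata; supply 'dpi_override'", path)
  }
  plate_image(pixels, dpi = dpi, source = path)
}

gray_from_channels <- function(arr, method) {
  r <- arr[, , 1, drop = FALSE]; g <- arr[, , 2, drop = FALSE]
  b <- arr[, , 3, drop = FALSE]
  out <- if (method == "luma") {
    0.299 * r + 0.587 * g + 0.114 * b
  } else {
    (r + g + b) / 3
  }
  matrix(round_half_up(out), dim(arr)[1], dim(arr)[2])
}

#' Convert an RGB raster to 8-bit greyscale
#'
#' Default conversion is the unweighted channel mean `(r + g + b) / 3`,
#' rounded half-up -- the plain 8-bit conversion of common image software.
#' `method = "luma"` uses Rec.601 weights (0.299, 0.587, 0.114) instead.
#' Already-grey triples `(v, v, v)` map to `v` under either method.
#'
#' @param rgb Numeric array `h x w x 3` with channel values in 0--255, or a
#'   matrix (already grey, returned after rounding).
#' @param dpi Resolution for the returned image.
#' @param method `"mean"` (default) or `"luma"`.
#' @return A [plate_image()].
#' @export
to_grayscale_8bit <- function(rgb, dpi = 1200, method = c("mean", "luma")) {
  method <- match.arg(method)
  if (is.matrix(rgb)) {
    return(plate_image(round_half_up(rgb), dpi = dpi, source = "<grayscale>"))
  }
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L) {
    stop_validation("'rgb' must be an h x w x 3 array or a matrix")
  }
  if (anyNA(rgb) || min(rgb) < 0 || max(rgb) > 255) {
    stop_validation("channel values must lie in [0, 255]")
  }
  plate_image(gray_from_channels(rgb, method), dpi = dpi, source = "<rgb>")
}

measurement_columns <- c("well_id", "area_pct", "intensity_pct",
                         "threshold", "threshold_method", "flags")

#' Write a measurement table to CSV
#'
#' Column order is fixed: `well_id, area_pct, intensity_pct, threshold,
#' threshold_method, flags`. With `digits = NULL` (default) percentages are
#' printed at full double precision so that [read_measurements()] reproduces
#' them bit-exactly; pass `digits = 4` for a compact report.
#'
#' @param table Data frame with the columns above (extra columns are kept,
#'   after the fixed ones).
#' @param path Output path.
#' @param digits `NULL` for full precision, or number of decimal places.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path, digits = NULL) {
  if (!is.data.frame(table) || nrow(table) < 1L) {
    stop_validation("measurement table must be a non-empty data frame")
  }
  missing_cols <- setdiff(measurement_columns, names(table))
  if (length(missing_cols)) {
    stop_validation("measurement table lacks columns: %s",
                    paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(table$well_id)) {
    stop_validation("well ids must be unique")
  }
  extra <- setdiff(names(table), measurement_columns)
  out <- table[, c(measurement_columns, extra), drop = FALSE]
  for (col in c("area_pct", "intensity_pct")) {
    out[[col]] <- if (is.null(digits)) {
      sprintf("%.17g", out[[col]])
    } else {
      sprintf(paste0("%.", digits, "f"), out[[col]])
    }
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write measurements to ", path)
  invisible(path)
}

#' Read a measurement table written by [write_measurements()]
#'
#' @param path CSV path.
#' @return Data frame with numeric `area_pct`, `intensity_pct`, `threshold`.
#' @export
read_measurements <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(flags = "character",
                                        well_id = "character"))
  for (col in c("area_pct", "intensity_pct", "threshold")) {
    tab[[col]] <- as.numeric(tab[[col]])
  }
  tab
}

#' Write a before/after well montage for visual QC
#'
#' One PNG with a row per well: the cropped 8-bit well on the left, the
#' thresholded and inverted density image on the right (background white,
#' cell density dark), each panel labelled by well id. The montage is the
#' check that the background threshold landed where a human would put it.
#'
#' @param before List of `well_image` objects (from [crop_well_stack()]).
#' @param after List of `thresholded_well` objects of equal length.
#' @param path Output PNG path.
#' @param panel_px Display width of one panel in pixels.
#' @return `path`, invisibly.
#' @export
write_well_montage <- function(before, after, path, panel_px = 160) {
  if (length(before) < 1L || length(before) != length(after)) {
    stop_validation("'before' and 'after' must be equal-length, non-empty lists")
  }
  n <- length(before)
  grDevices::png(path, width = 2 * panel_px, height = n * (panel_px + 18))
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(n, 2), mar = c(0.2, 0.2, 1.2, 0.2))
  for (i in seq_len(n)) {
    w <- before[[i]]
    tw <- after[[i]]
    raster_before <- w$pixels / 255
    raster_before[!w$mask] <- 1
    plot_panel(raster_before, sprintf("%s", w$well_id))
    raster_after <- 1 - tw$density / 255
    raster_after[!tw$mask] <- 1
    plot_panel(raster_after, sprintf("%s thresholded", tw$well_id))
  }
  invisible(path)
}

plot_panel <- function(gray01, label) {
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 1), ylim = c(0, 1), asp = 1)
  graphics::rasterImage(gray01, 0, 0, 1, 1, interpolate = FALSE)
  graphics::title(main = label, cex.main = 0.8)
}
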