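# Well-grid geometry: lattice placement from a user selection, inter-well
# masking, and concentric cropping into a per-well stack.
#
# Wells are located purely by arithmetic from the selection rectangle and the
# plate's published dimensions -- no image-based circle detection. This keeps
# the mapping deterministic and independent of staining level.

# Dimensions (mm) of common CELLSTAR-style culture plates. Overridable via
# plate_layout(); the ratio diameter/pitch is what actually matters, the
# absolute values only through the scan dpi.
.builtin_layouts <- list(
  "6"  = list(rows = 2L, cols = 3L, well_diameter = 34.8, well_pitch = 39.12),
  "12" = list(rows = 3L, cols = 4L, well_diameter = 22.1, well_pitch = 26.01),
  "24" = list(rows = 4L, cols = 6L, well_diameter = 15.6, well_pitch = 19.3)
)

#' Describe a multi-well plate geometry
#'
#' Built-in layouts `"6"`, `"12"` and `"24"` carry typical manufacturer
#' dimensions; any field can be overridden, and fully custom layouts are
#' allowed.
#'
#' @param name `"6"`, `"12"`, `"24"`, or a custom label (then all other
#'   arguments are required).
#' @param rows,cols Number of well rows / columns.
#' @param well_diameter Well diameter in mm.
#' @param well_pitch Centre-to-centre well spacing in mm; must exceed the
#'   diameter.
#' @return An object of class `plate_layout`.
#' @examples
#' plate_layout("12")
#' plate_layout("custom", rows = 2, cols = 2, well_diameter = 10, well_pitch = 12)
#' @export
plate_layout <- function(name = "12", rows = NULL, cols = NULL,
                         well_diameter = NULL, well_pitch = NULL) {
  name <- as.character(name)
  base <- .builtin_layouts[[name]]
  if (is.null(base)) {
    base <- list(rows = rows, cols = cols, well_diameter = well_diameter,
                 well_pitch = well_pitch)
    if (any(vapply(base, is.null, logical(1)))) {
      stop_validation(
        "unknown layout '%s'; custom layouts need rows, cols, well_diameter, well_pitch",
        name)
    }
  }
  if (!is.null(rows)) base$rows <- rows
  if (!is.null(cols)) base$cols <- cols
  if (!is.null(well_diameter)) base$well_diameter <- well_diameter
  if (!is.null(well_pitch)) base$well_pitch <- well_pitch
  if (base$rows < 1L || base$cols < 1L) {
    stop_validation("layout must have at least one row and one column")
  }
  if (!(base$well_diameter > 0) || !(base$well_diameter < base$well_pitch)) {
    stop_validation("need 0 < well_diameter < well_pitch (got %g, %g)",
                    base$well_diameter, base$well_pitch)
  }
  structure(list(name = name, rows = as.integer(base$rows),
                 cols = as.integer(base$cols),
                 well_diameter = base$well_diameter,
                 well_pitch = base$well_pitch),
            class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout> %s: %d x %d wells, diameter %g mm, pitch %g mm\n",
              x$name, x$rows, x$cols, x$well_diameter, x$well_pitch))
  invisible(x)
}

#' Load a plate layout from a CSV config file
#'
#' Expected columns: `name, rows, cols, well_diameter_mm, well_pitch_mm`
#' (one row per layout; the first row is returned unless `name` is given).
#'
#' @param path CSV file path.
#' @param name Optional layout name to select from the file.
#' @return A [plate_layout()].
#' @export
plate_layout_from_file <- function(path, name = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "rows", "cols", "well_diameter_mm", "well_pitch_mm")
  if (!all(need %in% names(tab))) {
    stop_validation("layout file must have columns: %s", paste(need, collapse = ", "))
  }
  row <- if (is.null(name)) tab[1L, ] else tab[tab$name == name, , drop = FALSE]
  if (nrow(row) != 1L) stop_validation("layout '%s' not found in %s", name, path)
  plate_layout(row$name, rows = row$rows, cols = row$cols,
               well_diameter = row$well_diameter_mm,
               well_pitch = row$well_pitch_mm)
}

well_id_label <- function(row, col) paste0(LETTERS[row], col)

#' Expand a well range such as "A1:C4"
#'
#' @param spec Either a character vector of well ids (returned as-is) or a
#'   single `"A1:C4"`-style rectangular range.
#' @return Character vector of well ids in row-major order.
#' @export
well_range <- function(spec) {
  if (length(spec) == 1L && grepl(":", spec, fixed = TRUE)) {
    parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
    pr <- parse_well_id(parts[1]); qr <- parse_well_id(parts[2])
    rows <- seq(min(pr[1], qr[1]), max(pr[1], qr[1]))
    cols <- seq(min(pr[2], qr[2]), max(pr[2], qr[2]))
    return(as.vector(t(outer(rows, cols, well_id_label))))
  }
  as.character(spec)
}

parse_well_id <- function(id) {
  m <- regmatches(id, regexec("^([A-Z])([0-9]+)$", id))[[1]]
  if (length(m) != 3L) stop_validation("malformed well id '%s'", id)
  c(match(m[2], LETTERS), as.integer(m[3]))
}

#' Place well centres on a lattice filling a rectangular selection
#'
#' The user draws one rectangle enclosing the block of wells to analyse;
#' centres are placed on a uniform row x column lattice filling it. The
#' nominal well radius in pixels is `(well_diameter / well_pitch)` times half
#' the smaller lattice cell span, so wells never touch their lattice cell
#' boundaries.
#'
#' @param selection Numeric `c(x0, y0, x1, y1)` in pixel coordinates (origin
#'   top-left, x rightward, y downward).
#' @param layout A [plate_layout()].
#' @param selected_wells Character vector of well ids (or an `"A1:C4"` range)
#'   forming a contiguous sub-grid of the layout; default all wells.
#' @param image Optional [plate_image()]; when given, the selection is
#'   checked against the image bounds.
#' @return A data frame of class `well_grid` with columns `well_id`, `cx`,
#'   `cy` (pixel centre coordinates) and `radius` (nominal well radius in
#'   px), in row-major well order (A1, A2, ...).
#' @export
grid_from_selection <- function(selection, layout, selected_wells = NULL,
                                image = NULL) {
  if (length(selection) != 4L || anyNA(selection)) {
    stop_validation("'selection' must be c(x0, y0, x1, y1)")
  }
  x0 <- min(selection[c(1, 3)]); x1 <- max(selection[c(1, 3)])
  y0 <- min(selection[c(2, 4)]); y1 <- max(selection[c(2, 4)])
  if (x1 - x0 <= 0 || y1 - y0 <= 0) {
    stop_validation("selection has zero width or height")
  }
  if (!is.null(image)) {
    d <- dim(image$pixels)
    if (x0 < 0 || y0 < 0 || x1 > ncol(image$pixels) || y1 > nrow(image$pixels)) {
      stop_validation("selection (%g,%g)-(%g,%g) exceeds image %d x %d",
                      x0, y0, x1, y1, d[2], d[1])
    }
  }

  if (is.null(selected_wells)) {
    rows <- seq_len(layout$rows); cols <- seq_len(layout$cols)
  } else {
    ids <- well_range(selected_wells)
    rc <- t(vapply(ids, parse_well_id, integer(2)))
    rows <- sort(unique(rc[, 1])); cols <- sort(unique(rc[, 2]))
    contiguous <- identical(rows, seq(min(rows), max(rows))) &&
      identical(cols, seq(min(cols), max(cols))) &&
      length(ids) == length(rows) * length(cols)
    if (!contiguous) {
      stop_validation("selected wells must form a contiguous rectangular block")
    }
    if (max(rows) > layout$rows || max(cols) > layout$cols) {
      stop_validation("selected wells exceed the %s layout (%d x %d)",
                      layout$name, layout$rows, layout$cols)
    }
  }
  nr <- length(rows); nc <- length(cols)
  span_x <- (x1 - x0) / nc
  span_y <- (y1 - y0) / nr
  radius <- (layout$well_diameter / layout$well_pitch) * min(span_x, span_y) / 2
  if (radius < 1) {
    stop_validation("selection too small: implied well radius %.2f px < 1", radius)
  }

  grid <- expand.grid(col = seq_len(nc), row = seq_len(nr))[, c("row", "col")]
  out <- data.frame(
    well_id = well_id_label(rows[grid$row], cols[grid$col]),
    cx = x0 + (grid$col - 0.5) * span_x,
    cy = y0 + (grid$row - 0.5) * span_y,
    radius = radius,
    stringsAsFactors = FALSE
  )
  class(out) <- c("well_grid", "data.frame")
  out
}

# Disc membership at pixel centres: pixel (i, j) has centre (j - 0.5, i - 0.5);
# half-open rule dx^2 + dy^2 < r^2.
disc_mask_in_box <- function(rows, cols, cx, cy, r) {
  dx <- (cols - 0.5) - cx
  dy <- (rows - 0.5) - cy
  outer(dy^2, dx^2, "+") < r^2
}

#' Zero out inter-well plastic
#'
#' Pixels outside every well disc (at the nominal radius) are set to 0;
#' pixels inside any disc are untouched. Purely cosmetic for downstream
#' statistics -- the per-well analysis masks never include inter-well space --
#' but it makes the QC imagery unambiguous.
#'
#' @param image A [plate_image()].
#' @param grid A `well_grid` from [grid_from_selection()].
#' @return A [plate_image()] with inter-well pixels zeroed.
#' @export
mask_interwell <- function(image, grid) {
  if (!inherits(image, "plate_image")) stop_validation("'image' must be a plate_image")
  if (nrow(grid) < 1L) stop_validation("'grid' must contain at least one well")
  keep <- matrix(FALSE, nrow(image$pixels), ncol(image$pixels))
  for (k in seq_len(nrow(grid))) {
    r <- grid$radius[k]
    rows <- max(1L, floor(grid$cy[k] - r)):min(nrow(keep), ceiling(grid$cy[k] + r))
    cols <- max(1L, floor(grid$cx[k] - r)):min(ncol(keep), ceiling(grid$cx[k] + r))
    keep[rows, cols] <- keep[rows, cols] |
      disc_mask_in_box(rows, cols, grid$cx[k], grid$cy[k], r)
  }
  px <- image$pixels
  px[!keep] <- 0L
  plate_image(px, dpi = image$dpi, source = image$source)
}

#' Construct a single cropped well image
#'
#' @param well_id Well label.
#' @param pixels Integer matrix of 8-bit intensities (square crop).
#' @param mask Logical matrix of the same shape; `TRUE` marks the circular
#'   analysis region. Pixels outside it are ignored by all statistics.
#' @return An object of class `well_image`.
#' @export
well_image <- function(well_id, pixels, mask) {
  if (!identical(dim(pixels), dim(mask))) {
    stop_validation("pixels and mask must have identical dimensions")
  }
  if (!any(mask)) stop_validation("well %s has an empty analysis mask", well_id)
  storage.mode(pixels) <- "integer"
  structure(list(well_id = well_id, pixels = pixels, mask = mask),
            class = "well_image")
}

#' @export
print.well_image <- function(x, ...) {
  cat(sprintf("<well_image> %s: %d x %d px, %d masked px\n",
              x$well_id, ncol(x$pixels), nrow(x$pixels), sum(x$mask)))
  invisible(x)
}

#' Concentrically crop each well into a stack
#'
#' Each well's analysis disc is the nominal disc shrunk by `crop_fraction`
#' (default 5% off the diameter), excluding the well rim where cells grow
#' abnormally. Each `well_image` is the square bounding box of the reduced
#' disc together with its circular mask.
#'
#' @param image A [plate_image()].
#' @param grid A `well_grid` from [grid_from_selection()].
#' @param crop_fraction Proportion of the diameter removed; in `[0, 1)`.
#' @return List of [well_image()] objects in grid (row-major) order.
#' @export
crop_well_stack <- function(image, grid, crop_fraction = 0.05) {
  if (!is_scalar_number(crop_fraction) || crop_fraction < 0 || crop_fraction >= 1) {
    stop_validation("'crop_fraction' must lie in [0, 1)")
  }
  h <- nrow(image$pixels); w <- ncol(image$pixels)
  lapply(seq_len(nrow(grid)), function(k) {
    r <- grid$radius[k] * (1 - crop_fraction)
    cx <- grid$cx[k]; cy <- grid$cy[k]
    jmin <- floor(cx - r) + 1L; jmax <- ceiling(cx + r)
    imin <- floor(cy - r) + 1L; imax <- ceiling(cy + r)
    # pad to a square box, growing at the far edge
    side <- max(jmax - jmin, imax - imin)
    jmax <- jmin + side; imax <- imin + side
    if (jmin < 1L || imin < 1L || jmax > w || imax > h) {
      stop_validation("well %s: analysis disc extends beyond the image",
                      grid$well_id[k])
    }
    rows <- imin:imax; cols <- jmin:jmax
    well_image(grid$well_id[k],
               image$pixels[rows, cols, drop = FALSE],
               disc_mask_in_box(rows, cols, cx, cy, r))
  })
}
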