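# The two output statistics, computed on thresholded and inverted wells:
#
#   colony area %      = 100 * (# region pixels with density > 0) / (# region pixels)
#   colony intensity % = 100 * sum(density over region) / (255 * # region pixels)
#
# The intensity percentage is the area percentage weighted by cell density,
# normalised to full saturation (every cell pixel completely dark); it never
# exceeds the area percentage. Region denominators count pixels of the
# analysis mask intersected with any sub-region rectangle.

region_pixels <- function(tw, region = NULL) {
  m <- tw$mask
  if (!is.null(region)) {
    if (length(region) != 4L) {
      stop_validation("'region' must be c(col0, row0, col1, row1)")
    }
    c0 <- max(1L, as.integer(region[1])); r0 <- max(1L, as.integer(region[2]))
    c1 <- min(ncol(m), as.integer(region[3])); r1 <- min(nrow(m), as.integer(region[4]))
    if (c0 > c1 || r0 > r1) {
      stop_validation("well %s: region is empty or outside the well", tw$well_id)
    }
    rect <- matrix(FALSE, nrow(m), ncol(m))
    rect[r0:r1, c0:c1] <- TRUE
    m <- m & rect
  }
  if (!any(m)) {
    stop_validation("well %s: region contains no analysis pixels", tw$well_id)
  }
  m
}

#' Colony area percentage of a (sub-)region
#'
#' @param tw A `thresholded_well` from [apply_threshold_invert()].
#' @param region Optional sub-region rectangle `c(col0, row0, col1, row1)` in
#'   well-image pixel indices (1-based, inclusive), intersected with the
#'   circular analysis mask; default the full mask.
#' @return Percentage of region pixels classified as cells, in `[0, 100]`.
#' @export
colony_area_pct <- function(tw, region = NULL) {
  m <- region_pixels(tw, region)
  100 * sum(tw$density[m] > 0L) / sum(m)
}

#' Intensity-weighted colony percentage of a (sub-)region
#'
#' @inheritParams colony_area_pct
#' @return `100 * sum(density) / (255 * n_region_pixels)`, in `[0, 100]`;
#'   bounded above by [colony_area_pct()] of the same region.
#' @export
colony_intensity_pct <- function(tw, region = NULL) {
  m <- region_pixels(tw, region)
  100 * sum(as.numeric(tw$density[m])) / (255 * sum(m))
}

#' Measure a stack of thresholded wells
#'
#' Computes both statistics per well (or per sub-region of each well) and
#' assembles the results table, carrying each well's threshold, method and
#' consistency-check flag.
#'
#' @param tws List of `thresholded_well` objects.
#' @param region Optional sub-region rectangle applied to every selected
#'   well (see [colony_area_pct()]).
#' @param subset Optional character vector of well ids to (re)analyse.
#' @return Data frame with columns `well_id`, `area_pct`, `intensity_pct`,
#'   `threshold`, `threshold_method`, `flags`, `region`, `n_pixels`.
#' @export
measure_stack <- function(tws, region = NULL, subset = NULL) {
  ids <- vapply(tws, function(x) x$well_id, character(1))
  if (!is.null(subset)) {
    unknown <- setdiff(subset, ids)
    if (length(unknown)) {
      stop_validation("unknown well id(s) in subset: %s",
                      paste(unknown, collapse = ", "))
    }
    tws <- tws[ids %in% subset]
    ids <- ids[ids %in% subset]
  }
  region_label <- if (is.null(region)) "full" else {
    paste0("rect[", paste(as.integer(region), collapse = ","), "]")
  }
  rows <- lapply(tws, function(tw) {
    m <- region_pixels(tw, region)
    n <- sum(m)
    flags <- c(if (tw$flagged) "flagged",
               if (identical(tw$method, "no_colonies")) "no_colonies")
    data.frame(
      well_id = tw$well_id,
      area_pct = 100 * sum(tw$density[m] > 0L) / n,
      intensity_pct = 100 * sum(as.numeric(tw$density[m])) / (255 * n),
      threshold = tw$threshold,
      threshold_method = tw$method,
      flags = paste(flags, collapse = ";"),
      region = region_label,
      n_pixels = n,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
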