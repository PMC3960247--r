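# Per-well background thresholding.
#
# Crystal-violet-stained cells are dark on a light background, so the
# cumulative intensity histogram of a well -- the colony area percentage as a
# function of an applied threshold, A(t) -- rises through the cell mode,
# flattens across the gap, then jumps to 100% as the background mode is
# swallowed. The background threshold is the valley of the first derivative
# dA just below the background peak: the last intensity at which only cells
# are selected.

#' Colony-area-versus-threshold curve of a well
#'
#' `A[t]` is the percentage of masked pixels with intensity `<= t`
#' (t = 0..255); `dA` and `d2A` are backward first and second differences
#' (`dA[0] = A[0]`). `A` is non-decreasing with `A[255] = 100` exactly, and
#' `dA` sums to 100.
#'
#' @param well A [well_image()].
#' @return An object of class `threshold_curve` with fields `well_id`, `A`,
#'   `dA`, `d2A` (numeric length-256, index = intensity + 1), `max_intensity`
#'   (largest masked intensity) and `n` (masked pixel count).
#' @export
area_threshold_curve <- function(well) {
  if (!inherits(well, "well_image")) stop_validation("'well' must be a well_image")
  px <- well$pixels[well$mask]
  n <- length(px)
  if (n < 1L) stop_validation("well %s: empty analysis mask", well$well_id)
  counts <- tabulate(px + 1L, nbins = 256L)
  A <- 100 * cumsum(counts) / n
  dA <- c(A[1L], diff(A))
  d2A <- c(dA[1L], diff(dA))
  structure(list(well_id = well$well_id, A = A, dA = dA, d2A = d2A,
                 max_intensity = max(px), n = n),
            class = "threshold_curve")
}

# centred moving average, window 3, partial windows at the edges
smooth3 <- function(x) {
  n <- length(x)
  s <- (c(x[1L], x[-n]) + x + c(x[-1L], x[n])) / 3
  s[1L] <- (x[1L] + x[2L]) / 2
  s[n] <- (x[n - 1L] + x[n]) / 2
  s
}

#' Construct a threshold result
#'
#' @param threshold Background threshold in native intensity units (pixels
#'   `<= threshold` are cells).
#' @param max_intensity The well's maximum masked intensity.
#' @param method One of `"auto"`, `"restricted"`, `"manual"`, `"no_colonies"`.
#' @param flagged Whether the cross-well consistency check flagged the well.
#' @param area_at_threshold Value of `A` at the threshold (colony area %).
#' @return An object of class `threshold_result`; `scaled_threshold` is the
#'   threshold after linear rescaling of the well to maximum intensity 200,
#'   rounded half-up.
#' @export
threshold_result <- function(threshold, max_intensity,
                             method = c("auto", "restricted", "manual", "no_colonies"),
                             flagged = FALSE, area_at_threshold = NA_real_) {
  method <- match.arg(method)
  if (threshold < 0 || threshold > 255) {
    stop_validation("threshold %g outside [0, 255]", threshold)
  }
  scaled <- if (max_intensity > 0) {
    round_half_up(threshold * 200 / max_intensity)
  } else threshold
  structure(list(threshold = as.integer(threshold),
                 scaled_threshold = as.integer(scaled),
                 max_intensity = as.integer(max_intensity),
                 method = method, flagged = isTRUE(flagged),
                 area_at_threshold = area_at_threshold),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> t = %d (scaled %d), method %s%s, area %.2f%%\n",
              x$threshold, x$scaled_threshold, x$method,
              if (x$flagged) " [flagged]" else "", x$area_at_threshold))
  invisible(x)
}

#' Detect the background threshold from a curve
#'
#' Locates the global maximum of the (lightly smoothed) first derivative
#' `dA` -- the background mode -- then takes the valley below it: among all
#' intensities below the peak, the deepest minimum of the smoothed `dA`, and
#' among equally deep candidates the one at the highest intensity (the
#' plateau edge nearest the background mode, equivalently the last
#' negative-to-positive zero crossing of `d2A` before the background rise).
#' Pixels at or below the returned intensity are classified as cells.
#'
#' If no valley with cell mass exists (`A[valley] <= min_cell_area`), the
#' well is reported as `no_colonies`, with the threshold placed at the
#' largest intensity where `A` is still 0; applying it yields an all-zero
#' density image.
#'
#' @param curve A [area_threshold_curve()].
#' @param min_cell_area Minimum colony area percentage at the valley for the
#'   well to count as containing colonies (default 0: any cell mass).
#' @param range Optional `c(lo, hi)` native intensity window restricting the
#'   search (used by the consistency check).
#' @return A [threshold_result()].
#' @export
detect_threshold <- function(curve, min_cell_area = 0, range = c(0L, 255L)) {
  if (!inherits(curve, "threshold_curve")) {
    stop_validation("'curve' must be a threshold_curve")
  }
  lo <- max(0L, as.integer(floor(range[1])))
  hi <- min(255L, as.integer(ceiling(range[2])))
  if (lo >= hi) stop_validation("invalid search range [%d, %d]", lo, hi)
  s <- smooth3(curve$dA)
  idx <- (lo:hi) + 1L                     # R indices for intensities lo..hi
  # background mode = global maximum of smoothed dA; the background is the
  # high-intensity mode, so ties resolve toward higher intensity
  peak <- lo + max(which(s[idx] == max(s[idx]))) - 1L
  if (peak == lo) {
    return(no_colonies_result(curve))
  }
  below <- (lo:(peak - 1L)) + 1L
  vmin <- min(s[below])
  valley <- lo + max(which(s[below] == vmin)) - 1L
  area <- curve$A[valley + 1L]
  if (!(area > min_cell_area)) {
    return(no_colonies_result(curve))
  }
  threshold_result(valley, curve$max_intensity, method = "auto",
                   area_at_threshold = area)
}

no_colonies_result <- function(curve) {
  zeros <- which(curve$A == 0)
  t0 <- if (length(zeros)) max(zeros) - 1L else 0L
  threshold_result(t0, curve$max_intensity, method = "no_colonies",
                   area_at_threshold = 0)
}

#' Cross-well consistency check on detected thresholds
#'
#' The area-threshold curve can carry several local minima, so a threshold
#' found in isolation is occasionally wrong. Thresholds are compared on a
#' common footing by linearly rescaling each well so its maximum intensity is
#' 200 (countering non-uniform illumination): any scaled threshold deviating
#' more than `tolerance` intensity units from the plate average is flagged,
#' and its well is re-thresholded with the search restricted to the average
#' +/- `tolerance` (mapped back to the well's native intensities). Scaled
#' values stay real-valued during comparison; rounding happens only when
#' mapping back.
#'
#' @param wells List of [well_image()] objects.
#' @param initial List of [threshold_result()] objects, aligned with `wells`.
#' @param tolerance Allowed deviation from the plate mean, in scaled
#'   intensity units (default 50).
#' @param exclude_flagged If `TRUE`, recompute the mean without flagged wells
#'   and re-evaluate against it (one extra pass). The default keeps flagged
#'   wells in the average.
#' @param min_cell_area Passed to [detect_threshold()] for re-evaluation.
#' @return List of [threshold_result()] objects; re-evaluated wells have
#'   `method = "restricted"` and `flagged = TRUE`.
#' @export
harmonize_thresholds <- function(wells, initial, tolerance = 50,
                                 exclude_flagged = FALSE, min_cell_area = 0) {
  n <- length(wells)
  if (n != length(initial)) stop_validation("'wells' and 'initial' must align")
  if (n < 2L) return(initial)

  max_int <- vapply(initial, function(r) r$max_intensity, numeric(1))
  thr <- vapply(initial, function(r) as.numeric(r$threshold), numeric(1))
  scaled <- ifelse(max_int > 0, thr * 200 / max_int, thr)
  mu <- mean(scaled)
  flag <- abs(scaled - mu) > tolerance
  if (exclude_flagged && any(flag) && !all(flag)) {
    mu <- mean(scaled[!flag])
    flag <- abs(scaled - mu) > tolerance
  }
  out <- initial
  for (i in which(flag)) {
    m <- if (max_int[i] > 0) max_int[i] else 200
    native_lo <- max(0, round_half_up((mu - tolerance) * m / 200))
    native_hi <- min(255, round_half_up((mu + tolerance) * m / 200))
    curve <- area_threshold_curve(wells[[i]])
    res <- detect_threshold(curve, min_cell_area = min_cell_area,
                            range = c(native_lo, native_hi))
    res$method <- "restricted"
    res$flagged <- TRUE
    out[[i]] <- res
  }
  out
}

#' Threshold a well and invert it into a density image
#'
#' Masked pixels at or below the threshold (cells) become `255 - intensity`
#' (at least 1); everything else -- background and pixels outside the
#' analysis mask -- becomes 0. Higher density values therefore mean denser
#' staining, i.e. more cells.
#'
#' @param well A [well_image()].
#' @param threshold Background threshold in 0--254. A threshold of 255 would
#'   classify saturated white as cells and is rejected.
#' @param method Provenance label carried into the result.
#' @return An object of class `thresholded_well` with fields `well_id`,
#'   `density`, `mask`, `threshold`, `method`, `flagged`.
#' @export
apply_threshold_invert <- function(well, threshold, method = "auto",
                                   flagged = FALSE) {
  if (!inherits(well, "well_image")) stop_validation("'well' must be a well_image")
  if (!is_scalar_number(threshold) || threshold < 0 || threshold > 254) {
    stop_validation("well %s: threshold must lie in [0, 254], got %s",
                    well$well_id, format(threshold))
  }
  density <- matrix(0L, nrow(well$pixels), ncol(well$pixels))
  sel <- well$mask & well$pixels <= threshold
  density[sel] <- 255L - well$pixels[sel]
  structure(list(well_id = well$well_id, density = density, mask = well$mask,
                 threshold = as.integer(threshold), method = method,
                 flagged = isTRUE(flagged)),
            class = "thresholded_well")
}

#' @export
print.thresholded_well <- function(x, ...) {
  cat(sprintf("<thresholded_well> %s: t = %d (%s), %d cell px\n",
              x$well_id, x$threshold, x$method, sum(x$density > 0)))
  invisible(x)
}

#' Apply user-defined manual thresholds
#'
#' The escape hatch for wells where the automatic valley detection fails
#' visual inspection: one global threshold, or a per-well map.
#'
#' @param wells List of [well_image()] objects.
#' @param threshold Single intensity in 0--254, or a named numeric vector /
#'   list keyed by well id covering every well.
#' @return List of `thresholded_well` objects with `method = "manual"`.
#' @export
manual_threshold <- function(wells, threshold) {
  ids <- vapply(wells, function(w) w$well_id, character(1))
  if (length(threshold) == 1L && is.null(names(threshold))) {
    thr <- stats::setNames(rep(as.numeric(threshold), length(ids)), ids)
  } else {
    thr <- unlist(threshold)
    missing_ids <- setdiff(ids, names(thr))
    if (length(missing_ids)) {
      stop_validation("manual thresholds missing for wells: %s",
                      paste(missing_ids, collapse = ", "))
    }
  }
  lapply(wells, function(w) {
    apply_threshold_invert(w, thr[[w$well_id]], method = "manual")
  })
}
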