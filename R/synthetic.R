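# Synthetic plate and dose-response generators with exact ground truth.
#
# The generator emulates what the thresholding pipeline actually sees in a
# flatbed scan: a light uniform background inside circular wells, darker
# inter-well plastic, colonies as dark blobs whose darkness scales with cell
# density, optional one-sided shading and additive Gaussian noise. Truth
# (per-well covered fraction and intensity-weighted fraction) is computed on
# the rendered raster inside the analysis mask, so pipeline results can be
# compared pixel-exactly.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Specify one synthetic well
#'
#' @param target_coverage Fraction of the analysis disc to cover with
#'   colonies, in `[0, 1]`.
#' @param colony_radius_range Colony radius range in px, `c(min, max)`.
#' @param colony_intensity_range 8-bit intensity range of colonies (dark);
#'   each colony draws one uniform intensity from it.
#' @param background_intensity 8-bit intensity of the empty well (light);
#'   must exceed the maximum colony intensity.
#' @param profile `"flat"` (hard discs, default) or `"gaussian"`
#'   (centre-dark blobs fading towards the background).
#' @return An object of class `synthetic_well_spec`.
#' @export
synthetic_well_spec <- function(target_coverage = 0.2,
                                colony_radius_range = c(3, 6),
                                colony_intensity_range = c(60, 110),
                                background_intensity = 220,
                                profile = c("flat", "gaussian")) {
  profile <- match.arg(profile)
  if (target_coverage < 0 || target_coverage > 1) {
    stop_validation("'target_coverage' must lie in [0, 1]")
  }
  if (max(colony_intensity_range) >= background_intensity) {
    stop_validation("colonies must be darker than the background")
  }
  structure(list(target_coverage = target_coverage,
                 colony_radius_range = colony_radius_range,
                 colony_intensity_range = colony_intensity_range,
                 background_intensity = background_intensity,
                 profile = profile),
            class = "synthetic_well_spec")
}

# Place non-overlapping colony discs until the labelled fraction of the
# analysis mask reaches the target (overshoot of at most one colony).
place_colonies <- function(spec, mask_rows, mask_cols, cx, cy, r_analysis,
                           retry_cap = 4000L) {
  n_mask <- sum(disc_mask_in_box(mask_rows, mask_cols, cx, cy, r_analysis))
  placed <- list()
  covered_px <- 0L
  misses <- 0L
  while (covered_px / n_mask < spec$target_coverage) {
    rad <- stats::runif(1, spec$colony_radius_range[1], spec$colony_radius_range[2])
    if (rad >= r_analysis) rad <- r_analysis / 2
    # uniform position over the disc that keeps the colony fully inside
    rho <- (r_analysis - rad) * sqrt(stats::runif(1))
    ang <- stats::runif(1, 0, 2 * pi)
    px <- cx + rho * cos(ang); py <- cy + rho * sin(ang)
    clash <- any(vapply(placed, function(p) {
      (p$x - px)^2 + (p$y - py)^2 < (p$r + rad)^2
    }, logical(1)))
    if (clash) {
      misses <- misses + 1L
      if (misses > retry_cap) {
        stop_validation(
          "cannot reach coverage %.2f with colony radii [%g, %g] (placement jammed)",
          spec$target_coverage, spec$colony_radius_range[1],
          spec$colony_radius_range[2])
      }
      next
    }
    misses <- 0L
    intensity <- round_half_up(stats::runif(1, spec$colony_intensity_range[1],
                                            spec$colony_intensity_range[2]))
    placed[[length(placed) + 1L]] <- list(x = px, y = py, r = rad,
                                          intensity = intensity)
    npix <- sum(disc_mask_in_box(mask_rows, mask_cols, px, py, rad))
    covered_px <- covered_px + npix
  }
  placed
}

#' Render a synthetic multi-well plate with known ground truth
#'
#' Deterministic for a fixed seed. Colonies are random non-overlapping discs
#' placed until each well's target coverage is met (overshooting by at most
#' one colony); truth is then counted on the rendered raster, not on the
#' request. Optional one-sided shading darkens the image linearly from
#' `shading_start` (fraction of the width) to the right edge, emulating
#' non-uniform scanner illumination while leaving the left part of the image
#' clean; optional i.i.d. Gaussian noise is rounded and clipped to
#' `[0, 255]`.
#'
#' @param layout A [plate_layout()].
#' @param dpi Rendering resolution (dots per inch).
#' @param specs A single [synthetic_well_spec()] (recycled), or a list keyed
#'   by well id covering every well.
#' @param shading Amplitude of the shading gradient in intensity units
#'   (default 0: none).
#' @param shading_start Fraction of the image width where the gradient
#'   starts (default 0.5).
#' @param shading_ramp Fraction of the image width over which the darkening
#'   ramps linearly from 0 to the full amplitude. The default (`NULL`) ramps
#'   all the way to the right edge; `0` gives a sharp shadow edge at
#'   `shading_start`.
#' @param noise_sd Gaussian noise standard deviation in intensity units.
#' @param seed Integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @param crop_fraction Concentric crop defining the analysis mask on which
#'   truth is counted; keep equal to the analysis setting (default 0.05).
#' @param interwell_intensity Intensity of the plastic between wells.
#' @param margin_mm Margin around the well block, in mm.
#' @param enforce_separability If `TRUE` (default), require
#'   `background - max colony intensity > 4 * noise_sd` so that exactness
#'   tests are meaningful; disable for deliberately hard images.
#' @return An object of class `synthetic_plate`: `image` (a
#'   [plate_image()]), `truth` (data frame: `well_id`,
#'   `true_area_fraction`, `true_intensity_fraction`, `n_colonies`,
#'   `n_mask_pixels`), `labels` (plate-sized logical matrix of cell pixels),
#'   `selection` (the rectangle enclosing the well block, ready for
#'   [grid_from_selection()]), and `layout`.
#' @export
render_plate <- function(layout, dpi = 150, specs = synthetic_well_spec(),
                         shading = 0, shading_start = 0.5,
                         shading_ramp = NULL, noise_sd = 0,
                         seed = 1, crop_fraction = 0.05,
                         interwell_intensity = 140, margin_mm = 2,
                         enforce_separability = TRUE) {
  ids <- as.vector(t(outer(seq_len(layout$rows), seq_len(layout$cols),
                           well_id_label)))
  if (inherits(specs, "synthetic_well_spec")) {
    specs <- stats::setNames(rep(list(specs), length(ids)), ids)
  }
  missing_ids <- setdiff(ids, names(specs))
  if (length(missing_ids)) {
    stop_validation("specs missing for wells: %s", paste(missing_ids, collapse = ", "))
  }
  if (enforce_separability) {
    for (id in ids) {
      sp <- specs[[id]]
      if (!(sp$background_intensity - max(sp$colony_intensity_range) > 4 * noise_sd)) {
        stop_validation(
          "well %s: background - max colony intensity must exceed 4 * noise_sd", id)
      }
    }
  }

  px_per_mm <- dpi / 25.4
  pitch <- layout$well_pitch * px_per_mm
  r_nominal <- layout$well_diameter / 2 * px_per_mm
  margin <- margin_mm * px_per_mm
  W <- as.integer(ceiling(layout$cols * pitch + 2 * margin))
  H <- as.integer(ceiling(layout$rows * pitch + 2 * margin))
  selection <- c(margin, margin,
                 margin + layout$cols * pitch, margin + layout$rows * pitch)

  img <- matrix(as.numeric(interwell_intensity), H, W)
  labels <- matrix(FALSE, H, W)
  truth_rows <- vector("list", length(ids))

  with_seed(seed, {
    k <- 0L
    for (row in seq_len(layout$rows)) {
      for (col in seq_len(layout$cols)) {
        k <- k + 1L
        id <- well_id_label(row, col)
        sp <- specs[[id]]
        cx <- margin + (col - 0.5) * pitch
        cy <- margin + (row - 0.5) * pitch
        rows_box <- max(1L, floor(cy - r_nominal)):min(H, ceiling(cy + r_nominal))
        cols_box <- max(1L, floor(cx - r_nominal)):min(W, ceiling(cx + r_nominal))
        well_disc <- disc_mask_in_box(rows_box, cols_box, cx, cy, r_nominal)
        sub <- img[rows_box, cols_box]
        sub[well_disc] <- sp$background_intensity
        r_analysis <- r_nominal * (1 - crop_fraction)
        colonies <- place_colonies(sp, rows_box, cols_box, cx, cy, r_analysis)
        for (co in colonies) {
          cdisc <- disc_mask_in_box(rows_box, cols_box, co$x, co$y, co$r)
          if (sp$profile == "gaussian") {
            dx <- (cols_box - 0.5) - co$x
            dy <- (rows_box - 0.5) - co$y
            dist2 <- outer(dy^2, dx^2, "+")
            depth <- (sp$background_intensity - co$intensity) *
              exp(-dist2 / (2 * (co$r / 2)^2))
            sub[cdisc] <- round_half_up(sp$background_intensity - depth[cdisc])
          } else {
            sub[cdisc] <- co$intensity
          }
        }
        img[rows_box, cols_box] <- sub
        lab <- labels[rows_box, cols_box]
        amask <- disc_mask_in_box(rows_box, cols_box, cx, cy, r_analysis)
        for (co in colonies) {
          lab <- lab | (disc_mask_in_box(rows_box, cols_box, co$x, co$y, co$r) & amask)
        }
        labels[rows_box, cols_box] <- lab
        truth_rows[[k]] <- list(well_id = id, row = rows_box[1], col = cols_box[1],
                                amask_n = sum(amask), n_colonies = length(colonies),
                                rows_box = rows_box, cols_box = cols_box,
                                amask = amask)
      }
    }

    if (shading > 0) {
      start_col <- shading_start * (W - 1)
      ramp_len <- if (is.null(shading_ramp)) {
        (W - 1) - start_col
      } else {
        shading_ramp * (W - 1)
      }
      x <- (seq_len(W) - 1) - start_col
      ramp <- if (ramp_len > 0) pmin(1, pmax(0, x / ramp_len)) else as.numeric(x > 0)
      img <- img - matrix(shading * ramp, H, W, byrow = TRUE)
    }
    if (noise_sd > 0) {
      img <- img + round_half_up(matrix(stats::rnorm(H * W, 0, noise_sd), H, W))
    }
  })
  img <- pmin(pmax(round_half_up(img), 0), 255)

  truth <- do.call(rbind, lapply(truth_rows, function(tr) {
    lab <- labels[tr$rows_box, tr$cols_box] & tr$amask
    n_cells <- sum(lab)
    vals <- img[tr$rows_box, tr$cols_box][lab]
    data.frame(well_id = tr$well_id,
               true_area_fraction = n_cells / tr$amask_n,
               true_intensity_fraction = sum(255 - vals) / (255 * tr$amask_n),
               n_colonies = tr$n_colonies,
               n_mask_pixels = tr$amask_n,
               stringsAsFactors = FALSE)
  }))

  structure(list(image = plate_image(img, dpi = dpi,
                                     source = sprintf("synthetic(seed=%s)", seed)),
                 truth = truth, labels = labels, selection = selection,
                 layout = layout, crop_fraction = crop_fraction, seed = seed),
            class = "synthetic_plate")
}

#' @export
print.synthetic_plate <- function(x, ...) {
  cat(sprintf("<synthetic_plate> %s, %d x %d px, %d wells, mean coverage %.3f\n",
              x$layout$name, ncol(x$image$pixels), nrow(x$image$pixels),
              nrow(x$truth), mean(x$truth$true_area_fraction)))
  invisible(x)
}

#' Simulate response-level dose-response data
#'
#' Draws `replicates` responses per dose from the LL.4 curve plus Gaussian
#' noise, truncated to `[0, 100]` (the statistics are percentages).
#'
#' @param model Named list or vector with `b`, `c`, `d`, `e`.
#' @param doses Positive concentrations.
#' @param replicates Replicates per dose (>= 1).
#' @param noise_sd Response noise standard deviation.
#' @param seed Integer seed.
#' @return Data frame with columns `dose`, `replicate`, `response`.
#' @export
simulate_dose_response <- function(model, doses, replicates = 4,
                                   noise_sd = 0, seed = 1) {
  if (any(doses <= 0)) stop_validation("doses must be positive")
  if (replicates < 1L) stop_validation("'replicates' must be >= 1")
  m <- as.list(model)
  truth <- ll4(doses, m$b, m$c, m$d, m$e)
  with_seed(seed, {
    out <- data.frame(
      dose = rep(doses, each = replicates),
      replicate = rep(seq_len(replicates), times = length(doses)),
      response = rep(truth, each = replicates) +
        stats::rnorm(length(doses) * replicates, 0, noise_sd)
    )
    out$response <- pmin(pmax(out$response, 0), 100)
    out
  })
}

#' Render a full dose-response experiment as a plate image
#'
#' Assigns doses and replicates to wells in row-major order and sets each
#' well's target coverage to `ll4(dose) / 100`, enabling end-to-end
#' image -> measurement -> IC50 recovery tests against a known generating
#' model.
#'
#' @param model Named list or vector with `b`, `c`, `d`, `e` (responses on
#'   the percentage scale; upper limit `d` must be placeable as coverage,
#'   i.e. well below the disc-packing limit).
#' @param doses Positive concentrations; `length(doses) * replicates` must
#'   not exceed the number of wells.
#' @param replicates Wells per dose.
#' @param layout A [plate_layout()]; default 24-well.
#' @param base_spec A [synthetic_well_spec()] providing colony appearance;
#'   its `target_coverage` is overridden per well.
#' @param seed Integer seed.
#' @param ... Passed to [render_plate()] (`dpi`, `noise_sd`, `shading`, ...).
#' @return List: `plate` (a `synthetic_plate`), `dose_map` (data frame
#'   `well_id`, `dose`, `replicate`), `model`.
#' @export
render_dose_response_plates <- function(model, doses, replicates = 3,
                                        layout = plate_layout("24"),
                                        base_spec = synthetic_well_spec(),
                                        seed = 1, ...) {
  n_needed <- length(doses) * replicates
  n_wells <- layout$rows * layout$cols
  if (n_needed > n_wells) {
    stop_validation("%d dose x replicate wells needed but layout has %d",
                    n_needed, n_wells)
  }
  m <- as.list(model)
  ids <- as.vector(t(outer(seq_len(layout$rows), seq_len(layout$cols),
                           well_id_label)))[seq_len(n_needed)]
  dose_map <- data.frame(
    well_id = ids,
    dose = rep(doses, times = replicates)[seq_len(n_needed)],
    replicate = rep(seq_len(replicates), each = length(doses))[seq_len(n_needed)],
    stringsAsFactors = FALSE
  )
  coverage <- pmin(pmax(ll4(dose_map$dose, m$b, m$c, m$d, m$e) / 100, 0), 1)
  specs <- stats::setNames(lapply(coverage, function(f) {
    sp <- base_spec
    sp$target_coverage <- f
    sp
  }), ids)
  # any spare wells stay empty
  spare <- setdiff(as.vector(t(outer(seq_len(layout$rows), seq_len(layout$cols),
                                     well_id_label))), ids)
  for (id in spare) {
    sp <- base_spec; sp$target_coverage <- 0
    specs[[id]] <- sp
  }
  plate <- render_plate(layout, specs = specs, seed = seed, ...)
  list(plate = plate, dose_map = dose_map, model = m)
}
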