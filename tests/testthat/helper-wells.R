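# Builders for small in-memory wells and plates used across tests.

# A well_image whose masked pixels are exactly `px` (row-filled into the
# smallest square that holds them); unmasked filler is white.
mk_well <- function(px, id = "T1") {
  n <- length(px)
  side <- ceiling(sqrt(n))
  m <- matrix(255L, side, side)
  m[seq_len(n)] <- as.integer(px)
  mask <- matrix(FALSE, side, side)
  mask[seq_len(n)] <- TRUE
  well_image(id, m, mask)
}

# Well with cells drawn uniformly from cell_range and background from
# bg_range (disjoint, cells darker). Returns the well plus its ground truth.
mk_bimodal_well <- function(n = 4000, cell_frac = 0.3,
                            cell_range = c(60, 100), bg_range = c(200, 240),
                            id = "T1") {
  n_cells <- round(n * cell_frac)
  px <- c(sample(cell_range[1]:cell_range[2], n_cells, replace = TRUE),
          sample(bg_range[1]:bg_range[2], n - n_cells, replace = TRUE))
  list(well = mk_well(px, id), cell_frac = n_cells / n,
       cell_range = cell_range, bg_range = bg_range)
}

# Independent oracle: cumulative-histogram area percentage by direct count.
brute_area_curve <- function(px) {
  vapply(0:255, function(t) 100 * sum(px <= t) / length(px), numeric(1))
}

# A thresholded_well with a given density matrix over a full mask.
mk_density_well <- function(density, id = "D1") {
  structure(list(well_id = id, density = density,
                 mask = matrix(TRUE, nrow(density), ncol(density)),
                 threshold = 128L, method = "manual", flagged = FALSE),
            class = "thresholded_well")
}
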