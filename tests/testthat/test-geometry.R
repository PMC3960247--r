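test_that("built-in layouts carry plausible dimensions and validate", {
  l12 <- plate_layout("12")
  expect_equal(c(l12$rows, l12$cols), c(3L, 4L))
  expect_lt(l12$well_diameter, l12$well_pitch)
  expect_error(plate_layout("96"), class = "colonyquant_validation_error")
  custom <- plate_layout("custom", rows = 2, cols = 2,
                         well_diameter = 10, well_pitch = 12)
  expect_equal(custom$rows, 2L)
  expect_error(plate_layout("custom", rows = 2, cols = 2,
                            well_diameter = 12, well_pitch = 10),
               class = "colonyquant_validation_error")
})

test_that("lattice placement matches the hand-computed 12-well example", {
  g <- grid_from_selection(c(0, 0, 1200, 800), plate_layout("12"))
  expect_equal(nrow(g), 12L)
  expect_equal(g$well_id[1:5], c("A1", "A2", "A3", "A4", "B1"))  # row-major
  expect_equal(unique(g$cx), c(150, 450, 750, 1050))
  expect_equal(unique(g$cy), c(800 / 6, 800 / 2, 800 * 5 / 6))
  # nominal radius from the smaller span: (22.1 / 26.01) * (800/3) / 2
  expect_equal(g$radius[1], (22.1 / 26.01) * (800 / 3) / 2, tolerance = 1e-12)
  expect_equal(round(g$radius[1], 1), 113.3)
})

test_that("single-well selections and degenerate selections behave", {
  lay <- plate_layout("custom", rows = 1, cols = 1,
                      well_diameter = 10, well_pitch = 12)
  g <- grid_from_selection(c(10, 20, 110, 120), lay)
  expect_equal(c(g$cx, g$cy), c(60, 70))
  expect_error(grid_from_selection(c(10, 20, 10, 120), lay),
               "zero width", class = "colonyquant_validation_error")
})

test_that("selected wells must form a contiguous block inside the layout", {
  lay <- plate_layout("12")
  g <- grid_from_selection(c(0, 0, 600, 400), lay, selected_wells = "A1:B2")
  expect_equal(g$well_id, c("A1", "A2", "B1", "B2"))
  expect_error(grid_from_selection(c(0, 0, 600, 400), lay,
                                   selected_wells = c("A1", "B2")),
               "contiguous", class = "colonyquant_validation_error")
  expect_error(grid_from_selection(c(0, 0, 600, 400), lay,
                                   selected_wells = "Z9"),
               class = "colonyquant_validation_error")
})

test_that("inter-well masking zeroes exactly the pixels outside all discs", {
  img <- plate_image(matrix(200L, 120, 160), dpi = 100)
  lay <- plate_layout("custom", rows = 1, cols = 2,
                      well_diameter = 20, well_pitch = 24)
  g <- grid_from_selection(c(0, 0, 160, 120), lay)
  masked <- mask_interwell(img, g)
  # well centre untouched, far corner zeroed
  expect_equal(masked$pixels[round(g$cy[1]), round(g$cx[1])], 200L)
  expect_equal(masked$pixels[1, 1], 0L)
  # unchanged-pixel count equals the union area of the discs by direct count
  inside <- matrix(FALSE, 120, 160)
  for (k in 1:2) {
    for (i in 1:120) for (j in 1:160) {
      if ((j - 0.5 - g$cx[k])^2 + (i - 0.5 - g$cy[k])^2 < g$radius[k]^2) {
        inside[i, j] <- TRUE
      }
    }
  }
  expect_equal(sum(masked$pixels == 200L), sum(inside))
})

test_that("concentric cropping shrinks the radius and masks a near-disc area", {
  img <- plate_image(matrix(200L, 300, 300), dpi = 100)
  lay <- plate_layout("custom", rows = 1, cols = 1,
                      well_diameter = 25, well_pitch = 26)
  g <- grid_from_selection(c(10, 10, 290, 290), lay)
  wells05 <- crop_well_stack(img, g, crop_fraction = 0.05)
  wells00 <- crop_well_stack(img, g, crop_fraction = 0)
  r <- g$radius[1]
  # crop 0: mask is the nominal disc, pixel count within perimeter slack of pi r^2
  expect_equal(sum(wells00[[1]]$mask), pi * r^2, tolerance = 2 * pi * r / (pi * r^2))
  # crop 0.05: radius scaled once by 0.95
  r95 <- 0.95 * r
  expect_equal(sum(wells05[[1]]$mask), pi * r95^2,
               tolerance = 2 * pi * r95 / (pi * r95^2))
  expect_lt(sum(wells05[[1]]$mask), sum(wells00[[1]]$mask))
  expect_error(crop_well_stack(img, g, crop_fraction = 1),
               class = "colonyquant_validation_error")
})

test_that("larger crop fractions give strictly nested analysis masks", {
  img <- plate_image(matrix(150L, 200, 200), dpi = 100)
  lay <- plate_layout("custom", rows = 1, cols = 1,
                      well_diameter = 20, well_pitch = 22)
  g <- grid_from_selection(c(0, 0, 200, 200), lay)
  fr <- c(0, 0.05, 0.15, 0.3)
  # compare in plate coordinates so differing crop boxes don't matter
  full_masks <- lapply(fr, function(a) {
    w <- crop_well_stack(img, g, crop_fraction = a)[[1]]
    m <- matrix(FALSE, 200, 200)
    r <- g$radius[1] * (1 - a)
    for (i in 1:200) for (j in 1:200) {
      m[i, j] <- (j - 0.5 - g$cx[1])^2 + (i - 0.5 - g$cy[1])^2 < r^2
    }
    expect_equal(sum(w$mask), sum(m))  # crop mask matches the disc inequality
    m
  })
  for (k in 2:length(fr)) {
    expect_true(all(full_masks[[k]] <= full_masks[[k - 1]]))
    expect_lt(sum(full_masks[[k]]), sum(full_masks[[k - 1]]))
  }
})

test_that("cropping a well that leaves the image names the well", {
  img <- plate_image(matrix(200L, 50, 50), dpi = 100)
  lay <- plate_layout("custom", rows = 1, cols = 1,
                      well_diameter = 60, well_pitch = 61)
  g <- grid_from_selection(c(-20, -20, 70, 70), lay)
  expect_error(crop_well_stack(img, g), "A1",
               class = "colonyquant_validation_error")
})

test_that("masking inter-well space never changes per-well statistics", {
  set.seed(21)
  p <- render_plate(plate_layout("custom", rows = 1, cols = 2,
                                 well_diameter = 10, well_pitch = 12),
                    dpi = 200, specs = synthetic_well_spec(0.2), seed = 3)
  g <- grid_from_selection(p$selection, p$layout)
  direct <- crop_well_stack(p$image, g)
  via_mask <- crop_well_stack(mask_interwell(p$image, g), g)
  for (k in seq_along(direct)) {
    expect_identical(direct[[k]]$pixels[direct[[k]]$mask],
                     via_mask[[k]]$pixels[via_mask[[k]]$mask])
  }
})

test_that("well ranges expand row-major and reject malformed ids", {
  expect_equal(well_range("A1:B3"), c("A1", "A2", "A3", "B1", "B2", "B3"))
  expect_equal(well_range(c("C2", "C3")), c("C2", "C3"))
  expect_error(grid_from_selection(c(0, 0, 100, 100), plate_layout("12"),
                                   selected_wells = "1A:B2"),
               class = "colonyquant_validation_error")
})
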