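test_that("area-threshold curve matches the brute-force cumulative histogram", {
  set.seed(7)
  px <- sample(0:255, 10, replace = TRUE)
  cu <- area_threshold_curve(mk_well(px))
  expect_equal(cu$A, brute_area_curve(px))
  expect_equal(cu$dA, c(cu$A[1], diff(cu$A)))
  expect_equal(cu$d2A, c(cu$dA[1], diff(cu$dA)))
})

test_that("curve invariants hold over random wells", {
  set.seed(8)
  for (i in 1:20) {
    px <- sample(0:255, sample(50:500, 1), replace = TRUE)
    cu <- area_threshold_curve(mk_well(px))
    expect_true(all(diff(cu$A) >= 0))
    expect_equal(cu$A[256], 100)
    expect_true(all(cu$dA >= 0))
    expect_equal(sum(cu$dA), 100)
    expect_equal(cu$max_intensity, max(px))
  }
})

test_that("degenerate wells produce trivial curves", {
  cu <- area_threshold_curve(mk_well(rep(255L, 16)))
  expect_true(all(cu$A[1:255] == 0) && cu$A[256] == 100)
  px <- c(rep(0L, 8), rep(255L, 8))
  cu2 <- area_threshold_curve(mk_well(px))
  expect_equal(cu2$A[1], 50)    # t = 0
  expect_equal(cu2$A[255], 50)  # t = 254
  expect_equal(cu2$A[256], 100)
})

test_that("the detected threshold separates two disjoint intensity modes", {
  set.seed(9)
  bw <- mk_bimodal_well(n = 10000, cell_frac = 0.3,
                        cell_range = c(60, 100), bg_range = c(200, 240))
  r <- detect_threshold(area_threshold_curve(bw$well))
  expect_gte(r$threshold, 100)
  expect_lt(r$threshold, 200)
  expect_equal(r$area_at_threshold, 100 * bw$cell_frac)
  expect_equal(r$method, "auto")
})

test_that("a perfectly bimodal well thresholds at a separating intensity", {
  r <- detect_threshold(area_threshold_curve(mk_well(c(rep(50L, 500),
                                                       rep(250L, 500)))))
  expect_gte(r$threshold, 50)
  expect_lte(r$threshold, 249)
  expect_equal(r$area_at_threshold, 50)
})

test_that("constant and colony-free wells come back as no_colonies", {
  r <- detect_threshold(area_threshold_curve(mk_well(rep(220L, 100))))
  expect_equal(r$method, "no_colonies")
  expect_equal(r$area_at_threshold, 0)
  # threshold sits at the largest intensity where A is still zero
  expect_equal(r$threshold, 219L)
  # background-only well with spread
  set.seed(10)
  r2 <- detect_threshold(area_threshold_curve(
    mk_well(sample(200:240, 5000, replace = TRUE))))
  expect_equal(r2$method, "no_colonies")
})

test_that("rescaling all intensities rescales the threshold within rounding", {
  set.seed(12)
  bw <- mk_bimodal_well(n = 8000, cell_frac = 0.25,
                        cell_range = c(70, 110), bg_range = c(190, 230))
  t0 <- detect_threshold(area_threshold_curve(bw$well))$threshold
  px <- bw$well$pixels[bw$well$mask]
  for (s in c(0.9, 0.7, 0.5)) {
    ts <- detect_threshold(area_threshold_curve(
      mk_well(floor(px * s + 0.5))))$threshold
    expect_lte(abs(ts - s * t0), 2)
  }
})

test_that("scaled thresholds follow the scale-to-200 rule", {
  r <- threshold_result(110, max_intensity = 220, method = "auto")
  expect_equal(r$scaled_threshold, 100L)  # 110 * 200 / 220
  r2 <- threshold_result(101, max_intensity = 201, method = "auto")
  expect_equal(r2$scaled_threshold, round(101 * 200 / 201))
})

test_that("the consistency check flags exactly the deviant well and re-evaluates it", {
  # three wells with max intensity 200, so scaled == native thresholds;
  # cells on [40, 80], background on [150, 199]: true valley in (80, 150)
  set.seed(42)
  mkw <- function(id) {
    px <- c(sample(40:80, 1200, replace = TRUE),
            sample(150:199, 2800, replace = TRUE), rep(200L, 20))
    mk_well(px, id)
  }
  wells <- list(mkw("A1"), mkw("A2"), mkw("A3"))
  initial <- list(
    threshold_result(100, 200, "auto", area_at_threshold = 30),
    threshold_result(105, 200, "auto", area_at_threshold = 30),
    threshold_result(180, 200, "auto", area_at_threshold = 90))
  # scaled [100, 105, 180]: mean 128.33; only |180 - 128.33| = 51.67 > 50
  out <- harmonize_thresholds(wells, initial, tolerance = 50)
  expect_equal(vapply(out, function(r) r$flagged, logical(1)),
               c(FALSE, FALSE, TRUE))
  expect_equal(out[[3]]$method, "restricted")
  # re-detected threshold falls in the restricted window and the true gap
  expect_gte(out[[3]]$threshold, 128.33 - 50)
  expect_lte(out[[3]]$threshold, 128.33 + 50)
  expect_gt(out[[3]]$threshold, 80)
  expect_lt(out[[3]]$threshold, 150)
  # unflagged wells pass through untouched
  expect_identical(out[[1]], initial[[1]])
  expect_identical(out[[2]], initial[[2]])

  # idempotence: a second pass re-evaluates nothing
  out2 <- harmonize_thresholds(wells, out, tolerance = 50)
  expect_identical(vapply(out2, function(r) r$threshold, integer(1)),
                   vapply(out, function(r) r$threshold, integer(1)))
  expect_identical(vapply(out2, function(r) r$method, character(1)),
                   vapply(out, function(r) r$method, character(1)))
})

test_that("concordant plates and single wells pass through unchanged", {
  set.seed(13)
  wells <- lapply(1:3, function(i) mk_bimodal_well(id = paste0("A", i))$well)
  initial <- list(threshold_result(100, 200, "auto"),
                  threshold_result(105, 200, "auto"),
                  threshold_result(110, 200, "auto"))
  expect_identical(harmonize_thresholds(wells, initial), initial)
  expect_identical(harmonize_thresholds(wells[1], initial[1]), initial[1])
})

test_that("threshold-and-invert maps cells to 255 - intensity and the rest to 0", {
  w <- mk_well(c(80L, 200L, 150L, 255L))
  tw <- apply_threshold_invert(w, 150)
  d <- tw$density[tw$mask]
  expect_equal(d, c(175L, 0L, 105L, 0L))      # <= 150 inverted, rest zero
  expect_true(all(tw$density[!tw$mask] == 0L))
  expect_true(all(d[d > 0] >= 1))
  expect_error(apply_threshold_invert(w, 255),
               class = "colonyquant_validation_error")
})

test_that("manual thresholding covers all wells and matches the auto path", {
  set.seed(14)
  wells <- lapply(1:3, function(i) mk_bimodal_well(id = paste0("B", i))$well)
  tws <- manual_threshold(wells, 120)
  expect_true(all(vapply(tws, function(x) x$method, character(1)) == "manual"))
  auto <- apply_threshold_invert(wells[[1]], 120)
  expect_identical(tws[[1]]$density, auto$density)

  per_well <- c(B1 = 120, B2 = 130)
  expect_error(manual_threshold(wells, per_well), "B3",
               class = "colonyquant_validation_error")
})
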