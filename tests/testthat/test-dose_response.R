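test_that("the log-logistic function honours its identities", {
  # midpoint: response at x = e is (c + d) / 2
  expect_equal(ll4(35, b = 1.5, c = 5, d = 95, e = 35), 50)
  # asymptotes for b > 0: d at low dose, c at high dose
  expect_equal(ll4(1e-9, b = 1.5, c = 5, d = 95, e = 35), 95, tolerance = 1e-6)
  expect_equal(ll4(1e9, b = 1.5, c = 5, d = 95, e = 35), 5, tolerance = 1e-6)
  # plug-in arithmetic
  expect_equal(ll4(10, b = 1, c = 0, d = 100, e = 10), 50)
  expect_equal(ll4(100, b = 1, c = 0, d = 100, e = 10), 100 / 11)
  expect_error(ll4(-1, 1, 0, 100, 10), class = "colonyquant_validation_error")
  expect_error(ll4(0, 1, 0, 100, 10), class = "colonyquant_validation_error")
})

test_that("ll4 is monotone decreasing in dose for b > 0, d > c", {
  x <- sort(exp(runif(50, log(0.1), log(1000))))
  y <- ll4(x, b = 2, c = 10, d = 90, e = 20)
  expect_true(all(diff(y) < 0))
})

test_that("noiseless data reproduce the generating parameters", {
  doses <- c(2, 5, 10, 20, 35, 50, 75, 100)
  sim <- simulate_dose_response(list(b = 1.5, c = 5, d = 95, e = 35),
                                doses, replicates = 4, noise_sd = 0, seed = 1)
  fit <- fit_ll4(sim$dose, sim$response)
  expect_equal(unname(coef(fit)), c(1.5, 5, 95, 35), tolerance = 1e-6)
  est <- ic50(fit)
  expect_equal(unname(est["ic50"]), 35, tolerance = 1e-6)
  expect_lt(est["se"], 1e-4)
  # methods are consistent with the estimates
  expect_equal(predict(fit, 35), 50, tolerance = 1e-6)
  expect_equal(length(residuals(fit)), 32L)
  expect_s3_class(summary(fit), "summary.ll4_fit")
})

test_that("degenerate and underdetermined inputs are rejected", {
  expect_error(fit_ll4(c(1, 2, 4, 8, 16), rep(50, 5)),
               class = "colonyquant_fit_error")
  expect_error(fit_ll4(c(1, 2, 4), c(90, 50, 10)),
               "distinct", class = "colonyquant_validation_error")
  expect_error(fit_ll4(rep(c(1, 2, 4), 2), c(90, 50, 10, 91, 51, 11)),
               class = "colonyquant_validation_error")
  expect_error(ic50(structure(list(converged = FALSE), class = "ll4_fit")),
               class = "colonyquant_validation_error")
})

test_that("zero-dose controls are excluded unless anchoring the upper limit", {
  doses <- c(0, 0, 2, 5, 10, 20, 35, 50, 75, 100)
  resp <- c(96, 94, ll4(doses[-(1:2)], 1.5, 5, 95, 35))
  fit <- fit_ll4(doses, resp)
  expect_equal(fit$n_excluded_zero_dose, 2L)
  expect_equal(unname(coef(fit)["e"]), 35, tolerance = 1e-6)
  anchored <- fit_ll4(doses, resp, anchor_upper = TRUE)
  expect_equal(unname(coef(anchored)["d"]), 95)  # control mean
  expect_equal(unname(anchored$se["d"]), 0)
})

test_that("the IC50 estimator is calibrated under replicate noise", {
  doses <- c(2, 5, 10, 20, 35, 50, 75, 100)
  model <- list(b = 1.5, c = 5, d = 95, e = 35)
  est <- vapply(1:100, function(s) {
    sim <- simulate_dose_response(model, doses, replicates = 4,
                                  noise_sd = 0.05 * 95, seed = s)
    unname(ic50(fit_ll4(sim$dose, sim$response))["ic50"])
  }, numeric(1))
  # the estimator's sampling distribution is right-skewed at n = 32, so the
  # median is the appropriate central measure
  expect_lt(abs(stats::median(est) - 35) / 35, 0.05)
})

test_that("area- and intensity-style responses from one curve agree on the IC50", {
  doses <- c(2, 5, 10, 20, 35, 50, 75, 100)
  sim_a <- simulate_dose_response(list(b = 1.5, c = 5, d = 95, e = 35),
                                  doses, 4, noise_sd = 4.75, seed = 99)
  # intensity responses: same inflection, compressed limits
  sim_i <- simulate_dose_response(list(b = 1.5, c = 3, d = 63, e = 35),
                                  doses, 4, noise_sd = 3.15, seed = 199)
  fa <- ic50(fit_ll4(sim_a$dose, sim_a$response))
  fi <- ic50(fit_ll4(sim_i$dose, sim_i$response))
  expect_lt(abs(fa["ic50"] - fi["ic50"]),
            3 * sqrt(fa["se"]^2 + fi["se"]^2))
})

test_that("plotting a fit draws without error", {
  sim <- simulate_dose_response(list(b = 1.5, c = 5, d = 95, e = 35),
                                c(2, 5, 10, 20, 35, 50, 75, 100), 4,
                                noise_sd = 3, seed = 5)
  fit <- fit_ll4(sim$dose, sim$response)
  f <- tempfile(fileext = ".png")
  grDevices::png(f)
  expect_no_error(plot(fit))
  grDevices::dev.off()
  expect_true(file.size(f) > 0)
})

test_that("pearson correlation matches hand-computed values", {
  x <- c(1, 2, 3, 4)
  r <- pearson_correlation(x, 2 * x + 1)
  expect_equal(r$r, 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  expect_equal(pearson_correlation(x, c(2, 1, 4, 3))$r, 0.6)
  expect_error(pearson_correlation(x, rep(1, 4)),
               class = "colonyquant_validation_error")
  expect_error(pearson_correlation(1:2, 1:2),
               class = "colonyquant_validation_error")
})
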