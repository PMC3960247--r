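# Four-parameter log-logistic (LL.4) dose-response fitting.
#
# response(x) = c + (d - c) / (1 + exp(b * (log x - log e)))
#
# c and d are the lower and upper response limits, b the steepness of the
# transition, and e the inflection concentration -- the IC50 for inhibition
# curves (b > 0, d > c). Fitting is nonlinear least squares on the raw
# replicate points (not dose means), on the log-dose scale.

#' Evaluate the four-parameter log-logistic function
#'
#' @param x Concentration(s), strictly positive.
#' @param b Steepness (positive for inhibition with `d > c`).
#' @param c Lower response limit.
#' @param d Upper response limit.
#' @param e Inflection concentration (IC50), positive. At `x = e` the
#'   response is exactly `(c + d) / 2`.
#' @return Response value(s).
#' @examples
#' ll4(10, b = 1, c = 0, d = 100, e = 10)  # 50
#' @export
ll4 <- function(x, b, c, d, e) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop_validation("concentrations must be finite and > 0")
  }
  if (!(e > 0)) stop_validation("'e' (IC50) must be positive")
  c + (d - c) / (1 + exp(b * (log(x) - log(e))))
}

#' Fit the four-parameter log-logistic model
#'
#' Levenberg-Marquardt nonlinear least squares of the LL.4 model to raw
#' replicate responses. Zero-dose (control) points are excluded (`log x`
#' undefined); set `anchor_upper = TRUE` to fix the upper limit `d` at the
#' control mean instead of estimating it. Starting values: `d` at the
#' maximum response, `c` at the minimum, `e` at the dose nearest the
#' half-range crossing, `b = 1`; `e` is bounded to
#' `[min(dose)/10, max(dose) * 10]`.
#'
#' @param doses Numeric vector of concentrations (replicates repeated).
#' @param responses Numeric vector of responses (same length).
#' @param anchor_upper If `TRUE` and zero-dose points are present, `d` is
#'   fixed at their mean response.
#' @return An object of class `ll4_fit` with coefficients `b`, `c`, `d`,
#'   `e`, their standard errors (from the estimated covariance), residuals
#'   and fit diagnostics. `e` is the IC50; see [ic50()].
#' @export
fit_ll4 <- function(doses, responses, anchor_upper = FALSE) {
  if (length(doses) != length(responses)) {
    stop_validation("'doses' and 'responses' must have equal length")
  }
  keep <- is.finite(doses) & is.finite(responses)
  doses <- doses[keep]; responses <- responses[keep]
  control_mean <- if (any(doses <= 0)) mean(responses[doses <= 0]) else NULL
  pos <- doses > 0
  x <- doses[pos]; y <- responses[pos]
  distinct <- length(unique(x))
  if (length(x) < 5L || distinct < 4L) {
    stop_validation(
      "need >= 5 points with >= 4 distinct positive doses (got %d points, %d distinct)",
      length(x), distinct)
  }
  if (stats::sd(y) == 0) {
    stop_fit("responses show no dose effect (constant)")
  }

  d0 <- max(y); c0 <- min(y)
  mid <- (c0 + d0) / 2
  dose_means <- tapply(y, x, mean)
  e0 <- as.numeric(names(dose_means))[which.min(abs(dose_means - mid))]
  e_lim <- c(min(x) / 10, max(x) * 10)
  df <- data.frame(lx = log(x), y = y)

  fix_d <- isTRUE(anchor_upper) && !is.null(control_mean)
  if (fix_d) {
    d_fix <- control_mean
    form <- y ~ c + (d_fix - c) / (1 + exp(b * (lx - log(e))))
    start <- list(b = 1, c = c0, e = e0)
    lower <- c(b = -Inf, c = -Inf, e = e_lim[1])
    upper <- c(b = Inf, c = Inf, e = e_lim[2])
  } else {
    form <- y ~ c + (d - c) / (1 + exp(b * (lx - log(e))))
    start <- list(b = 1, c = c0, d = d0, e = e0)
    lower <- c(b = -Inf, c = -Inf, d = -Inf, e = e_lim[1])
    upper <- c(b = Inf, c = Inf, d = Inf, e = e_lim[2])
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = start, lower = lower,
                      upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(err) {
      stop_fit("LL.4 fit failed: %s", conditionMessage(err),
               diagnostics = list(start = start, n = length(y)))
    })
  if (!isTRUE(fit$convInfo$isConv) && fit$convInfo$stopCode == 0) {
    stop_fit("LL.4 fit did not converge",
             diagnostics = fit$convInfo)
  }

  est <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  se <- if (!is.null(vc)) sqrt(pmax(diag(vc), 0)) else rep(NA_real_, length(est))
  names(se) <- names(est)
  if (fix_d) {
    est <- c(est["b"], est["c"], d = unname(d_fix), est["e"])
    se <- c(se["b"], se["c"], d = 0, se["e"])
  }
  est <- est[c("b", "c", "d", "e")]
  se <- se[c("b", "c", "d", "e")]

  res <- stats::residuals(fit)
  structure(list(
    coefficients = est,
    se = se,
    vcov = vc,
    fitted.values = stats::fitted(fit),
    residuals = res,
    sigma = sqrt(sum(res^2) / max(1L, length(y) - length(start))),
    data = data.frame(dose = x, response = y),
    n_points = length(y),
    n_excluded_zero_dose = sum(!pos),
    control_mean = control_mean,
    anchor_upper = fix_d,
    converged = TRUE
  ), class = "ll4_fit")
}

#' @export
coef.ll4_fit <- function(object, ...) object$coefficients

#' @export
residuals.ll4_fit <- function(object, ...) object$residuals

#' @export
fitted.ll4_fit <- function(object, ...) object$fitted.values

#' @export
vcov.ll4_fit <- function(object, ...) object$vcov

#' Predict responses from a fitted LL.4 model
#'
#' @param object An `ll4_fit`.
#' @param newdata Optional data frame with a `dose` column, or a numeric
#'   vector of doses; default the fitted doses.
#' @param ... Unused.
#' @export
predict.ll4_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) {
    object$data$dose
  } else if (is.data.frame(newdata)) {
    newdata$dose
  } else {
    as.numeric(newdata)
  }
  p <- object$coefficients
  ll4(x, p[["b"]], p[["c"]], p[["d"]], p[["e"]])
}

#' @export
print.ll4_fit <- function(x, ...) {
  p <- x$coefficients
  cat("Four-parameter log-logistic fit\n")
  cat(sprintf("  b (steepness)   %8.4g  (SE %.3g)\n", p["b"], x$se["b"]))
  cat(sprintf("  c (lower limit) %8.4g  (SE %.3g)\n", p["c"], x$se["c"]))
  cat(sprintf("  d (upper limit) %8.4g  (SE %.3g)%s\n", p["d"], x$se["d"],
              if (x$anchor_upper) " [anchored to controls]" else ""))
  cat(sprintf("  e (IC50)        %8.4g  (SE %.3g)\n", p["e"], x$se["e"]))
  cat(sprintf("  %d points, residual SD %.4g\n", x$n_points, x$sigma))
  invisible(x)
}

#' @export
summary.ll4_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se)
  structure(list(coefficients = tab, sigma = object$sigma,
                 n_points = object$n_points,
                 ic50 = ic50(object)), class = "summary.ll4_fit")
}

#' @export
print.summary.ll4_fit <- function(x, ...) {
  cat("LL.4 dose-response fit\n\nCoefficients:\n")
  print(round(x$coefficients, 5))
  cat(sprintf("\nResidual SD: %.4g on %d points\nIC50: %.4g (SE %.3g)\n",
              x$sigma, x$n_points, x$ic50[["ic50"]], x$ic50[["se"]]))
  invisible(x)
}

#' Plot a fitted dose-response curve
#'
#' Dose means with +/- one standard deviation error bars on a log
#' concentration axis, overlaid with the fitted LL.4 curve.
#'
#' @param x An `ll4_fit`.
#' @param xlab,ylab,main Plot labels.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ll4_fit <- function(x, xlab = "dose", ylab = "response",
                         main = "LL.4 dose-response fit", ...) {
  means <- tapply(x$data$response, x$data$dose, mean)
  sds <- tapply(x$data$response, x$data$dose, stats::sd)
  dd <- as.numeric(names(means))
  graphics::plot(dd, means, log = "x", xlab = xlab, ylab = ylab, main = main,
                 pch = 16, ylim = range(c(means - sds, means + sds, x$fitted.values),
                                        na.rm = TRUE), ...)
  ok <- !is.na(sds) & sds > 0
  graphics::arrows(dd[ok], (means - sds)[ok], dd[ok], (means + sds)[ok],
                   angle = 90, code = 3, length = 0.04)
  grid_x <- exp(seq(log(min(dd)), log(max(dd)), length.out = 200))
  graphics::lines(grid_x, predict(x, grid_x))
  invisible(x)
}

#' IC50 of a fitted LL.4 model
#'
#' @param fit A converged `ll4_fit`.
#' @return Named numeric `c(ic50 = e, se = SE(e))`.
#' @export
ic50 <- function(fit) {
  if (!inherits(fit, "ll4_fit") || !isTRUE(fit$converged)) {
    stop_validation("'fit' must be a converged ll4_fit")
  }
  c(ic50 = unname(fit$coefficients["e"]), se = unname(fit$se["e"]))
}

#' Pearson correlation with regression line
#'
#' Product-moment correlation between two quantification read-outs (e.g.
#' colony area percentage versus an absorbance measurement), with the
#' ordinary least-squares line of `y` on `x`.
#'
#' @param x,y Numeric vectors of equal length (>= 3), each with nonzero
#'   variance.
#' @return Object of class `correlation_result`: fields `r`, `slope`,
#'   `intercept`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop_validation("'x' and 'y' must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_validation("zero variance in 'x' or 'y'")
  }
  fit <- stats::lm(y ~ x)
  structure(list(r = stats::cor(x, y),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (n = %d); y = %.4g x + %.4g\n",
              x$r, x$n, x$slope, x$intercept))
  invisible(x)
}
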