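#' Four-parameter sigmoid curve
#'
#' The logistic family `y(t) = y0 + a / (1 + exp(-(t - t0)/tau))` used to
#' smooth biomass, surfactin, ComX and nutrient time courses before they are
#' differentiated. The analytic derivative is
#' `y'(t) = (a / tau) * s * (1 - s)` with `s` the logistic factor. A logistic
#' growth curve with inoculum `x0`, capacity `K` and rate `mu` is the special
#' case `y0 = 0`, `a = K`, `tau = 1/mu`, `t0 = log((K - x0)/x0)/mu`.
#'
#' @param y0 Baseline (units of the fitted quantity).
#' @param a Amplitude (same units; may be negative for decreasing curves).
#' @param t0 Inflection time (h).
#' @param tau Shape scale (h), non-zero.
#' @param residual_sse Residual sum of squares of the fit, if any.
#' @return An object of class `sigmoid_fit4`.
#' @export
sigmoid_fit4 <- function(y0, a, t0, tau, residual_sse = NA_real_) {
  if (!is.finite(tau) || tau == 0) stop("`tau` must be non-zero", call. = FALSE)
  structure(list(y0 = y0, a = a, t0 = t0, tau = tau,
                 residual_sse = residual_sse),
            class = "sigmoid_fit4")
}

#' Three-parameter exponential curve
#'
#' The family `y(t) = y0 + a * exp(k * t)`; `y(0) = y0 + a`.
#'
#' @param y0 Baseline.
#' @param a Scale.
#' @param k Rate (1/h); negative for decay.
#' @param residual_sse Residual sum of squares of the fit, if any.
#' @return An object of class `exp3_fit`.
#' @export
exp3_fit <- function(y0, a, k, residual_sse = NA_real_) {
  structure(list(y0 = y0, a = a, k = k, residual_sse = residual_sse),
            class = "exp3_fit")
}

#' Logistic growth curve helper
#'
#' Convenience constructor expressing logistic growth
#' `X(t) = K / (1 + ((K - x0)/x0) * exp(-mu * t))` as a [sigmoid_fit4()],
#' so it can drive the ComX model with an analytic derivative.
#'
#' @param x0 Inoculation biomass (g/L), `0 < x0 < K`.
#' @param K Carrying capacity (g/L).
#' @param mu Specific growth rate (1/h).
#' @return A `sigmoid_fit4`.
#' @export
#' @examples
#' bio <- logistic_curve(x0 = 0.031, K = 5.4, mu = 0.52)
#' eval_fit(bio, 0)$value   # = 0.031
logistic_curve <- function(x0, K, mu) {
  stopifnot(x0 > 0, K > x0, mu > 0)
  sigmoid_fit4(y0 = 0, a = K, t0 = log((K - x0) / x0) / mu, tau = 1 / mu)
}

#' Evaluate a fitted curve and its analytic derivative
#'
#' @param fit A [sigmoid_fit4()] or [exp3_fit()].
#' @param t Times (h) at which to evaluate.
#' @return A list with numeric vectors `value` and `derivative` (closed
#'   forms; no numerical differencing).
#' @export
eval_fit <- function(fit, t) UseMethod("eval_fit")

#' @export
eval_fit.sigmoid_fit4 <- function(fit, t) {
  s <- 1 / (1 + exp(-(t - fit$t0) / fit$tau))
  list(value = fit$y0 + fit$a * s,
       derivative = (fit$a / fit$tau) * s * (1 - s))
}

#' @export
eval_fit.exp3_fit <- function(fit, t) {
  e <- exp(fit$k * t)
  list(value = fit$y0 + fit$a * e,
       derivative = fit$a * fit$k * e)
}

#' @export
print.sigmoid_fit4 <- function(x, ...) {
  cat(sprintf("<sigmoid_fit4> y0=%.6g a=%.6g t0=%.6g h tau=%.6g h (SSE %.4g)\n",
              x$y0, x$a, x$t0, x$tau, x$residual_sse))
  invisible(x)
}

#' @export
print.exp3_fit <- function(x, ...) {
  cat(sprintf("<exp3_fit> y0=%.6g a=%.6g k=%.6g 1/h (SSE %.4g)\n",
              x$y0, x$a, x$k, x$residual_sse))
  invisible(x)
}

.sse <- function(obs, pred) sum((obs - pred)^2)

# Levenberg-Marquardt least squares from a fixed start; returns NULL on failure
.lm_fit <- function(par, resid_fn, lower = NULL, upper = NULL) {
  out <- tryCatch(
    minpack.lm::nls.lm(
      par = par, fn = resid_fn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500,
                                           ftol = 1e-14, ptol = 1e-14)
    ),
    error = function(e) NULL
  )
  out
}

#' Fit a four-parameter sigmoid by least squares
#'
#' Deterministic initialization: `y0 = min(y)`, `a = max(y) - min(y)`,
#' `t0` the earliest time where `y` crosses the half range, and
#' `tau = (time range)/10`; a mirrored start with negative amplitude is also
#' tried so monotonically decreasing series (e.g. glucose) fit without user
#' intervention, and the start with the lower residual wins (ties go to the
#' first start). The residual sum of squares never exceeds that of the flat
#' fit `y == mean(y)`.
#'
#' @param time Sampling times (h), at least 5 points.
#' @param y Observed values, not all equal.
#' @return A [sigmoid_fit4()] with `residual_sse` filled in.
#' @export
fit_sigmoid4 <- function(time, y) {
  ok <- is.finite(time) & is.finite(y)
  time <- time[ok]; y <- y[ok]
  if (length(time) < 5L) {
    stop("fit_sigmoid4 needs at least 5 points", call. = FALSE)
  }
  if (diff(range(y)) == 0) {
    stop("`y` has no variation; cannot fit a sigmoid", call. = FALSE)
  }
  rng <- diff(range(time))
  half_up <- y >= min(y) + diff(range(y)) / 2
  t0_up <- time[which(half_up)[1L]]
  t0_dn <- time[which(!half_up)[1L]]
  if (is.na(t0_dn)) t0_dn <- time[1L]
  starts <- list(
    c(y0 = min(y), a = diff(range(y)), t0 = t0_up, tau = rng / 10),
    c(y0 = max(y), a = -diff(range(y)), t0 = t0_dn, tau = rng / 10)
  )
  resid_fn <- function(p) {
    s <- 1 / (1 + exp(-(time - p[["t0"]]) / p[["tau"]]))
    y - (p[["y0"]] + p[["a"]] * s)
  }
  best <- NULL
  for (p0 in starts) {
    fit <- .lm_fit(p0, resid_fn)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("sigmoid fit did not converge", call. = FALSE)
  p <- best$par
  flat_sse <- .sse(y, mean(y))
  if (best$deviance > flat_sse + 1e-12 * max(1, flat_sse)) {
    stop("sigmoid fit worse than flat fit; optimizer failed", call. = FALSE)
  }
  sigmoid_fit4(p[["y0"]], p[["a"]], p[["t0"]], p[["tau"]],
               residual_sse = best$deviance)
}

#' Fit a three-parameter exponential by least squares
#'
#' Deterministic initialization from a log-linear regression of the
#' baseline-shifted data; both growth and decay starts are tried and the
#' lower residual wins.
#'
#' @param time Sampling times (h), at least 4 points.
#' @param y Observed values.
#' @return An [exp3_fit()] with `residual_sse` filled in.
#' @export
fit_exp3 <- function(time, y) {
  ok <- is.finite(time) & is.finite(y)
  time <- time[ok]; y <- y[ok]
  if (length(time) < 4L) {
    stop("fit_exp3 needs at least 4 points", call. = FALSE)
  }
  rng <- diff(range(y))
  eps <- max(rng, abs(mean(y)), 1) * 1e-3
  starts <- list()
  # growth-like: baseline below data
  z <- y - min(y) + eps
  sl <- stats::coef(stats::lm(log(z) ~ time))
  starts[[1]] <- c(y0 = min(y) - eps, a = exp(sl[[1]]), k = sl[[2]])
  # decay-like: baseline above data
  z2 <- max(y) - y + eps
  sl2 <- stats::coef(stats::lm(log(z2) ~ time))
  starts[[2]] <- c(y0 = max(y) + eps, a = -exp(sl2[[1]]), k = sl2[[2]])
  # near-flat fallback
  starts[[3]] <- c(y0 = mean(y), a = if (rng > 0) rng / 10 else eps, k = 0.01)
  resid_fn <- function(p) y - (p[["y0"]] + p[["a"]] * exp(p[["k"]] * time))
  best <- NULL
  for (p0 in starts) {
    fit <- .lm_fit(p0, resid_fn)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("exponential fit did not converge", call. = FALSE)
  p <- best$par
  exp3_fit(p[["y0"]], p[["a"]], p[["k"]], residual_sse = best$deviance)
}
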