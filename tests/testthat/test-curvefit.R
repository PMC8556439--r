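test_that("noiseless sigmoid parameters are recovered to 1e-6 relative", {
  tt <- seq(0, 30, by = 1)
  truth <- sigmoid_fit4(y0 = 0, a = 5.4, t0 = 12, tau = 2)
  fit <- fit_sigmoid4(tt, eval_fit(truth, tt)$value)
  expect_equal(fit$a, 5.4, tolerance = 1e-6)
  expect_equal(fit$t0, 12, tolerance = 1e-6)
  expect_equal(fit$tau, 2, tolerance = 1e-6)
  expect_lt(abs(fit$y0), 5.4 * 1e-6)
})

test_that("decreasing series (substrate-like) fit without intervention", {
  tt <- seq(0, 48, by = 2)
  truth <- sigmoid_fit4(y0 = 40, a = -36, t0 = 15, tau = 3)
  fit <- fit_sigmoid4(tt, eval_fit(truth, tt)$value)
  expect_equal(eval_fit(fit, tt)$value, eval_fit(truth, tt)$value,
               tolerance = 1e-6)
})

test_that("degenerate sigmoid inputs raise informative errors", {
  expect_error(fit_sigmoid4(1:4, c(1, 2, 3, 4)), "at least 5")
  expect_error(fit_sigmoid4(1:6, rep(2, 6)), "variation")
})

test_that("sigmoid value and derivative identities hold", {
  f <- sigmoid_fit4(y0 = 1.5, a = 7, t0 = 10, tau = 2.5)
  at_t0 <- eval_fit(f, 10)
  expect_equal(at_t0$value, 1.5 + 7 / 2)
  expect_equal(at_t0$derivative, 7 / (4 * 2.5))
  far <- eval_fit(f, c(-1e4, 1e4))
  expect_equal(far$derivative, c(0, 0), tolerance = 1e-12)
})

test_that("analytic derivatives match central differences", {
  h <- 1e-4
  fits <- list(sigmoid_fit4(0.2, 5.4, 12, 2), exp3_fit(1, 0.5, 0.3))
  tt <- seq(0.5, 20, length.out = 29)
  for (f in fits) {
    analytic <- eval_fit(f, tt)$derivative
    numeric <- (eval_fit(f, tt + h)$value - eval_fit(f, tt - h)$value) / (2 * h)
    expect_true(all(abs(analytic - numeric) <= 1e-6 * pmax(1, abs(analytic))))
  }
})

test_that("noiseless exponential parameters are recovered to 1e-6 relative", {
  tt <- seq(0, 10, by = 0.5)
  truth <- exp3_fit(y0 = 1, a = 0.5, k = 0.3)
  fit <- fit_exp3(tt, eval_fit(truth, tt)$value)
  expect_equal(fit$y0, 1, tolerance = 1e-6)
  expect_equal(fit$a, 0.5, tolerance = 1e-6)
  expect_equal(fit$k, 0.3, tolerance = 1e-6)
  expect_equal(eval_fit(fit, 0)$value, fit$y0 + fit$a)
  expect_error(fit_exp3(1:3, c(1, 2, 4)), "at least 4")
})

test_that("trend-free noisy data yield an essentially flat exponential fit", {
  withr::with_seed(42, {
    tt <- seq(0, 40, by = 2)
    y <- 10 + rnorm(length(tt), 0, 0.1)
    fit <- fit_exp3(tt, y)
    pred <- eval_fit(fit, tt)$value
    expect_lt(diff(range(pred)), 3 * 0.1)
  })
})

test_that("fit residual never exceeds the flat-fit residual", {
  withr::with_seed(7, {
    for (i in 1:10) {
      tt <- sort(runif(12, 0, 48))
      y <- runif(1, 0, 5) + runif(1, 1, 10) /
        (1 + exp(-(tt - runif(1, 5, 40)) / runif(1, 0.5, 6))) +
        rnorm(12, 0, 0.5)
      fit <- fit_sigmoid4(tt, y)
      expect_lte(fit$residual_sse, sum((y - mean(y))^2) * (1 + 1e-9))
    }
  })
})

test_that("sigmoid recovery under 5% noise stays within 5% median error", {
  errs <- withr::with_seed(99, vapply(1:50, function(i) {
    tt <- seq(0, 48, by = 2)
    truth <- sigmoid_fit4(y0 = 0, a = 5.4, t0 = 12, tau = 2)
    y <- eval_fit(truth, tt)$value * (1 + rnorm(length(tt), 0, 0.05))
    fit <- fit_sigmoid4(tt, y)
    max(abs(c(fit$a - 5.4, fit$t0 - 12, fit$tau - 2) / c(5.4, 12, 2)))
  }, numeric(1)))
  expect_lt(median(errs), 0.05)
})

test_that("logistic_curve matches the logistic growth closed form", {
  x0 <- 0.031; K <- 5.4; mu <- 0.52
  bio <- logistic_curve(x0, K, mu)
  tt <- seq(0, 48, by = 4)
  closed <- K / (1 + ((K - x0) / x0) * exp(-mu * tt))
  expect_equal(eval_fit(bio, tt)$value, closed, tolerance = 1e-12)
})
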