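ref_series <- function() {
  # compact 40 g/L-style batch: biomass peaks 5.4, surfactin 1346.6 at 40 h
  cultivation_series(tibble::tibble(
    time_h = c(0, 10, 20, 30, 40, 48),
    cdw_g_L = c(0.031, 1.2, 4.0, 5.2, 5.4, 5.0),
    glucose_g_L = c(40, 32, 15, 6, 4, 4),
    surfactin_mg_L = c(0, 150, 600, 1100, 1346.6, 1330),
    comx_MU = c(26, 120, 216, 180, 160, 150)
  ))
}

test_that("the >= 90% rule picks the earliest qualifying sampled time", {
  expect_equal(t_at_fraction(c(0, 10, 20), c(0, 4, 5), 0.9), 20)
  expect_equal(t_at_fraction(c(0, 10, 20), c(0, 4.6, 5), 0.9), 10)
  # frac = 1 gives the earliest maximum when tied
  expect_equal(t_at_fraction(c(0, 5, 10), c(1, 3, 3), 1), 5)
})

test_that("yield coefficients match their defining ratios", {
  s <- ref_series()
  # X: 0.031 -> 5.4 while S: 40 -> 4
  expect_equal(yield_biomass_substrate(s, 40), (5.4 - 0.031) / 36)
  expect_equal(yield_biomass_substrate(s, 40), 0.149, tolerance = 1e-3)
  expect_equal(yield_product_substrate(s, 40), 1.3466 / 36)
  expect_equal(yield_product_biomass(s, 40, 40),
               1.3466 / ((0.031 + 5.4) / 2))
  expect_equal(yield_product_biomass(s, 40, 40), 0.496, tolerance = 1e-3)
  # scaling both deltas leaves Y_X/S unchanged
  s2 <- ref_series()
  s2$cdw_g_L <- 0.031 + 2 * (s2$cdw_g_L - 0.031)
  s2$glucose_g_L <- 40 - 2 * (40 - s2$glucose_g_L)
  expect_equal(yield_biomass_substrate(s2, 40),
               yield_biomass_substrate(ref_series(), 40))
})

test_that("undefined yields are signalled", {
  s <- cultivation_series(tibble::tibble(
    time_h = c(0, 10), cdw_g_L = c(0.1, 1), glucose_g_L = c(40, 40)))
  expect_error(yield_biomass_substrate(s, 10), "undefined")
})

test_that("growth rates follow the log-ratio definition", {
  expect_equal(growth_rate(1, 2, 0, 1), log(2))
  expect_equal(growth_rate(3, 3, 0, 5), 0)
  doubling <- cultivation_series(tibble::tibble(
    time_h = seq(0, 10, 2), cdw_g_L = 0.1 * 2^(seq(0, 10, 2) / 2)))
  expect_equal(mu_max(doubling), log(2) / 2)
  expect_error(growth_rate(0, 1, 0, 1), "> 0")
})

test_that("specific productivity and q_overall are internally consistent", {
  expect_equal(specific_productivity(1, 1, 3, 1), 0.5)
  expect_equal(specific_productivity(0, 1, 3, 2), 0)
  s <- ref_series()
  # manual reconstruction via the >= 90% reference points
  t_p <- t_at_fraction(s$time_h, s$surfactin_mg_L, 0.9)   # 40 h
  t_x <- t_at_fraction(s$time_h, s$cdw_g_L, 0.9)          # 30 h
  manual <- specific_productivity(1.3466, 0.031, s$cdw_g_L[s$time_h == t_x],
                                  t_p - 0)
  expect_equal(q_overall(s), manual)
  expect_equal(q_overall(s), 0.0124, tolerance = 0.02)
})

test_that("process_metrics summarises each replicate like the process table", {
  s <- ref_series()
  m <- process_metrics(s)
  expect_equal(nrow(m), 1L)
  expect_equal(m$x_max, 5.4)
  expect_equal(m$p_max, 1346.6)
  expect_equal(m$comx_max, 216)
  expect_equal(m$comx_t_end, 150)
  expect_equal(m$t_x90, 30)
  expect_equal(m$t_p90, 40)
  expect_equal(m$y_xs, yield_biomass_substrate(s, 30))
  expect_equal(m$mu_max, mu_max(s))
  # two replicates give two rows
  two <- tibble::as_tibble(s)
  two2 <- two; two2$replicate <- "R2"
  m2 <- process_metrics(cultivation_series(rbind(two, two2)))
  expect_equal(nrow(m2), 2L)
})

test_that("q_vs_comx peaks before the ComX maximum on a decoupled instance", {
  bio <- sigmoid_fit4(y0 = 2, a = 0, t0 = 0, tau = 1)       # flat biomass
  surf <- sigmoid_fit4(y0 = 0, a = 1000, t0 = 9, tau = 2)   # P' peaks at 9 h
  comx <- sigmoid_fit4(y0 = 20, a = 200, t0 = 16, tau = 1.5)
  tt <- seq(0, 20, by = 0.1)
  qc <- q_vs_comx(bio, surf, comx, tt)
  expect_equal(attr(qc, "t_at_q_max"), 9, tolerance = 1e-6)
  expect_lt(attr(qc, "t_at_q_max"), tt[which.max(eval_fit(comx, tt)$value)])
  expect_lt(attr(qc, "comx_at_q_max"), max(qc$comx_MU))
  # constant surfactin means zero productivity everywhere
  qc0 <- q_vs_comx(bio, sigmoid_fit4(500, 0, 0, 1), comx, tt)
  expect_true(all(qc0$q_surfactin == 0))
  # truncation at an interior ComX maximum
  comx_dec <- sigmoid_fit4(y0 = 20, a = -150, t0 = 10, tau = 2)
  qc_dec <- q_vs_comx(bio, surf, comx_dec, tt)
  expect_true(attr(qc_dec, "truncated_at_comx_max"))
  expect_equal(nrow(qc_dec), 1L)
})

test_that("q_vs_comx reproduces the generator's analytic productivity", {
  gen <- noiseless_gen(seed = 3)
  s <- tibble::as_tibble(gen$series)
  bio_fit <- fit_sigmoid4(s$time_h, s$cdw_g_L)
  surf_fit <- fit_sigmoid4(s$time_h, s$surfactin_mg_L)
  comx_fit <- fit_sigmoid4(s$time_h, s$comx_MU)
  tt <- seq(2, 40, by = 0.5)
  qc <- q_vs_comx(bio_fit, surf_fit, comx_fit, tt)
  truth_q <- 1e-3 * eval_fit(gen$truth$surfactin_curve, qc$time_h)$derivative /
    eval_fit(gen$truth$biomass_curve, qc$time_h)$value
  expect_lt(max(abs(qc$q_surfactin - truth_q)) / max(abs(truth_q)), 0.02)
})
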