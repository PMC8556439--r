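flat_biomass <- function(level) sigmoid_fit4(y0 = level, a = 0, t0 = 0, tau = 1)

test_that("with zero biomass the CSP balance follows its closed form", {
  p <- comx_params(a0 = 26.5, b = 0, d = 0, e = 0)
  tt <- seq(0, 60, by = 0.5)
  tr <- simulate_comx(p, flat_biomass(0), tt)
  expect_equal(tr$comx_MU, rep(26.5, length(tt)), tolerance = 1e-8)
  expect_equal(tr$ea_csp, ea_const_a(tt, 26.5, 0, p$f, p$g),
               tolerance = 1e-6)
  # long-time limit (f/g) * a0 = 9.29 EA
  expect_equal(tail(tr$ea_csp, 1), 0.115 / 0.328 * 26.5, tolerance = 1e-4)
})

test_that("with e = b = 0 the growth term integrates the biomass derivative", {
  p <- comx_params(a0 = 26.5, b = 0, d = 476, e = 0)
  bio <- logistic_curve(0.031, 5.4, 0.52)
  tt <- seq(0, 48, by = 2)
  tr <- simulate_comx(p, bio, tt)
  x <- eval_fit(bio, tt)$value
  expected <- 26.5 + 476 * (x - x[1])
  expect_equal(tr$comx_MU, expected, tolerance = 1e-6)
})

test_that("constant biomass drives ComX to the closed-form steady state", {
  p <- comx_params_midpoint()
  ss <- steady_state_comx(p, 5.4)
  expect_equal(ss$a_ss, p$b * 5.4 * p$g / (p$e * p$f))
  expect_equal(ss$a_ss, 197.34, tolerance = 1e-4)
  expect_equal(ss$ea_ss, 69.19, tolerance = 1e-4)
  tr <- simulate_comx(p, flat_biomass(5.4), c(0, 100, 200))
  expect_equal(tail(tr$comx_MU, 1), ss$a_ss, tolerance = 1e-5)
  # linearity of the steady state in b
  p2 <- comx_params(a0 = p$a0, b = 2 * p$b, d = p$d, e = p$e)
  expect_equal(steady_state_comx(p2, 5.4)$a_ss, 2 * ss$a_ss)
  expect_equal(steady_state_comx(p, 0)$a_ss, 0)
})

test_that("steady state without protease coupling is flagged", {
  p <- comx_params(e = 0)
  expect_error(steady_state_comx(p, 5.4), "steady state")
})

test_that("solution is homogeneous in initial state and biomass forcing", {
  p <- comx_params_midpoint()
  bio1 <- logistic_curve(0.031, 5.4, 0.52)
  bio2 <- sigmoid_fit4(y0 = 0, a = 2 * 5.4, t0 = bio1$t0, tau = bio1$tau)
  tt <- seq(0, 48, by = 1)
  p2 <- comx_params(a0 = 2 * p$a0, b = p$b, d = p$d, e = p$e)
  tr1 <- simulate_comx(p, bio1, tt, ea0 = 1, quiet = TRUE)
  tr2 <- simulate_comx(p2, bio2, tt, ea0 = 2, quiet = TRUE)
  expect_equal(tr2$comx_MU, 2 * tr1$comx_MU, tolerance = 1e-6)
  expect_equal(tr2$ea_csp, 2 * tr1$ea_csp, tolerance = 1e-6)
})

test_that("adaptive solver matches the forward-Euler oracle", {
  p <- comx_params_midpoint()
  bio <- logistic_curve(0.031, 5.4, 0.52)
  tt <- seq(0, 48, by = 0.5)
  tr <- simulate_comx(p, bio, tt, quiet = TRUE)
  eu <- euler_comx(p, bio, tt, dt = 1e-3)
  sup <- max(abs(pmax(eu$a, 0) - tr$comx_MU)) / max(abs(tr$comx_MU))
  expect_lt(sup, 1e-3)
})

test_that("ComX peaks after the growth-rate maximum, then settles lower", {
  p <- comx_params_midpoint()
  bio <- logistic_curve(0.031, 5.4, 0.52)
  tt <- seq(0, 48, by = 0.1)
  tr <- simulate_comx(p, bio, tt, quiet = TRUE)
  t_peak_a <- tt[which.max(tr$comx_MU)]
  t_peak_dx <- tt[which.max(eval_fit(bio, tt)$derivative)]
  expect_gt(t_peak_a, t_peak_dx)
  expect_lt(tail(tr$comx_MU, 1), max(tr$comx_MU))
})

test_that("sensitivity envelope collapses at zero and nests by fraction", {
  p <- comx_params_midpoint()
  tt <- seq(0, 48, by = 2)
  withr::with_seed(3, {
    for (i in 1:2) {
      bio <- logistic_curve(runif(1, 0.02, 0.05), runif(1, 4, 6),
                            runif(1, 0.3, 0.7))
      env0 <- sensitivity_envelope(p, bio, tt, frac = 0)
      expect_equal(env0$lower, env0$nominal)
      expect_equal(env0$upper, env0$nominal)
      env4 <- sensitivity_envelope(p, bio, tt, frac = 0.04)
      env8 <- sensitivity_envelope(p, bio, tt, frac = 0.08)
      expect_true(all(env8$lower <= env4$lower + 1e-9))
      expect_true(all(env8$upper >= env4$upper - 1e-9))
      expect_true(all(env8$lower <= env8$nominal & env8$nominal <= env8$upper))
    }
  })
})

test_that("simulation guards its preconditions", {
  p <- comx_params_midpoint()
  expect_error(simulate_comx(p, flat_biomass(-1), c(0, 1)), "non-negative")
  expect_error(simulate_comx(p, flat_biomass(1), c(2, 1)), "increasing")
  expect_error(comx_params(g = 0), "positive")
  expect_error(comx_params(b = -1), "non-negative")
})

test_that("trajectories can be written as model CSV", {
  p <- comx_params_midpoint()
  tr <- simulate_comx(p, flat_biomass(5.4), seq(0, 10, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_named(back, c("time_h", "comx_MU_model", "ea_csp_model", "cdw_g_L"))
  expect_equal(back$comx_MU_model, tr$comx_MU)
})
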