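#' Configuration of the synthetic cultivation generator
#'
#' Defaults emulate the 40 g/L glucose reference batch: logistic biomass
#' from 0.031 to 5.4 g/L at specific growth rate 0.52 1/h over 48 h sampled
#' every 2 h, glucose tied to biomass through a 0.15 g/g yield, a sigmoidal
#' surfactin curve reaching 1346.6 mg/L, ComX activity simulated from the
#' ComX / CSP model at the calibration midpoints with additive Gaussian
#' noise, and total endopeptidase activity tracking cell density.
#'
#' @param x0 Inoculation biomass (g/L).
#' @param x_max Biomass capacity (g/L).
#' @param mu Logistic growth rate (1/h).
#' @param t_end Cultivation length (h).
#' @param sample_every Sampling interval (h).
#' @param s0 Initial glucose (g/L).
#' @param y_xs Biomass yield on glucose (g/g) tying glucose to biomass.
#' @param surfactin_max Surfactin plateau (mg/L).
#' @param surfactin_t50 Surfactin half-maximum time (h).
#' @param surfactin_tau Surfactin sigmoid shape scale (h).
#' @param comx_params True [comx_params()] driving the ComX column.
#' @param ea0 Initial CSP activity for the simulation.
#' @param noise_sd_comx Additive Gaussian SD on ComX (MU).
#' @param noise_cv_other Multiplicative CV on concentrations and activities.
#' @param ea_per_cdw Total endopeptidase activity per unit biomass
#'   (dA/(h*mL) per g/L).
#' @param n_replicates Number of biological replicates.
#' @param seed Integer seed; identical seeds give identical output.
#' @return An object of class `synth_config` (a list).
#' @export
synth_config <- function(x0 = 0.031, x_max = 5.4, mu = 0.52, t_end = 48,
                         sample_every = 2, s0 = 40, y_xs = 0.15,
                         surfactin_max = 1346.6, surfactin_t50 = 20,
                         surfactin_tau = 4,
                         comx_params = comx_params_midpoint(), ea0 = 0,
                         noise_sd_comx = 5, noise_cv_other = 0.05,
                         ea_per_cdw = 15, n_replicates = 2L, seed = 1L) {
  stopifnot(x0 > 0, x_max > x0, mu > 0, t_end > 0, sample_every > 0,
            s0 > 0, y_xs > 0, surfactin_max >= 0, surfactin_tau > 0,
            noise_sd_comx >= 0, noise_cv_other >= 0, ea_per_cdw >= 0,
            n_replicates >= 1)
  structure(
    list(x0 = x0, x_max = x_max, mu = mu, t_end = t_end,
         sample_every = sample_every, s0 = s0, y_xs = y_xs,
         surfactin_max = surfactin_max, surfactin_t50 = surfactin_t50,
         surfactin_tau = surfactin_tau, comx_params = comx_params,
         ea0 = ea0, noise_sd_comx = noise_sd_comx,
         noise_cv_other = noise_cv_other, ea_per_cdw = ea_per_cdw,
         n_replicates = as.integer(n_replicates), seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate a synthetic cultivation time series
#'
#' Produces noisy sampled observables plus the generating truth: with the
#' noise SDs set to zero the ComX column equals the model simulation
#' exactly, which closes the generator/estimator validation loop. Glucose is
#' floored at zero; if the floor is reached before `t_end` the result
#' carries a `depleted = TRUE` attribute (a flag, not an error).
#'
#' @param cfg A [synth_config()].
#' @return A list with `series` (a [cultivation_series()]) and `truth`
#'   (list with `biomass_curve`, `surfactin_curve`, `comx_trajectory`,
#'   `params`, `ea0`, `config`).
#' @export
generate_cultivation <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  tt <- seq(0, cfg$t_end, by = cfg$sample_every)
  biomass_curve <- logistic_curve(cfg$x0, cfg$x_max, cfg$mu)
  surfactin_curve <- sigmoid_fit4(y0 = 0, a = cfg$surfactin_max,
                                  t0 = cfg$surfactin_t50,
                                  tau = cfg$surfactin_tau)
  x_true <- eval_fit(biomass_curve, tt)$value
  s_true <- pmax(cfg$s0 - (x_true - cfg$x0) / cfg$y_xs, 0)
  p_true <- eval_fit(surfactin_curve, tt)$value
  traj <- simulate_comx(cfg$comx_params, biomass_curve, tt, ea0 = cfg$ea0,
                        quiet = TRUE)
  ea_true <- cfg$ea_per_cdw * x_true
  conv <- conversion_config()

  reps <- withr::with_seed(cfg$seed, lapply(seq_len(cfg$n_replicates),
    function(r) {
      cv <- cfg$noise_cv_other
      n <- length(tt)
      mult <- function(v) v * (1 + stats::rnorm(n, 0, cv))
      cdw <- pmax(mult(x_true), 0)
      tibble::tibble(
        time_h = tt,
        replicate = sprintf("R%d", r),
        od600 = cdw * conv$od_cdw_factor,
        cdw_g_L = cdw,
        glucose_g_L = pmax(mult(s_true), 0),
        surfactin_mg_L = pmax(mult(p_true), 0),
        comx_MU = traj$comx_MU + stats::rnorm(n, 0, cfg$noise_sd_comx),
        ea_total = pmax(mult(ea_true), 0)
      )
    }))
  series <- cultivation_series(do.call(rbind, reps))
  attr(series, "depleted") <- any(s_true == 0)
  list(series = series,
       truth = list(biomass_curve = biomass_curve,
                    surfactin_curve = surfactin_curve,
                    comx_trajectory = traj, params = cfg$comx_params,
                    ea0 = cfg$ea0, config = cfg))
}

#' Generate synthetic bioassay blank measurements
#'
#' @param mean Blank mean (MU).
#' @param sd Blank SD (MU, >= 0).
#' @param n Number of blanks (>= 1).
#' @param seed Integer seed.
#' @return Numeric vector of `n` seeded normal draws.
#' @export
generate_blanks <- function(mean, sd, n, seed = 1L) {
  stopifnot(n >= 1, sd >= 0)
  withr::with_seed(seed, stats::rnorm(n, mean, sd))
}

#' Generate a synthetic ComX degradation series
#'
#' Linear decline `a0 - rate * t`, floored at zero, with optional additive
#' Gaussian noise; the default sampling grid mirrors an 8-h supernatant
#' incubation.
#'
#' @param a0 Initial activity (MU).
#' @param rate Degradation rate (MU/h, >= 0).
#' @param times Sampling times (h).
#' @param noise_sd Additive noise SD (MU).
#' @param seed Integer seed.
#' @return A tibble with columns `time_h` and `comx_MU`.
#' @export
generate_degradation_series <- function(a0, rate,
                                        times = c(0, 1, 2, 3, 4, 6, 8),
                                        noise_sd = 0, seed = 1L) {
  stopifnot(rate >= 0)
  clean <- pmax(a0 - rate * times, 0)
  noisy <- withr::with_seed(seed,
    pmax(clean + stats::rnorm(length(times), 0, noise_sd), 0))
  tibble::tibble(time_h = times, comx_MU = noisy)
}

#' Generate a raw Miller-assay record hitting a target activity
#'
#' Inverts the Miller-unit formula for OD420 so that
#' `miller_units(record) == target_mu` exactly; used to test the assay
#' arithmetic end to end.
#'
#' @param target_mu Target activity (MU).
#' @param od600 Culture density (> 0).
#' @param t_reaction Reaction time (min, > 0).
#' @param v_sample Sample volume (mL, > 0).
#' @param od550 Debris-correction absorbance.
#' @return A [miller_record()].
#' @export
generate_miller_raw <- function(target_mu, od600 = 0.5, t_reaction = 30,
                                v_sample = 0.1, od550 = 0.05) {
  od420 <- target_mu * t_reaction * v_sample * od600 / 1000 + 1.75 * od550
  if (od420 < 0) {
    stop("target activity infeasible: implied OD420 is negative",
         call. = FALSE)
  }
  miller_record(od420, od550, od600, t_reaction, v_sample)
}
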