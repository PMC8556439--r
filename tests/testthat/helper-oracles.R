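# Independent oracles used to cross-check the package's solvers.

# fixed-step forward-Euler integration of the ComX / CSP system,
# deliberately independent of the adaptive-solver path in the package
euler_comx <- function(params, biomass, t_out, dt = 1e-3, ea0 = 0) {
  t0 <- t_out[1L]
  n_steps <- round((t_out[length(t_out)] - t0) / dt)
  a <- params$a0
  ea <- ea0
  out_idx <- round((t_out - t0) / dt)
  res_a <- numeric(length(t_out))
  res_ea <- numeric(length(t_out))
  hit <- 1L
  if (out_idx[1L] == 0L) {
    res_a[1L] <- a; res_ea[1L] <- ea; hit <- 2L
  }
  for (k in seq_len(n_steps)) {
    tk <- t0 + (k - 1L) * dt
    bx <- eval_fit(biomass, tk)
    da <- params$b * bx$value + params$d * bx$derivative - params$e * ea
    dea <- params$f * a - params$g * ea
    a <- a + dt * da
    ea <- ea + dt * dea
    if (hit <= length(t_out) && k == out_idx[hit]) {
      res_a[hit] <- a; res_ea[hit] <- ea; hit <- hit + 1L
    }
  }
  list(time = t_out, a = res_a, ea = res_ea)
}

# analytic solution of dEA/dt = f*a0 - g*EA at constant a and biomass zero
ea_const_a <- function(t, a0, ea0, f, g) {
  (f / g) * a0 * (1 - exp(-g * t)) + ea0 * exp(-g * t)
}

# convenience: noiseless single-replicate synthetic cultivation
noiseless_gen <- function(seed = 1L, ...) {
  generate_cultivation(synth_config(noise_sd_comx = 0, noise_cv_other = 0,
                                    n_replicates = 1L, seed = seed, ...))
}
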