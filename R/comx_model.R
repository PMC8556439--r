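#' ComX model parameters
#'
#' Parameters of the coupled ComX / ComX-specific-protease (CSP) model
#' \deqn{da/dt = b \cdot c_{CDW} + d \cdot dc_{CDW}/dt - e \cdot EA_{CSP}}
#' \deqn{dEA_{CSP}/dt = f \cdot a - g \cdot EA_{CSP}}
#' where `a` is the ComX activity (Miller units), `c_CDW` the cell dry weight
#' (g/L) and `EA_CSP` the putative protease activity (dA/(h*mL)).
#'
#' Defaults are the midpoints of the published calibration ranges; `f` and
#' `g` are fixed values of that calibration. Units: `b` (MU*L)/(g*h),
#' `d` (MU*L)/g, `e` MU/(EA*h), `f` EA/(MU*h), `g` 1/h.
#'
#' @param a0 Initial ComX activity at t0 (MU).
#' @param b Biomass-dependent ComX formation rate.
#' @param d Growth-dependent ComX formation coefficient.
#' @param e CSP-dependent ComX degradation rate.
#' @param f CSP formation rate.
#' @param g CSP first-order degradation rate (must be > 0).
#' @param bounds Per-parameter bounds, as returned by [comx_bounds()].
#' @return An object of class `comx_params`.
#' @export
#' @examples
#' comx_params()          # calibration midpoints
comx_params <- function(a0 = 26.5, b = 18.835, d = 476, e = 1.47,
                        f = 0.115, g = 0.328, bounds = comx_bounds()) {
  p <- c(a0 = a0, b = b, d = d, e = e, f = f, g = g)
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("all parameters must be finite and non-negative", call. = FALSE)
  }
  if (g <= 0) stop("`g` must be positive", call. = FALSE)
  structure(list(a0 = a0, b = b, d = d, e = e, f = f, g = g, bounds = bounds),
            class = "comx_params")
}

#' Default parameter bounds of the ComX model calibration
#'
#' `a0` 21--32 MU, `b` 17.72--19.95 (MU*L)/(g*h), `d` 436--516 (MU*L)/g,
#' `e` 1.36--1.58 MU/(EA*h); `f` = 0.115 and `g` = 0.328 are fixed.
#'
#' @return A data frame with columns `parameter`, `lower`, `upper`, `fixed`.
#' @export
comx_bounds <- function() {
  data.frame(
    parameter = c("a0", "b", "d", "e", "f", "g"),
    lower = c(21, 17.72, 436, 1.36, 0.115, 0.328),
    upper = c(32, 19.95, 516, 1.58, 0.115, 0.328),
    fixed = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Midpoints of the free-parameter calibration ranges
#' @return A `comx_params` at the bound midpoints (f, g fixed).
#' @export
comx_params_midpoint <- function() {
  b <- comx_bounds()
  mid <- (b$lower + b$upper) / 2
  names(mid) <- b$parameter
  comx_params(a0 = mid[["a0"]], b = mid[["b"]], d = mid[["d"]],
              e = mid[["e"]], f = mid[["f"]], g = mid[["g"]])
}

#' @export
print.comx_params <- function(x, ...) {
  cat(sprintf(
    "<comx_params> a0=%.4g MU  b=%.4g  d=%.4g  e=%.4g  f=%.4g  g=%.4g\n",
    x$a0, x$b, x$d, x$e, x$f, x$g))
  invisible(x)
}

#' Simulate the ComX / CSP model over a biomass trajectory
#'
#' Solves the coupled linear system with a stiff-capable adaptive solver
#' (deSolve's `lsoda`) at relative tolerance 1e-8. The biomass forcing can be
#' any object with an [eval_fit()] method providing value and analytic
#' derivative (typically a [sigmoid_fit4()] or [logistic_curve()]).
#' Trajectories are clipped at zero on output (with a warning if the raw
#' solution dips below -1e-9); the solver state itself is never clipped.
#'
#' @param params A [comx_params()].
#' @param biomass Biomass curve with an [eval_fit()] method, defined on the
#'   grid; must be non-negative there.
#' @param t_grid Strictly increasing times (h).
#' @param ea0 Initial CSP activity (default 0: no ComX-induced protease at
#'   inoculation).
#' @param rtol,atol Solver tolerances.
#' @param quiet Suppress the clipping warning (used by callers that run many
#'   simulations, e.g. the fitting residual and the envelope factorial).
#' @return A tibble of class `comx_trajectory` with columns `time_h`,
#'   `comx_MU`, `ea_csp`, `cdw_g_L`; solver diagnostics in attribute
#'   `solver_report`.
#' @export
simulate_comx <- function(params, biomass, t_grid, ea0 = 0,
                          rtol = 1e-8, atol = 1e-8, quiet = FALSE) {
  stopifnot(inherits(params, "comx_params"))
  if (length(t_grid) < 2L || is.unsorted(t_grid, strictly = TRUE)) {
    stop("`t_grid` must be strictly increasing with >= 2 points", call. = FALSE)
  }
  bio <- eval_fit(biomass, t_grid)
  if (any(bio$value < 0)) stop("biomass must be non-negative", call. = FALSE)
  rhs <- function(t, y, p) {
    bx <- eval_fit(biomass, t)
    list(c(p$b * bx$value + p$d * bx$derivative - p$e * y[2L],
           p$f * y[1L] - p$g * y[2L]))
  }
  sol <- deSolve::ode(
    y = c(a = params$a0, ea = ea0), times = t_grid, func = rhs,
    parms = params, method = "lsoda", rtol = rtol, atol = atol
  )
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1L] < 0) {
    stop("ODE solver failed (istate ", diagn[1L], ")", call. = FALSE)
  }
  a <- sol[, "a"]; ea <- sol[, "ea"]
  if (!quiet && (any(a < -1e-9) || any(ea < -1e-9))) {
    warning("trajectory dipped below -1e-9; clipped at zero on output")
  }
  out <- tibble::tibble(
    time_h = sol[, "time"],
    comx_MU = pmax(a, 0),
    ea_csp = pmax(ea, 0),
    cdw_g_L = bio$value
  )
  structure(out,
            class = c("comx_trajectory", class(out)),
            solver_report = list(method = "lsoda", rtol = rtol, atol = atol,
                                 istate = diagn),
            params = params, ea0 = ea0)
}

#' Closed-form steady state of the ComX / CSP model
#'
#' At constant biomass `x` and with both derivatives zero, the CSP balance
#' gives `EA = (f/g) * a` and the ComX balance `b*x = e*EA`, hence
#' `a_ss = b*x*g/(e*f)` and `ea_ss = f*a_ss/g`.
#'
#' @param params A [comx_params()].
#' @param x Constant biomass (g/L).
#' @return A list with `a_ss` (MU) and `ea_ss` (dA/(h*mL)).
#' @export
#' @examples
#' steady_state_comx(comx_params_midpoint(), x = 5.4)  # about 197 MU
steady_state_comx <- function(params, x) {
  stopifnot(inherits(params, "comx_params"))
  if (params$e * params$f <= 0) {
    stop("no finite steady state: e*f must be positive", call. = FALSE)
  }
  a_ss <- params$b * x * params$g / (params$e * params$f)
  list(a_ss = a_ss, ea_ss = params$f * a_ss / params$g)
}

#' Pointwise sensitivity envelope of the ComX trajectory
#'
#' Perturbs each free parameter (`a0`, `b`, `d`, `e`) by factors
#' `(1 - frac)`, 1, `(1 + frac)` in a full factorial (3^4 = 81 simulations;
#' `f` and `g` stay fixed) and returns the pointwise minimum and maximum of
#' the ComX trajectory, together with the nominal one. This mirrors the
#' observation that a parameter variation below 8% spans the entire cloud of
#' replicate measurements.
#'
#' @param params Nominal [comx_params()].
#' @param biomass Biomass curve for [simulate_comx()].
#' @param t_grid Time grid (h).
#' @param frac Relative perturbation, `0 <= frac < 1` (default 0.08).
#' @param ea0 Initial CSP activity.
#' @return A tibble with columns `time_h`, `lower`, `nominal`, `upper`.
#' @export
sensitivity_envelope <- function(params, biomass, t_grid, frac = 0.08,
                                 ea0 = 0) {
  stopifnot(inherits(params, "comx_params"), frac >= 0, frac < 1)
  nominal <- simulate_comx(params, biomass, t_grid, ea0 = ea0, quiet = TRUE)
  lo <- nominal$comx_MU
  hi <- nominal$comx_MU
  if (frac > 0) {
    fac <- c(1 - frac, 1, 1 + frac)
    grid <- expand.grid(a0 = fac, b = fac, d = fac, e = fac)
    for (i in seq_len(nrow(grid))) {
      if (all(grid[i, ] == 1)) next
      p <- comx_params(a0 = params$a0 * grid$a0[i], b = params$b * grid$b[i],
                       d = params$d * grid$d[i], e = params$e * grid$e[i],
                       f = params$f, g = params$g, bounds = params$bounds)
      tr <- simulate_comx(p, biomass, t_grid, ea0 = ea0, quiet = TRUE)
      lo <- pmin(lo, tr$comx_MU)
      hi <- pmax(hi, tr$comx_MU)
    }
  }
  tibble::tibble(time_h = nominal$time_h, lower = lo,
                 nominal = nominal$comx_MU, upper = hi)
}

#' Write a simulated trajectory as a cultivation-style CSV
#'
#' @param trajectory A `comx_trajectory`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "comx_trajectory"))
  out <- tibble::tibble(
    time_h = trajectory$time_h,
    comx_MU_model = trajectory$comx_MU,
    ea_csp_model = trajectory$ea_csp,
    cdw_g_L = trajectory$cdw_g_L
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}
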