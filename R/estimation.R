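#' Fit ComX model parameters to a measured time series
#'
#' Bounded least squares over the free parameters (`a0`, `b`, `d`, `e`) of
#' the ComX / CSP model, with `f` and `g` held at their fixed calibration
#' values. The objective is the plain (unweighted) sum of squared residuals
#' between the simulated and measured ComX activity at the sampled times.
#' A seeded multistart (bounds midpoint plus 4 Latin-hypercube points) guards
#' against local minima; the lowest residual wins, ties broken by start
#' order, so the result is deterministic for a fixed seed.
#'
#' @param series A [cultivation_series()] with a `comx_MU` column (single
#'   replicate; at least 6 non-missing observations), or a data frame with
#'   `time_h` and `comx_MU`.
#' @param biomass Biomass curve with an [eval_fit()] method covering the
#'   observation window.
#' @param bounds Bounds table as from [comx_bounds()].
#' @param ea0 Initial CSP activity (default 0).
#' @param n_starts Number of multistart points (default 5).
#' @param seed Integer seed for the Latin-hypercube starts.
#' @return An object of class `comx_fit`: a list with elements `params`
#'   ([comx_params()]), `sse` (MU^2), `n_obs`, `converged`, and `at_bounds`
#'   (named logical vector for the free parameters).
#' @export
fit_comx_params <- function(series, biomass, bounds = comx_bounds(),
                            ea0 = 0, n_starts = 5, seed = 1) {
  df <- tibble::as_tibble(series)
  if (!all(c("time_h", "comx_MU") %in% names(df))) {
    stop("`series` needs columns time_h and comx_MU", call. = FALSE)
  }
  if ("replicate" %in% names(df) && length(unique(df$replicate)) > 1L) {
    stop("fit one replicate at a time", call. = FALSE)
  }
  ok <- is.finite(df$time_h) & is.finite(df$comx_MU)
  t_obs <- df$time_h[ok]
  a_obs <- df$comx_MU[ok]
  if (length(t_obs) < 6L) {
    stop("need at least 6 ComX observations", call. = FALSE)
  }
  free <- bounds[!bounds$fixed, , drop = FALSE]
  fixed <- bounds[bounds$fixed, , drop = FALSE]
  lower <- stats::setNames(free$lower, free$parameter)
  upper <- stats::setNames(free$upper, free$parameter)
  fixed_vals <- stats::setNames(fixed$lower, fixed$parameter)

  make_params <- function(p) {
    full <- c(p, fixed_vals)
    comx_params(a0 = full[["a0"]], b = full[["b"]], d = full[["d"]],
                e = full[["e"]], f = full[["f"]], g = full[["g"]],
                bounds = bounds)
  }
  sim_grid <- sort(unique(c(min(t_obs), t_obs)))
  idx <- match(t_obs, sim_grid)
  resid_fn <- function(p) {
    tr <- simulate_comx(make_params(p), biomass, sim_grid, ea0 = ea0,
                        quiet = TRUE)
    tr$comx_MU[idx] - a_obs
  }

  starts <- list((lower + upper) / 2)
  if (n_starts > 1) {
    u <- withr::with_seed(seed, lhs::randomLHS(n_starts - 1L, length(lower)))
    for (i in seq_len(nrow(u))) {
      starts[[i + 1L]] <- lower + u[i, ] * (upper - lower)
    }
  }

  best <- NULL
  best_i <- NA_integer_
  any_conv <- FALSE
  for (i in seq_along(starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[[i]], fn = resid_fn, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (fit$info %in% 1:4) any_conv <- TRUE
    if (is.null(best) || fit$deviance < best$deviance) {
      best <- fit
      best_i <- i
    }
  }
  if (is.null(best)) stop("all optimization starts failed", call. = FALSE)
  p <- best$par
  tol <- 1e-6 * (upper - lower)
  at_bounds <- (p - lower <= tol) | (upper - p <= tol)
  structure(
    list(params = make_params(p), sse = best$deviance, n_obs = length(t_obs),
         converged = any_conv, at_bounds = at_bounds, start_index = best_i,
         ea0 = ea0),
    class = "comx_fit"
  )
}

#' @export
print.comx_fit <- function(x, ...) {
  cat(sprintf("<comx_fit> SSE %.6g MU^2 over %d observations (%s)\n",
              x$sse, x$n_obs,
              if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  ab <- names(x$at_bounds)[x$at_bounds]
  if (length(ab)) cat("at bound:", paste(ab, collapse = ", "), "\n")
  invisible(x)
}

#' Parameter-recovery experiment for the ComX model fit
#'
#' Generates replicate synthetic cultivations with known true parameters
#' (via [generate_cultivation()]), refits each with [fit_comx_params()], and
#' reports signed relative errors per free parameter. This is the package's
#' validation harness for the estimation machinery.
#'
#' @param true_params True [comx_params()] used to generate the data.
#' @param noise_sd Gaussian observation noise on ComX (MU).
#' @param n_points Number of sampling points over the cultivation.
#' @param n_reps Number of replicate experiments (>= 1).
#' @param seed Integer seed; results are reproducible for identical seeds.
#' @param bounds Bounds used for refitting.
#' @return A tibble with columns `rep`, `parameter`, `true`, `estimate`,
#'   `rel_error`; the median absolute relative error per parameter is in
#'   attribute `summary`.
#' @export
recovery_experiment <- function(true_params, noise_sd = 5, n_points = 25,
                                n_reps = 20, seed = 1,
                                bounds = comx_bounds()) {
  stopifnot(n_reps >= 1)
  t_end <- 48
  cfg <- synth_config(
    t_end = t_end, sample_every = t_end / (n_points - 1),
    comx_params = true_params, noise_sd_comx = noise_sd,
    n_replicates = 1L, seed = seed
  )
  free <- bounds$parameter[!bounds$fixed]
  truth_vec <- unlist(true_params[free])
  rows <- list()
  for (r in seq_len(n_reps)) {
    cfg_r <- cfg
    cfg_r$seed <- seed + r - 1L
    gen <- generate_cultivation(cfg_r)
    fit <- fit_comx_params(gen$series, gen$truth$biomass_curve,
                           bounds = bounds, ea0 = gen$truth$ea0,
                           seed = seed)
    est <- unlist(fit$params[free])
    rows[[r]] <- tibble::tibble(
      rep = r, parameter = free, true = truth_vec, estimate = est,
      rel_error = (est - truth_vec) / truth_vec
    )
  }
  out <- do.call(rbind, rows)
  med <- vapply(split(abs(out$rel_error), out$parameter), stats::median,
                numeric(1))
  attr(out, "summary") <- med
  out
}
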