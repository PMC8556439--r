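# Batch-process performance calculus: yields, growth rates, specific
# productivity with the ">= 90% of maximum" reference-point rule, and the
# specific-productivity-versus-ComX correlation curve.

.one_rep <- function(series) {
  df <- tibble::as_tibble(series)
  if ("replicate" %in% names(df) && length(unique(df$replicate)) > 1L) {
    stop("process metrics operate on a single replicate", call. = FALSE)
  }
  df
}

.value_at <- function(df, col, t) {
  i <- which(df$time_h == t)
  if (!length(i) || !col %in% names(df) || is.na(df[[col]][i[1L]])) {
    stop("no sampled value of '", col, "' at t = ", t, " h", call. = FALSE)
  }
  df[[col]][i[1L]]
}

#' Earliest sampled time reaching a fraction of the maximum
#'
#' Process parameters are referenced to the first sampled time point at
#' which an observable reaches at least `frac` of its maximum (the
#' ">= 90% rule"); no interpolation is used.
#'
#' @param time Sampled times (h).
#' @param value Observable at those times.
#' @param frac Fraction of the maximum, `0 < frac <= 1` (default 0.9).
#' @return The earliest time (h) with `value >= frac * max(value)`.
#' @export
#' @examples
#' t_at_fraction(c(0, 10, 20), c(0, 4.6, 5))  # 10
t_at_fraction <- function(time, value, frac = 0.9) {
  stopifnot(length(time) == length(value), frac > 0, frac <= 1)
  ok <- is.finite(time) & is.finite(value)
  time <- time[ok]; value <- value[ok]
  if (!length(time)) stop("empty series", call. = FALSE)
  time[which(value >= frac * max(value))[1L]]
}

#' Biomass yield on substrate
#'
#' `Y_X/S = (X(t_ref) - X(t0)) / (S(t0) - S(t_ref))` in g/g, evaluated at
#' sampled time points (by convention `t_ref` is the biomass >= 90% point).
#'
#' @param series Single-replicate [cultivation_series()] with `cdw_g_L` and
#'   `glucose_g_L`.
#' @param t_ref Reference time (h), a sampled time point.
#' @return Yield in g/g.
#' @export
yield_biomass_substrate <- function(series, t_ref) {
  df <- .one_rep(series)
  t0 <- min(df$time_h)
  dx <- .value_at(df, "cdw_g_L", t_ref) - .value_at(df, "cdw_g_L", t0)
  ds <- .value_at(df, "glucose_g_L", t0) - .value_at(df, "glucose_g_L", t_ref)
  if (ds <= 0) stop("no substrate consumed up to t_ref; yield undefined",
                    call. = FALSE)
  dx / ds
}

#' Product (surfactin) yield on substrate
#'
#' `Y_P/S = dm_P / dm_S` in g/g with surfactin converted from mg/L to g/L;
#' by convention `t_ref` is the product >= 90% point.
#'
#' @inheritParams yield_biomass_substrate
#' @return Yield in g/g.
#' @export
yield_product_substrate <- function(series, t_ref) {
  df <- .one_rep(series)
  t0 <- min(df$time_h)
  dp <- (.value_at(df, "surfactin_mg_L", t_ref) -
           .value_at(df, "surfactin_mg_L", t0)) / 1000
  ds <- .value_at(df, "glucose_g_L", t0) - .value_at(df, "glucose_g_L", t_ref)
  if (ds <= 0) stop("no substrate consumed up to t_ref; yield undefined",
                    call. = FALSE)
  dp / ds
}

#' Product yield on biomass
#'
#' `Y_P/X = dm_P / ((m_X1 + m_X2) / 2)` in g/g, with `m_X1 = X(t0)` and
#' `m_X2 = X(t_x)`; product change taken up to `t_p` (product >= 90% point),
#' biomass reference at `t_x` (biomass >= 90% point).
#'
#' @param series Single-replicate series with `cdw_g_L` and `surfactin_mg_L`.
#' @param t_p Product reference time (h).
#' @param t_x Biomass reference time (h).
#' @return Yield in g/g.
#' @export
yield_product_biomass <- function(series, t_p, t_x) {
  df <- .one_rep(series)
  t0 <- min(df$time_h)
  dp <- (.value_at(df, "surfactin_mg_L", t_p) -
           .value_at(df, "surfactin_mg_L", t0)) / 1000
  xbar <- (.value_at(df, "cdw_g_L", t0) + .value_at(df, "cdw_g_L", t_x)) / 2
  if (xbar <= 0) stop("mean biomass is zero", call. = FALSE)
  dp / xbar
}

#' Specific growth rate between two biomass measurements
#'
#' `mu = ln(x2 / x1) / (t2 - t1)`.
#'
#' @param x1,x2 Biomass (g/L, > 0).
#' @param t1,t2 Times (h), `t2 > t1`.
#' @return Growth rate in 1/h.
#' @export
growth_rate <- function(x1, x2, t1, t2) {
  if (any(x1 <= 0) || any(x2 <= 0)) stop("biomass must be > 0", call. = FALSE)
  if (any(t2 <= t1)) stop("`t2` must exceed `t1`", call. = FALSE)
  log(x2 / x1) / (t2 - t1)
}

#' Maximum specific growth rate over a sampled series
#'
#' Maximum of the pairwise growth rates between consecutive sampled points
#' with positive biomass.
#'
#' @param series Single-replicate series with `cdw_g_L`.
#' @return `mu_max` in 1/h.
#' @export
mu_max <- function(series) {
  df <- .one_rep(series)
  ok <- is.finite(df$cdw_g_L) & df$cdw_g_L > 0
  x <- df$cdw_g_L[ok]; tt <- df$time_h[ok]
  if (length(x) < 2L) stop("need at least 2 positive biomass points",
                           call. = FALSE)
  max(growth_rate(x[-length(x)], x[-1L], tt[-length(tt)], tt[-1L]))
}

#' Specific productivity over an interval
#'
#' `q = dm_P / (((m_X1 + m_X2) / 2) * dt)` in g/(g*h).
#'
#' @param dm_p Product formed (g/L).
#' @param x1,x2 Biomass at the interval ends (g/L).
#' @param dt Interval length (h, > 0).
#' @return Specific productivity in g/(g*h).
#' @export
specific_productivity <- function(dm_p, x1, x2, dt) {
  if (any(dt <= 0)) stop("`dt` must be > 0", call. = FALSE)
  xbar <- (x1 + x2) / 2
  if (any(xbar <= 0)) stop("mean biomass must be > 0", call. = FALSE)
  dm_p / (xbar * dt)
}

#' Overall specific productivity of a batch
#'
#' Applies the interval formula with `t0` as first time point, the product
#' change up to the product >= 90% point, the biomass mean of `X(t0)` and
#' `X` at the biomass >= 90% point, and `dt` the span from `t0` to the
#' product reference point.
#'
#' @param series Single-replicate series with `cdw_g_L` and `surfactin_mg_L`.
#' @return `q_overall` in g/(g*h).
#' @export
q_overall <- function(series) {
  df <- .one_rep(series)
  t0 <- min(df$time_h)
  okp <- is.finite(df$surfactin_mg_L)
  okx <- is.finite(df$cdw_g_L)
  t_p <- t_at_fraction(df$time_h[okp], df$surfactin_mg_L[okp], 0.9)
  t_x <- t_at_fraction(df$time_h[okx], df$cdw_g_L[okx], 0.9)
  dp <- (.value_at(df, "surfactin_mg_L", t_p) -
           .value_at(df, "surfactin_mg_L", t0)) / 1000
  specific_productivity(dp, .value_at(df, "cdw_g_L", t0),
                        .value_at(df, "cdw_g_L", t_x), t_p - t0)
}

#' Summary process metrics for each replicate
#'
#' Computes the Table-1-style panel per replicate: maxima, reference times
#' by the >= 90% rule, yields, `mu_max` and `q_overall`. Metrics whose
#' required columns are missing come back as `NA`.
#'
#' @param series A [cultivation_series()] (any number of replicates).
#' @return A tibble with one row per replicate.
#' @export
process_metrics <- function(series) {
  df <- tibble::as_tibble(series)
  if (!"replicate" %in% names(df)) df$replicate <- "R1"
  res <- lapply(split(df, df$replicate), function(d) {
    d <- d[order(d$time_h), ]
    g <- function(expr) tryCatch(expr, error = function(e) NA_real_)
    okx <- is.finite(d$cdw_g_L)
    okp <- "surfactin_mg_L" %in% names(d) && any(is.finite(d$surfactin_mg_L))
    t_x90 <- g(t_at_fraction(d$time_h[okx], d$cdw_g_L[okx], 0.9))
    t_p90 <- if (okp) {
      okpv <- is.finite(d$surfactin_mg_L)
      g(t_at_fraction(d$time_h[okpv], d$surfactin_mg_L[okpv], 0.9))
    } else NA_real_
    comx <- if ("comx_MU" %in% names(d)) d$comx_MU else NA_real_
    tibble::tibble(
      replicate = d$replicate[1L],
      x_max = g(max(d$cdw_g_L, na.rm = TRUE)),
      p_max = if (okp) g(max(d$surfactin_mg_L, na.rm = TRUE)) else NA_real_,
      comx_max = if (all(is.na(comx))) NA_real_ else max(comx, na.rm = TRUE),
      comx_t_end = if (all(is.na(comx))) NA_real_ else
        comx[which.max(d$time_h)],
      t_x90 = t_x90, t_p90 = t_p90,
      y_xs = g(yield_biomass_substrate(d, t_x90)),
      y_ps = if (okp) g(yield_product_substrate(d, t_p90)) else NA_real_,
      y_px = if (okp) g(yield_product_biomass(d, t_p90, t_x90)) else NA_real_,
      mu_max = g(mu_max(d)),
      q_overall = if (okp) g(q_overall(d)) else NA_real_
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Instantaneous specific productivity versus ComX activity
#'
#' From fitted smooth curves, computes the instantaneous specific surfactin
#' productivity `q(t) = P'(t) / X(t)` (the short-interval limit of the
#' interval formula) using analytic derivatives, pairs it with the fitted
#' ComX activity, and truncates the grid at the ComX maximum, the domain on
#' which the productivity--pheromone correlation is established.
#'
#' @param biomass_fit Fitted biomass curve (g/L) with [eval_fit()] support.
#' @param surfactin_fit Fitted surfactin curve with [eval_fit()] support.
#' @param comx_fit Fitted ComX activity curve (MU) with [eval_fit()] support.
#' @param t_grid Evaluation grid (h), strictly increasing.
#' @param surfactin_units Units of the surfactin fit, `"mg/L"` (default,
#'   converted to g/L) or `"g/L"`.
#' @return A tibble of class `q_comx_curve` with columns `time_h`,
#'   `comx_MU`, `q_surfactin` (g/(g*h)); attributes `q_max`,
#'   `t_at_q_max`, `comx_at_q_max` and `truncated_at_comx_max`.
#' @export
q_vs_comx <- function(biomass_fit, surfactin_fit, comx_fit, t_grid,
                      surfactin_units = c("mg/L", "g/L")) {
  surfactin_units <- match.arg(surfactin_units)
  stopifnot(!is.unsorted(t_grid, strictly = TRUE))
  x <- eval_fit(biomass_fit, t_grid)
  p <- eval_fit(surfactin_fit, t_grid)
  cx <- eval_fit(comx_fit, t_grid)
  if (any(x$value <= 0)) {
    stop("biomass fit non-positive on the grid", call. = FALSE)
  }
  scale <- if (surfactin_units == "mg/L") 1e-3 else 1
  q <- scale * p$derivative / x$value
  i_max <- which.max(cx$value)
  keep <- seq_len(i_max)
  out <- tibble::tibble(time_h = t_grid[keep], comx_MU = cx$value[keep],
                        q_surfactin = q[keep])
  i_q <- which.max(out$q_surfactin)
  structure(out,
            class = c("q_comx_curve", class(out)),
            q_max = out$q_surfactin[i_q],
            t_at_q_max = out$time_h[i_q],
            comx_at_q_max = out$comx_MU[i_q],
            truncated_at_comx_max = i_max < length(t_grid))
}
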