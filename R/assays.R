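#' Raw Miller-assay measurement record
#'
#' Holds the absorbances and assay settings needed to compute beta-
#' galactosidase activity in Miller units. Following the Miller convention,
#' `t_reaction` is the colorimetric reaction time in minutes (not the
#' bioassay pre-incubation) and `v_sample` the assayed volume in mL.
#'
#' @param od420 Absorbance at 420 nm.
#' @param od550 Absorbance at 550 nm (cell-debris correction).
#' @param od600 Culture density at 600 nm (> 0).
#' @param t_reaction Reaction time in minutes (> 0).
#' @param v_sample Sample volume in mL (> 0).
#' @return An object of class `miller_record`.
#' @export
miller_record <- function(od420, od550, od600, t_reaction, v_sample) {
  if (any(t_reaction <= 0)) stop("`t_reaction` must be > 0", call. = FALSE)
  if (any(v_sample <= 0)) stop("`v_sample` must be > 0", call. = FALSE)
  if (any(od600 <= 0)) stop("`od600` must be > 0", call. = FALSE)
  structure(list(od420 = od420, od550 = od550, od600 = od600,
                 t_reaction = t_reaction, v_sample = v_sample),
            class = "miller_record")
}

#' Miller units from raw absorbances
#'
#' `MU = 1000 * (OD420 - 1.75 * OD550) / (t * v * OD600)`. The result may be
#' negative for blank-level noise and is deliberately not clipped.
#'
#' @param rec A [miller_record()], or the OD420 value when the remaining
#'   components are given individually.
#' @param od550,od600,t_reaction,v_sample Individual components (ignored
#'   when `rec` is a `miller_record`). All vectorized.
#' @return ComX activity in Miller units.
#' @export
#' @examples
#' miller_units(miller_record(0.9, 0.2, 0.5, 30, 0.1))  # 366.67 MU
miller_units <- function(rec, od550 = NULL, od600 = NULL,
                         t_reaction = NULL, v_sample = NULL) {
  if (!inherits(rec, "miller_record")) {
    rec <- miller_record(rec, od550, od600, t_reaction, v_sample)
  }
  1000 * (rec$od420 - 1.75 * rec$od550) /
    (rec$t_reaction * rec$v_sample * rec$od600)
}

#' Blank statistics with z-score screening
#'
#' Computes mean and sample SD of bioassay blanks after a single-pass
#' exclusion of values whose absolute z-score (relative to the mean and SD
#' of the full set) meets the threshold. Normality of the retained blanks is
#' reported via a Shapiro-Wilk p-value but never enforced; a p-value below
#' 0.05 triggers a warning only.
#'
#' @param blanks Blank measurements in MU (>= 3 values).
#' @param z_threshold Exclusion threshold on |z| (default 2.0).
#' @return An object of class `blank_statistics`: list with `mean_blank`,
#'   `sd_blank`, `n_used`, `n_excluded`, `normality_p`, `z_threshold`.
#' @export
blank_statistics <- function(blanks, z_threshold = 2.0) {
  blanks <- blanks[is.finite(blanks)]
  n <- length(blanks)
  if (n < 3L) stop("need at least 3 blank values", call. = FALSE)
  m0 <- mean(blanks)
  s0 <- stats::sd(blanks)
  if (s0 > 0) {
    keep <- abs((blanks - m0) / s0) < z_threshold
  } else {
    keep <- rep(TRUE, n)
  }
  used <- blanks[keep]
  p <- NA_real_
  if (length(unique(used)) > 1L && length(used) >= 3L && length(used) <= 5000L) {
    p <- tryCatch(stats::shapiro.test(used)$p.value, error = function(e) NA_real_)
  }
  if (!is.na(p) && p < 0.05) {
    warning("retained blanks fail Shapiro-Wilk normality (p = ",
            signif(p, 3), ")")
  }
  structure(
    list(mean_blank = mean(used),
         sd_blank = if (length(used) > 1L) stats::sd(used) else 0,
         n_used = length(used), n_excluded = n - length(used),
         normality_p = p, z_threshold = z_threshold),
    class = "blank_statistics"
  )
}

#' @export
print.blank_statistics <- function(x, ...) {
  cat(sprintf(
    "<blank_statistics> mean %.4g MU, SD %.4g MU (n = %d used, %d excluded; Shapiro-Wilk p = %.3g)\n",
    x$mean_blank, x$sd_blank, x$n_used, x$n_excluded, x$normality_p))
  invisible(x)
}

#' Bioassay detection and quantification limits
#'
#' `LOD = mean_blank + 3 * sd_blank`; `LOQ = mean_blank + 10 * sd_blank`, so
#' `LOQ - LOD = 7 * sd_blank` exactly.
#'
#' @param stats A [blank_statistics()] object, or the blank mean (MU) when
#'   `sd_blank` is given separately.
#' @param sd_blank Blank SD (MU), ignored when `stats` is a
#'   `blank_statistics`.
#' @return An object of class `detection_limits`: list with `lod`, `loq`
#'   (MU) and the screening `z_threshold`.
#' @export
#' @examples
#' detection_limits(15.84, 2.686)   # LOD 23.9, LOQ 42.7 MU
detection_limits <- function(stats, sd_blank = NULL) {
  if (inherits(stats, "blank_statistics")) {
    m <- stats$mean_blank; s <- stats$sd_blank; z <- stats$z_threshold
  } else {
    m <- stats; s <- sd_blank; z <- 2.0
    if (is.null(s)) stop("provide `sd_blank`", call. = FALSE)
  }
  if (s < 0) stop("`sd_blank` must be >= 0", call. = FALSE)
  structure(list(lod = m + 3 * s, loq = m + 10 * s, z_threshold = z),
            class = "detection_limits")
}

#' @export
print.detection_limits <- function(x, ...) {
  cat(sprintf("<detection_limits> LOD %.4g MU, LOQ %.4g MU\n", x$lod, x$loq))
  invisible(x)
}

#' Volumetric endopeptidase activity from the azocasein assay
#'
#' Absorbance difference between sample and blank at 450 nm per hour and mL
#' of cell-free supernatant, scaled by the sample dilution.
#'
#' @param a450_sample,a450_blank Absorbances at 450 nm.
#' @param dilution Fold dilution of the supernatant (>= 1).
#' @param t_incubation Incubation time in hours (> 0; the protocol uses 1 h).
#' @param v_supernatant Supernatant volume in mL (> 0; the protocol uses
#'   0.1 mL).
#' @return Activity in dA/(h*mL).
#' @export
endopeptidase_activity <- function(a450_sample, a450_blank, dilution = 1,
                                   t_incubation = 1, v_supernatant = 0.1) {
  if (any(t_incubation <= 0)) stop("`t_incubation` must be > 0", call. = FALSE)
  if (any(v_supernatant <= 0)) stop("`v_supernatant` must be > 0", call. = FALSE)
  if (any(dilution < 1)) stop("`dilution` must be >= 1", call. = FALSE)
  (a450_sample - a450_blank) * dilution / (t_incubation * v_supernatant)
}

#' ComX degradation rate from an incubation series
#'
#' The rate of activity loss in MU/h over a cell-free supernatant incubation.
#' By default the negated slope of the ordinary least-squares line of
#' activity versus time; `method = "endpoint"` uses the difference quotient
#' of the first and last points instead. Positive values mean loss.
#'
#' @param time Sampling times (h), strictly increasing, >= 2 points.
#' @param comx ComX activity (MU) at those times.
#' @param method `"regression"` (default) or `"endpoint"`.
#' @return Degradation rate in MU/h.
#' @export
degradation_rate <- function(time, comx, method = c("regression", "endpoint")) {
  method <- match.arg(method)
  ok <- is.finite(time) & is.finite(comx)
  time <- time[ok]; comx <- comx[ok]
  if (length(time) < 2L) stop("need at least 2 points", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  if (method == "endpoint") {
    n <- length(time)
    return(-(comx[n] - comx[1L]) / (time[n] - time[1L]))
  }
  -unname(stats::coef(stats::lm(comx ~ time))[2L])
}

#' Percent activity loss between two measurements
#'
#' @param a_start Initial activity (MU, > 0).
#' @param a_end Final activity (MU).
#' @return Loss in percent: `100 * (1 - a_end / a_start)`.
#' @export
#' @examples
#' percent_activity_loss(268.6, 251.1)  # 6.5 percent
percent_activity_loss <- function(a_start, a_end) {
  if (any(a_start <= 0)) stop("`a_start` must be > 0", call. = FALSE)
  100 * (1 - a_end / a_start)
}
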