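#' Conversion settings for optical density to cell dry weight
#'
#' Bundles the OD600-to-CDW correlation factor used throughout the package.
#' The default factor of 3.2 (relative SD about 10%) converts optical density
#' to cell dry weight as `cdw = od600 / od_cdw_factor`, so that an OD600 of
#' about 17 corresponds to the 5.4 g/L biomass maximum of a 40 g/L glucose
#' batch and the inoculation OD600 of 0.1 to roughly 0.031 g/L.
#'
#' @param od_cdw_factor Positive dimensionless correlation factor (default 3.2).
#' @param od_cdw_factor_sd Standard deviation of the factor (default 0.3),
#'   used to derive the tolerance when checking stored `od600`/`cdw_g_L`
#'   column consistency.
#' @return An object of class `conversion_config`.
#' @export
#' @examples
#' conversion_config()
conversion_config <- function(od_cdw_factor = 3.2, od_cdw_factor_sd = 0.3) {
  if (!is.numeric(od_cdw_factor) || length(od_cdw_factor) != 1L ||
      !is.finite(od_cdw_factor) || od_cdw_factor <= 0) {
    stop("`od_cdw_factor` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(od_cdw_factor_sd) || length(od_cdw_factor_sd) != 1L ||
      od_cdw_factor_sd < 0) {
    stop("`od_cdw_factor_sd` must be a single non-negative number", call. = FALSE)
  }
  structure(
    list(od_cdw_factor = od_cdw_factor, od_cdw_factor_sd = od_cdw_factor_sd),
    class = "conversion_config"
  )
}

#' Convert optical density to cell dry weight
#'
#' @param od600 Optical density at 600 nm (non-negative, vectorized).
#' @param factor Positive correlation factor; default from
#'   [conversion_config()].
#' @return Cell dry weight in g/L.
#' @export
#' @examples
#' cdw_from_od(17.28)          # 5.4 g/L
#' cdw_from_od(0.1)            # inoculation density, 0.03125 g/L
cdw_from_od <- function(od600, factor = conversion_config()$od_cdw_factor) {
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0) {
    stop("`factor` must be a single positive number", call. = FALSE)
  }
  if (any(od600 < 0, na.rm = TRUE)) {
    stop("`od600` must be non-negative", call. = FALSE)
  }
  od600 / factor
}

# canonical column order for cultivation CSV files
.canonical_cols <- c(
  "time_h", "replicate", "od600", "cdw_g_L", "glucose_g_L",
  "ammonium_mg_L", "surfactin_mg_L", "comx_MU", "ea_total"
)
.observable_cols <- setdiff(.canonical_cols, c("time_h", "replicate"))
.nonneg_cols <- c("od600", "cdw_g_L", "glucose_g_L", "ammonium_mg_L",
                  "surfactin_mg_L", "ea_total")

#' Construct and validate a cultivation time series
#'
#' A `cultivation_series` is a tibble with canonical columns `time_h`,
#' `replicate` and any subset of the observables `od600`, `cdw_g_L`,
#' `glucose_g_L`, `ammonium_mg_L`, `surfactin_mg_L`, `comx_MU` (ComX activity
#' in Miller units; may be negative, blank noise is not clipped) and
#' `ea_total` (endopeptidase activity, dA/(h*mL)). Extra columns are kept
#' untouched. If `od600` is present but `cdw_g_L` is not, cell dry weight is
#' derived with the conversion factor; if both are present their consistency
#' is checked within a tolerance of three relative SDs of the factor.
#'
#' @param data A data frame with at least `time_h` and one observable column.
#'   Column names are matched case-insensitively.
#' @param conversion A [conversion_config()].
#' @param validate Run invariant checks (default `TRUE`).
#' @return A tibble of class `cultivation_series`.
#' @export
cultivation_series <- function(data, conversion = conversion_config(),
                               validate = TRUE) {
  data <- tibble::as_tibble(data)
  # case-insensitive canonical name matching
  lower <- tolower(names(data))
  for (cc in .canonical_cols) {
    hit <- which(lower == tolower(cc))
    if (length(hit) > 1L) {
      stop("multiple columns match canonical name '", cc, "'", call. = FALSE)
    }
    if (length(hit) == 1L) names(data)[hit] <- cc
  }
  if (!"time_h" %in% names(data)) {
    stop("column 'time_h' is required", call. = FALSE)
  }
  if (!"replicate" %in% names(data)) data$replicate <- "R1"
  data$replicate <- as.character(data$replicate)
  if (!"cdw_g_L" %in% names(data) && "od600" %in% names(data)) {
    data$cdw_g_L <- cdw_from_od(data$od600, conversion$od_cdw_factor)
  }
  present <- intersect(.canonical_cols, names(data))
  extra <- setdiff(names(data), .canonical_cols)
  data <- data[, c(present, extra)]
  out <- structure(data,
    class = c("cultivation_series", class(tibble::tibble())),
    conversion = conversion
  )
  if (validate) validate_cultivation_series(out)
  out
}

#' @rdname cultivation_series
#' @param x A `cultivation_series` to validate.
#' @export
validate_cultivation_series <- function(x) {
  conversion <- attr(x, "conversion")
  if (!any(.observable_cols %in% names(x))) {
    stop("at least one observable column must be present", call. = FALSE)
  }
  if (any(!is.finite(x$time_h) | x$time_h < 0)) {
    stop("`time_h` must be finite and non-negative", call. = FALSE)
  }
  for (rep_id in unique(x$replicate)) {
    tt <- x$time_h[x$replicate == rep_id]
    if (anyDuplicated(tt)) {
      stop("duplicate time points in replicate '", rep_id, "'", call. = FALSE)
    }
    if (is.unsorted(tt, strictly = TRUE)) {
      stop("time must be strictly increasing within replicate '", rep_id, "'",
           call. = FALSE)
    }
  }
  for (cc in intersect(.nonneg_cols, names(x))) {
    bad <- which(!is.na(x[[cc]]) & x[[cc]] < 0)
    if (length(bad)) {
      stop("negative value in column '", cc, "' at row ", bad[1L], call. = FALSE)
    }
  }
  if (all(c("od600", "cdw_g_L") %in% names(x))) {
    both <- !is.na(x$od600) & !is.na(x$cdw_g_L)
    if (any(both)) {
      expected <- x$od600[both] / conversion$od_cdw_factor
      reltol <- 3 * conversion$od_cdw_factor_sd / conversion$od_cdw_factor
      off <- abs(x$cdw_g_L[both] - expected) >
        reltol * pmax(expected, .Machine$double.eps)
      if (any(off)) {
        stop("`cdw_g_L` inconsistent with `od600` / ",
             conversion$od_cdw_factor, " beyond tolerance", call. = FALSE)
      }
    }
  }
  invisible(x)
}

#' Read a cultivation time series from CSV
#'
#' Expects a comma-separated file with a header row; canonical column names
#' (`time_h`, `replicate`, `od600`, `cdw_g_L`, `glucose_g_L`,
#' `ammonium_mg_L`, `surfactin_mg_L`, `comx_MU`, `ea_total`) are matched
#' case-insensitively and unknown columns are preserved. Empty cells become
#' `NA`, never zero.
#'
#' @param path Path to a CSV file.
#' @param conversion A [conversion_config()].
#' @return A [cultivation_series()].
#' @export
read_timeseries <- function(path, conversion = conversion_config()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # base parser: strtod gives correctly-rounded doubles, so full-precision
  # text written by write_timeseries reads back bit-for-bit
  raw <- utils::read.csv(path, na.strings = c("", "NA"), check.names = FALSE)
  cultivation_series(tibble::as_tibble(raw), conversion = conversion)
}

#' Write a cultivation time series to CSV
#'
#' Writes canonical column names with full double precision (values survive a
#' read/write round trip bit-for-bit); missing values are written as empty
#' cells.
#'
#' @param series A [cultivation_series()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_timeseries <- function(series, path) {
  stopifnot(inherits(series, "cultivation_series"))
  out <- tibble::as_tibble(series)
  for (cc in names(out)) {
    if (is.double(out[[cc]])) {
      # 17 significant digits: decimal text parses back to the same double
      out[[cc]] <- ifelse(is.na(out[[cc]]), NA_character_,
                          sprintf("%.17g", out[[cc]]))
    }
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @export
print.cultivation_series <- function(x, ...) {
  obs <- intersect(.observable_cols, names(x))
  cat("<cultivation_series> ", nrow(x), " samples, ",
      length(unique(x$replicate)), " replicate(s), observables: ",
      paste(obs, collapse = ", "), "\n", sep = "")
  NextMethod()
}
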