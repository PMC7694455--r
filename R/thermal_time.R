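#' Daily thermal units above a base temperature
#'
#' Converts a day's minimum and maximum temperature into growing degree days:
#' the daily mean temperature minus the base temperature, clamped at zero when
#' the mean is at or below the base. The default base of 1 degree C is the
#' value commonly used for winter cereals and the grass weeds that accompany
#' them.
#'
#' @param tmin,tmax Daily minimum and maximum air or soil temperature
#'   (degrees C). Vectorised; recycled to a common length.
#' @param base Base temperature (degrees C) below which no thermal time
#'   accrues. Default 1.
#' @return Numeric vector of daily thermal units (degree C day), `>= 0`.
#' @examples
#' daily_thermal_units(tmin = 4, tmax = 10)        # 6
#' daily_thermal_units(tmin = -2, tmax = 0)        # 0 (mean below base)
#' @export
daily_thermal_units <- function(tmin, tmax, base = 1) {
  if (length(tmin) != length(tmax)) {
    n <- max(length(tmin), length(tmax))
    tmin <- rep_len(tmin, n)
    tmax <- rep_len(tmax, n)
  }
  bad <- !is.na(tmin) & !is.na(tmax) & tmin > tmax
  if (any(bad)) {
    pk_stop(
      sprintf("invalid weather record(s): tmin > tmax at position(s) %s",
              paste(utils::head(which(bad), 5L), collapse = ", ")),
      "invalid_record"
    )
  }
  pmax(0, (tmax + tmin) / 2 - base)
}

#' Accumulate cumulative thermal time from a sowing date
#'
#' Builds the cumulative thermal-time series (growing degree days above
#' `base`) that serves as the physiological time axis for emergence, growth
#' and phenology analyses. Accumulation starts on the origin (sowing) day
#' itself, so the value for the day before sowing is 0.
#'
#' The weather series must come from a single sensor source (`"air"` or
#' `"soil"`) and be contiguous over `[origin, end]`. Single-day gaps may be
#' filled by linear interpolation of `tmin`/`tmax` when
#' `allow_gap_fill = TRUE`; by default any gap is an error.
#'
#' @param weather Data frame with columns `date` (`Date` or ISO-8601
#'   character), `tmin_c`, `tmax_c` and optionally `source`
#'   (all `"air"` or all `"soil"`).
#' @param origin Sowing date (`Date` or ISO-8601 character): the reference
#'   point of the series.
#' @param base Base temperature (degrees C), default 1.
#' @param allow_gap_fill If `TRUE`, single missing days are filled by linear
#'   interpolation of their neighbours' `tmin`/`tmax`; longer gaps still
#'   error. Default `FALSE`.
#' @return An object of class `thermal_time_series`: a data frame with
#'   columns `date` and `cum_tt_c`, plus attributes `origin`, `base` and
#'   `source`.
#' @seealso [tt_at()] to query the series at arbitrary covered dates,
#'   [daily_thermal_units()] for the per-day conversion.
#' @export
accumulate_thermal_time <- function(weather, origin, base = 1,
                                    allow_gap_fill = FALSE) {
  check_columns(weather, c("date", "tmin_c", "tmax_c"), "weather data")
  weather$date <- as.Date(weather$date)
  origin <- as.Date(origin)

  src <- "unknown"
  if ("source" %in% names(weather)) {
    srcs <- unique(as.character(weather$source))
    if (length(srcs) > 1L) {
      pk_stop(
        sprintf("weather series mixes sources: %s", paste(srcs, collapse = ", ")),
        "source_mix"
      )
    }
    src <- srcs
  }

  weather <- weather[order(weather$date), , drop = FALSE]
  if (anyDuplicated(weather$date)) {
    pk_stop("duplicate dates in weather series", "invalid_record")
  }
  if (origin < min(weather$date) || origin > max(weather$date)) {
    pk_stop("origin date is not covered by the weather series", "coverage")
  }

  steps <- as.integer(diff(weather$date))
  if (any(steps > 1L)) {
    if (!allow_gap_fill || any(steps > 2L)) {
      first_gap <- weather$date[which(steps > 1L)[1L]] + 1L
      pk_stop(
        sprintf("weather series has a gap starting %s (set allow_gap_fill = TRUE to interpolate single days)",
                format(first_gap)),
        "contiguity"
      )
    }
    full <- data.frame(date = seq(min(weather$date), max(weather$date), by = "day"))
    filled <- merge(full, weather, by = "date", all.x = TRUE)
    filled$tmin_c <- stats::approx(weather$date, weather$tmin_c, xout = filled$date)$y
    filled$tmax_c <- stats::approx(weather$date, weather$tmax_c, xout = filled$date)$y
    weather <- filled
  }

  keep <- weather$date >= origin
  w <- weather[keep, , drop = FALSE]
  units <- daily_thermal_units(w$tmin_c, w$tmax_c, base = base)

  out <- data.frame(date = w$date, cum_tt_c = cumsum(units))
  structure(out,
            origin = origin, base = base, source = src,
            class = c("thermal_time_series", "data.frame"))
}

#' Query cumulative thermal time at given dates
#'
#' @param series A `thermal_time_series` from [accumulate_thermal_time()].
#' @param dates Dates (or ISO-8601 character) to query; each must be covered
#'   by the series or precede its origin (returning 0).
#' @return Numeric vector of cumulative degree C days, one per date.
#' @export
tt_at <- function(series, dates) {
  stopifnot(inherits(series, "thermal_time_series"))
  dates <- as.Date(dates)
  origin <- attr(series, "origin")
  out <- numeric(length(dates))
  before <- dates < origin
  covered <- !before & dates <= max(series$date)
  if (any(!before & !covered)) {
    pk_stop("query date beyond the covered weather window", "coverage")
  }
  idx <- match(dates[covered], series$date)
  if (anyNA(idx)) pk_stop("query date not present in the series", "coverage")
  out[covered] <- series$cum_tt_c[idx]
  out
}

#' @export
print.thermal_time_series <- function(x, ...) {
  cat(sprintf("Thermal-time series (%s temperature), origin %s, base %g C\n",
              attr(x, "source"), format(attr(x, "origin")), attr(x, "base")))
  cat(sprintf("  %d days, final cumulative thermal time %.1f C d\n",
              nrow(x), x$cum_tt_c[nrow(x)]))
  invisible(x)
}

#' Read a weather CSV
#'
#' Expects columns `date` (ISO-8601), `tmin_c`, `tmax_c`, `source` (`air` or
#' `soil`). Rows from multiple sources may coexist in one file; use
#' `source` to select one before accumulation.
#'
#' @param path Path to the CSV file.
#' @param source Optional filter, `"air"` or `"soil"`.
#' @return Data frame of weather records.
#' @export
read_weather_csv <- function(path, source = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("date", "tmin_c", "tmax_c", "source"), basename(path))
  df$date <- as.Date(df$date)
  if (!is.null(source)) df <- df[df$source == source, , drop = FALSE]
  df
}
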