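#' Accumulate growing degree days from a daily temperature log
#'
#' Thermal time (growing degree days, GDD) is the running sum of the daily
#' mean temperature's excess over a species-specific base temperature.
#' Days whose mean falls below the base contribute 0 (standard GDD
#' clipping: below the base the plant does not grow or grows very slowly).
#'
#' @param log A data frame with one row per day, containing a day column
#'   (strictly increasing) and a daily mean temperature column (degrees C).
#' @param base_temp Base temperature, degrees C (e.g. maize 10,
#'   Miscanthus 8).
#' @param day Column holding the day index or date. Default `day`.
#' @param temp Column holding the daily mean temperature. Default
#'   `mean_temp`.
#'
#' @return The input as a tibble with an added `gdd` column: cumulative
#'   thermal time (degree-days) through each day. Nonnegative and
#'   nondecreasing.
#' @examples
#' log <- data.frame(day = 1:3, mean_temp = c(12, 9, 15))
#' accumulate_gdd(log, base_temp = 10)  # gdd = 2, 2, 7
#' @export
accumulate_gdd <- function(log, base_temp, day = "day", temp = "mean_temp") {
  if (!is.data.frame(log) || nrow(log) == 0) {
    stop("temperature log must be a non-empty data frame", call. = FALSE)
  }
  if (!all(c(day, temp) %in% names(log))) {
    stop(sprintf("temperature log must contain columns '%s' and '%s'",
                 day, temp), call. = FALSE)
  }
  d <- log[[day]]
  tt <- log[[temp]]
  if (anyNA(tt) || !all(is.finite(tt))) {
    stop("temperatures must be finite", call. = FALSE)
  }
  if (is.unsorted(d, strictly = TRUE)) {
    stop("days must be strictly increasing", call. = FALSE)
  }
  out <- tibble::as_tibble(log)
  out$gdd <- cumsum(pmax(tt - base_temp, 0))
  out
}

#' Convert between thermal time and calendar days at constant temperature
#'
#' Under a constant daily mean temperature, each day accrues
#' `constant_temp - base_temp` degree-days, so thermal time and calendar
#' time are proportional: `days = gdd / (constant_temp - base_temp)`.
#'
#' @param x Value(s) to convert: degree-days when `to = "days"`, days when
#'   `to = "gdd"`.
#' @param constant_temp Constant daily mean temperature, degrees C. Must
#'   exceed `base_temp` (otherwise no thermal time accrues).
#' @param base_temp Base temperature, degrees C.
#' @param to Direction of conversion: `"days"` or `"gdd"`.
#'
#' @return Converted value(s).
#' @examples
#' gdd_days_convert(231, constant_temp = 24, base_temp = 10)  # 16.5 days
#' gdd_days_convert(16.5, 24, 10, to = "gdd")                  # 231 degree-days
#' @export
gdd_days_convert <- function(x, constant_temp, base_temp,
                             to = c("days", "gdd")) {
  to <- match.arg(to)
  stopifnot(is.numeric(x))
  daily <- constant_temp - base_temp
  if (daily <= 0) {
    stop("constant temperature must exceed the base temperature",
         call. = FALSE)
  }
  if (to == "days") x / daily else x * daily
}

#' Attach thermal time to measurements recorded by calendar day
#'
#' Maps each measurement's day onto cumulative thermal time using a daily
#' temperature log: the thermal time of day `d` is the GDD accumulated
#' through `d`. Fractional days are interpolated linearly between
#' neighbouring log days.
#'
#' @param data Measurement data frame with a day column.
#' @param temp_log Daily temperature log (see [accumulate_gdd()]).
#' @param base_temp Base temperature, degrees C.
#' @param day Column in `data` (and `temp_log`) holding the day.
#' @param temp Temperature column in `temp_log`.
#'
#' @return `data` as a tibble with an added `t` column of thermal times
#'   (degree-days).
#' @export
add_thermal_time <- function(data, temp_log, base_temp,
                             day = "day", temp = "mean_temp") {
  stopifnot(is.data.frame(data))
  if (!day %in% names(data)) {
    stop(sprintf("measurement table lacks day column '%s'", day),
         call. = FALSE)
  }
  acc <- accumulate_gdd(temp_log, base_temp, day = day, temp = temp)
  d <- data[[day]]
  if (any(d < min(acc[[day]]) | d > max(acc[[day]]))) {
    stop("measurement days fall outside the temperature log", call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  out$t <- stats::approx(acc[[day]], acc$gdd, xout = d)$y
  out
}
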