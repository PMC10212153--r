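# Solar and lunar geometry: solar noon, the nocturnality statistic, and the
# lunar illuminated fraction. Solar transit times follow the NOAA
# solar-position formulation (equation of time + longitude correction + UTC
# offset), accurate to well under a minute over 1950-2100; the moon uses the
# standard low-precision ecliptic series for the phase angle.

#' Solar context
#'
#' Bundles the coordinates and fixed UTC offset under which solar quantities
#' are evaluated. Fields may be vectors (e.g. per-station longitudes) and are
#' recycled against timestamps.
#'
#' @param latitude,longitude degrees (north / east positive).
#' @param utc_offset_hours signed clock offset from UTC (e.g. `-8` for the
#'   study area's Pacific Standard Time).
#' @return an object of class `solar_ctx`.
#' @export
solar_ctx <- function(latitude, longitude, utc_offset_hours = 0) {
  stopifnot(all(abs(latitude) <= 90), all(abs(longitude) <= 180),
            is.numeric(utc_offset_hours))
  structure(list(latitude = as.numeric(latitude),
                 longitude = as.numeric(longitude),
                 utc_offset_hours = utc_offset_hours[1L]),
            class = "solar_ctx")
}

# equation of time (minutes) and solar declination via the NOAA fractional-
# year expansion; `frac_day` is local-clock fraction used to refine gamma.
noaa_eqtime <- function(doy, ndays, frac_day) {
  g <- 2 * pi / ndays * (doy - 1 + frac_day)
  229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
              0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
}

# local clock hour of solar transit, vectorized over dates/longitudes
solar_noon_hours <- function(dates, longitude, utc_offset_hours) {
  lt <- as.POSIXlt(dates)
  doy <- lt$yday + 1
  yr <- lt$year + 1900
  ndays <- 365 + (yr %% 4 == 0 & (yr %% 100 != 0 | yr %% 400 == 0))
  snoon <- rep_len(12, max(length(dates), length(longitude)))
  for (i in 1:2) {  # one refinement pass: evaluate gamma at the noon itself
    eqt <- noaa_eqtime(doy, ndays, (snoon - 12) / 24)
    snoon <- (720 - 4 * longitude - eqt + 60 * utc_offset_hours) / 60
  }
  snoon
}

#' Local clock time of solar noon
#'
#' Solar noon is the instant the sun crosses the local meridian (its apex).
#' Computed from the equation of time, the longitude correction (4 min per
#' degree) and the UTC offset.
#'
#' @param date `Date` vector (years 1950-2100).
#' @param ctx a [solar_ctx()].
#' @return `POSIXct` clock time(s) of transit on each date.
#' @export
solar_noon <- function(date, ctx) {
  date <- as.Date(date)
  yr <- as.POSIXlt(date)$year + 1900
  if (any(yr < 1950 | yr > 2100)) {
    stop("solar_noon: dates must fall in 1950-2100")
  }
  h <- solar_noon_hours(date, ctx$longitude, ctx$utc_offset_hours)
  as.POSIXct(as.character(date), tz = "UTC") + h * 3600
}

#' Nocturnality of a timestamp
#'
#' The response statistic of the analysis: the circular 24-hour distance, in
#' decimal hours, between an event's timestamp and the solar noon of the same
#' calendar date, `min(|delta|, 24 - |delta|)`. 0 means the event occurred at
#' solar noon, 12 at solar midnight; a value of 1.50 means 1 h 30 min either
#' before or after solar noon.
#'
#' @param timestamp `POSIXct` clock times (see [parse_timestamp()]).
#' @param ctx a [solar_ctx()]; `longitude` may be a vector aligned with
#'   `timestamp` (per-station solar noon).
#' @return numeric vector in `[0, 12]`.
#' @export
nocturnality <- function(timestamp, ctx) {
  timestamp <- parse_timestamp(timestamp)
  noon <- solar_noon_hours(local_date(timestamp), ctx$longitude,
                           ctx$utc_offset_hours)
  delta <- (hour_of_day(timestamp) - noon) %% 24
  pmin(delta, 24 - delta)
}

# Julian date from a UTC instant
julian_date <- function(utc) as.numeric(utc) / 86400 + 2440587.5

#' Lunar illuminated fraction
#'
#' Fraction of the moon's disk illuminated at an instant, from 0 (new moon)
#' to 1 (full moon), computed as `(1 + cos i)/2` with the phase angle `i`
#' obtained from low-precision sun/moon ecliptic-longitude series
#' (accurate to about 0.002 in fraction).
#'
#' @param timestamp `POSIXct` clock times.
#' @param utc_offset_hours offset of the clock times from UTC.
#' @return numeric vector in `[0, 1]`.
#' @export
lunar_fraction <- function(timestamp, utc_offset_hours = 0) {
  timestamp <- parse_timestamp(timestamp)
  t_utc <- timestamp - utc_offset_hours * 3600
  T <- (julian_date(t_utc) - 2451545) / 36525
  deg <- pi / 180
  D  <- (297.8501921 + 445267.1114034 * T - 0.0018819 * T^2) %% 360  # elongation
  M  <- (357.5291092 + 35999.0502909 * T - 0.0001536 * T^2) %% 360   # sun anomaly
  Mp <- (134.9633964 + 477198.8675055 * T + 0.0087414 * T^2) %% 360  # moon anomaly
  i <- 180 - D - 6.289 * sin(Mp * deg) + 2.100 * sin(M * deg) -
    1.274 * sin((2 * D - Mp) * deg) - 0.658 * sin(2 * D * deg) -
    0.214 * sin(2 * Mp * deg) - 0.110 * sin(D * deg)
  pmin(pmax((1 + cos(i * deg)) / 2, 0), 1)
}
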