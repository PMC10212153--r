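# Timestamp handling
#
# All timestamps in the package are local civil clock times under one fixed
# UTC offset for the whole study (no daylight-saving transitions). They are
# stored as POSIXct in the "UTC" timezone so that arithmetic is pure clock
# arithmetic; the study's actual UTC offset is carried separately and used
# only by the solar/lunar computations.

#' Parse timestamps from ISO-8601 strings
#'
#' Accepts `"YYYY-MM-DD HH:MM:SS"` or `"YYYY-MM-DDTHH:MM:SS"` with an optional
#' trailing UTC offset (`Z`, `+HH:MM`, `-HHMM`), which is stripped: the clock
#' time written in the string is taken at face value and the study-wide offset
#' is handled separately. Already-parsed `POSIXct` input is passed through.
#'
#' @param x character vector of timestamps (or `POSIXct`).
#' @return `POSIXct` vector (tz `"UTC"`, used as a DST-free clock).
#' @export
parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  x <- as.character(x)
  y <- sub("[Zz]$", "", x)
  y <- sub("([+-][0-9]{2}:?[0-9]{2})$", "", y)
  y <- sub("T", " ", y, fixed = TRUE)
  ok <- grepl(
    "^\\d{4}-\\d{2}-\\d{2}( \\d{2}:\\d{2}(:\\d{2}(\\.\\d+)?)?)?$", y)
  out <- as.POSIXct(ifelse(ok, y, NA), tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop("unparseable timestamp(s) at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " (first offending value: '", x[bad[1L]], "')")
  }
  out
}

#' Format timestamps as ISO-8601 with a fixed UTC offset
#'
#' @param x `POSIXct` clock times (see [parse_timestamp()]).
#' @param utc_offset_hours signed offset to annotate, e.g. `-8`.
#' @return character vector like `"2019-06-01T14:30:00-08:00"`.
#' @export
format_timestamp <- function(x, utc_offset_hours = 0) {
  stopifnot(inherits(x, "POSIXct"))
  off <- utc_offset_hours
  sgn <- ifelse(off < 0, "-", "+")
  ao <- abs(off)
  hh <- formatC(floor(ao), width = 2, flag = "0")
  mm <- formatC(round((ao - floor(ao)) * 60), width = 2, flag = "0")
  paste0(format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC"), sgn, hh, ":", mm)
}

#' Calendar date of a clock timestamp
#' @param x `POSIXct` clock times.
#' @return `Date` vector.
#' @export
local_date <- function(x) as.Date(x, tz = "UTC")

# decimal hour of day (0-24) of a clock timestamp
hour_of_day <- function(x) {
  lt <- as.POSIXlt(x, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}
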