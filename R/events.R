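# Independence filtering of raw camera-trap records into detection events.
#
# A record starts a new event iff its gap to the immediately preceding record
# of the same station x species group strictly exceeds the threshold (the
# "chain" rule; a gap of exactly 30:00 under a 30-minute threshold does NOT
# break an event, matching "more than 30 minutes"). Wildlife uses a 30-minute
# threshold, humans 1 minute.

#' Collapse raw detection records into independent events
#'
#' @param records data frame with columns `station_id`, `species`,
#'   `timestamp` (`POSIXct` or ISO-8601 strings).
#' @param threshold_minutes independence gap; a new event starts when the gap
#'   to the previous record strictly exceeds this. 30 for wildlife, 1 for
#'   humans.
#' @param group_cols columns defining independent streams
#'   (default station x species).
#' @param anchor `"chain"` (gap measured from the immediately preceding
#'   record; the default and standard camera-trap practice) or
#'   `"event_start"` (gap measured from the first record of the open event).
#' @return data frame of events: group columns, `start_timestamp`,
#'   `n_records`, sorted by group then time.
#' @export
filter_independent_events <- function(records, threshold_minutes = 30,
                                      group_cols = c("station_id", "species"),
                                      anchor = c("chain", "event_start")) {
  anchor <- match.arg(anchor)
  stopifnot(is.data.frame(records), threshold_minutes > 0,
            all(c(group_cols, "timestamp") %in% names(records)))
  if (nrow(records) == 0L) {
    out <- records[, group_cols, drop = FALSE]
    out$start_timestamp <- parse_timestamp(character(0))
    out$n_records <- integer(0)
    return(out)
  }
  ts <- parse_timestamp(records$timestamp)
  key <- do.call(paste, c(lapply(group_cols, function(k) records[[k]]),
                          sep = "\r"))
  o <- order(key, ts)
  key <- key[o]
  ts <- ts[o]
  n <- length(ts)
  new_grp <- c(TRUE, key[-1L] != key[-n])
  thr_sec <- threshold_minutes * 60

  if (anchor == "chain") {
    gap <- c(Inf, as.numeric(ts[-1L]) - as.numeric(ts[-n]))
    new_event <- new_grp | gap > thr_sec
  } else {
    # anchored to the open event's first record: sequential scan
    new_event <- logical(n)
    start <- -Inf
    for (i in seq_len(n)) {
      if (new_grp[i] || as.numeric(ts[i]) - start > thr_sec) {
        new_event[i] <- TRUE
        start <- as.numeric(ts[i])
      }
    }
  }
  eid <- cumsum(new_event)
  starts <- which(new_event)
  out <- records[o, group_cols, drop = FALSE][starts, , drop = FALSE]
  out$start_timestamp <- ts[starts]
  out$n_records <- tabulate(eid)
  rownames(out) <- NULL
  out
}

#' Period key of a timestamp
#'
#' Maps timestamps to calendar-day (`"2019-06-01"`), ISO-8601 week
#' (`"2019-W22"`, Monday-Sunday) or calendar-month (`"2019-06"`) identifiers.
#'
#' @param x `POSIXct` or `Date`.
#' @param scale `"day"`, `"week"` or `"month"`.
#' @return character vector of period identifiers.
#' @export
period_key <- function(x, scale = c("day", "week", "month")) {
  scale <- match.arg(scale)
  if (inherits(x, "POSIXct")) x <- local_date(x)
  switch(scale,
         day = format(x, "%Y-%m-%d"),
         week = format(x, "%G-W%V"),
         month = format(x, "%Y-%m"))
}

#' Count events at a station within a calendar interval
#'
#' @param events output of [filter_independent_events()].
#' @param station_id station to count at.
#' @param interval a `Date` (calendar day) or a period identifier produced by
#'   [period_key()] (`"2019-06-01"`, `"2019-W22"`, `"2019-06"`).
#' @return integer count of events whose `start_timestamp` falls in the
#'   interval at that station.
#' @export
count_detections <- function(events, station_id, interval) {
  stopifnot(all(c("station_id", "start_timestamp") %in% names(events)))
  if (inherits(interval, "Date")) interval <- format(interval, "%Y-%m-%d")
  interval <- as.character(interval)
  scale <- if (grepl("^\\d{4}-W\\d{2}$", interval)) "week"
           else if (grepl("^\\d{4}-\\d{2}$", interval)) "month"
           else if (grepl("^\\d{4}-\\d{2}-\\d{2}$", interval)) "day"
           else stop("unrecognized interval: ", interval)
  sel <- events$station_id == station_id
  sum(period_key(events$start_timestamp[sel], scale) == interval)
}
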