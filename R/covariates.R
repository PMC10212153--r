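# Predictor construction: direct human presence at three temporal scales
# (daily count, weekly and monthly rates per active camera-day),
# infrastructure geometry, environmental attributes, and assembly of the
# per-event model table.

#' Validate an effort log
#'
#' @param effort data frame with columns `station_id`, `date` (`Date` or
#'   string) and logical/0-1 `active`.
#' @return the effort log with `date` coerced to `Date` and `active` logical.
#' @export
as_effort <- function(effort) {
  stopifnot(is.data.frame(effort),
            all(c("station_id", "date", "active") %in% names(effort)))
  effort$date <- as.Date(effort$date)
  effort$active <- as.logical(effort$active)
  effort
}

# active camera-days per station x period; named vector "station\rperiod"
active_days_by_period <- function(effort, scale) {
  act <- effort[effort$active, , drop = FALSE]
  key <- paste(act$station_id, period_key(act$date, scale), sep = "\r")
  c(table(key))
}

# human event counts per station x period
human_counts_by_period <- function(human_events, scale) {
  key <- paste(human_events$station_id,
               period_key(human_events$start_timestamp, scale), sep = "\r")
  c(table(key))
}

#' Direct human-presence measures for wildlife events
#'
#' For each wildlife event: the number of human detection events at the same
#' station on the same calendar day (`daily_count`); and the number of human
#' events at the station during the event's ISO week (calendar month) divided
#' by the station's active camera-days in that week (month):
#' `weekly_rate` / `monthly_rate`, accounting for sampling effort. A rate is
#' `NA` when the station had zero active days in the period (a camera that was
#' off is not evidence of zero human use).
#'
#' @param events wildlife events (needs `station_id`, `start_timestamp`).
#' @param human_events human detection events from
#'   [filter_independent_events()] at the 1-minute threshold.
#' @param effort effort log (see [as_effort()]); must cover every station in
#'   `events`.
#' @return data frame aligned row-by-row with `events`: `daily_count`,
#'   `weekly_rate`, `monthly_rate`.
#' @export
human_presence <- function(events, human_events, effort) {
  effort <- as_effort(effort)
  missing_st <- setdiff(unique(events$station_id), unique(effort$station_id))
  if (length(missing_st)) {
    stop("human_presence: station(s) absent from effort log: ",
         paste(missing_st, collapse = ", "))
  }
  hp_lookup(events, hp_tables(human_events, effort))
}

# precomputed station x period count/effort tables backing human_presence;
# split out so the generator can reuse them across iterations
hp_tables <- function(human_events, effort) {
  list(daily = human_counts_by_period(human_events, "day"),
       counts_week = human_counts_by_period(human_events, "week"),
       counts_month = human_counts_by_period(human_events, "month"),
       adays_week = active_days_by_period(effort, "week"),
       adays_month = active_days_by_period(effort, "month"))
}

hp_lookup <- function(events, tabs) {
  ts <- parse_timestamp(events$start_timestamp)
  dkey <- paste(events$station_id, period_key(ts, "day"), sep = "\r")
  daily <- unname(tabs$daily[dkey])
  daily[is.na(daily)] <- 0L
  rate <- function(counts, adays, scale) {
    key <- paste(events$station_id, period_key(ts, scale), sep = "\r")
    n_h <- unname(counts[key]); n_h[is.na(n_h)] <- 0L
    n_d <- unname(adays[key])   # NA when zero active days in the period
    n_h / n_d
  }
  data.frame(daily_count = as.integer(daily),
             weekly_rate = rate(tabs$counts_week, tabs$adays_week, "week"),
             monthly_rate = rate(tabs$counts_month, tabs$adays_month,
                                 "month"))
}

#' Human-presence measures for a single event
#'
#' Per-event convenience wrapper around [human_presence()].
#'
#' @param event one-row data frame (`station_id`, `start_timestamp`).
#' @inheritParams human_presence
#' @return list with `daily_count`, `weekly_rate`, `monthly_rate`.
#' @export
human_presence_for_event <- function(event, human_events, effort) {
  as.list(human_presence(event[1L, , drop = FALSE], human_events, effort))
}

#' Assemble the per-species model table
#'
#' One row per wildlife detection event: the nocturnality response plus the
#' raw (unscaled) predictors of the analysis — a direct human-presence
#' measure, trail density, road density, distance to the urban-wildland
#' boundary, lunar illuminated fraction at the event timestamp, and crown
#' closure at the station. Rows with any missing covariate (e.g. a rate in a
#' zero-effort week) are dropped with a message.
#'
#' @param species_events events of one species.
#' @param stations station table with `station_id`, `latitude`, `longitude`,
#'   `trail_density`, `road_density`, `dist_boundary`, `crown_closure`.
#' @param human data frame from [human_presence()] aligned with
#'   `species_events` (omitted/`NULL` allowed when `human_scale = "none"`).
#' @param utc_offset_hours study clock offset from UTC.
#' @param human_scale which human measure to carry: `"daily"`, `"weekly"`,
#'   `"monthly"`, `"all"` (all three columns) or `"none"`.
#' @return data frame with attribute `n_dropped`; columns `species`,
#'   `station_id`, `start_timestamp`, `nocturnality`, the human column(s),
#'   `trail_density`, `road_density`, `dist_boundary`, `lunar`,
#'   `crown_closure`.
#' @export
assemble_model_table <- function(species_events, stations, human = NULL,
                                 utc_offset_hours = 0,
                                 human_scale = c("all", "daily", "weekly",
                                                 "monthly", "none")) {
  human_scale <- match.arg(human_scale)
  if (nrow(species_events) == 0L) {
    stop("assemble_model_table: zero events for species '",
         paste(unique(species_events$species), collapse = ","), "'")
  }
  need <- c("station_id", "latitude", "longitude", "trail_density",
            "road_density", "dist_boundary", "crown_closure")
  miss <- setdiff(need, names(stations))
  if (length(miss)) {
    stop("assemble_model_table: station table lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  idx <- match(species_events$station_id, stations$station_id)
  if (anyNA(idx)) {
    stop("assemble_model_table: events at unknown station(s): ",
         paste(unique(species_events$station_id[is.na(idx)]), collapse = ", "))
  }
  ts <- parse_timestamp(species_events$start_timestamp)
  ctx <- solar_ctx(stations$latitude[idx], stations$longitude[idx],
                   utc_offset_hours)
  tab <- data.frame(
    species = species_events$species,
    station_id = species_events$station_id,
    start_timestamp = ts,
    nocturnality = nocturnality(ts, ctx),
    stringsAsFactors = FALSE)
  if (human_scale != "none") {
    if (is.null(human)) {
      stop("assemble_model_table: human presence table required for ",
           "human_scale = '", human_scale, "'")
    }
    stopifnot(nrow(human) == nrow(species_events))
    cols <- switch(human_scale,
                   daily = "daily_count", weekly = "weekly_rate",
                   monthly = "monthly_rate",
                   all = c("daily_count", "weekly_rate", "monthly_rate"))
    tab <- cbind(tab, human[, cols, drop = FALSE])
  }
  tab$trail_density <- stations$trail_density[idx]
  tab$road_density <- stations$road_density[idx]
  tab$dist_boundary <- stations$dist_boundary[idx]
  tab$lunar <- lunar_fraction(ts, utc_offset_hours)
  tab$crown_closure <- stations$crown_closure[idx]

  complete <- stats::complete.cases(tab)
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    message("assemble_model_table: dropped ", n_dropped,
            " event(s) with missing covariates (",
            unique(tab$species)[1L], ")")
  }
  out <- tab[complete, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}
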