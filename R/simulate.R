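# Synthetic camera-trap study generator.
#
# Emulates the statistical structure the analysis assumes: a 58-station
# study over ~18 months in a planar landscape; trail/road polylines and a
# southern urban-wildland boundary from which the infrastructure covariates
# are computed exactly; camera effort with random gap days; diurnally
# concentrated human traffic whose intensity scales log-linearly with trail
# density; and wildlife detection events whose nocturnality follows a linear
# model on the standardized covariates, mapped back to clock timestamps
# around each date's solar noon. The generator returns the ground truth
# (beta, sigma, per-event covariates) needed for parameter-recovery tests.

#' Default geometry/covariate generation settings
#'
#' Controls the simulated line layers and station attributes: numbers of
#' trail/road polylines, their segment counts and step lengths (meters), the
#' Beta distribution of crown closure, and the jitter of the southern
#' boundary polyline.
#'
#' @return a named list consumed by [sim_config()].
#' @export
default_covariate_spec <- function() {
  list(trails = list(n = 40, segments = 12, step_m = 300),
       roads = list(n = 10, segments = 12, step_m = 400),
       crown_closure = list(shape1 = 6, shape2 = 3),
       boundary = list(n_vertices = 21, amplitude_m = 200))
}

#' Default species table of the simulated study
#'
#' Six focal species with diel intercepts equal to the study's reported mean
#' nocturnalities (decimal hours) and expected events per station chosen so
#' the study-wide totals match the reported event counts (~1,912 events over
#' 58 stations).
#'
#' @return data frame with `species`, `intercept`, `events_per_station_mean`.
#' @export
default_species_table <- function() {
  data.frame(
    species = c("cougar", "black_bear", "black_tailed_deer",
                "snowshoe_hare", "coyote", "bobcat"),
    intercept = c(6.47, 4.70, 5.74, 9.23, 7.27, 8.11),
    events_per_station_mean = c(46, 290, 709, 248, 416, 203) / 58)
}

#' Simulation configuration
#'
#' Defaults are the study conditions: 58 stations in a 10 km planar extent
#' anchored at 49.4N, -122.5E (UTC-8), March 2019 - September 2020, a 29%
#' camera-day gap rate (~23.9k camera-days), human traffic averaging 4.7
#' detections per camera-day with 87.8% falling in 09:00-18:00 and a
#' log-linear trail-density effect, and slope coefficients (standardized
#' scale, decimal hours) equal to the study's reported effect magnitudes.
#'
#' @param n_stations number of camera stations (>= 2).
#' @param extent_m width/height of the square planar landscape, meters.
#' @param study_start,study_end calendar dates.
#' @param utc_offset_hours fixed clock offset from UTC.
#' @param ref_latitude,ref_longitude landscape anchor (degrees) for solar
#'   geometry; the planar frame is centered here.
#' @param covariate_spec see [default_covariate_spec()].
#' @param human_intensity list: `base_rate` (mean human detections per
#'   camera-day across stations), `trail_effect` (log-linear effect of
#'   standardized trail density), `station_sd` (SD of a station-level
#'   log-normal popularity term: access, visibility, trailhead proximity)
#'   and `week_sd` (SD of a station-week log-normal fluctuation: weather,
#'   season, holidays). The two heterogeneity terms keep the three
#'   human-presence measures mutually collinear (pairwise r > 0.7) while
#'   holding their correlation with trail density below the 0.7 screen, the
#'   correlation structure the analysis expects of field data.
#' @param human_diurnal_window clock-hour interval holding most traffic.
#' @param human_diurnal_fraction fraction of human detections inside the
#'   window (default 0.878).
#' @param beta named slope vector on the standardized covariate scale, order
#'   `human`, `trail_density`, `road_density`, `dist_boundary`, `lunar`,
#'   `crown_closure` (decimal hours per SD).
#' @param sigma residual SD of nocturnality (decimal hours, >= 0).
#' @param human_scale the temporal scale through which the human coefficient
#'   acts: `"daily"`, `"weekly"`, `"monthly"` or `"none"`.
#' @param species species table (see [default_species_table()]); a one-row
#'   table gives a single-species scenario.
#' @param effort_gap_rate probability a camera-day is inactive.
#' @param seed integer root seed; all stages derive their seeds from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_stations = 58, extent_m = 10000,
                       study_start = "2019-03-01", study_end = "2020-09-30",
                       utc_offset_hours = -8,
                       ref_latitude = 49.4, ref_longitude = -122.5,
                       covariate_spec = default_covariate_spec(),
                       human_intensity = list(base_rate = 4.7,
                                              trail_effect = 0.6,
                                              station_sd = 0.8,
                                              week_sd = 0.5),
                       human_diurnal_window = c(9, 18),
                       human_diurnal_fraction = 0.878,
                       beta = c(human = 0.35, trail_density = 0.81,
                                road_density = -0.87, dist_boundary = -0.29,
                                lunar = 0.27, crown_closure = 0.27),
                       sigma = 2,
                       human_scale = c("monthly", "daily", "weekly", "none"),
                       species = default_species_table(),
                       effort_gap_rate = 0.29, seed = 1) {
  human_scale <- match.arg(human_scale)
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  stopifnot(n_stations >= 2, extent_m > 0, study_start < study_end,
            sigma >= 0, effort_gap_rate >= 0, effort_gap_rate <= 1,
            all(human_diurnal_window >= 0), all(human_diurnal_window < 24),
            human_diurnal_fraction >= 0, human_diurnal_fraction <= 1,
            is.data.frame(species), nrow(species) >= 1)
  stopifnot(all(c("human", "trail_density", "road_density", "dist_boundary",
                  "lunar", "crown_closure") %in% names(beta)))
  structure(list(
    n_stations = n_stations, extent_m = extent_m,
    study_start = study_start, study_end = study_end,
    utc_offset_hours = utc_offset_hours,
    ref_latitude = ref_latitude, ref_longitude = ref_longitude,
    covariate_spec = covariate_spec, human_intensity = human_intensity,
    human_diurnal_window = human_diurnal_window,
    human_diurnal_fraction = human_diurnal_fraction,
    beta = beta, sigma = sigma, human_scale = human_scale,
    species = species, effort_gap_rate = effort_gap_rate,
    seed = as.integer(seed)), class = "sim_config")
}

# deterministic per-stage seeds derived from the root seed
stage_seeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(2147483646L, 4),
                  c("stations", "effort", "human", "wildlife"))
}

# random-walk polyline inside [0, extent]^2, reflected at the borders
random_polyline <- function(extent, segments, step_m) {
  x <- stats::runif(1, 0, extent)
  y <- stats::runif(1, 0, extent)
  heading <- stats::runif(1, 0, 2 * pi)
  pts <- matrix(0, segments + 1L, 2)
  pts[1L, ] <- c(x, y)
  for (i in seq_len(segments)) {
    heading <- heading + stats::rnorm(1, 0, 0.6)
    len <- step_m * stats::runif(1, 0.5, 1.5)
    x <- x + len * cos(heading)
    y <- y + len * sin(heading)
    if (x < 0) x <- -x else if (x > extent) x <- 2 * extent - x
    if (y < 0) y <- -y else if (y > extent) y <- 2 * extent - y
    pts[i + 1L, ] <- c(x, y)
  }
  pts
}

#' Simulate camera stations and infrastructure geometry
#'
#' Places stations uniformly (>= 1 m apart) in the planar extent, lays down
#' trail and road polylines and a southern urban-wildland boundary, and
#' computes each station's infrastructure covariates *from those geometries*
#' (500 m buffer line densities; minimum distance to the boundary), so the
#' emitted covariates are exactly reproducible from the emitted layers.
#'
#' @param config a [sim_config()].
#' @return list: `stations` (data frame with ids, planar and geographic
#'   coordinates, covariates), `trails`, `roads`, `boundary` (lists of
#'   planar polylines).
#' @export
simulate_stations <- function(config) {
  set.seed(stage_seeds(config$seed)["stations"])
  n <- config$n_stations
  ext <- config$extent_m
  if (ext^2 < 4 * n) {
    stop("simulate_stations: extent too small to place ", n,
         " stations at least 1 m apart")
  }
  x <- stats::runif(n, 0, ext)
  y <- stats::runif(n, 0, ext)
  for (iter in 1:1000) {
    d <- as.matrix(stats::dist(cbind(x, y)))
    diag(d) <- Inf
    bad <- which(apply(d, 1, min) < 1)
    if (!length(bad)) break
    x[bad] <- stats::runif(length(bad), 0, ext)
    y[bad] <- stats::runif(length(bad), 0, ext)
    if (iter == 1000) {
      stop("simulate_stations: could not separate stations by 1 m")
    }
  }
  cs <- config$covariate_spec
  trails <- lapply(seq_len(cs$trails$n), function(i) {
    random_polyline(ext, cs$trails$segments, cs$trails$step_m)
  })
  roads <- lapply(seq_len(cs$roads$n), function(i) {
    random_polyline(ext, cs$roads$segments, cs$roads$step_m)
  })
  bx <- seq(-0.05 * ext, 1.05 * ext, length.out = cs$boundary$n_vertices)
  boundary <- list(cbind(bx, stats::runif(length(bx), 0,
                                          cs$boundary$amplitude_m)))
  crown <- stats::rbeta(n, cs$crown_closure$shape1, cs$crown_closure$shape2)

  geo <- local_unproject(x - ext / 2, y - ext / 2,
                         config$ref_latitude, config$ref_longitude)
  stations <- data.frame(
    station_id = sprintf("st%02d", seq_len(n)),
    x = x, y = y, latitude = geo$lat, longitude = geo$lon,
    trail_density = line_density_in_buffer(trails, x, y, 500),
    road_density = line_density_in_buffer(roads, x, y, 500),
    dist_boundary = distance_to_boundary(x, y, boundary),
    crown_closure = crown,
    stringsAsFactors = FALSE)
  list(stations = stations, trails = trails, roads = roads,
       boundary = boundary)
}

#' Simulate the camera effort log
#'
#' Every study day is independently inactive with probability
#' `effort_gap_rate`, per station.
#'
#' @param config a [sim_config()].
#' @param stations station table from [simulate_stations()].
#' @return data frame `station_id`, `date`, `active` with attribute
#'   `camera_days` (total active days).
#' @export
simulate_effort <- function(config, stations) {
  set.seed(stage_seeds(config$seed)["effort"])
  days <- seq(config$study_start, config$study_end, by = "day")
  ids <- stations$station_id
  effort <- data.frame(
    station_id = rep(ids, each = length(days)),
    date = rep(days, times = length(ids)),
    active = stats::runif(length(days) * length(ids)) >=
      config$effort_gap_rate)
  attr(effort, "camera_days") <- sum(effort$active)
  effort
}

#' Simulate human detection records
#'
#' Per active camera-day, a Poisson count of human detections whose log-mean
#' combines a standardized trail-density effect, a station-level popularity
#' term and a station-week fluctuation (each mean-calibrated so the average
#' station sees `base_rate` detections per camera-day); detection clock times
#' fall inside the diurnal window with the configured probability, uniform
#' within each regime.
#'
#' @param config a [sim_config()].
#' @param stations station table.
#' @param effort effort log from [simulate_effort()].
#' @return data frame of records `station_id`, `species` (`"human"`),
#'   `timestamp`, ordered by station and time.
#' @export
simulate_human_activity <- function(config, stations, effort) {
  set.seed(stage_seeds(config$seed)["human"])
  hi <- config$human_intensity
  st_sd <- if (is.null(hi$station_sd)) 0 else hi$station_sd
  wk_sd <- if (is.null(hi$week_sd)) 0 else hi$week_sd
  td <- stations$trail_density
  z <- if (stats::sd(td) > 0) (td - mean(td)) / stats::sd(td) else td * 0
  eff <- hi$trail_effect
  # each multiplicative term is mean-one so base_rate stays the average rate
  u_st <- stats::rnorm(nrow(stations), 0, st_sd)
  log_lam_st <- log(hi$base_rate) + eff * z - eff^2 / 2 + u_st - st_sd^2 / 2
  act <- effort[effort$active, , drop = FALSE]
  sidx <- match(act$station_id, stations$station_id)
  wkey <- paste(act$station_id, period_key(act$date, "week"), sep = "\r")
  uw <- unique(wkey)
  w_eff <- stats::setNames(stats::rnorm(length(uw), 0, wk_sd) - wk_sd^2 / 2,
                           uw)
  counts <- stats::rpois(nrow(act), exp(log_lam_st[sidx] + w_eff[wkey]))
  if (sum(counts) == 0L) {
    return(data.frame(station_id = character(0), species = character(0),
                      timestamp = parse_timestamp(character(0))))
  }
  st <- rep(act$station_id, counts)
  dt <- rep(act$date, counts)
  n <- length(st)
  w <- config$human_diurnal_window
  inside <- stats::runif(n) < config$human_diurnal_fraction
  tod <- numeric(n)
  tod[inside] <- stats::runif(sum(inside), w[1], w[2])
  out_len <- 24 - (w[2] - w[1])
  u <- stats::runif(sum(!inside), 0, out_len)
  tod[!inside] <- ifelse(u < w[1], u, u + (w[2] - w[1]))
  ts <- as.POSIXct(as.character(dt), tz = "UTC") + tod * 3600
  o <- order(st, ts)
  data.frame(station_id = st[o], species = "human", timestamp = ts[o],
             stringsAsFactors = FALSE)
}

# triangle-wave fold of decimal hours into [0, 12] (reflection at 0 and 12)
fold_nocturnality <- function(x) {
  t <- x %% 24
  pmin(t, 24 - t)
}

# z-scale a column, mapping a constant column to zeros (a covariate with no
# variation carries no effect in the generator)
safe_z <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(x * 0)
  (x - mean(x)) / s
}

# core generator for one species; see simulate_wildlife_detections.
# `htabs` holds precomputed human count/effort tables (hp_tables), or NULL
# when human_scale = "none".
sim_species_events <- function(config, stations, effort, htabs,
                               sp_name, intercept, mean_events) {
  n_st <- nrow(stations)
  active <- effort[effort$active &
                     effort$date > config$study_start &
                     effort$date < config$study_end, , drop = FALSE]
  days_by_st <- split(active$date, active$station_id)
  n_ev <- stats::rpois(n_st, mean_events)
  n_ev[!(stations$station_id %in% names(days_by_st))] <- 0L
  N <- sum(n_ev)
  if (N == 0L) return(NULL)
  st_idx <- rep(seq_len(n_st), n_ev)
  ids <- stations$station_id[st_idx]
  draw_dates <- function(k_idx) {
    as.Date(vapply(k_idx, function(i) {
      pool <- days_by_st[[stations$station_id[st_idx[i]]]]
      as.numeric(pool[sample.int(length(pool), 1L)])
    }, 0), origin = "1970-01-01")
  }
  dates <- draw_dates(seq_len(N))
  eps <- stats::rnorm(N, 0, config$sigma)
  coin <- stats::runif(N) < 0.5

  beta <- config$beta
  use_human <- config$human_scale != "none"
  hcol <- switch(config$human_scale, daily = "daily_count",
                 weekly = "weekly_rate", monthly = "monthly_rate", NULL)
  lon <- stations$longitude[st_idx]
  off <- config$utc_offset_hours
  ts_cur <- as.POSIXct(as.character(dates), tz = "UTC") + 12 * 3600
  min_gap <- 30 * 60 + 1  # strict 30-minute independence plus a 1 s margin

  raw <- zmat <- h <- NULL
  side <- ifelse(coin, 1, -1)
  for (iter in 1:40) {
    ev_df <- data.frame(station_id = ids, start_timestamp = ts_cur)
    raw <- data.frame(
      trail_density = stations$trail_density[st_idx],
      road_density = stations$road_density[st_idx],
      dist_boundary = stations$dist_boundary[st_idx],
      lunar = lunar_fraction(ts_cur, off),
      crown_closure = stations$crown_closure[st_idx])
    if (use_human) {
      hp <- hp_lookup(ev_df, htabs)
      raw <- cbind(human = hp[[hcol]], raw)
    }
    zmat <- vapply(raw, safe_z, numeric(N))
    if (N == 1L) zmat <- matrix(zmat, 1L, dimnames = list(NULL, names(raw)))
    mu <- intercept + as.vector(zmat %*% beta[colnames(zmat)])
    h <- fold_nocturnality(mu + eps)
    noon <- solar_noon_hours(dates, lon, off)
    # keep each event's before/after-noon side sticky across iterations,
    # flipping only when that side would leave the calendar date (at least
    # one side always stays inside it)
    side <- ifelse(side < 0 & h > noon, 1,
                   ifelse(side > 0 & h >= 24 - noon, -1, side))
    ts_new <- as.POSIXct(as.character(dates), tz = "UTC") +
      (noon + side * h) * 3600
    # 30-min independence between events of the same station
    o <- order(ids, ts_new)
    gap <- c(Inf, diff(as.numeric(ts_new[o])))
    same <- c(FALSE, ids[o][-1L] == ids[o][-N])
    clash <- o[which(same & gap < min_gap)]
    delta <- abs(as.numeric(ts_new) - as.numeric(ts_cur))
    ts_cur <- ts_new
    if (!length(clash) && max(delta) < 0.5) break
    redraw <- clash
    if (iter >= 12) {  # break rare side-flip oscillation near h = 12
      redraw <- union(redraw, which(delta > 60))
    }
    if (length(redraw)) {  # redraw the event's date, keep its epsilon
      dates[redraw] <- draw_dates(redraw)
      ts_cur[redraw] <- as.POSIXct(as.character(dates[redraw]),
                                   tz = "UTC") + 12 * 3600
    }
    if (iter == 40) {
      stop("sim_species_events: could not enforce 30-min spacing (", sp_name,
           ")")
    }
  }
  records <- data.frame(station_id = ids, species = sp_name,
                        timestamp = ts_cur, stringsAsFactors = FALSE)
  truth_tab <- cbind(
    data.frame(station_id = ids, timestamp = ts_cur, nocturnality = h),
    raw, stats::setNames(as.data.frame(zmat), paste0("z_", colnames(zmat))))
  list(records = records, truth = truth_tab)
}

#' Simulate wildlife detection records with known ground truth
#'
#' For each species: event counts per station are Poisson; each event's
#' nocturnality is drawn as `intercept + sum(beta_k z_k) + eps` on the
#' species' standardized covariate scale, with Gaussian residual `eps`
#' reflected into `[0, 12]`; the event is stamped at that circular distance
#' from its date's solar noon, before/after noon by fair coin (flipped only
#' when one side would leave the calendar date); and events at a station are
#' spaced more than 30 minutes apart so independence filtering preserves
#' them. The drawn covariates, coefficients and nocturnality values are
#' returned as ground truth.
#'
#' @param config a [sim_config()].
#' @param stations station table from [simulate_stations()].
#' @param effort effort log; wildlife occurs only on active camera-days.
#' @param human_events independence-filtered human events (1-minute
#'   threshold), required unless `human_scale = "none"`.
#' @return list: `records` (data frame `station_id`, `species`,
#'   `timestamp`) and `truth` (class `synthetic_truth`): `beta_true`,
#'   `sigma_true`, `per_station_covariates`, `seed`, and a per-species list
#'   of event-level truth tables.
#' @export
simulate_wildlife_detections <- function(config, stations, effort,
                                         human_events = NULL) {
  if (config$human_scale != "none" && is.null(human_events)) {
    stop("simulate_wildlife_detections: human_events required for ",
         "human_scale = '", config$human_scale, "'")
  }
  set.seed(stage_seeds(config$seed)["wildlife"])
  effort <- as_effort(effort)
  htabs <- if (config$human_scale != "none") {
    hp_tables(human_events, effort)
  }
  recs <- list()
  truths <- list()
  for (i in seq_len(nrow(config$species))) {
    sp <- config$species$species[i]
    res <- sim_species_events(config, stations, effort, htabs, sp,
                              config$species$intercept[i],
                              config$species$events_per_station_mean[i])
    if (is.null(res)) next
    recs[[sp]] <- res$records
    truths[[sp]] <- res$truth
  }
  records <- if (length(recs)) {
    do.call(rbind, c(recs, list(make.row.names = FALSE)))
  } else {
    data.frame(station_id = character(0), species = character(0),
               timestamp = parse_timestamp(character(0)))
  }
  truth <- structure(list(
    beta_true = config$beta, sigma_true = config$sigma,
    intercepts = stats::setNames(config$species$intercept,
                                 config$species$species),
    human_scale = config$human_scale,
    per_station_covariates = stations[, c("station_id", "trail_density",
                                          "road_density", "dist_boundary",
                                          "crown_closure")],
    events = truths, seed = config$seed), class = "synthetic_truth")
  list(records = records, truth = truth)
}

#' Simulate a complete camera-trap study
#'
#' Runs all generator stages: stations and geometry, effort, human activity
#' (filtered to 1-minute independent events for the covariates), and
#' wildlife detections with ground truth.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_study`: `config`, `stations`, `trails`,
#'   `roads`, `boundary`, `effort`, `human_records`, `human_events`,
#'   `wildlife_records`, `truth`.
#' @export
simulate_study <- function(config = sim_config()) {
  geo <- simulate_stations(config)
  effort <- simulate_effort(config, geo$stations)
  human_records <- simulate_human_activity(config, geo$stations, effort)
  human_events <- filter_independent_events(human_records,
                                            threshold_minutes = 1)
  wl <- simulate_wildlife_detections(config, geo$stations, effort,
                                     human_events)
  structure(c(list(config = config), geo,
              list(effort = effort, human_records = human_records,
                   human_events = human_events,
                   wildlife_records = wl$records, truth = wl$truth)),
            class = "sim_study")
}

#' Write a simulated study to disk
#'
#' Emits the pipeline's file interface: `detections.csv` (wildlife + human
#' records, ISO-8601 timestamps with the study's UTC offset), `effort.csv`,
#' `stations.csv`, `trails.geojson` / `roads.geojson` / `boundary.geojson`
#' (WGS84 LineStrings), and `truth.json`.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- study$config
  det <- rbind(study$wildlife_records, study$human_records)
  det <- det[order(det$station_id, det$timestamp), ]
  det$timestamp <- format_timestamp(det$timestamp, cfg$utc_offset_hours)
  utils::write.csv(det, file.path(dir, "detections.csv"), row.names = FALSE)
  utils::write.csv(study$effort, file.path(dir, "effort.csv"),
                   row.names = FALSE)
  utils::write.csv(study$stations, file.path(dir, "stations.csv"),
                   row.names = FALSE)
  half <- cfg$extent_m / 2
  to_geo <- function(lines) {
    unproject_lines(lapply(lines, function(m) cbind(m[, 1] - half,
                                                    m[, 2] - half)),
                    cfg$ref_latitude, cfg$ref_longitude)
  }
  write_lines_geojson(to_geo(study$trails), file.path(dir, "trails.geojson"))
  write_lines_geojson(to_geo(study$roads), file.path(dir, "roads.geojson"))
  write_lines_geojson(to_geo(study$boundary),
                      file.path(dir, "boundary.geojson"))
  tr <- study$truth
  jsonlite::write_json(
    list(beta_true = as.list(tr$beta_true), sigma_true = tr$sigma_true,
         intercepts = as.list(tr$intercepts), human_scale = tr$human_scale,
         seed = tr$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
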