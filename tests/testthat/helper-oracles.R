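# Independent oracles used to validate the implementation. Each is written
# from a different formulation than the code under test.

# --- Solar transit oracle -----------------------------------------------
# Astronomical Almanac low-precision solar position (Michalsky 1988):
# right ascension from the sun's ecliptic longitude, Greenwich mean sidereal
# time, and a root search for the local clock hour at which the sun's local
# hour angle crosses zero.
oracle_solar_noon_hour <- function(date, lon, utc_offset) {
  deg <- pi / 180
  hour_angle <- function(hour_local) {
    utc_hours <- hour_local - utc_offset
    jd <- as.numeric(as.POSIXct(paste(date, "00:00:00"), tz = "UTC")) /
      86400 + 2440587.5 + utc_hours / 24
    n <- jd - 2451545
    L <- (280.460 + 0.9856474 * n) %% 360
    g <- (357.528 + 0.9856003 * n) %% 360
    lambda <- L + 1.915 * sin(g * deg) + 0.020 * sin(2 * g * deg)
    eps <- 23.439 - 4e-7 * n
    ra <- atan2(cos(eps * deg) * sin(lambda * deg), cos(lambda * deg)) / deg
    gmst <- (6.697375 + 0.0657098242 * n + utc_hours) %% 24
    lmst <- gmst * 15 + lon
    ha <- (lmst - ra) %% 360
    if (ha > 180) ha <- ha - 360
    ha
  }
  stats::uniroot(hour_angle, c(9, 15), tol = 1e-6)$root
}

# --- Event-filter oracle -------------------------------------------------
# Plain nested-loop scan over the sorted records of each station x species
# group; a record opens a new event iff its gap to the previous record
# strictly exceeds the threshold.
oracle_filter_events <- function(records, threshold_minutes) {
  ts <- noctshift::parse_timestamp(records$timestamp)
  out <- NULL
  for (st in unique(records$station_id)) {
    for (sp in unique(records$species)) {
      sel <- which(records$station_id == st & records$species == sp)
      if (!length(sel)) next
      sel <- sel[order(ts[sel])]
      start <- NULL
      nrec <- 0
      for (i in sel) {
        if (is.null(start) ||
            difftime(ts[i], prev, units = "mins") > threshold_minutes) {
          if (!is.null(start)) {
            out <- rbind(out, data.frame(station_id = st, species = sp,
                                         start_timestamp = start,
                                         n_records = nrec))
          }
          start <- ts[i]
          nrec <- 0
        }
        nrec <- nrec + 1
        prev <- ts[i]
      }
      out <- rbind(out, data.frame(station_id = st, species = sp,
                                   start_timestamp = start,
                                   n_records = nrec))
    }
  }
  out <- out[order(out$station_id, out$species, out$start_timestamp), ]
  rownames(out) <- NULL
  out
}

# random record stream for property tests
random_stream <- function(n_records = 20, n_stations = 2, n_species = 2) {
  data.frame(
    station_id = sample(paste0("s", seq_len(n_stations)), n_records,
                        replace = TRUE),
    species = sample(paste0("sp", seq_len(n_species)), n_records,
                     replace = TRUE),
    timestamp = as.POSIXct("2019-06-01", tz = "UTC") +
      round(runif(n_records, 0, 6 * 3600)))
}

# --- Least-squares oracle ------------------------------------------------
# direct normal equations, independent of the QR path in the package
oracle_ols <- function(X, y) as.numeric(solve(crossprod(X), crossprod(X, y)))

# --- Moran's I oracle ----------------------------------------------------
# literal double sum
oracle_moran <- function(x, w) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + w[i, j] * z[i] * z[j]
  (n / sum(w)) * num / sum(z^2)
}

# --- Line-length-in-disk oracle -----------------------------------------
# dense sampling along each segment
oracle_length_in_disk <- function(lines, cx, cy, r, step = 0.05) {
  tot <- 0
  for (line in lines) {
    for (k in seq_len(nrow(line) - 1)) {
      a <- line[k, ]; b <- line[k + 1, ]
      len <- sqrt(sum((b - a)^2))
      if (len == 0) next
      m <- max(2L, ceiling(len / step))
      tt <- (seq_len(m) - 0.5) / m
      px <- a[1] + tt * (b[1] - a[1])
      py <- a[2] + tt * (b[2] - a[2])
      tot <- tot + sum((px - cx)^2 + (py - cy)^2 <= r^2) * len / m
    }
  }
  tot
}

# --- Point-segment distance oracle --------------------------------------
oracle_dist_boundary <- function(x, y, lines) {
  best <- Inf
  for (line in lines) {
    for (k in seq_len(nrow(line) - 1)) {
      a <- line[k, ]; b <- line[k + 1, ]
      # endpoints plus projection
      cand <- c(sqrt(sum((c(x, y) - a)^2)), sqrt(sum((c(x, y) - b)^2)))
      L2 <- sum((b - a)^2)
      if (L2 > 0) {
        t <- sum((c(x, y) - a) * (b - a)) / L2
        if (t > 0 && t < 1) {
          pr <- a + t * (b - a)
          cand <- c(cand, sqrt(sum((c(x, y) - pr)^2)))
        }
      }
      best <- min(best, cand)
    }
  }
  best
}

# frozen syzygy instants (UTC) from published almanac tables
FULL_MOONS_UTC <- as.POSIXct(c("2019-01-21 05:16", "2019-05-18 21:11"),
                             tz = "UTC")
NEW_MOONS_UTC <- as.POSIXct(c("2019-06-03 10:02", "2019-08-30 10:37"),
                            tz = "UTC")
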