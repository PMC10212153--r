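# The synthetic study generator: determinism, geometry consistency, effort,
# human traffic shape, and the wildlife nocturnality round trip.

test_that("identical config and seed reproduce the study exactly", {
  cfg <- tiny_config(seed = 3)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$stations, s2$stations)
  expect_identical(s1$effort$active, s2$effort$active)
  expect_identical(s1$human_records$timestamp, s2$human_records$timestamp)
  expect_identical(s1$wildlife_records, s2$wildlife_records)
})

test_that("a config with zero trail segments gives zero trail density everywhere", {
  cfg <- tiny_config()
  cfg$covariate_spec$trails$n <- 0
  geo <- simulate_stations(cfg)
  expect_true(all(geo$stations$trail_density == 0))
})

test_that("emitted covariates survive the GeoJSON round trip within 1%", {
  cfg <- tiny_config(seed = 8)
  st <- simulate_study(cfg)
  dir <- tempfile("study")
  write_study(st, dir)
  inp <- load_inputs(dir)
  rel <- function(a, b) abs(a - b) / pmax(abs(b), 1e-12)
  nz <- st$stations$trail_density > 0
  expect_true(all(rel(inp$stations$trail_density,
                      st$stations$trail_density)[nz] < 0.01))
  expect_true(all(rel(inp$stations$road_density,
                      st$stations$road_density)[st$stations$road_density > 0]
                  < 0.01))
  expect_true(all(rel(inp$stations$dist_boundary,
                      st$stations$dist_boundary) < 0.01))
  unlink(dir, recursive = TRUE)
})

test_that("effort gap rate 0 and 1 are the two degenerate extremes", {
  cfg <- tiny_config(effort_gap_rate = 0)
  eff <- simulate_effort(cfg, simulate_stations(cfg)$stations)
  expect_true(all(eff$active))
  cfg1 <- tiny_config(effort_gap_rate = 1)
  eff1 <- simulate_effort(cfg1, simulate_stations(cfg1)$stations)
  expect_equal(attr(eff1, "camera_days"), 0)
  # downstream rates must flag the missing effort
  ev <- data.frame(station_id = eff1$station_id[1],
                   start_timestamp = parse_timestamp(paste(
                     cfg1$study_start + 10, "12:00:00")))
  he <- data.frame(station_id = character(0), species = character(0),
                   start_timestamp = parse_timestamp(character(0)))
  hp <- human_presence(ev, he, eff1)
  expect_true(is.na(hp$weekly_rate) && is.na(hp$monthly_rate))
})

test_that("the active-day fraction concentrates near 1 - gap rate", {
  cfg <- sim_config(effort_gap_rate = 0.1, study_start = "2019-03-01",
                    study_end = "2020-07-13")  # 58 stations x 500 days
  eff <- simulate_effort(cfg, simulate_stations(cfg)$stations)
  n <- nrow(eff)
  phat <- mean(eff$active)
  expect_lt(abs(phat - 0.9), 3 * sqrt(0.9 * 0.1 / n))
})

test_that("zero baseline intensity produces no human records", {
  cfg <- tiny_config(human_intensity = list(base_rate = 0, trail_effect = 1,
                                            station_sd = 0.5, week_sd = 0.5))
  geo <- simulate_stations(cfg)
  eff <- simulate_effort(cfg, geo$stations)
  expect_equal(nrow(simulate_human_activity(cfg, geo$stations, eff)), 0)
})

hour_of_day_sim <- function(ts) {
  lt <- as.POSIXlt(ts, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}

test_that("the configured diurnal fraction is reproduced at large n", {
  cfg <- sim_config(n_stations = 2, study_start = "2019-06-01",
                    study_end = "2019-09-30", effort_gap_rate = 0,
                    human_intensity = list(base_rate = 500, trail_effect = 0,
                                           station_sd = 0, week_sd = 0),
                    human_diurnal_fraction = 0.88, seed = 17)
  geo <- simulate_stations(cfg)
  eff <- simulate_effort(cfg, geo$stations)
  hr <- simulate_human_activity(cfg, geo$stations, eff)
  expect_gt(nrow(hr), 1e5)
  frac <- diurnal_fraction(hour_of_day_sim(hr$timestamp))
  expect_lt(abs(frac - 0.88), 0.01)
  # no detections on inactive days
  cfg2 <- tiny_config(effort_gap_rate = 0.5, seed = 2)
  geo2 <- simulate_stations(cfg2)
  eff2 <- simulate_effort(cfg2, geo2$stations)
  hr2 <- simulate_human_activity(cfg2, geo2$stations, eff2)
  key_active <- paste(eff2$station_id, eff2$date)[eff2$active]
  expect_true(all(paste(hr2$station_id, local_date(hr2$timestamp)) %in%
                    key_active))
})

test_that("a positive trail effect raises human counts with trail density", {
  cfg <- tiny_config(seed = 5)
  st <- simulate_study(cfg)
  counts <- table(factor(st$human_records$station_id,
                         levels = st$stations$station_id))
  expect_gt(cor(st$stations$trail_density, as.numeric(counts),
                method = "spearman"), 0)
})

test_that("with zero slopes and zero noise every event sits at the intercept", {
  cfg <- tiny_config(
    beta = c(human = 0, trail_density = 0, road_density = 0,
             dist_boundary = 0, lunar = 0, crown_closure = 0),
    sigma = 0, human_scale = "none",
    species = data.frame(species = "spA", intercept = 6,
                         events_per_station_mean = 4))
  geo <- simulate_stations(cfg)
  eff <- simulate_effort(cfg, geo$stations)
  wl <- simulate_wildlife_detections(cfg, geo$stations, eff)
  expect_equal(wl$truth$events$spA$nocturnality,
               rep(6, nrow(wl$truth$events$spA)))
  ctx <- solar_ctx(geo$stations$latitude[match(wl$records$station_id,
                                               geo$stations$station_id)],
                   geo$stations$longitude[match(wl$records$station_id,
                                                geo$stations$station_id)],
                   cfg$utc_offset_hours)
  expect_equal(nocturnality(wl$records$timestamp, ctx),
               rep(6, nrow(wl$records)), tolerance = 1e-9)
})

test_that("filtering plus nocturnality recovers the drawn values to one second", {
  cfg <- tiny_config(seed = 21)
  st <- simulate_study(cfg)
  ev <- filter_independent_events(st$wildlife_records, 30)
  # event counts preserved: all inter-event gaps exceed the threshold
  expect_equal(nrow(ev), nrow(st$wildlife_records))
  truth <- do.call(rbind, lapply(names(st$truth$events), function(sp) {
    cbind(species = sp, st$truth$events[[sp]])
  }))
  i <- match(paste(ev$species, ev$station_id, format(ev$start_timestamp)),
             paste(truth$species, truth$station_id, format(truth$timestamp)))
  expect_false(anyNA(i))
  sidx <- match(ev$station_id, st$stations$station_id)
  ctx <- solar_ctx(st$stations$latitude[sidx], st$stations$longitude[sidx],
                   cfg$utc_offset_hours)
  got <- nocturnality(ev$start_timestamp, ctx)
  expect_lt(max(abs(got - truth$nocturnality[i])), 1 / 3600)
  expect_true(all(truth$nocturnality >= 0 & truth$nocturnality <= 12))
})

test_that("same-station wildlife events are separated by more than 30 minutes", {
  cfg <- tiny_config(seed = 13)
  st <- simulate_study(cfg)
  w <- st$wildlife_records
  for (sp in unique(w$species)) {
    d <- w[w$species == sp, ]
    d <- d[order(d$station_id, d$timestamp), ]
    gaps <- diff(as.numeric(d$timestamp))
    same <- d$station_id[-1] == d$station_id[-nrow(d)]
    if (any(same)) expect_gt(min(gaps[same]), 30 * 60)
  }
})

test_that("analysis covariates match the generator truth table within 1%", {
  cfg <- recovery_config(seed = 4)
  st <- simulate_study(cfg)
  ev <- filter_independent_events(st$wildlife_records, 30)
  hp <- human_presence(ev, st$human_events, st$effort)
  mt <- assemble_model_table(ev, st$stations, hp, cfg$utc_offset_hours,
                             "all")
  truth <- st$truth$events$species_a
  i <- match(paste(mt$station_id, format(mt$start_timestamp)),
             paste(truth$station_id, format(truth$timestamp)))
  expect_false(anyNA(i))
  expect_equal(mt$monthly_rate, truth$human[i], tolerance = 1e-12)
  expect_equal(mt$trail_density, truth$trail_density[i], tolerance = 1e-12)
  expect_equal(mt$lunar, truth$lunar[i], tolerance = 1e-6)
  expect_equal(mt$nocturnality, truth$nocturnality[i], tolerance = 1e-7)
})

test_that("undersized extents raise a sizing error", {
  expect_error(sim_config(n_stations = 100, extent_m = 10),
               NA)  # construction is fine; placement must fail
  cfg <- sim_config(n_stations = 100, extent_m = 10)
  expect_error(simulate_stations(cfg), "too small")
})
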