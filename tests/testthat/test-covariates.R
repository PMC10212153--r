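# Human-presence rates, buffer line densities, boundary distances, and
# model-table assembly.

mk_effort <- function(station = "a", from = "2019-06-03", n = 28,
                      active = TRUE) {
  data.frame(station_id = station,
             date = seq(as.Date(from), by = "day", length.out = n),
             active = active)
}

human_ev <- function(times, station = "a") {
  data.frame(station_id = station, species = "human",
             start_timestamp = parse_timestamp(times))
}

test_that("weekly and monthly rates divide by active camera-days", {
  # 2019-06-03 is a Monday: the first 7 effort days are one ISO week
  eff <- mk_effort()
  he <- human_ev(paste("2019-06-0", 3:9, " 12:00:00", sep = ""))
  ev <- data.frame(station_id = "a",
                   start_timestamp = parse_timestamp("2019-06-05 10:00:00"))
  hp <- human_presence(ev, he, eff)
  expect_equal(hp$weekly_rate, 1.0)       # 7 events / 7 active days
  expect_equal(hp$daily_count, 1L)
  expect_equal(hp$monthly_rate, 7 / 28)   # 7 events / 28 active June days
})

test_that("monthly rate: 3 events over 10 active days is 0.3", {
  eff <- mk_effort(n = 10)
  he <- human_ev(c("2019-06-04 09:00:00", "2019-06-07 11:00:00",
                   "2019-06-11 15:00:00"))
  ev <- data.frame(station_id = "a",
                   start_timestamp = parse_timestamp("2019-06-10 22:00:00"))
  expect_equal(human_presence(ev, he, eff)$monthly_rate, 0.3)
})

test_that("a zero-effort period yields a missing rate, not zero", {
  eff <- mk_effort()
  eff$active[eff$date >= as.Date("2019-06-10") &
               eff$date <= as.Date("2019-06-16")] <- FALSE
  ev <- data.frame(station_id = "a",
                   start_timestamp = parse_timestamp("2019-06-12 10:00:00"))
  hp <- human_presence(ev, human_ev("2019-06-05 12:00:00"), eff)
  expect_true(is.na(hp$weekly_rate))
  expect_false(is.na(hp$monthly_rate))
})

test_that("stations absent from the effort log are a configuration error", {
  ev <- data.frame(station_id = "ghost",
                   start_timestamp = parse_timestamp("2019-06-12 10:00:00"))
  expect_error(human_presence(ev, human_ev("2019-06-05 12:00:00"),
                              mk_effort()), "ghost")
})

test_that("line density: empty layers give zero, a diameter chord gives 2/(pi r)", {
  expect_equal(line_density_in_buffer(list(), 0, 0, 500), 0)
  chord <- list(cbind(c(-2000, 2000), c(0, 0)))
  expect_equal(line_density_in_buffer(chord, 0, 0, 500),
               2 / (pi * 500), tolerance = 1e-12)
  # the printed value of the worked geometry: ~1.2732e-3 m/m^2
  expect_equal(line_density_in_buffer(chord, 0, 0, 500), 1.2732e-3,
               tolerance = 1e-4)
})

test_that("line density doubles when every line is duplicated", {
  set.seed(21)
  lines <- lapply(1:5, function(i) matrix(runif(8, -800, 800), 4))
  d1 <- line_density_in_buffer(lines, 0, 0, 500)
  d2 <- line_density_in_buffer(c(lines, lines), 0, 0, 500)
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
})

test_that("line density agrees with a dense-sampling oracle within 0.5%", {
  set.seed(77)
  for (i in 1:10) {
    lines <- lapply(seq_len(sample(1:4, 1)),
                    function(j) matrix(runif(10, -1200, 1200), 5))
    got <- line_density_in_buffer(lines, 0, 0, 500) * pi * 500^2
    want <- oracle_length_in_disk(lines, 0, 0, 500)
    if (want > 1) expect_lt(abs(got - want) / want, 0.005)
  }
})

test_that("distance to boundary is exact point-segment distance", {
  xaxis <- list(cbind(c(-100, 100), c(0, 0)))
  expect_equal(distance_to_boundary(0, 0, xaxis), 0)
  expect_equal(distance_to_boundary(0, 37.5, xaxis), 37.5)
  expect_equal(distance_to_boundary(250, 40, xaxis),  # beyond the endpoint
               sqrt(150^2 + 40^2))
  expect_error(distance_to_boundary(0, 0, list()), "empty")
  set.seed(8)
  for (i in 1:20) {
    lines <- lapply(1:2, function(j) matrix(runif(8, -50, 50), 4))
    p <- runif(2, -80, 80)
    expect_equal(distance_to_boundary(p[1], p[2], lines),
                 oracle_dist_boundary(p[1], p[2], lines), tolerance = 1e-10)
  }
})

stations_fixture <- function() {
  data.frame(station_id = c("a", "b"), latitude = c(49.40, 49.41),
             longitude = c(-122.50, -122.52), trail_density = c(1e-3, 0),
             road_density = c(0, 5e-4), dist_boundary = c(100, 2500),
             crown_closure = c(0.8, 0.3))
}

test_that("the model table has one response and six predictors per event", {
  ev <- data.frame(species = "coyote", station_id = c("a", "a", "b", "b", "a"),
                   start_timestamp = parse_timestamp(
                     paste0("2019-06-", 10:14, " 22:30:00")))
  hp <- human_presence(ev, human_ev("2019-06-10 12:00:00"),
                       rbind(mk_effort("a"), mk_effort("b")))
  tab <- assemble_model_table(ev, stations_fixture(), hp, -8, "weekly")
  expect_equal(nrow(tab), 5)
  preds <- c("weekly_rate", "trail_density", "road_density", "dist_boundary",
             "lunar", "crown_closure")
  expect_true(all(c("nocturnality", preds) %in% names(tab)))
  expect_equal(attr(tab, "n_dropped"), 0)
  expect_true(all(tab$nocturnality >= 0 & tab$nocturnality <= 12))
})

test_that("events in zero-effort weeks are dropped and counted", {
  eff <- rbind(mk_effort("a"), mk_effort("b"))
  eff$active[eff$station_id == "a" & eff$date >= as.Date("2019-06-10") &
               eff$date <= as.Date("2019-06-16")] <- FALSE
  ev <- data.frame(species = "coyote",
                   station_id = c("a", "a", "b", "b", "a"),
                   start_timestamp = parse_timestamp(c(
                     "2019-06-12 22:30:00",  # inside the dead week
                     paste0("2019-06-", 20:23, " 22:30:00"))))
  hp <- human_presence(ev, human_ev("2019-06-20 12:00:00"), eff)
  expect_message(
    tab <- assemble_model_table(ev, stations_fixture(), hp, -8, "weekly"),
    "dropped 1")
  expect_equal(nrow(tab), 4)
  expect_equal(attr(tab, "n_dropped"), 1)
})

test_that("a species with zero events is an explicit error", {
  ev <- data.frame(species = character(0), station_id = character(0),
                   start_timestamp = parse_timestamp(character(0)))
  expect_error(assemble_model_table(ev, stations_fixture(), NULL, -8,
                                    "none"), "zero events")
})
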