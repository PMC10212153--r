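# Shared fixture builders (all data generated in code).

# single-species recovery scenario: 58 stations, ~2,000 events
recovery_config <- function(seed = 1, ...) {
  sim_config(species = data.frame(species = "species_a", intercept = 6.5,
                                  events_per_station_mean = 35),
             seed = seed, ...)
}

# small, fast multi-species study for pipeline tests
tiny_config <- function(seed = 1,
                        species = data.frame(
                          species = c("cougar", "black_bear",
                                      "black_tailed_deer", "snowshoe_hare",
                                      "coyote", "bobcat"),
                          intercept = c(6.47, 4.70, 5.74, 9.23, 7.27, 8.11),
                          events_per_station_mean = c(2, 5, 10, 5, 7, 4)),
                        ...) {
  sim_config(
    n_stations = 12, extent_m = 4000,
    study_start = "2019-06-01", study_end = "2019-09-30",
    covariate_spec = list(
      trails = list(n = 14, segments = 8, step_m = 250),
      roads = list(n = 5, segments = 8, step_m = 300),
      crown_closure = list(shape1 = 6, shape2 = 3),
      boundary = list(n_vertices = 9, amplitude_m = 150)),
    species = species, seed = seed, ...)
}

# a deterministic small model table for inference tests
toy_model_table <- function(n = 120, seed = 42, beta = c(0.5, -0.8, 0.3),
                            sigma = 1.5, intercept = 6) {
  set.seed(seed)
  X <- matrix(rnorm(n * length(beta)), n)
  colnames(X) <- paste0("x", seq_along(beta))
  Z <- scale(X)
  y <- intercept + as.vector(Z %*% beta) + rnorm(n, 0, sigma)
  data.frame(nocturnality = y, X)
}
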