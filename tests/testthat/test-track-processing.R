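# Flight-altitude derivation, position-based ground speed, EM behavioural
# clustering, hourly subsampling, and commuting-bout extraction.

mk_track <- function(x, y, t0 = "2021-06-01 00:00:00", dt_min = 20, id = "a",
                     height = 0) {
  data.frame(individual_id = id,
             timestamp = as.POSIXct(t0, tz = "UTC") + (seq_along(x) - 1) * dt_min * 60,
             x = x, y = y, height_ellipsoid = height)
}

test_that("flight altitude is ellipsoid height minus geoid minus ground", {
  dem <- raster_grid(matrix(1200, 5, 5), cell_size = 100)
  trk <- mk_track(c(250, 250), c(250, 250), height = c(1500, 1250))
  out <- compute_flight_altitude(trk, dem, geoid = 50)
  expect_equal(out$altitude_msl, c(1450, 1200))
  expect_equal(out$flight_altitude, c(250, 0))   # second fix is on the ground

  # geoid as a raster behaves identically
  geoid_r <- raster_grid(matrix(50, 5, 5), cell_size = 100)
  expect_equal(compute_flight_altitude(trk, dem, geoid_r)$flight_altitude,
               out$flight_altitude)

  # fixes outside the DEM are excluded with a warning
  trk2 <- mk_track(c(250, 9999), c(250, 250), height = 1500)
  expect_warning(out2 <- compute_flight_altitude(trk2, dem, 50), "outside")
  expect_equal(nrow(out2), 1)
})

test_that("recovered flight altitude on a simulated track is within GPS noise", {
  cfg <- sim_config(seed = 19, n_individuals = 1L, extent_m = 40000, cell_m = 100,
                    gamma_shape = 36, gamma_scale = 150,
                    pre_emigration_days = 2, post_emigration_weeks = 2L,
                    commute_gap_mean_hr = 10)
  world <- build_world(cfg)
  trk <- simulate_track(world, 1)
  out <- compute_flight_altitude(trk, world$dem, cfg$geoid_offset)
  err <- out$flight_altitude - out$sim_flight_alt
  expect_gt(mean(abs(err) <= 3 * cfg$altitude_noise_sd), 0.99)
})

test_that("ground speed is distance over elapsed time", {
  trk <- mk_track(c(0, 1200, 1200), c(0, 0, 0))
  out <- compute_ground_speed(trk)
  expect_equal(out$ground_speed, c(1, 1, 0))  # first fix inherits the second's

  still <- mk_track(rep(5, 4), rep(5, 4))
  expect_equal(compute_ground_speed(still)$ground_speed, rep(0, 4))

  dup <- mk_track(c(0, 10, 20), c(0, 0, 0))
  dup$timestamp[2] <- dup$timestamp[1]
  expect_error(compute_ground_speed(dup), "timestamp")
})

test_that("EM separates well-separated classes and its log-likelihood never
           decreases", {
  set.seed(301)
  n <- 3000
  commuting <- rbinom(n, 1, 0.3) == 1
  spd <- ifelse(commuting, rnorm(n, 12, 2), rnorm(n, 1, 0.5))
  alt <- ifelse(commuting, rnorm(n, 300, 80), rnorm(n, 20, 15))
  trk <- data.frame(individual_id = "a", ground_speed = spd, flight_altitude = alt)
  model <- fit_behavior_model(trk)
  lab <- classify_behavior(trk, model)$behavior_class
  expect_gt(mean((lab == "HH") == commuting), 0.99)
  expect_true(all(diff(model$speed$loglik) >= -1e-8))
  expect_true(all(diff(model$altitude$loglik) >= -1e-8))
  # the high component is the one with the larger mean, by construction
  expect_gt(model$speed$means[2], model$speed$means[1])
})

test_that("overlapping mixtures trigger the low-separation warning", {
  set.seed(302)
  trk <- data.frame(individual_id = "a",
                    ground_speed = c(rnorm(300, 1, 1), rnorm(300, 1.5, 1)),
                    flight_altitude = c(rnorm(300, 10, 20), rnorm(300, 25, 20)))
  w <- capture_warnings(fit_behavior_model(trk))
  expect_true(any(grepl("low separation", w)))
})

test_that("a posterior of exactly 0.5 is assigned to the low class", {
  sym <- list(weights = c(0.5, 0.5), means = c(0, 2), sds = c(1, 1))
  model <- structure(list(speed = sym, altitude = sym), class = "behavior_model")
  trk <- data.frame(ground_speed = 1, flight_altitude = 1)   # exact midpoint
  expect_equal(classify_behavior(trk, model)$behavior_class, "LL")
})

test_that("hourly subsampling keeps the nearest in-tolerance fix and is
           idempotent", {
  trk <- mk_track(seq(0, 3000, by = 500), rep(0, 7))  # fixes every 20 min
  h1 <- subsample_hourly(trk)
  expect_equal(as.numeric(format(h1$timestamp, "%M")), rep(0, nrow(h1)))
  expect_identical(subsample_hourly(h1), h1)
  # a fix 40 min past the hour is outside the +/-10 min tolerance
  lone <- mk_track(0, 0, t0 = "2021-06-01 05:40:00")
  expect_equal(nrow(subsample_hourly(lone)), 0)
})

test_that("commuting bouts are maximal runs of hourly HH fixes", {
  lab_track <- function(labels, gap_min = 60) {
    n <- length(labels)
    data.frame(individual_id = "a",
               timestamp = as.POSIXct("2021-06-01 00:00:00", tz = "UTC") +
                 (seq_len(n) - 1) * gap_min * 60,
               x = 0, y = 0, behavior_class = labels)
  }
  one <- extract_commuting_bouts(lab_track(c("HH", "HH", "HH")))
  expect_equal(nrow(one$bouts), 1)
  expect_equal(one$bouts$duration_hr, 2)
  expect_equal(one$bouts$n_points, 3)

  alt <- extract_commuting_bouts(lab_track(rep(c("HH", "LL"), 5)))
  expect_equal(nrow(alt$bouts), 0)   # isolated HH fixes never make a bout

  # a 2-h hole splits a run (gap above 75 min)
  tr <- lab_track(rep("HH", 6))
  tr$timestamp[4:6] <- tr$timestamp[4:6] + 3600
  two <- extract_commuting_bouts(tr)
  expect_equal(nrow(two$bouts), 2)
  # no point is claimed by two bouts
  expect_false(any(duplicated(two$points$timestamp)))
})

test_that("bout extraction recovers the simulated bout schedule", {
  cfg <- sim_config(seed = 23, n_individuals = 2L, extent_m = 60000, cell_m = 100,
                    pre_emigration_days = 2, post_emigration_weeks = 2L,
                    commute_gap_mean_hr = 10)
  world <- build_world(cfg)
  trk <- simulate_tracks(world)
  trk <- compute_flight_altitude(trk, world$dem, cfg$geoid_offset)
  trk <- compute_ground_speed(trk)
  model <- fit_behavior_model(trk)
  trk <- classify_behavior(trk, model)
  found <- extract_commuting_bouts(trk)
  # ground truth: apply the same run-length rule to the generating labels
  truth_tr <- trk
  truth_tr$behavior_class <- ifelse(trk$sim_behavior == "commute", "HH", "LL")
  truth <- extract_commuting_bouts(truth_tr)
  for (id in unique(trk$individual_id)) {
    n_found <- sum(found$bouts$individual_id == id)
    n_true <- sum(truth$bouts$individual_id == id)
    expect_lte(abs(n_found - n_true), 1)
  }
})
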