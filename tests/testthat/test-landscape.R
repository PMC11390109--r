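# Flyability prediction arithmetic, flyable-area counting, logistic growth
# of the area series, hotspot KDE, and serialization round trips.

test_that("zero coefficients predict flyability 0.5 everywhere", {
  terr <- toy_terrain(matrix(rnorm(25, 40, 10), 5, 5),
                      matrix(rgamma(25, 2, 0.01), 5, 5))
  fit <- manual_fit(c(tri = 0))
  fly <- predict_flyability(fit, terr, week = 3, mean_step_length = 500,
                            params = manual_params())
  expect_true(all(fly$values == 0.5))
  expect_error(predict_flyability(fit, terr, week = 0, 500, manual_params()),
               "week")
  expect_error(predict_flyability(fit, terr, week = 157, 500, manual_params()),
               "week")
})

test_that("predicted values equal hand-computed inverse logits", {
  tri <- matrix(c(10, 20, 30), 1, 3)
  dst <- matrix(c(100, 200, 300), 1, 3)
  terr <- toy_terrain(tri, dst)
  p <- manual_params(tri = c(20, 10), dist_ridge = c(200, 100),
                     step_length = c(1000, 500), week = c(50, 25))
  beta <- c(tri = 0.8, dist_ridge = -0.6, step_length = 0.4, tri_week = -0.3)
  fit <- manual_fit(beta)
  wk <- 75; msl <- 1500
  fly <- predict_flyability(fit, terr, wk, msl, p)
  ztri <- (tri - 20) / 10; zdst <- (dst - 200) / 100
  zlen <- (msl - 1000) / 500; zwk <- (wk - 50) / 25
  lp <- 0.8 * ztri - 0.6 * zdst + 0.4 * zlen - 0.3 * ztri * zwk
  expect_equal(fly$values, plogis(lp))
  # cell at the dataset means of everything predicts exactly 0.5
  fly_mid <- predict_flyability(fit, toy_terrain(matrix(20), matrix(200)),
                                50, 1000, p)
  expect_equal(fly_mid$values[1, 1], 0.5)
})

test_that("nodata cells propagate through prediction", {
  tri <- matrix(rnorm(9, 40, 5), 3, 3); tri[2, 2] <- NA
  terr <- toy_terrain(tri, matrix(500, 3, 3))
  fly <- predict_flyability(manual_fit(c(tri = 1)), terr, 1, 500, manual_params())
  expect_true(is.na(fly$values[2, 2]))
  expect_equal(sum(is.na(fly$values)), 1)
})

test_that("flyable area counts strict exceedances on the 100 m grid", {
  all1 <- raster_grid(matrix(1, 50, 50), 100)
  expect_equal(flyable_area(all1), 25)              # 2500 cells x 0.01 km2
  at_thr <- raster_grid(matrix(0.7, 10, 10), 100)
  expect_equal(flyable_area(at_thr), 0)             # strictly above only
  set.seed(501)
  v <- matrix(runif(400), 20, 20); v[3, 3] <- NA
  g <- raster_grid(v, 100)
  expect_equal(flyable_area(g, 0.6), sum(v > 0.6, na.rm = TRUE) * 0.01)
  expect_error(flyable_area(raster_grid(v, 50)), "100 m")
})

test_that("flyable area is monotone non-increasing in the threshold", {
  set.seed(502)
  g <- raster_grid(matrix(runif(900), 30, 30), 100)
  areas <- vapply(seq(0.1, 0.9, by = 0.1), function(th) flyable_area(g, th), 0)
  expect_true(all(diff(areas) <= 0))
})

test_that("logistic growth recovery, degenerate series, and fold change", {
  set.seed(503)
  wk <- 1:120
  truth <- 80 / (1 + exp(-0.1 * (wk - 30)))
  g <- area_growth(wk, truth * (1 + rnorm(120, 0, 0.01)))
  expect_false(g$no_fit)
  expect_lt(abs(g$A - 80) / 80, 0.05)
  expect_lt(abs(g$k - 0.1) / 0.1, 0.05)
  expect_lt(abs(g$t0 - 30) / 30, 0.05)

  flat <- area_growth(1:20, rep(5, 20))
  expect_true(flat$no_fit || flat$degenerate)

  ramp <- area_growth(1:30, c(1, seq(2, 100, length.out = 28), 2170))
  expect_equal(ramp$fold_change, 2170)

  zero_start <- area_growth(1:12, c(0, 1:11))
  expect_true(zero_start$fold_undefined)
  expect_true(is.na(zero_start$fold_change))
})

test_that("weekly mean step lengths borrow the global mean when sparse", {
  steps <- data.frame(step_length = c(rep(100, 10), rep(900, 2)),
                      week = c(rep(1, 10), rep(2, 2)))
  msl <- weekly_mean_step_length(steps, 1:3, min_steps = 5)
  glob <- mean(steps$step_length)
  expect_equal(msl$mean_step_length, c(100, glob, glob))
  expect_equal(msl$n_steps, c(10L, 2L, 0L))
})

test_that("hotspot density peaks at a single flyable cell and integrates to 1", {
  v <- matrix(0.1, 15, 15); v[8, 8] <- 0.9
  g <- raster_grid(v, 100)
  d <- hotspot_density(g)
  expect_equal(which.max(d$values), which(v == 0.9))
  expect_equal(sum(d$values) * 100^2, 1, tolerance = 1e-9)
  expect_error(hotspot_density(raster_grid(matrix(0.1, 5, 5), 100)), "no flyable")
})

test_that("hotspot density matches a brute-force KDE and respects symmetry", {
  v <- matrix(0, 21, 21)
  v[5:6, 5:6] <- 1; v[16:17, 16:17] <- 1   # two identical distant clusters
  g <- raster_grid(v, 100)
  bw <- c(200, 200)
  d <- hotspot_density(g, threshold = 0.5, bandwidth = bw)
  ref <- kde_brute(raster_grid(v, 100), bw)
  expect_equal(d$values, ref, tolerance = 1e-6)
  expect_equal(d$values[5, 5], d$values[17, 17], tolerance = 1e-9)

  # near-uniform mask: interior density is near-flat
  u <- raster_grid(matrix(1, 40, 40), 100)
  du <- hotspot_density(u, threshold = 0.5, bandwidth = c(300, 300))
  inner <- du$values[15:26, 15:26]
  expect_lt(max(inner) / min(inner), 1.2)
})

test_that("a serialized fit reproduces the same prediction map", {
  rec <- small_recovery()
  terr <- small_world()$terrain
  fly1 <- predict_flyability(rec$fit, terr, 5, 5000, rec$params)
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(ssf_fit_to_list(rec$fit, rec$params), path,
                       auto_unbox = TRUE, digits = NA)
  back <- ssf_fit_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
  fly2 <- predict_flyability(back$fit, terr, 5, 5000, back$params)
  expect_equal(fly2$values, fly1$values, tolerance = 1e-12)
})
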