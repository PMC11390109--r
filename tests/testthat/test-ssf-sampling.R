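# Movement-kernel fitting, random-step generation, covariate annotation and
# the z-transform / correlation screen.

test_that("turning angles are counter-clockwise positive relative to the
           previous bearing", {
  # east, then north: a +pi/2 (left/CCW) turn
  pts <- data.frame(individual_id = "a", bout_id = 1,
                    timestamp = as.POSIXct("2021-06-01", tz = "UTC") + (0:2) * 3600,
                    x = c(0, 1000, 1000), y = c(0, 0, 1000), week = 1L)
  st <- steps_from_bouts(pts)
  expect_equal(st$bearing, c(0, pi / 2))
  expect_equal(st$turning_angle, c(NA, pi / 2))
  expect_equal(st$step_length, c(1000, 1000))
  # east, then south: a -pi/2 (right/CW) turn
  pts$y <- c(0, 0, -1000)
  expect_equal(steps_from_bouts(pts)$turning_angle[2], -pi / 2)
})

test_that("gamma and von Mises MLEs recover generating parameters", {
  set.seed(401)
  st <- data.frame(step_length = rgamma(10000, shape = 2, scale = 500),
                   turning_angle = runif(10000, -pi, pi))
  k <- fit_movement_kernels(st)
  expect_gt(k$gamma_shape, 1.9); expect_lt(k$gamma_shape, 2.1)
  expect_gt(k$gamma_scale, 475); expect_lt(k$gamma_scale, 525)
  expect_lt(k$vm_kappa, 0.05)          # uniform angles imply kappa -> 0

  set.seed(402)
  st2 <- data.frame(step_length = rgamma(5000, 36, scale = 1200),
                    turning_angle = rvonmises(5000, 0, 2))
  k2 <- fit_movement_kernels(st2)
  expect_lt(abs(k2$vm_kappa - 2) / 2, 0.1)
  expect_lt(abs(k2$gamma_shape - 36) / 36, 0.05)
})

test_that("degenerate angles cap kappa with a warning; stationary data error", {
  st <- data.frame(step_length = rgamma(100, 2, scale = 500),
                   turning_angle = rep(0, 100))
  expect_warning(k <- fit_movement_kernels(st), "capped")
  expect_equal(k$vm_kappa, 500)

  stale <- data.frame(step_length = c(rep(0, 80), rgamma(20, 2, scale = 500)),
                      turning_angle = runif(100, -pi, pi))
  expect_error(fit_movement_kernels(stale), "stationary")
})

test_that("strata have exactly one used and 50 alternative rows sharing the
           start point and week", {
  rec <- small_recovery()
  strata <- rec$strata
  sizes <- table(strata$stratum_id)
  expect_true(all(sizes == 51))
  used_per <- tapply(strata$used, strata$stratum_id, sum)
  expect_true(all(used_per == 1))
  expect_true(all(tapply(strata$x1, strata$stratum_id,
                         function(v) length(unique(v))) == 1))
  expect_true(all(tapply(strata$week, strata$stratum_id,
                         function(v) length(unique(v))) == 1))
})

test_that("alternative draws are reproducible and follow the kernels", {
  ker <- movement_kernels(2, 500, 0, 1)
  set.seed(77)
  a1 <- generate_random_steps(0, 0, 0.3, ker, 50)
  set.seed(77)
  a2 <- generate_random_steps(0, 0, 0.3, ker, 50)
  expect_identical(a1, a2)

  set.seed(403)
  many <- generate_random_steps(0, 0, 0.3, ker, 10000)
  ks <- suppressWarnings(stats::ks.test(many$step_length, stats::pgamma,
                                        shape = 2, scale = 500))
  expect_gt(ks$p.value, 0.01)
})

test_that("a near-degenerate kernel yields collinear alternatives", {
  ker <- movement_kernels(1e8, 5000 / 1e8, 0, 500)   # ~fixed length, kappa cap
  set.seed(404)
  alt <- generate_random_steps(0, 0, 0.7, ker, 50)
  bear <- atan2(alt$y, alt$x)
  expect_lt(max(abs(bear - 0.7)), 0.3)
  expect_lt(max(abs(alt$step_length - 5000)) / 5000, 0.01)
})

test_that("z-transform equals hand-computed (x - mean)/sd and records params", {
  strata <- data.frame(stratum_id = rep(1:3, each = 3),
                       individual_id = "a", used = rep(c(1, 0, 0), 3),
                       tri = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                       dist_ridge = c(9:1), step_length = rep(c(100, 200, 300), 3),
                       week = rep(c(1, 5, 9), each = 3))
  ann <- annotate_and_transform(strata)
  expect_equal(ann$strata$z_tri, (strata$tri - mean(strata$tri)) / sd(strata$tri))
  expect_equal(ann$strata$z_week, (strata$week - mean(strata$week)) / sd(strata$week))
  expect_equal(ann$params$tri[["mean"]], mean(strata$tri))
  # the dataset maximum has the maximum z-score
  expect_equal(which.max(ann$strata$z_tri), which.max(strata$tri))

  # externally supplied constants are applied unchanged
  p <- manual_params(tri = c(5, 2))
  ann2 <- annotate_and_transform(strata, params = p)
  expect_equal(ann2$strata$z_tri, (strata$tri - 5) / 2)

  const <- strata; const$tri <- 1
  expect_error(annotate_and_transform(const), "constant")
})

test_that("correlation screen flags |r| >= 0.5 pairs and passes independent
           covariates", {
  set.seed(405)
  d <- data.frame(tri = rnorm(10000), dist_ridge = rnorm(10000),
                  step_length = rnorm(10000), week = rnorm(10000))
  sc <- correlation_screen(d)
  expect_equal(nrow(sc$flagged), 0)
  expect_true(all(abs(sc$matrix[upper.tri(sc$matrix)]) < 0.1))

  d$dist_ridge <- d$tri                      # duplicated covariate
  sc2 <- correlation_screen(d)
  expect_true(any(sc2$flagged$r == 1))
  d$dist_ridge <- -d$tri                     # perfectly anti-correlated
  sc3 <- correlation_screen(d)
  expect_true(any(sc3$flagged$r == -1))
})
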