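# Shared synthetic worlds and derived datasets, built once per test run.
# Small worlds use a proportionally scaled-down movement kernel so that steps
# fit the extent; the full-scale study world keeps the package defaults.

.world_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .world_cache)) assign(key, force(expr), envir = .world_cache)
  get(key, envir = .world_cache)
}

# 40 km world, 100 m cells, ~5.4 km hourly steps: fast all-purpose fixture.
small_world <- function() cached("small_world", {
  build_world(sim_config(
    seed = 42, n_individuals = 6, extent_m = 40000, cell_m = 100,
    gamma_shape = 36, gamma_scale = 150, post_emigration_weeks = 10,
    commute_gap_mean_hr = 30))
})

# Steps, strata and fixed-effects fit on the small world (generating kernels,
# world-level z constants): the small recovery dataset.
small_recovery <- function() cached("small_recovery", {
  world <- small_world()
  recovery_replicate(world, seed = 42)
})

# Hand-sized terrain stack on the 100 m analysis grid, for prediction tests.
toy_terrain <- function(tri_vals, dist_vals, cell = 100) {
  structure(list(
    tri_agg = raster_grid(tri_vals, cell),
    dist_ridge_agg = raster_grid(dist_vals, cell),
    params = list(target_cell_m = cell)),
    class = "terrain_layers")
}

# An ssf_fit with hand-set coefficients (NA-filled elsewhere), for oracle
# tests of prediction and RMSE arithmetic.
manual_fit <- function(beta) {
  terms <- ssf_terms()
  cf <- setNames(rep(0, length(terms)), terms)
  cf[names(beta)] <- beta
  structure(list(coefficients = cf, se = cf * NA, ci_lower = cf * NA,
                 ci_upper = cf * NA, vcov = NULL, loglik = NA_real_,
                 null_loglik = NA_real_, converged = TRUE, iterations = 0L,
                 dropped_terms = character(), n_strata = 0L,
                 random_effects = NULL, method = "manual"),
            class = "ssf_fit")
}

manual_params <- function(tri = c(0, 1), dist_ridge = c(0, 1),
                          step_length = c(0, 1), week = c(0, 1)) {
  transform_params(tri, dist_ridge, step_length, week)
}
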