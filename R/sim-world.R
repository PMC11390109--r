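#' Generate a synthetic ridged elevation model
#'
#' The elevation field is a superposition of straight ridge crests with
#' Gaussian cross-sections (random position, orientation, amplitude, and
#' width) on top of smooth low-frequency noise (a coarse Gaussian field,
#' bilinearly interpolated to the DEM grid). Deterministic given the config
#' seed.
#'
#' @param config a [sim_config()].
#' @return a `raster_grid` DEM; the drawn ridge parameters are attached as
#'   attribute `"ridges"` (data frame with columns `x0`, `y0`, `theta`,
#'   `amp`, `width`).
#' @export
generate_dem <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$extent_m; cell <- config$cell_m
  if (L <= 0 || cell <= 0) stop("non-positive extent or cell size")
  n <- as.integer(round(L / cell))
  if (n < 3) stop("extent too small for the cell size")
  with_seed(derive_seed(config$seed, 1L), {
    nr <- config$n_ridges
    ridges <- data.frame(
      x0 = runif(nr, 0.1 * L, 0.9 * L),
      y0 = runif(nr, 0.1 * L, 0.9 * L),
      theta = runif(nr, 0, pi),
      amp = config$ridge_amp_m * runif(nr, 0.6, 1),
      width = config$ridge_width_m * runif(nr, 0.7, 1.3))
    xs <- (seq_len(n) - 0.5) * cell
    ys <- L - (seq_len(n) - 0.5) * cell
    X <- matrix(xs, n, n, byrow = TRUE)
    Y <- matrix(ys, n, n)
    elev <- matrix(1500, n, n)
    if (nr > 0 && config$ridge_amp_m > 0) {
      for (i in seq_len(nr)) {
        # perpendicular distance to the crest line through (x0, y0) at angle theta
        d <- abs((X - ridges$x0[i]) * sin(ridges$theta[i]) -
                 (Y - ridges$y0[i]) * cos(ridges$theta[i]))
        elev <- elev + ridges$amp[i] * exp(-d^2 / (2 * ridges$width[i]^2))
      }
    }
    if (config$noise_amp_m > 0) {
      m <- max(4L, as.integer(ceiling(L / 10000)) + 2L)
      G <- matrix(rnorm(m * m, 0, config$noise_amp_m), m, m)
      # bilinear interpolation of the coarse field onto cell centres
      u <- as.vector(X / L) * (m - 1) + 1
      v <- as.vector((L - Y) / L) * (m - 1) + 1
      i0 <- pmin(floor(v), m - 1); j0 <- pmin(floor(u), m - 1)
      fv <- v - i0; fu <- u - j0
      noise <- G[cbind(i0, j0)] * (1 - fu) * (1 - fv) +
        G[cbind(i0, j0 + 1)] * fu * (1 - fv) +
        G[cbind(i0 + 1, j0)] * (1 - fu) * fv +
        G[cbind(i0 + 1, j0 + 1)] * fu * fv
      elev <- elev + matrix(noise, n, n)
    }
    dem <- raster_grid(elev, cell_size = cell, origin_x = 0, origin_y = L)
    attr(dem, "ridges") <- ridges
    dem
  })
}

#' Place nests for the simulated individuals
#'
#' Nests are drawn uniformly over the central half of the world so that the
#' pre-emigration bounded walk never reaches the raster edge.
#'
#' @param config a [sim_config()].
#' @return data frame with `individual_id`, `x`, `y`.
#' @export
place_nests <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$extent_m
  with_seed(derive_seed(config$seed, 2L), {
    data.frame(
      individual_id = sprintf("bird%02d", seq_len(config$n_individuals)),
      x = runif(config$n_individuals, 0.25 * L, 0.75 * L),
      y = runif(config$n_individuals, 0.25 * L, 0.75 * L),
      stringsAsFactors = FALSE)
  })
}

#' z-transform constants
#'
#' Per-covariate mean and SD used to place covariates on the z-scale. The
#' synthetic world records world-level constants at generation time (grid
#' moments for the terrain layers, kernel moments for step length, the
#' tracked week range for week) so that the ground-truth coefficients have a
#' defined scale; the analysis pipeline computes the same structure from the
#' used+available dataset.
#'
#' @param tri,dist_ridge,step_length,week length-2 vectors `c(mean, sd)`.
#' @return a `transform_params` object.
#' @export
transform_params <- function(tri, dist_ridge, step_length, week) {
  p <- list(tri = tri, dist_ridge = dist_ridge,
            step_length = step_length, week = week)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (length(v) != 2 || !all(is.finite(v))) stop("bad transform entry: ", nm)
    if (v[2] <= 0) stop("z-transform SD must be positive for ", nm)
    names(p[[nm]]) <- c("mean", "sd")
  }
  structure(p, class = "transform_params")
}

z_apply <- function(params, var, x) (x - params[[var]][["mean"]]) / params[[var]][["sd"]]

#' Build the full synthetic world
#'
#' Generates the DEM, derives the terrain layers on the analysis grid, places
#' the nests, and records the world-level z-transform constants.
#'
#' @param config a [sim_config()].
#' @param inner_radius_m,outer_radius_m,ridge_sd_threshold,target_cell_m
#'   terrain-layer parameters (see [terrain_layers()]).
#' @return a `sim_world` list: `config`, `dem`, `terrain`, `nests`, `tparams`.
#' @export
build_world <- function(config, inner_radius_m = 10, outer_radius_m = 200,
                        ridge_sd_threshold = 1.0, target_cell_m = 100) {
  dem <- generate_dem(config)
  terrain <- terrain_layers(dem, inner_radius_m, outer_radius_m,
                            ridge_sd_threshold, target_cell_m)
  nests <- place_nests(config)
  tri_v <- terrain$tri_agg$values[is.finite(terrain$tri_agg$values)]
  dst_v <- terrain$dist_ridge_agg$values[is.finite(terrain$dist_ridge_agg$values)]
  wk <- seq_len(config$post_emigration_weeks)
  tparams <- transform_params(
    tri = c(mean(tri_v), stats::sd(tri_v)),
    dist_ridge = c(mean(dst_v), stats::sd(dst_v)),
    step_length = c(config$gamma_shape * config$gamma_scale,
                    sqrt(config$gamma_shape) * config$gamma_scale),
    week = c(mean(wk), stats::sd(wk)))
  structure(list(config = config, dem = dem, terrain = terrain,
                 nests = nests, tparams = tparams),
            class = "sim_world")
}

#' Reuse a world's terrain under a different agent configuration
#'
#' Terrain generation is the expensive part of [build_world()]; this swaps
#' the agent-level configuration (individuals, weeks, schedules, kernels,
#' coefficients) while keeping the already-computed DEM and terrain layers.
#' The world geometry (seed, extent, cell size, ridge parameters) must be
#' unchanged. Nests and the z-transform constants are recomputed.
#'
#' @param world a [build_world()] result.
#' @param config a [sim_config()] sharing the world-geometry fields.
#' @return a `sim_world` with the new configuration.
#' @export
reconfigure_world <- function(world, config) {
  stopifnot(inherits(world, "sim_world"), inherits(config, "sim_config"))
  old <- world$config
  for (f in c("seed", "extent_m", "cell_m", "n_ridges", "ridge_amp_m",
              "ridge_width_m", "noise_amp_m"))
    if (!identical(as.numeric(old[[f]]), as.numeric(config[[f]])))
      stop("world geometry field '", f, "' differs; rebuild the world instead")
  world$config <- config
  world$nests <- place_nests(config)
  wk <- seq_len(config$post_emigration_weeks)
  world$tparams$step_length <- c(
    mean = config$gamma_shape * config$gamma_scale,
    sd = sqrt(config$gamma_shape) * config$gamma_scale)
  world$tparams$week <- c(mean = mean(wk), sd = stats::sd(wk))
  world
}

#' @export
print.sim_world <- function(x, ...) {
  cat("sim_world:\n")
  print(x$config)
  print(x$terrain)
  invisible(x)
}
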