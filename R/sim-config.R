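#' Default ground-truth selection coefficients for the synthetic world
#'
#' Named on the z-scale of the step-selection design. The sign pattern mirrors
#' a juvenile soaring bird: preference for rugged terrain (`tri` +) close to
#' ridge lines (`dist_ridge` -) and for long steps (`step_length` +), with the
#' terrain preferences attenuating (`tri_week` -, `dist_week` +) and the
#' step-length preference strengthening (`step_week` +) as the bird ages.
#'
#' @return named numeric vector over the design terms (week main effect is
#'   stratum-constant and carries no selection, so it is absent).
#' @export
default_true_beta <- function() {
  c(tri = 0.8, dist_ridge = -0.8, step_length = 0.5,
    tri_step = 0.15, dist_step = -0.15,
    tri_week = -0.4, dist_week = 0.4, step_week = 0.35,
    tri_step_week = -0.15, dist_step_week = 0.15)
}

#' Configuration of the synthetic world and its agents
#'
#' Bundles every parameter of the synthetic data generator: terrain geometry,
#' movement kernels, the ground-truth selection coefficients, the behavioural
#' (commuting / non-commuting) mixture, and the sampling schedule. Defaults
#' describe the study conditions used throughout the package: 20 individuals
#' tracked for 100 weeks after emigration at one fix per 20 min, commuting in
#' bouts averaging 3 h so that a run yields roughly 4,000 observed commuting
#' steps (strata).
#'
#' @param seed integer master seed; every stochastic output derives from it.
#' @param n_individuals number of simulated birds.
#' @param extent_m side length of the square world (m).
#' @param cell_m DEM cell size (m); must divide `target_cell_m`.
#' @param n_ridges number of terrain ridge crests.
#' @param ridge_amp_m typical crest amplitude (m).
#' @param ridge_width_m Gaussian cross-section SD of the crests (m).
#' @param noise_amp_m SD of the smooth low-frequency elevation noise (m).
#' @param true_beta named ground-truth coefficients on the z-scale.
#' @param gamma_shape,gamma_scale hourly step-length kernel (scale in m). The
#'   defaults give hourly commuting displacements of 43.2 +/- 7.2 km,
#'   consistent with the commuting ground-speed class below.
#' @param vm_kappa turning-angle concentration within a commuting bout.
#' @param fix_interval_min GPS fix cadence (min); must divide 60.
#' @param pre_emigration_days days of natal-territory residency before emigration.
#' @param post_emigration_weeks tracked weeks after emigration (<= 156).
#' @param commute_bout_mean_hr mean commuting-bout duration (h, geometric).
#' @param commute_gap_mean_hr mean non-commuting gap between bouts (h, geometric).
#' @param speed_commute,speed_other mean/SD (m/s) of the ground-speed classes.
#' @param alt_commute,alt_other mean/SD (m) of the flight-altitude classes.
#' @param altitude_noise_sd GPS vertical noise SD (m).
#' @param geoid_offset geoid undulation above the ellipsoid (m), constant.
#' @param nest_radius_m radius of the pre-emigration bounded walk (m).
#' @param n_candidates candidate endpoints per simulated step decision. Large
#'   enough that selecting among candidates is indistinguishable from the
#'   kernel-times-exp(beta z) target density, yet unrelated to the analysis'
#'   50 alternatives.
#' @param rs_sd_tri,rs_sd_dist between-individual SDs of the `tri` and
#'   `dist_ridge` coefficients (0 = no individual variation).
#' @param start_date UTC date of tagging.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_individuals = 20L,
                       extent_m = 160000,
                       cell_m = 50,
                       n_ridges = 8L,
                       ridge_amp_m = 900,
                       ridge_width_m = 1200,
                       noise_amp_m = 150,
                       true_beta = default_true_beta(),
                       gamma_shape = 36,
                       gamma_scale = 1200,
                       vm_kappa = 1,
                       fix_interval_min = 20L,
                       pre_emigration_days = 30,
                       post_emigration_weeks = 100L,
                       commute_bout_mean_hr = 3,
                       commute_gap_mean_hr = 250,
                       speed_commute = c(mean = 12, sd = 2),
                       speed_other = c(mean = 1, sd = 0.5),
                       alt_commute = c(mean = 300, sd = 80),
                       alt_other = c(mean = 20, sd = 15),
                       altitude_noise_sd = 10,
                       geoid_offset = 48,
                       nest_radius_m = 3000,
                       n_candidates = 3000L,
                       rs_sd_tri = 0,
                       rs_sd_dist = 0,
                       start_date = "2021-03-01") {
  cfg <- as.list(environment())
  if (extent_m <= 0 || cell_m <= 0) stop("extent_m and cell_m must be positive")
  if (gamma_shape <= 0 || gamma_scale <= 0) stop("gamma kernel parameters must be positive")
  if (vm_kappa < 0) stop("vm_kappa must be >= 0")
  if (60 %% fix_interval_min != 0) stop("fix_interval_min must divide 60")
  if (post_emigration_weeks > 156) stop("post_emigration_weeks must be <= 156")
  if (speed_commute[["mean"]] <= speed_other[["mean"]] ||
      alt_commute[["mean"]] <= alt_other[["mean"]])
    stop("commuting class means must exceed the non-commuting class means")
  missing_terms <- setdiff(names(default_true_beta()), names(true_beta))
  if (length(missing_terms))
    stop("true_beta lacks terms: ", paste(missing_terms, collapse = ", "))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: seed %d, %d individuals, %d weeks post-emigration\n",
              x$seed, x$n_individuals, x$post_emigration_weeks))
  cat(sprintf("  world: %g km square, %g m DEM cells, %d ridges\n",
              x$extent_m / 1000, x$cell_m, x$n_ridges))
  cat(sprintf("  kernels: gamma(%g, %g m), von Mises kappa %g\n",
              x$gamma_shape, x$gamma_scale, x$vm_kappa))
  invisible(x)
}
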