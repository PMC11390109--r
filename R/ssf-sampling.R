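# Step-selection sampling: observed steps from commuting bouts, movement
# kernels (gamma lengths, von Mises turns), 50 random alternatives per
# observed step, covariate annotation from the 100 m terrain layers, and the
# z-transform / correlation screen that precede modeling.

#' Build observed steps from hourly commuting-bout points
#'
#' Each pair of consecutive hourly fixes within a bout is one step. Bearings
#' are planar; the turning angle (counter-clockwise positive) is relative to
#' the previous step within the same bout and is undefined for bout-initial
#' steps.
#'
#' @param points hourly bout fixes with `individual_id`, `bout_id`,
#'   `timestamp`, `x`, `y`, and (if available) `week`.
#' @return data frame of steps: `x1`, `y1`, `x2`, `y2`, `step_length` (m),
#'   `bearing`, `turning_angle` (rad, NA for bout-initial), `week`.
#' @export
steps_from_bouts <- function(points) {
  need <- c("individual_id", "bout_id", "timestamp", "x", "y")
  if (!all(need %in% names(points))) stop("missing bout-point columns")
  parts <- split(points, list(points$individual_id, points$bout_id), drop = TRUE)
  out <- lapply(parts, function(p) {
    p <- p[order(p$timestamp), , drop = FALSE]
    n <- nrow(p)
    if (n < 2) return(NULL)
    b <- atan2(diff(p$y), diff(p$x))
    data.frame(
      individual_id = p$individual_id[1], bout_id = p$bout_id[1],
      t_start = p$timestamp[-n],
      x1 = p$x[-n], y1 = p$y[-n], x2 = p$x[-1], y2 = p$y[-1],
      step_length = sqrt(diff(p$x)^2 + diff(p$y)^2),
      bearing = wrap_angle(b),
      turning_angle = c(NA_real_, wrap_angle(diff(b))),
      week = if ("week" %in% names(p)) p$week[-n] else NA_integer_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit the movement kernels to observed steps
#'
#' Maximum-likelihood gamma fit to the step lengths (all steps) and von
#' Mises fit to the turning angles (steps with a defined turning angle, i.e.
#' excluding bout-initial steps).
#'
#' @param steps data frame with `step_length` and `turning_angle`.
#' @param kappa_max cap for the von Mises concentration (degenerate angles).
#' @return a `movement_kernels` list: `gamma_shape`, `gamma_scale` (m),
#'   `vm_mu`, `vm_kappa`, `n_steps`, `n_angles`.
#' @export
fit_movement_kernels <- function(steps, kappa_max = 500) {
  len <- steps$step_length[is.finite(steps$step_length)]
  ang <- steps$turning_angle[is.finite(steps$turning_angle)]
  if (length(ang) < 30) stop("need at least 30 steps with defined turning angles")
  if (mean(len == 0) > 0.5) stop("more than half of the steps have zero length: stationary data")
  len_pos <- len[len > 0]
  m <- mean(len_pos); v <- stats::var(len_pos)
  fit_g <- fitdistrplus::fitdist(
    len_pos, "gamma", method = "mle",
    start = list(shape = m^2 / v, rate = m / v),
    lower = c(1e-8, 1e-12))
  fit_vm <- fit_vonmises(ang, kappa_max)
  structure(list(
    gamma_shape = unname(fit_g$estimate[["shape"]]),
    gamma_scale = 1 / unname(fit_g$estimate[["rate"]]),
    vm_mu = fit_vm$mu, vm_kappa = fit_vm$kappa,
    n_steps = length(len), n_angles = length(ang)),
    class = "movement_kernels")
}

#' @export
print.movement_kernels <- function(x, ...) {
  cat(sprintf("movement_kernels: gamma(shape %.3g, scale %.4g m), von Mises(mu %.3f, kappa %.3g)\n",
              x$gamma_shape, x$gamma_scale, x$vm_mu, x$vm_kappa))
  cat(sprintf("  fitted on %d steps (%d with turning angles)\n", x$n_steps, x$n_angles))
  invisible(x)
}

#' Movement kernels from known parameters
#'
#' Wraps known gamma / von Mises parameters (e.g. a synthetic world's
#' generating kernels) in the structure returned by [fit_movement_kernels()].
#'
#' @param gamma_shape,gamma_scale gamma step-length kernel (scale in m).
#' @param vm_mu,vm_kappa von Mises turning-angle kernel.
#' @export
movement_kernels <- function(gamma_shape, gamma_scale, vm_mu = 0, vm_kappa = 1) {
  stopifnot(gamma_shape > 0, gamma_scale > 0, vm_kappa >= 0)
  structure(list(gamma_shape = gamma_shape, gamma_scale = gamma_scale,
                 vm_mu = vm_mu, vm_kappa = vm_kappa,
                 n_steps = NA_integer_, n_angles = NA_integer_),
            class = "movement_kernels")
}

#' Generate the random alternative steps for one observed step
#'
#' Draws `n` endpoints from the movement kernels, sharing the observed
#' step's start point: length ~ gamma, bearing = previous bearing + von
#' Mises turn (uniform bearing when the previous bearing is undefined).
#' Endpoints outside the reference raster extent (or on nodata cells) are
#' redrawn.
#'
#' @param x1,y1 shared start point (m).
#' @param prev_bearing bearing of the previous observed step (rad) or NA.
#' @param kernels a `movement_kernels` object.
#' @param n number of alternatives (50 in the standard design).
#' @param ref a `raster_grid` delimiting valid endpoints.
#' @param max_rounds redraw rounds before giving up.
#' @return data frame with `x`, `y`, `step_length`, `turning_angle`.
#' @export
generate_random_steps <- function(x1, y1, prev_bearing, kernels, n = 50,
                                  ref = NULL, max_rounds = 1000) {
  need <- n
  xs <- ys <- ls <- tu <- numeric(0)
  rounds <- 0
  while (need > 0) {
    rounds <- rounds + 1
    if (rounds > max_rounds) stop("could not place alternative endpoints inside the extent")
    l <- rgamma(need, shape = kernels$gamma_shape, scale = kernels$gamma_scale)
    if (is.na(prev_bearing)) {
      b <- runif(need, -pi, pi); turn <- rep(NA_real_, need)
    } else {
      turn <- rvonmises(need, kernels$vm_mu, kernels$vm_kappa)
      b <- prev_bearing + turn
    }
    xe <- x1 + l * cos(b); ye <- y1 + l * sin(b)
    ok <- if (is.null(ref)) rep(TRUE, need) else is.finite(rg_sample(ref, xe, ye))
    k <- sum(ok)
    if (k > 0) {
      xs <- c(xs, xe[ok]); ys <- c(ys, ye[ok]); ls <- c(ls, l[ok]); tu <- c(tu, turn[ok])
      need <- need - k
    }
  }
  data.frame(x = xs[seq_len(n)], y = ys[seq_len(n)],
             step_length = ls[seq_len(n)], turning_angle = tu[seq_len(n)])
}

#' Build the stratified used/available dataset
#'
#' For every observed step, generates `n_alternatives` random steps sharing
#' its start point, individual, and week, and annotates every end point with
#' TRI and distance-to-ridge from the 100 m terrain layers. Alternatives
#' whose endpoint falls on nodata are redrawn; strata whose used endpoint
#' falls on nodata are dropped with a warning.
#'
#' @param steps observed steps (see [steps_from_bouts()]).
#' @param kernels a `movement_kernels` object.
#' @param terrain a [terrain_layers()] stack (the aggregated layers are used).
#' @param n_alternatives alternatives per stratum (default 50).
#' @return data frame with one used row (`used = 1`) plus `n_alternatives`
#'   available rows per stratum; columns `stratum_id`, `individual_id`,
#'   `used`, `x1`, `y1`, `x`, `y`, `step_length`, `turning_angle`, `week`,
#'   `tri`, `dist_ridge`.
#' @export
build_strata <- function(steps, kernels, terrain, n_alternatives = 50) {
  stopifnot(inherits(kernels, "movement_kernels"), inherits(terrain, "terrain_layers"))
  ref <- terrain$tri_agg
  used_tri <- rg_sample(terrain$tri_agg, steps$x2, steps$y2)
  used_dst <- rg_sample(terrain$dist_ridge_agg, steps$x2, steps$y2)
  drop <- !is.finite(used_tri) | !is.finite(used_dst)
  if (any(drop)) {
    warning(sum(drop), " strata dropped: used endpoint on nodata")
    steps <- steps[!drop, , drop = FALSE]
    used_tri <- used_tri[!drop]; used_dst <- used_dst[!drop]
  }
  S <- nrow(steps)
  if (!S) stop("no observed steps left to stratify")
  # previous bearing of each step: bearing minus its own turn (bout-initial NA)
  prev_b <- ifelse(is.na(steps$turning_angle), NA_real_,
                   steps$bearing - steps$turning_angle)
  out <- vector("list", S)
  for (s in seq_len(S)) {
    alt <- generate_random_steps(steps$x1[s], steps$y1[s], prev_b[s],
                                 kernels, n_alternatives, ref)
    out[[s]] <- data.frame(
      stratum_id = s,
      individual_id = steps$individual_id[s],
      used = c(1L, rep(0L, n_alternatives)),
      x1 = steps$x1[s], y1 = steps$y1[s],
      x = c(steps$x2[s], alt$x), y = c(steps$y2[s], alt$y),
      step_length = c(steps$step_length[s], alt$step_length),
      turning_angle = c(steps$turning_angle[s], alt$turning_angle),
      week = steps$week[s])
  }
  strata <- do.call(rbind, out)
  rownames(strata) <- NULL
  alt_rows <- strata$used == 0L
  strata$tri <- NA_real_; strata$dist_ridge <- NA_real_
  strata$tri[!alt_rows] <- used_tri
  strata$dist_ridge[!alt_rows] <- used_dst
  strata$tri[alt_rows] <- rg_sample(terrain$tri_agg, strata$x[alt_rows], strata$y[alt_rows])
  strata$dist_ridge[alt_rows] <- rg_sample(terrain$dist_ridge_agg,
                                           strata$x[alt_rows], strata$y[alt_rows])
  strata
}

#' z-transform the stratified dataset
#'
#' Adds `z_tri`, `z_dist_ridge`, `z_step_length`, `z_week` columns. By
#' default the transform constants (mean and SD per covariate) are computed
#' over the full used+available dataset and returned for prediction-time
#' reuse; externally supplied constants (e.g. a synthetic world's recorded
#' ones) are applied unchanged.
#'
#' @param strata a [build_strata()] result.
#' @param params optional [transform_params()]; computed from the data when NULL.
#' @return list with `strata` (z-scored) and `params`.
#' @export
annotate_and_transform <- function(strata, params = NULL) {
  vars <- c(tri = "tri", dist_ridge = "dist_ridge",
            step_length = "step_length", week = "week")
  if (is.null(params)) {
    ms <- lapply(vars, function(v) {
      x <- strata[[v]]
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0) stop("covariate ", v, " is constant: z-transform undefined")
      c(mean(x), s)
    })
    params <- transform_params(ms$tri, ms$dist_ridge, ms$step_length, ms$week)
  }
  for (v in vars)
    strata[[paste0("z_", v)]] <- z_apply(params, v, strata[[v]])
  list(strata = strata, params = params)
}

#' Correlation screen of the predictor variables
#'
#' Pearson correlations among the predictors over all rows of the stratified
#' dataset; pairs with `|r| >= threshold` are flagged (reported, not fatal).
#'
#' @param strata data frame containing the predictor columns.
#' @param vars predictor columns to screen.
#' @param threshold flag level (default 0.5).
#' @return list with the correlation `matrix`, a data frame of `flagged`
#'   pairs, and the `threshold`.
#' @export
correlation_screen <- function(strata,
                               vars = c("tri", "dist_ridge", "step_length", "week"),
                               threshold = 0.5) {
  vars <- intersect(vars, names(strata))
  if (length(vars) < 2) stop("need at least 2 covariates to screen")
  M <- stats::cor(strata[, vars], use = "pairwise.complete.obs")
  pairs <- which(upper.tri(M) & abs(M) >= threshold, arr.ind = TRUE)
  flagged <- data.frame(var1 = vars[pairs[, 1]], var2 = vars[pairs[, 2]],
                        r = M[pairs])
  list(matrix = M, flagged = flagged, threshold = threshold)
}
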