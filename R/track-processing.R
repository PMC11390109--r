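# Track segmentation: flight altitude above ground, ground speed from
# positions, two-class EM clustering of speed and altitude at the population
# level, hourly subsampling, and extraction of commuting bouts (>= 1 h of
# consecutive high-speed/high-altitude fixes).

#' Derive flight altitude above ground
#'
#' Altitude above mean sea level is the recorded height above the ellipsoid
#' minus the geoid undulation; flight altitude is that minus the ground
#' elevation sampled from the DEM at the containing cell. Fixes outside the
#' DEM extent are dropped with a warning.
#'
#' @param track data frame with `x`, `y`, `height_ellipsoid`.
#' @param dem a `raster_grid` elevation model.
#' @param geoid a `raster_grid` of geoid undulations or a single constant (m).
#' @return `track` with added `altitude_msl` and `flight_altitude`, excluding
#'   fixes outside the DEM.
#' @export
compute_flight_altitude <- function(track, dem, geoid = 0) {
  stopifnot(is.data.frame(track), inherits(dem, "raster_grid"))
  g <- if (inherits(geoid, "raster_grid")) rg_sample(geoid, track$x, track$y)
       else rep(as.numeric(geoid), nrow(track))
  ground <- rg_sample(dem, track$x, track$y)
  bad <- !is.finite(ground) | !is.finite(g)
  if (any(bad)) {
    warning(sum(bad), " fixes outside the DEM extent were excluded")
    track <- track[!bad, , drop = FALSE]
    ground <- ground[!bad]; g <- g[!bad]
  }
  track$altitude_msl <- track$height_ellipsoid - g
  track$flight_altitude <- track$altitude_msl - ground
  track
}

#' Ground speed from consecutive positions
#'
#' Speed at fix i is the planar distance from fix i-1 divided by the elapsed
#' time; the first fix of each individual inherits the second's value.
#'
#' @param track data frame with `individual_id`, `timestamp`, `x`, `y`,
#'   time-ordered within individual.
#' @return `track` with an added `ground_speed` column (m/s).
#' @export
compute_ground_speed <- function(track) {
  stopifnot(is.data.frame(track))
  parts <- split(track, track$individual_id)
  parts <- lapply(parts, function(tr) {
    if (nrow(tr) < 2) stop("need at least 2 fixes per individual")
    dt <- diff(as.numeric(tr$timestamp))
    if (any(dt <= 0)) stop("duplicate or non-increasing timestamps")
    d <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
    tr$ground_speed <- c(d[1] / dt[1], d / dt)
    tr
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

# Two-component 1-D Gaussian EM with percentile initialization. Restarts with
# perturbed means when a component collapses. Components are ordered so that
# component 2 ("high") has the larger mean.
em_gauss2 <- function(x, max_iter = 500, tol = 1e-8, max_restarts = 5) {
  x <- x[is.finite(x)]
  n <- length(x)
  run_em <- function(mu) {
    s <- rep(stats::sd(x), 2)
    w <- c(0.5, 0.5)
    ll_trace <- numeric(0)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      d1 <- w[1] * dnorm(x, mu[1], s[1])
      d2 <- w[2] * dnorm(x, mu[2], s[2])
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      ll <- sum(log(tot))
      ll_trace <- c(ll_trace, ll)
      r2 <- d2 / tot
      w <- c(mean(1 - r2), mean(r2))
      mu <- c(sum((1 - r2) * x) / sum(1 - r2), sum(r2 * x) / sum(r2))
      s <- sqrt(c(sum((1 - r2) * (x - mu[1])^2) / sum(1 - r2),
                  sum(r2 * (x - mu[2])^2) / sum(r2)))
      if (any(!is.finite(s)) || any(s < 1e-6)) return(NULL)
      if (abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    list(weights = w, means = mu, sds = s, loglik = ll_trace)
  }
  mu0 <- as.numeric(quantile(x, c(0.25, 0.75)))
  fit <- NULL
  for (attempt in 0:max_restarts) {
    mu_try <- if (attempt == 0) mu0 else mu0 + rnorm(2, 0, stats::sd(x) * 0.5 * attempt)
    fit <- run_em(sort(mu_try))
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("EM degenerate: a component variance collapsed after restarts")
  if (fit$means[1] > fit$means[2]) {  # order: component 2 = high
    fit$means <- rev(fit$means); fit$sds <- rev(fit$sds); fit$weights <- rev(fit$weights)
  }
  fit
}

# Posterior probability of the "high" component under a fitted 1-D mixture.
em_posterior_high <- function(fit, x) {
  d1 <- fit$weights[1] * dnorm(x, fit$means[1], fit$sds[1])
  d2 <- fit$weights[2] * dnorm(x, fit$means[2], fit$sds[2])
  out <- d2 / (d1 + d2)
  out[!is.finite(out)] <- as.numeric(x[!is.finite(out)] > mean(fit$means))
  out
}

#' Fit the population-level two-class behaviour model
#'
#' Independent two-component Gaussian EM on ground speed and on flight
#' altitude, pooled over all individuals. Each variable is split into a low
#' and a high class; the joint label of a point is one of LL, LH, HL, HH
#' (speed class first, altitude class second), and HH is interpreted as
#' commuting flight.
#'
#' @param track data frame with `ground_speed` and `flight_altitude`.
#' @return a `behavior_model` with elements `speed` and `altitude` (weights,
#'   means, SDs, log-likelihood trace per EM iteration).
#' @export
fit_behavior_model <- function(track) {
  ok <- is.finite(track$ground_speed) & is.finite(track$flight_altitude)
  if (sum(ok) < 100) stop("need at least 100 points with finite speed and altitude")
  model <- structure(
    list(speed = em_gauss2(track$ground_speed[ok]),
         altitude = em_gauss2(track$flight_altitude[ok])),
    class = "behavior_model")
  for (v in c("speed", "altitude")) {
    f <- model[[v]]
    if (diff(f$means) < 2 * max(f$sds))
      warning("low separation between the ", v, " mixture components")
  }
  model
}

#' @export
print.behavior_model <- function(x, ...) {
  for (v in c("speed", "altitude")) {
    f <- x[[v]]
    cat(sprintf("%s: low %.2f (sd %.2f, w %.2f) | high %.2f (sd %.2f, w %.2f)\n",
                v, f$means[1], f$sds[1], f$weights[1],
                f$means[2], f$sds[2], f$weights[2]))
  }
  invisible(x)
}

#' Label track points with the four-corner behaviour classes
#'
#' Maximum-posterior assignment per variable; a posterior of exactly 0.5 is
#' assigned to the low class.
#'
#' @param track data frame with `ground_speed` and `flight_altitude`.
#' @param model a [fit_behavior_model()] result.
#' @return `track` with an added `behavior_class` column (LL/LH/HL/HH).
#' @export
classify_behavior <- function(track, model) {
  hs <- em_posterior_high(model$speed, track$ground_speed) > 0.5
  ha <- em_posterior_high(model$altitude, track$flight_altitude) > 0.5
  track$behavior_class <- paste0(ifelse(hs, "H", "L"), ifelse(ha, "H", "L"))
  track$behavior_class[!is.finite(track$ground_speed) |
                       !is.finite(track$flight_altitude)] <- NA_character_
  track
}

#' Subsample a track to hourly resolution
#'
#' For each whole hour, keeps the fix nearest the hour mark within
#' `tol_min` minutes; hours without such a fix are empty. Idempotent.
#'
#' @param track data frame with `individual_id`, `timestamp`.
#' @param tol_min alignment tolerance (min).
#' @return the subsampled track.
#' @export
subsample_hourly <- function(track, tol_min = 10) {
  parts <- split(track, track$individual_id)
  parts <- lapply(parts, function(tr) {
    tt <- as.numeric(tr$timestamp)
    hr <- round(tt / 3600) * 3600
    off <- abs(tt - hr)
    keep <- off <= tol_min * 60
    tr <- tr[keep, , drop = FALSE]; hr <- hr[keep]; off <- off[keep]
    if (!nrow(tr)) return(tr)
    # nearest fix per hour mark (ties: earliest)
    ord <- order(hr, off, as.numeric(tr$timestamp))
    tr <- tr[ord, , drop = FALSE]; hr <- hr[ord]
    tr[!duplicated(hr), , drop = FALSE]
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$individual_id, out$timestamp), , drop = FALSE]
}

#' Extract commuting bouts (>= 1 h of consecutive hourly HH fixes)
#'
#' Subsamples to hourly resolution, then takes maximal runs of consecutive
#' HH-labelled hourly fixes (runs break at non-HH fixes or at gaps longer
#' than `max_gap_min`). Runs with at least two fixes — spanning at least one
#' hour of nonstop commuting flight — are kept as bouts.
#'
#' @param track labelled track (see [classify_behavior()]).
#' @param tol_min hourly alignment tolerance (min).
#' @param max_gap_min a run breaks when consecutive fixes are further apart.
#' @return list with `points` (hourly HH fixes with `bout_id`) and `bouts`
#'   (one row per bout: individual, start, end, duration in h, fix count).
#' @export
extract_commuting_bouts <- function(track, tol_min = 10, max_gap_min = 75) {
  if (!"behavior_class" %in% names(track)) stop("track must be labelled first")
  hourly <- subsample_hourly(track, tol_min)
  parts <- split(hourly, hourly$individual_id)
  pts <- list(); bouts <- list()
  next_id <- 1L
  for (tr in parts) {
    if (!nrow(tr)) next
    hh <- tr$behavior_class == "HH" & !is.na(tr$behavior_class)
    gap <- c(Inf, diff(as.numeric(tr$timestamp))) / 60
    new_run <- !hh | c(TRUE, !hh[-length(hh)]) | gap > max_gap_min
    run_id <- cumsum(new_run)
    for (rid in unique(run_id[hh])) {
      idx <- which(run_id == rid & hh)
      if (length(idx) < 2) next
      seg <- tr[idx, , drop = FALSE]
      seg$bout_id <- next_id
      pts[[length(pts) + 1L]] <- seg
      bouts[[length(bouts) + 1L]] <- data.frame(
        individual_id = seg$individual_id[1], bout_id = next_id,
        start = seg$timestamp[1], end = seg$timestamp[nrow(seg)],
        duration_hr = as.numeric(difftime(seg$timestamp[nrow(seg)],
                                          seg$timestamp[1], units = "hours")),
        n_points = nrow(seg))
      next_id <- next_id + 1L
    }
  }
  list(points = if (length(pts)) do.call(rbind, pts) else hourly[0, ],
       bouts = if (length(bouts)) do.call(rbind, bouts) else
         data.frame(individual_id = character(), bout_id = integer(),
                    duration_hr = numeric(), n_points = integer()))
}
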