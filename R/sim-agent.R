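# Agent simulation: step-selection-driven commuting movement over the
# synthetic terrain, emitted either at the hourly decision level (fast path,
# used for parameter recovery) or as a full 20-min GPS track.

# Linear predictor of the step-selection design at z-scored covariates.
# `beta` is named; the week main effect, when present, is ignored here
# because it is constant within a choice set.
design_linpred <- function(beta, ztri, zdist, zlen, zweek) {
  b <- function(nm) if (nm %in% names(beta)) beta[[nm]] else 0
  b("tri") * ztri + b("dist_ridge") * zdist + b("step_length") * zlen +
    b("tri_step") * ztri * zlen + b("dist_step") * zdist * zlen +
    b("tri_week") * ztri * zweek + b("dist_week") * zdist * zweek +
    b("step_week") * zlen * zweek +
    b("tri_step_week") * ztri * zlen * zweek +
    b("dist_step_week") * zdist * zlen * zweek
}

# Draw `m` candidate endpoints from the movement kernels, redrawing any that
# fall outside the raster extent (or on nodata analysis cells).
draw_candidates <- function(world, x0, y0, prev_bearing, m, max_rounds = 1000) {
  cfg <- world$config
  tri_agg <- world$terrain$tri_agg
  dst_agg <- world$terrain$dist_ridge_agg
  need <- m
  len <- bear <- tri <- dst <- numeric(0)
  rounds <- 0
  while (need > 0) {
    rounds <- rounds + 1
    if (rounds > max_rounds)
      stop("could not place candidate endpoints inside the world extent")
    l <- rgamma(need, shape = cfg$gamma_shape, scale = cfg$gamma_scale)
    if (is.na(prev_bearing)) {
      b <- runif(need, -pi, pi)
    } else {
      b <- prev_bearing + rvonmises(need, 0, cfg$vm_kappa)
    }
    xe <- x0 + l * cos(b); ye <- y0 + l * sin(b)
    tri_c <- rg_sample(tri_agg, xe, ye)
    dst_c <- rg_sample(dst_agg, xe, ye)
    ok <- is.finite(tri_c) & is.finite(dst_c)
    k <- sum(ok)
    if (k > 0) {
      len <- c(len, l[ok]); bear <- c(bear, b[ok])
      tri <- c(tri, tri_c[ok]); dst <- c(dst, dst_c[ok])
      need <- need - k
    }
  }
  list(len = len[seq_len(m)], bearing = bear[seq_len(m)],
       tri = tri[seq_len(m)], dist = dst[seq_len(m)])
}

# One SSF decision: choose among candidates with probability proportional to
# exp(beta . z). Returns the chosen candidate index and the candidate set.
ssf_decision <- function(world, beta, x0, y0, prev_bearing, zweek, m) {
  cand <- draw_candidates(world, x0, y0, prev_bearing, m)
  tp <- world$tparams
  lp <- design_linpred(beta,
                       z_apply(tp, "tri", cand$tri),
                       z_apply(tp, "dist_ridge", cand$dist),
                       z_apply(tp, "step_length", cand$len),
                       zweek)
  w <- exp(lp - max(lp))
  pick <- sample.int(m, 1L, prob = w)
  list(pick = pick, cand = cand)
}

# Geometric bout/gap schedule over `total_hr` hours: data frame of commuting
# bouts with 1-based start hour and length (h).
commute_schedule <- function(total_hr, bout_mean_hr, gap_mean_hr) {
  starts <- integer(0); lens <- integer(0)
  t <- 0
  repeat {
    gap <- rgeom(1, 1 / gap_mean_hr) + 1L
    t <- t + gap
    if (t >= total_hr) break
    len <- rgeom(1, 1 / bout_mean_hr) + 1L
    len <- min(len, total_hr - t)
    starts <- c(starts, t + 1L); lens <- c(lens, len)
    t <- t + len
  }
  data.frame(start_hr = starts, len_hr = lens)
}

# Individual-level coefficient vector: fixed truth plus Gaussian random
# slopes on tri and dist_ridge when configured.
individual_beta <- function(config) {
  beta <- config$true_beta
  if (config$rs_sd_tri > 0)
    beta[["tri"]] <- beta[["tri"]] + rnorm(1, 0, config$rs_sd_tri)
  if (config$rs_sd_dist > 0)
    beta[["dist_ridge"]] <- beta[["dist_ridge"]] + rnorm(1, 0, config$rs_sd_dist)
  beta
}

#' Simulate the hourly commuting step decisions of one individual
#'
#' The fast emission path: only the hourly step-selection decisions inside
#' commuting bouts are generated (no 20-min interpolation, no altitudes).
#' Each decision draws `n_candidates` endpoints from the movement kernels
#' (gamma length; von Mises turn relative to the previous bearing, uniform
#' bearing at bout starts) and selects one with probability proportional to
#' `exp(beta . z)`, where the week covariate implements the ontogenetic
#' attenuation of the terrain preferences.
#'
#' @param world a [build_world()] result.
#' @param individual_id index (1-based) into the world's nests.
#' @return data frame of used steps: start/end coordinates, `step_length`,
#'   `bearing`, `turning_angle` (NA at bout starts), `hour`, `week`,
#'   `bout_id`. The individual's realized coefficient vector is attached as
#'   attribute `"beta"`.
#' @export
simulate_steps <- function(world, individual_id) {
  stopifnot(inherits(world, "sim_world"))
  cfg <- world$config
  nest <- world$nests[individual_id, ]
  with_seed(derive_seed(cfg$seed, 100L + individual_id), {
    beta <- individual_beta(cfg)
    total_hr <- cfg$post_emigration_weeks * 168L
    sched <- commute_schedule(total_hr, cfg$commute_bout_mean_hr, cfg$commute_gap_mean_hr)
    out <- vector("list", nrow(sched))
    x <- nest$x; y <- nest$y
    for (b in seq_len(nrow(sched))) {
      nh <- sched$len_hr[b]
      rows <- data.frame(
        individual_id = nest$individual_id, bout_id = b,
        step_in_bout = seq_len(nh), hour = sched$start_hr[b] + seq_len(nh) - 1L,
        x1 = NA_real_, y1 = NA_real_, x2 = NA_real_, y2 = NA_real_,
        step_length = NA_real_, bearing = NA_real_, turning_angle = NA_real_)
      prev_bearing <- NA_real_
      for (s in seq_len(nh)) {
        week <- (rows$hour[s] - 1L) %/% 168L + 1L
        zweek <- z_apply(world$tparams, "week", week)
        dec <- ssf_decision(world, beta, x, y, prev_bearing, zweek, cfg$n_candidates)
        i <- dec$pick
        rows$x1[s] <- x; rows$y1[s] <- y
        rows$x2[s] <- x + dec$cand$len[i] * cos(dec$cand$bearing[i])
        rows$y2[s] <- y + dec$cand$len[i] * sin(dec$cand$bearing[i])
        rows$step_length[s] <- dec$cand$len[i]
        rows$bearing[s] <- wrap_angle(dec$cand$bearing[i])
        rows$turning_angle[s] <-
          if (is.na(prev_bearing)) NA_real_ else wrap_angle(dec$cand$bearing[i] - prev_bearing)
        x <- rows$x2[s]; y <- rows$y2[s]
        prev_bearing <- dec$cand$bearing[i]
      }
      rows$week <- (rows$hour - 1L) %/% 168L + 1L
      out[[b]] <- rows
    }
    res <- do.call(rbind, out)
    attr(res, "beta") <- beta
    res
  })
}

#' Simulate the hourly commuting steps of every individual
#' @param world a [build_world()] result.
#' @return row-bound [simulate_steps()] results; per-individual realized
#'   coefficient vectors are attached as attribute `"betas"` (a matrix).
#' @export
simulate_steps_all <- function(world) {
  parts <- lapply(seq_len(world$config$n_individuals),
                  function(i) simulate_steps(world, i))
  betas <- do.call(rbind, lapply(parts, attr, "beta"))
  rownames(betas) <- world$nests$individual_id
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  attr(res, "betas") <- betas
  res
}

#' Simulate the full 20-min GPS track of one individual
#'
#' Emits the complete bio-logging record: a bounded random walk inside the
#' natal territory for `pre_emigration_days`, then the commuting/other
#' behavioural alternation after emigration. Commuting hours take
#' step-selection decisions (as in [simulate_steps()]) and are emitted as
#' 20-min fixes interpolated along the hourly step with the commuting
#' speed/altitude class; other hours wander slowly with the non-commuting
#' class. `height_ellipsoid` is geoid offset + ground elevation at the fix +
#' behaviour-dependent flight altitude + Gaussian GPS noise.
#'
#' @param world a [build_world()] result.
#' @param individual_id index (1-based) into the world's nests.
#' @return data frame with `individual_id`, `timestamp` (POSIXct UTC), `x`,
#'   `y`, `height_ellipsoid`, plus ground-truth columns `sim_behavior`,
#'   `sim_flight_alt`, `sim_week` (0 before emigration) used only for
#'   validation.
#' @export
simulate_track <- function(world, individual_id) {
  stopifnot(inherits(world, "sim_world"))
  cfg <- world$config
  nest <- world$nests[individual_id, ]
  dt_s <- cfg$fix_interval_min * 60
  per_hr <- 60L %/% cfg$fix_interval_min
  t0 <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = "UTC")
  emi_time <- t0 + cfg$pre_emigration_days * 86400
  ext <- rg_extent(world$dem)
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)

  with_seed(derive_seed(cfg$seed, 500L + individual_id), {
    beta <- individual_beta(cfg)
    ## pre-emigration: bounded walk around the nest
    n_pre <- as.integer(cfg$pre_emigration_days * 24 * per_hr)
    px <- py <- numeric(n_pre)
    x <- nest$x; y <- nest$y
    for (i in seq_len(n_pre)) {
      x <- x - 0.1 * (x - nest$x) + rnorm(1, 0, 150)
      y <- y - 0.1 * (y - nest$y) + rnorm(1, 0, 150)
      r <- sqrt((x - nest$x)^2 + (y - nest$y)^2)
      if (r > cfg$nest_radius_m) {  # project back onto the territory boundary
        x <- nest$x + (x - nest$x) * cfg$nest_radius_m / r
        y <- nest$y + (y - nest$y) * cfg$nest_radius_m / r
      }
      px[i] <- x; py[i] <- y
    }
    pre <- data.frame(
      timestamp = t0 + seq_len(n_pre) * dt_s, x = px, y = py,
      sim_behavior = "other", sim_week = 0L)

    ## post-emigration: hourly behavioural alternation
    total_hr <- cfg$post_emigration_weeks * 168L
    sched <- commute_schedule(total_hr, cfg$commute_bout_mean_hr, cfg$commute_gap_mean_hr)
    commuting_hr <- logical(total_hr)
    for (b in seq_len(nrow(sched)))
      commuting_hr[sched$start_hr[b] + seq_len(sched$len_hr[b]) - 1L] <- TRUE
    n_post <- total_hr * per_hr
    fx_all <- fy_all <- numeric(n_post)
    commute_fix <- logical(n_post)
    prev_bearing <- NA_real_
    fr <- seq_len(per_hr) / per_hr
    for (h in seq_len(total_hr)) {
      at <- (h - 1L) * per_hr + seq_len(per_hr)
      if (commuting_hr[h]) {
        week <- (h - 1L) %/% 168L + 1L
        zweek <- z_apply(world$tparams, "week", week)
        dec <- ssf_decision(world, beta, x, y, prev_bearing, zweek, cfg$n_candidates)
        i <- dec$pick
        xe <- x + dec$cand$len[i] * cos(dec$cand$bearing[i])
        ye <- y + dec$cand$len[i] * sin(dec$cand$bearing[i])
        fx_all[at] <- x + (xe - x) * fr; fy_all[at] <- y + (ye - y) * fr
        x <- xe; y <- ye
        prev_bearing <- dec$cand$bearing[i]
        commute_fix[at] <- TRUE
      } else {
        for (i in seq_len(per_hr)) {
          repeat {
            sp <- max(rnorm(1, cfg$speed_other[["mean"]], cfg$speed_other[["sd"]]), 0)
            ang <- runif(1, -pi, pi)
            xn <- x + sp * dt_s * cos(ang); yn <- y + sp * dt_s * sin(ang)
            if (rg_inside(world$dem, xn, yn)) break
          }
          x <- xn; y <- yn
          fx_all[at[i]] <- x; fy_all[at[i]] <- y
        }
        prev_bearing <- NA_real_
      }
    }
    post <- data.frame(
      timestamp = emi_time + seq_len(n_post) * dt_s,
      x = fx_all, y = fy_all,
      sim_behavior = ifelse(commute_fix, "commute", "other"),
      sim_week = rep(seq_len(cfg$post_emigration_weeks), each = 168L * per_hr))
    trk <- rbind(pre, post)
    n <- nrow(trk)
    is_com <- trk$sim_behavior == "commute"
    alt <- numeric(n)
    alt[is_com] <- rnorm(sum(is_com), cfg$alt_commute[["mean"]], cfg$alt_commute[["sd"]])
    alt[!is_com] <- rnorm(sum(!is_com), cfg$alt_other[["mean"]], cfg$alt_other[["sd"]])
    alt <- pmax(alt, 0)
    ground <- rg_sample(world$dem, clamp(trk$x, ext["xmin"], ext["xmax"] - 1),
                        clamp(trk$y, ext["ymin"] + 1, ext["ymax"]))
    trk$height_ellipsoid <- cfg$geoid_offset + ground + alt +
      rnorm(n, 0, cfg$altitude_noise_sd)
    trk$sim_flight_alt <- alt
    trk$individual_id <- nest$individual_id
    trk[, c("individual_id", "timestamp", "x", "y", "height_ellipsoid",
            "sim_behavior", "sim_flight_alt", "sim_week")]
  })
}

#' Simulate full tracks for every individual
#' @param world a [build_world()] result.
#' @return row-bound [simulate_track()] results.
#' @export
simulate_tracks <- function(world) {
  res <- do.call(rbind, lapply(seq_len(world$config$n_individuals),
                               function(i) simulate_track(world, i)))
  rownames(res) <- NULL
  res
}
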