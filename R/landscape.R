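# Weekly flyability prediction maps and their summaries: flyable area above
# a threshold, logistic growth of the flyable area along the ontogenetic
# axis, fold change, and kernel-density hotspot maps.

#' Predict a weekly flyability map
#'
#' Per 100 m cell: z-score TRI and distance to ridge with the stored
#' transform constants, set step length to the week's mean value and week to
#' the target week (both z-scored the same way), evaluate the fixed-effects
#' linear predictor (random effects at the population mean, stratum effect
#' omitted), and apply the inverse logit. The result is the flyability
#' index in [0, 1].
#'
#' @param fit an `ssf_fit`.
#' @param terrain a [terrain_layers()] stack (aggregated layers are used).
#' @param week target week since emigration (1..156).
#' @param mean_step_length step length (m) representing the week.
#' @param params the [transform_params()] recorded when the model dataset
#'   was built.
#' @return a `raster_grid` of flyability values; nodata propagates.
#' @export
predict_flyability <- function(fit, terrain, week, mean_step_length, params) {
  stopifnot(inherits(fit, "ssf_fit"), inherits(terrain, "terrain_layers"),
            inherits(params, "transform_params"))
  if (week < 1 || week > 156) stop("week must be within 1..156")
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  ztri <- z_apply(params, "tri", terrain$tri_agg$values)
  zdist <- z_apply(params, "dist_ridge", terrain$dist_ridge_agg$values)
  zlen <- z_apply(params, "step_length", mean_step_length)
  zweek <- z_apply(params, "week", week)
  lp <- design_linpred(beta, ztri, zdist, zlen, zweek) +
    beta[["week"]] * zweek
  raster_grid(inv_logit(lp), terrain$tri_agg$cell_size,
              terrain$tri_agg$origin_x, terrain$tri_agg$origin_y)
}

#' Flyable area of a flyability map
#'
#' Number of 100 m cells with flyability strictly above the threshold,
#' converted to km^2 (each cell is 0.01 km^2). Nodata cells are excluded.
#'
#' @param flyability a 100 m `raster_grid` of flyability values.
#' @param threshold flyability cutoff (default 0.7).
#' @return area in km^2.
#' @export
flyable_area <- function(flyability, threshold = 0.7) {
  stopifnot(inherits(flyability, "raster_grid"))
  if (abs(flyability$cell_size - 100) > 1e-9)
    stop("flyable_area is defined on the 100 m analysis grid")
  sum(flyability$values > threshold, na.rm = TRUE) * 0.01
}

#' Mean observed step length per week
#'
#' Weeks with fewer than `min_steps` observed steps borrow the global mean.
#'
#' @param steps observed steps with `step_length` and `week`.
#' @param weeks weeks to report.
#' @param min_steps minimum sample size for a week-specific mean.
#' @return data frame with `week`, `mean_step_length`, `n_steps`.
#' @export
weekly_mean_step_length <- function(steps, weeks, min_steps = 5) {
  glob <- mean(steps$step_length, na.rm = TRUE)
  out <- data.frame(week = weeks, mean_step_length = glob, n_steps = 0L)
  for (i in seq_along(weeks)) {
    sl <- steps$step_length[steps$week == weeks[i] & is.finite(steps$step_length)]
    out$n_steps[i] <- length(sl)
    if (length(sl) >= min_steps) out$mean_step_length[i] <- mean(sl)
  }
  out
}

#' Logistic growth fit and fold change of a flyable-area series
#'
#' Least-squares fit of `A / (1 + exp(-k (t - t0)))` with positivity
#' constraints on the asymptote `A` and rate `k`. Fold change is
#' `area(last) / area(first)`; a zero first-week area leaves it undefined
#' (flagged, not an error), and a fit failure or a near-zero rate is
#' flagged rather than thrown.
#'
#' @param weeks week numbers.
#' @param areas flyable areas (km^2), same length.
#' @return list with `A`, `k`, `t0`, `fitted`, `fold_change`, and flags
#'   `no_fit`, `degenerate`, `fold_undefined`.
#' @export
area_growth <- function(weeks, areas) {
  stopifnot(length(weeks) == length(areas))
  if (length(weeks) < 10) stop("need at least 10 weeks of areas")
  fold_undefined <- areas[1] == 0
  fold <- if (fold_undefined) NA_real_ else areas[length(areas)] / areas[1]
  dat <- data.frame(t = weeks, y = areas)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A / (1 + exp(-k * (t - t0))), data = dat,
                      start = list(A = max(areas), k = 0.1, t0 = stats::median(weeks)),
                      lower = c(A = 1e-12, k = 0, t0 = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(A = NA_real_, k = NA_real_, t0 = NA_real_, fitted = NULL,
                fold_change = fold, no_fit = TRUE, degenerate = FALSE,
                fold_undefined = fold_undefined))
  }
  cf <- stats::coef(fit)
  list(A = unname(cf["A"]), k = unname(cf["k"]), t0 = unname(cf["t0"]),
       fitted = stats::fitted(fit), fold_change = fold,
       no_fit = FALSE, degenerate = unname(cf["k"]) < 1e-6,
       fold_undefined = fold_undefined)
}

#' Weekly energy-landscape series
#'
#' Predicts a flyability map for each requested week (using that week's mean
#' observed step length), computes the flyable area above the threshold,
#' and fits the logistic growth curve to the resulting series.
#'
#' @param fit an `ssf_fit`.
#' @param terrain a [terrain_layers()] stack.
#' @param steps observed steps (for per-week mean step lengths).
#' @param weeks weeks to predict (default 1..156).
#' @param threshold flyability cutoff for "flyable".
#' @param params the [transform_params()] of the model dataset.
#' @param store_maps keep the per-week rasters (memory-heavy; default FALSE).
#' @return a `landscape_series`: data frame `areas` (week, mean step length,
#'   flyable area), `growth` (see [area_growth()]), `threshold`, and
#'   optionally `maps`.
#' @export
landscape_series <- function(fit, terrain, steps, weeks = 1:156, threshold = 0.7,
                             params, store_maps = FALSE) {
  msl <- weekly_mean_step_length(steps, weeks)
  areas <- numeric(length(weeks))
  maps <- if (store_maps) vector("list", length(weeks)) else NULL
  for (i in seq_along(weeks)) {
    fly <- predict_flyability(fit, terrain, weeks[i], msl$mean_step_length[i], params)
    areas[i] <- flyable_area(fly, threshold)
    if (store_maps) maps[[i]] <- fly
  }
  growth <- if (length(weeks) >= 10) {
    area_growth(weeks, areas)
  } else {  # too short for a growth curve; still report the fold change
    list(A = NA_real_, k = NA_real_, t0 = NA_real_, fitted = NULL,
         fold_change = if (areas[1] > 0) areas[length(areas)] / areas[1] else NA_real_,
         no_fit = TRUE, degenerate = FALSE, fold_undefined = areas[1] == 0)
  }
  structure(list(
    areas = data.frame(week = weeks, mean_step_length = msl$mean_step_length,
                       flyable_area_km2 = areas),
    growth = growth,
    threshold = threshold, maps = maps),
    class = "landscape_series")
}

#' @export
print.landscape_series <- function(x, ...) {
  a <- x$areas
  cat(sprintf("landscape_series: %d weeks, threshold %.2f\n", nrow(a), x$threshold))
  cat(sprintf("  flyable area: %.2f km2 (week %d) -> %.2f km2 (week %d)\n",
              a$flyable_area_km2[1], a$week[1],
              a$flyable_area_km2[nrow(a)], a$week[nrow(a)]))
  g <- x$growth
  if (!g$no_fit)
    cat(sprintf("  logistic growth: A %.2f km2, k %.3g, t0 %.1f\n", g$A, g$k, g$t0))
  cat(sprintf("  fold change: %s\n",
              if (g$fold_undefined) "undefined (week-1 area is 0)"
              else format(g$fold_change, digits = 4)))
  invisible(x)
}

#' Hotspot density of flyable areas
#'
#' Gaussian kernel density of the flyable-cell centres, evaluated on the
#' 100 m grid and renormalized to integrate to 1 over the region. Bandwidths
#' default to Silverman's rule per axis; the kernel is truncated at 6 SD
#' (separable convolution).
#'
#' @param flyability a `raster_grid` of flyability values.
#' @param threshold flyability cutoff defining flyable cells.
#' @param bandwidth length-2 bandwidths (m) for x and y, or NULL for
#'   Silverman's rule.
#' @return a `raster_grid` of densities (per m^2).
#' @export
hotspot_density <- function(flyability, threshold = 0.7, bandwidth = NULL) {
  stopifnot(inherits(flyability, "raster_grid"))
  v <- flyability$values
  mask <- !is.na(v) & v > threshold
  n <- sum(mask)
  if (n == 0) stop("no flyable cells above the threshold")
  cell <- flyability$cell_size
  if (is.null(bandwidth)) {
    ctr <- rg_centers(flyability)
    xs <- ctr$x[mask]; ys <- ctr$y[mask]
    bw1 <- function(z) if (length(z) > 1 && stats::sd(z) > 0) stats::bw.nrd(z) else cell
    bandwidth <- c(bw1(xs), bw1(ys))
  }
  hx <- bandwidth[1]; hy <- bandwidth[2]
  # separable truncated-Gaussian convolution of the mask (columns = x axis)
  kx_off <- seq(-ceiling(6 * hx / cell), ceiling(6 * hx / cell))
  ky_off <- seq(-ceiling(6 * hy / cell), ceiling(6 * hy / cell))
  kx <- dnorm(kx_off * cell, 0, hx)
  ky <- dnorm(ky_off * cell, 0, hy)
  M <- matrix(as.numeric(mask), nrow(v), ncol(v))
  conv_rows <- function(A, k, off) {   # convolve down columns (y direction)
    out <- matrix(0, nrow(A), ncol(A))
    for (j in seq_along(off)) {
      o <- off[j]
      src <- seq_len(nrow(A)) + o
      okk <- src >= 1 & src <= nrow(A)
      out[okk, ] <- out[okk, ] + k[j] * A[src[okk], ]
    }
    out
  }
  D <- conv_rows(M, ky, ky_off)
  D <- t(conv_rows(t(D), kx, kx_off))
  D <- D / (n)
  tot <- sum(D) * cell^2
  D <- D / tot
  D[is.na(v)] <- NA_real_
  raster_grid(D, cell, flyability$origin_x, flyability$origin_y)
}
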