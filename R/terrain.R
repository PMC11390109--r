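#' Topographic ruggedness index (TRI)
#'
#' Per cell, the mean of the absolute elevation differences between the cell
#' and its up-to-8 adjacent cells. Edge cells use the neighbours available;
#' NA cells propagate. TRI is a standard proxy for terrain heterogeneity and
#' hence for uplift potential.
#'
#' @param dem a `raster_grid` elevation model with at least 3 x 3 cells.
#' @return a `raster_grid` of TRI values (m), same geometry as `dem`.
#' @export
compute_tri <- function(dem) {
  stopifnot(inherits(dem, "raster_grid"))
  v <- dem$values
  if (nrow(v) < 3 || ncol(v) < 3) stop("TRI needs a DEM of at least 3 x 3 cells")
  if (all(is.na(v))) stop("DEM is entirely nodata")
  out <- tri_cpp(v)
  raster_grid(out, dem$cell_size, dem$origin_x, dem$origin_y)
}

#' Topographic position index (TPI)
#'
#' Focal elevation minus the mean elevation over the annulus of cells whose
#' centre lies at distance `inner_radius_m < d <= outer_radius_m` from the
#' focal centre. Positive on ridges and hilltops, negative in valleys.
#'
#' @param dem a `raster_grid` elevation model.
#' @param inner_radius_m inner annulus radius (m), `>= 0`.
#' @param outer_radius_m outer annulus radius (m), `> inner_radius_m`.
#' @return a `raster_grid` of TPI values (m); cells with an empty annulus are NA.
#' @export
compute_tpi <- function(dem, inner_radius_m = 10, outer_radius_m = 200) {
  stopifnot(inherits(dem, "raster_grid"))
  if (inner_radius_m < 0 || outer_radius_m <= inner_radius_m)
    stop("need 0 <= inner_radius_m < outer_radius_m")
  if (outer_radius_m < dem$cell_size)
    stop("outer radius smaller than one cell: annulus is empty everywhere")
  if (all(is.na(dem$values))) stop("DEM is entirely nodata")
  out <- tpi_cpp(dem$values, dem$cell_size, inner_radius_m, outer_radius_m)
  raster_grid(out, dem$cell_size, dem$origin_x, dem$origin_y)
}

#' Extract ridge cells from a TPI layer
#'
#' Standardizes TPI over its valid cells (subtract mean, divide by SD) and
#' classifies cells with standardized TPI above `sd_threshold` as ridge, the
#' ridge class of the landform classification based on standardized TPI.
#'
#' @param tpi a `raster_grid` of TPI values.
#' @param sd_threshold standardized-TPI cutoff for the ridge class (default +1 SD).
#' @return a 0/1 `raster_grid` ridge mask (NA where TPI is NA).
#' @export
extract_ridge_mask <- function(tpi, sd_threshold = 1.0) {
  stopifnot(inherits(tpi, "raster_grid"))
  v <- tpi$values
  ok <- is.finite(v)
  if (!any(ok)) stop("TPI has no valid cells")
  m <- mean(v[ok]); s <- stats::sd(v[ok])
  if (!is.finite(s) || s < .Machine$double.eps^0.5)
    stop("TPI has zero variance: no landforms definable")
  mask <- matrix(NA_real_, nrow(v), ncol(v))
  mask[ok] <- as.numeric((v[ok] - m) / s > sd_threshold)
  raster_grid(mask, tpi$cell_size, tpi$origin_x, tpi$origin_y)
}

#' Euclidean distance to the nearest ridge cell
#'
#' Per cell, the distance in metres from its centre to the nearest ridge-cell
#' centre (a proximity raster). Exact Euclidean distance transform; 0 on
#' ridge cells.
#'
#' @param ridge_mask a 0/1 `raster_grid` with at least one ridge cell.
#' @return a `raster_grid` of distances (m).
#' @export
distance_to_ridge <- function(ridge_mask) {
  stopifnot(inherits(ridge_mask, "raster_grid"))
  v <- ridge_mask$values
  m <- matrix(0L, nrow(v), ncol(v))
  m[which(v == 1)] <- 1L
  if (!any(m == 1L)) stop("ridge mask contains no ridge cells")
  d <- edt_cpp(m) * ridge_mask$cell_size
  raster_grid(d, ridge_mask$cell_size, ridge_mask$origin_x, ridge_mask$origin_y)
}

#' Aggregate a raster to a coarser grid by block averaging
#'
#' Averages the k x k fine cells under each coarse cell, where
#' `k = target_cell_m / layer$cell_size` must be a whole number. The mean is
#' NA-aware and partial edge blocks use the cells available.
#'
#' @param layer a `raster_grid`.
#' @param target_cell_m coarse cell size (m), a positive multiple of the
#'   layer's cell size.
#' @return a `raster_grid` with `cell_size = target_cell_m`.
#' @export
aggregate_to_grid <- function(layer, target_cell_m = 100) {
  stopifnot(inherits(layer, "raster_grid"))
  k <- target_cell_m / layer$cell_size
  if (!isTRUE(all.equal(k, round(k))) || k < 1)
    stop("target_cell_m must be a positive integer multiple of the cell size")
  k <- as.integer(round(k))
  out <- blockmean_cpp(layer$values, k)
  raster_grid(out, target_cell_m, layer$origin_x, layer$origin_y)
}

#' Compute the full stack of terrain layers used by the step-selection analysis
#'
#' TRI and TPI from the DEM, the ridge mask from standardized TPI, the
#' distance-to-ridge proximity raster, and block-averaged versions of TRI and
#' distance-to-ridge on the analysis grid (default 100 m).
#'
#' @param dem a `raster_grid` elevation model.
#' @param inner_radius_m,outer_radius_m TPI annulus radii (m).
#' @param ridge_sd_threshold standardized-TPI cutoff for the ridge class.
#' @param target_cell_m analysis grid cell size (m).
#' @return a `terrain_layers` list: `tri`, `tpi`, `ridge_mask`, `dist_ridge`,
#'   `tri_agg`, `dist_ridge_agg`, plus the parameters used.
#' @export
terrain_layers <- function(dem, inner_radius_m = 10, outer_radius_m = 200,
                           ridge_sd_threshold = 1.0, target_cell_m = 100) {
  tri <- compute_tri(dem)
  tpi <- compute_tpi(dem, inner_radius_m, outer_radius_m)
  ridge <- extract_ridge_mask(tpi, ridge_sd_threshold)
  dist <- distance_to_ridge(ridge)
  structure(list(
    tri = tri, tpi = tpi, ridge_mask = ridge, dist_ridge = dist,
    tri_agg = aggregate_to_grid(tri, target_cell_m),
    dist_ridge_agg = aggregate_to_grid(dist, target_cell_m),
    params = list(inner_radius_m = inner_radius_m, outer_radius_m = outer_radius_m,
                  ridge_sd_threshold = ridge_sd_threshold, target_cell_m = target_cell_m)),
    class = "terrain_layers")
}

#' @export
print.terrain_layers <- function(x, ...) {
  cat("terrain_layers:\n")
  cat(sprintf("  fine grid: %d x %d at %g m; analysis grid: %d x %d at %g m\n",
              nrow(x$tri$values), ncol(x$tri$values), x$tri$cell_size,
              nrow(x$tri_agg$values), ncol(x$tri_agg$values), x$tri_agg$cell_size))
  cat(sprintf("  ridge cells: %d (TPI annulus %g-%g m, threshold %+g SD)\n",
              sum(x$ridge_mask$values == 1, na.rm = TRUE),
              x$params$inner_radius_m, x$params$outer_radius_m,
              x$params$ridge_sd_threshold))
  invisible(x)
}
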