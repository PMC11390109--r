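#' Planar single-band raster grid
#'
#' A minimal matrix-backed raster used for the elevation model and every
#' derived terrain layer. The grid is north-up and row-major: row 1 is the
#' northernmost row. `origin_x`, `origin_y` give the planar coordinates (m)
#' of the outer corner of the top-left cell, so the centre of cell (r, c) is
#' `(origin_x + (c - 0.5) * cell_size, origin_y - (r - 0.5) * cell_size)`.
#' Missing cells are stored as `NA`.
#'
#' @param values numeric matrix (row 1 = northernmost row).
#' @param cell_size cell edge length in metres (> 0).
#' @param origin_x,origin_y planar coordinates of the top-left outer corner.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size, origin_x = 0, origin_y = nrow(values) * cell_size) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || !is.finite(cell_size) || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y)),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("raster_grid: %d x %d cells, %g m cells\n", nrow(v), ncol(v), x$cell_size))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              x$origin_x, x$origin_x + ncol(v) * x$cell_size,
              x$origin_y - nrow(v) * x$cell_size, x$origin_y))
  fin <- v[is.finite(v)]
  if (length(fin))
    cat(sprintf("  values: [%g, %g], %d NA\n", min(fin), max(fin), sum(is.na(v))))
  else cat("  values: all NA\n")
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Raster extent as c(xmin, xmax, ymin, ymax)
#' @param grid a `raster_grid`.
#' @export
rg_extent <- function(grid) {
  c(xmin = grid$origin_x,
    xmax = grid$origin_x + ncol(grid$values) * grid$cell_size,
    ymin = grid$origin_y - nrow(grid$values) * grid$cell_size,
    ymax = grid$origin_y)
}

#' Are points inside the raster extent?
#' @param grid a `raster_grid`.
#' @param x,y planar coordinates (m).
#' @export
rg_inside <- function(grid, x, y) {
  e <- rg_extent(grid)
  x >= e["xmin"] & x < e["xmax"] & y > e["ymin"] & y <= e["ymax"]
}

#' Row/column indices of the cells containing points (NA outside the extent)
#' @inheritParams rg_inside
#' @return list with integer vectors `row`, `col`.
#' @export
rg_rowcol <- function(grid, x, y) {
  inside <- rg_inside(grid, x, y)
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1L
  row <- floor((grid$origin_y - y) / grid$cell_size) + 1L
  # points exactly on the top/left outer edge belong to the first row/col
  col[inside & col < 1L] <- 1L
  row[inside & row < 1L] <- 1L
  col[!inside] <- NA_integer_
  row[!inside] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Sample raster values at point locations (containing-cell lookup)
#' @inheritParams rg_inside
#' @return numeric vector; NA for points outside the extent or on NA cells.
#' @export
rg_sample <- function(grid, x, y) {
  rc <- rg_rowcol(grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- grid$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Cell-centre coordinates of every cell
#' @param grid a `raster_grid`.
#' @return list with matrices `x`, `y` matching `dim(grid)`.
#' @export
rg_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  xs <- grid$origin_x + (seq_len(nc) - 0.5) * grid$cell_size
  ys <- grid$origin_y - (seq_len(nr) - 0.5) * grid$cell_size
  list(x = matrix(xs, nr, nc, byrow = TRUE), y = matrix(ys, nr, nc))
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format (`ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value` header followed by rows north to south).
#'
#' @param grid a `raster_grid`.
#' @param path output file path.
#' @param nodata sentinel written for NA cells.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", grid$origin_x),
    sprintf("yllcorner %.10g", grid$origin_y - nr * grid$cell_size),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", nodata))
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(v, trim = TRUE, digits = 10, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path file path.
#' @return a `raster_grid` (nodata cells become NA).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 6)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid: ", path)
  v <- matrix(scan(path, skip = 6, quiet = TRUE),
              nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) v[v == hdr$nodata_value] <- NA_real_
  raster_grid(v, cell_size = hdr$cellsize, origin_x = hdr$xllcorner,
              origin_y = hdr$yllcorner + hdr$nrows * hdr$cellsize)
}
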