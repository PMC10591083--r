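#' Define an analysis grid
#'
#' An analysis lattice of square cells in decimal degrees, anchored at its
#' upper-left (north-west) corner. The default resolution of 2.5 arc-minutes
#' matches the WorldClim 2.5-min product (cells of roughly 4 x 4 km in
#' mid-latitudes), the resolution at which occurrence records are rasterised
#' before niche modelling.
#'
#' Cell indices are zero-based: row 0 is the northernmost row, column 0 the
#' westernmost column. Cells are half-open intervals `[edge, edge + res)` in
#' both axes; points on the extreme eastern or southern boundary of the grid
#' are clamped into the last cell.
#'
#' @param lon_min western edge, decimal degrees.
#' @param lat_max northern edge, decimal degrees.
#' @param res_arcmin cell size in arc-minutes (default 2.5).
#' @param n_rows,n_cols grid dimensions.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(lon_min = -32, lat_max = 72, res_arcmin = 2.5,
#'                n_rows = 100, n_cols = 200)
#' grid_index(-31.99, 71.99, g)
#' @export
grid_spec <- function(lon_min, lat_max, res_arcmin = 2.5, n_rows, n_cols) {
  stopifnot(is.numeric(lon_min), is.numeric(lat_max),
            is.numeric(res_arcmin), res_arcmin > 0,
            n_rows >= 1, n_cols >= 1)
  g <- list(lon_min = as.numeric(lon_min), lat_max = as.numeric(lat_max),
            res_arcmin = as.numeric(res_arcmin),
            res_deg = as.numeric(res_arcmin) / 60,
            n_rows = as.integer(n_rows), n_cols = as.integer(n_cols))
  g$lon_max <- g$lon_min + g$n_cols * g$res_deg
  g$lat_min <- g$lat_max - g$n_rows * g$res_deg
  class(g) <- "grid_spec"
  g
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d rows x %d cols at %.4g' (%.6g deg)\n",
              x$n_rows, x$n_cols, x$res_arcmin, x$res_deg))
  cat(sprintf("  lon [%.6g, %.6g], lat [%.6g, %.6g]\n",
              x$lon_min, x$lon_max, x$lat_min, x$lat_max))
  invisible(x)
}

#' Map coordinates to grid cells
#'
#' `row = floor((lat_max - lat) / res)`, `col = floor((lon - lon_min) / res)`.
#' Points on the extreme east/south boundary clamp to the last column/row.
#'
#' @param lon,lat numeric vectors of equal length, decimal degrees.
#' @param grid a [grid_spec()].
#' @return Integer matrix with columns `row`, `col` (zero-based).
#' @export
grid_index <- function(lon, lat, grid) {
  stopifnot(inherits(grid, "grid_spec"), length(lon) == length(lat))
  eps <- 1e-9
  outside <- lon < grid$lon_min - eps | lon > grid$lon_max + eps |
    lat < grid$lat_min - eps | lat > grid$lat_max + eps | !is.finite(lon) | !is.finite(lat)
  if (any(outside)) {
    stop(sprintf("%d point(s) outside grid extent (first: lon=%s lat=%s)",
                 sum(outside), format(lon[which(outside)[1]]),
                 format(lat[which(outside)[1]])), call. = FALSE)
  }
  col <- floor((lon - grid$lon_min) / grid$res_deg)
  row <- floor((grid$lat_max - lat) / grid$res_deg)
  col <- pmin(pmax(col, 0L), grid$n_cols - 1L)
  row <- pmin(pmax(row, 0L), grid$n_rows - 1L)
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Construct a cell set
#'
#' A set of occupied grid cells, stored as a duplicate-free integer matrix
#' with columns `row` and `col` (zero-based), sorted in row-major order so
#' that equal sets have identical representations.
#'
#' @param cells matrix or data frame with columns `row`, `col`.
#' @param grid optional [grid_spec()]; if given, indices are range-checked.
#' @return Integer matrix of class `cell_set`.
#' @export
cell_set <- function(cells, grid = NULL) {
  if (is.null(cells) || NROW(cells) == 0) {
    m <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("row", "col")))
    class(m) <- c("cell_set", class(m))
    return(m)
  }
  if (is.data.frame(cells)) cells <- as.matrix(cells[, c("row", "col")])
  if (is.null(colnames(cells))) colnames(cells) <- c("row", "col")
  m <- cbind(row = as.integer(cells[, "row"]), col = as.integer(cells[, "col"]))
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "grid_spec"))
    bad <- m[, 1] < 0 | m[, 1] >= grid$n_rows | m[, 2] < 0 | m[, 2] >= grid$n_cols
    if (any(bad)) stop(sum(bad), " cell(s) outside grid", call. = FALSE)
  }
  m <- unique(m)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  class(m) <- c("cell_set", class(m))
  m
}

cell_keys <- function(cells) {
  if (NROW(cells) == 0) return(character(0))
  paste(cells[, 1], cells[, 2], sep = ":")
}

#' Set operations on cell sets
#'
#' Pure set functions used by the range-change metrics.
#' @param a,b cell sets (matrices with `row`/`col` columns).
#' @return A `cell_set`.
#' @export
cells_intersect <- function(a, b) {
  a <- cell_set(a); b <- cell_set(b)
  cell_set(a[cell_keys(a) %in% cell_keys(b), , drop = FALSE])
}

#' @rdname cells_intersect
#' @export
cells_union <- function(a, b) cell_set(rbind(cell_set(a), cell_set(b)))

#' @rdname cells_intersect
#' @export
cells_diff <- function(a, b) {
  a <- cell_set(a); b <- cell_set(b)
  cell_set(a[!(cell_keys(a) %in% cell_keys(b)), , drop = FALSE])
}

#' Cell centre coordinates
#'
#' @param cells a cell set.
#' @param grid a [grid_spec()].
#' @return Data frame with `row`, `col`, `lon`, `lat` (cell centres).
#' @export
cell_centers <- function(cells, grid) {
  cells <- cell_set(cells, grid)
  data.frame(row = cells[, 1], col = cells[, 2],
             lon = grid$lon_min + (cells[, 2] + 0.5) * grid$res_deg,
             lat = grid$lat_max - (cells[, 1] + 0.5) * grid$res_deg)
}
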