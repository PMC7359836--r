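#' Landscape grid geometry
#'
#' A regular lon-lat grid of square (in degrees) cells. Cells are addressed by
#' a 1-based row-major linear index: cell 1 is the north-west corner, indices
#' run west to east along each row, rows run north to south. `origin_lon` and
#' `origin_lat` are the coordinates of the *center* of the upper-left cell.
#'
#' @param n_rows,n_cols positive integers, grid dimensions.
#' @param origin_lon,origin_lat degrees, center of the upper-left cell.
#' @param cell_size degrees per cell side (> 0).
#' @return an object of class `landscape_grid`.
#' @examples
#' g <- landscape_grid(3, 4, origin_lon = 0, origin_lat = 1, cell_size = 1)
#' cell_centers(g, c(1, 12))
#' @export
landscape_grid <- function(n_rows, n_cols, origin_lon, origin_lat,
                           cell_size) {
  stopifnot(length(n_rows) == 1, length(n_cols) == 1,
            n_rows >= 1, n_cols >= 1,
            n_rows == as.integer(n_rows), n_cols == as.integer(n_cols),
            is.finite(origin_lon), is.finite(origin_lat), cell_size > 0)
  lat_south <- origin_lat - (n_rows - 1) * cell_size
  if (origin_lat > 90 || lat_south < -90)
    stop("cell-center latitudes must lie in [-90, 90]", call. = FALSE)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 origin_lon = origin_lon, origin_lat = origin_lat,
                 cell_size = cell_size),
            class = "landscape_grid")
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf(
    "landscape_grid: %d x %d cells of %g deg, upper-left center (%g, %g)\n",
    x$n_rows, x$n_cols, x$cell_size, x$origin_lon, x$origin_lat))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

same_grid <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

#' Cell index / coordinate conversions
#'
#' @param grid a [landscape_grid()].
#' @param cells integer vector of linear cell indices (1-based, row-major).
#' @return `cell_centers` returns a two-column matrix of `lon`, `lat` cell
#'   centers in degrees; `cell_rowcol` a two-column matrix of `row`, `col`.
#' @export
cell_centers <- function(grid, cells = seq_len(n_cells(grid))) {
  rc <- cell_rowcol(grid, cells)
  cbind(lon = grid$origin_lon + (rc[, "col"] - 1) * grid$cell_size,
        lat = grid$origin_lat - (rc[, "row"] - 1) * grid$cell_size)
}

#' @rdname cell_centers
#' @export
cell_rowcol <- function(grid, cells) {
  cells <- as.integer(cells)
  if (any(cells < 1L | cells > n_cells(grid)))
    stop("cell index out of range", call. = FALSE)
  row <- (cells - 1L) %/% grid$n_cols + 1L
  col <- (cells - 1L) %% grid$n_cols + 1L
  cbind(row = row, col = col)
}

#' @rdname cell_centers
#' @param row,col integer vectors of row and column indices.
#' @export
cell_index <- function(grid, row, col) {
  stopifnot(all(row >= 1), all(row <= grid$n_rows),
            all(col >= 1), all(col <= grid$n_cols))
  as.integer((row - 1L) * grid$n_cols + col)
}

#' Great-circle distance in kilometers
#'
#' Haversine distance on a sphere of radius 6371.0 km. Used for all edge
#' lengths, dispersal thresholds and site-to-cell assignment so that grids at
#' continental extent do not suffer planar distortion.
#'
#' @param a,b two-column matrices (or length-2 vectors) of `lon`, `lat` in
#'   degrees; recycled against each other row-wise.
#' @return numeric vector of distances in km.
#' @examples
#' great_circle_km(c(0, 0), c(1, 0)) # one equatorial degree, ~111.19 km
#' @export
great_circle_km <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 2)
  b <- matrix(as.numeric(b), ncol = 2)
  if (any(abs(a[, 2]) > 90) || any(abs(b[, 2]) > 90))
    stop("latitude outside [-90, 90]", call. = FALSE)
  if (nrow(a) == 0 || nrow(b) == 0) return(numeric(0))
  geosphere::distHaversine(a, b, r = 6371000) / 1000
}
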