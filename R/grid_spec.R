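#' Raster lattice specification
#'
#' A `grid_spec` describes the regular longitude/latitude lattice shared by
#' all environmental layers, masks and gridded occurrences.  Cells are
#' half-open `[lower, upper)` intervals counted from the lower-left corner:
#' row 1 is the southernmost latitude band, column 1 the westernmost.  Cell
#' values live in `n_rows x n_cols` matrices with the same indexing.
#'
#' The default bounds cover the North Atlantic study region (longitude
#' -85 to 50, latitude 35 to 75) at 0.05 degree resolution; synthetic
#' desk-scale worlds use [synthetic_grid()] instead.
#'
#' @param lon_min,lon_max,lat_min,lat_max bounding box in decimal degrees.
#' @param resolution cell size in degrees (square cells).
#' @return An object of class `grid_spec`.
#' @seealso [cell_center()], [locate_cells()], [synthetic_grid()]
#' @export
#' @examples
#' g <- grid_spec(0, 1, 50, 51, resolution = 0.5)
#' g$n_rows; g$n_cols
grid_spec <- function(lon_min = -85, lon_max = 50, lat_min = 35, lat_max = 75,
                      resolution = 0.05) {
  stopifnot(resolution > 0, lon_max > lon_min, lat_max > lat_min)
  n_cols <- as.integer(round((lon_max - lon_min) / resolution))
  n_rows <- as.integer(round((lat_max - lat_min) / resolution))
  if (n_cols < 1L || n_rows < 1L)
    stop("grid has no cells: check bounds and resolution")
  structure(list(lon_min = lon_min, lon_max = lon_max,
                 lat_min = lat_min, lat_max = lat_max,
                 resolution = resolution,
                 n_rows = n_rows, n_cols = n_cols),
            class = "grid_spec")
}

#' Compact synthetic-study lattice
#'
#' A small grid (200 rows x 300 columns at 0.05 degrees, a 10 x 15 degree
#' window) over which the full pipeline runs in minutes; the default world
#' used by [make_world()].
#'
#' @param lon_min,lat_min lower-left corner (degrees).
#' @param n_rows,n_cols lattice dimensions.
#' @param resolution cell size in degrees.
#' @return A `grid_spec`.
#' @export
synthetic_grid <- function(lon_min = 0, lat_min = 40, n_rows = 200, n_cols = 300,
                           resolution = 0.05) {
  grid_spec(lon_min, lon_min + n_cols * resolution,
            lat_min, lat_min + n_rows * resolution, resolution)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d rows x %d cols at %g deg\n", x$n_rows, x$n_cols,
              x$resolution))
  cat(sprintf("  lon [%g, %g]  lat [%g, %g]\n", x$lon_min, x$lon_max,
              x$lat_min, x$lat_max))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

# cell id <-> (row, col); column-major like R matrices
cell_id <- function(grid, row, col) (col - 1L) * grid$n_rows + row
cell_row <- function(grid, id) ((id - 1L) %% grid$n_rows) + 1L
cell_col <- function(grid, id) ((id - 1L) %/% grid$n_rows) + 1L

#' Cell centers of a grid
#'
#' @param grid a [grid_spec()].
#' @param id integer cell ids (column-major, as in an R matrix over the
#'   grid); defaults to all cells.
#' @return A data frame with columns `id`, `row`, `col`, `lon`, `lat`.
#' @export
cell_center <- function(grid, id = seq_len(n_cells(grid))) {
  row <- cell_row(grid, id)
  col <- cell_col(grid, id)
  data.frame(id = id, row = row, col = col,
             lon = grid$lon_min + (col - 0.5) * grid$resolution,
             lat = grid$lat_min + (row - 0.5) * grid$resolution)
}

# latitude of each row center
row_lat <- function(grid, row = seq_len(grid$n_rows)) {
  grid$lat_min + (row - 0.5) * grid$resolution
}

#' Locate coordinates on a grid
#'
#' Maps points to half-open cells: `cell = floor((coord - origin)/res) + 1`,
#' so a point exactly on a cell boundary belongs to the higher-index cell.
#' Points outside the bounding box get `NA`.
#'
#' @param grid a [grid_spec()].
#' @param lon,lat coordinate vectors (degrees).
#' @return A data frame with columns `row`, `col`, `id` (`NA` outside grid).
#' @export
locate_cells <- function(grid, lon, lat) {
  col <- floor((lon - grid$lon_min) / grid$resolution) + 1
  row <- floor((lat - grid$lat_min) / grid$resolution) + 1
  inside <- row >= 1 & row <= grid$n_rows & col >= 1 & col <= grid$n_cols
  row[!inside] <- NA_integer_
  col[!inside] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col),
             id = ifelse(inside, cell_id(grid, as.integer(row), as.integer(col)),
                         NA_integer_))
}

same_grid <- function(a, b, tol = 1e-9) {
  all(abs(c(a$lon_min - b$lon_min, a$lat_min - b$lat_min,
            a$resolution - b$resolution)) < tol) &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

#' Grid-cell area
#'
#' Area of a `resolution x resolution` degree cell at a given latitude on a
#' spherical Earth: `(resolution * pi/180 * R)^2 * cos(lat)` with
#' `R = 6371.0088` km.
#'
#' @param latitude latitude of the cell center in degrees (|lat| < 90).
#' @param resolution cell size in degrees.
#' @return Cell area in square kilometres.
#' @export
#' @examples
#' cell_area_km2(0) # about 30.911 km2 for a 0.05 degree cell at the equator
cell_area_km2 <- function(latitude, resolution = 0.05) {
  stopifnot(all(abs(latitude) < 90))
  r_earth <- 6371.0088
  (resolution * pi / 180 * r_earth)^2 * cos(latitude * pi / 180)
}
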