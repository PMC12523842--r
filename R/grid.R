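#' Define a regular longitude/latitude analysis grid
#'
#' The analysis grid is a regular lon/lat lattice with its origin at the
#' south-west corner. Cell \code{(i, j)} (0-based) covers the half-open box
#' \code{[lon_min + j*res, lon_min + (j+1)*res) x [lat_min + i*res,
#' lat_min + (i+1)*res)}. The default corresponds to the North Pacific high-seas
#' study region, 135-180 E / 30-65 N at 1/12 degree.
#'
#' @param lon_min,lon_max,lat_min,lat_max Extent in decimal degrees.
#' @param res Cell size in degrees; must divide both extents into whole cells.
#' @return An object of class \code{grid_spec}: a list with the extent,
#'   resolution, cell counts \code{nx} (longitude) and \code{ny} (latitude),
#'   and cell-center coordinate vectors \code{lon} and \code{lat}.
#' @examples
#' g <- grid_spec()            # 540 x 420 cells
#' g$nx * g$ny                 # 226800
#' @export
grid_spec <- function(lon_min = 135, lon_max = 180, lat_min = 30, lat_max = 65,
                      res = 1 / 12) {
  if (!is.numeric(res) || length(res) != 1L || res <= 0)
    stop("`res` must be a single positive number", call. = FALSE)
  if (lon_min < -180 || lon_max > 180 || lat_min < -90 || lat_max > 90)
    stop("extent must lie within [-180, 180] x [-90, 90]", call. = FALSE)
  if (lon_max <= lon_min || lat_max <= lat_min)
    stop("extent is empty", call. = FALSE)
  nx <- (lon_max - lon_min) / res
  ny <- (lat_max - lat_min) / res
  if (abs(nx - round(nx)) > 1e-8 || abs(ny - round(ny)) > 1e-8)
    stop("`res` must divide the extent into whole cells", call. = FALSE)
  nx <- as.integer(round(nx)); ny <- as.integer(round(ny))
  structure(list(
    lon_min = lon_min, lon_max = lon_max,
    lat_min = lat_min, lat_max = lat_max,
    res = res, nx = nx, ny = ny,
    lon = lon_min + (seq_len(nx) - 0.5) * res,
    lat = lat_min + (seq_len(ny) - 0.5) * res
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %g-%g E x %g-%g N @ %g deg (%d x %d = %d cells)\n",
              x$lon_min, x$lon_max, x$lat_min, x$lat_max, x$res,
              x$nx, x$ny, x$nx * x$ny))
  invisible(x)
}

#' Map points to grid cells
#'
#' Returns 0-based cell indices following the half-open south-west-origin
#' convention; points outside the extent (including points exactly on the
#' north/east edge) get \code{NA}.
#'
#' @param lon,lat Point coordinates (degrees).
#' @param grid A \code{grid_spec}.
#' @return A data.frame with integer columns \code{cell_i} (latitude row) and
#'   \code{cell_j} (longitude column).
#' @export
cell_index <- function(lon, lat, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  j <- floor((lon - grid$lon_min) / grid$res)
  i <- floor((lat - grid$lat_min) / grid$res)
  bad <- j < 0 | j >= grid$nx | i < 0 | i >= grid$ny |
    is.na(lon) | is.na(lat)
  j[bad] <- NA_integer_; i[bad] <- NA_integer_
  data.frame(cell_i = as.integer(i), cell_j = as.integer(j))
}

#' Cell centers for 0-based cell indices
#' @inheritParams cell_index
#' @param cell_i,cell_j 0-based indices.
#' @return data.frame with \code{lon}, \code{lat} of cell centers.
#' @export
cell_center <- function(cell_i, cell_j, grid) {
  data.frame(lon = grid$lon_min + (cell_j + 0.5) * grid$res,
             lat = grid$lat_min + (cell_i + 0.5) * grid$res)
}

#' Spherical area of a grid cell
#'
#' Area of a \code{res x res} lon/lat cell on a sphere of radius 6371 km:
#' \code{R^2 * dlambda * (sin(phi2) - sin(phi1))}, with \code{phi1, phi2} the
#' cell's bounding parallels.
#'
#' @param lat_center Latitude of the cell center, degrees (vectorised).
#' @param res Cell size in degrees.
#' @return Area in km^2.
#' @examples
#' cell_area(0, 1)   # ~12364 km^2
#' @export
cell_area <- function(lat_center, res) {
  stopifnot(all(abs(lat_center) <= 90))
  R <- 6371
  phi1 <- (lat_center - res / 2) * pi / 180
  phi2 <- (lat_center + res / 2) * pi / 180
  R^2 * (res * pi / 180) * (sin(phi2) - sin(phi1))
}

#' Per-row cell areas for a grid
#'
#' @param grid A \code{grid_spec}.
#' @return Numeric vector of length \code{ny}: the area (km^2) of one cell in
#'   each latitude row (cells in a row share their area).
#' @export
grid_row_areas <- function(grid) cell_area(grid$lat, grid$res)

#' Great-circle distance between two points
#'
#' Haversine formula on a sphere of radius 6371 km.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (vectorised).
#' @return Distance in km.
#' @examples
#' haversine_km(0, 0, 1, 0)   # ~111.19
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  R <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

#' Initial great-circle bearing from point 1 to point 2
#'
#' @inheritParams haversine_km
#' @return Bearing in degrees in [0, 360), clockwise from north.
#' @export
bearing_deg <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlon <- (lon2 - lon1) * to_rad
  y <- sin(dlon) * cos(lat2 * to_rad)
  x <- cos(lat1 * to_rad) * sin(lat2 * to_rad) -
    sin(lat1 * to_rad) * cos(lat2 * to_rad) * cos(dlon)
  (atan2(y, x) / to_rad) %% 360
}
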