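#' Construct an environmental raster stack
#'
#' An \code{env_stack} bundles co-registered named layers (matrices with
#' \code{ny} rows = latitude, row 1 southernmost, and \code{nx} columns =
#' longitude) on one analysis grid, plus a period/scenario tag. Missing values
#' are \code{NA} in the layer matrices.
#'
#' @param grid A \code{grid_spec}.
#' @param layers Named list of \code{ny x nx} numeric matrices.
#' @param tag Character label, e.g. \code{"current"} or \code{"2100s SSP3-7.0"}.
#' @return An object of class \code{env_stack}.
#' @export
env_stack <- function(grid, layers, tag = "current") {
  stopifnot(inherits(grid, "grid_spec"), is.list(layers), length(layers) >= 1)
  if (is.null(names(layers)) || any(names(layers) == ""))
    stop("all layers must be named", call. = FALSE)
  for (nm in names(layers)) {
    m <- layers[[nm]]
    if (!is.matrix(m) || nrow(m) != grid$ny || ncol(m) != grid$nx)
      stop(sprintf("layer '%s' is not a %d x %d matrix", nm, grid$ny, grid$nx),
           call. = FALSE)
  }
  structure(list(grid = grid, layers = layers, tag = tag),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack '%s'> layers: %s on %d x %d grid\n", x$tag,
              paste(names(x$layers), collapse = ", "),
              x$grid$ny, x$grid$nx))
  invisible(x)
}

#' Current velocity magnitude from component layers
#'
#' Cellwise Euclidean magnitude \code{sqrt(Uo^2 + Vo^2)} of the eastward and
#' northward sea-water velocity components; missing wherever either component
#' is missing. Invariant under joint sign flip of both components.
#'
#' @param uo,vo Co-registered matrices (m/s).
#' @return Matrix of speeds (m/s), same dimensions.
#' @examples
#' derive_cv(matrix(3), matrix(4))  # 5
#' @export
derive_cv <- function(uo, vo) {
  if (!identical(dim(uo), dim(vo)))
    stop("Uo and Vo grids do not match", call. = FALSE)
  sqrt(uo^2 + vo^2)
}

#' Add a derived CV layer to a stack
#' @param stack An \code{env_stack} containing layers \code{Uo} and \code{Vo}.
#' @return The stack with a \code{CV} layer appended (replaced if present).
#' @export
add_cv <- function(stack) {
  stopifnot(inherits(stack, "env_stack"))
  if (!all(c("Uo", "Vo") %in% names(stack$layers)))
    stop("stack lacks Uo/Vo layers", call. = FALSE)
  stack$layers[["CV"]] <- derive_cv(stack$layers[["Uo"]], stack$layers[["Vo"]])
  stack
}

#' Resample a layer onto a target grid
#'
#' Regrids a single layer between regular lon/lat grids by interpolating at the
#' target cell centers. \code{"bilinear"} (default, for continuous fields) is
#' exact on constant and planar fields; \code{"nearest"} copies the value of
#' the nearest source cell center. Beyond the outermost source cell centers the
#' edge value is used (constant extrapolation within the overlap region).
#' Missing source values propagate: a bilinear target cell is \code{NA} if any
#' of its (up to four) contributing source cells is \code{NA}.
#'
#' @param layer Matrix on \code{src_grid}.
#' @param src_grid,target_grid \code{grid_spec}s; extents must overlap.
#' @param method \code{"bilinear"} or \code{"nearest"}.
#' @return Matrix on \code{target_grid}.
#' @export
resample_layer <- function(layer, src_grid, target_grid,
                           method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(is.matrix(layer),
            nrow(layer) == src_grid$ny, ncol(layer) == src_grid$nx)
  if (src_grid$lon_min >= target_grid$lon_max ||
      src_grid$lon_max <= target_grid$lon_min ||
      src_grid$lat_min >= target_grid$lat_max ||
      src_grid$lat_max <= target_grid$lat_min)
    stop("source and target extents are disjoint", call. = FALSE)

  # fractional position of target centers in source cell-center coordinates
  fx <- (target_grid$lon - src_grid$lon[1]) / src_grid$res
  fy <- (target_grid$lat - src_grid$lat[1]) / src_grid$res

  if (method == "nearest") {
    jx <- pmin(pmax(round(fx), 0), src_grid$nx - 1) + 1
    jy <- pmin(pmax(round(fy), 0), src_grid$ny - 1) + 1
    return(layer[jy, jx, drop = FALSE])
  }

  j0 <- pmin(pmax(floor(fx), 0), src_grid$nx - 1)
  i0 <- pmin(pmax(floor(fy), 0), src_grid$ny - 1)
  j1 <- pmin(j0 + 1, src_grid$nx - 1)
  i1 <- pmin(i0 + 1, src_grid$ny - 1)
  wx <- pmin(pmax(fx - j0, 0), 1)   # clamped: constant extrapolation at edges
  wy <- pmin(pmax(fy - i0, 0), 1)

  A <- layer[i0 + 1, j0 + 1, drop = FALSE]
  B <- layer[i0 + 1, j1 + 1, drop = FALSE]
  C <- layer[i1 + 1, j0 + 1, drop = FALSE]
  D <- layer[i1 + 1, j1 + 1, drop = FALSE]
  WX <- matrix(wx, nrow = target_grid$ny, ncol = target_grid$nx, byrow = TRUE)
  WY <- matrix(wy, nrow = target_grid$ny, ncol = target_grid$nx)
  A * (1 - WX) * (1 - WY) + B * WX * (1 - WY) +
    C * (1 - WX) * WY + D * WX * WY
}

#' Climatological mean of monthly layers
#'
#' Cellwise arithmetic mean of a list of co-registered monthly layers, ignoring
#' missing values; a cell is missing in the output only when it is missing in
#' every month.
#'
#' @param monthly_layers Non-empty list of matrices of identical dimensions.
#' @return Matrix of per-cell means.
#' @export
climatology <- function(monthly_layers) {
  if (!is.list(monthly_layers) || length(monthly_layers) == 0)
    stop("need at least one monthly layer", call. = FALSE)
  d <- dim(monthly_layers[[1]])
  for (m in monthly_layers)
    if (!identical(dim(m), d)) stop("layers on different grids", call. = FALSE)
  tot <- matrix(0, d[1], d[2])
  cnt <- matrix(0L, d[1], d[2])
  for (m in monthly_layers) {
    ok <- !is.na(m)
    tot[ok] <- tot[ok] + m[ok]
    cnt <- cnt + ok
  }
  out <- tot / cnt
  out[cnt == 0L] <- NA_real_
  out
}

#' Variance inflation factors for a predictor table
#'
#' For each variable j, regresses it on all other variables (with intercept,
#' via ordinary least squares) and reports \code{VIF_j = 1 / (1 - R^2_j)}
#' together with a pass flag against the conventional screening threshold.
#' Perfectly collinear variables are reported with \code{Inf}, not an error.
#'
#' @param table data.frame of predictor values at occurrence points.
#' @param variables Character vector of column names (>= 2).
#' @param threshold Pass threshold; default 5 (moderate collinearity).
#' @return data.frame with columns \code{variable}, \code{vif},
#'   \code{pass_lt_threshold}.
#' @export
vif_screen <- function(table, variables = colnames(table), threshold = 5) {
  stopifnot(length(variables) >= 2, all(variables %in% colnames(table)))
  tab <- stats::na.omit(table[, variables, drop = FALSE])
  if (nrow(tab) < length(variables) + 1)
    stop("need at least p + 1 complete rows", call. = FALSE)
  sds <- vapply(tab, stats::sd, numeric(1))
  if (any(sds == 0))
    stop(sprintf("constant column(s): %s",
                 paste(variables[sds == 0], collapse = ", ")), call. = FALSE)
  vifs <- vapply(variables, function(v) {
    fit <- stats::lm(stats::reformulate(setdiff(variables, v), response = v),
                     data = tab)
    # perfect fits are reported as unbounded VIF below; silence the
    # "essentially perfect fit" note summary.lm emits for them
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(variable = variables, vif = unname(vifs),
             pass_lt_threshold = unname(vifs) < threshold,
             row.names = NULL)
}

#' Extract predictor values at grid cells
#'
#' Value of the containing cell (no interpolation), matching the thinning grid.
#'
#' @param stack An \code{env_stack}.
#' @param cell_i,cell_j 0-based cell indices.
#' @param variables Layer names; default all layers.
#' @return data.frame, one column per variable.
#' @export
extract_cells <- function(stack, cell_i, cell_j,
                          variables = names(stack$layers)) {
  stopifnot(all(variables %in% names(stack$layers)))
  idx <- cbind(cell_i + 1L, cell_j + 1L)
  out <- lapply(variables, function(v) stack$layers[[v]][idx])
  names(out) <- variables
  as.data.frame(out)
}

# ---- stack I/O ------------------------------------------------------------

#' Write / read an environmental stack as long-form CSV
#'
#' Plain-text interchange format: one row per (cell, variable) with cell-center
#' coordinates. Grid metadata travel in a header comment line.
#'
#' @param stack An \code{env_stack}.
#' @param path Output file.
#' @return \code{write_stack_csv}: the path, invisibly. \code{read_stack_csv}:
#'   an \code{env_stack}.
#' @export
write_stack_csv <- function(stack, path) {
  g <- stack$grid
  hdr <- sprintf("# grid %g %g %g %g %g tag=%s",
                 g$lon_min, g$lon_max, g$lat_min, g$lat_max, g$res, stack$tag)
  long <- do.call(rbind, lapply(names(stack$layers), function(v) {
    data.frame(variable = v,
               cell_i = rep(0:(g$ny - 1L), times = g$nx),
               cell_j = rep(0:(g$nx - 1L), each = g$ny),
               value = as.vector(stack$layers[[v]]))
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(long, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stack_csv
#' @export
read_stack_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec(
    "^# grid (\\S+) (\\S+) (\\S+) (\\S+) (\\S+) tag=(.*)$", hdr))[[1]]
  if (length(m) != 7) stop("not a stack CSV (missing grid header)", call. = FALSE)
  g <- grid_spec(as.numeric(m[2]), as.numeric(m[3]),
                 as.numeric(m[4]), as.numeric(m[5]), as.numeric(m[6]))
  long <- utils::read.csv(path, skip = 1)
  layers <- lapply(split(long, long$variable), function(d) {
    mat <- matrix(NA_real_, g$ny, g$nx)
    mat[cbind(d$cell_i + 1L, d$cell_j + 1L)] <- d$value
    mat
  })
  env_stack(g, layers, tag = sub("^tag=", "", m[7]))
}

#' Write / read an environmental stack as NetCDF
#'
#' One NetCDF variable per layer on CF-style \code{lon}/\code{lat} coordinate
#' dimensions (cell centers). Requires the \pkg{ncdf4} package.
#'
#' @inheritParams write_stack_csv
#' @export
write_stack_nc <- function(stack, path) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("NetCDF I/O requires the 'ncdf4' package", call. = FALSE)
  g <- stack$grid
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", g$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", g$lat)
  vars <- lapply(names(stack$layers), function(v)
    ncdf4::ncvar_def(v, "", list(dlon, dlat), missval = NA_real_, prec = "double"))
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  for (k in seq_along(vars))
    ncdf4::ncvar_put(nc, vars[[k]], t(stack$layers[[k]]))  # nc is (lon, lat)
  ncdf4::ncatt_put(nc, 0, "tag", stack$tag)
  invisible(path)
}

#' @rdname write_stack_nc
#' @export
read_stack_nc <- function(path) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("NetCDF I/O requires the 'ncdf4' package", call. = FALSE)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  lon <- as.vector(ncdf4::ncvar_get(nc, "lon"))
  lat <- as.vector(ncdf4::ncvar_get(nc, "lat"))
  res <- lon[2] - lon[1]
  g <- grid_spec(min(lon) - res / 2, max(lon) + res / 2,
                 min(lat) - res / 2, max(lat) + res / 2, res)
  layers <- lapply(names(nc$var), function(v) t(ncdf4::ncvar_get(nc, v)))
  names(layers) <- names(nc$var)
  tag <- ncdf4::ncatt_get(nc, 0, "tag")
  env_stack(g, layers, tag = if (isTRUE(tag$hasatt)) tag$value else "current")
}
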