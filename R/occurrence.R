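#' Spatially thin presence points to one per grid cell
#'
#' Fishery-dependent presence points are heavily clustered along fishing
#' grounds; retaining one record per analysis cell removes much of the
#' sampling bias and the worst spatial pseudo-replication. The retained record
#' per occupied cell is the first by input order (deterministic); optionally
#' its coordinates are replaced by the cell center. Points outside the grid
#' extent are dropped with a message.
#'
#' @param points data.frame with \code{lon}, \code{lat} columns.
#' @param grid A \code{grid_spec}.
#' @param representative \code{"first"} (keep the retained point's own
#'   coordinates) or \code{"center"} (cell-center coordinates).
#' @return data.frame with \code{cell_i}, \code{cell_j}, \code{lon},
#'   \code{lat}, \code{n_in_cell} (pre-thinning count), \code{role =
#'   "presence"}; zero rows for empty input.
#' @export
spatial_thin <- function(points, grid, representative = c("first", "center")) {
  representative <- match.arg(representative)
  stopifnot(all(c("lon", "lat") %in% colnames(points)))
  if (nrow(points) == 0)
    return(data.frame(cell_i = integer(0), cell_j = integer(0),
                      lon = numeric(0), lat = numeric(0),
                      n_in_cell = integer(0), role = character(0)))
  idx <- cell_index(points$lon, points$lat, grid)
  inside <- !is.na(idx$cell_i)
  n_out <- sum(!inside)
  if (n_out > 0)
    message(sprintf("spatial_thin: dropped %d point(s) outside the grid extent",
                    n_out))
  pts <- points[inside, , drop = FALSE]
  idx <- idx[inside, , drop = FALSE]
  key <- idx$cell_i * grid$nx + idx$cell_j
  first <- !duplicated(key)
  counts <- table(key)
  out <- data.frame(cell_i = idx$cell_i[first], cell_j = idx$cell_j[first],
                    lon = pts$lon[first], lat = pts$lat[first],
                    n_in_cell = as.integer(counts[as.character(key[first])]),
                    role = "presence", row.names = NULL)
  if (representative == "center") {
    cc <- cell_center(out$cell_i, out$cell_j, grid)
    out$lon <- cc$lon; out$lat <- cc$lat
  }
  out
}

#' Sample background (pseudo-absence) cells
#'
#' Uniform random cells over the full study extent, without replacement,
#' deterministic for a fixed seed. Background cells may coincide with presence
#' cells by default (true pseudo-absences over the entire study area);
#' exclusion is available.
#'
#' @param grid A \code{grid_spec}.
#' @param n Number of background points (the full-data fishery analysis uses
#'   50000; synthetic runs scale this down via configuration).
#' @param seed Integer seed.
#' @param exclude_cells Optional data.frame with \code{cell_i}, \code{cell_j}
#'   to exclude (e.g. presence cells).
#' @return data.frame with \code{cell_i}, \code{cell_j}, \code{lon},
#'   \code{lat} (cell centers), \code{role = "background"}.
#' @export
sample_background <- function(grid, n, seed = 1, exclude_cells = NULL) {
  ncell <- grid$nx * grid$ny
  eligible <- seq_len(ncell) - 1L          # 0-based flat index i*nx + j
  if (!is.null(exclude_cells) && nrow(exclude_cells) > 0) {
    excl <- exclude_cells$cell_i * grid$nx + exclude_cells$cell_j
    eligible <- setdiff(eligible, excl)
  }
  if (n > length(eligible))
    stop(sprintf("n = %d exceeds the %d eligible cells", n, length(eligible)),
         call. = FALSE)
  keys <- withr::with_seed(seed, sample(eligible, n))
  ci <- keys %/% grid$nx
  cj <- keys %% grid$nx
  cc <- cell_center(ci, cj, grid)
  data.frame(cell_i = as.integer(ci), cell_j = as.integer(cj),
             lon = cc$lon, lat = cc$lat, role = "background")
}

#' Assemble an occurrence set
#'
#' Binds thinned presences and sampled background records on a common grid.
#'
#' @param presences Output of \code{\link{spatial_thin}}.
#' @param background Output of \code{\link{sample_background}}.
#' @param grid The shared \code{grid_spec}.
#' @return Object of class \code{occurrence_set}: data.frame with a
#'   \code{role} column plus the grid as an attribute.
#' @export
occurrence_set <- function(presences, background, grid) {
  cols <- c("cell_i", "cell_j", "lon", "lat", "role")
  occ <- rbind(presences[, cols], background[, cols])
  attr(occ, "grid") <- grid
  class(occ) <- c("occurrence_set", "data.frame")
  occ
}

#' Build the model-fitting table
#'
#' Extracts predictor values at each occurrence's grid cell (containing-cell
#' value, no interpolation) and attaches the binary response \code{pa}
#' (1 = presence, 0 = background). Rows with any missing predictor are dropped
#' with a message.
#'
#' @param occ An \code{occurrence_set} (or data.frame with \code{cell_i},
#'   \code{cell_j}, \code{role}).
#' @param stack The fitted-period \code{env_stack}.
#' @param variables Predictor layer names.
#' @return data.frame: predictors, \code{pa}, \code{cell_i}, \code{cell_j}.
#' @export
build_model_table <- function(occ, stack,
                              variables = c("SST", "CHL", "SSS", "MLD",
                                            "CV")) {
  vals <- extract_cells(stack, occ$cell_i, occ$cell_j, variables)
  tab <- cbind(vals,
               pa = as.integer(occ$role == "presence"),
               occ[, c("cell_i", "cell_j")])
  keep <- stats::complete.cases(tab[, variables, drop = FALSE])
  if (any(!keep))
    message(sprintf("build_model_table: dropped %d row(s) with missing predictors",
                    sum(!keep)))
  tab[keep, , drop = FALSE]
}
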