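#' Habitat suitability map
#'
#' Per-cell suitability in [0, 1] on the analysis grid for one period/scenario,
#' with \code{NA} for missing cells.
#'
#' @param grid A \code{grid_spec}.
#' @param hsi \code{ny x nx} matrix of suitabilities.
#' @param tag Period/scenario label.
#' @return Object of class \code{hsi_map}.
#' @export
hsi_map <- function(grid, hsi, tag = "current") {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(hsi),
            nrow(hsi) == grid$ny, ncol(hsi) == grid$nx)
  if (any(!is.na(hsi))) {
    rng <- range(hsi, na.rm = TRUE)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      stop("suitability must lie in [0, 1]", call. = FALSE)
  }
  structure(list(grid = grid, hsi = hsi, tag = tag), class = "hsi_map")
}

#' @export
print.hsi_map <- function(x, ...) {
  cat(sprintf("<hsi_map '%s'> %d x %d, mean %.3f\n", x$tag,
              x$grid$ny, x$grid$nx, mean(x$hsi, na.rm = TRUE)))
  invisible(x)
}

#' Project an ensemble onto an environmental stack
#'
#' Evaluates the ensemble cellwise over the stack's predictor layers; cells
#' with any missing predictor are missing in the output.
#'
#' @param ensemble An \code{sdm_ensemble}.
#' @param stack An \code{env_stack} containing every model predictor.
#' @return An \code{hsi_map} tagged with the stack's tag.
#' @export
project_ensemble <- function(ensemble, stack) {
  stopifnot(inherits(ensemble, "sdm_ensemble"), inherits(stack, "env_stack"))
  missing <- setdiff(ensemble$variables, names(stack$layers))
  if (length(missing))
    stop(sprintf("stack lacks predictor layer(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  g <- stack$grid
  tab <- as.data.frame(lapply(stack$layers[ensemble$variables], as.vector))
  ok <- stats::complete.cases(tab)
  out <- rep(NA_real_, nrow(tab))
  if (any(ok)) out[ok] <- predict_ensemble(ensemble, tab[ok, , drop = FALSE])
  hsi_map(g, matrix(out, g$ny, g$nx), tag = stack$tag)
}

#' Zonal habitat areas
#'
#' Classifies cells into the four suitability zones — Non-Suitable [0, 0.4),
#' Low [0.4, 0.6), Moderate [0.6, 0.8), High [0.8, 1.0] (bins left-closed,
#' top bin closed) — and sums spherical cell areas per zone. The zone areas
#' sum to the total non-missing study area.
#'
#' @param map An \code{hsi_map}.
#' @param breaks Zone edges (default \code{c(0, 0.4, 0.6, 0.8, 1)}).
#' @return data.frame with \code{zone}, \code{hsi_min}, \code{hsi_max},
#'   \code{area_km2}.
#' @export
zone_areas <- function(map, breaks = c(0, 0.4, 0.6, 0.8, 1)) {
  stopifnot(inherits(map, "hsi_map"))
  if (all(is.na(map$hsi))) stop("all-missing suitability map", call. = FALSE)
  g <- map$grid
  area_m <- matrix(grid_row_areas(g), g$ny, g$nx)
  zones <- c("Non-Suitable", "Low", "Moderate", "High")[
    seq_len(length(breaks) - 1)]
  cls <- findInterval(map$hsi, breaks, rightmost.closed = TRUE)
  cls[cls < 1] <- NA; cls[cls > length(zones)] <- NA
  areas <- vapply(seq_along(zones), function(k)
    sum(area_m[which(cls == k)]), numeric(1))
  data.frame(zone = zones,
             hsi_min = breaks[-length(breaks)], hsi_max = breaks[-1],
             area_km2 = areas)
}

#' Habitat transition map between two periods
#'
#' Binarizes both maps at a suitability threshold and classifies each
#' non-missing cell as improvement (unsuitable to suitable), degradation
#' (suitable to unsuitable), stable suitable, or stable unsuitable. The four
#' categories partition the classified cells; percentages are over total
#' classified area.
#'
#' @param current,future \code{hsi_map}s on the same grid.
#' @param threshold Binarization threshold (default 0.4, the Non-Suitable
#'   boundary).
#' @return List with \code{map} (character matrix of categories),
#'   \code{areas} (data.frame: category, area_km2, pct), \code{threshold}.
#' @export
transitions <- function(current, future, threshold = 0.4) {
  stopifnot(inherits(current, "hsi_map"), inherits(future, "hsi_map"))
  if (!identical(dim(current$hsi), dim(future$hsi)))
    stop("grids do not match", call. = FALSE)
  g <- current$grid
  cur <- current$hsi >= threshold
  fut <- future$hsi >= threshold
  cat_m <- matrix(NA_character_, g$ny, g$nx)
  cat_m[!cur & fut] <- "improvement"
  cat_m[cur & !fut] <- "degradation"
  cat_m[cur & fut] <- "stable suitable"
  cat_m[!cur & !fut] <- "stable unsuitable"
  area_m <- matrix(grid_row_areas(g), g$ny, g$nx)
  cats <- c("improvement", "degradation", "stable suitable",
            "stable unsuitable")
  areas <- vapply(cats, function(k)
    sum(area_m[which(cat_m == k)]), numeric(1))
  total <- sum(areas)
  list(map = cat_m,
       areas = data.frame(category = cats, area_km2 = unname(areas),
                          pct = unname(100 * areas / total)),
       threshold = threshold)
}

#' Habitat centroid
#'
#' Area-weighted geographic center of the habitat: in the default
#' suitability-weighted mode the weights are HSI times spherical cell area;
#' in binary mode, cell area over cells at or above the threshold.
#'
#' @param map An \code{hsi_map}.
#' @param mode \code{"weighted"} or \code{"binary"}.
#' @param threshold Suitability threshold for binary mode (default 0.4).
#' @return List with \code{lon}, \code{lat}, \code{mode}.
#' @export
hsi_centroid <- function(map, mode = c("weighted", "binary"),
                         threshold = 0.4) {
  mode <- match.arg(mode)
  g <- map$grid
  area_m <- matrix(grid_row_areas(g), g$ny, g$nx)
  w <- if (mode == "weighted") map$hsi * area_m
       else (map$hsi >= threshold) * area_m
  w[is.na(w)] <- 0
  if (sum(w) <= 0) stop("no cell carries positive weight", call. = FALSE)
  lonm <- matrix(g$lon, g$ny, g$nx, byrow = TRUE)
  latm <- matrix(g$lat, g$ny, g$nx)
  list(lon = sum(w * lonm) / sum(w), lat = sum(w * latm) / sum(w),
       mode = mode)
}

#' Great-circle displacement between two centroids
#'
#' @param a,b Centroids (lists with \code{lon}, \code{lat}).
#' @return List with \code{km} (haversine distance, R = 6371 km) and
#'   \code{bearing_deg} (initial bearing a -> b, clockwise from north).
#' @export
centroid_displacement <- function(a, b) {
  list(km = haversine_km(a$lon, a$lat, b$lon, b$lat),
       bearing_deg = bearing_deg(a$lon, a$lat, b$lon, b$lat))
}
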