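#' Niche ground truth for synthetic experiments
#'
#' Describes the simulated species' environmental niche as one scaled Gaussian
#' response per variable: \code{g_v(x) = exp(-0.5 ((x - optimum)/width)^2)},
#' combined as the weighted product \code{prod_v g_v(x)^weight_v}, which is 1
#' exactly when every variable sits at its optimum and lies in [0, 1]
#' everywhere.
#'
#' Defaults encode the cold-water, mid-pelagic preferences of Pacific saury:
#' a narrow thermal optimum near 9.5 C, peak suitability near chlorophyll-a
#' 0.5 mg m-3, mixed-layer optimum ~44 m, preference for weak currents
#' (< 0.3 m/s) and for salinity above ~32.5 permille. Weights set SST as the
#' dominant driver, CHL second.
#'
#' @param responses data.frame with columns \code{variable}, \code{optimum},
#'   \code{width}, \code{weight}. Widths are in the variable's units; weights
#'   in [0, 1].
#' @return Object of class \code{niche_truth}.
#' @export
niche_truth <- function(responses = NULL) {
  if (is.null(responses)) {
    responses <- data.frame(
      variable = c("SST", "CHL", "MLD", "SSS", "CV"),
      optimum  = c(9.5,   0.5,   44,    34,    0),
      width    = c(1.5,   0.2,   11,    1.2,   0.3),
      weight   = c(1.0,   0.7,   0.3,   0.2,   0.2)
    )
  }
  stopifnot(all(c("variable", "optimum", "width", "weight") %in%
                  colnames(responses)),
            all(responses$width > 0),
            all(responses$weight >= 0 & responses$weight <= 1))
  structure(list(responses = responses), class = "niche_truth")
}

#' Gaussian response curve
#' @param x Values in the variable's units.
#' @param optimum,width Peak location and Gaussian width (same units).
#' @return Response in [0, 1], 1 at the optimum.
#' @export
gaussian_response <- function(x, optimum, width)
  exp(-0.5 * ((x - optimum) / width)^2)

#' True suitability of an environmental stack under a known niche
#'
#' Cellwise weighted product of the per-variable Gaussian responses.
#'
#' @param stack An \code{env_stack} containing every variable named in
#'   \code{truth}.
#' @param truth A \code{niche_truth}.
#' @return An \code{hsi_map} with values in [0, 1].
#' @export
true_suitability <- function(stack, truth) {
  stopifnot(inherits(stack, "env_stack"), inherits(truth, "niche_truth"))
  rs <- truth$responses
  missing <- setdiff(rs$variable, names(stack$layers))
  if (length(missing))
    stop(sprintf("stack lacks layer(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  g <- stack$grid
  s <- matrix(1, g$ny, g$nx)
  for (k in seq_len(nrow(rs))) {
    resp <- gaussian_response(stack$layers[[rs$variable[k]]],
                              rs$optimum[k], rs$width[k])
    s <- s * resp^rs$weight[k]
  }
  hsi_map(g, s, tag = paste0("truth:", stack$tag))
}

# Gaussian-filtered white noise, rescaled to unit variance. Correlation
# length is set in degrees so texture is resolution-independent in spirit
# (not in realisation).
smooth_noise <- function(grid, corr_deg = 1.0) {
  sigma <- max(corr_deg / grid$res, 0.75)
  kern1d <- function(n) {
    centers <- seq_len(n)
    K <- outer(centers, centers,
               function(a, b) exp(-0.5 * ((a - b) / sigma)^2))
    K / rowSums(K)
  }
  Klat <- kern1d(grid$ny)
  Klon <- kern1d(grid$nx)
  z <- matrix(stats::rnorm(grid$ny * grid$nx), grid$ny, grid$nx)
  sm <- Klat %*% z %*% t(Klon)
  sm / stats::sd(sm)
}

# Deterministic (noise-free) trend functions of the synthetic ocean. SST is a
# pure monotone function of latitude; CHL carries a zonal Gaussian ridge (a
# productivity front) so the truly suitable habitat is localised in longitude
# as well as latitude.
synthetic_trends <- function() {
  list(
    SST = function(lon, lat) 24 - 0.62 * (lat - 30),
    CHL = function(lon, lat)
      exp(log(0.1) + log(0.5 / 0.1) * exp(-((lon - 150)^2) / (2 * 6^2))),
    SSS = function(lon, lat) 34.2 - 0.03 * (lat - 30),
    MLD = function(lon, lat) 38 + 0.2 * (lat - 30),
    Uo  = function(lon, lat) 0.05 + 0 * lon,
    Vo  = function(lon, lat) 0.05 + 0 * lon
  )
}

#' Generate a synthetic baseline environmental stack
#'
#' Builds co-registered SST, CHL, SSS, MLD, Uo, Vo layers (plus derived CV) on
#' the requested grid: each layer is a smooth deterministic trend plus
#' spatially autocorrelated (Gaussian-filtered) noise. SST decreases
#' monotonically with latitude; CHL is log-normal (strictly positive) with a
#' zonal productivity ridge; MLD is kept positive. The generator is a pure
#' function of (grid, seed, noise_sd): the same arguments reproduce the stack
#' bit-identically.
#'
#' @param grid A \code{grid_spec} (default: full study grid at 1/12 degree).
#' @param seed Integer seed.
#' @param noise_sd Named list of noise standard deviations per variable (CHL's
#'   is on the log scale). Set a value to 0 for a noise-free layer.
#' @return An \code{env_stack} tagged \code{"current"}, carrying its trend
#'   functions in \code{attr(, "trends")} so scenario deltas can translate
#'   them.
#' @export
make_env_stack <- function(grid = grid_spec(), seed = 1,
                           noise_sd = list(SST = 0.6, CHL = 0.2, SSS = 0.2,
                                           MLD = 5, Uo = 0.08, Vo = 0.08)) {
  stopifnot(inherits(grid, "grid_spec"))
  trends <- synthetic_trends()
  lonm <- matrix(grid$lon, grid$ny, grid$nx, byrow = TRUE)
  latm <- matrix(grid$lat, grid$ny, grid$nx)
  layers <- withr::with_seed(seed, {
    out <- list()
    for (v in names(trends)) {
      tr <- trends[[v]](lonm, latm)
      sdv <- if (is.null(noise_sd[[v]])) 0 else noise_sd[[v]]
      nz <- if (sdv > 0) sdv * smooth_noise(grid) else 0
      out[[v]] <- if (v == "CHL") exp(log(tr) + nz) else tr + nz
    }
    out$MLD <- pmax(out$MLD, 1)
    out
  })
  stack <- env_stack(grid, layers, tag = "current")
  stack <- add_cv(stack)
  attr(stack, "trends") <- trends
  stack
}

#' Define a climate-scenario perturbation of a baseline stack
#'
#' A scenario delta perturbs selected variables additively:
#' \code{delta_v(lon, lat) = add + lat_grad * (lat - lat_min) + lon_grad *
#' (lon - lon_min)}, optionally plus a rigid translation of the variable's
#' deterministic trend by \code{(shift_dlat, shift_dlon)} degrees (used to
#' move the niche by a known displacement in recovery experiments; requires a
#' stack produced by \code{\link{make_env_stack}}).
#'
#' @param label Scenario label (e.g. \code{"SSP5-8.5"}).
#' @param period Period label (\code{"2050s"} or \code{"2100s"}).
#' @param terms Named list; per variable a list with any of \code{add},
#'   \code{lat_grad}, \code{lon_grad} (units of the variable, per degree for
#'   the gradients).
#' @param shift Optional list \code{(dlat, dlon, variables)}: translate those
#'   variables' trends by the given offset.
#' @return Object of class \code{scenario_delta}.
#' @export
scenario_delta <- function(label = "custom", period = "2050s",
                           terms = list(), shift = NULL) {
  for (tm in terms)
    stopifnot(all(names(tm) %in% c("add", "lat_grad", "lon_grad")))
  structure(list(label = label, period = period, terms = terms, shift = shift),
            class = "scenario_delta")
}

#' Default scenario/period delta library
#'
#' Plausible CMIP6-style perturbations for the four Shared Socioeconomic
#' Pathways at mid-century (2050s) and end-of-century (2100s): surface warming
#' increasing with emission intensity, with a weak poleward amplification
#' gradient; a slight chlorophyll decline; mixed-layer shoaling; minor
#' salinification.
#'
#' @return Named list of \code{scenario_delta}s keyed \code{"<period> <SSP>"}.
#' @export
default_scenario_deltas <- function() {
  sst_add <- c("SSP1-2.6" = 0.8, "SSP2-4.5" = 1.0,
               "SSP3-7.0" = 1.3, "SSP5-8.5" = 1.5)
  sst_add_2100 <- c("SSP1-2.6" = 1.2, "SSP2-4.5" = 2.0,
                    "SSP3-7.0" = 3.2, "SSP5-8.5" = 4.0)
  out <- list()
  for (period in c("2050s", "2100s")) {
    adds <- if (period == "2050s") sst_add else sst_add_2100
    for (ssp in names(adds)) {
      f <- adds[[ssp]] / 4          # intensity relative to strongest warming
      out[[paste(period, ssp)]] <- scenario_delta(
        label = ssp, period = period,
        terms = list(
          SST = list(add = adds[[ssp]], lat_grad = 0.01 * f),
          CHL = list(add = -0.06 * f),
          MLD = list(add = -6 * f),
          SSS = list(add = 0.2 * f)
        ))
    }
  }
  out
}

#' Apply a scenario delta to a stack
#'
#' Returns a new stack; the baseline is left untouched. A delta with no terms
#' and no shift returns the stack bit-identically. CHL is floored at a small
#' positive value and MLD at 1 m to keep layers physically admissible; the
#' derived CV layer is recomputed if Uo or Vo changed.
#'
#' @param stack An \code{env_stack}.
#' @param delta A \code{scenario_delta}; may only name variables present in
#'   the stack.
#' @return A new \code{env_stack} tagged \code{"<period> <label>"}.
#' @export
apply_scenario <- function(stack, delta) {
  stopifnot(inherits(stack, "env_stack"), inherits(delta, "scenario_delta"))
  bad <- setdiff(names(delta$terms), names(stack$layers))
  if (length(bad))
    stop(sprintf("delta names variable(s) absent from stack: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  g <- stack$grid
  lonm <- matrix(g$lon, g$ny, g$nx, byrow = TRUE)
  latm <- matrix(g$lat, g$ny, g$nx)
  out <- stack
  touched <- character(0)
  for (v in names(delta$terms)) {
    tm <- delta$terms[[v]]
    add <- if (is.null(tm$add)) 0 else tm$add
    lg <- if (is.null(tm$lat_grad)) 0 else tm$lat_grad
    lo <- if (is.null(tm$lon_grad)) 0 else tm$lon_grad
    if (add == 0 && lg == 0 && lo == 0) next
    out$layers[[v]] <- out$layers[[v]] + add +
      lg * (latm - g$lat_min) + lo * (lonm - g$lon_min)
    touched <- c(touched, v)
  }
  if (!is.null(delta$shift)) {
    trends <- attr(stack, "trends")
    if (is.null(trends))
      stop("shift deltas need a stack with trend functions (make_env_stack)",
           call. = FALSE)
    sh <- delta$shift
    for (v in sh$variables) {
      if (!v %in% names(stack$layers))
        stop(sprintf("shift names variable absent from stack: %s", v),
             call. = FALSE)
      tr <- trends[[v]]
      # CHL is log-normal (trend x multiplicative noise): translate its trend
      # multiplicatively so the structure moves rigidly in log space;
      # additive-noise layers translate additively
      if (v == "CHL") {
        out$layers[[v]] <- out$layers[[v]] *
          tr(lonm - sh$dlon, latm - sh$dlat) / tr(lonm, latm)
      } else {
        out$layers[[v]] <- out$layers[[v]] +
          tr(lonm - sh$dlon, latm - sh$dlat) - tr(lonm, latm)
      }
      touched <- c(touched, v)
    }
  }
  if (length(touched) == 0) return(stack)
  if ("CHL" %in% touched) out$layers$CHL <- pmax(out$layers$CHL, 0.005)
  if ("MLD" %in% touched) out$layers$MLD <- pmax(out$layers$MLD, 1)
  if (any(c("Uo", "Vo") %in% touched) && "CV" %in% names(out$layers))
    out <- add_cv(out)
  attr(out, "trends") <- attr(stack, "trends")
  out$tag <- paste(delta$period, delta$label)
  out
}

#' Delta that translates the niche by a known displacement
#'
#' Convenience wrapper: a \code{scenario_delta} that rigidly translates the
#' deterministic trends of the niche-defining variables by \code{(dlat, dlon)}
#' degrees, so the truly suitable habitat moves by a known great-circle
#' distance — the ground truth for centroid-shift recovery experiments.
#'
#' @param dlat,dlon Translation in degrees (positive = north / east).
#' @param variables Trend layers to translate.
#' @return A \code{scenario_delta}.
#' @export
shift_delta <- function(dlat, dlon, variables = c("SST", "CHL")) {
  scenario_delta(label = sprintf("shift(%+.2f,%+.2f)", dlat, dlon),
                 period = "synthetic",
                 shift = list(dlat = dlat, dlon = dlon, variables = variables))
}

# ---- vessel trajectories --------------------------------------------------

#' Local solar hour and night test
#'
#' Local solar time approximated as UTC + longitude / 15 hours.
#'
#' @param timestamp POSIXct (UTC).
#' @param lon Longitude, degrees.
#' @return \code{local_solar_hour}: hour in [0, 24).
#' @export
local_solar_hour <- function(timestamp, lon) {
  utc_h <- as.numeric(timestamp - as.POSIXct(trunc(timestamp, "days"),
                                             tz = "UTC"),
                      units = "hours")
  (utc_h + lon / 15) %% 24
}

#' Simulate vessel trajectories over a suitability field
#'
#' Emits AIS-like position fixes for a fleet alternating between two labelled
#' behavioural states. In transit, vessels steam (speeds above 6 knots, nearly
#' constant heading) toward target cells sampled preferentially from
#' high-suitability water. On arriving at night they switch to fishing:
#' stick-held dip-net style operation with low speeds (0.1-4.0 knots), long
#' drifting spells below 1 knot, and large heading swings; fishing ends at
#' dawn. Significant wave height follows a per-vessel AR(1) sea state, mostly
#' below 2.5 m. Every fix carries its ground-truth state label.
#'
#' @param stack Baseline \code{env_stack}.
#' @param truth \code{niche_truth} defining where fishing concentrates.
#' @param n_vessels,n_fixes Fleet size and fixes per vessel.
#' @param seed Integer seed (the simulation is a pure function of its
#'   arguments and this seed).
#' @param dt_min Fix cadence in minutes (AIS report interval).
#' @param p_fish Probability a vessel starts fishing on reaching its target at
#'   night; 0 gives an all-transit fleet.
#' @param start POSIXct start time (UTC).
#' @return data.frame with columns \code{vessel_id}, \code{timestamp} (UTC),
#'   \code{lon}, \code{lat}, \code{sog_kn}, \code{cog_deg}, \code{swh_m},
#'   \code{true_state}.
#' @export
simulate_trajectories <- function(stack, truth, n_vessels = 20,
                                  n_fixes = 2000, seed = 1, dt_min = 10,
                                  p_fish = 0.95,
                                  start = as.POSIXct("2023-06-01 00:00:00",
                                                     tz = "UTC")) {
  stopifnot(n_vessels >= 1, n_fixes >= 2)
  g <- stack$grid
  S <- true_suitability(stack, truth)$hsi
  if (all(S <= 0 | is.na(S)))
    stop("degenerate grid: suitability is zero everywhere", call. = FALSE)
  w <- as.vector(S)^3
  w[is.na(w)] <- 0
  cells <- which(w > 0)
  wp <- w[cells] / sum(w[cells])
  dt_h <- dt_min / 60
  times <- start + (seq_len(n_fixes) - 1) * dt_min * 60

  sample_target <- function() {
    k <- cells[sample.int(length(cells), 1, prob = wp)]
    i <- (k - 1) %% g$ny          # row (lat)
    j <- (k - 1) %/% g$ny         # col (lon)
    c(lon = g$lon_min + (j + 0.5) * g$res,
      lat = g$lat_min + (i + 0.5) * g$res)
  }

  one_vessel <- function(vid) {
    lon <- numeric(n_fixes); lat <- numeric(n_fixes)
    sog <- numeric(n_fixes); cog <- numeric(n_fixes)
    swh <- numeric(n_fixes); st <- character(n_fixes)
    pos <- sample_target() + stats::runif(2, -0.2, 0.2)
    target <- sample_target()
    heading <- stats::runif(1, 0, 360)
    state <- "transit"
    wv <- 1.5 + stats::rnorm(1, 0, 0.3)
    for (k in seq_len(n_fixes)) {
      hr <- local_solar_hour(times[k], pos[["lon"]])
      night <- hr >= 18 | hr < 6
      if (state == "fishing" && !night) {
        state <- "transit"
        target <- sample_target()
      } else if (state == "transit" && night) {
        d <- sqrt((pos[["lon"]] - target[["lon"]])^2 +
                    (pos[["lat"]] - target[["lat"]])^2)
        if (d < 0.3 && stats::runif(1) < p_fish) state <- "fishing"
      }
      if (state == "fishing") {
        if (stats::runif(1) < 0.55) {           # drifting with gear out
          speed <- stats::runif(1, 0.1, 0.9)
          heading <- (heading + stats::rnorm(1, 0, 25)) %% 360
        } else {                                 # repositioning between sets
          speed <- stats::runif(1, 1.2, 4.0)
          heading <- (heading +
                        sample(c(-1, 1), 1) * stats::runif(1, 40, 180)) %% 360
        }
      } else {
        b <- bearing_deg(pos[["lon"]], pos[["lat"]],
                         target[["lon"]], target[["lat"]])
        heading <- (b + stats::rnorm(1, 0, 4)) %% 360
        speed <- stats::runif(1, 6.5, 10.5)
      }
      wv <- 1.5 + 0.9 * (wv - 1.5) + stats::rnorm(1, 0, 0.22)
      wv <- min(max(wv, 0.2), 6)
      lon[k] <- pos[["lon"]]; lat[k] <- pos[["lat"]]
      sog[k] <- speed; cog[k] <- heading
      swh[k] <- wv; st[k] <- state
      # advance position
      nm <- speed * dt_h
      pos[["lat"]] <- pos[["lat"]] + nm / 60 * cos(heading * pi / 180)
      pos[["lon"]] <- pos[["lon"]] +
        nm / 60 * sin(heading * pi / 180) / cos(pos[["lat"]] * pi / 180)
      if (pos[["lat"]] < g$lat_min || pos[["lat"]] > g$lat_max ||
          pos[["lon"]] < g$lon_min || pos[["lon"]] > g$lon_max) {
        pos[["lat"]] <- min(max(pos[["lat"]], g$lat_min + 0.1),
                            g$lat_max - 0.1)
        pos[["lon"]] <- min(max(pos[["lon"]], g$lon_min + 0.1),
                            g$lon_max - 0.1)
        target <- sample_target()
        state <- "transit"
      }
    }
    data.frame(vessel_id = vid, timestamp = times, lon = lon, lat = lat,
               sog_kn = sog, cog_deg = cog, swh_m = swh, true_state = st)
  }

  withr::with_seed(seed, {
    do.call(rbind, lapply(sprintf("V%03d", seq_len(n_vessels)), one_vessel))
  })
}

#' Write / read trajectory fixes as CSV (ISO-8601 UTC timestamps)
#' @param fixes data.frame as returned by \code{\link{simulate_trajectories}}.
#' @param path File path.
#' @export
write_trajectories_csv <- function(fixes, path) {
  out <- fixes
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories_csv
#' @export
read_trajectories_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$timestamp <- as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                            tz = "UTC")
  d
}
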