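#' Fishing-detection rule set
#'
#' Conservative threshold rules identifying stick-held dip-net fishing
#' operations in AIS trajectories: low speed over ground, a large heading
#' change (or near-stationary drift), nighttime, and low significant wave
#' height. A fix is labelled fishing only when all configured conditions hold.
#'
#' @param speed_min,speed_max Fishing speed bounds, knots (default 0.1-4.0).
#' @param dheading_min Heading-change threshold in degrees (default 30).
#' @param drift_speed Below this speed (knots) the heading condition is waived
#'   (drifting vessels fish with little way on); set to \code{-Inf} to disable
#'   the drift clause.
#' @param night_start,night_end Local-solar-time night window, hours (default
#'   18:00-06:00; the window wraps midnight when start > end).
#' @param wave_max Significant-wave-height ceiling, m (default 2.5).
#' @return Object of class \code{fishing_rules}.
#' @export
fishing_rules <- function(speed_min = 0.1, speed_max = 4.0,
                          dheading_min = 30, drift_speed = 1.0,
                          night_start = 18, night_end = 6, wave_max = 2.5) {
  stopifnot(speed_min < speed_max, wave_max > 0)
  structure(list(speed_min = speed_min, speed_max = speed_max,
                 dheading_min = dheading_min, drift_speed = drift_speed,
                 night_start = night_start, night_end = night_end,
                 wave_max = wave_max),
            class = "fishing_rules")
}

#' Minimal angular difference between two courses
#'
#' @param prev_course,curr_course Courses over ground in degrees [0, 360).
#' @return Absolute heading change in degrees [0, 180].
#' @examples
#' heading_change(350, 10)  # 20
#' @export
heading_change <- function(prev_course, curr_course) {
  d <- abs(curr_course - prev_course) %% 360
  pmin(d, 360 - d)
}

#' Is a fix at night (local solar time)?
#'
#' Local solar time is UTC + lon/15 hours; night is the configured window,
#' wrapping midnight when \code{night_start > night_end}. A window covering
#' the whole day makes every fix "night".
#'
#' @param timestamp POSIXct, UTC.
#' @param lon Longitude in degrees.
#' @param rules A \code{fishing_rules}.
#' @return Logical.
#' @export
is_night <- function(timestamp, lon, rules = fishing_rules()) {
  h <- local_solar_hour(timestamp, lon)
  s <- rules$night_start; e <- rules$night_end
  if (s == e) return(rep(TRUE, length(h)))         # degenerate = full day
  if (s < e) h >= s & h < e else h >= s | h < e
}

#' Classify trajectory fixes as fishing / non-fishing
#'
#' Applies the threshold rule set per vessel, in time order. A fix is fishing
#' iff all of: speed within bounds; heading change from the previous fix at
#' least \code{dheading_min} degrees OR speed below \code{drift_speed}; night;
#' wave height below \code{wave_max}. The first fix of each vessel uses
#' heading change 0. Fixes must be sorted by time within vessel.
#'
#' @param fixes data.frame with columns \code{vessel_id}, \code{timestamp},
#'   \code{lon}, \code{lat}, \code{sog_kn}, \code{cog_deg}, \code{swh_m}.
#' @param rules A \code{fishing_rules}.
#' @return The input with added columns \code{dheading_deg}, \code{is_night},
#'   and \code{label} (\code{"fishing"} / \code{"non-fishing"}).
#' @export
classify_fixes <- function(fixes, rules = fishing_rules()) {
  need <- c("vessel_id", "timestamp", "lon", "lat", "sog_kn", "cog_deg",
            "swh_m")
  stopifnot(all(need %in% colnames(fixes)))
  ord_ok <- tapply(as.numeric(fixes$timestamp), fixes$vessel_id,
                   function(t) all(diff(t) > 0))
  if (!all(unlist(ord_ok)))
    stop("timestamps must be strictly increasing within each vessel",
         call. = FALSE)

  # previous course within vessel (runs of a vessel are contiguous or not;
  # handle either by splitting on vessel id)
  dh <- numeric(nrow(fixes))
  for (v in unique(fixes$vessel_id)) {
    idx <- which(fixes$vessel_id == v)
    cg <- fixes$cog_deg[idx]
    dh[idx] <- c(0, heading_change(cg[-length(cg)], cg[-1]))
  }
  night <- is_night(fixes$timestamp, fixes$lon, rules)
  speed_ok <- fixes$sog_kn >= rules$speed_min & fixes$sog_kn <= rules$speed_max
  turn_ok <- dh >= rules$dheading_min | fixes$sog_kn < rules$drift_speed
  wave_ok <- fixes$swh_m < rules$wave_max
  fishing <- speed_ok & turn_ok & night & wave_ok

  out <- fixes
  out$dheading_deg <- dh
  out$is_night <- night
  out$label <- ifelse(fishing, "fishing", "non-fishing")
  out
}

#' Detection skill against ground-truth state labels
#'
#' @param labels Predicted labels (\code{"fishing"} / \code{"non-fishing"}).
#' @param truth True state labels (\code{"fishing"} / \code{"transit"}).
#' @return List with \code{precision}, \code{recall}, \code{f1} and the
#'   confusion counts.
#' @export
detection_metrics <- function(labels, truth) {
  pred <- labels == "fishing"
  act <- truth == "fishing"
  tp <- sum(pred & act); fp <- sum(pred & !act); fn <- sum(!pred & act)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn)
}
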