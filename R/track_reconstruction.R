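#' Horizontal swim speed from depth rate and body pitch
#'
#' Threshold speed model for a diving swimmer: near-surface samples get a
#' fixed surface swimming speed; low-pitch underwater swimming gets the
#' commuting speed; steep-pitch diving gets `|depth_rate| / |sin(pitch)|`,
#' clipped to a maximum. NA inputs propagate and are filled with the last
#' valid estimate.
#'
#' @param depth depth in metres, positive down.
#' @param depth_rate rate of change of depth (m/s).
#' @param pitch body pitch in degrees (positive nose-up).
#' @param params list of thresholds: `surface_depth_threshold` (m, default
#'   0.3), `pitch_threshold` (degrees, default 10), `surface_speed` (default
#'   1.0 m/s), `commute_speed` (default 2.1 m/s), `max_speed` (default 3.5
#'   m/s). Defaults follow the ~2.1 m/s travel speed typical of Spheniscus
#'   penguins and must be echoed in any run's configuration.
#' @return speed in m/s.
#' @export
estimate_speed <- function(depth, depth_rate, pitch, params = speed_params()) {
  n <- max(length(depth), length(depth_rate), length(pitch))
  depth <- rep_len(depth, n); depth_rate <- rep_len(depth_rate, n)
  pitch <- rep_len(pitch, n)
  out <- rep(NA_real_, n)
  surface <- !is.na(depth) & depth < params$surface_depth_threshold
  lowp <- !surface & !is.na(pitch) & abs(pitch) < params$pitch_threshold
  steep <- !surface & !lowp & !is.na(pitch) & !is.na(depth_rate)
  out[surface] <- params$surface_speed
  out[lowp] <- params$commute_speed
  out[steep] <- pmin(pmax(abs(depth_rate[steep]) /
                            abs(sin(.deg2rad(pitch[steep]))), 0),
                     params$max_speed)
  .fill_forward(out)
}

#' @rdname estimate_speed
#' @param surface_depth_threshold,pitch_threshold,surface_speed,commute_speed,max_speed
#'   see above.
#' @export
speed_params <- function(surface_depth_threshold = 0.3, pitch_threshold = 10,
                         surface_speed = 1.0, commute_speed = 2.1,
                         max_speed = 3.5) {
  list(surface_depth_threshold = surface_depth_threshold,
       pitch_threshold = pitch_threshold, surface_speed = surface_speed,
       commute_speed = commute_speed, max_speed = max_speed)
}

.fill_forward <- function(x) {
  if (!anyNA(x)) return(x)
  ok <- !is.na(x)
  if (!any(ok)) stop("no valid samples to fill from")
  idx <- cumsum(ok)
  first <- which(ok)[1]
  filled <- x[ok][pmax(idx, 1)]
  filled[seq_len(first - 1)] <- x[first] # leading NAs take first valid value
  filled
}

#' Tilt-compensated compass heading
#'
#' Recovers heading from quasi-static tri-axial accelerometer and
#' magnetometer readings. Pitch and roll are estimated from the gravity
#' vector (body frame: x forward, y right, z down; NED world frame), the
#' magnetic vector is de-rotated to the horizontal plane, and heading is
#' `atan2(east, north)` plus the local declination, on [0, 360).
#'
#' Samples whose acceleration magnitude falls outside the quasi-static band
#' [0.5, 1.5] g are flagged and take the last valid heading.
#'
#' @param accel n x 3 matrix of acceleration (g).
#' @param mag n x 3 matrix of magnetic field (any consistent unit).
#' @param declination magnetic declination in degrees, added to the result.
#' @return data.frame with `heading` (degrees) and `flagged` (logical).
#' @export
tilt_compensated_heading <- function(accel, mag, declination = 0) {
  accel <- rbind(accel); mag <- rbind(mag)
  stopifnot(ncol(accel) == 3, ncol(mag) == 3, nrow(accel) == nrow(mag))
  amag <- sqrt(rowSums(accel^2))
  flagged <- amag < 0.5 | amag > 1.5
  a <- accel / amag
  # NED body frame, ZYX attitude: static accel = (-sin(pitch),
  # sin(roll)cos(pitch), cos(roll)cos(pitch))
  pitch <- asin(pmin(pmax(-a[, 1], -1), 1))
  roll <- atan2(a[, 2], a[, 3])
  # de-rotate magnetometer: roll first, then pitch (inverse of body attitude)
  my2 <- mag[, 2] * cos(roll) - mag[, 3] * sin(roll)
  mz2 <- mag[, 2] * sin(roll) + mag[, 3] * cos(roll)
  mx2 <- mag[, 1] * cos(pitch) + mz2 * sin(pitch)
  north <- mx2
  east <- -my2
  heading <- .wrap360(.rad2deg(atan2(east, north)) + declination)
  heading[flagged] <- NA_real_
  heading <- .fill_forward(heading)
  data.frame(heading = heading, flagged = flagged)
}

#' Dead-reckon a water-frame track
#'
#' Integrates heading and speed through the water from a known start on a
#' sphere of radius 6,371,000 m. Per step, `dnorth = speed*cos(heading)*dt`
#' and `deast = speed*sin(heading)*dt`; longitude increments use the latitude
#' at the start of each step.
#'
#' @param heading degrees clockwise from north.
#' @param speed m/s through the water.
#' @param start `c(lat, lon)` of the first computed position's predecessor.
#' @param dt timestep in seconds (default 1).
#' @return data.frame `lat`, `lon` of length `length(heading)`; the start
#'   point itself is not included.
#' @export
dead_reckon <- function(heading, speed, start, dt = 1) {
  stopifnot(length(heading) == length(speed), length(start) == 2)
  uv <- speed_dir_to_uv(speed, heading)
  p <- .integrate_lonlat(uv$u, uv$v, start[1], start[2], dt)
  data.frame(lat = p$lat, lon = p$lon)
}

#' Anchor a dead-reckoned track to GPS fixes
#'
#' For each inter-fix segment, the terminal error vector (fix minus
#' dead-reckoned prediction at the fix time) is distributed linearly in time
#' across the segment's samples, so the corrected track passes through every
#' fix exactly. Samples before the first fix receive that fix's offset
#' uniformly; samples after the last fix carry its offset forward. Correcting
#' an already-corrected track with the same fixes is a no-op.
#'
#' @param track data.frame with `t`, `lat`, `lon` (1 Hz dead-reckoned).
#' @param fixes data.frame with `t`, `lat`, `lon` (strictly increasing `t`,
#'   within the track's time span).
#' @return `track` with corrected `lat`, `lon`.
#' @export
gps_correct <- function(track, fixes) {
  stopifnot(all(c("t", "lat", "lon") %in% names(track)),
            all(c("t", "lat", "lon") %in% names(fixes)))
  if (nrow(fixes) < 1) stop("at least one GPS fix required")
  if (is.unsorted(fixes$t, strictly = TRUE)) {
    stop("fix times must be strictly increasing")
  }
  # predict DR position at each fix time (linear in t between samples)
  pred_lat <- stats::approx(track$t, track$lat, xout = fixes$t, rule = 2)$y
  pred_lon <- stats::approx(track$t, track$lon, xout = fixes$t, rule = 2)$y
  err_lat <- fixes$lat - pred_lat
  err_lon <- fixes$lon - pred_lon
  # offset series: constant before first and after last fix, linear between
  if (nrow(fixes) == 1) {
    off_lat <- rep(err_lat, nrow(track))
    off_lon <- rep(err_lon, nrow(track))
  } else {
    off_lat <- stats::approx(fixes$t, err_lat, xout = track$t, rule = 2)$y
    off_lon <- stats::approx(fixes$t, err_lon, xout = track$t, rule = 2)$y
  }
  track$lat <- track$lat + off_lat
  track$lon <- track$lon + off_lon
  track
}

#' Correct pressure-sensor depth drift
#'
#' Re-zeroes the depth channel by subtracting a slowly varying baseline: the
#' 5th percentile of depth in consecutive 10-minute blocks, linearly
#' interpolated between block centres and clamped at zero. Assumes the animal
#' surfaces at least once per block.
#'
#' @param depth metres, positive down, 1 Hz.
#' @param window block length in seconds (default 600).
#' @return corrected depth, clamped at >= 0.
#' @export
correct_depth_drift <- function(depth, window = 600) {
  n <- length(depth)
  if (n <= window) {
    base <- stats::quantile(depth, 0.05, names = FALSE, na.rm = TRUE)
    return(pmax(depth - base, 0))
  }
  starts <- seq(1, n, by = window)
  centres <- pmin(starts + window / 2, n)
  q <- vapply(starts, function(s) {
    stats::quantile(depth[s:min(s + window - 1, n)], 0.05, names = FALSE,
                    na.rm = TRUE)
  }, numeric(1))
  base <- stats::approx(centres, q, xout = seq_len(n), rule = 2)$y
  pmax(depth - base, 0)
}

#' Locate the outbound-to-inbound transition
#'
#' Smooths the distance-to-colony series with a centred rolling median, then
#' scans backward from arrival: the inbound start is the earliest time from
#' which the smoothed distance never rises by more than `rise_tolerance`
#' before arrival (i.e., the start of the continuous downward trend marking
#' the homing trajectory). If GPS fix times are supplied the transition snaps
#' to the first fix at or after that time.
#'
#' @param track data.frame with `t` and `dist_to_colony` (1 Hz).
#' @param fixes optional data.frame with fix times `t`.
#' @param smooth_window rolling-median window in seconds (default 900).
#' @param rise_tolerance maximum tolerated rise in metres (default 1000).
#' @return the index (row) in `track` where the inbound phase starts.
#' @export
segment_phases <- function(track, fixes = NULL, smooth_window = 900,
                           rise_tolerance = 1000) {
  stopifnot(all(c("t", "dist_to_colony") %in% names(track)))
  d <- .rolling_median(track$dist_to_colony, smooth_window)
  n <- length(d)
  if (n < 2) stop("track too short to segment")
  # rise[i]: how far the smoothed distance ever rises above its value at i
  # before arrival; the inbound start is the earliest i where this stays
  # within tolerance
  suffix_max <- rev(cummax(rev(d)))
  rise <- suffix_max - d
  idx <- which(rise <= rise_tolerance)[1]
  if (is.na(idx) || idx == n || d[idx] - d[n] <= rise_tolerance) {
    stop("no inbound phase found (distance never enters a continuous downward trend)")
  }
  if (!is.null(fixes) && nrow(fixes) > 0) {
    ft <- fixes$t[fixes$t >= track$t[idx]]
    if (length(ft) > 0) {
      idx <- which(track$t >= ft[1])[1]
    }
  }
  idx
}

.rolling_median <- function(x, window) {
  if (window <= 1 || length(x) < 3) return(x)
  k <- min(window, length(x))
  if (k %% 2 == 0) k <- k - 1 # runmed needs odd
  stats::runmed(x, k, endrule = "median")
}

#' Classify resting versus commuting activity
#'
#' Contiguous surface bouts (depth below the surface threshold) lasting at
#' least `min_rest` seconds are RESTING; every other sample is COMMUTING.
#'
#' @param depth metres, positive down, 1 Hz.
#' @param surface_threshold metres (default 0.3).
#' @param min_rest seconds (default 60).
#' @return character vector of "RESTING"/"COMMUTING" labels.
#' @export
classify_activity <- function(depth, surface_threshold = 0.3, min_rest = 60) {
  surface <- depth < surface_threshold
  r <- rle(surface)
  lab <- ifelse(r$values & r$lengths >= min_rest, "RESTING", "COMMUTING")
  inverse.rle(list(lengths = r$lengths, values = lab))
}

#' Reconstruct a corrected 1 Hz track from sensor and GPS inputs
#'
#' Convenience wrapper running the dead-reckoning stage end to end: dead
#' reckon the water-frame heading/speed channels from the first GPS fix,
#' anchor to all fixes, attach depth, distance to colony, phase and activity
#' labels.
#'
#' @param stream data.frame with `t`, `heading`, `speed`, `depth` (1 Hz).
#' @param fixes data.frame with `t`, `lat`, `lon`.
#' @param colony `c(lat, lon)`.
#' @param smooth_window,rise_tolerance passed to [segment_phases()].
#' @return data.frame track with columns `t`, `lat`, `lon`, `heading_water`,
#'   `speed_water`, `depth`, `dist_to_colony`, `phase`, `activity`.
#' @export
reconstruct_track <- function(stream, fixes, colony, smooth_window = 900,
                              rise_tolerance = 1000) {
  stopifnot(all(c("t", "heading", "speed", "depth") %in% names(stream)))
  if (nrow(fixes) < 1) stop("at least one GPS fix required")
  start <- c(fixes$lat[1], fixes$lon[1])
  dr <- dead_reckon(stream$heading, stream$speed, start)
  dr <- data.frame(t = stream$t, lat = dr$lat, lon = dr$lon)
  corr <- gps_correct(dr, fixes)
  track <- data.frame(
    t = stream$t, lat = corr$lat, lon = corr$lon,
    heading_water = stream$heading, speed_water = stream$speed,
    depth = stream$depth
  )
  track$dist_to_colony <- distance_to_colony(track$lat, track$lon, colony)
  inb <- segment_phases(track, fixes, smooth_window, rise_tolerance)
  track$phase <- ifelse(seq_len(nrow(track)) >= inb, "INBOUND", "OUTBOUND")
  track$activity <- classify_activity(track$depth)
  track
}
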