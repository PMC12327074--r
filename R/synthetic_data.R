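# Synthetic trip generator: seeded, policy-driven trips through a current
# field, with dive cycles, pursuit wiggles, GPS fixes at surfacings and
# optional raw accelerometer/magnetometer channels. The generator is the
# ground-truth oracle for the reconstruction and vector stages: per step the
# ground displacement equals water velocity plus sampled current exactly.

#' Navigation policy
#'
#' How a simulated bird chooses its water-frame heading at each 1 Hz step:
#' `FULL_COMPENSATION` crabs toward the goal (via [compensated_heading()]),
#' `FIXED_HEADING` holds the initial line-of-sight bearing, `DRIFT_TOLERANT`
#' always points along the current line of sight through the water, and
#' `CURRENT_ALIGNED` takes the circular weighted mean of the line-of-sight
#' heading (weight `1 - alpha`) and the current heading (weight `alpha`)
#' whenever the current lies within 90 degrees of the line of sight, else the
#' line of sight.
#'
#' @param kind one of `"FULL_COMPENSATION"`, `"FIXED_HEADING"`,
#'   `"DRIFT_TOLERANT"`, `"CURRENT_ALIGNED"`.
#' @param alpha alignment weight in `[0, 1]`; only meaningful (and only
#'   accepted) for `CURRENT_ALIGNED`.
#' @return an object of class `nav_policy`.
#' @export
nav_policy <- function(kind = c("DRIFT_TOLERANT", "FULL_COMPENSATION",
                                "FIXED_HEADING", "CURRENT_ALIGNED"),
                       alpha = NULL) {
  kind <- match.arg(kind)
  if (kind == "CURRENT_ALIGNED") {
    if (is.null(alpha)) alpha <- 0.5
    stopifnot(alpha >= 0, alpha <= 1)
  } else if (!is.null(alpha)) {
    stop("alpha is defined only for CURRENT_ALIGNED policies")
  }
  structure(list(kind = kind, alpha = alpha), class = "nav_policy")
}

#' Trip scenario
#'
#' Parameters of one synthetic foraging trip. Defaults reproduce the study
#' conditions the pipeline targets: return journeys beginning 50 +/- 15 km
#' (range 20-75 km) from the colony, ~2.1 m/s swim speed, von Mises heading
#' noise, dive cycles with pursuit wiggles, occasional long surface rests and
#' metre-scale GPS noise at surfacings. Identical scenario + seed gives
#' byte-identical outputs.
#'
#' @param colony `c(lat, lon)` (default the Peninsula Valdes region colony
#'   at -42.08, -63.86).
#' @param trip_start_distance metres from the colony at which the return leg
#'   begins; `NULL` (default) draws from a normal(50000, 15000) truncated to
#'   [20000, 75000].
#' @param outbound_bearing initial bearing of the outbound leg (degrees;
#'   default 0, i.e. due north, the looping-trip geometry).
#' @param outbound_policy,inbound_policy [nav_policy()] objects.
#' @param swim_speed_mean m/s (default 2.1).
#' @param speed_noise_sd truncated-Gaussian speed noise sd (default 0.2 m/s,
#'   floor 0.1 m/s).
#' @param heading_noise_kappa von Mises concentration for the inbound leg
#'   (default 50, ~8 degree sd).
#' @param outbound_noise_kappa concentration for the outbound leg (default
#'   10; departures are less goal-directed than returns).
#' @param dive_cycle named numeric vector `descent`, `bottom`, `ascent`,
#'   `surface` durations (s) and `max_depth` (m).
#' @param pursuit_rate wiggle events per bottom-second (default 0.01).
#' @param wiggle_rate_ms vertical speed of injected wiggles (m/s, default
#'   0.65, about twice the detector threshold).
#' @param wiggle_leg_s duration of each wiggle leg (s, default 3).
#' @param rest_prob probability that a surfacing extends into a rest bout
#'   (default 0.18).
#' @param rest_mean_s mean rest-bout duration (s, exponential, minimum 60).
#' @param gps_noise_sd metres (default 5).
#' @param arrival_radius metres (default 500).
#' @param max_leg_duration seconds (default 24 h).
#' @param dive_cycles set FALSE for a flat surface-swimming profile (no
#'   dives, rests or wiggles); used for closed-form checks.
#' @param seed integer RNG seed.
#' @return an object of class `trip_scenario`.
#' @export
trip_scenario <- function(colony = c(-42.08, -63.86),
                          trip_start_distance = NULL,
                          outbound_bearing = 0,
                          outbound_policy = nav_policy("DRIFT_TOLERANT"),
                          inbound_policy = nav_policy("DRIFT_TOLERANT"),
                          swim_speed_mean = 2.1,
                          speed_noise_sd = 0.2,
                          heading_noise_kappa = 50,
                          outbound_noise_kappa = 10,
                          dive_cycle = c(descent = 30, bottom = 60,
                                         ascent = 30, surface = 20,
                                         max_depth = 25),
                          pursuit_rate = 0.01,
                          wiggle_rate_ms = 0.65,
                          wiggle_leg_s = 3,
                          rest_prob = 0.18,
                          rest_mean_s = 600,
                          gps_noise_sd = 5,
                          arrival_radius = 500,
                          max_leg_duration = 24 * 3600,
                          dive_cycles = TRUE,
                          seed = 1L) {
  stopifnot(inherits(outbound_policy, "nav_policy"),
            inherits(inbound_policy, "nav_policy"),
            swim_speed_mean > 0,
            all(dive_cycle[c("descent", "bottom", "ascent", "surface")] > 0),
            dive_cycle["max_depth"] > 0,
            pursuit_rate >= 0, gps_noise_sd >= 0, arrival_radius > 0)
  if (!is.null(trip_start_distance)) {
    stopifnot(trip_start_distance > 0)
  }
  structure(as.list(environment()), class = "trip_scenario")
}

#' @export
print.trip_scenario <- function(x, ...) {
  cat("<trip_scenario>\n")
  cat(sprintf("  colony: (%.3f, %.3f); start distance: %s m\n",
              x$colony[1], x$colony[2],
              if (is.null(x$trip_start_distance)) "drawn 20-75 km"
              else format(x$trip_start_distance)))
  cat(sprintf("  policies: out %s / in %s; swim %.2f m/s; kappa %g/%g\n",
              x$outbound_policy$kind, x$inbound_policy$kind,
              x$swim_speed_mean, x$outbound_noise_kappa,
              x$heading_noise_kappa))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Von Mises sampler (Best & Fisher 1979 wrapping rejection), radians about 0.
.rvm <- function(n, kappa) {
  if (n == 0) return(numeric(0))
  if (!is.finite(kappa)) return(numeric(n)) # kappa = Inf: no heading noise
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * 1.3) + 8
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1))
    out <- c(out, theta[ok])
  }
  out[seq_len(n)]
}

# Activity states used by the dive scheduler.
.ST_DIVE <- 1L
.ST_SURF <- 2L
.ST_REST <- 3L

# Build a per-second dive/rest schedule of length n. Uses the current RNG
# stream. Returns depth (m), state, and the true injected wiggle count.
.dive_schedule <- function(n, scenario) {
  dc <- scenario$dive_cycle
  desc <- dc[["descent"]]; bott <- dc[["bottom"]]; asc <- dc[["ascent"]]
  surf <- dc[["surface"]]; dmax <- dc[["max_depth"]]
  leg <- scenario$wiggle_leg_s
  wig_len <- 2 * leg
  depth <- numeric(0); state <- integer(0)
  n_wiggles <- 0L
  while (length(depth) < n) {
    down <- seq_len(desc) * (dmax / desc)
    bottom <- rep(dmax, bott)
    # inject non-overlapping pursuit wiggles into the bottom phase
    k <- stats::rpois(1, scenario$pursuit_rate * bott)
    max_slots <- floor(bott / (wig_len + 2))
    k <- min(k, max_slots)
    if (k > 0) {
      slots <- sort(sample.int(max_slots, k))
      for (s in slots) {
        at <- (s - 1) * (wig_len + 2) + 2
        shape <- c(seq_len(leg), rev(seq_len(leg) - 1)) * scenario$wiggle_rate_ms
        bottom[at:(at + wig_len - 1)] <- dmax - shape[seq_len(wig_len)]
      }
      n_wiggles <- n_wiggles + k
    }
    up <- rev(seq_len(asc) - 1) * (dmax / asc)
    surface <- rep(0, surf)
    st_surface <- rep(.ST_SURF, surf)
    if (stats::runif(1) < scenario$rest_prob) {
      rest_len <- max(60, round(stats::rexp(1, 1 / scenario$rest_mean_s)))
      surface <- c(surface, rep(0, rest_len))
      st_surface <- c(st_surface, rep(.ST_REST, rest_len))
    }
    depth <- c(depth, down, bottom, up, surface)
    state <- c(state, rep(.ST_DIVE, desc + bott + asc), st_surface)
  }
  list(depth = depth[seq_len(n)], state = state[seq_len(n)],
       n_wiggles = n_wiggles)
}

#' Overlay a dive profile on a sensor stream
#'
#' Replaces the depth channel of a 1 Hz stream with trapezoidal dive cycles
#' (descent, bottom, ascent, surface) drawn from the scenario, inserting
#' Poisson-distributed pursuit wiggles into bottom phases. Each wiggle is an
#' excursion whose vertical speed exceeds the pursuit detector's threshold
#' for more than one second, so detector recall is measurable against the
#' returned truth count.
#'
#' @param stream data.frame with a `t` column (1 Hz).
#' @param scenario a [trip_scenario()].
#' @param seed optional integer; if supplied, seeds the RNG first.
#' @return `stream` with a replaced `depth` column and attribute
#'   `n_wiggles_true` carrying the injected wiggle count.
#' @export
inject_dive_profile <- function(stream, scenario, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sch <- .dive_schedule(nrow(stream), scenario)
  stream$depth <- sch$depth
  attr(stream, "n_wiggles_true") <- sch$n_wiggles
  stream
}

# Fast scalar current sampler used in the 1 Hz stepping loops: same
# nearest-hour + bilinear rule as sample_current(), without the data.frame
# overhead. fld must be a list from .field_cache().
.field_cache <- function(field) {
  list(lon0 = field$lon_axis[1],
       dlon = if (length(field$lon_axis) > 1)
         field$lon_axis[2] - field$lon_axis[1] else 1,
       nlon = length(field$lon_axis),
       lat0 = field$lat_axis[1],
       dlat = if (length(field$lat_axis) > 1)
         field$lat_axis[2] - field$lat_axis[1] else 1,
       nlat = length(field$lat_axis),
       t0 = field$time_axis[1], nt = length(field$time_axis),
       lon_max = field$lon_axis[length(field$lon_axis)],
       lat_max = field$lat_axis[length(field$lat_axis)],
       t_max = field$time_axis[length(field$time_axis)],
       u = field$u, v = field$v)
}

.sample_current_fast <- function(fc, lon, lat, t) {
  if (lon < fc$lon0 || lon > fc$lon_max || lat < fc$lat0 ||
      lat > fc$lat_max || t < fc$t0 || t > fc$t_max) {
    stop(sprintf(
      "agent left the current-field hull at (%.5f, %.5f, t=%.0f)",
      lon, lat, t))
  }
  off <- (t - fc$t0) / 3600
  k <- floor(off)
  ti <- if (off - k <= 0.5) k + 1 else k + 2
  if (ti > fc$nt) ti <- fc$nt
  i <- floor((lon - fc$lon0) / fc$dlon) + 1
  if (i >= fc$nlon) i <- fc$nlon - 1
  j <- floor((lat - fc$lat0) / fc$dlat) + 1
  if (j >= fc$nlat) j <- fc$nlat - 1
  wx <- (lon - (fc$lon0 + (i - 1) * fc$dlon)) / fc$dlon
  wy <- (lat - (fc$lat0 + (j - 1) * fc$dlat)) / fc$dlat
  u <- fc$u; v <- fc$v
  w11 <- (1 - wx) * (1 - wy); w21 <- wx * (1 - wy)
  w12 <- (1 - wx) * wy; w22 <- wx * wy
  c(w11 * u[ti, j, i] + w21 * u[ti, j, i + 1] +
      w12 * u[ti, j + 1, i] + w22 * u[ti, j + 1, i + 1],
    w11 * v[ti, j, i] + w21 * v[ti, j, i + 1] +
      w12 * v[ti, j + 1, i] + w22 * v[ti, j + 1, i + 1])
}

# Inline spherical bearing (degrees 0-360) from (lat1,lon1) to (lat2,lon2).
.bearing_fast <- function(lat1, lon1, lat2, lon2) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  b <- atan2(sin(dl) * cos(p2),
             cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl))
  (b * 180 / pi) %% 360
}

.haversine_fast <- function(lat1, lon1, lat2, lon2) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dphi <- p2 - p1; dl <- (lon2 - lon1) * pi / 180
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * EARTH_RADIUS_M * asin(pmin(sqrt(a), 1))
}

# Simulate one goal-seeking leg. Returns a list of per-second vectors.
.sim_leg <- function(scenario, fc, start, goal, policy, kappa, t_start,
                     noise = TRUE) {
  n_max <- scenario$max_leg_duration
  sch <- if (isTRUE(scenario$dive_cycles)) .dive_schedule(n_max, scenario) else
    list(depth = numeric(n_max), state = rep(.ST_DIVE, n_max), n_wiggles = 0L)
  hd_noise <- if (noise) .rvm(n_max, kappa) * 180 / pi else numeric(n_max)
  sp_dive <- pmax(stats::rnorm(n_max, scenario$swim_speed_mean,
                               if (noise) scenario$speed_noise_sd else 0), 0.1)
  sp_surf <- pmax(stats::rnorm(n_max, 1.0,
                               if (noise) scenario$speed_noise_sd else 0), 0.1)

  lat <- numeric(n_max); lon <- numeric(n_max)
  hdg <- numeric(n_max); spd <- numeric(n_max)
  cu <- numeric(n_max); cv <- numeric(n_max)

  la <- start[1]; lo <- start[2]
  goal_lat <- goal[1]; goal_lon <- goal[2]
  h_fixed <- .bearing_fast(la, lo, goal_lat, goal_lon)
  kind <- policy$kind
  alpha <- if (is.null(policy$alpha)) 0 else policy$alpha
  deg <- 180 / pi; rad <- pi / 180
  arrived <- FALSE
  i <- 0L
  while (i < n_max) {
    i <- i + 1L
    t <- t_start + i - 1
    cur <- .sample_current_fast(fc, lo, la, t)
    los <- .bearing_fast(la, lo, goal_lat, goal_lon)
    base <- if (kind == "DRIFT_TOLERANT") {
      los
    } else if (kind == "FIXED_HEADING") {
      h_fixed
    } else if (kind == "FULL_COMPENSATION") {
      s <- if (sch$state[i] == .ST_DIVE) scenario$swim_speed_mean else
        if (sch$state[i] == .ST_SURF) 1.0 else 0
      if (s > 0) {
        losr <- los * rad
        c_perp <- cur[1] * cos(losr) - cur[2] * sin(losr)
        c_par <- cur[1] * sin(losr) + cur[2] * cos(losr)
        root <- s^2 - c_perp^2
        if (root > 0 && sqrt(root) + c_par > 0) {
          (los + asin(-c_perp / s) * deg) %% 360
        } else {
          .next_best_heading(s, cur[1], cur[2], los, "angle")
        }
      } else los
    } else { # CURRENT_ALIGNED
      ch <- (atan2(cur[1], cur[2]) * deg) %% 360
      dlc <- ((ch - los + 180) %% 360) - 180
      if (abs(dlc) <= 90 && (cur[1] != 0 || cur[2] != 0)) {
        wl <- (1 - alpha); wc <- alpha
        (atan2(wl * sin(los * rad) + wc * sin(ch * rad),
               wl * cos(los * rad) + wc * cos(ch * rad)) * deg) %% 360
      } else los
    }
    st <- sch$state[i]
    s_w <- if (st == .ST_DIVE) sp_dive[i] else
      if (st == .ST_SURF) sp_surf[i] else 0
    h_w <- if (s_w > 0) (base + hd_noise[i]) %% 360 else base %% 360
    wu <- s_w * sin(h_w * rad); wv <- s_w * cos(h_w * rad)
    gu <- wu + cur[1]; gv <- wv + cur[2]
    la_new <- la + (gv / EARTH_RADIUS_M) * deg
    lo_new <- lo + (gu / (EARTH_RADIUS_M * cos(la * rad))) * deg
    lat[i] <- la_new; lon[i] <- lo_new
    hdg[i] <- h_w; spd[i] <- s_w; cu[i] <- cur[1]; cv[i] <- cur[2]
    la <- la_new; lo <- lo_new
    if (.haversine_fast(la, lo, goal_lat, goal_lon) <=
          scenario$arrival_radius) {
      arrived <- TRUE
      break
    }
  }
  n <- i
  list(t = t_start + seq_len(n) - 1, lat = lat[seq_len(n)],
       lon = lon[seq_len(n)], heading = hdg[seq_len(n)],
       speed = spd[seq_len(n)], depth = sch$depth[seq_len(n)],
       state = sch$state[seq_len(n)], cur_u = cu[seq_len(n)],
       cv = cv[seq_len(n)], arrived = arrived,
       n_wiggles = sch$n_wiggles)
}

#' Simulate a foraging trip through a current field
#'
#' Generates the ground truth for one bird: an outbound leg from the colony
#' to a turning point (drawn 20-75 km away unless fixed by the scenario) and
#' an inbound leg back, each driven by its navigation policy at 1 Hz. Per
#' step, the ground displacement is exactly the water-frame velocity plus the
#' locally sampled current; heading noise is von Mises, speed noise truncated
#' Gaussian; depth follows the scenario's dive cycles (speed is the swim
#' speed while diving, ~1 m/s while breathing at the surface, and zero during
#' rest bouts, when the bird drifts with the current). The trip start time is
#' drawn uniformly within the first tidal period of the field, randomising
#' the tidal phase each bird experiences.
#'
#' @param scenario a [trip_scenario()].
#' @param field a [current_field()] covering the trip in space and time.
#' @param legs `"both"` (default) or `"inbound"` (start at the turning point;
#'   faster when only the return is analysed).
#' @return list of class `sim_trip` with elements `true_track` (data.frame
#'   `t`, `lat`, `lon`, `heading_water`, `speed_water`, `depth`, `phase`,
#'   `cur_u`, `cur_v`), `stream` (the sensor dialect `t`, `heading`, `speed`,
#'   `depth`), `gps` (`t`, `lat`, `lon`), `scenario`, plus bookkeeping
#'   (`turn_point`, `arrived`, `n_wiggles_true`).
#' @export
simulate_trip <- function(scenario, field, legs = c("both", "inbound")) {
  stopifnot(inherits(scenario, "trip_scenario"),
            inherits(field, "current_field"))
  legs <- match.arg(legs)
  set.seed(scenario$seed)
  fc <- .field_cache(field)

  dist0 <- scenario$trip_start_distance
  if (is.null(dist0)) {
    repeat {
      dist0 <- stats::rnorm(1, 50000, 15000)
      if (dist0 >= 20000 && dist0 <= 75000) break
    }
  }
  brg <- scenario$outbound_bearing
  colony <- scenario$colony
  turn <- c(colony[1] + (dist0 * cos(brg * pi / 180) / EARTH_RADIUS_M) *
              180 / pi,
            colony[2] + (dist0 * sin(brg * pi / 180) /
                           (EARTH_RADIUS_M * cos(colony[1] * pi / 180))) *
              180 / pi)

  period <- 44712
  t0 <- field$time_axis[1] + floor(stats::runif(1, 0, period))

  out_leg <- NULL
  if (legs == "both") {
    out_leg <- .sim_leg(scenario, fc, colony, turn, scenario$outbound_policy,
                        scenario$outbound_noise_kappa, t0)
    t_in <- out_leg$t[length(out_leg$t)] + 1
    start_in <- c(out_leg$lat[length(out_leg$lat)],
                  out_leg$lon[length(out_leg$lon)])
  } else {
    t_in <- t0
    start_in <- turn
  }
  in_leg <- .sim_leg(scenario, fc, start_in, colony, scenario$inbound_policy,
                     scenario$heading_noise_kappa, t_in)

  bind <- function(leg, phase) {
    data.frame(t = leg$t, lat = leg$lat, lon = leg$lon,
               heading_water = leg$heading, speed_water = leg$speed,
               depth = leg$depth, phase = phase,
               cur_u = leg$cur_u, cur_v = leg$cv,
               state = leg$state)
  }
  true_track <- if (is.null(out_leg)) bind(in_leg, "INBOUND") else
    rbind(bind(out_leg, "OUTBOUND"), bind(in_leg, "INBOUND"))

  stream <- data.frame(t = true_track$t, heading = true_track$heading_water,
                       speed = true_track$speed_water,
                       depth = true_track$depth)
  gps <- emit_gps_fixes(true_track, scenario$gps_noise_sd)

  structure(list(
    true_track = true_track, stream = stream, gps = gps,
    scenario = scenario, turn_point = turn, start_inbound = start_in,
    t_inbound = t_in, arrived = in_leg$arrived,
    n_wiggles_true = (if (is.null(out_leg)) 0L else out_leg$n_wiggles) +
      in_leg$n_wiggles
  ), class = "sim_trip")
}

#' @export
print.sim_trip <- function(x, ...) {
  tt <- x$true_track
  cat("<sim_trip>\n")
  cat(sprintf("  %d s at 1 Hz (%d inbound); arrived: %s\n", nrow(tt),
              sum(tt$phase == "INBOUND"), x$arrived))
  cat(sprintf("  %d GPS fixes; %d injected wiggles\n", nrow(x$gps),
              x$n_wiggles_true))
  invisible(x)
}

#' Emit GPS fixes at surfacings
#'
#' One fix at the first sample of each contiguous surface interval
#' (optionally thinned to every k-th surfacing), with isotropic Gaussian
#' position noise in metres.
#'
#' @param true_track data.frame with `t`, `lat`, `lon`, `depth`.
#' @param gps_noise_sd metres.
#' @param thinning keep every `thinning`-th surfacing (default 1).
#' @param seed optional integer; if supplied, seeds the RNG first.
#' @param surface_threshold depth below which the bird is at the surface (m).
#' @return data.frame `t`, `lat`, `lon`. Empty (with a warning) if the track
#'   never surfaces.
#' @export
emit_gps_fixes <- function(true_track, gps_noise_sd = 5, thinning = 1,
                           seed = NULL, surface_threshold = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  surf <- true_track$depth < surface_threshold
  r <- rle(surf)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  si <- starts[r$values]
  if (length(si) == 0) {
    warning("track has no surface intervals; no GPS fixes emitted")
    return(data.frame(t = numeric(0), lat = numeric(0), lon = numeric(0)))
  }
  si <- si[seq(1, length(si), by = thinning)]
  lat <- true_track$lat[si]
  lon <- true_track$lon[si]
  n <- length(si)
  dn <- stats::rnorm(n, 0, gps_noise_sd)
  de <- stats::rnorm(n, 0, gps_noise_sd)
  data.frame(
    t = true_track$t[si],
    lat = lat + .dlat_deg(dn, 1),
    lon = lon + .dlon_deg(de, 1, lat)
  )
}

#' Degrade a derived stream to raw accelerometer/magnetometer channels
#'
#' Synthesises quasi-static tri-axial acceleration (g) and magnetometer
#' channels consistent with the stream's heading and a pitch derived from the
#' depth rate and swim speed (roll = 0), using the NED body frame that
#' [tilt_compensated_heading()] inverts. Noise-free recovery is exact to
#' well under 0.1 degree.
#'
#' @param stream data.frame with `t`, `heading`, `speed`, `depth`.
#' @param inclination magnetic inclination of the synthetic field (degrees,
#'   default -40, southern hemisphere).
#' @param pitch optional explicit pitch series (degrees); derived from depth
#'   rate and speed when omitted.
#' @return data.frame `t`, `ax`, `ay`, `az`, `mx`, `my`, `mz`, `depth`.
#' @export
degrade_to_sensor_channels <- function(stream, inclination = -40,
                                       pitch = NULL) {
  n <- nrow(stream)
  if (is.null(pitch)) {
    vv <- c(diff(stream$depth), 0)
    ratio <- ifelse(stream$speed > 0.05,
                    pmin(pmax(vv / pmax(stream$speed, 0.05), -1), 1), 0)
    pitch <- -asin(ratio) * 180 / pi
  }
  th <- .deg2rad(pitch); ps <- .deg2rad(stream$heading)
  # roll = 0; accel = (-sin(pitch), 0, cos(pitch)) in g
  ax <- -sin(th); ay <- rep(0, n); az <- cos(th)
  inc <- .deg2rad(inclination)
  mN <- cos(inc); mZ <- sin(inc)
  # mag_body = Ry(pitch) Rz(yaw) m_world, roll = 0
  m1 <- mN * cos(ps); m2 <- -mN * sin(ps); m3 <- mZ
  mx <- cos(th) * m1 - sin(th) * m3
  my <- m2
  mz <- sin(th) * m1 + cos(th) * m3
  data.frame(t = stream$t, ax = ax, ay = ay, az = az,
             mx = mx, my = my, mz = mz, depth = stream$depth)
}

#' Default synthetic study field
#'
#' A convenience wrapper building the default reversing east-west tidal field
#' over a grid that comfortably contains looping trips of up to 75 km from
#' the colony: lon -64.8 to -62.9, lat -42.4 to -41.2 at 0.05 degree
#' spacing, five days of hourly snapshots from epoch 0.
#'
#' @param spec a [harmonic_spec()] (default [default_tidal_spec()]).
#' @param days length of the field in days.
#' @return a [current_field()].
#' @export
default_study_field <- function(spec = default_tidal_spec(), days = 5) {
  build_harmonic_field(
    spec,
    lon_axis = seq(-64.8, -62.9, by = 0.05),
    lat_axis = seq(-42.4, -41.2, by = 0.05),
    time_range = c(0, days * 86400)
  )
}
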