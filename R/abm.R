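# Fixed-heading counterfactual: agents that hold their initial line-of-sight
# bearing to the colony with no drift correction, advected by the current
# field sampled at their own (displaced) positions, reusing the real bird's
# per-second speed series aligned to clock time.

#' Run one fixed-heading agent
#'
#' The agent starts where the real bird started its return, locks its heading
#' to the initial line-of-sight bearing to the colony, and each second moves
#' by its water vector (the real bird's speed at that second, along the fixed
#' heading) plus the current sampled at the agent's own position and time. It
#' terminates by reaching the arrival radius (outcome `REACHED`), exhausting
#' the real bird's return duration, crossing the colony's latitude-equivalent
#' goal line when `longitude_mode = TRUE`, or leaving the field hull (both
#' `FAILED`).
#'
#' @param speeds the real bird's 1 Hz water-speed series (m/s); its length
#'   sets the time budget.
#' @param start `c(lat, lon)` of the real inbound start.
#' @param colony `c(lat, lon)`.
#' @param field a [current_field()].
#' @param t_start epoch-second of the first step (must match the field).
#' @param arrival_radius metres (default 500).
#' @param longitude_mode if TRUE, additionally terminate when the agent
#'   crosses the colony's longitude (the strict reading of "returning to the
#'   colony's longitude"); default FALSE.
#' @return list of class `agent_result`: `trajectory` (data.frame `t`, `lat`,
#'   `lon`), `outcome` ("REACHED"/"FAILED"), `landing_offset_m`,
#'   `duration_s`, `heading` and `exit_reason`.
#' @export
run_agent <- function(speeds, start, colony, field, t_start,
                      arrival_radius = 500, longitude_mode = FALSE) {
  stopifnot(inherits(field, "current_field"), length(start) == 2,
            length(colony) == 2, length(speeds) >= 1)
  fc <- .field_cache(field)
  heading <- .bearing_fast(start[1], start[2], colony[1], colony[2])
  rad <- pi / 180; deg <- 180 / pi
  hu <- sin(heading * rad); hv <- cos(heading * rad)
  n <- length(speeds)
  lat <- numeric(n); lon <- numeric(n)
  la <- start[1]; lo <- start[2]
  outcome <- "FAILED"; reason <- "real bird's return time exhausted"
  i <- 0L
  lon_sign0 <- sign(start[2] - colony[2])
  while (i < n) {
    i <- i + 1L
    cur <- tryCatch(.sample_current_fast(fc, lo, la, t_start + i - 1),
                    error = function(e) NULL)
    if (is.null(cur)) {
      i <- i - 1L
      reason <- "agent left the current-field hull"
      break
    }
    gu <- speeds[i] * hu + cur[1]
    gv <- speeds[i] * hv + cur[2]
    la_new <- la + (gv / EARTH_RADIUS_M) * deg
    lo_new <- lo + (gu / (EARTH_RADIUS_M * cos(la * rad))) * deg
    lat[i] <- la_new; lon[i] <- lo_new
    la <- la_new; lo <- lo_new
    if (.haversine_fast(la, lo, colony[1], colony[2]) <= arrival_radius) {
      outcome <- "REACHED"; reason <- "within arrival radius"
      break
    }
    if (longitude_mode && lon_sign0 != 0 &&
          sign(lo - colony[2]) != lon_sign0) {
      reason <- "crossed colony longitude"
      break
    }
  }
  n_used <- max(i, 1L)
  traj <- data.frame(t = t_start + seq_len(n_used) - 1,
                     lat = c(lat[seq_len(i)], if (i == 0) start[1]),
                     lon = c(lon[seq_len(i)], if (i == 0) start[2]))
  structure(list(
    trajectory = traj, outcome = outcome,
    landing_offset_m = .haversine_fast(la, lo, colony[1], colony[2]),
    duration_s = i, heading = heading, exit_reason = reason
  ), class = "agent_result")
}

#' @export
print.agent_result <- function(x, ...) {
  cat(sprintf("<agent_result> %s after %d s; landing offset %.0f m (%s)\n",
              x$outcome, x$duration_s, x$landing_offset_m, x$exit_reason))
  invisible(x)
}

#' Signed lateral (east-west) displacement along a trajectory
#'
#' Path-integrated eastward offset from the baseline start, in metres (east
#' positive): each step contributes `R * cos(lat) * dlon`. The sign flips
#' where the trajectory returns across the start meridian. Also returns the
#' proportion of total along-path distance travelled, the x-coordinate used
#' by the distance-binned summaries.
#'
#' @param lat,lon trajectory coordinates (degrees), first sample at the
#'   baseline start.
#' @return data.frame with `prop` (0-1 proportion of path distance) and
#'   `east_m` (signed metres).
#' @export
lateral_displacement <- function(lat, lon) {
  n <- length(lat)
  stopifnot(length(lon) == n, n >= 1)
  if (n == 1) return(data.frame(prop = 0, east_m = 0))
  dlon <- diff(lon) * pi / 180
  east <- c(0, cumsum(EARTH_RADIUS_M * cos(.deg2rad(lat[-n])) * dlon))
  step <- .haversine_fast(lat[-n], lon[-n], lat[-1], lon[-1])
  path <- c(0, cumsum(step))
  total <- path[n]
  data.frame(prop = if (total > 0) path / total else rep(0, n),
             east_m = east)
}

#' Run the fixed-heading cohort
#'
#' Applies [run_agent()] to each simulated (or reconstructed) bird's inbound
#' leg and collects the cohort summary table.
#'
#' @param trips list of `sim_trip` objects (or lists with `true_track`,
#'   `t_inbound`, `start_inbound`).
#' @param colony `c(lat, lon)`.
#' @param field a [current_field()].
#' @param arrival_radius metres.
#' @return data.frame `bird_id`, `outcome`, `landing_offset_m`, `duration_s`.
#' @export
run_agent_cohort <- function(trips, colony, field, arrival_radius = 500) {
  rows <- lapply(seq_along(trips), function(k) {
    tr <- trips[[k]]
    inb <- tr$true_track[tr$true_track$phase == "INBOUND", ]
    res <- run_agent(inb$speed_water, c(inb$lat[1], inb$lon[1]), colony,
                     field, inb$t[1], arrival_radius)
    data.frame(bird_id = k, outcome = res$outcome,
               landing_offset_m = res$landing_offset_m,
               duration_s = res$duration_s)
  })
  do.call(rbind, rows)
}
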