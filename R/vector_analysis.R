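#' Signed angular difference between two headings
#'
#' `heading_deviation(a, b)` is the signed difference `a - b` wrapped onto
#' `(-180, 180]` degrees. Positive values mean `a` lies clockwise of `b`.
#'
#' @param a,b headings in degrees.
#' @return signed degrees in `(-180, 180]`.
#' @export
heading_deviation <- function(a, b) {
  d <- ((a - b + 180) %% 360) - 180
  d[d == -180] <- 180
  d
}

#' Fully-compensated water-frame heading
#'
#' The heading which, at the given swim speed through the water, yields a
#' ground vector (water + current) pointing as closely as possible along the
#' line of sight to the goal. If the swimmer can cancel the cross-track
#' current and still make forward progress, the solution is the classic crab
#' angle and the resultant heading equals the line of sight exactly. If the
#' current overpowers the swimmer, the "next best" heading is returned: the
#' one minimising the absolute angular deviation of the resultant from the
#' line of sight (geometrically, the tangent from the origin to the circle of
#' reachable resultants). Symmetric optima (current dead against the line of
#' sight) are broken first by larger resultant speed projected on the line of
#' sight, then by smaller numeric heading.
#'
#' @param speed_water swim speed through the water (m/s, >= 0).
#' @param current_u,current_v current components (m/s).
#' @param los_heading line-of-sight heading (degrees).
#' @param objective for the unachievable branch: `"angle"` (default) minimises
#'   angular deviation; `"los_speed"` maximises the resultant speed projected
#'   on the line of sight.
#' @return data.frame with `heading` (degrees, water frame) and `achievable`
#'   (logical: TRUE when the resultant points exactly along the line of sight
#'   with positive speed).
#' @export
compensated_heading <- function(speed_water, current_u, current_v, los_heading,
                                objective = c("angle", "los_speed")) {
  objective <- match.arg(objective)
  n <- max(length(speed_water), length(current_u), length(current_v),
           length(los_heading))
  s <- rep_len(speed_water, n)
  cu <- rep_len(current_u, n)
  cv <- rep_len(current_v, n)
  los <- rep_len(los_heading, n)
  if (any(s < 0)) stop("speed_water must be >= 0")

  losr <- .deg2rad(los)
  # decompose current into along-track (c_par) and cross-track (c_perp,
  # positive to the right of the line of sight)
  c_par  <- cu * sin(losr) + cv * cos(losr)
  c_perp <- cu * cos(losr) - cv * sin(losr)

  heading <- numeric(n)
  achievable <- logical(n)

  root <- s^2 - c_perp^2
  ok <- s > 0 & root > 0 & (sqrt(pmax(root, 0)) + c_par > 0)
  # crab into the current: resultant aligns with los exactly
  heading[ok] <- .wrap360(los[ok] + .rad2deg(asin(-c_perp[ok] / s[ok])))
  achievable[ok] <- TRUE

  if (any(!ok)) {
    idx <- which(!ok)
    hs <- vapply(idx, function(i) {
      .next_best_heading(s[i], cu[i], cv[i], los[i], objective)
    }, numeric(1))
    heading[idx] <- hs
  }
  data.frame(heading = heading, achievable = achievable)
}

# Unachievable branch: origin lies outside (or on) the circle of reachable
# resultants centred at the current vector with radius = swim speed, and the
# los ray does not cross it at positive range. The minimal angular deviation
# is attained at the tangent point; both tangents tie only when the current
# is dead against the line of sight.
.next_best_heading <- function(s, cu, cv, los, objective) {
  c_speed <- sqrt(cu^2 + cv^2)
  if (s == 0) return(.wrap360(los)) # movement fully current-determined
  c_head <- uv_to_speed_dir(cu, cv)$heading
  dev_lc <- heading_deviation(los, c_head) # signed: los relative to current

  # s >= c_speed would always be achievable; here s < c_speed (or the
  # forward-progress condition failed with s == |c_perp| edge cases)
  half_cone <- .rad2deg(asin(min(s / c_speed, 1)))

  cand_res_head <- function(side) .wrap360(c_head + side * half_cone)
  water_heading_for <- function(res_head) {
    # tangent point lies at range sqrt(c^2 - s^2) along res_head
    r <- sqrt(max(c_speed^2 - s^2, 0))
    rh <- .deg2rad(res_head)
    tu <- r * sin(rh); tv <- r * cos(rh)
    uv_to_speed_dir(tu - cu, tv - cv)$heading
  }

  if (objective == "los_speed") {
    # maximise projection of resultant on los over the reachable circle:
    # optimum is the circle point furthest along the los unit vector
    losr <- .deg2rad(los)
    lu <- sin(losr); lv <- cos(losr)
    # resultant = current + s * (unit along los) maximises the projection
    return(uv_to_speed_dir(lu * s, lv * s)$heading) # water vector along los
  }

  side_to_los <- sign(dev_lc)
  if (abs(abs(dev_lc) - 180) < 1e-9 || side_to_los == 0) {
    # symmetric optima; both tangents give equal deviation and equal
    # along-los projection -> smaller numeric heading
    h1 <- water_heading_for(cand_res_head(1))
    h2 <- water_heading_for(cand_res_head(-1))
    return(min(h1, h2))
  }
  water_heading_for(cand_res_head(side_to_los))
}

#' Ground travel vector
#'
#' Componentwise sum of the water-referenced travel vector and the current
#' vector; exact by construction.
#'
#' @param water_u,water_v water-frame travel components (m/s).
#' @param current_u,current_v current components (m/s).
#' @return data.frame with `u`, `v`.
#' @export
ground_vector <- function(water_u, water_v, current_u, current_v) {
  data.frame(u = water_u + current_u, v = water_v + current_v)
}

#' Deviation index
#'
#' Lateral (off-axis) component of travel relative to the line of sight:
#' speed multiplied by the sine of the heading deviation. The sign carries
#' the side of the track (positive to the right of the line of sight).
#'
#' @param speed travel speed (m/s).
#' @param dev signed heading deviation from the line of sight (degrees).
#' @return signed m/s.
#' @export
deviation_index <- function(speed, dev) {
  speed * sin(.deg2rad(dev))
}

#' Against-current flag
#'
#' TRUE when the absolute angular difference between the water-frame heading
#' and the current heading strictly exceeds 90 degrees.
#'
#' @param heading_water,current_heading degrees.
#' @return logical vector.
#' @export
against_current <- function(heading_water, current_heading) {
  abs(heading_deviation(heading_water, current_heading)) > 90
}

#' Per-timestep travel-vector decomposition
#'
#' For every sample of a (typically inbound) track, computes the five travel
#' vectors: the ocean current, the real water-frame travel vector, the real
#' ground vector (water + current), the fully-compensated water-frame vector
#' at the same swim speed, and the compensated ground vector; plus
#' line-of-sight geometry, signed heading deviations, deviation indices and
#' the against-current flag.
#'
#' @param track data.frame with columns `t`, `lat`, `lon`, `heading_water`,
#'   `speed_water` (1 Hz).
#' @param field a [current_field()].
#' @param colony `c(lat, lon)`.
#' @return data.frame, one row per sample, with u/v and speed/heading forms of
#'   all five vectors (`cur_*`, `water_*`, `ground_*`, `comp_water_*`,
#'   `comp_ground_*`), `los_heading`, signed deviations `dev_water`,
#'   `dev_ground`, `dev_current`, deviation indices `devindex_water`,
#'   `devindex_ground`, and logicals `achievable_los`, `against_current`.
#' @export
compute_vector_set <- function(track, field, colony) {
  req <- c("t", "lat", "lon", "heading_water", "speed_water")
  stopifnot(all(req %in% names(track)))
  cur <- sample_current(field, track$lon, track$lat, track$t)
  los <- line_of_sight_heading(track$lat, track$lon, colony)

  w <- speed_dir_to_uv(track$speed_water, track$heading_water)
  g <- ground_vector(w$u, w$v, cur$u, cur$v)
  comp <- compensated_heading(track$speed_water, cur$u, cur$v, los)
  cw <- speed_dir_to_uv(track$speed_water, comp$heading)
  cg <- ground_vector(cw$u, cw$v, cur$u, cur$v)

  cur_sd <- uv_to_speed_dir(cur$u, cur$v)
  g_sd <- uv_to_speed_dir(g$u, g$v)
  cg_sd <- uv_to_speed_dir(cg$u, cg$v)

  dev_water <- heading_deviation(track$heading_water, los)
  dev_ground <- heading_deviation(g_sd$heading, los)
  dev_current <- heading_deviation(track$heading_water, cur_sd$heading)

  data.frame(
    t = track$t, lat = track$lat, lon = track$lon,
    cur_u = cur$u, cur_v = cur$v,
    cur_speed = cur_sd$speed, cur_heading = cur_sd$heading,
    water_u = w$u, water_v = w$v,
    water_speed = track$speed_water, water_heading = track$heading_water,
    ground_u = g$u, ground_v = g$v,
    ground_speed = g_sd$speed, ground_heading = g_sd$heading,
    comp_water_u = cw$u, comp_water_v = cw$v,
    comp_water_speed = track$speed_water, comp_water_heading = comp$heading,
    comp_ground_u = cg$u, comp_ground_v = cg$v,
    comp_ground_speed = cg_sd$speed, comp_ground_heading = cg_sd$heading,
    los_heading = los,
    dev_water = dev_water, dev_ground = dev_ground, dev_current = dev_current,
    devindex_water = deviation_index(track$speed_water, dev_water),
    devindex_ground = deviation_index(g_sd$speed, dev_ground),
    achievable_los = comp$achievable,
    against_current = against_current(track$heading_water, cur_sd$heading)
  )
}
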