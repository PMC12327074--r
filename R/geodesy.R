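# Internal spherical-earth helpers shared by the reconstruction, vector and
# ABM stages. One earth radius is used everywhere; at trip scale (< 100 km)
# the spherical error is negligible relative to GPS noise.

#' @keywords internal
EARTH_RADIUS_M <- 6371000

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Wrap an angle in degrees onto [0, 360)
#' @keywords internal
.wrap360 <- function(x) {
  out <- x %% 360
  out[out == 360] <- 0
  out
}

# One 1 Hz integration step on the sphere, vectorised over steps.
# u east, v north (m/s), lat in degrees; returns degree increments.
# Longitude uses the pre-step latitude so that the generator's sequential
# stepping and the vectorised dead-reckoner agree bit for bit.
.dlat_deg <- function(v, dt) (v * dt / EARTH_RADIUS_M) * (180 / pi)
.dlon_deg <- function(u, dt, lat_deg) {
  (u * dt / (EARTH_RADIUS_M * cos(.deg2rad(lat_deg)))) * (180 / pi)
}

# Integrate eastward/northward velocity series from a start point.
# Latitude is independent of longitude; longitude increments use the
# latitude at the start of each step.
.integrate_lonlat <- function(u, v, lat0, lon0, dt = 1) {
  n <- length(u)
  lat <- lat0 + cumsum(.dlat_deg(v, dt))
  lat_pre <- c(lat0, lat[-n])
  lon <- lon0 + cumsum(.dlon_deg(u, dt, lat_pre))
  if (any(abs(lat) >= 89)) {
    stop("track latitude reached +/-89 degrees; spherical step invalid")
  }
  list(lat = lat, lon = lon)
}

#' Great-circle distance to the colony
#'
#' Haversine distance on a sphere of radius 6,371,000 m between track
#' positions and a fixed colony location.
#'
#' @param lat,lon numeric vectors of positions (decimal degrees).
#' @param colony numeric length-2 vector `c(lat, lon)` of the colony.
#' @return numeric vector of distances in metres.
#' @examples
#' distance_to_colony(-42.08, -63.86, c(-42.08, -63.86))
#' distance_to_colony(-41.08, -63.86, c(-42.08, -63.86)) # ~111.2 km
#' @export
distance_to_colony <- function(lat, lon, colony) {
  stopifnot(length(colony) == 2, is.finite(colony))
  geosphere::distHaversine(
    cbind(lon, lat), c(colony[2], colony[1]),
    r = EARTH_RADIUS_M
  )
}

#' Line-of-sight heading to the colony
#'
#' Initial great-circle bearing from a position to the colony on a sphere,
#' in degrees clockwise from true north on [0, 360). Spherical (not
#' ellipsoidal) on purpose: every other geometric step in the package uses
#' the same 6,371 km sphere, and mixing conventions would bias the crab-angle
#' solver by ~0.1 degree at trip scale.
#'
#' @param lat,lon numeric vectors of positions (decimal degrees).
#' @param colony numeric length-2 vector `c(lat, lon)`.
#' @return numeric vector of bearings in degrees on [0, 360).
#' @export
line_of_sight_heading <- function(lat, lon, colony) {
  stopifnot(length(colony) == 2, is.finite(colony))
  p1 <- .deg2rad(lat)
  p2 <- .deg2rad(colony[1])
  dl <- .deg2rad(colony[2] - lon)
  b <- .wrap360(.rad2deg(atan2(
    sin(dl) * cos(p2),
    cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl)
  )))
  # a position exactly at the colony has no defined bearing; use 0
  b[lat == colony[1] & lon == colony[2]] <- 0
  b
}
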