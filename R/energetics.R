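#' Swim power model
#'
#' Cubic mass-specific power-speed relationship for Spheniscus penguins:
#' `P(s) = 2.954 s^3 - 6.354 s^2 + 5.818 s + 5.9` in W/kg, with `s` the
#' horizontal swimming speed through the water in m/s. `power_total()`
#' multiplies by body mass (default 4 kg) to give J/s per bird.
#'
#' @param s horizontal swim speed through the water (m/s, >= 0).
#' @param params list with coefficients `c3`, `c2`, `c1`, `c0` and `mass`
#'   (kg); see [power_params()].
#' @return W/kg (`power_per_kg`) or W (`power_total`).
#' @examples
#' power_per_kg(0)    # 5.9 W/kg at rest in water
#' power_per_kg(2.1)  # commuting speed
#' power_total(2.1)   # per 4-kg bird
#' @export
power_per_kg <- function(s, params = power_params()) {
  if (any(s < 0)) stop("swim speed must be >= 0")
  params$c3 * s^3 + params$c2 * s^2 + params$c1 * s + params$c0
}

#' @rdname power_per_kg
#' @export
power_total <- function(s, params = power_params()) {
  power_per_kg(s, params) * params$mass
}

#' @rdname power_per_kg
#' @param c3,c2,c1,c0 polynomial coefficients (W/kg per (m/s)^k).
#' @param mass body mass in kg (> 0).
#' @export
power_params <- function(c3 = 2.954, c2 = -6.354, c1 = 5.818, c0 = 5.9,
                         mass = 4.0) {
  if (mass <= 0) stop("mass must be > 0")
  list(c3 = c3, c2 = c2, c1 = c1, c0 = c0, mass = mass)
}

#' Ease of transport, any colony-ward direction
#'
#' Metres progressed per joule for movement in any direction within the 180
#' degree arc facing the colony: `|ground vector| / power` for ground
#' headings within 90 degrees (inclusive) of the line of sight, zero
#' otherwise.
#'
#' @param ground_u,ground_v ground travel vector components (m/s).
#' @param los_heading line-of-sight heading (degrees).
#' @param power metabolic power (W, > 0).
#' @return m/J.
#' @export
ease_any_direction <- function(ground_u, ground_v, los_heading, power) {
  if (any(power <= 0)) stop("power must be > 0")
  sd <- uv_to_speed_dir(ground_u, ground_v)
  within <- abs(heading_deviation(sd$heading, los_heading)) <= 90
  ifelse(within & sd$speed > 0, sd$speed / power, 0)
}

#' Ease of transport along the line of sight
#'
#' Metres of line-of-sight distance closed per joule:
#' `max(0, -d(dist_to_colony)/dt) / power`. Movement that opens the distance
#' scores zero.
#'
#' @param delta_los_distance change in distance-to-colony over the step
#'   (metres per second; negative when closing).
#' @param power metabolic power (W, > 0).
#' @return m/J.
#' @export
ease_line_of_sight <- function(delta_los_distance, power) {
  if (any(power <= 0)) stop("power must be > 0")
  pmax(0, -delta_los_distance) / power
}

#' Attach power and ease-of-transport columns to a vector-set table
#'
#' For every sample, evaluates the swim power at the water-referenced speed
#' (drag acts in the water frame, and the compensated counterfactual reuses
#' the observed swim speeds, so the power series is identical between the
#' real and compensated scenarios) and the two ease variants for both the
#' real and the fully-compensated ground vectors. Line-of-sight ease is
#' computed from each scenario's own advanced position.
#'
#' @param vecs output of [compute_vector_set()].
#' @param colony `c(lat, lon)`.
#' @param params [power_params()].
#' @return `vecs` with columns `power_W`, `ease_real_any`, `ease_real_los`,
#'   `ease_comp_any`, `ease_comp_los`.
#' @export
add_energetics <- function(vecs, colony, params = power_params()) {
  p <- power_total(vecs$water_speed, params)
  vecs$power_W <- p
  vecs$ease_real_any <- ease_any_direction(vecs$ground_u, vecs$ground_v,
                                           vecs$los_heading, p)
  vecs$ease_comp_any <- ease_any_direction(vecs$comp_ground_u,
                                           vecs$comp_ground_v,
                                           vecs$los_heading, p)
  d0 <- distance_to_colony(vecs$lat, vecs$lon, colony)
  adv <- function(u, v) {
    lat1 <- vecs$lat + .dlat_deg(v, 1)
    lon1 <- vecs$lon + .dlon_deg(u, 1, vecs$lat)
    distance_to_colony(lat1, lon1, colony) - d0
  }
  vecs$ease_real_los <- ease_line_of_sight(adv(vecs$ground_u, vecs$ground_v), p)
  vecs$ease_comp_los <- ease_line_of_sight(adv(vecs$comp_ground_u,
                                               vecs$comp_ground_v), p)
  vecs
}
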