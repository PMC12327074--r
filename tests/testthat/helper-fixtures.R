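# Shared fixtures, built in code at test time.

# Uniform (constant in space and time) current field over a generous box.
uniform_field <- function(u = 0, v = 0, hours = 48,
                          lon_axis = seq(-66, -61, by = 1),
                          lat_axis = seq(-46, -40, by = 1)) {
  nt <- hours + 1
  dims <- c(nt, length(lat_axis), length(lon_axis))
  current_field(lon_axis, lat_axis, seq(0, hours * 3600, by = 3600),
                array(u, dims), array(v, dims))
}

# Spatially uniform, sinusoidal-in-time eastward current (period divisible by
# 3600 so hourly snapshots tile a period exactly).
sinusoid_field <- function(amp = 0.5, period = 43200, hours = 48,
                           lon_axis = seq(-66, -61, by = 1),
                           lat_axis = seq(-46, -40, by = 1)) {
  build_harmonic_field(
    harmonic_spec(data.frame(amp_u = amp, amp_v = 0, period = period,
                             phase = 0)),
    lon_axis, lat_axis, c(0, hours * 3600)
  )
}

# A noise-free scenario for closed-form checks.
noise_free_scenario <- function(...) {
  trip_scenario(speed_noise_sd = 0, heading_noise_kappa = Inf,
                outbound_noise_kappa = Inf, dive_cycles = FALSE,
                gps_noise_sd = 0, ...)
}

# Rebuild a scenario with some fields replaced.
trip_scenario_patch <- function(sc, ...) {
  args <- utils::modifyList(unclass(sc), list(...))
  do.call(trip_scenario, args)
}

# Independent geodesy oracles (hand-written, never geosphere).
oracle_haversine <- function(lat1, lon1, lat2, lon2, R = 6371000) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dphi <- p2 - p1; dl <- (lon2 - lon1) * pi / 180
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * R * asin(pmin(sqrt(a), 1))
}

oracle_bearing <- function(lat1, lon1, lat2, lon2) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  (atan2(sin(dl) * cos(p2),
         cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl)) * 180 / pi) %% 360
}

# Brute-force grid minimiser for the compensated-heading solver: evaluates
# every candidate water heading on a regular grid and returns the minimal
# absolute deviation of the resultant from the line of sight.
brute_force_compensation <- function(s, cu, cv, los, step = 0.01) {
  h <- seq(0, 360 - step, by = step)
  hr <- h * pi / 180
  ru <- cu + s * sin(hr)
  rv <- cv + s * cos(hr)
  dev <- abs(heading_deviation(atan2(ru, rv) * 180 / pi, los))
  i <- which.min(dev)
  list(heading = h[i], dev = dev[i],
       res_speed = sqrt(ru[i]^2 + rv[i]^2))
}

# Deviation of the resultant produced by a given water heading.
resultant_deviation <- function(s, cu, cv, los, heading) {
  hr <- heading * pi / 180
  ru <- cu + s * sin(hr)
  rv <- cv + s * cos(hr)
  abs(heading_deviation(atan2(ru, rv) * 180 / pi, los))
}

# Draw random solver test triples away from the achievability boundary and
# from degenerate slow-progress optima (continuity across the boundary is
# tested separately): returns a data.frame of (s, cu, cv, los).
draw_solver_triples <- function(n, seed) {
  set.seed(seed)
  out <- data.frame(s = numeric(0), cu = numeric(0), cv = numeric(0),
                    los = numeric(0))
  while (nrow(out) < n) {
    m <- (n - nrow(out)) * 2 + 16
    s <- runif(m, 0.5, 2.5)
    cs <- runif(m, 0, 3)
    ch <- runif(m, 0, 360)
    cu <- cs * sin(ch * pi / 180)
    cv <- cs * cos(ch * pi / 180)
    los <- runif(m, 0, 360)
    losr <- los * pi / 180
    c_perp <- cu * cos(losr) - cv * sin(losr)
    c_par <- cu * sin(losr) + cv * cos(losr)
    achievable <- s^2 - c_perp^2 > 0 & sqrt(pmax(s^2 - c_perp^2, 0)) + c_par > 0
    # margins: away from the |c_perp| = s boundary; achievable cases make
    # >= 0.3 m/s progress; unachievable cases have a tangent deviation
    # >= 0.15 degrees so the 0.01-degree grid can resolve the flag
    margin <- abs(abs(c_perp) - s) > 0.05
    prog <- sqrt(pmax(s^2 - c_perp^2, 0)) + c_par
    keep_a <- achievable & margin & prog >= 0.3
    tangent_dev <- ifelse(cs > s,
                          abs(heading_deviation(atan2(cu, cv) * 180 / pi, los)) -
                            asin(pmin(s / cs, 1)) * 180 / pi, 0)
    keep_u <- !achievable & margin & cs > s + 0.05 & tangent_dev >= 0.15 &
      sqrt(pmax(cs^2 - s^2, 0)) >= 0.15
    keep <- keep_a | keep_u
    out <- rbind(out, data.frame(s = s, cu = cu, cv = cv,
                                 los = los)[keep, ])
  }
  out[seq_len(n), ]
}
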