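# Synthetic-data generator: determinism, conservation, policy behaviour,
# dive injection and GPS emission.

test_that("identical scenario and seed give identical outputs", {
  field <- sinusoid_field()
  sc <- trip_scenario(trip_start_distance = 20000, seed = 99)
  a <- simulate_trip(sc, field, legs = "inbound")
  b <- simulate_trip(sc, field, legs = "inbound")
  expect_identical(a$true_track, b$true_track)
  expect_identical(a$gps, b$gps)
  c <- simulate_trip(trip_scenario(trip_start_distance = 20000, seed = 100),
                     field, legs = "inbound")
  expect_false(identical(a$true_track$lat, c$true_track$lat))
})

test_that("ground displacement equals water plus current exactly", {
  field <- sinusoid_field(amp = 0.8)
  sc <- trip_scenario(trip_start_distance = 20000, seed = 3)
  tr <- simulate_trip(sc, field, legs = "inbound")
  tt <- tr$true_track
  w <- speed_dir_to_uv(tt$speed_water, tt$heading_water)
  gu <- w$u + tt$cur_u
  gv <- w$v + tt$cur_v
  # reconstruct the positions from the logged ground vectors
  R <- 6371000
  lat_pre <- c(tr$start_inbound[1], tt$lat[-nrow(tt)])
  lon_pre <- c(tr$start_inbound[2], tt$lon[-nrow(tt)])
  expect_equal(tt$lat, lat_pre + (gv / R) * 180 / pi, tolerance = 1e-12)
  expect_equal(tt$lon,
               lon_pre + (gu / (R * cos(lat_pre * pi / 180))) * 180 / pi,
               tolerance = 1e-12)
  # and the logged currents match sampling the field at the pre-step position
  cur <- sample_current(field, lon_pre, lat_pre, tt$t)
  expect_equal(tt$cur_u, cur$u, tolerance = 1e-12)
})

test_that("drift-tolerant birds fly straight in still water", {
  field <- uniform_field(0, 0)
  sc <- noise_free_scenario(trip_start_distance = 10000, arrival_radius = 10,
                            seed = 5)
  tr <- simulate_trip(sc, field, legs = "inbound")
  tt <- tr$true_track
  # straight southward track, arrival in ~ 10000 / 2.1 s
  expect_lt(max(abs(tt$lon - sc$colony[2])), 1e-9)
  expect_true(all(diff(tt$lat) < 0))
  expect_equal(nrow(tt), round(10000 / 2.1), tolerance = 10)
  expect_true(tr$arrived)
})

test_that("full compensation holds the straight line through a cross-current", {
  field <- uniform_field(0.5, 0)
  sc <- noise_free_scenario(trip_start_distance = 10000, arrival_radius = 50,
                            swim_speed_mean = 2.0, seed = 6)
  tr <- simulate_trip(trip_scenario_patch(sc, inbound_policy =
                                            nav_policy("FULL_COMPENSATION")),
                      field, legs = "inbound")
  tt <- tr$true_track
  # ground track stays within 1 m of the start-goal meridian
  dev_m <- abs(tt$lon - sc$colony[2]) * pi / 180 * 6371000 *
    cos(tt$lat * pi / 180)
  expect_lt(max(dev_m), 1)
  expect_true(tr$arrived)
})

test_that("reversing cross-currents produce S-shaped drift-tolerant tracks", {
  # short-period reversal so the noise-free return spans > 1 full cycle
  field <- sinusoid_field(amp = 0.8, period = 10800)
  # slow swimmer, long trip: the return spans a full reversal
  sc <- noise_free_scenario(trip_start_distance = 40000, seed = 8)
  tr <- simulate_trip(sc, field, legs = "inbound")
  tt <- tr$true_track
  ld <- lateral_displacement(c(tr$start_inbound[1], tt$lat),
                             c(tr$start_inbound[2], tt$lon))
  e <- ld$east_m[abs(ld$east_m) > 1]
  expect_gt(sum(diff(sign(e)) != 0), 0) # changes sign at least once
})

test_that("policies separate in water-frame deviation and ground straightness", {
  # pure cross-current: full compensation crabs (water-frame deviation > 0)
  # but tracks straight; drift tolerance points at the goal (deviation 0)
  # but drifts
  field <- uniform_field(0.8, 0)
  mk <- function(policy) {
    sc <- noise_free_scenario(trip_start_distance = 10000,
                              arrival_radius = 100, seed = 10)
    simulate_trip(trip_scenario_patch(sc, inbound_policy = policy), field,
                  legs = "inbound")
  }
  dt <- mk(nav_policy("DRIFT_TOLERANT"))
  fc <- mk(nav_policy("FULL_COMPENSATION"))
  dev_of <- function(tr) {
    tt <- tr$true_track
    los <- line_of_sight_heading(tt$lat, tt$lon, c(-42.08, -63.86))
    mean(abs(heading_deviation(tt$heading_water, los)))
  }
  expect_lt(dev_of(dt), 0.5)
  expect_gt(dev_of(fc), 10)
  # ground straightness is ordered the other way (lateral spread)
  spread <- function(tr) diff(range(lateral_displacement(
    tr$true_track$lat, tr$true_track$lon)$east_m))
  expect_lt(spread(fc), spread(dt))
})

test_that("current-aligned birds blend toward favourable flows", {
  field <- uniform_field(0.8, -0.8) # south-east current, within 90 of los
  sc <- noise_free_scenario(trip_start_distance = 10000,
                            arrival_radius = 100, seed = 13)
  ca <- simulate_trip(trip_scenario_patch(
    sc, inbound_policy = nav_policy("CURRENT_ALIGNED", alpha = 0.5)),
    field, legs = "inbound")
  tt <- ca$true_track
  los0 <- line_of_sight_heading(ca$start_inbound[1], ca$start_inbound[2],
                                sc$colony)
  cur_h <- uv_to_speed_dir(0.8, -0.8)$heading
  d0 <- abs(heading_deviation(tt$heading_water[1], los0))
  dc <- abs(heading_deviation(tt$heading_water[1], cur_h))
  expect_gt(d0, 1)  # pulled off the line of sight...
  expect_lt(dc, abs(heading_deviation(los0, cur_h))) # ...toward the current
  expect_error(nav_policy("DRIFT_TOLERANT", alpha = 0.3), "alpha")
})

test_that("dive injection matches the detector's expectations", {
  stream <- data.frame(t = 0:19999)
  sc0 <- trip_scenario(pursuit_rate = 0, rest_prob = 0, seed = 20)
  s0 <- inject_dive_profile(stream, sc0, seed = 20)
  dt0 <- dive_table(s0$depth, s0$t)
  expect_gt(nrow(dt0), 50)
  expect_equal(sum(dt0$n_pursuits), 0)
  expect_equal(attr(s0, "n_wiggles_true"), 0L)
  # trapezoid max depth is reproduced
  sc8 <- trip_scenario(dive_cycle = c(descent = 20, bottom = 30, ascent = 20,
                                      surface = 15, max_depth = 8),
                       pursuit_rate = 0, rest_prob = 0, seed = 21)
  s8 <- inject_dive_profile(stream, sc8, seed = 21)
  expect_equal(max(detect_dives(s8$depth)$max_depth), 8, tolerance = 1e-9)
  # injected wiggles are recovered
  schi <- trip_scenario(pursuit_rate = 0.05, rest_prob = 0, seed = 22)
  si <- inject_dive_profile(stream, schi, seed = 22)
  truth <- attr(si, "n_wiggles_true")
  found <- sum(dive_table(si$depth, si$t)$n_pursuits)
  expect_gt(truth, 50)
  expect_gte(found, 0.95 * truth)
  expect_lte(found, 1.05 * truth)
})

test_that("GPS fixes appear at surfacings with the requested noise", {
  field <- sinusoid_field()
  sc <- trip_scenario(trip_start_distance = 20000, gps_noise_sd = 0, seed = 30)
  tr <- simulate_trip(sc, field, legs = "inbound")
  tt <- tr$true_track
  # zero noise: fixes coincide with true positions at their times
  at <- match(tr$gps$t, tt$t)
  expect_equal(tr$gps$lat, tt$lat[at])
  expect_equal(tr$gps$lon, tt$lon[at])
  # every fix is at the surface
  expect_true(all(tt$depth[at] < 0.05))
  # thinning keeps every k-th surfacing
  g1 <- emit_gps_fixes(tt, gps_noise_sd = 0, thinning = 1, seed = 1)
  g3 <- emit_gps_fixes(tt, gps_noise_sd = 0, thinning = 3, seed = 1)
  expect_equal(nrow(g3), ceiling(nrow(g1) / 3))
  # mean radial error of 2-D Gaussian noise: sigma * sqrt(pi / 2) ~ 6.27 m
  n <- 4000
  gn <- emit_gps_fixes(data.frame(t = seq_len(2 * n), lat = rep(-42, 2 * n),
                                  lon = rep(-63.86, 2 * n),
                                  depth = rep(c(0, 10), n)),
                       gps_noise_sd = 5, seed = 77)
  expect_equal(nrow(gn), n)
  r <- oracle_haversine(gn$lat, gn$lon, -42, -63.86)
  expect_gt(mean(r), 4)
  expect_lt(mean(r), 6.5)
  # a track that never surfaces yields no fixes, with a warning
  expect_warning(
    g0 <- emit_gps_fixes(data.frame(t = 1:10, lat = -42, lon = -63.86,
                                    depth = rep(10, 10)), 5),
    "no surface")
  expect_equal(nrow(g0), 0)
})
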