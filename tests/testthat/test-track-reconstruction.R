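# Dead-reckoning stage: speed model, compass, integration, GPS anchoring,
# phase and activity segmentation.

test_that("speed model applies surface, low-pitch and steep-pitch rules", {
  p <- speed_params()
  expect_equal(estimate_speed(5, 1.0, -30, p), 2.0, tolerance = 1e-12)
  expect_equal(estimate_speed(0.1, 99, 80, p), p$surface_speed)
  expect_equal(estimate_speed(5, 99, 2, p), p$commute_speed)
  # clipping at max_speed
  expect_equal(estimate_speed(5, 3.5, -20, p), p$max_speed)
  # NA propagates as missing and takes the last valid value
  out <- estimate_speed(c(5, NA, 5), c(1, NA, 1), c(-30, NA, -90), p)
  expect_equal(out[2], out[1])
})

test_that("tilt-compensated heading inverts synthetic attitudes", {
  # level tag, magnetic field pointing north
  r <- tilt_compensated_heading(c(0, 0, 1), c(0.7, 0, 0.6))
  expect_equal(r$heading, 0)
  expect_false(r$flagged)
  # synthetic attitude round-trip at heading 90, pitch -30
  stream <- data.frame(t = 0:4, heading = rep(90, 5), speed = rep(2, 5),
                       depth = c(0, 1, 2, 3, 4))
  raw <- degrade_to_sensor_channels(stream, pitch = rep(-30, 5))
  rec <- tilt_compensated_heading(as.matrix(raw[, c("ax", "ay", "az")]),
                                  as.matrix(raw[, c("mx", "my", "mz")]))
  expect_equal(rec$heading, rep(90, 5), tolerance = 0.1)
  # declination shifts all headings additively
  rec5 <- tilt_compensated_heading(as.matrix(raw[, c("ax", "ay", "az")]),
                                   as.matrix(raw[, c("mx", "my", "mz")]),
                                   declination = 5)
  expect_equal(rec5$heading, (rec$heading + 5) %% 360, tolerance = 1e-9)
  # dynamic (non-quasi-static) samples are flagged and carried forward
  acc <- rbind(c(0, 0, 1), c(0, 0, 2.5))
  mag <- rbind(c(0.7, 0, 0.6), c(0, 0.7, 0.6))
  r2 <- tilt_compensated_heading(acc, mag)
  expect_equal(r2$flagged, c(FALSE, TRUE))
  expect_equal(r2$heading[2], r2$heading[1])
})

test_that("attitude recovery is exact over random attitudes", {
  set.seed(31)
  n <- 10000
  heading <- runif(n, 0, 360)
  pitch <- runif(n, -80, 80)
  stream <- data.frame(t = seq_len(n), heading = heading, speed = 2,
                       depth = 0)
  raw <- degrade_to_sensor_channels(stream, pitch = pitch)
  rec <- tilt_compensated_heading(as.matrix(raw[, c("ax", "ay", "az")]),
                                  as.matrix(raw[, c("mx", "my", "mz")]))
  expect_lt(max(abs(heading_deviation(rec$heading, heading))), 0.1)
})

test_that("dead reckoning integrates the spherical step formula", {
  start <- c(-42.08, -63.86)
  dr <- dead_reckon(rep(0, 100), rep(2, 100), start)
  expect_lt(abs(dr$lat[100] - start[1] - 0.0017986), 1e-7)
  expect_equal(dr$lon[100], start[2])
  # out and back returns to the start
  dr2 <- dead_reckon(c(rep(0, 50), rep(180, 50)), rep(2, 100), start)
  expect_lt(abs(dr2$lat[100] - start[1]), 1e-6)
  expect_lt(abs(dr2$lon[100] - start[2]), 1e-6)
  # zero speed holds position
  dr3 <- dead_reckon(rep(77, 10), rep(0, 10), start)
  expect_true(all(dr3$lat == start[1] & dr3$lon == start[2]))
  # polar guard
  expect_error(dead_reckon(rep(0, 10), rep(1e6, 10), c(88.9, 0)), "89")
})

test_that("GPS anchoring distributes errors linearly and is idempotent", {
  n <- 101
  track <- data.frame(t = 0:(n - 1), lat = rep(-42, n),
                      lon = -63.86 + seq(0, 1e-3, length.out = n))
  # single fix equal to the DR prediction: unchanged
  fix0 <- data.frame(t = 50, lat = track$lat[51], lon = track$lon[51])
  expect_equal(gps_correct(track, fix0), track)
  # 100 m east terminal error over 100 s: sample at 50 s moves 50 m east
  dlon100 <- (100 / (6371000 * cos(-42 * pi / 180))) * 180 / pi
  fixes <- data.frame(t = c(0, 100), lat = track$lat[c(1, n)],
                      lon = track$lon[c(1, n)] + c(0, dlon100))
  corr <- gps_correct(track, fixes)
  # float cancellation at lon ~ -63.86 leaves ~1e-14 degrees (~1e-9 m)
  expect_lt(abs(corr$lon[51] - track$lon[51] - dlon100 / 2), 1e-12)
  expect_lt(abs(corr$lon[n] - track$lon[n] - dlon100), 1e-12)
  expect_equal(corr$lat, track$lat)
  # idempotent: re-anchoring with the same fixes changes nothing
  expect_equal(gps_correct(corr, fixes), corr)
  expect_error(gps_correct(track, fixes[c(2, 1), ]), "increasing")
})

test_that("distance to colony is the haversine great-circle distance", {
  colony <- c(-42.08, -63.86)
  expect_equal(distance_to_colony(colony[1], colony[2], colony), 0)
  d1 <- distance_to_colony(-41.08, -63.86, colony)
  expect_equal(d1, 111195, tolerance = 1)
  expect_equal(distance_to_colony(-41.5, -63.2, colony),
               oracle_haversine(-41.5, -63.2, colony[1], colony[2]),
               tolerance = 1e-6)
  # symmetry
  expect_equal(distance_to_colony(-41.5, -63.2, colony),
               distance_to_colony(colony[1], colony[2], c(-41.5, -63.2)))
})

test_that("phase segmentation finds the start of the homing descent", {
  # noiseless triangular profile: transition at the peak
  d <- c(seq(0, 50000, by = 25), seq(50000 - 25, 0, by = -25))
  track <- data.frame(t = seq_along(d) - 1, dist_to_colony = d)
  idx <- segment_phases(track, smooth_window = 1, rise_tolerance = 0)
  expect_equal(idx, which.max(d))
  # with noise, the transition lands near the peak
  set.seed(9)
  track$dist_to_colony <- d + runif(length(d), -200, 200)
  idxn <- segment_phases(track, smooth_window = 900, rise_tolerance = 1000)
  expect_lt(abs(idxn - which.max(d)), 1500)
  # strictly decreasing profile: the whole trip is inbound
  dec <- data.frame(t = 0:999, dist_to_colony = seq(5000, 10, length.out = 1000))
  expect_equal(segment_phases(dec, smooth_window = 1, rise_tolerance = 0), 1)
  # monotone increasing distance: no return
  inc <- data.frame(t = 0:999, dist_to_colony = seq(10, 5000, length.out = 1000))
  expect_error(segment_phases(inc), "no inbound")
  # transition snaps to the first GPS fix at/after the trend start
  fixes <- data.frame(t = which.max(d) + 120)
  idxf <- segment_phases(track, fixes, smooth_window = 900,
                         rise_tolerance = 1000)
  expect_equal(track$t[idxf], fixes$t[1])
})

test_that("activity labels need 60 s at the surface to count as resting", {
  depth <- c(rep(5, 100), rep(0, 59), rep(5, 50), rep(0, 60), rep(5, 20))
  lab <- classify_activity(depth)
  expect_true(all(lab[101:159] == "COMMUTING")) # 59 s bout
  expect_true(all(lab[210:269] == "RESTING"))   # 60 s bout
  expect_equal(sum(classify_activity(rep(5, 500)) == "RESTING"), 0)
})

test_that("depth drift correction re-zeroes a drifting baseline", {
  # dives to 10 m from a surface that drifts linearly to 1.5 m of offset
  n <- 3600
  true_depth <- rep(c(rep(0, 60), seq(1, 10, length.out = 30), rep(10, 60),
                      seq(10, 1, length.out = 30)), length.out = n)
  drift <- seq(0, 1.5, length.out = n)
  corrected <- correct_depth_drift(true_depth + drift)
  surf <- true_depth == 0
  expect_lt(max(corrected[surf]), 0.35)
  expect_gt(mean(corrected[true_depth == 10]), 9)
})

test_that("end-to-end reconstruction recovers a noise-free synthetic trip", {
  field <- sinusoid_field(amp = 0.5)
  sc <- noise_free_scenario(trip_start_distance = 8000, arrival_radius = 300,
                            seed = 12)
  tr <- simulate_trip(sc, field, legs = "inbound")
  truth <- tr$true_track
  # fixes every 60 s, no GPS noise
  sel <- seq(1, nrow(truth), by = 60)
  fixes <- data.frame(t = truth$t[sel], lat = truth$lat[sel],
                      lon = truth$lon[sel])
  dr <- dead_reckon(tr$stream$heading, tr$stream$speed, tr$start_inbound)
  # dead reckoning alone drifts with the current...
  raw_err <- oracle_haversine(dr$lat, dr$lon, truth$lat, truth$lon)
  corr <- gps_correct(data.frame(t = tr$stream$t, lat = dr$lat,
                                 lon = dr$lon), fixes)
  err <- oracle_haversine(corr$lat, corr$lon, truth$lat, truth$lon)
  # ...and GPS anchoring removes it
  expect_gt(max(raw_err), 100)
  expect_lt(sqrt(mean(err^2)), 5)
  # the corrected track passes through every fix
  expect_lt(max(err[sel]), 1e-6)
})
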