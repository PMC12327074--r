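# tidenav

Navigation analysis for swimming central-place foragers (penguins and their
kin) returning home through tidal currents.

A bird swimming at heading *h* and speed *s* through water moving with
current **c** travels over the ground at **g** = *s*·(sin *h*, cos *h*) +
**c**. Biologging tags observe the water frame (compass heading, modelled
swim speed, depth) plus sparse GPS fixes at surfacings; an ocean model
supplies **c** on a grid. `tidenav` turns these into:

- **GPS-corrected dead-reckoned tracks** at 1 Hz: heading/speed integration
  on a 6,371 km sphere, with inter-fix error vectors distributed linearly in
  time so the track passes through every fix;
- **the five travel vectors** at every inbound second: current, real
  water-frame, real ground, fully-compensated water-frame, compensated
  ground. The compensated heading solves the crab angle
  `asin(-c_perp / s)` against the line of sight to the colony, falling back
  to the tangent ("next best") heading when the current overpowers the
  swimmer;
- **energetics**: mass-specific swim power
  `P(s) = 2.954 s^3 - 6.354 s^2 + 5.818 s + 5.9` W/kg (times 4 kg), and two
  ease-of-transport variants (m/J) — progress in any colony-ward direction
  vs progress along the line of sight;
- **dives and prey pursuits**: dives are runs deeper than 0.3 m; pursuits
  are trend-opposing depth wiggles whose vertical speed exceeds 0.3 m/s for
  at least 1 s;
- **a fixed-heading agent-based counterfactual**: agents that never correct
  for drift, advected by the current at their own displaced positions;
- **cohort statistics**: per-bird normalised distance/heading bins,
  slack (< 0.3 m/s) vs appreciable current classes, against-current time,
  and a bird-level bootstrapped two-sample Kolmogorov–Smirnov comparison;
- **a seeded synthetic generator** (reversing semi-diurnal current field,
  policy-driven trips, dive cycles, GPS fixes) so the entire pipeline is
  testable without any raw deployment data.

## Worked example

```r
library(tidenav)

field <- default_study_field()                       # reversing tidal field
sc    <- trip_scenario(seed = 7, trip_start_distance = 50000)
trip  <- simulate_trip(sc, field)                    # ground truth + tag data
trip
#> <sim_trip>
#>   98699 s at 1 Hz (52357 inbound); arrived: TRUE
#>   412 GPS fixes; 394 injected wiggles

track   <- reconstruct_track(trip$stream, trip$gps, sc$colony)
inbound <- track[track$phase == "INBOUND", ]
vecs    <- add_energetics(compute_vector_set(inbound, field, sc$colony),
                          sc$colony)
mean(vecs$ease_real_any)   # 0.0189 m/J  - real (flow-assisted) travel
mean(vecs$ease_comp_any)   # 0.0178 m/J  - fully-compensated counterfactual
```

The simulated bird takes 14.5 h home (52,357 inbound seconds for a 50 km
start — about one tidal period, hence the S-shaped return), and its real,
drift-tolerant movement is *more* energy-efficient per joule than the
straight-home compensated counterfactual, because compensation spends speed
fighting the cross-current.

A whole cohort, end to end:

```r
run <- run_pipeline(run_config(mode = "synthetic", n_birds = 10, seed = 42))
summary(run)
#> Cohort summary
#>   birds: 10
#>   time in eastward currents: 41.8% +/- 6.0% (sd)
#>   time against the current: 64.1% +/- 6.2%
#>   ABM median landing offset: 5976 m
```

Fixed-heading agents miss the colony by ~6 km (median) under the same
currents that the drift-tolerant birds ride home to within 500 m — the
package's restatement of why continuous drift correction matters in a
reversing tidal regime.

## Documentation

The methods vignette (`vignettes/tidal-navigation-methods.Rmd`) documents
the model conventions, the compensation geometry (including where the
minimal deviation is and is not continuous), the generator's defaults and
what they do and do not emulate, and the package's numerical choices.
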