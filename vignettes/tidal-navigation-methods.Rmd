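---
title: "Methods: dead-reckoned navigation analysis under tidal drift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dead-reckoned navigation analysis under tidal drift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidenav)
```

## The problem

A swimming central-place forager returning to its colony through a tidal
regime is continuously displaced by the water it swims in. Its compass
heading and swim speed describe motion *through the water*; what brings it
home is motion *over the ground*, the vector sum of the two. `tidenav`
reconstructs both frames from tag data, asks what heading the animal *should*
have held to travel dead-straight home (the fully-compensated
counterfactual), prices both strategies in joules, and checks what would have
happened had the animal ignored the drift altogether (the fixed-heading
agent-based model). Because raw deployments of this kind are rarely
redistributable, the package ships a seeded generator that produces trips
with the statistical structure the analysis assumes, so every stage is
testable offline.

## Frames, conventions and the five travel vectors

All headings are degrees clockwise from true north on [0, 360); `u` is the
eastward and `v` the northward velocity component (m/s). All geometry lives
on a sphere of radius 6,371 km — at trip scale (< 100 km) the spherical
error is far below GPS noise, and one consistent convention matters more
than ellipsoidal precision (an ellipsoidal bearing differs by ~0.1 degree
here, which would masquerade as a systematic crab angle).

At every 1 Hz step of an inbound track, `compute_vector_set()` forms:

1. the **ocean current vector** sampled from the gridded field;
2. the **real water-frame travel vector** (heading + speed from the tag);
3. the **real ground vector** — their exact componentwise sum;
4. the **fully-compensated water-frame vector**: the heading that, at the
   same swim speed, makes the resultant point along the line of sight to the
   colony;
5. the **compensated ground vector** — (4) plus (1).

The compensation solver decomposes the current into along- and cross-track
components \(c_\parallel, c_\perp\) relative to the line of sight. When the
swim speed \(s\) exceeds \(|c_\perp|\) and forward progress
\(\sqrt{s^2-c_\perp^2}+c_\parallel\) is positive, the crab angle is
\(\arcsin(-c_\perp/s)\) and the resultant aligns with the line of sight
exactly. Otherwise the "next best" heading is chosen: the tangent from the
origin to the circle of reachable resultants (centre = current vector,
radius = \(s\)), which minimises the angular deviation. Symmetric optima —
current dead against the line of sight — are broken by larger along-track
resultant speed, then by smaller numeric heading, so results are
deterministic. Minimising the *angle* (rather than the along-track speed) is
a design choice; the speed objective is available via `objective =
"los_speed"`.

One geometric subtlety is worth recording: the minimal deviation is
continuous in current magnitude across the *cross-current* boundary
(\(|c_\perp| \to s\)), but genuinely discontinuous across the *head-on*
boundary where the current magnitude overtakes the swim speed — the circle
of reachable resultants sweeps through the origin and the attainable
direction set collapses. The test suite checks the first and documents the
second.

## Dead reckoning and GPS anchoring

Tracks integrate heading and speed through the water
(`dnorth = s cos(h) dt`, `deast = s sin(h) dt`) from a known start;
longitude increments use the pre-step latitude so the simulator and the
reconstructor agree bit for bit. Dead reckoning alone drifts with the
current; `gps_correct()` distributes each inter-fix error vector linearly in
time across the segment, passes through every fix exactly, applies the first
fix's offset uniformly before it, and is idempotent. Linear-in-time (rather
than distance-weighted) distribution is exactly testable and matches the
standard practice of the dead-reckoning frameworks this stage emulates.

The speed model is a three-regime threshold rule — surface swimming
(1.0 m/s below 0.3 m depth), low-pitch underwater commuting (2.1 m/s below
10 degrees of pitch), and steep-pitch diving (`|depth rate| / |sin pitch|`,
capped at 3.5 m/s). These defaults follow the ~2.1 m/s travel speed typical
of the genus and are explicit, configurable stand-ins; every run's manifest
echoes them. Pressure drift is re-zeroed by subtracting the 5th percentile
of depth per 10-minute block (interpolated between block centres, clamped at
zero) — a documented stand-in for tag-specific drift corrections.

Phase segmentation smooths distance-to-colony with a centred 900 s rolling
median and takes the earliest time after which the smoothed distance never
rises more than 1,000 m above its value there, snapped to the next GPS fix.
With these defaults the detected start can sit earlier than the true
turning point by up to the tolerance divided by the closing speed
(~15 minutes at 1.1 m/s); the tests budget for that rather than pretending
the rule is sharper than it is. Resting is any surface bout of at least
60 s; everything else is commuting.

## Energetics

Mass-specific swim power follows the cubic
\(P(s) = 2.954 s^3 - 6.354 s^2 + 5.818 s + 5.9\) W/kg, times 4 kg of bird.
Power is always evaluated on the *water*-frame speed — drag acts in the
water, and the compensated counterfactual reuses the observed speeds — so
the real and counterfactual power series are identical and all ease
differences are purely geometric. Two ease-of-transport variants (m/J):
*any-direction* ease credits the full ground speed when the ground heading
is within 90 degrees (inclusive) of the line of sight and zero otherwise;
*line-of-sight* ease credits only the per-second reduction in
distance-to-colony, clamped at zero. Surface-resting seconds are included in
both by default (they cost the resting rate of 5.9 W/kg and usually earn
little), since excluding them is a downstream filter, not a property of the
metric.

## Dives and prey pursuits

A dive is a maximal run deeper than 0.3 m. Vertical speed is the centred
first difference of depth. A pursuit "wiggle" is a maximal interval of
vertical motion opposing the enclosing dive trend (upward before the depth
maximum, downward after) whose absolute vertical speed exceeds 0.3 m/s for
at least one second. Counting all trend-opposing wiggles (with an optional
descent/ascent filter) is our operationalisation of the undulation rule;
the fixture suite measures the detector against generator-injected wiggles
of known count and amplitude, where it achieves >= 95% recall with <= 5%
false positives.

## The synthetic generator

The generator is first-class code, and its defaults *are* the study
conditions the analysis targets:

* a reversing east-west semi-diurnal current (fundamental period 44,712 s)
  with a weaker first overtone at phase \(-\pi/3\). The overtone keeps the
  time-mean flow at zero and the eastward/westward time split near 50/50
  while making eastward peaks stronger (mean eastward speed ~0.69 m/s vs
  ~0.51 m/s westward at the default 0.9 m/s amplitude, overall mean
  ~0.59 m/s) — the asymmetry pattern of the gulf regime the package
  emulates. A constant eastward offset would have reproduced the speed
  asymmetry but skewed the time split and suppressed meridian re-crossings,
  so the zero-mean waveform was chosen;
* return legs starting 50 +/- 15 km (truncated to 20-75 km) from the
  colony, swim speed 2.1 m/s with truncated Gaussian noise (sd 0.2 m/s,
  floor 0.1 m/s), von Mises heading noise (kappa = 50 inbound, ~8 degrees
  sd; kappa = 10 outbound, since departures are less goal-directed);
* dive cycles (30 s descent, 60 s bottom, 30 s ascent, 20 s breathing,
  25 m depth) with Poisson pursuit wiggles at 0.65 m/s vertical speed, and
  occasional rest bouts (probability 0.18 per surfacing, mean 600 s) during
  which the bird drifts with the current. The resulting effective inbound
  speed of ~1.1-1.2 m/s makes a 50 km return take ~12 h — about one tidal
  period — which is what produces consistently S-shaped drift-tolerant
  returns;
* GPS fixes at surfacings with 5 m isotropic noise;
* four navigation policies (full compensation, fixed heading, drift
  tolerance, current alignment) that span the contrast between the
  compensated counterfactual, the naive agent, and observed
  flow-exploiting behaviour.

Per step, ground displacement is *exactly* water velocity plus sampled
current, which makes the generator the algebraic oracle for every
downstream stage. Identical scenario + seed gives byte-identical output.
What the generator does **not** emulate: prey fields (pursuit wiggles are
scheduled, not earned), multi-day trips, heading-dependent wave drag,
depth-varying currents (the field is one 2-D layer, since the source ocean
model's vertical structure is not part of this analysis), or any real
sensor's calibration errors. Passing tests therefore demonstrate that the
*pipeline* is correct under its stated assumptions, not that those
assumptions exhaust real tag data.

## The fixed-heading counterfactual

Agents hold the initial line-of-sight bearing, reuse the real bird's
per-second speed series aligned to clock time, and are advected by the
current sampled at their own displaced position. They terminate on reaching
the 500 m arrival radius, on exhausting the real bird's return time (the
default reading of "failing to return before the real bird"; a strict
longitude-crossing mode exists behind `longitude_mode`), or on leaving the
field hull — which, with a coastal colony, is the model's version of coming
ashore far away. The 500 m radius is a package default chosen below the
~300 m landing-accuracy scale of the birds the analysis emulates but large
enough for 1 s steps.

Lateral displacement is reported as the *path-integrated* eastward offset
(sum of `R cos(lat) dlon` over steps). On a sphere the "east-west offset
from the start meridian" is ambiguous to ~7 m per 5 km of drift across a
0.2-degree latitude band, depending on the latitude at which meridian
separation is evaluated; the path integral is the one definition under
which a uniform current of speed `c` for time `T` displaces an agent by
exactly `cT`, which is the closed form the ABM is validated against.

## Statistics

All cohort summaries normalise per bird first (proportions or per-bin
means), then average across birds with equal weight; the SE uses n-1 and
birds absent from a bin are dropped from that bin only. Current conditions
split at 0.3 m/s (slack below, appreciable at or above); "against the
current" means the water-frame heading differs from the current heading by
strictly more than 90 degrees; `u = 0` counts as westward by convention
(measure zero in practice). The two-sample KS statistic is the classical
sup-difference of ECDFs. The bootstrap resamples *birds* with replacement
(1,000 replicates by default) — the defensible unit when samples within a
bird are autocorrelated — and reports the mean D with a 2.5/97.5 percentile
interval; a within-bird block bootstrap is provided as an alternative.

## Problem sizes and numerical choices

The shipped tests exercise cohorts of up to 10 birds at full 1 Hz
resolution (~10^5 samples per bird), solver-oracle comparisons on 10,000
random triples against a 0.01-degree brute-force grid (drawn away from the
achievability boundary by a small margin, since the flag is not decidable
at grid resolution exactly on the boundary; continuity there is tested
separately), and 500-replicate bootstraps. Ties in the nearest-hour rule
round down; the achievable branch of the solver is closed-form, so no
iteration or tolerance is involved; all randomness flows from one named
seed per scenario, and the pipeline derives per-stage child seeds from the
master seed by a fixed affine map.

## Worked example

```{r example, eval = FALSE}
field <- default_study_field()
sc <- trip_scenario(seed = 7, trip_start_distance = 50000)
trip <- simulate_trip(sc, field)
track <- reconstruct_track(trip$stream, trip$gps, sc$colony)
inbound <- track[track$phase == "INBOUND", ]
vecs <- add_energetics(compute_vector_set(inbound, field, sc$colony),
                       sc$colony)
mean(vecs$ease_real_any) > mean(vecs$ease_comp_any) # flow-assisted gain
```

## Known limitations

* The current field is a single depth layer sampled at the nearest hourly
  snapshot; no temporal interpolation is attempted, matching the analysis
  this package operationalises but understating smooth tidal evolution.
* Phase segmentation assumes one outbound-inbound cycle; multi-looping
  trips need manual splitting.
* The wiggle rule is a depth-only proxy; it cannot distinguish pursuit
  from other undulations.
* Magnetometer calibration (hard/soft iron) is assumed done upstream; only
  a declination offset is applied.
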