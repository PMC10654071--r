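---
title: "Run statistics and data-driven simulation of aggregate dispersal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Run statistics and data-driven simulation of aggregate dispersal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`myxorun` quantifies the cell behaviors that build and destroy *Myxococcus
xanthus* aggregates during starvation development, and simulates those
behaviors back with a data-driven agent-based model. This vignette explains
the underlying model, every consequential parameter, and the design choices
made where the methodology left the design open. Nothing here states an
empirical result that the package's test suite or `scripts/acceptance.R`
does not itself compute.

## The behavioral model

A developing *M. xanthus* cell alternates between a **persistent** state
(steady gliding along its long axis) and a **non-persistent** state (little
net displacement). Within the persistent state, cells periodically **reverse**
polarity. A **run** is the trajectory segment between two such events — a
state change or a reversal — and is the atomic record of the analysis:
duration, mean speed, net displacement, orientation, and the event that ended
it.

Two families of behavior shape aggregation:

* **Reversal bias.** Runs pointed toward the nearest aggregate last longer on
  average than runs pointed away. The statistic is

  `reversal bias = (t_toward - t_away) / t_all`

  where `t_toward` and `t_away` are the mean durations of runs oriented
  within and beyond 90 degrees of the direction to the nearest aggregate
  centroid, and `t_all` is the mean duration of all persistent runs in the
  subset. Positive values produce net drift toward aggregates.

* **Traffic jam.** Inside aggregates, run speeds drop, the probability that a
  run ends in a stop rather than a reversal rises, and stops last longer.

Dispersal is driven by a size dependence of the reversal bias: near small
aggregates the bias weakens and can change sign during the coarsening phase,
so cells drain away.

## The synthetic world

`synth_config()` defines a ground-truth world: disk aggregates with optional
growth and dispersal, cells performing biased persistent random walks, and a
density field of Gaussian blobs standing in for the population-density
channel. The generator's defaults were chosen once, from the biology:

| parameter | default | rationale |
|---|---|---|
| speed | 2.5 +/- 0.5 um/min | gliding speeds of *M. xanthus* on agar |
| tau_toward / tau_away | 10 / 7 min | reversal period ~8-14 min; bias ~0.35, the scale of the measured effect |
| p_stop(rho) | 0.08 + 0.6 rho (cap 0.45) | ~0.1 in the background, ~0.4 at blob centers |
| tau_stop(rho) | 6 + 16 rho min | minutes-long stops, ~2.5x longer inside aggregates |
| frame interval | 1 min | tracking-channel cadence |
| movie interval | 15 min | density-channel cadence |
| orientation noise | 0.3 rad | imperfect 180-degree reversals |

Dispersal is emulated two ways: a `disperse_at` time ramps a blob to zero
over 60 min (any smooth monotone ramp would satisfy the downstream
contracts), and a `flip_time`/`flip_area` pair swaps the toward/away duration
means for aggregates below the area threshold — the size-dependent bias
reversal at the heart of the phenomenon. The traffic jam near flipped
aggregates is attenuated (`flip_pstop_factor`), mirroring the reduced
stopping observed near unstable aggregates.

The generator emulates the *statistical* structure the analysis assumes —
exponential run durations, density-dependent stopping, isotropic Gaussian
aggregates — and deliberately not the mechanics of real monolayers: no
steric interactions, no streams or rippling, no slime trails, no measurement
noise on positions, and reflecting (rather than open) boundaries. Passing
tests therefore demonstrate that the estimators recover the behavioral
parameters *when the model holds*; they do not certify performance on
microscopy data with tracking noise and unmodeled correlations.

### Which mean does the bias estimator converge to?

Under pure reversals, toward and away runs alternate one-for-one, so the
run-level estimator's `t_all` converges to the *arithmetic* mean
`(tau_toward + tau_away) / 2`, and `expected_bias()` implements that
weighting: constant means of 6 and 4 min give a bias of 0.4. A
run-frequency-per-unit-time weighting would instead give the harmonic mean
(bias 0.417 for the same means); simulation confirms the arithmetic
convention is the one the estimator realizes.

## Run extraction

Frames are labeled persistent when, over a centered 3-min window, the mean
speed is at least 1 um/min *and* the net displacement is at least 1 um;
bouts shorter than 2 frames merge into their flanking label. Classification
runs on raw positions: smoothing blurs the sharp 180-degree turn of a
reversal into an apparent 2-3 frame stop, which inflates the stopping
probability. (These thresholds are calibration knobs in `run_params()`; the
3-min window and 1-um displacement floor were calibrated against the
generator's ground truth — a 5-min window misses non-persistent bouts
shorter than ~3 min and biases `p_stop` low by more than 20%.)

Reversals are detected where displacement vectors before and after a frame
differ by more than 120 degrees, using both two-frame windows and a
skip-frame single-step test that resolves reversals flanked by runs as short
as one frame. Events are clustered, the largest-angle frame kept, and events
closer than the dwell minimum suppressed.

Two estimator details matter for the bias statistic:

* **Toward/away classification uses the run's initial direction**
  (`orientation_start`, the displacement over the first frames), not the
  net-displacement direction. Run durations are drawn conditional on the
  outgoing direction; the net direction is corrupted by undetected reversals
  (merged runs) and boundary reflections, and using it attenuates the bias
  estimate asymmetrically.
* **Runs that graze the reflecting boundary are flagged** (`boundary_touch`)
  when the field of view is supplied: a head-on wall reflection reverses the
  displayed direction of motion and masquerades as a reversal. Real fields
  of view do not reflect cells, so synthetic-world bias statistics exclude
  flagged runs.

**Known limitation — attenuation at the tracking cadence.** At a 1-min frame
interval, runs shorter than about one frame are unresolvable; the missed
boundaries merge neighboring runs and inflate mean durations, attenuating
the bias estimate by roughly 15-25% when run means are 7-10 min. The
parameter-recovery fixtures (`bias_recovery_config()`) therefore place the
small aggregate's basin in the field interior and pool replicate worlds; the
residual attenuation is a property of run-level estimation at this cadence,
not of the implementation, and would apply equally to experimental data.

Each run is annotated with the local density (bilinear sample of the
nearest normalized density frame at the run midpoint), the nematic alignment
`gamma = cos(2(theta_i - theta_bar))` to neighbors within 12 um over the
preceding 7 min, the signed distance to the nearest aggregate boundary at
the run start *and end* (transitions happen where runs end, so the jam
statistics stratify on the end-of-run distance), the relative angle to the
nearest aggregate, and the aggregate's identity, area, and fate. The nearest
aggregate is the one with the smallest boundary distance (ties to the larger
area). Reorientation angles are stored relative to the flipped direction
when the preceding event was a reversal, so that values are comparable
across event types and can be applied after adding pi on simulated
reversals.

## Aggregate segmentation and fates

Frames are normalized by subtracting the mean, shifting by the minimum, and
scaling to total 1. (The plain mean-subtract-then-scale order is
ill-defined — a mean-subtracted frame sums to zero — so the shift preserves
the intent of a frame-to-frame invariant total while making the scaling
well-posed. This choice is deliberate and documented here prominently.) A
single reference frame, midway between aggregate initiation and coarsening
start, is rescaled to [0, 1]; Otsu's threshold on a 256-bin histogram is
computed there and mapped back through the frame's extremes, giving one
threshold valid for every frame.

Segmentation takes 8-connected supra-threshold components of at least
100 um^2, links them across frames by maximal pixel overlap (falling back to
the nearest centroid within 20 um, bridging single-frame dropouts), flags
components touching the border (`partial_fov`; runs near such aggregates are
dropped), detects merges (a track whose pixels are absorbed by a neighbor
did not disperse and is labeled `merged`), and classifies motility (median
smoothed centroid speed above 3 um/min). Fates are censoring-safe: a track
must end at least 30 min before the movie does to count as unstable.

The coarsening start is the last maximum of the 30-min-smoothed total area
of unstable, stationary, long-lived aggregates after which the series falls
below 95% of that maximum and never recovers. "Continually decrease" needs
an operationalization because a smooth decline stays above 95% immediately
after its peak; requiring no *recovery* above 95% (rather than an immediate
drop) matches both triangle-shaped and slowly decaying area curves.

## The data-driven agent-based model

Agents move in straight lines between events; at each event three
nearest-neighbour searches against the run database decide (1) whether the
run ends in a reversal or a state change, (2) the reorientation, and (3) the
speed and duration of the next run jointly, the third search using the
relative angle *after* reorienting. Searches operate within time bins
(100-min bins before the coarsening start, two equal bins after) and state
strata, over z-score-standardized cue vectors (equal weight per cue): local
density (dropped during coarsening, when the boundary distance carries the
same information), alignment, boundary distance, relative angle, and — per
the experiment variant — the nearest-aggregate area in the state and/or
duration search. The match is drawn uniformly among the `knn_k = 20` nearest
rows: strict 1-NN would make agents deterministic copies of database cells,
and 20 neighbors adds sampling diversity at negligible cost in cue
resolution (`knn_k = 1` restores strict copying).

Numerical choices:

* Simulated density is a Gaussian KDE of agent positions on the movie pixel
  grid, normalized to total 1 so thresholds live on the same scale as
  normalized experimental frames. Simulated and database densities are
  reconciled by standardizing each side against its own statistics
  (database: per-stratum; simulation: across agents at each refresh).
* Sampled durations are floored at one time step — shorter runs are
  unobservable at the tracking cadence that produced the database.
* The no-aggregate sentinel distance must sit at the scale of the largest
  *observable* boundary distance (200 um in the scaled world). A sentinel
  far outside the database's range dominates the standardized metric and
  pins all matches to far-field rows, silencing the density-driven jamming
  feedback that nucleates aggregates.
* Boundaries reflect, matching the generator.
* The exact k-selection of the nearest-neighbour search is implemented in
  C++ (`std::partial_sort` per query row); distances are formed with BLAS.

## The scaled dispersal study

`dispersal_scenario_config()` and `dispersal_scenario_sim()` fix the
desk-scale study: 2,000 agents in 500 x 400 um, 10 simulated hours with the
coarsening start (and the ground-truth bias flip) at minute 300, a database
world of four stable disks of which only the smallest (~2,800 um^2) sits
below the size threshold A* = 4000 um^2. Bandwidth (10 um) and detection
threshold (1.6x the uniform pixel mass) were calibrated once — following the
method's own calibration procedure of matching aggregation outcomes — so
that the simulation nucleates a persistent population of aggregates
spanning A* by the coarsening start; the 300 um^2 pinpoint filter is
unchanged. A* itself is set so that "small" aggregates still contain
100-300 agents: with fewer agents per aggregate, individual fates are
dominated by kernel-density fluctuations rather than behavior.

Fate statistics consider aggregates alive at the coarsening start, at least
60 min old by then (conditioning only on pre-coarsening information),
stationary, and not ending by merging.

**Known limitation — demographic noise at desk scale.** At 1/25th of an
experimental field of view, each simulation yields only a handful of
qualifying sub-A* aggregates, and a baseline level of fluctuation-driven
turnover (Ostwald-like competition between neighboring aggregates) persists
in every cue condition. The dispersal *contrast* between conditions — more
sub-A* dispersal with the area cue in the duration search than without, and
jamming-only indistinguishable from area-off — is the robust readout; the
absolute dispersal fractions carry this churn and are noisier than at full
scale, where aggregates hold thousands of cells.

## Interfaces

Trajectories and run databases travel as CSV (sentinels as empty cells, a
JSON sidecar carrying bin edges); density movies as multi-page 32-bit TIFF
with a JSON sidecar recording pixel size, frame times, and per-frame
intensity ranges (frames are rescaled to [0, 1] for storage and
reconstructed on read to within 1e-9 of each frame's dynamic range);
aggregate sets as CSV plus contour polygons in JSON. `run_pipeline()` chains
segmentation, coarsening detection, run extraction, annotation, statistics,
and optionally the simulation, and writes a JSON report; identical
configuration and seed reproduce the report byte for byte. The package's
functions are the interface; `scripts/acceptance.R` is a worked end-to-end
driver.
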