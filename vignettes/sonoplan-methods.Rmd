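---
title: "Planning ultrasound-guided robotic radiotherapy with sonoplan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning ultrasound-guided robotic radiotherapy with sonoplan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Robotic stereotactic radiotherapy of the prostate delivers dose through a
few hundred narrow photon beams chosen from thousands of candidate
directions. Continuous intra-fraction tracking with a robot-held
ultrasound transducer is attractive because it needs no ionizing imaging
and no implanted fiducials — but the transducer and its carrying arm are
radio-opaque, so every robot pose blocks a subset of the candidate beams.
`sonoplan` implements the full optimization stack for studying this
trade-off on synthetic pelvic phantoms: inverse planning as a two-stage
linear program, acoustic-viewport feasibility by CT ray tracing, a
capsule-model robot with projection-based beam blocking, simulated
annealing over the robot setup, and a small convolutional network that
scores candidate beams so that sampling can concentrate on directions
that plans actually use.

This vignette is the package's account of the models it implements, the
parameters that matter, and the choices made where the design was open.

## Synthetic pelvic phantoms

Clinical planning CTs cannot be shipped with a package, so `phantom_spec()`
and `generate_phantom()` build parametric stand-ins with the geometric
structure the method relies on: an ellipsoidal soft-tissue body
(gray 1050), an ellipsoidal prostate target (PTV) with volume drawn from
25–120 cm³, a bladder anterior–superior and a rectum posterior to it,
femoral-head and iliac bone capsules (gray > 1300), and optional bowel-gas
spheres (gray < 400). Gray values follow the offset-1000 scanner
convention, `gray = HU + 1000`: the ultrasound feasibility thresholds
(dense tissue above 1300, gas below 400) are only coherent on that scale —
with signed HU every soft-tissue voxel would fail the gas rule. The
default anatomy keeps roughly 9 mm between the PTV and the anterior rectal
wall so that the planning problem can reach the 95% coverage premise of
the shell calibration (below); organ poses and sizes are jittered by
`random_phantom_spec()`.

What the phantoms deliberately do **not** model: CT texture and noise,
deformable anatomy, non-ellipsoidal organs, breathing motion (handled
solely through the 20 mm blocking margin). Tests passing on phantoms
therefore validate the *optimization machinery*, not clinical dosimetry.

`build_shells()` adds band structures at 3 mm and 9 mm around the target
(distance measured to the nearest PTV voxel centre), excluding PTV and
OAR voxels so every voxel carries exactly one label — the planning LP
needs disjoint row blocks. `voxelize()` discretizes all structures at the
3 mm planning resolution (configurable; the desk-scale studies below use
4 mm).

## Dose model and candidate beams

Candidate beams (`sample_candidate_beams()`) take sources uniformly on a
spherical cap of an 800 mm-radius sphere around the target centroid —
anterior, lateral and superior directions; the table side is excluded —
targets uniformly over PTV voxel centres, and circular collimators of
10/15/20/30/40 mm. 6000 candidates is the full-scale default; the studies
in this package use 500–1500.

Dosimetry uses a deliberately minimal pencil-cone kernel
(`compute_dose_matrix()`): voxel `p` receives dose from a beam iff it
lies inside the cone of radius `(d/2)·|p−s|/800` around the axis, and then

```
dose/MU = D0 · exp(−mu · rd(t)) · (800 / |p−s|)²,   mu = 0.005 mm⁻¹
```

where `rd(t)` is the water-equivalent (radiological) depth from the
source along the beam's **central axis**, linearly interpolated at the
voxel's axis projection — the standard pencil-beam convention, and the
reason one axis march serves all voxels of a beam. `D0` is calibrated so
a single 40 mm beam can deliver the 36.25 Gy prescription to a voxel at
100 mm water-equivalent depth on the source sphere within the 300 MU
per-beam cap. The model is linear in beam weight (the premise of the
planning LP), attenuates with tissue density, and falls off with
distance; it makes no claim to clinical accuracy and is isolated behind
the `dose_matrix` interface so a measured kernel could be substituted.
Radiological depth itself (`radiological_depth()`) integrates
`max(gray/1000, 0)` with a 1 mm midpoint rule and trilinear
interpolation.

## Two-stage planning LP

Stage 1 (`optimize_coverage()`) maximizes target coverage through its
linear surrogate — minimizing total underdose `Σ max(0, 36.25 − d_i)`
over PTV voxels — under hard maximum doses (PTV 40.25 Gy, OARs 36 Gy,
shells as calibrated), 300 MU per beam and 40,000 MU total. Coverage (the
fraction of PTV voxels at or above prescription, with a fixed 1e-9 Gy
threshold tolerance) is evaluated post hoc and is never part of the LP.
Stage 2 (`optimize_mu()`) minimizes total MU while fixing per-voxel lower
bounds at the stage-1 doses, so coverage cannot decrease and MU cannot
increase; when the stage-1 lower bounds are numerically infeasible they
are relaxed once by 1e-9 Gy. Dose is evaluated on the optimization grid —
no resampling between optimization and evaluation.

Two solver backends exist behind one formulation. The bundled dense
bounded-variable two-phase simplex (`src/lp.cpp`) is exact and
self-contained: it prices slack and artificial columns in O(1), starts
the stage-1 LP from the primal-feasible all-underdose basis (skipping
phase 1), applies a deterministic 1e-8-scale bound perturbation against
degenerate stalling, and falls back to Bland's rule after long stalls.
It is used for instances up to ~200 rows and as the fallback everywhere.
Large planning LPs (thousands of dose rows) are delegated to HiGHS
through the system `python`'s scipy interface, as a one-shot sparse
formulation solved with the interior-point method plus crossover (much
faster than the dual simplex on these dense-column dose matrices, and
still returning a basic, i.e. sparse, weight vector). Cap rows that are
unreachable even with every beam at 300 MU are dropped up front. The two
backends are cross-checked against each other and against an independent
`pracma::linprog` formulation in the test suite.

`calibrate_shell_dose()` reproduces the per-case tuning of the shell
bounds: a single scale factor `s` over base bounds
`shell3 = s·36.25 Gy`, `shell9 = 0.6·s·36.25 Gy` is bisected (at most 12
stage-1 solves) until the no-robot stage-1 coverage is within 0.25
percentage points above the 95% target. One knob keeps the calibration
deterministic; the 0.6 inner/outer ratio is a package choice — the
original per-case procedure is not public. Because coverage is a count,
its response to `s` is a step function: the calibration can only land in
the band when the anatomy and candidate set bracket the target, which is
a documented precondition (otherwise the unconstrained bounds are
returned with a warning flag).

## Ultrasound viewports

`viewport_map()` discretizes the skin (voxels of the flood-filled body
adjacent to outside air — enclosed gas cavities are not skin — thinned to
5 mm, restricted to the anterior/lateral/perineal accessible zone) and
traces the CT gray values from each skin point to the target centroid
with 1 mm nearest-voxel sampling. A viewport is feasible iff the maximum
gray on the path is ≤ 1300 (no bone), the minimum is ≥ 400 (no gas) and
the tissue depth is ≤ 120 mm; rejection reasons are reported with
priority dense > gas > depth. The first 2 mm at the skin are excluded
from the gas test: the air/skin partial-volume boundary would otherwise
reject every viewport. Classification samples nearest voxels (the rules
act on discrete HU values), unlike the dosimetric depth integrals, which
interpolate.

## Robot model and beam blocking

The transducer sits on the skin point with its axial axis at the target
centroid; the mounting roll faces the robot base (projection of
base−position onto the plane normal to the axis, with a superior-direction
fallback when degenerate). The 7-DoF arm is reduced to the minimal
kinematics that exhibits the elbow self-motion: a capsule chain
base→elbow→wrist→mount with links 400/400/120 mm and the forearm held
straight, so the elbow moves on the self-motion circle of a two-bar
(400, 520 mm) linkage — parameterized by the LIFT angle, 2π-periodic,
with reach 920 mm and a 150 mm minimum. Capsule radii (60/50/45 mm links,
16 mm probe for the 24×26 mm footprint, 80 mm probe body) are
configuration defaults.

A beam is blocked (`beam_blocked()`) when some capsule comes closer to
the source→target segment than capsule radius + local cone radius +
20 mm margin (the margin absorbs transducer and target breathing motion).
The closed-form capsule-vs-cone clearance is the production test; a
500-ray sampling oracle is kept in the test suite and agrees on ≥ 99% of
random configurations with all disagreements within 0.5 mm of the margin
boundary. With three LIFT angles (default −30°/0°/+30°) a beam counts as
blocked only if *all* solvable configurations block it — the robot can
move its elbow during treatment without moving the probe.

## Beam scorer

`beam_features()` builds the scorer input: 7 projection images on the
plane through the PTV centroid perpendicular to the source–centroid line
— a binary beam aperture and min/max radiological-depth maps (from the
source, water-equivalent mm) for PTV, rectum and bladder, 0 where a ray
misses the structure. The full-scale geometry is 150×150 px at 1 mm; the
desk-scale default is 24×24 px at 6 mm with a 3 mm march on a 5 mm
resampled volume (cache-resident, which makes the tens of thousands of
feature evaluations of rejection sampling affordable). The in-plane
up-vector is the patient-superior direction projected onto the plane.

The scorer itself is a small convolutional network written in the
package (no deep-learning framework is part of the stack): two stride-2
convolutions (16×5×5, 32×3×3), a flattened dense layer of width 32 and a
scalar head. Training (`train_beam_scorer()`) uses Adam (β₁ = 0.9,
β₂ = 0.999, ε = 1e-7) for 15 epochs with the learning rate stepped
1e-3 → 1e-4 → 1e-5 every 5 epochs, per-channel input standardization
computed on the training data, and the coverage-weighted loss

```
l = (w_p − w_g)² · c_des / c_p   if w_g = 0
l = (w_p − w_g)² · c_p / c_des   if w_g > 0,     c_des = 0.95
```

which weights weighted beams of high-coverage plans up and unweighted
beams of low-coverage plans up — the loss is genuinely discontinuous in
`w_g` (a label-class weighting). Training data come from stage-1 plans on
random candidate sets (`build_training_data()`); the class imbalance
`w_b = #unweighted/#weighted` (≈ 19 at full scale, much smaller at desk
scale where plans use a larger fraction of a 500-beam candidate set) is
rebalanced by keeping unweighted examples with probability `1/w_b`. The
alternative literal reading — *dropping* with probability `1/w_b`, which
would barely rebalance — is available behind `mode = "drop"`.
`train_beam_scorer_cv()` adds the three-fold split with phantom-level
stratification by PTV volume. A DenseNet-scale backbone and pretrained
first-layer surgery are out of scope here: the method's structure is
backbone-agnostic and the small network is the desk-scale default.

`sample_cnn_beams()` generates candidates by rejection: draw a random
beam, accept with probability `w_p / 300` (predictions are clamped to
[0, 300] MU before sampling); a run that stays under a 1e-4 acceptance
rate after 10⁵ draws aborts.

## Setup optimization

`optimize_setup()` anneals over the robot setup — base position
(continuous inside boxes left/right of the torso and between the legs),
viewport, and LIFT angle — under one of four blocking objectives: the
count of blocked random candidates (BR), their summed plan MU (BRW), the
count of blocked scorer-generated candidates (BC), or their summed
predicted weight (BCW). The schedule is geometric: temperature 10 halved
every 100 iterations, 1000 iterations, best of 5 random restarts;
improving moves are always accepted and worsening moves with probability
`exp(−Δ/Θ)`. The move set (a package choice; equal probability of base
jitter σ = 30 mm, box switch, viewport jump within 25 mm — uniform with
probability 0.1 — and LIFT jitter σ = 15°, re-drawn until feasible, at
most 50 tries) and the restart policy (all restarts share one candidate
beam set) are config-exposed. `run_workflow()` composes the stages,
including the variant that scores the pose search on the weighted subset
only but applies the found pose to the full candidate set.

## Desk-scale study sizes

The bundled tests and the acceptance script run everything end to end at
sizes a single CPU handles in minutes, chosen once: planning grids of
4 mm for cohort studies (3 mm remains the default and is used for single-
case examples), 500 candidate beams per plan (1000–1500 where the 95%
calibration premise needs the larger pool), cohorts of 10 training + 5
held-out phantoms with PTVs of 25–70 cm³, 10 candidate draws per training
phantom, and the 24 px feature setting. The directional findings these
runs check — scorer-guided candidates covering at least as well as random
ones, weighted objectives taking more distinct values than counting ones,
three LIFT angles never blocking more than one — are scale-free
properties of the method; absolute clinical numbers are not reproduced at
desk scale and are not claimed.

## Known limitations

* The dose kernel is a shaped exponential cone, not clinical dosimetry;
  absolute MU and dose values are internally consistent only.
* The robot is a three-capsule proxy with an analytic redundancy circle;
  joint limits and couch collisions are not modelled.
* Viewport feasibility is ray-trace geometry on gray values, not acoustic
  simulation.
* The `NIfTI` reader/writer round-trips arrays and voxel spacing but not
  full orientation metadata; the phantom writer records the origin in a
  JSON sidecar.
* Coverage responds to the shell scale as a step function, so the 95%
  calibration can overshoot its band on anatomies whose response jumps;
  the calibration reports this instead of hiding it.
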