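# sonoplan

Treatment planning and setup optimization for ultrasound-guided robotic
radiotherapy of the prostate, on synthetic pelvic CT phantoms.

Robotic stereotactic radiotherapy treats the prostate with a small subset
of weighted beams chosen from thousands of candidate directions by
inverse planning. Continuous target tracking with a robot-held ultrasound
transducer avoids ionizing imaging and implanted fiducials — but the
transducer and its 7-DoF carrying arm are radio-opaque and block part of
the candidate beam space. `sonoplan` implements the optimization stack
for studying that trade-off:

* **Phantoms** — parametric pelvic CT stand-ins (ellipsoidal body, PTV,
  bladder, rectum, bone capsules, bowel gas) on the offset-1000 gray
  scale, with 3 mm / 9 mm shell structures and planning-grid
  discretization.
* **Planning** — the two-stage linear program: stage 1 minimizes the
  total PTV underdose `Σᵢ max(0, D_Rx − dᵢ)` (`D_Rx = 36.25 Gy`) under
  hard maximum doses (PTV 40.25 Gy, OARs 36 Gy, calibrated shell bounds)
  and activation-time caps (300 MU/beam, 40 000 MU total); stage 2
  minimizes total MU at fixed per-voxel PTV lower bounds. Shell bounds
  are bisected per case until the no-robot coverage hits 95%.
* **Viewports** — acoustic-window feasibility by CT ray tracing: a skin
  point can image the target iff the path to the centroid has
  `max(gray) ≤ 1300` (no bone), `min(gray) ≥ 400` (no gas) and tissue
  depth ≤ 120 mm.
* **Robot & blocking** — a capsule-chain arm with an analytic elbow
  redundancy (LIFT) circle; a beam is blocked when a capsule comes closer
  to its axis than capsule radius + cone radius + 20 mm motion margin;
  with three LIFT angles a beam counts as blocked only if all
  configurations block it.
* **Beam scorer** — a small convolutional network over 7-channel
  projection images (beam aperture + min/max radiological-depth maps of
  PTV/rectum/bladder) trained with the coverage-weighted loss
  `(w_p − w_g)² · c_des/c_p` (unweighted beams) or `· c_p/c_des`
  (weighted beams); candidates are then drawn by rejection with
  acceptance `w_p / 300`.
* **Setup search** — simulated annealing over robot base position,
  viewport and LIFT angle under the four blocking objectives BR / BRW /
  BC / BCW (count or summed weight of blocked random / scorer-generated
  beams), temperature 10 halved every 100 of 1000 iterations, best of 5
  restarts.

See `vignettes/sonoplan-methods.Rmd` for the models, parameters and
design choices in detail.

## Worked example

```r
library(sonoplan)
phantom    <- generate_phantom(phantom_spec())
structures <- build_shells(phantom$structures)
grid       <- voxelize(structures, resolution = 4)
beams      <- sample_candidate_beams(grid, n = 1000, seed = 1)
D          <- compute_dose_matrix(phantom$ct, grid, beams)

cal  <- calibrate_shell_dose(phantom$ct, grid, beams, dose = D)
cons <- plan_constraints(shell3_max = cal$shell3_max,
                         shell9_max = cal$shell9_max)
plan1 <- optimize_coverage(D, cons)
plan2 <- optimize_mu(D, cons, plan1)
plan2
#> <treatment_plan> stage=mu: coverage 95.30%, total 2167 MU, 333/1000 beams, underdose 44.167 Gy
glance(plan2)
#> # A tibble: 1 × 7
#>   stage coverage total_mu objective_underdose n_beams n_active prescribed_dose
#>   <chr>    <dbl>    <dbl>               <dbl>   <int>    <int>           <dbl>
#> 1 mu       0.953    2167.                44.2    1000      333            36.2
```

The shell calibration has pinned the stage-1 coverage just above the 95%
target; the plan activates 333 of the 1000 candidates. Now the
ultrasound side: feasible viewports, and a robot setup that minimizes the
summed plan weight of blocked beams (BRW) over base position, viewport
and three LIFT angles:

```r
vps <- viewport_map(phantom$ct, grid)
table(vps$reason)
#> dense   gas depth  none
#>   649     0  3230  1552

sa <- optimize_setup(objective_spec("BRW", beams, weights = plan1$weights),
                     vps, schedule = anneal_schedule(seed = 1),
                     lift_offsets = c(-pi / 6, 0, pi / 6))
sa
#> <anneal_result> best objective 0 after 5 restarts x 1000 iterations
```

1552 skin points admit acoustic imaging of the target; the annealer finds
a setup whose blocked beams carry zero plan weight — the transducer can
track the prostate without degrading this plan at all. `autoplot()`
methods visualize viewport maps, annealing traces, plans and training
curves; `run_workflow()` and `evaluate_cohort()` compose the full
pipelines (including scorer training via `build_training_data()` and
`train_beam_scorer()`) across phantom cohorts.

A thin command-line wrapper is included:

```sh
exec/sonoplan phantom --seed 3 --out case3/
exec/sonoplan plan --phantom case3/ --n-beams 500 --out plan.json
```

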