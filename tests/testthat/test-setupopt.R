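test_that("blocking objectives sum weights over the blocked set", {
  bd <- test_bundle()
  vps <- test_viewports()
  beams <- sample_candidate_beams(bd$grid, 3, seed = 2)
  spec <- objective_spec("BRW", beams, weights = c(10, 0, 50))
  # hand-made states: far-away base blocks nothing
  st_clear <- robot_setup(c(400, 0, 0), "left", which(vps$feasible)[1], 0)
  obj <- setup_objective(st_clear, spec, vps, bd$centroid)
  bl <- blocked_set(beams, st_clear, vps, bd$centroid)
  expect_equal(obj, sum(c(10, 0, 50)[bl]))
  # BR counts beams
  spec_br <- objective_spec("BR", beams)
  expect_equal(setup_objective(st_clear, spec_br, vps, bd$centroid),
               length(bl))
  # weighted objectives validate their weights
  expect_error(objective_spec("BCW", beams), "weights")
  expect_error(objective_spec("BRW", beams, weights = c(1, 2)), "length")
})

test_that("neighbourhood moves stay in their boxes and cover all kinds", {
  bd <- test_bundle()
  vps <- test_viewports()
  beams <- sample_candidate_beams(bd$grid, 50, seed = 3)
  prob <- robot_setup_problem(objective_spec("BR", beams), vps, bd$centroid)
  boxes <- default_base_boxes()
  with_seed(21, {
    st <- prob$random_state()
    kinds <- c(base = 0, box = 0, vp = 0, lift = 0)
    for (k in 1:400) {
      nx <- prob$neighbor(st, 5)
      if (nx$box != st$box) kinds["box"] <- kinds["box"] + 1
      else if (nx$viewport_index != st$viewport_index) kinds["vp"] <- kinds["vp"] + 1
      else if (nx$lift != st$lift) kinds["lift"] <- kinds["lift"] + 1
      else if (any(nx$base_position != st$base_position)) kinds["base"] <- kinds["base"] + 1
      bx <- boxes[[nx$box]]
      expect_true(all(nx$base_position >= bx$lo - 1e-9) &&
                    all(nx$base_position <= bx$hi + 1e-9))
      expect_true(vps$feasible[nx$viewport_index])
      st <- nx
    }
    expect_true(all(kinds > 0))
  })
})

test_that("annealing bookkeeping: constant objectives and best-trace", {
  prob <- table_sa_problem(array(42, dim = c(4, 4, 4)))
  sched <- anneal_schedule(iterations = 50, restarts = 2, seed = 3)
  res <- anneal(prob, sched)
  expect_equal(res$best_objective, 42)
  expect_true(!is.null(res$best_state))
  # incumbent-best is non-increasing within each restart
  prob2 <- table_sa_problem(with_seed(2, {
    array(round(runif(4 * 4 * 4, 0, 100), 1), dim = c(4, 4, 4))
  }))
  res2 <- anneal(prob2, anneal_schedule(iterations = 300, restarts = 3,
                                        seed = 9))
  for (r in 1:3) {
    tr <- res2$trace[res2$trace$restart == r, ]
    expect_true(all(diff(tr$best) <= 0))
  }
  # temperature halves every halve_every iterations
  tr1 <- res2$trace[res2$trace$restart == 1, ]
  expect_equal(tr1$theta[1], 10)
  expect_equal(tr1$theta[101], 5)
  expect_equal(tr1$theta[201], 2.5)
  # best-of-restarts no worse than any single restart
  per_restart <- tapply(res2$trace$best, res2$trace$restart, min)
  expect_equal(res2$best_objective, min(per_restart))
  # determinism per seed
  res3 <- anneal(prob2, anneal_schedule(iterations = 300, restarts = 3,
                                        seed = 9))
  expect_identical(res2$trace, res3$trace)
})

test_that("annealing recovers the exhaustive optimum of the toy space", {
  prob <- toy_brw_problem()
  best <- min(prob$table[is.finite(prob$table)])
  hits <- 0
  for (seed in 1:10) {
    res <- anneal(prob, anneal_schedule(iterations = 1000, restarts = 5,
                                        seed = 100 + seed))
    if (abs(res$best_objective - best) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("weighted objectives take more distinct values than counting ones", {
  bd <- test_bundle()
  vps <- test_viewports()
  beams <- sample_candidate_beams(bd$grid, 120, seed = 6)
  wts <- with_seed(2, runif(120, 0, 60))
  sbr <- objective_spec("BR", beams)
  sbrw <- objective_spec("BRW", beams, weights = wts)
  feas <- which(vps$feasible)
  with_seed(9, {
    vals_br <- c(); vals_brw <- c()
    for (k in 1:40) {
      bx <- default_base_boxes()$legs
      st <- robot_setup(bx$lo + runif(3) * (bx$hi - bx$lo), "legs",
                        sample(feas, 1), runif(1, -pi, pi))
      o1 <- setup_objective(st, sbr, vps, bd$centroid)
      o2 <- setup_objective(st, sbrw, vps, bd$centroid)
      if (is.finite(o1)) { vals_br <- c(vals_br, o1); vals_brw <- c(vals_brw, o2) }
    }
    expect_gte(length(unique(round(vals_brw, 9))),
               length(unique(vals_br)))
  })
})

test_that("workflows compose: baseline identity and full robot path", {
  bd <- test_bundle()
  vps <- test_viewports()
  wf0 <- run_workflow(bd, "random", "none", n_beams = 150, seed = 5,
                      two_stage = FALSE)
  expect_equal(length(wf0$blocked), 0)
  expect_equal(length(wf0$kept), 150)
  expect_null(wf0$setup)
  sched <- anneal_schedule(iterations = 150, restarts = 2)
  wf1 <- run_workflow(bd, "random", "BRW", n_beams = 150, seed = 5,
                      schedule = sched, viewports = vps, two_stage = TRUE)
  expect_s3_class(wf1$plan1, "treatment_plan")
  expect_s3_class(wf1$plan2, "treatment_plan")
  expect_s3_class(wf1$setup, "anneal_result")
  # blocked beams are removed before planning
  expect_true(all(!(wf1$blocked %in% wf1$kept)))
  # zero blocked beams at the optimum reproduces the baseline stage-1 plan
  if (length(wf1$blocked) == 0) {
    expect_equal(wf1$plan1$coverage, wf1$baseline_plan1$coverage,
                 tolerance = 1e-9)
  }
  # restriction property: blocking cannot improve the same-candidate plan
  expect_lte(wf1$plan1$coverage, wf1$baseline_plan1$coverage + 1e-9)
  f <- tempfile(fileext = ".json")
  write_plan_json(wf1$plan2, f)
  expect_true(file.exists(f))
  # B*: pose search on the weighted subset, blocking applied to all beams
  wfb <- run_workflow(bd, "random", "BRW", n_beams = 150, seed = 5,
                      schedule = sched, viewports = vps, bstar = TRUE,
                      two_stage = FALSE)
  expect_equal(length(wfb$kept) + length(wfb$blocked), 150)
})
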