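test_that("the coverage-weighted loss evaluates the printed formula", {
  expect_equal(beam_loss(42, 42, 0.8), 0)
  expect_equal(beam_loss(0, 0, 0.3), 0)
  expect_equal(beam_loss(10, 0, 0.475, 0.95), 200)
  expect_equal(beam_loss(0, 10, 0.475, 0.95), 50)
  expect_error(beam_loss(1, 1, 0), "positive")
  # monotone in coverage, opposite directions per branch
  cps <- seq(0.2, 1, by = 0.1)
  l0 <- beam_loss(10, 0, cps)
  expect_true(all(diff(l0) < 0))
  l1 <- beam_loss(0, 10, cps)
  expect_true(all(diff(l1) > 0))
})

test_that("aperture channel is the analytic cone section", {
  bd <- test_bundle()
  beams <- sample_candidate_beams(bd$grid, 1, seed = 31)
  beams$diameter_mm <- 40
  beams$tx <- bd$centroid[1]; beams$ty <- bd$centroid[2]
  beams$tz <- bd$centroid[3]  # axis through the plane origin
  fs <- feature_spec(size = 48, pixel_mm = 2, step = 5)
  f <- beam_features(bd$ct, bd$structures, beams, fs)
  img <- array(f[, 1], dim = c(48, 48, 7))
  ap <- img[, , 1]
  # the beam aims at the centroid, so the aperture is a centred disc with
  # radius ~ diameter/2 (magnification |q - src| / sad ~ 1 at the plane)
  ctr <- (48 + 1) / 2
  rad_px <- 20 / 2
  for (r in seq_len(48)) {
    for (cc in seq(1, 48, by = 3)) {
      dist_px <- sqrt((r - ctr)^2 + (cc - ctr)^2)
      if (dist_px < rad_px - 1) expect_equal(ap[r, cc], 1)
      if (dist_px > rad_px + 1) expect_equal(ap[r, cc], 0)
    }
  }
})

test_that("feature depth channels satisfy min <= max and match an R oracle", {
  bd <- test_bundle()
  beams <- sample_candidate_beams(bd$grid, 3, seed = 13)
  fs <- feature_spec(size = 16, pixel_mm = 8, step = 4)
  f <- beam_features(bd$ct, bd$structures, beams, fs)
  for (b in 1:3) {
    img <- array(f[, b], dim = c(16, 16, 7))
    for (s in 1:3) {
      mn <- img[, , 2 * s]
      mx <- img[, , 2 * s + 1]
      expect_true(all(mx >= mn))
      expect_true(all((mn == 0) == (mx == 0) | mn <= mx))
    }
  }
  # R ray-march oracle on a handful of pixels of beam 1
  img <- array(f[, 1], dim = c(16, 16, 7))
  src <- c(beams$sx[1], beams$sy[1], beams$sz[1])
  n <- unitize(bd$centroid - src)
  up <- c(0, 0, 1) - n[3] * n
  up <- up / vnorm(up)
  rt <- cross3(up, n)
  labs <- bd$labels
  d <- dim(labs)
  for (px in list(c(8, 8), c(6, 11), c(12, 5))) {
    r <- px[1]; cc <- px[2]
    q <- bd$centroid + ((16 - 1) / 2 - (r - 1)) * 8 * up +
      ((cc - 1) - (16 - 1) / 2) * 8 * rt
    L <- vnorm(q - src) + 120
    dirn <- unitize(q - src)
    nseg <- ceiling(L / 4)
    h <- L / nseg
    cum <- 0
    mn <- rep(-1, 3); mx <- rep(-1, 3)
    for (k in seq_len(nseg)) {
      p <- src + (k - 0.5) * h * dirn
      ii <- round((p - bd$ct$origin) / bd$ct$spacing) + 1
      if (any(ii < 1) || any(ii > d)) next
      g <- bd$ct$values[ii[1], ii[2], ii[3]]
      if (g > 0) cum <- cum + g / 1000 * h
      lv <- labs[ii[1], ii[2], ii[3]]
      if (lv > 0) {
        if (mn[lv] < 0) mn[lv] <- cum
        mx[lv] <- cum
      }
    }
    for (s in 1:3) {
      expect_equal(img[r, cc, 2 * s], max(mn[s], 0), tolerance = 1e-9)
      expect_equal(img[r, cc, 2 * s + 1], max(mx[s], 0), tolerance = 1e-9)
    }
  }
  # degenerate plane
  degen <- beams[1, ]
  degen$sx <- bd$centroid[1]; degen$sy <- bd$centroid[2]
  degen$sz <- bd$centroid[3]
  expect_error(beam_features(bd$ct, bd$structures, degen, fs), "coincide")
})

test_that("training rebalance keeps weighted beams and thins the rest", {
  ex <- tibble::tibble(w_g = c(rep(0, 19000), rep(50, 1000)))
  out <- subsample_training(ex, w_b = 19, seed = 5)
  kept0 <- sum(out$w_g == 0)
  expect_equal(sum(out$w_g > 0), 1000)  # weighted always retained
  sigma <- sqrt(19000 * (1 / 19) * (18 / 19))
  expect_lt(abs(kept0 - 1000), 3 * sigma)
  # w_b = 1 retains everything
  expect_equal(nrow(subsample_training(ex, w_b = 1, seed = 1)), 20000)
  # the literal drop-with-1/w_b reading barely thins
  out_drop <- subsample_training(ex, w_b = 19, seed = 5, mode = "drop")
  expect_gt(sum(out_drop$w_g == 0), 17000)
  expect_error(subsample_training(tibble::tibble(w_g = c(0, 0))), "weighted")
})

test_that("the learning-rate schedule steps as printed", {
  expect_equal(lr_schedule(0), 1e-3)
  expect_equal(lr_schedule(5), 1e-4)
  expect_equal(lr_schedule(10), 1e-5)
  expect_equal(lr_schedule(c(4, 9, 14)), c(1e-3, 1e-4, 1e-5))
})

test_that("the scorer's training loss descends and predictions clamp", {
  with_seed(8, {
    fs <- feature_spec(size = 16, pixel_mm = 8, step = 4)
    N <- 120
    X <- matrix(rnorm(16 * 16 * 7 * N), ncol = N)
    # plant a linear signal on the first channel
    w_g <- pmax(0, 30 * colMeans(X[1:256, ]) + rnorm(N, 0, 0.5))
    td <- list(X = X, w_g = w_g, c_p = rep(0.9, N), fspec = fs)
    sc <- train_beam_scorer(td, epochs = 4, batch_size = 16, seed = 2)
    expect_lt(utils::tail(sc$loss_history, 1), sc$loss_history[1])
    pr <- predict_weight(sc, X)
    expect_true(all(pr >= 0 & pr <= 300))
    expect_identical(pr, predict_weight(sc, X))  # deterministic inference
    # gradient check: numerical vs analytic on a few parameters
    params <- sc$params
    Xs <- (X[, 1:8] - sc$norm$mean[rep(1:7, each = 256)]) /
      sc$norm$sd[rep(1:7, each = 256)]
    dout <- rep(1, 8)
    gb <- .net_run_cpp(params, Xs, 16L, 7L, dout)
    eps <- 1e-5
    for (nm in c("W1", "W5", "b2")) {
      p2 <- params
      p2[[nm]][1] <- p2[[nm]][1] + eps
      up <- sum(.net_run_cpp(p2, Xs, 16L, 7L, numeric(0))$pred)
      p2[[nm]][1] <- p2[[nm]][1] - 2 * eps
      dn <- sum(.net_run_cpp(p2, Xs, 16L, 7L, numeric(0))$pred)
      expect_equal(gb$grads[[nm]][1], (up - dn) / (2 * eps),
                   tolerance = 1e-4)
    }
  })
})

test_that("fold stratification balances PTV volumes", {
  with_seed(3, {
    vols <- runif(12, 25, 120)
    fold <- stratify_folds(vols, 3)
    expect_equal(as.numeric(table(fold)), rep(4, 3))
    means <- tapply(vols, fold, mean)
    expect_lt(max(means) / min(means), 1.2)
  })
})

test_that("scorer-guided sampling follows the acceptance law", {
  bd <- test_bundle()
  # constant scorers via a stub with a zeroed network and fixed bias
  stub_scorer <- function(value) {
    p <- sonoplan:::net_init(H = 8, seed = 1)
    for (nm in names(p)) p[[nm]] <- p[[nm]] * 0
    p$b5 <- value
    structure(list(params = p, norm = list(mean = rep(0, 7), sd = rep(1, 7)),
                   fspec = feature_spec(size = 8, pixel_mm = 16, step = 8),
                   H = 8L, C = 7L, loss_history = 0, seed = 1L,
                   c_des = 0.95), class = "beam_scorer")
  }
  s300 <- stub_scorer(300)
  out <- sample_cnn_beams(s300, bd$ct, bd$structures, bd$grid, 200, seed = 4)
  expect_equal(nrow(out), 200)
  expect_equal(attr(out, "provenance"), "cnn")
  expect_true(all(out$weight_mu == 300))
  # a hopeless scorer stalls out
  expect_error(
    sample_cnn_beams(stub_scorer(0), bd$ct, bd$structures, bd$grid, 10,
                     seed = 4, max_draws = 2000),
    "stalled")
  # acceptance frequency for a constant mid scorer
  s150 <- stub_scorer(150)
  out2 <- sample_cnn_beams(s150, bd$ct, bd$structures, bd$grid, 500, seed = 9)
  drawn <- attr(out2, "n_drawn")
  phat <- attr(out2, "n_accepted") / drawn
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / drawn))
})

test_that("scorers and beam sets round-trip through JSON", {
  with_seed(4, {
    fs <- feature_spec(size = 8, pixel_mm = 16, step = 8)
    X <- matrix(rnorm(8 * 8 * 7 * 40), ncol = 40)
    td <- list(X = X, w_g = runif(40, 0, 30), c_p = rep(0.8, 40), fspec = fs)
    sc <- train_beam_scorer(td, epochs = 1, batch_size = 8, seed = 2)
    f <- tempfile(fileext = ".json")
    write_beam_scorer(sc, f)
    back <- read_beam_scorer(f)
    expect_equal(predict_weight(back, X), predict_weight(sc, X),
                 tolerance = 1e-12)
  })
  bd <- test_bundle()
  beams <- sample_candidate_beams(bd$grid, 10, seed = 3)
  f2 <- tempfile(fileext = ".json")
  write_beams_json(beams, f2)
  b2 <- read_beams_json(f2)
  expect_equal(b2$sx, beams$sx, tolerance = 1e-12)
  expect_equal(attr(b2, "provenance"), "random")
})
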