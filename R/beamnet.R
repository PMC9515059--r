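#' Feature-image specification
#'
#' Geometry of the per-beam projection images: `size` x `size` pixels of
#' `pixel_mm` mm on the plane through the PTV centroid perpendicular to
#' the source-centroid line, ray-marched at `step` mm. The full-scale
#' setting is 150 x 150 at 1 mm; the desk-scale default used by the
#' bundled trainer is 24 x 24 at 6 mm with a 3 mm march on a 5 mm volume.
#'
#' @param size image side, pixels.
#' @param pixel_mm pixel pitch at the projection plane, mm.
#' @param step ray-march step, mm.
#' @param vol_mm optional isotropic volume resampling (mm) applied before
#'   ray marching; `NULL` keeps the native lattice.
#' @return A `feature_spec` list.
#' @export
feature_spec <- function(size = 150, pixel_mm = 1, step = 1, vol_mm = NULL) {
  structure(list(size = as.integer(size), pixel_mm = pixel_mm, step = step,
                 vol_mm = vol_mm),
            class = "feature_spec")
}

#' @rdname feature_spec
#' @export
feature_spec_small <- function() {
  feature_spec(size = 24, pixel_mm = 6, step = 3, vol_mm = 5)
}

# nearest-neighbour resampling of volume + labels onto a coarser isotropic
# lattice; the small feature setting marches on a 5 mm volume, which fits in
# cache and matches the 5 mm pixel pitch
downsample_for_features <- function(ct, labels, vol_mm) {
  d <- dim(ct$values)
  idx <- lapply(1:3, function(ax) {
    ext <- ct$origin[ax] + (d[ax] - 1) * ct$spacing[ax]
    xs <- seq(ct$origin[ax], ext, by = vol_mm)
    pmin(pmax(round((xs - ct$origin[ax]) / ct$spacing[ax]) + 1, 1), d[ax])
  })
  list(values = ct$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
       labels = labels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
       spacing = rep(vol_mm, 3),
       origin = ct$origin)
}

# integer label volume for feature ray tracing: 1 PTV, 2 rectum, 3 bladder
structure_labels <- function(structures) {
  lab <- array(0L, dim = dim(structures$masks[[1]]))
  if (!is.null(structures$masks$BLADDER)) lab[structures$masks$BLADDER] <- 3L
  if (!is.null(structures$masks$RECTUM)) lab[structures$masks$RECTUM] <- 2L
  lab[structures$masks$PTV] <- 1L
  lab
}

#' Per-beam projection features
#'
#' Builds the 7-channel input tensor of the beam scorer for each beam:
#' channel 1 is the binary beam aperture on the projection plane through
#' the PTV centroid; channels 2-7 are minimum and maximum radiological
#' depth (water-equivalent mm from the beam source) at which the ray
#' through each pixel traverses the PTV, rectum and bladder, 0 where the
#' structure is not hit. The images carry both the distance to the beam
#' source and the radiological properties of the intervening tissue.
#'
#' @param ct a [ct_volume].
#' @param structures a [structure_set] with PTV (and optionally
#'   bladder/rectum) masks.
#' @param beams `candidate_beams` tibble.
#' @param fspec a [feature_spec()].
#' @param labels optional precomputed label volume (internal reuse).
#' @param centroid optional PTV centroid override, mm.
#' @return Matrix with `size^2 * 7` rows, one column per beam; each column
#'   is an array of dim `c(size, size, 7)`.
#' @export
beam_features <- function(ct, structures, beams, fspec = feature_spec(),
                          labels = NULL, centroid = NULL) {
  labels <- labels %||% structure_labels(structures)
  centroid <- centroid %||%
    mask_centroid(structures$masks$PTV, structures$spacing, structures$origin)
  if (!is.null(fspec$vol_mm) && fspec$vol_mm > max(ct$spacing)) {
    dsv <- downsample_for_features(ct, labels, fspec$vol_mm)
    vals <- dsv$values; labs <- dsv$labels
    sp <- dsv$spacing; org <- dsv$origin
  } else {
    vals <- ct$values; labs <- labels
    sp <- ct$spacing; org <- ct$origin
  }
  .beam_features_cpp(
    vals, labs, dim(vals), sp, org,
    cbind(beams$sx, beams$sy, beams$sz),
    cbind(beams$tx, beams$ty, beams$tz),
    beams$diameter_mm, centroid, fspec$size, fspec$pixel_mm, fspec$step)
}

#' Coverage-weighted training loss
#'
#' Piecewise squared-error loss for beam-weight regression. For an
#' unweighted ground truth (`w_g = 0`) the squared error is scaled by
#' `c_des / c_p`, for a weighted one by `c_p / c_des`: unweighted beams of
#' low-coverage plans are penalised harder when predicted useful, while
#' weighted beams matter more the better their plan's coverage. The two
#' branches are deliberately discontinuous in `w_g` (a label-class
#' weighting, not a function of dose).
#'
#' @param w_p predicted weight, MU.
#' @param w_g ground-truth weight, MU (0 = unweighted).
#' @param c_p coverage of the plan that produced `w_g` (in (0, 1]).
#' @param c_des desired coverage (0.95).
#' @return Loss value(s), vectorized over the inputs.
#' @export
beam_loss <- function(w_p, w_g, c_p, c_des = 0.95) {
  if (any(c_p <= 0)) abort("c_p must be positive")
  se <- (w_p - w_g)^2
  ifelse(w_g == 0, se * c_des / c_p, se * c_p / c_des)
}

# per-example loss scale (the branch factor); gradient = 2 * scale * resid
loss_scale <- function(w_g, c_p, c_des = 0.95) {
  ifelse(w_g == 0, c_des / c_p, c_p / c_des)
}

#' Rebalance training examples
#'
#' Training data are dominated by unweighted beams (imbalance ratio
#' `w_b = n_unweighted / n_weighted`, about 19 at full scale). Weighted
#' examples are always retained; each unweighted example is kept
#' independently with probability `1 / w_b` (default reading, restoring an
#' approximate 1:1 class balance). The alternative literal reading —
#' *dropping* unweighted examples with probability `1 / w_b` — is
#' available as `mode = "drop"`.
#'
#' @param examples tibble with a `w_g` column.
#' @param w_b imbalance ratio (>= 1); default: measured from `examples`.
#' @param seed integer seed.
#' @param mode `"keep"` (retain with prob `1/w_b`) or `"drop"` (discard
#'   with prob `1/w_b`).
#' @return The subsampled tibble.
#' @export
subsample_training <- function(examples, w_b = NULL, seed = 1L,
                               mode = c("keep", "drop")) {
  mode <- match.arg(mode)
  weighted <- examples$w_g > 0
  if (!any(weighted)) abort("no weighted examples to balance against")
  w_b <- w_b %||% max(1, sum(!weighted) / sum(weighted))
  if (w_b < 1) abort("w_b must be >= 1")
  keep_prob <- if (mode == "keep") 1 / w_b else 1 - 1 / w_b
  with_seed(seed, {
    keep <- weighted | (runif(nrow(examples)) < keep_prob)
  })
  examples[keep, , drop = FALSE]
}

#' Step learning-rate schedule
#'
#' Learning rate decreased from `base` by `factor` every `every` epochs
#' down to `floor` (1e-3 to 1e-5 over 15 epochs at the defaults).
#'
#' @param epoch 0-based epoch index.
#' @param base,factor,every,floor schedule parameters.
#' @return Learning rate at `epoch`.
#' @export
lr_schedule <- function(epoch, base = 1e-3, factor = 10, every = 5,
                        floor = 1e-5) {
  pmax(base / factor^(epoch %/% every), floor)
}

# He-initialised parameters of the small backbone; H is the input side
net_init <- function(C = 7, H = 32, F1 = 16, F2 = 32, F3 = 32, seed = 1L) {
  oh1 <- (H + 4 - 5) %/% 2 + 1
  oh2 <- (oh1 + 2 - 3) %/% 2 + 1
  flat <- F2 * oh2^2
  with_seed(seed, {
    he <- function(nr, nc, fan) matrix(rnorm(nr * nc, 0, sqrt(2 / fan)), nr, nc)
    list(W1 = he(F1, C * 25, C * 25), b1 = rep(0, F1),
         W2 = he(F2, F1 * 9, F1 * 9), b2 = rep(0, F2),
         W4 = he(F3, flat, flat), b4 = rep(0, F3),
         W5 = he(1, F3, F3), b5 = 0)
  })
}

#' Train the beam scorer
#'
#' Trains the small convolutional backbone (two stride-2 convolutions,
#' global average pooling, two dense layers, single scalar output) on a
#' beam training set under the coverage-weighted loss, using Adam
#' (`beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-7`) for 15 epochs with the
#' step learning-rate schedule of [lr_schedule()]. Inputs are
#' standardized per channel with statistics computed from the training
#' data and stored in the scorer.
#'
#' @param data a `beam_training_set` from [build_training_data()] (any
#'   list with `X` (features x examples), `w_g`, `c_p` and `fspec`).
#' @param epochs,batch_size training schedule.
#' @param seed integer seed (shuffling and initialisation).
#' @param lr_base base learning rate.
#' @param c_des desired coverage in the loss.
#' @param verbose print per-epoch loss.
#' @return A `beam_scorer`: parameters, channel normalisation, feature
#'   spec, per-epoch mean training loss.
#' @export
train_beam_scorer <- function(data, epochs = 15, batch_size = 32, seed = 1L,
                              lr_base = 1e-3, c_des = 0.95, verbose = FALSE) {
  X <- data$X
  N <- ncol(X)
  if (N < batch_size) abort("fewer examples than one batch")
  H <- data$fspec$size
  C <- 7L
  npix <- H * H
  # per-channel standardisation on the training data
  chan <- rep(seq_len(C), each = npix)
  mu <- vapply(seq_len(C), function(c) mean(X[chan == c, ]), 0)
  sg <- vapply(seq_len(C), function(c) sd(X[chan == c, ]), 0)
  sg[sg < 1e-8] <- 1
  Xs <- (X - mu[chan]) / sg[chan]
  scale <- loss_scale(data$w_g, data$c_p, c_des)

  params <- net_init(C = C, H = H, seed = seed)
  mstate <- lapply(params, function(p) p * 0)
  vstate <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-7
  tstep <- 0
  hist <- numeric(epochs)
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      lr <- lr_schedule(ep - 1, base = lr_base)
      ord <- sample.int(N)
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1, N - batch_size + 1, by = batch_size)) {
        idx <- ord[start:(start + batch_size - 1)]
        fb <- .net_run_cpp(params, Xs[, idx, drop = FALSE], H, C,
                           numeric(0))
        resid <- fb$pred - data$w_g[idx]
        ep_loss <- ep_loss + mean(scale[idx] * resid^2)
        dout <- 2 * scale[idx] * resid / length(idx)
        gb <- .net_run_cpp(params, Xs[, idx, drop = FALSE], H, C, dout)
        tstep <- tstep + 1
        for (nm in names(params)) {
          g <- gb$grads[[nm]]
          mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g
          vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g^2
          mhat <- mstate[[nm]] / (1 - b1^tstep)
          vhat <- vstate[[nm]] / (1 - b2^tstep)
          params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
        nb <- nb + 1L
      }
      hist[ep] <- ep_loss / nb
      if (verbose) {
        message(sprintf("epoch %2d lr %.0e loss %.1f", ep, lr, hist[ep]))
      }
    }
  })
  structure(list(params = params, norm = list(mean = mu, sd = sg),
                 fspec = data$fspec, H = H, C = C, loss_history = hist,
                 seed = seed, c_des = c_des),
            class = "beam_scorer")
}

#' @export
print.beam_scorer <- function(x, ...) {
  cat(sprintf("<beam_scorer> small backbone, %d x %d x %d input, final training loss %.1f\n",
              x$H, x$H, x$C, utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Predict beam weights
#'
#' Forward pass of the scorer; outputs are clamped to the physical weight
#' range `[0, 300]` MU.
#'
#' @param scorer a `beam_scorer`.
#' @param features feature matrix from [beam_features()] (columns =
#'   beams), computed with the scorer's own `fspec`.
#' @return Numeric vector of predicted weights, MU.
#' @export
predict_weight <- function(scorer, features) {
  features <- as.matrix(features)
  if (nrow(features) != scorer$H^2 * scorer$C) {
    abort("feature dimension does not match the scorer's feature spec")
  }
  npix <- scorer$H^2
  chan <- rep(seq_len(scorer$C), each = npix)
  Xs <- (features - scorer$norm$mean[chan]) / scorer$norm$sd[chan]
  pred <- .net_run_cpp(scorer$params, Xs, scorer$H, scorer$C, numeric(0))$pred
  if (any(!is.finite(pred))) abort("scorer produced non-finite output")
  pmin(pmax(pred, 0), 300)
}

#' Sample candidate beams from the scorer
#'
#' Rejection sampling of the learned beam-importance law: random beams are
#' drawn as in [sample_candidate_beams()], scored, and accepted with
#' probability `w_p / w_max` (`w_max = 300`), until `n` beams have been
#' selected.
#'
#' @param scorer a `beam_scorer`.
#' @param ct,structures,grid phantom volume, structures and planning grid.
#' @param n number of beams to select.
#' @param seed integer seed.
#' @param w_max acceptance normalisation, MU (300).
#' @param max_draws stall guard: error when the acceptance rate is below
#'   1e-4 after this many draws.
#' @return A `candidate_beams` tibble (provenance `"cnn"`) with predicted
#'   weights in `weight_mu`.
#' @export
sample_cnn_beams <- function(scorer, ct, structures, grid, n, seed = 1L,
                             w_max = 300, max_draws = 1e5) {
  if (n <= 0) abort("n must be positive")
  labels <- structure_labels(structures)
  accepted <- list()
  got <- 0L
  drawn <- 0L
  chunk <- 0L
  while (got < n) {
    chunk <- chunk + 1L
    m <- min(max(256L, 2L * (n - got)), 4096L)
    cand <- sample_candidate_beams(grid, m, seed = derive_seed(seed, chunk))
    feats <- beam_features(ct, structures, cand, scorer$fspec, labels = labels)
    wp <- predict_weight(scorer, feats)
    u <- with_seed(derive_seed(seed, 100000L + chunk), runif(m))
    take <- which(u < wp / w_max)
    drawn <- drawn + m
    if (length(take)) {
      cand <- cand[take, , drop = FALSE]
      cand$weight_mu <- wp[take]
      accepted[[length(accepted) + 1]] <- cand
      got <- got + length(take)
    }
    if (drawn >= max_draws && got / drawn < 1e-4) {
      abort("beam sampling stalled: acceptance rate below 1e-4")
    }
  }
  out <- dplyr::bind_rows(accepted)[seq_len(n), , drop = FALSE]
  out$id <- seq_len(n)
  attr(out, "n_drawn") <- drawn
  attr(out, "n_accepted") <- got  # may exceed n within the final chunk
  as_candidate_beams(out, "cnn")
}

#' Save / load a beam scorer
#'
#' Scorers are stored as plain JSON: parameters, channel normalisation,
#' feature spec and training metadata.
#' @param scorer a `beam_scorer`.
#' @param path file path (`.json`).
#' @export
write_beam_scorer <- function(scorer, path) {
  jsonlite::write_json(list(
    params = lapply(scorer$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = length(p), data = as.numeric(p))
    }),
    norm = scorer$norm,
    fspec = unclass(scorer$fspec),
    H = scorer$H, C = scorer$C,
    loss_history = scorer$loss_history,
    seed = scorer$seed, c_des = scorer$c_des),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_beam_scorer
#' @export
read_beam_scorer <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(x$params, function(p) {
    if (length(p$dim) == 2) matrix(p$data, p$dim[1], p$dim[2]) else p$data
  })
  fs <- do.call(feature_spec, as.list(x$fspec))
  structure(list(params = params,
                 norm = list(mean = x$norm$mean, sd = x$norm$sd),
                 fspec = fs, H = as.integer(x$H), C = as.integer(x$C),
                 loss_history = x$loss_history, seed = x$seed,
                 c_des = x$c_des),
            class = "beam_scorer")
}
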