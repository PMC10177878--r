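# Mask branch: coarse head, uncertainty point selection, point features,
# point head, iterative refinement.

test_that("coarse mask head outputs probabilities with the zero-weight limit", {
  set.seed(40)
  pars <- init_mask_head(4L)
  roi <- array(rnorm(14 * 14 * 4), c(14, 14, 4))
  p <- coarse_mask_head(roi, pars)
  expect_equal(dim(p), c(14, 14, 3))
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p, coarse_mask_head(roi, pars))   # deterministic

  zp <- init_mask_head(4L)
  for (nm in c("c1", "c2")) {
    zp[[nm]]$w$value[] <- 0; zp[[nm]]$b$value[] <- 0
    zp[[nm]]$norm$gamma$value[] <- 0; zp[[nm]]$norm$beta$value[] <- 0
  }
  zp$out$w$value[] <- 0; zp$out$b$value[] <- 0
  expect_equal(coarse_mask_head(roi, zp), array(0.5, c(14, 14, 3)))
})

test_that("training point selection honours the beta split", {
  set.seed(41)
  grid <- matrix(runif(196), 14, 14)
  selA <- select_training_points(grid, k = 3, beta = 1, n_points = 20,
                                 rng = 5)
  expect_equal(nrow(selA$points), 20L)
  # beta = 1: the selected points are the 20 most uncertain candidates
  cu <- abs(selA$candidate_probability - 0.5)
  expect_equal(sort(selA$uncertainty), sort(cu[order(cu)[1:20]]),
               tolerance = 1e-12)
  worst_kept <- max(selA$uncertainty)
  unselected <- sort(cu, decreasing = FALSE)[-(1:20)]
  expect_true(all(unselected >= worst_kept - 1e-12))

  selB <- select_training_points(grid, k = 3, beta = 0, n_points = 20,
                                 rng = 5)
  expect_equal(selB$n_uncertain, 0L)
  expect_equal(nrow(selB$points), 20L)
  expect_error(select_training_points(grid, k = 0.5, beta = 0.5,
                                      n_points = 5))
  gg <- grid; gg[1] <- NA
  expect_error(select_training_points(gg, n_points = 5), "finite")
})

test_that("uncertainty ranking picks probabilities closest to 0.5", {
  g <- matrix(c(0.1, 0.45, 0.8, 0.52), 2, 2, byrow = TRUE)
  sel <- select_inference_points(g, 2)
  expect_equal(sort(sel$probability), c(0.45, 0.52))
  expect_equal(sel$probability[1], 0.52)   # |0.52-0.5| < |0.45-0.5|
})

test_that("inference selection matches an exhaustive sort with row-major ties", {
  # all certainties equal: first N in row-major order
  g01 <- matrix(rep(c(0, 1), 18), 6, 6)
  sel <- select_inference_points(g01, 7)
  expect_equal(sel$idx[, "row"], c(1, 1, 1, 1, 1, 1, 2), ignore_attr = TRUE)
  expect_equal(sel$idx[, "col"], c(1, 2, 3, 4, 5, 6, 1), ignore_attr = TRUE)

  gg <- matrix(0.9, 5, 5); gg[c(3, 11, 20)] <- 0.5
  s3 <- select_inference_points(gg, 3)
  expect_setequal(gg[s3$idx], c(0.5, 0.5, 0.5))

  set.seed(42)
  for (t in 1:20) {
    g <- matrix(runif(256), 16, 16)
    n <- 21
    sel <- select_inference_points(g, n)
    # oracle: exhaustive sort keyed by (uncertainty, row-major index)
    rm_idx <- as.numeric(t(matrix(seq_len(256), 16, 16, byrow = TRUE)))
    u <- abs(as.numeric(t(g)) - 0.5)        # row-major traversal
    ord <- order(u, seq_len(256))[1:n]
    rows <- (ord - 1) %/% 16 + 1; cols <- (ord - 1) %% 16 + 1
    expect_equal(unname(sel$idx[, "row"]), rows)
    expect_equal(unname(sel$idx[, "col"]), cols)
  }
})

test_that("point features concatenate exact bilinear reads", {
  set.seed(43)
  fine <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
  coarse <- matrix(runif(16), 4, 4)
  # exact grid node (pixel centre)
  pt <- cbind((3 - 0.5) / 8, (6 - 0.5) / 8)    # col 3, row 6
  v <- point_features(fine, coarse, pt)
  expect_equal(v[1, 1:5], fine[6, 3, ], tolerance = 1e-12)

  cf <- array(1.7, c(8, 8, 2))
  pts <- cbind(runif(10), runif(10))
  vv <- point_features(cf, coarse, pts)
  expect_true(all(abs(vv[, 1:2] - 1.7) < 1e-12))

  # midpoint of two nodes on a linear ramp -> average of node values
  ramp <- array(rep(1:8, each = 8), c(8, 8, 1))   # value = column index
  mid <- cbind((3 - 0.5 + 0.5) / 8, (4 - 0.5) / 8)
  vm <- point_features(ramp, coarse, mid)
  expect_equal(vm[1, 1], 3.5, tolerance = 1e-12)
})

test_that("point head is a shared point-wise map", {
  set.seed(44)
  pars <- init_point_head(8L, hidden = 16L, n_layers = 3L)
  x <- matrix(rnorm(40), 5, 8)
  p <- point_head(x, pars)
  expect_equal(dim(p), c(5, 3))
  expect_true(all(p > 0 & p < 1))
  perm <- c(4, 2, 5, 1, 3)
  expect_equal(point_head(x[perm, ], pars), p[perm, ], tolerance = 1e-12)

  zp <- init_point_head(8L, hidden = 16L, n_layers = 3L)
  for (ly in zp$hidden) { ly$w$value[] <- 0; ly$b$value[] <- 0 }
  zp$out$w$value[] <- 0; zp$out$b$value[] <- 0
  expect_equal(point_head(x, zp), matrix(0.5, 5, 3))

  # full-scale profile keeps the published 3 x 256 shape
  full <- init_point_head(67L)
  expect_length(full$hidden, 3L)
  expect_equal(ncol(full$hidden[[1]]$w$value), 256L)
})

test_that("iterative refinement only rewrites the selected points", {
  set.seed(45)
  g <- matrix(runif(16), 4, 4)
  expect_identical(iterative_refine(g, 0, 10, function(p) stop("unused")), g)

  # constant-replacement predictor, one step: exactly n_per_step cells may
  # change and every unselected cell is bit-identical to plain upsampling
  plain1 <- cpp_upsample2x_fwd(array(g, c(dim(g), 1)))[, , 1]
  out1 <- iterative_refine(g, 1, 5, function(pts) rep(0.123456, nrow(pts)))
  expect_lte(sum(out1 != plain1), 5)
  expect_true(all(out1[out1 != plain1] == 0.123456))
  # shape arithmetic: 4x4 with 3 steps -> 32x32
  out3 <- iterative_refine(g, 3, 5, function(pts) rep(0.5, nrow(pts)))
  expect_equal(dim(out3), c(32, 32))
})

test_that("refinement with an interpolation-faithful head equals upsampling", {
  set.seed(46)
  g <- matrix(runif(16), 4, 4)
  plain <- g
  for (s in 1:2) plain <- cpp_upsample2x_fwd(array(plain,
                                                   c(dim(plain), 1)))[, , 1]
  # predictor returning the already-interpolated value at each query point:
  # emulated by sampling the upsampled-so-far grid, which iterative_refine
  # exposes through the query coordinates
  step_grids <- list()
  cur <- g
  for (s in 1:2) {
    cur <- cpp_upsample2x_fwd(array(cur, c(dim(cur), 1)))[, , 1]
    step_grids[[s]] <- cur
  }
  step <- 0
  out <- iterative_refine(g, 2, 6, function(pts) {
    step <<- step + 1
    gs <- step_grids[[step]]
    gs[cbind(round(pts[, 2] * nrow(gs) + 0.5), round(pts[, 1] * ncol(gs) + 0.5))]
  })
  expect_equal(out, plain, tolerance = 1e-12)
})

test_that("a trained point head sharpens boundaries beyond plain upsampling", {
  set.seed(60)
  S <- 64L
  mask <- ellipse_mask(S, 33, 30, 21, 13, pi / 7)
  # fine signal: noisy soft version of the shape at full resolution
  soft <- ellipse_mask(S, 33, 30, 21, 13, pi / 7) * 1
  fine <- array(soft + matrix(rnorm(S * S, 0, 0.15), S, S), c(S, S, 1))
  # coarse probability: heavily downsampled (8x8) soft mask, upsample source
  coarse <- cpp_avgpool2_fwd(cpp_avgpool2_fwd(cpp_avgpool2_fwd(
    array(mask * 1, c(S, S, 1)))))[, , 1]

  pars <- init_point_head(2L, hidden = 32L, n_layers = 3L, n_classes = 1L)
  params <- collect_params(pars)
  opt <- sgd_optimizer(params, lr = 0.5, momentum = 0.9, weight_decay = 0)
  gt_at <- function(pts) {
    as.numeric(cpp_point_sample_fwd(array(mask * 1, c(S, S, 1)), pts)) > 0.5
  }
  for (it in 1:150) {
    sel <- select_training_points(coarse, n_points = 64, rng = it)
    feats <- point_features(fine, coarse, sel$points)
    lg <- ag_point_head(ag_const(feats), pars)
    loss <- ag_bce_logits(lg, as.numeric(gt_at(sel$points)))
    ag_backward(loss)
    opt$step(); ag_zero_grad(params)
  }

  predictor <- function(pts) {
    feats <- point_features(fine, coarse, pts)
    1 / (1 + exp(-ag_point_head(ag_const(feats), pars)$value[, 1]))
  }
  refined <- iterative_refine(coarse, steps = 3L, n_per_step = 200L,
                              predictor)
  plain <- coarse
  for (s in 1:3) plain <- cpp_upsample2x_fwd(array(plain,
                                                   c(dim(plain), 1)))[, , 1]
  # boundary IoU within a 2-px band of the GT contour
  band <- mask_boundary_band(mask, 2L)
  biou <- function(pred) {
    pm <- pred > 0.5
    pm_band <- pm & band
    gt_band <- mask & band
    u <- sum(pm_band | gt_band)
    if (u == 0) 1 else sum(pm_band & gt_band) / u
  }
  expect_gte(biou(refined), biou(plain))
})
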