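# Backbone: deformable convolution limits, CBAM attention, pyramid shapes,
# gradient flow.

test_that("deformable convolution with zero offsets equals regular convolution", {
  set.seed(20)
  for (t in 1:5) {
    x <- array(rnorm(9 * 9 * 2), c(9, 9, 2))
    w <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
    b <- rnorm(4)
    offs <- array(0, c(9, 9, 18))
    expect_lt(max(abs(deformable_conv(x, w, b, offs) -
                        naive_conv2d(x, w, b))), 1e-5)
  }
})

test_that("constant input with unit-sum kernel is reproduced at interior pixels", {
  x <- array(3.7, c(10, 10, 1))
  w <- array(1 / 9, c(3, 3, 1, 1))
  offs <- array(0, c(10, 10, 18))
  y <- deformable_conv(x, w, numeric(1), offs)
  expect_equal(y[3:8, 3:8, 1], matrix(3.7, 6, 6), tolerance = 1e-12)
})

test_that("integer offsets shift the sampling grid", {
  set.seed(21)
  x <- array(rnorm(12 * 12), c(12, 12, 1))
  w <- array(rnorm(9), c(3, 3, 1, 1))
  # offset (dy, dx) = (0, +1) everywhere: samples the input shifted left
  offs <- array(0, c(12, 12, 18))
  offs[, , seq(2, 18, by = 2)] <- 1
  y <- deformable_conv(x, w, numeric(1), offs)
  xs <- array(0, c(12, 12, 1))
  xs[, 1:11, 1] <- x[, 2:12, 1]       # shifted input
  yref <- naive_conv2d(xs, w, numeric(1))
  expect_lt(max(abs(y[3:10, 3:9, 1] - yref[3:10, 3:9, 1])), 1e-10)
})

test_that("offset tensor shape mismatches error", {
  x <- array(0, c(8, 8, 1)); w <- array(0, c(3, 3, 1, 1))
  expect_error(deformable_conv(x, w, numeric(1), array(0, c(8, 8, 10))),
               "kernel position")
})

test_that("channel attention follows the shared-MLP construction", {
  set.seed(22)
  pars <- init_cbam(6L, reduction = 2L)
  f <- array(rnorm(5 * 5 * 6), c(5, 5, 6))
  mc <- channel_attention(f, pars)
  expect_length(mc, 6L)
  expect_true(all(mc > 0 & mc < 1))

  # zero MLP -> sigmoid(0) = 0.5
  z <- init_cbam(6L, reduction = 2L)
  z$mlp1$w$value[] <- 0; z$mlp1$b$value[] <- 0
  z$mlp2$w$value[] <- 0; z$mlp2$b$value[] <- 0
  expect_equal(channel_attention(f, z), rep(0.5, 6))

  # spatially constant map: avg pool == max pool -> Mc = sigmoid(2 MLP(v))
  fc <- array(rep(1:6, each = 25), c(5, 5, 6))
  v <- as.numeric(1:6)
  mlp <- function(x) {
    h <- pmax(as.numeric(x %*% pars$mlp1$w$value) + pars$mlp1$b$value, 0)
    as.numeric(h %*% pars$mlp2$w$value) + pars$mlp2$b$value
  }
  expect_equal(channel_attention(fc, pars),
               1 / (1 + exp(-2 * mlp(matrix(v, 1)))), tolerance = 1e-10)

  # invariant to spatial permutation
  perm <- sample(25)
  fp <- array(apply(f, 3, function(s) as.numeric(s)[perm]), c(5, 5, 6))
  expect_equal(channel_attention(fp, pars), mc, tolerance = 1e-12)
})

test_that("spatial attention pools channels and is flip-equivariant", {
  set.seed(23)
  pars <- init_cbam(4L, reduction = 2L, spatial_kernel = 3L)
  f <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  ms <- spatial_attention(f, pars)
  expect_equal(dim(ms), c(6, 6))
  expect_true(all(ms > 0 & ms < 1))

  z <- init_cbam(4L, reduction = 2L, spatial_kernel = 3L)
  z$sconv$w$value[] <- 0; z$sconv$b$value[] <- 0
  expect_equal(spatial_attention(f, z), matrix(0.5, 6, 6))

  # horizontal flip in -> flip out requires a horizontally symmetric kernel
  sym <- init_cbam(4L, reduction = 2L, spatial_kernel = 3L)
  sym$sconv$w$value <- (sym$sconv$w$value +
                          sym$sconv$w$value[, 3:1, , , drop = FALSE])
  fflip <- f[, 6:1, , drop = FALSE]
  expect_equal(spatial_attention(fflip, sym),
               spatial_attention(f, sym)[, 6:1], tolerance = 1e-12)
})

test_that("CBAM attenuates and approaches identity with saturated gates", {
  set.seed(24)
  pars <- init_cbam(4L, reduction = 2L)
  f <- array(rnorm(5 * 5 * 4), c(5, 5, 4))
  out <- cbam(f, pars)
  expect_true(all(abs(out[f != 0]) < abs(f[f != 0])))
  expect_equal(cbam(array(0, dim(f)), pars), array(0, dim(f)),
               tolerance = 1e-12)

  sat <- init_cbam(4L, reduction = 2L)
  sat$mlp1$w$value[] <- 0; sat$mlp1$b$value[] <- 0
  sat$mlp2$w$value[] <- 0; sat$mlp2$b$value[] <- 30   # Mc ~ 1
  sat$sconv$w$value[] <- 0; sat$sconv$b$value[] <- 30 # Ms ~ 1
  expect_equal(cbam(f, sat), f, tolerance = 1e-8)
})

test_that("pyramid shapes follow stride arithmetic and inputs are validated", {
  cfg <- model_config("desk")
  m <- build_model(cfg)
  p <- extract_pyramid(m, matrix(0, 128, 128))
  expect_equal(dim(p$P3)[1:2], c(16, 16))
  expect_equal(dim(p$P4)[1:2], c(8, 8))
  expect_equal(dim(p$P5)[1:2], c(4, 4))
  p2 <- extract_pyramid(m, matrix(0, 256, 256))
  expect_equal(dim(p2$P3)[1:2], c(32, 32))
  expect_error(extract_pyramid(m, matrix(0, 100, 100)), "divisible")
})

test_that("a loss on any pyramid level reaches the first conv and DCN offsets", {
  cfg <- model_config("desk", seed = 3L)
  m <- build_model(cfg)
  x <- ag_const(array(rnorm(128 * 128), c(128, 128, 1)))
  pyr <- backbone_forward(m$backbone, x)
  loss <- ag_mean(ag_mul(pyr$P5, pyr$P5))
  ag_backward(loss)
  g_stem <- m$backbone$stem1$w$grad
  expect_false(is.null(g_stem))
  expect_gt(max(abs(g_stem)), 0)
  offs_params <- m$params[grepl("offs", names(m$params)) &
                            grepl("\\.w$", names(m$params))]
  expect_true(length(offs_params) > 0)
  got_offs_grad <- any(vapply(offs_params, function(p)
    !is.null(p$grad) && max(abs(p$grad)) > 0, logical(1)))
  expect_true(got_offs_grad)
})

test_that("saturated CBAM gates reproduce the attention-free backbone", {
  cfg <- model_config("desk", seed = 5L)
  m <- build_model(cfg)
  img <- matrix(rnorm(128 * 128), 128, 128)
  with_cbam <- extract_pyramid(m, img)
  for (k in 1:3) {
    cb <- m$backbone$cbam[[k]]
    cb$mlp1$w$value[] <- 0; cb$mlp1$b$value[] <- 0
    cb$mlp2$w$value[] <- 0; cb$mlp2$b$value[] <- 30
    cb$sconv$w$value[] <- 0; cb$sconv$b$value[] <- 30
  }
  saturated <- extract_pyramid(m, img)
  m$backbone$use_cbam <- FALSE
  plain <- extract_pyramid(m, img)
  expect_equal(saturated$P3, plain$P3, tolerance = 1e-8)
  expect_equal(saturated$P5, plain$P5, tolerance = 1e-8)
  expect_false(isTRUE(all.equal(with_cbam$P3, plain$P3)))
})
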