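# Detection utilities: anchor generation, matching, box coding, NMS,
# ROIAlign, box/class head.

test_that("anchor generation covers every feature pixel with each size", {
  shapes <- list(P3 = c(16, 16), P4 = c(8, 8), P5 = c(4, 4))
  sizes <- default_anchor_levels()
  a <- generate_anchors(shapes, sizes)
  expect_equal(sum(a$level == "P3"), 3 * 16 * 16)
  expect_equal(nrow(a), (16^2 + 8^2 + 4^2) * 3)   # 1008 on the desk profile
  # centres at stride * (index + 0.5)
  p4 <- a[a$level == "P4", ]
  expect_true(all(p4$cx == 16 * (p4$col + 0.5)))
  expect_true(all(p4$cy == 16 * (p4$row + 0.5)))
  # deterministic ordering: level, row, col, size
  first <- a[1:6, ]
  expect_true(all(first$row == 0) && all(first$col %in% c(0, 1)))
})

test_that("anchor matching labels by IoU with GT force-matching", {
  anchors <- rbind(c(10, 10, 20, 20),    # identical to gt 1
                   c(200, 200, 10, 10),  # no overlap
                   c(48, 48, 24, 24))    # moderate overlap with gt 2
  gt <- rbind(c(10, 10, 20, 20),
              c(50, 50, 30, 30))
  mt <- match_anchors(anchors, gt, pos_iou = 0.7, neg_iou = 0.3)
  expect_equal(mt$labels[1], 1)
  expect_equal(mt$labels[2], 0)
  expect_equal(mt$labels[3], 1)          # force-matched argmax for gt 2
  expect_equal(mt$matched_gt[3], 2L)
  # without any gts everything is negative
  mt0 <- match_anchors(anchors, matrix(0, 0, 4))
  expect_true(all(mt0$labels == 0))
})

test_that("box encode/decode is exact and matches closed forms", {
  expect_equal(as.numeric(encode_box(c(10, 10, 20, 20), c(10, 10, 20, 20))),
               rep(0, 4))
  t <- encode_box(c(0, 0, 40, 20), c(5, 5, 20, 20))
  expect_equal(t[3], log(2))
  set.seed(30)
  for (i in 1:100) {
    g <- c(runif(2, 0, 100), runif(2, 5, 80))
    a <- c(runif(2, 0, 100), runif(2, 5, 80))
    back <- decode_box(encode_box(g, a), a)
    expect_lt(max(abs(back - g)), 1e-6)
  }
})

test_that("NMS matches the brute-force greedy oracle", {
  expect_equal(nms(matrix(c(0, 0, 10, 10), 1), 0.9, 0.5), 1L)
  two <- rbind(c(0, 0, 10, 10), c(0, 0, 10, 10))
  expect_equal(nms(two, c(0.5, 0.9), 0.5), 2L)
  expect_equal(nms(two, c(0.7, 0.7), 0.5), 1L)   # tie -> lower index
  set.seed(31)
  for (t in 1:5) {
    boxes <- cbind(runif(50, 0, 80), runif(50, 0, 80),
                   runif(50, 5, 40), runif(50, 5, 40))
    scores <- runif(50)
    expect_equal(nms(boxes, scores, 0.4), naive_nms(boxes, scores, 0.4))
  }
})

test_that("ROIAlign reproduces an integer-aligned crop and basic symmetries", {
  set.seed(32)
  f <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  crop <- cpp_roi_align_fwd(f, c(4, 6, 12, 14), 8L, 8L, 1L)
  expect_equal(crop, f[7:14, 5:12, , drop = FALSE], tolerance = 1e-12)

  const <- array(2.5, c(16, 16, 1))
  pooled <- roi_align(const, c(1.3, 2.7, 9.1, 11.4), 7, 2)
  expect_equal(as.numeric(pooled), rep(2.5, 49), tolerance = 1e-12)

  # integer translation of feature and ROI leaves the output unchanged
  f2 <- array(0, c(16, 16, 1))
  f2[3:10, 3:10, 1] <- matrix(rnorm(64), 8, 8)
  f3 <- array(0, c(16, 16, 1))
  f3[5:12, 6:13, 1] <- f2[3:10, 3:10, 1]
  a <- roi_align(f2, c(2, 2, 10, 10), 4, 2)
  b <- roi_align(f3, c(5, 4, 13, 12), 4, 2)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("ROI-to-level mapping is a pure area function with clamps", {
  expect_equal(roi_to_level(c(1, 100, 224^2, 1e6)), c(3, 3, 3, 5))
  expect_equal(roi_to_level((224 / 2)^2), 3)
  expect_true(all(diff(roi_to_level(seq(100, 1e6, length.out = 50))) >= 0))
})

test_that("box/class head emits normalised scores and per-class deltas", {
  set.seed(33)
  pars <- init_box_head(7 * 7 * 4, hidden = 16L, n_classes = 3L)
  pooled <- lapply(1:5, function(i) array(rnorm(7 * 7 * 4), c(7, 7, 4)))
  out <- box_class_head(pooled, pars)
  expect_equal(dim(out$scores), c(5, 4))
  expect_equal(rowSums(out$scores), rep(1, 5), tolerance = 1e-6)
  expect_equal(dim(out$deltas), c(5, 16))

  zp <- init_box_head(7 * 7 * 4, hidden = 16L, n_classes = 3L)
  zp$fc$w$value[] <- 0; zp$fc$b$value[] <- 0
  zp$cls$w$value[] <- 0; zp$cls$b$value[] <- 0
  outz <- box_class_head(pooled, zp)
  expect_equal(outz$scores, matrix(0.25, 5, 4), tolerance = 1e-12)

  # batch-order independence
  perm <- c(3, 1, 5, 2, 4)
  outp <- box_class_head(pooled[perm], pars)
  expect_equal(outp$scores, out$scores[perm, ], tolerance = 1e-12)
})

test_that("proposal pipeline conserves counts", {
  cfg <- model_config("desk", seed = 9L)
  m <- build_model(cfg)
  img <- preprocess_train_image(generate_phantom(
    phantom_config(image_size = 128, seed = 9), 1)$image, 128)
  x <- ag_const(array(img, c(128, 128, 1)))
  pyr <- backbone_forward(m$backbone, x)
  rpn_out <- rpn_forward(m, pyr)
  adf <- model_anchors(m, 128)
  pr <- make_proposals(m, rpn_out, adf, training = FALSE)
  expect_lte(nrow(pr$boxes), cfg$detector$post_nms_test)
  expect_lte(cfg$detector$post_nms_test, cfg$detector$pre_nms_test)
  expect_lte(cfg$detector$pre_nms_test, nrow(adf))
})
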