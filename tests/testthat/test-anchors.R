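# Anchor toolkit: box statistics, IoU distance, k-means, elbow, levels.

test_that("box statistics come straight from the annotations", {
  dir <- withr::local_tempdir()
  imgs <- data.frame(id = 1L, file_name = "x.tiff", width = 64L, height = 64L)
  mk <- matrix(FALSE, 64, 64); mk[11:30, 6:15] <- TRUE   # w 10, h 20
  write_coco(imgs, list(list(image_id = 1L, category = "myoma", mask = mk)),
             file.path(dir, "a.json"))
  st <- collect_box_stats(file.path(dir, "a.json"))
  expect_equal(st$widths, 10)
  expect_equal(st$heights, 20)
  expect_equal(st$aspect_ratios, 0.5)

  write_coco(imgs, list(), file.path(dir, "empty.json"))
  expect_error(collect_box_stats(file.path(dir, "empty.json")),
               "no annotations")
})

test_that("center-aligned IoU matches hand-computed values", {
  expect_equal(iou_center_aligned(c(10, 10), c(10, 10)), 1.0)
  expect_equal(iou_center_aligned(c(10, 10), c(20, 20)), 0.25)
  expect_equal(iou_center_aligned(c(10, 40), c(40, 10)), 1 / 7)
  expect_error(iou_center_aligned(c(0, 10), c(5, 5)), "positive")
})

test_that("k-means degenerate and separable cases are exact", {
  same <- matrix(rep(c(12, 18), each = 6), ncol = 2)
  r1 <- kmeans_iou(same, 1)
  expect_equal(r1$centroids, matrix(c(12, 18), 1), ignore_attr = TRUE)
  expect_equal(r1$avg_iou, 1.0)
  expect_error(kmeans_iou(same, 2), "distinct")

  two <- rbind(matrix(rep(c(10, 10), 5), ncol = 2, byrow = TRUE),
               matrix(rep(c(100, 100), 5), ncol = 2, byrow = TRUE))
  r2 <- kmeans_iou(two, 2, seed = 3)
  expect_equal(r2$centroids, rbind(c(10, 10), c(100, 100)),
               ignore_attr = TRUE)
  expect_equal(r2$avg_iou, 1.0)
})

test_that("clustering is invariant to input ordering under a fixed seed", {
  set.seed(9)
  boxes <- cbind(runif(40, 5, 120), runif(40, 5, 120))
  a <- kmeans_iou(boxes, 4, seed = 5)
  b <- kmeans_iou(boxes[sample(40), ], 4, seed = 5)
  expect_equal(a$centroids, b$centroids, tolerance = 1e-12)
  expect_equal(a$avg_iou, b$avg_iou, tolerance = 1e-12)
})

test_that("every box is assigned to its maximum-IoU centroid", {
  set.seed(10)
  boxes <- cbind(runif(60, 5, 200), runif(60, 5, 200))
  r <- kmeans_iou(boxes, 5, seed = 1)
  for (i in seq_len(nrow(boxes))) {
    ious <- apply(r$centroids, 1, function(ctr)
      iou_center_aligned(boxes[i, ], ctr))
    expect_equal(r$assignments[i], which.max(ious))
  }
  expect_true(r$avg_iou >= 0 && r$avg_iou <= 1)
  areas <- r$centroids[, 1] * r$centroids[, 2]
  expect_true(all(diff(areas) >= 0))
})

test_that("elbow curve is non-decreasing and saturates at k = n", {
  set.seed(12)
  boxes <- unique(round(cbind(runif(15, 5, 150), runif(15, 5, 150))))
  ec <- elbow_curve(boxes, seq_len(nrow(boxes)), seed = 2, restarts = 10)
  expect_true(all(diff(ec$avg_iou) >= -1e-9))
  expect_equal(ec$avg_iou[nrow(boxes)], 1.0, tolerance = 1e-12)
})

test_that("the published nine anchors group into levels by area", {
  cents <- rbind(c(17, 16), c(28, 28), c(50, 45), c(74, 75), c(103, 167),
                 c(112, 100), c(142, 137), c(189, 171), c(235, 255))
  lv <- assign_anchors_to_levels(cents)
  expect_equal(lv$P3, rbind(c(17, 16), c(28, 28), c(50, 45)),
               ignore_attr = TRUE)
  expect_equal(lv$P5, rbind(c(142, 137), c(189, 171), c(235, 255)),
               ignore_attr = TRUE)
  expect_equal(lv$P4, rbind(c(74, 75), c(112, 100), c(103, 167)),
               ignore_attr = TRUE)
  expect_error(assign_anchors_to_levels(cents[1:8, ]), "divisible")
  same9 <- matrix(rep(c(30, 30), each = 9), ncol = 2)
  lv2 <- assign_anchors_to_levels(same9)
  expect_equal(nrow(lv2$P4), 3L)
  expect_true(all(lv2$P4 == 30))
})

test_that("fitted anchors beat the fixed scale/ratio baseline on phantoms", {
  dir <- withr::local_tempdir()
  generate_dataset(tiny_phantom_config(n_images = 30L, image_size = 128L,
                                       seed = 17L), dir)
  st <- collect_box_stats(file.path(dir, "annotations", "train.json"))
  boxes <- cbind(st$widths, st$heights)
  fitted <- kmeans_iou(boxes, 9, seed = 0)
  base <- anchor_set_avg_iou(boxes, default_anchor_levels())
  expect_gte(fitted$avg_iou, base)
})
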