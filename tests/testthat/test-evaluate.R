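# COCO-style evaluator: buckets, matching, AP computation, equivalence
# with an independently coded oracle, confusion matrix.

test_that("area buckets use the 32^2 and 96^2 breakpoints", {
  expect_equal(area_bucket(300), "small")
  expect_equal(area_bucket(2000), "medium")
  expect_equal(area_bucket(10000), "large")
  expect_equal(area_bucket(c(1023, 1025, 9215, 9217)),
               c("small", "medium", "medium", "large"))
})

make_det <- function(image_id, cid, mask, score) {
  list(image_id = image_id, category_id = cid, score = score,
       bbox = tight_bbox(mask), mask = mask)
}

test_that("detection matching follows greedy single-match rules", {
  mk <- matrix(FALSE, 64, 64); mk[10:30, 10:30] <- TRUE
  gt <- list(list(image_id = 1L, category_id = 1L, bbox = tight_bbox(mk),
                  area = sum(mk), mask = mk))
  d1 <- make_det(1L, 1L, mk, 0.9)
  m <- match_detections(list(d1), gt, 0.5, "mask", 64)
  expect_true(all(m$det$tp))
  expect_length(m$fn, 0)

  # two detections on one GT: one TP, one FP
  d2 <- make_det(1L, 1L, mk, 0.8)
  m2 <- match_detections(list(d1, d2), gt, 0.5, "mask", 64)
  expect_equal(sum(m2$det$tp), 1L)
  expect_true(m2$det$tp[1])              # higher score matched first

  # IoU 0.6 instance: TP at 0.5, FP at 0.75
  mk2 <- matrix(FALSE, 64, 64); mk2[10:30, 14:34] <- TRUE
  iou <- sum(mk & mk2) / sum(mk | mk2)
  expect_gt(iou, 0.5); expect_lt(iou, 0.75)
  d3 <- make_det(1L, 1L, mk2, 0.9)
  expect_true(match_detections(list(d3), gt, 0.5, "mask", 64)$det$tp)
  expect_false(match_detections(list(d3), gt, 0.75, "mask", 64)$det$tp)
})

test_that("average precision matches hand-computed 101-point values", {
  expect_equal(average_precision(c(TRUE, TRUE), 2), 1.0)
  expect_equal(average_precision(logical(0), 2), 0.0)
  # 1 TP then 1 FP with 2 GT: precision 1 up to recall 0.5, 0 beyond
  expect_equal(average_precision(c(TRUE, FALSE), 2), 51 / 101)
  # FP first, then TP: precisions (0, 1/2); interpolated max 0.5 to r=0.5
  expect_equal(average_precision(c(FALSE, TRUE), 2), 0.5 * 51 / 101)
})

test_that("perfect predictions score 1.0 and empty predictions 0.0", {
  cfg <- tiny_phantom_config(myoma_count_range = c(1L, 2L))
  res <- list(); gts <- list()
  for (i in 1:3) {
    ph <- generate_phantom(cfg, i)
    for (inst in ph$instances) {
      cid <- match(inst$category, uterseg_categories()$name)
      gts[[length(gts) + 1L]] <- list(image_id = i, category_id = cid,
                                      bbox = inst$bbox, area = inst$area,
                                      mask = inst$mask)
      res[[length(res) + 1L]] <- make_det(i, cid, inst$mask, 0.99)
    }
  }
  ev <- evaluate_detections(res, gts, cfg$image_size)
  expect_equal(unname(ev$box["AP"]), 1.0)
  expect_equal(unname(ev$mask["AP50"]), 1.0)
  expect_equal(unname(ev$mask["AP"]), 1.0)
  ev0 <- evaluate_detections(list(), gts, cfg$image_size)
  expect_equal(unname(ev0$mask["AP"]), 0.0)
  expect_equal(unname(ev0$box["AP50"]), 0.0)
  # adding a high-confidence false positive never raises AP
  fp_mask <- matrix(FALSE, 96, 96); fp_mask[80:90, 80:90] <- TRUE
  res_fp <- c(res, list(make_det(1L, 1L, fp_mask, 1.0)))
  ev_fp <- evaluate_detections(res_fp, gts, cfg$image_size)
  expect_lte(ev_fp$mask["AP"], ev$mask["AP"])
  expect_lte(ev_fp$box["AP50"], ev$box["AP50"])
})

test_that("evaluator agrees with the independent oracle on random cases", {
  for (seed in 1:3) {
    case <- make_eval_case(seed)
    ev <- evaluate_detections(case$dets, case$gts, case$image_size)
    for (kind in c("box", "mask")) {
      iou_fun <- if (kind == "box") {
        function(d, g) box_iou_ref(d$bbox, g$bbox)
      } else {
        function(d, g) mask_iou_ref(d$mask, g$mask)
      }
      # AP50 over categories, oracle side
      o50 <- sapply(1:3, function(cid) {
        dd <- Filter(function(d) d$category_id == cid, case$dets)
        gg <- Filter(function(g) g$category_id == cid, case$gts)
        if (!length(gg)) return(NA_real_)
        det_area <- if (kind == "mask")
          sapply(dd, function(d) sum(d$mask)) else NULL
        oracle_ap(dd, gg, 0.5, iou_fun, det_area = det_area)
      })
      expect_equal(unname(ev[[kind]]["AP50"]), mean(o50, na.rm = TRUE),
                   tolerance = 1e-6)
      # full AP at all ten thresholds
      oap <- sapply(seq(0.5, 0.95, 0.05), function(thr) {
        mean(sapply(1:3, function(cid) {
          dd <- Filter(function(d) d$category_id == cid, case$dets)
          gg <- Filter(function(g) g$category_id == cid, case$gts)
          if (!length(gg)) return(NA_real_)
          det_area <- if (kind == "mask")
            sapply(dd, function(d) sum(d$mask)) else NULL
          oracle_ap(dd, gg, thr, iou_fun, det_area = det_area)
        }), na.rm = TRUE)
      })
      expect_equal(unname(ev[[kind]]["AP"]), mean(oap), tolerance = 1e-6)
    }
  }
})

test_that("area-bucketed AP agrees with the oracle's ignore semantics", {
  for (seed in 7:8) {
    case <- make_eval_case(seed)
    ev <- evaluate_detections(case$dets, case$gts, case$image_size)
    ranges <- list(APs = c(0, 32^2), APm = c(32^2, 96^2), APl = c(96^2, Inf))
    for (rn in names(ranges)) {
      o <- sapply(seq(0.5, 0.95, 0.05), function(thr) {
        mean(sapply(1:3, function(cid) {
          dd <- Filter(function(d) d$category_id == cid, case$dets)
          gg <- Filter(function(g) g$category_id == cid, case$gts)
          if (!length(gg)) return(NA_real_)
          oracle_ap(dd, gg, thr, function(d, g) mask_iou_ref(d$mask, g$mask),
                    range = ranges[[rn]],
                    det_area = sapply(dd, function(d) sum(d$mask)))
        }), na.rm = TRUE)
      })
      got <- unname(ev$mask[rn])
      want <- mean(o, na.rm = TRUE)
      if (is.nan(want)) expect_true(is.nan(got) || is.na(got))
      else expect_equal(got, want, tolerance = 1e-6)
    }
  }
})

test_that("confusion matrix is row-normalised with identity at perfection", {
  cfg <- tiny_phantom_config(myoma_count_range = c(1L, 1L))
  res <- list(); gts <- list()
  for (i in 1:2) {
    ph <- generate_phantom(cfg, i)
    for (inst in ph$instances) {
      cid <- match(inst$category, uterseg_categories()$name)
      gts[[length(gts) + 1L]] <- list(image_id = i, category_id = cid,
                                      bbox = inst$bbox, area = inst$area,
                                      mask = inst$mask)
      res[[length(res) + 1L]] <- make_det(i, cid, inst$mask, 0.9)
    }
  }
  cm <- confusion_matrix(res, gts, 0.5, cfg$image_size)
  expect_equal(unname(cm[, 1:3]), diag(3))
  expect_equal(unname(rowSums(cm)), rep(1, 3))

  # a wall GT matched by a myoma-labelled detection fills (wall, myoma)
  res2 <- lapply(res, function(d) { if (d$category_id == 1L)
    d$category_id <- 3L; d })
  cm2 <- confusion_matrix(res2, gts, 0.5, cfg$image_size)
  expect_equal(unname(cm2["uterine_wall", "myoma"]), 1)
  expect_equal(unname(cm2["uterine_wall", "uterine_wall"]), 0)
})
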