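# COCO-style evaluation: AP averaged over IoU 0.50:0.05:0.95, AP50, AP75,
# area-bucketed APs/APm/APl for boxes and masks, per-category AP, and a
# row-normalised confusion matrix.

#' Area bucket of an instance
#'
#' small: area < 32^2; medium: 32^2 < area < 96^2; large: area > 96^2,
#' where area is the mask pixel count.
#' @param area_px area in pixels
#' @return character vector in {"small", "medium", "large"}
#' @export
area_bucket <- function(area_px) {
  ifelse(area_px < 32^2, "small", ifelse(area_px < 96^2, "medium", "large"))
}

area_ranges <- list(all = c(0, Inf), small = c(0, 32^2),
                    medium = c(32^2, 96^2), large = c(96^2, Inf))

record_mask <- function(r, h, w) {
  if (!is.null(r$mask)) r$mask else segmentation_to_mask(r$segmentation, h, w)
}

record_category <- function(r) {
  if (!is.null(r$category_id)) as.integer(r$category_id)
  else match(r$category, uterseg_categories()$name)
}

mask_iou <- function(a, b) {
  inter <- sum(a & b)
  u <- sum(a | b)
  if (u == 0) 0 else inter / u
}

box_iou_pair <- function(a, b) {
  cpp_box_iou(matrix(a, 1, 4), matrix(b, 1, 4))[1, 1]
}

#' Match detections to ground truth at one IoU threshold
#'
#' Greedy matching in descending confidence; each detection takes the
#' unmatched same-category GT with the highest IoU if that IoU reaches the
#' threshold; each GT is matched at most once.
#'
#' @param detections list of records (`image_id`, `category_id`, `score`,
#'   `bbox`, `mask`/`segmentation`)
#' @param gts list of GT records (`image_id`, `category`/`category_id`,
#'   `bbox`, `mask`)
#' @param iou_threshold matching threshold
#' @param iou_kind `"box"` or `"mask"`
#' @param image_size image side (needed to decode segmentations)
#' @return list: `det` data.frame (score-sorted, with `tp` flag and
#'   `matched_gt`), `n_gt`, `fn` (indices of unmatched GTs)
#' @export
match_detections <- function(detections, gts, iou_threshold,
                             iou_kind = c("mask", "box"), image_size = NULL) {
  iou_kind <- match.arg(iou_kind)
  dcat <- vapply(detections, record_category, integer(1))
  gcat <- vapply(gts, record_category, integer(1))
  dimg <- vapply(detections, function(d) as.integer(d$image_id), integer(1))
  gimg <- vapply(gts, function(g) as.integer(g$image_id), integer(1))
  scores <- vapply(detections, function(d) as.numeric(d$score), numeric(1))
  ord <- order(-scores)
  matched_gt <- rep(NA_integer_, length(detections))
  gt_taken <- logical(length(gts))
  for (i in ord) {
    cand <- which(gimg == dimg[i] & gcat == dcat[i] & !gt_taken)
    if (!length(cand)) next
    ious <- vapply(cand, function(j) {
      if (iou_kind == "box") {
        box_iou_pair(detections[[i]]$bbox, gts[[j]]$bbox)
      } else {
        S <- image_size %||% nrow(gts[[j]]$mask)
        mask_iou(record_mask(detections[[i]], S, S),
                 record_mask(gts[[j]], S, S))
      }
    }, numeric(1))
    best <- which.max(ious)
    if (ious[best] >= iou_threshold) {
      matched_gt[i] <- cand[best]
      gt_taken[cand[best]] <- TRUE
    }
  }
  list(det = data.frame(idx = ord, score = scores[ord],
                        tp = !is.na(matched_gt[ord]),
                        matched_gt = matched_gt[ord]),
       n_gt = length(gts), fn = which(!gt_taken))
}

#' Average precision from ordered match labels (101-point interpolation)
#'
#' @param labels logical TP flags of detections in descending-score order
#' @param n_gt number of ground-truth instances
#' @return AP at this threshold
#' @export
average_precision <- function(labels, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (!length(labels)) return(0)
  tp <- cumsum(labels)
  fp <- cumsum(!labels)
  recall <- tp / n_gt
  precision <- tp / (tp + fp)
  rec_grid <- seq(0, 1, by = 0.01)
  ap <- vapply(rec_grid, function(r) {
    ok <- recall >= r - 1e-12
    if (!any(ok)) 0 else max(precision[ok])
  }, numeric(1))
  mean(ap)
}

# internal: per-category, per-threshold, per-area-range AP with COCO ignore
# semantics (GTs outside the range are ignored; detections matched to
# ignored GTs or unmatched with out-of-range area are excluded)
ap_single <- function(dets, gts, thr, range, iou_mat, det_area) {
  g_ignore <- vapply(gts, function(g) {
    a <- g$area
    a <= range[1] || a >= range[2]
  }, logical(1))
  n_gt <- sum(!g_ignore)
  scores <- vapply(dets, function(d) as.numeric(d$score), numeric(1))
  ord <- order(-scores)
  gt_taken <- logical(length(gts))
  lab <- integer(length(dets))           # 1 TP, 0 FP, -1 ignored
  for (i in ord) {
    cand <- which(!gt_taken & iou_mat[i, ] >= thr)
    if (length(cand)) {
      unig <- cand[!g_ignore[cand]]
      j <- if (length(unig)) unig[which.max(iou_mat[i, unig])] else
        cand[which.max(iou_mat[i, cand])]
      gt_taken[j] <- TRUE
      lab[i] <- if (g_ignore[j]) -1L else 1L
    } else {
      lab[i] <- if (det_area[i] <= range[1] || det_area[i] >= range[2]) -1L
                else 0L
    }
  }
  keep <- lab[ord] >= 0L
  list(labels = lab[ord][keep] == 1L, n_gt = n_gt)
}

#' COCO-style evaluation of detection results against ground truth
#'
#' @param results list of detection records or a results JSON path
#' @param gts list of GT records, a [read_coco()] object, or a JSON path
#' @param image_size image side length (square images)
#' @return an `eval_report`: `$box` and `$mask` named vectors (AP, AP50,
#'   AP75, APs, APm, APl), `$per_category` data.frame, `$confusion` matrix
#' @export
evaluate_detections <- function(results, gts, image_size) {
  if (is.character(results)) results <- read_results_json(results)
  if (is.character(gts)) gts <- read_coco(gts)
  if (!is.null(gts$annotations)) {
    sz <- if (!is.null(gts$images)) gts$images$height[1] else image_size
    gts <- lapply(gts$annotations, function(a) {
      list(image_id = a$image_id, category_id = a$category_id,
           bbox = a$bbox, area = a$area,
           mask = segmentation_to_mask(a$segmentation, sz, sz))
    })
  }
  thrs <- seq(0.5, 0.95, by = 0.05)
  cats <- uterseg_categories()
  per_image_cap <- 100L

  # cap detections per image (descending score)
  if (length(results)) {
    dimg <- vapply(results, function(d) as.integer(d$image_id), integer(1))
    dsc <- vapply(results, function(d) as.numeric(d$score), numeric(1))
    keep <- unlist(lapply(unique(dimg), function(im) {
      ii <- which(dimg == im)
      ii[head(order(-dsc[ii]), per_image_cap)]
    }))
    results <- results[sort(keep)]
  }

  ap_tab <- array(NA_real_, dim = c(nrow(cats), length(thrs),
                                    length(area_ranges), 2),
                  dimnames = list(cats$name, NULL, names(area_ranges),
                                  c("box", "mask")))
  for (ci in seq_len(nrow(cats))) {
    cid <- cats$id[ci]
    dets <- Filter(function(d) record_category(d) == cid, results)
    g <- Filter(function(x) record_category(x) == cid, gts)
    if (!length(g)) next
    # IoU matrices (all images at once; cross-image pairs zeroed)
    dimg <- vapply(dets, function(d) as.integer(d$image_id), integer(1))
    gimg <- vapply(g, function(x) as.integer(x$image_id), integer(1))
    nd <- length(dets); ng <- length(g)
    iou_box <- matrix(0, nd, ng); iou_mask <- matrix(0, nd, ng)
    det_masks <- lapply(dets, function(d) record_mask(d, image_size, image_size))
    if (nd) {
      db <- do.call(rbind, lapply(dets, function(d) as.numeric(d$bbox)))
      gb <- do.call(rbind, lapply(g, function(x) as.numeric(x$bbox)))
      ib <- cpp_box_iou(db, gb)
      for (i in seq_len(nd)) for (j in seq_len(ng)) {
        if (dimg[i] != gimg[j]) next
        iou_box[i, j] <- ib[i, j]
        iou_mask[i, j] <- mask_iou(det_masks[[i]], g[[j]]$mask)
      }
    }
    area_box <- if (nd) vapply(dets, function(d) d$bbox[3] * d$bbox[4],
                               numeric(1)) else numeric(0)
    area_mask <- if (nd) vapply(det_masks, sum, numeric(1)) else numeric(0)
    for (ti in seq_along(thrs)) for (ri in seq_along(area_ranges)) {
      rb <- ap_single(dets, g, thrs[ti], area_ranges[[ri]], iou_box, area_box)
      rm <- ap_single(dets, g, thrs[ti], area_ranges[[ri]], iou_mask, area_mask)
      ap_tab[ci, ti, ri, "box"] <- average_precision(rb$labels, rb$n_gt)
      ap_tab[ci, ti, ri, "mask"] <- average_precision(rm$labels, rm$n_gt)
    }
  }
  summarise <- function(kind) {
    v <- function(ti, ri) mean(ap_tab[, ti, ri, kind], na.rm = TRUE)
    c(AP = mean(vapply(seq_along(thrs), function(t) v(t, 1), numeric(1)),
                na.rm = TRUE),
      AP50 = v(1, 1), AP75 = v(6, 1),
      APs = mean(vapply(seq_along(thrs), function(t) v(t, 2), numeric(1)),
                 na.rm = TRUE),
      APm = mean(vapply(seq_along(thrs), function(t) v(t, 3), numeric(1)),
                 na.rm = TRUE),
      APl = mean(vapply(seq_along(thrs), function(t) v(t, 4), numeric(1)),
                 na.rm = TRUE))
  }
  per_cat <- data.frame(
    category = cats$name,
    boxAP = vapply(seq_len(nrow(cats)),
                   function(ci) mean(ap_tab[ci, , 1, "box"]), numeric(1)),
    maskAP = vapply(seq_len(nrow(cats)),
                    function(ci) mean(ap_tab[ci, , 1, "mask"]), numeric(1)))
  rep <- list(box = summarise("box"), mask = summarise("mask"),
              per_category = per_cat,
              confusion = confusion_matrix(results, gts, 0.5, image_size))
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat("box :", paste(sprintf("%s=%.3f", names(x$box), x$box), collapse = " "),
      "\n")
  cat("mask:", paste(sprintf("%s=%.3f", names(x$mask), x$mask),
                     collapse = " "), "\n")
  invisible(x)
}

#' Confusion matrix of predicted vs true categories
#'
#' Detections are matched to GTs spatially (mask IoU >= threshold,
#' descending confidence, category-agnostic) and labels compared; GTs with
#' no matching detection count toward a `background` column.  Rows are
#' normalised to sum to one.
#'
#' @param detections list of detection records
#' @param gts list of GT records (with masks)
#' @param iou_threshold spatial matching threshold (masks), default 0.5
#' @param image_size image side length
#' @return C x (C + 1) row-normalised matrix
#' @export
confusion_matrix <- function(detections, gts, iou_threshold = 0.5,
                             image_size = NULL) {
  cats <- uterseg_categories()
  C <- nrow(cats)
  cm <- matrix(0, C, C + 1,
               dimnames = list(true = cats$name,
                               pred = c(cats$name, "background")))
  if (!length(gts)) return(cm)
  S <- image_size %||% nrow(gts[[1]]$mask)
  scores <- vapply(detections, function(d) as.numeric(d$score), numeric(1))
  dimg <- vapply(detections, function(d) as.integer(d$image_id), integer(1))
  gimg <- vapply(gts, function(g) as.integer(g$image_id), integer(1))
  gt_pred <- rep(NA_integer_, length(gts))   # predicted category per GT
  gt_taken <- logical(length(gts))
  det_used <- logical(length(detections))
  for (i in order(-scores)) {
    cand <- which(gimg == dimg[i] & !gt_taken)
    if (!length(cand)) next
    dm <- record_mask(detections[[i]], S, S)
    ious <- vapply(cand, function(j) mask_iou(dm, record_mask(gts[[j]], S, S)),
                   numeric(1))
    best <- which.max(ious)
    if (ious[best] >= iou_threshold) {
      gt_taken[cand[best]] <- TRUE
      det_used[i] <- TRUE
      gt_pred[cand[best]] <- record_category(detections[[i]])
    }
  }
  for (j in seq_along(gts)) {
    tr <- record_category(gts[[j]])
    pc <- if (is.na(gt_pred[j])) C + 1L else gt_pred[j]
    cm[tr, pc] <- cm[tr, pc] + 1
  }
  rs <- rowSums(cm)
  cm[rs > 0, ] <- cm[rs > 0, ] / rs[rs > 0]
  cm
}

#' Evaluate a results JSON against a ground-truth COCO JSON
#'
#' @param results_json path to COCO results (or list of records)
#' @param gt_json path to COCO ground truth (or [read_coco()] object)
#' @return an `eval_report`
#' @export
evaluate <- function(results_json, gt_json) {
  gt <- if (is.character(gt_json)) read_coco(gt_json) else gt_json
  sz <- gt$images$height[1]
  evaluate_detections(results_json, gt, sz)
}
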