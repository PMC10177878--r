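# Data-adaptive anchor design: box statistics, k-means clustering of box
# shapes under the 1 - IoU distance, elbow analysis, and assignment of the
# sorted centroids to the three pyramid levels.

#' Collect bounding-box statistics from a COCO file
#'
#' @param coco_path path to a COCO annotation JSON
#' @return list with numeric vectors `widths`, `heights`, `aspect_ratios`
#'   (width / height); zero-sized boxes are excluded with a warning
#' @export
collect_box_stats <- function(coco_path) {
  coco <- read_coco(coco_path)
  if (!length(coco$annotations)) stop("COCO file has no annotations")
  bb <- t(vapply(coco$annotations, function(a) a$bbox, numeric(4)))
  bad <- bb[, 3] <= 0 | bb[, 4] <= 0
  if (any(bad)) {
    warning(sum(bad), " zero-sized boxes excluded")
    bb <- bb[!bad, , drop = FALSE]
  }
  if (!nrow(bb)) stop("no valid boxes after exclusion")
  list(widths = bb[, 3], heights = bb[, 4],
       aspect_ratios = bb[, 3] / bb[, 4])
}

#' Center-aligned IoU between two box shapes
#'
#' Boxes are compared as (width, height) pairs with coincident centers:
#' intersection = min(w) * min(h).
#'
#' @param a,b length-2 numeric vectors (w, h), strictly positive
#' @return IoU in [0, 1]
#' @export
iou_center_aligned <- function(a, b) {
  if (any(c(a, b) <= 0)) stop("box dimensions must be positive")
  inter <- min(a[1], b[1]) * min(a[2], b[2])
  inter / (a[1] * a[2] + b[1] * b[2] - inter)
}

# n x k matrix of center-aligned IoUs between boxes (n x 2) and centroids
# (k x 2); vectorized
shape_iou_matrix <- function(boxes, centroids) {
  n <- nrow(boxes); k <- nrow(centroids)
  iw <- pmin(matrix(boxes[, 1], n, k), matrix(centroids[, 1], n, k, byrow = TRUE))
  ih <- pmin(matrix(boxes[, 2], n, k), matrix(centroids[, 2], n, k, byrow = TRUE))
  inter <- iw * ih
  areas <- matrix(boxes[, 1] * boxes[, 2], n, k) +
    matrix(centroids[, 1] * centroids[, 2], n, k, byrow = TRUE) - inter
  inter / areas
}

#' k-means clustering of box shapes under the 1 - IoU distance
#'
#' Lloyd-style alternation: boxes are assigned to their maximum-IoU centroid
#' (ties to the lowest cluster index) and centroids are updated to the
#' element-wise median of their members.  Initialisation is k-means++-style
#' seeding under D = 1 - IoU; the best of `restarts` runs by average IoU is
#' kept.  Centroids are returned sorted by area ascending.
#'
#' @param boxes n x 2 matrix (or data.frame) of (width, height)
#' @param k number of clusters, at most the number of distinct boxes
#' @param seed RNG seed
#' @param max_iter iteration cap per restart
#' @param restarts number of random restarts
#' @return list of class `cluster_result`: `centroids` (k x 2, area
#'   ascending), `assignments`, `avg_iou`
#' @export
kmeans_iou <- function(boxes, k, seed = 0L, max_iter = 100L, restarts = 10L) {
  boxes <- as.matrix(boxes)
  storage.mode(boxes) <- "double"
  if (any(boxes <= 0)) stop("box dimensions must be positive")
  n_distinct <- nrow(unique(boxes))
  if (k > n_distinct) stop("k exceeds the number of distinct boxes")
  old <- .Random.seed_guard(as.numeric(seed) %% 2147483647)
  on.exit(old(), add = TRUE)

  # canonical internal ordering makes the result independent of the
  # caller's row order under a fixed seed
  canon <- boxes[order(boxes[, 1], boxes[, 2]), , drop = FALSE]
  best <- NULL
  for (r in seq_len(restarts)) {
    res <- kmeans_iou_once(canon, k, max_iter)
    if (is.null(best) || res$avg_iou > best$avg_iou) best <- res
  }
  ord <- order(best$centroids[, 1] * best$centroids[, 2])
  centroids <- best$centroids[ord, , drop = FALSE]
  iou <- shape_iou_matrix(boxes, centroids)
  assignments <- max.col(iou, ties.method = "first")
  structure(list(centroids = centroids, assignments = assignments,
                 avg_iou = mean(iou[cbind(seq_len(nrow(boxes)), assignments)])),
            class = "cluster_result")
}

kmeans_iou_once <- function(boxes, k, max_iter) {
  n <- nrow(boxes)
  # k-means++ seeding under D = 1 - IoU
  cent <- boxes[sample(n, 1), , drop = FALSE]
  while (nrow(cent) < k) {
    d <- 1 - apply(shape_iou_matrix(boxes, cent), 1, max)
    p <- d^2
    if (sum(p) == 0) p <- rep(1, n)
    cent <- rbind(cent, boxes[sample(n, 1, prob = p), ])
  }
  assign_prev <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    iou <- shape_iou_matrix(boxes, cent)
    assignments <- max.col(iou, ties.method = "first")
    if (all(assignments == assign_prev)) break
    assign_prev <- assignments
    for (j in seq_len(k)) {
      members <- boxes[assignments == j, , drop = FALSE]
      if (nrow(members)) cent[j, ] <- apply(members, 2, stats::median)
    }
  }
  iou <- shape_iou_matrix(boxes, cent)
  assignments <- max.col(iou, ties.method = "first")
  list(centroids = cent, assignments = assignments,
       avg_iou = mean(iou[cbind(seq_len(n), assignments)]))
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("IoU k-means:", nrow(x$centroids), "centroids, average IoU",
      sprintf("%.4f", x$avg_iou), "\n")
  print(round(x$centroids, 1))
  invisible(x)
}

#' Average IoU as a function of the number of clusters
#'
#' @param boxes n x 2 matrix of (width, height)
#' @param k_range integer vector of cluster counts to evaluate
#' @param seed RNG seed
#' @param restarts restarts per k (best kept), default 10
#' @return data.frame with columns `k`, `avg_iou`
#' @export
elbow_curve <- function(boxes, k_range, seed = 0L, restarts = 10L) {
  data.frame(k = k_range,
             avg_iou = vapply(k_range, function(k) {
               kmeans_iou(boxes, k, seed = seed, restarts = restarts)$avg_iou
             }, numeric(1)))
}

#' Assign sorted anchor centroids to pyramid levels
#'
#' Groups the centroids by ascending area into equal thirds: the smallest
#' go to P3 (small receptive field, small objects), the middle to P4, the
#' largest to P5.
#'
#' @param centroids k x 2 matrix of (width, height); k divisible by 3
#' @return named list `P3`, `P4`, `P5` of 3-row matrices
#' @export
assign_anchors_to_levels <- function(centroids) {
  centroids <- as.matrix(centroids)
  k <- nrow(centroids)
  if (k %% 3 != 0) stop("centroid count must be divisible by the 3 levels")
  ord <- order(centroids[, 1] * centroids[, 2])
  sorted <- centroids[ord, , drop = FALSE]
  g <- k / 3
  list(P3 = sorted[seq_len(g), , drop = FALSE],
       P4 = sorted[g + seq_len(g), , drop = FALSE],
       P5 = sorted[2 * g + seq_len(g), , drop = FALSE])
}

#' Default Mask-RCNN-style anchor set
#'
#' Scales 32/64/128 with aspect ratios 0.5/1/2, grouped per level; used as
#' the comparison baseline for the fitted anchors.
#' @return named list `P3`, `P4`, `P5` of 3-row (w, h) matrices
#' @export
default_anchor_levels <- function() {
  mk <- function(s) {
    t(vapply(c(0.5, 1, 2), function(r) c(s * sqrt(r), s / sqrt(r)), numeric(2)))
  }
  list(P3 = mk(32), P4 = mk(64), P5 = mk(128))
}

#' Average best IoU of a box set against a fixed anchor set
#' @param boxes n x 2 (w, h) matrix
#' @param anchor_levels named list of (w, h) matrices as from
#'   [assign_anchors_to_levels()]
#' @return mean over boxes of the best center-aligned IoU
#' @export
anchor_set_avg_iou <- function(boxes, anchor_levels) {
  anchors <- do.call(rbind, anchor_levels)
  mean(apply(shape_iou_matrix(as.matrix(boxes), anchors), 1, max))
}
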