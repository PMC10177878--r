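# RPN utilities and ROI heads: anchor generation over the pyramid, anchor/GT
# matching, box encoding, NMS, ROIAlign and the box/class head.
#
# Box convention: 0-based, (x, y) top-left, half-open [x, x + w), matching
# COCO.  Anchors are explicit (w, h) pairs fitted by kmeans_iou().

pyramid_strides <- c(P3 = 8L, P4 = 16L, P5 = 32L)

#' Generate anchors over the feature pyramid
#'
#' One anchor per feature-map pixel per size, centred at
#' (stride * (col + 0.5), stride * (row + 0.5)), in deterministic order
#' (level, row, col, size index).
#'
#' @param pyramid_shapes named list P3/P4/P5 of c(h, w) feature-map shapes
#' @param anchors_per_level named list P3/P4/P5 of 3 x 2 (w, h) matrices
#' @return data.frame with columns level, row, col, size_idx, cx, cy, w, h,
#'   x, y (top-left)
#' @export
generate_anchors <- function(pyramid_shapes, anchors_per_level) {
  out <- vector("list", length(pyramid_shapes))
  for (k in seq_along(pyramid_shapes)) {
    lvl <- names(pyramid_shapes)[k]
    hw <- pyramid_shapes[[k]]
    sizes <- anchors_per_level[[lvl]]
    stride <- pyramid_strides[[lvl]]
    grid <- expand.grid(size_idx = seq_len(nrow(sizes)),
                        col = seq_len(hw[2]) - 1L,
                        row = seq_len(hw[1]) - 1L)
    # reorder to (row, col, size)
    grid <- grid[order(grid$row, grid$col, grid$size_idx), ]
    out[[k]] <- data.frame(level = lvl, row = grid$row, col = grid$col,
                           size_idx = grid$size_idx,
                           cx = stride * (grid$col + 0.5),
                           cy = stride * (grid$row + 0.5),
                           w = sizes[grid$size_idx, 1],
                           h = sizes[grid$size_idx, 2])
  }
  a <- do.call(rbind, out)
  a$x <- a$cx - a$w / 2
  a$y <- a$cy - a$h / 2
  rownames(a) <- NULL
  a
}

anchor_boxes <- function(anchors) {
  cbind(anchors$x, anchors$y, anchors$w, anchors$h)
}

#' Label anchors against ground-truth boxes for RPN training
#'
#' IoU >= `pos_iou` is positive, IoU < `neg_iou` negative, in between
#' ignored.  Every GT box is force-matched to its argmax-IoU anchor even if
#' that anchor's IoU is below `pos_iou`.
#'
#' @param anchors anchor data.frame from [generate_anchors()] or an n x 4
#'   (x, y, w, h) matrix
#' @param gt_boxes m x 4 matrix of (x, y, w, h)
#' @param pos_iou,neg_iou matching thresholds
#' @return list: `labels` (1 positive, 0 negative, NA ignore) and
#'   `matched_gt` (index of the matched GT for positives)
#' @export
match_anchors <- function(anchors, gt_boxes, pos_iou = 0.7, neg_iou = 0.3) {
  ab <- if (is.data.frame(anchors)) anchor_boxes(anchors) else as.matrix(anchors)
  gt <- matrix(as.numeric(gt_boxes), ncol = 4)
  n <- nrow(ab)
  if (nrow(gt) == 0) {
    return(list(labels = rep(0, n), matched_gt = rep(NA_integer_, n)))
  }
  iou <- cpp_box_iou(ab, gt)
  best <- apply(iou, 1, max)
  matched <- max.col(iou, ties.method = "first")
  labels <- rep(NA_real_, n)
  labels[best < neg_iou] <- 0
  labels[best >= pos_iou] <- 1
  # force-match each GT's best anchor
  for (j in seq_len(nrow(gt))) {
    i <- which.max(iou[, j])
    labels[i] <- 1
    matched[i] <- j
  }
  matched[labels != 1 | is.na(labels)] <- NA_integer_
  list(labels = labels, matched_gt = matched)
}

#' Encode a box against an anchor (Faster-RCNN parameterisation)
#'
#' t = ((gx - ax)/aw, (gy - ay)/ah, log(gw/aw), log(gh/ah)) on box centres.
#'
#' @param gt n x 4 or length-4 (x, y, w, h)
#' @param anchor matching anchor boxes, same shape
#' @return n x 4 matrix (or length-4 vector) of regression targets
#' @export
encode_box <- function(gt, anchor) {
  g <- matrix(as.numeric(gt), ncol = 4); a <- matrix(as.numeric(anchor), ncol = 4)
  t <- cbind((g[, 1] + g[, 3] / 2 - a[, 1] - a[, 3] / 2) / a[, 3],
             (g[, 2] + g[, 4] / 2 - a[, 2] - a[, 4] / 2) / a[, 4],
             log(g[, 3] / a[, 3]),
             log(g[, 4] / a[, 4]))
  t
}

#' Decode regression outputs against anchors
#' @param t n x 4 (or length-4) regression values
#' @param anchor matching anchors (x, y, w, h)
#' @return n x 4 matrix of decoded (x, y, w, h) boxes
#' @export
decode_box <- function(t, anchor) {
  t <- matrix(as.numeric(t), ncol = 4); a <- matrix(as.numeric(anchor), ncol = 4)
  cx <- a[, 1] + a[, 3] / 2 + t[, 1] * a[, 3]
  cy <- a[, 2] + a[, 4] / 2 + t[, 2] * a[, 4]
  w <- a[, 3] * exp(pmin(t[, 3], 10))
  h <- a[, 4] * exp(pmin(t[, 4], 10))
  cbind(cx - w / 2, cy - h / 2, w, h)
}

#' Greedy non-maximum suppression
#'
#' Boxes are visited in descending score order (ties by lower index); a box
#' is kept iff its IoU with every already-kept box is <= `iou_threshold`.
#'
#' @param boxes n x 4 (x, y, w, h) matrix
#' @param scores length-n scores
#' @param iou_threshold suppression threshold
#' @return integer vector of kept indices (original indexing)
#' @export
nms <- function(boxes, scores, iou_threshold = 0.7) {
  boxes <- matrix(as.numeric(boxes), ncol = 4)
  n <- nrow(boxes)
  if (n == 0) return(integer(0))
  ord <- order(-scores)            # stable: ties keep original order
  iou <- cpp_box_iou(boxes, boxes)
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(iou[i, kept] <= iou_threshold))
      kept <- c(kept, i)
  }
  kept
}

#' ROIAlign pooling (functional form)
#'
#' Quantisation-free pooling: each output bin averages `sampling_ratio`^2
#' bilinear reads at regularly spaced sub-bin points.  Continuous
#' coordinates with pixel centres at integer + 0.5.
#'
#' @param feature H x W x C array (or H x W matrix, treated as one channel)
#' @param roi (x0, y0, x1, y1) in feature-map coordinates
#' @param output_size c(h, w) or single integer
#' @param sampling_ratio samples per bin per axis; <= 0 picks
#'   ceiling(bin size)
#' @return output_size x C array
#' @export
roi_align <- function(feature, roi, output_size, sampling_ratio = 2L) {
  if (is.matrix(feature)) feature <- array(feature, dim = c(dim(feature), 1))
  os <- if (length(output_size) == 1) c(output_size, output_size) else output_size
  cpp_roi_align_fwd(feature, as.numeric(roi), as.integer(os[1]),
                    as.integer(os[2]), as.integer(sampling_ratio))
}

#' Map an ROI to its pyramid level by area
#'
#' level = floor(3 + log2(sqrt(area) / 224)) clamped to [3, 5] (FPN rule
#' adapted to a P3-P5 pyramid).
#' @param area box area in input pixels
#' @return integer level in 3..5
#' @export
roi_to_level <- function(area) {
  lvl <- floor(3 + log2(sqrt(pmax(area, 1)) / 224))
  pmin(pmax(lvl, 3), 5)
}

#' Initialise box/class head parameters
#' @param in_dim flattened pooled feature length (pool^2 * channels)
#' @param hidden hidden layer width
#' @param n_classes number of foreground classes
#' @return parameter list
#' @export
init_box_head <- function(in_dim, hidden = 128L, n_classes = 3L) {
  list(fc = init_linear(in_dim, hidden),
       cls = init_linear(hidden, n_classes + 1L, scale = 0.1),
       reg = init_linear(hidden, 4L * (n_classes + 1L), scale = 0.1),
       n_classes = n_classes)
}

ag_box_head <- function(pooled_mat, pars) {
  h <- ag_relu(ag_linear(pooled_mat, pars$fc$w, pars$fc$b))
  list(cls_logits = ag_linear(h, pars$cls$w, pars$cls$b),
       reg = ag_linear(h, pars$reg$w, pars$reg$b))
}

#' Box/class head predictions for pooled ROI features
#'
#' @param pooled one pooled ROI (h x w x C array) or a list of them
#' @param params parameters from [init_box_head()]
#' @return list: `scores` (n x (n_classes + 1) softmax rows, background
#'   first), `deltas` (n x 4*(n_classes + 1) per-class box regressions)
#' @export
box_class_head <- function(pooled, params) {
  if (!is.list(pooled)) pooled <- list(pooled)
  x <- do.call(rbind, lapply(pooled, as.numeric))
  out <- ag_box_head(ag_const(x), params)
  z <- out$cls_logits$value
  ez <- exp(z - apply(z, 1, max))
  list(scores = ez / rowSums(ez), deltas = out$reg$value)
}
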