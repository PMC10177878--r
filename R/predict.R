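# Inference: proposals -> box/class head -> per-class NMS -> mask branch
# with iterative point refinement -> full-resolution pasted masks.

#' Run the detector on one image
#'
#' @param model a trained [build_model()] model
#' @param image raw intensity matrix in [0, 1] (any square size; it is
#'   preprocessed and resized to the model input size)
#' @param preprocess apply CLAHE + Z-score (set FALSE if `image` is already
#'   a preprocessed, correctly sized matrix)
#' @return list of detections: `category_id` (COCO id), `score`, `bbox`
#'   (x, y, w, h at model input resolution), `mask` (logical matrix)
#' @export
predict_model <- function(model, image, preprocess = TRUE) {
  cfg <- model$cfg
  dc <- cfg$detector
  S <- cfg$input_size
  img <- if (preprocess) preprocess_train_image(image, S) else image
  x <- ag_const(array(img, dim = c(S, S, 1)))
  pyr <- backbone_forward(model$backbone, x)
  rpn_out <- rpn_forward(model, pyr)
  anchors_df <- model_anchors(model, S)
  props <- make_proposals(model, rpn_out, anchors_df, training = FALSE)
  if (!nrow(props$boxes)) return(list())

  pooled <- pool_rois(model, pyr, props$boxes, dc$box_pool, dc$sampling_ratio)
  bh <- ag_box_head(pooled$mat, model$box_head)
  z <- bh$cls_logits$value
  ez <- exp(z - apply(z, 1, max))
  scores <- ez / rowSums(ez)
  deltas <- bh$reg$value

  dets <- list()
  for (cls in 2:4) {                      # foreground head classes
    sc <- scores[, cls]
    keep <- which(sc >= dc$score_thresh)
    if (!length(keep)) next
    dd <- deltas[keep, 4L * (cls - 1L) + 1:4, drop = FALSE]
    bb <- clip_boxes(decode_box(dd, props$boxes[keep, , drop = FALSE]), S)
    kn <- nms(bb, sc[keep], dc$det_nms)
    for (i in kn) {
      dets[[length(dets) + 1L]] <- list(category_id = cls - 1L,
                                        score = sc[keep[i]],
                                        bbox = as.numeric(bb[i, ]))
    }
  }
  if (!length(dets)) return(list())
  ord <- order(-vapply(dets, `[[`, numeric(1), "score"))
  dets <- dets[head(ord, dc$max_dets)]

  for (i in seq_along(dets))
    dets[[i]]$mask <- predict_mask(model, pyr, dets[[i]]$bbox,
                                   dets[[i]]$category_id + 1L)
  dets
}

# mask for one detection: coarse grid + iterative point refinement + paste
predict_mask <- function(model, pyr, box, cls) {
  cfg <- model$cfg
  mh <- cfg$maskhead
  S <- cfg$input_size
  lvl <- paste0("P", roi_to_level(box[3] * box[4]))
  stride <- pyramid_strides[[lvl]]
  b <- box / stride
  mp <- ag_roi_align(pyr[[lvl]], c(b[1], b[2], b[1] + b[3], b[2] + b[4]),
                     mh$mask_pool, mh$mask_pool, cfg$detector$sampling_ratio)
  logits <- ag_coarse_mask(mp, model$mask_head)$value
  probs <- 1 / (1 + exp(-logits))
  grid <- probs[, , cls - 1L]

  if (isTRUE(cfg$pointrend)) {
    predictor <- function(pts_roi) {
      fine_pts <- roi_points_on_level(box, pts_roi, lvl, S)
      fine <- cpp_point_sample_fwd(pyr[[lvl]]$value, fine_pts)
      coarse_at <- cpp_point_sample_fwd(probs, pts_roi)
      pv <- cbind(fine, coarse_at)
      pl <- ag_point_head(ag_const(pv), model$point_head)$value
      1 / (1 + exp(-pl[, cls - 1L]))
    }
    grid <- iterative_refine(grid, mh$refine_steps, mh$n_per_step, predictor)
  } else {
    for (s in seq_len(mh$refine_steps))
      grid <- cpp_upsample2x_fwd(array(grid, dim = c(dim(grid), 1)))[, , 1]
  }
  paste_mask(grid, box, S, mh$mask_threshold)
}

# paste an ROI probability grid into the full image frame
paste_mask <- function(grid, box, S, threshold = 0.5) {
  out <- matrix(FALSE, S, S)
  x0 <- max(floor(box[1]) + 1L, 1L); x1 <- min(ceiling(box[1] + box[3]), S)
  y0 <- max(floor(box[2]) + 1L, 1L); y1 <- min(ceiling(box[2] + box[4]), S)
  if (x1 < x0 || y1 < y0) return(out)
  cols <- x0:x1; rows <- y0:y1
  u <- (rep(cols, each = length(rows)) - 0.5 - box[1]) / box[3]
  v <- (rep(rows, length(cols)) - 0.5 - box[2]) / box[4]
  ok <- u >= 0 & u <= 1 & v >= 0 & v <= 1
  vals <- numeric(length(u))
  g <- array(grid, dim = c(dim(grid), 1))
  vals[ok] <- as.numeric(cpp_point_sample_fwd(g, cbind(u[ok], v[ok])))
  out[cbind(rep(rows, length(cols)), rep(cols, each = length(rows)))] <-
    vals > threshold
  out
}

#' Convert detections to COCO results records
#'
#' @param detections list from [predict_model()]
#' @param image_id COCO image id
#' @return list of records with RLE segmentations, suitable for
#'   [write_results_json()]
#' @export
detections_to_results <- function(detections, image_id) {
  lapply(detections, function(d) {
    list(image_id = image_id, category_id = d$category_id,
         bbox = as.numeric(d$bbox), score = d$score,
         segmentation = mask_to_rle(d$mask))
  })
}

#' Write COCO-style results JSON
#' @param results list of result records
#' @param path output path
#' @return invisible path
#' @export
write_results_json <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read COCO-style results JSON
#' @param path results path
#' @return list of result records
#' @export
read_results_json <- function(path) {
  res <- jsonlite::read_json(path)
  lapply(res, function(r) {
    r$bbox <- as.numeric(unlist(r$bbox))
    r$score <- as.numeric(r$score)
    r
  })
}
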