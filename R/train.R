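# Training: composite-loss forward pass for one image, and the SGD loop
# with inverse-frequency class weighting, augmentation, per-epoch logging
# and best-validation checkpointing.

head_class <- function(category) {
  # 1 = background; categories enter in COCO id order
  match(category, uterseg_categories()$name) + 1L
}

instances_to_gt <- function(instances) {
  if (!length(instances))
    return(list(boxes = matrix(0, 0, 4), cls = integer(0), masks = list()))
  boxes <- t(vapply(instances, function(i) as.numeric(i$bbox), numeric(4)))
  list(boxes = boxes,
       cls = vapply(instances, function(i) head_class(i$category), integer(1)),
       masks = lapply(instances, `[[`, "mask"))
}

# ground-truth occupancy of a mask on a grid inside an ROI box
mask_grid_targets <- function(mask, box, grid) {
  S <- nrow(mask)
  i <- rep(seq_len(grid), each = grid)   # row
  j <- rep(seq_len(grid), grid)          # col
  px <- box[1] + (j - 0.5) / grid * box[3]
  py <- box[2] + (i - 0.5) / grid * box[4]
  pts <- cbind(px / S, py / S)
  v <- as.numeric(cpp_point_sample_fwd(array(mask * 1, dim = c(S, S, 1)), pts))
  matrix(as.numeric(v > 0.5), grid, grid, byrow = TRUE)
}

# sample a mask at normalised-in-ROI points
mask_point_targets <- function(mask, box, pts_roi) {
  S <- nrow(mask)
  px <- box[1] + pts_roi[, 1] * box[3]
  py <- box[2] + pts_roi[, 2] * box[4]
  v <- as.numeric(cpp_point_sample_fwd(array(mask * 1, dim = c(S, S, 1)),
                                       cbind(px / S, py / S)))
  as.numeric(v > 0.5)
}

# map normalised-in-ROI points to normalised coordinates on a pyramid level
roi_points_on_level <- function(box, pts_roi, level, input_size) {
  px <- box[1] + pts_roi[, 1] * box[3]
  py <- box[2] + pts_roi[, 2] * box[4]
  cbind(px / input_size, py / input_size)
}

#' One training forward pass: composite loss for a single image
#'
#' Runs backbone, RPN (anchor sampling + objectness/regression losses),
#' proposal generation, ROI box/class head losses and the mask branch
#' (coarse BCE + point-head BCE).  Returns tape nodes so the caller can
#' backpropagate.
#'
#' @param model a [build_model()] model
#' @param sample list(image = preprocessed matrix, instances = records)
#' @param class_weights per-category weights (wall, cavity, myoma)
#' @param anchors_df cached [generate_anchors()] table for the input size
#' @param rng integer seed for sampling decisions in this step
#' @return list of ag scalars: `total`, `l_cls`, `l_bbox`, `l_mask`
#' @keywords internal
train_step <- function(model, sample, class_weights = c(1, 1, 1),
                       anchors_df = NULL, rng = 0L) {
  cfg <- model$cfg
  dc <- cfg$detector
  S <- cfg$input_size
  old <- .Random.seed_guard(as.numeric(rng) %% 2147483647)
  on.exit(old(), add = TRUE)

  gt <- instances_to_gt(sample$instances)
  x <- ag_const(array(sample$image, dim = c(S, S, 1)))
  pyr <- backbone_forward(model$backbone, x)
  rpn_out <- rpn_forward(model, pyr)
  if (is.null(anchors_df)) anchors_df <- model_anchors(model, S)

  zero <- ag_const(0)
  l_rpn_cls <- zero; l_rpn_reg <- zero

  mt <- match_anchors(anchors_df, gt$boxes, dc$pos_iou, dc$neg_iou)
  pos <- which(!is.na(mt$labels) & mt$labels == 1)
  neg <- which(!is.na(mt$labels) & mt$labels == 0)
  n_pos <- min(length(pos), dc$rpn_samples %/% 2L)
  take_pos <- if (n_pos > 0) sample(pos, n_pos) else integer(0)
  n_neg <- min(length(neg), dc$rpn_samples - n_pos)
  take_neg <- if (n_neg > 0) sample(neg, n_neg) else integer(0)
  sampled <- c(take_pos, take_neg)

  if (length(sampled)) {
    nodes <- list(); targets <- numeric(0)
    for (lvl in names(rpn_out)) {
      sel <- sampled[anchors_df$level[sampled] == lvl]
      if (!length(sel)) next
      a <- anchors_df[sel, ]
      idx <- cbind(a$row + 1L, a$col + 1L, a$size_idx)
      nodes[[length(nodes) + 1L]] <- ag_gather(rpn_out[[lvl]]$obj, idx)
      targets <- c(targets, mt$labels[sel])
    }
    l_rpn_cls <- ag_bce_logits(ag_cat_vec(nodes), targets)

    if (length(take_pos)) {
      rnodes <- list(); rtargets <- numeric(0)
      for (lvl in names(rpn_out)) {
        sel <- take_pos[anchors_df$level[take_pos] == lvl]
        if (!length(sel)) next
        a <- anchors_df[sel, ]
        idx <- do.call(rbind, lapply(seq_along(sel), function(q) {
          cbind(a$row[q] + 1L, a$col[q] + 1L, 4L * (a$size_idx[q] - 1L) + 1:4)
        }))
        rnodes[[length(rnodes) + 1L]] <- ag_gather(rpn_out[[lvl]]$reg, idx)
        tt <- encode_box(gt$boxes[mt$matched_gt[sel], , drop = FALSE],
                         anchor_boxes(a))
        rtargets <- c(rtargets, as.numeric(t(tt)))
      }
      l_rpn_reg <- ag_mul_s(ag_smooth_l1_sum(ag_cat_vec(rnodes), rtargets),
                            1 / length(sampled))
    }
  }

  # ---- proposals and ROI heads -------------------------------------------
  props <- make_proposals(model, rpn_out, anchors_df, training = TRUE)
  pboxes <- rbind(props$boxes, gt$boxes)      # GT boxes help early training
  if (nrow(gt$boxes)) {
    iou <- cpp_box_iou(pboxes, gt$boxes)
    best <- apply(iou, 1, max)
    bidx <- max.col(iou, ties.method = "first")
  } else {
    best <- rep(0, nrow(pboxes)); bidx <- rep(NA_integer_, nrow(pboxes))
  }
  roi_cls <- ifelse(best >= dc$fg_iou, gt$cls[bidx], 1L)
  fg <- which(roi_cls > 1L)
  bg <- which(roi_cls == 1L)
  n_fg <- min(length(fg), ceiling(dc$fg_fraction * dc$roi_samples))
  take_fg <- if (n_fg > 0) sample(fg, n_fg) else integer(0)
  n_bg <- min(length(bg), dc$roi_samples - n_fg)
  take_bg <- if (n_bg > 0) sample(bg, n_bg) else integer(0)
  rois <- c(take_fg, take_bg)

  l_roi_cls <- zero; l_roi_reg <- zero
  l_mask_coarse <- zero; l_mask_point <- zero

  if (length(rois)) {
    rb <- pboxes[rois, , drop = FALSE]
    pooled <- pool_rois(model, pyr, rb, dc$box_pool, dc$sampling_ratio)
    bh <- ag_box_head(pooled$mat, model$box_head)
    labels <- roi_cls[rois]
    wts <- c(1, class_weights)
    l_roi_cls <- ag_softmax_ce(bh$cls_logits, labels, wts)

    fg_local <- which(labels > 1L)
    if (length(fg_local)) {
      idx <- do.call(rbind, lapply(fg_local, function(q) {
        cbind(q, 4L * (labels[q] - 1L) + 1:4)
      }))
      pred <- ag_gather(bh$reg, idx)
      gtb <- gt$boxes[bidx[rois[fg_local]], , drop = FALSE]
      tt <- encode_box(gtb, rb[fg_local, , drop = FALSE])
      l_roi_reg <- ag_mul_s(ag_smooth_l1_sum(pred, as.numeric(t(tt))),
                            1 / length(rois))
    }

    # ---- mask branch on foreground ROIs ----------------------------------
    mh <- cfg$maskhead
    mrois <- head(fg_local, mh$mask_rois)
    if (length(mrois)) {
      cnodes <- list(); ctargets <- list()
      pnodes <- list(); ptargets <- list()
      for (q in mrois) {
        box <- rb[q, ]
        cls <- labels[q]
        gmask <- gt$masks[[bidx[rois[q]]]]
        lvl <- paste0("P", roi_to_level(box[3] * box[4]))
        stride <- pyramid_strides[[lvl]]
        b <- box / stride
        mp <- ag_roi_align(pyr[[lvl]], c(b[1], b[2], b[1] + b[3], b[2] + b[4]),
                           mh$mask_pool, mh$mask_pool, dc$sampling_ratio)
        logits <- ag_coarse_mask(mp, model$mask_head)   # G x G x 3
        G <- mh$coarse_grid
        tgt <- mask_grid_targets(gmask, box, G)
        gi <- cbind(rep(seq_len(G), G), rep(seq_len(G), each = G),
                    cls - 1L)                            # all cells, class ch
        cnodes[[length(cnodes) + 1L]] <- ag_gather(logits, gi)
        ctargets[[length(ctargets) + 1L]] <- tgt[gi[, 1:2]]

        if (isTRUE(cfg$pointrend)) {
          probs <- ag_sigmoid(logits)
          sel <- select_training_points(probs$value[, , cls - 1L],
                                        k = mh$point_k, beta = mh$point_beta,
                                        n_points = mh$point_n)
          fine_pts <- roi_points_on_level(box, sel$points, lvl, S)
          # stop-gradient: the point head trains on detached features so
          # its (irreducibly noisy, boundary-focused) loss cannot disturb
          # the shared backbone and coarse head
          fine <- ag_const(cpp_point_sample_fwd(pyr[[lvl]]$value, fine_pts))
          coarse_at <- ag_const(cpp_point_sample_fwd(probs$value,
                                                     sel$points))
          pvec <- ag_cbind(fine, coarse_at)
          plog <- ag_point_head(pvec, model$point_head)
          pidx <- cbind(seq_len(nrow(sel$points)), cls - 1L)
          pnodes[[length(pnodes) + 1L]] <- ag_gather(plog, pidx)
          ptargets[[length(ptargets) + 1L]] <-
            mask_point_targets(gmask, box, sel$points)
        }
      }
      l_mask_coarse <- ag_bce_logits(ag_cat_vec(cnodes), unlist(ctargets))
      if (length(pnodes))
        l_mask_point <- ag_bce_logits(ag_cat_vec(pnodes), unlist(ptargets))
    }
  }

  l_cls <- ag_add(l_rpn_cls, l_roi_cls)
  l_bbox <- ag_add(l_rpn_reg, l_roi_reg)
  l_mask <- ag_add(l_mask_coarse, l_mask_point)
  total <- ag_add(ag_add(l_cls, ag_mul_s(l_bbox, 1.2)), l_mask)
  list(total = total, l_cls = l_cls, l_bbox = l_bbox, l_mask = l_mask,
       parts = c(rpn_cls = l_rpn_cls$value, roi_cls = l_roi_cls$value,
                 rpn_reg = l_rpn_reg$value, roi_reg = l_roi_reg$value,
                 coarse = l_mask_coarse$value, point = l_mask_point$value))
}

#' Train a model on phantom samples
#'
#' Samples are in-memory lists with a raw `image` in [0, 1] and `instances`
#' (as from [generate_phantom()]); preprocessing (CLAHE + Z-score) is
#' applied once up front.  Per-epoch branch losses are logged; when a
#' validation set is given, mask AP is computed each epoch and the best
#' parameters are kept.
#'
#' @param model a [build_model()] model
#' @param train_samples list of samples
#' @param val_samples optional validation samples
#' @param epochs number of epochs (default from the profile)
#' @param iters optional hard cap on total iterations (overrides epochs)
#' @param log_file optional JSON-lines log path
#' @param verbose print per-epoch summaries
#' @return list: `model`, `history` (data.frame), `best_val_ap`,
#'   `best_params`
#' @export
train_model <- function(model, train_samples, val_samples = NULL,
                        epochs = NULL, iters = NULL, log_file = NULL,
                        verbose = FALSE) {
  cfg <- model$cfg
  tc <- cfg$train
  if (is.null(epochs)) epochs <- tc$epochs
  prep <- lapply(train_samples, function(s) {
    list(image = preprocess_train_image(s$image, cfg$input_size),
         raw = s$image, instances = s$instances)
  })
  counts <- table(factor(unlist(lapply(train_samples, function(s)
    vapply(s$instances, `[[`, character(1), "category"))),
    levels = uterseg_categories()$name))
  cw <- if (isTRUE(tc$class_weighting) && all(counts > 0))
    as.numeric(inverse_frequency_weights(as.numeric(counts))) else c(1, 1, 1)

  opt <- sgd_optimizer(model$params, lr = tc$lr, momentum = tc$momentum,
                       weight_decay = tc$weight_decay,
                       clip_norm = tc$clip_norm %||% 2)
  anchors_df <- model_anchors(model, cfg$input_size)
  hist <- list()
  best_ap <- -Inf; best_params <- NULL
  it <- 0L
  done <- FALSE
  for (ep in seq_len(epochs)) {
    old <- .Random.seed_guard((as.numeric(cfg$seed) * 131 + ep) %% 2147483647)
    ord <- sample(length(prep))
    old()
    comp <- c(total = 0, l_cls = 0, l_bbox = 0, l_mask = 0)
    nb <- 0L
    batch_count <- 0L
    ag_zero_grad(model$params)
    for (i in ord) {
      it <- it + 1L
      s <- prep[[i]]
      if (isTRUE(tc$augment)) {
        aug <- augment(s$raw, s$instances,
                       rng = (as.numeric(cfg$seed) * 7919 + it),
                       rotate = isTRUE(tc$aug_rotate),
                       crop = isTRUE(tc$aug_crop))
        if (length(aug$instances)) {
          s <- list(image = preprocess_train_image(aug$image, cfg$input_size),
                    instances = aug$instances)
        }
      }
      ls <- train_step(model, s, cw, anchors_df,
                       rng = as.numeric(cfg$seed) * 104729 + it)
      if (!is.finite(ls$total$value))
        stop("divergent loss (non-finite) at iteration ", it,
             "; components: cls=", ls$l_cls$value,
             " bbox=", ls$l_bbox$value, " mask=", ls$l_mask$value)
      ag_backward(ls$total)
      comp <- comp + c(ls$total$value, ls$l_cls$value, ls$l_bbox$value,
                       ls$l_mask$value)
      nb <- nb + 1L
      batch_count <- batch_count + 1L
      if (batch_count >= tc$batch_size) {
        # average accumulated gradients over the batch
        for (p in model$params)
          if (!is.null(p$grad)) p$grad <- p$grad / batch_count
        opt$step()
        ag_zero_grad(model$params)
        batch_count <- 0L
      }
      if (!is.null(iters) && it >= iters) { done <- TRUE; break }
    }
    if (batch_count > 0L) {
      for (p in model$params)
        if (!is.null(p$grad)) p$grad <- p$grad / batch_count
      opt$step()
      ag_zero_grad(model$params)
    }
    comp <- comp / max(nb, 1L)
    val_ap <- NA_real_
    val_every <- tc$val_every %||% 1L
    if (!is.null(val_samples) && (ep %% val_every == 0L || ep == epochs ||
                                  done)) {
      val_ap <- quick_mask_ap(model, val_samples)
      if (val_ap > best_ap) {
        best_ap <- val_ap
        best_params <- param_values(model)
      }
    }
    rec <- data.frame(epoch = ep, total = comp[1], l_cls = comp[2],
                      l_bbox = comp[3], l_mask = comp[4], val_mask_ap = val_ap)
    hist[[ep]] <- rec
    if (!is.null(log_file))
      cat(jsonlite::toJSON(as.list(rec), auto_unbox = TRUE, digits = NA),
          "\n", file = log_file, append = TRUE)
    if (verbose)
      message(sprintf("epoch %d: total %.4f cls %.4f bbox %.4f mask %.4f%s",
                      ep, comp[1], comp[2], comp[3], comp[4],
                      if (is.na(val_ap)) "" else sprintf(" valAP %.3f", val_ap)))
    if (done) break
  }
  if (!is.null(best_params)) restore_params(model, best_params)
  list(model = model, history = do.call(rbind, hist),
       best_val_ap = if (is.finite(best_ap)) best_ap else NA_real_)
}

preprocess_train_image <- function(image, input_size) {
  x <- adaptive_hist_eq(image)
  x <- zscore_normalize(x)
  resize_input(x, target = input_size)$image
}

# mask AP (mean over IoU 0.50:0.05:0.95) on in-memory samples
quick_mask_ap <- function(model, samples) {
  res <- list(); gts <- list()
  for (i in seq_along(samples)) {
    dets <- predict_model(model, samples[[i]]$image)
    for (d in dets) {
      d$image_id <- i
      res[[length(res) + 1L]] <- d
    }
    for (inst in samples[[i]]$instances)
      gts[[length(gts) + 1L]] <- c(inst, list(image_id = i))
  }
  ev <- evaluate_detections(res, gts, model$cfg$input_size)
  ev$mask["AP"]
}
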