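# Model assembly: configuration profiles, parameter construction, and the
# shared forward passes used by training and inference.
#
# Class indexing inside the heads: 1 = background, then the COCO categories
# in id order (2 = uterine_wall, 3 = uterine_cavity, 4 = myoma); a head
# class c corresponds to COCO category id c - 1.

#' Model and training configuration
#'
#' Two built-in profiles: `"full"` mirrors the publication-scale defaults
#' (512 input, SGD lr 0.001, momentum 0.9, weight decay 0.0001, 60 epochs,
#' batch 4) and `"desk"` is a small CPU-trainable profile (128 input,
#' narrow widths, 10 epochs) used by the test-suite and example runs.
#' Ablation switches (`dcn`, `cbam`, `kmeans_anchors`, `pointrend`)
#' structurally reproduce the model-component study.
#'
#' @param profile `"desk"` or `"full"`
#' @param ... named overrides of any config field
#' @return a `uterseg_config` list
#' @export
model_config <- function(profile = c("desk", "full"), ...) {
  profile <- match.arg(profile)
  cfg <- if (profile == "full") {
    list(
      profile = "full", input_size = 512L,
      backbone = list(widths = c(18L, 36L, 72L, 144L), stages = 4L,
                      dcn = TRUE, cbam = TRUE, reduction_ratio = 16L,
                      pyramid_channels = 64L, offset_scale = 1,
                      spatial_kernel = 7L),
      anchors = list(kmeans = TRUE, k = 9L, restarts = 10L),
      detector = list(pos_iou = 0.7, neg_iou = 0.3, rpn_samples = 256L,
                      pre_nms_train = 2000L, pre_nms_test = 1000L,
                      post_nms_train = 1000L, post_nms_test = 300L,
                      proposal_nms = 0.7, roi_samples = 64L,
                      fg_fraction = 0.25, fg_iou = 0.5,
                      box_head_hidden = 1024L, box_pool = 7L,
                      sampling_ratio = 2L, score_thresh = 0.05,
                      det_nms = 0.5, max_dets = 100L),
      maskhead = list(mask_pool = 14L, coarse_grid = 14L, point_k = 3,
                      point_beta = 0.75, point_n = 196L,
                      point_hidden = 256L, point_layers = 3L,
                      refine_steps = 3L, n_per_step = 784L,
                      mask_rois = 16L, paste_size = 112L,
                      mask_threshold = 0.5),
      train = list(optimizer = "sgd", lr = 0.001, momentum = 0.9,
                   weight_decay = 1e-4, clip_norm = 2, epochs = 60L,
                   batch_size = 4L, augment = TRUE, aug_rotate = TRUE,
                   aug_crop = TRUE, class_weighting = TRUE,
                   val_every = 1L),
      pointrend = TRUE, seed = 0L
    )
  } else {
    list(
      profile = "desk", input_size = 128L,
      backbone = list(widths = c(8L, 16L, 32L), stages = 2L,
                      dcn = TRUE, cbam = TRUE, reduction_ratio = 4L,
                      pyramid_channels = 32L, offset_scale = 0.1,
                      spatial_kernel = 3L),
      anchors = list(kmeans = TRUE, k = 9L, restarts = 10L),
      detector = list(pos_iou = 0.7, neg_iou = 0.3, rpn_samples = 64L,
                      pre_nms_train = 600L, pre_nms_test = 300L,
                      post_nms_train = 200L, post_nms_test = 60L,
                      proposal_nms = 0.7, roi_samples = 48L,
                      fg_fraction = 0.25, fg_iou = 0.5,
                      box_head_hidden = 128L, box_pool = 7L,
                      sampling_ratio = 2L, score_thresh = 0.05,
                      det_nms = 0.5, max_dets = 30L),
      maskhead = list(mask_pool = 14L, coarse_grid = 14L, point_k = 3,
                      point_beta = 0.75, point_n = 96L,
                      point_hidden = 64L, point_layers = 3L,
                      refine_steps = 3L, n_per_step = 256L,
                      mask_rois = 12L, paste_size = 112L,
                      mask_threshold = 0.5),
      train = list(optimizer = "sgd", lr = 0.1, momentum = 0.9,
                   weight_decay = 1e-4, clip_norm = 2, epochs = 10L,
                   batch_size = 2L, augment = TRUE, aug_rotate = FALSE,
                   aug_crop = FALSE, class_weighting = TRUE,
                   val_every = 2L),
      pointrend = TRUE, seed = 0L
    )
  }
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "uterseg_config")
}

#' Build a model with freshly initialised parameters
#'
#' @param cfg a [model_config()]
#' @param anchors named list P3/P4/P5 of (w, h) anchor matrices; default is
#'   the fixed scale/ratio baseline set (replaced by fitted anchors in the
#'   pipeline when `cfg$anchors$kmeans` is on)
#' @return a `uterseg_model` list: `cfg`, parameter trees, `anchors`, and
#'   the flattened parameter list used by the optimiser
#' @export
build_model <- function(cfg, anchors = default_anchor_levels()) {
  old <- .Random.seed_guard(as.numeric(cfg$seed) %% 2147483647)
  on.exit(old(), add = TRUE)
  bbcfg <- cfg$backbone
  pc <- bbcfg$pyramid_channels
  m <- list(cfg = cfg, anchors = anchors)
  m$backbone <- init_backbone(widths = bbcfg$widths, stages = bbcfg$stages,
                              dcn = isTRUE(bbcfg$dcn),
                              use_cbam = isTRUE(bbcfg$cbam),
                              reduction = bbcfg$reduction_ratio,
                              pyramid_channels = pc,
                              offset_scale = bbcfg$offset_scale %||% 1,
                              spatial_kernel = bbcfg$spatial_kernel %||% 7L)
  A <- nrow(anchors$P3)
  m$rpn <- list(conv = c(init_conv(3, pc, pc),
                         list(norm = init_groupnorm(pc))),
                obj = init_conv(1, pc, A, scale = 0.1),
                reg = init_conv(1, pc, 4L * A, scale = 0.1))
  dc <- cfg$detector
  m$box_head <- init_box_head(dc$box_pool^2 * pc, dc$box_head_hidden, 3L)
  mh <- cfg$maskhead
  m$mask_head <- init_mask_head(pc, 3L)
  m$point_head <- init_point_head(pc + 3L, mh$point_hidden, mh$point_layers, 3L)
  m$params <- collect_params(m[c("backbone", "rpn", "box_head", "mask_head",
                                 "point_head")])
  class(m) <- "uterseg_model"
  m
}

#' @export
print.uterseg_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$value), numeric(1)))
  cat("uterseg model (", x$cfg$profile, " profile): ",
      format(np, big.mark = ","), " parameters, input ",
      x$cfg$input_size, "^2\n", sep = "")
  invisible(x)
}

collect_params <- function(tree) {
  out <- list()
  walk <- function(node, prefix) {
    if (is_ag(node)) {
      if (node$requires_grad) out[[prefix]] <<- node
      return()
    }
    if (is.list(node)) {
      nms <- names(node)
      for (i in seq_along(node)) {
        nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        walk(node[[i]], paste(prefix, nm, sep = "."))
      }
    }
  }
  walk(tree, "p")
  out
}

# deep copy / restore of parameter values (checkpointing)
param_values <- function(model) lapply(model$params, function(p) p$value)

restore_params <- function(model, values) {
  for (nm in names(values)) model$params[[nm]]$value <- values[[nm]]
  invisible(model)
}

# ---- shared forward pieces -------------------------------------------------

rpn_forward <- function(model, pyr) {
  lapply(pyr, function(p) {
    h <- cnr(p, model$rpn$conv, 1L, 1L)
    list(obj = ag_conv2d(h, model$rpn$obj$w, model$rpn$obj$b, 1L, 0L),
         reg = ag_conv2d(h, model$rpn$reg$w, model$rpn$reg$b, 1L, 0L))
  })
}

model_anchors <- function(model, input_size) {
  shapes <- list(P3 = rep(input_size %/% 8L, 2),
                 P4 = rep(input_size %/% 16L, 2),
                 P5 = rep(input_size %/% 32L, 2))
  generate_anchors(shapes, model$anchors)
}

# objectness scores and decoded boxes for all anchors (detached values)
rpn_decode_all <- function(rpn_out, anchors) {
  scores <- numeric(nrow(anchors))
  deltas <- matrix(0, nrow(anchors), 4)
  for (lvl in names(rpn_out)) {
    sel <- which(anchors$level == lvl)
    a <- anchors[sel, ]
    obj <- rpn_out[[lvl]]$obj$value
    reg <- rpn_out[[lvl]]$reg$value
    idx <- cbind(a$row + 1L, a$col + 1L, a$size_idx)
    scores[sel] <- 1 / (1 + exp(-obj[idx]))
    for (d in 1:4)
      deltas[sel, d] <- reg[cbind(a$row + 1L, a$col + 1L,
                                  4L * (a$size_idx - 1L) + d)]
  }
  list(scores = scores, boxes = decode_box(deltas, anchor_boxes(anchors)))
}

clip_boxes <- function(boxes, size) {
  x0 <- pmin(pmax(boxes[, 1], 0), size - 1)
  y0 <- pmin(pmax(boxes[, 2], 0), size - 1)
  x1 <- pmin(pmax(boxes[, 1] + boxes[, 3], 1), size)
  y1 <- pmin(pmax(boxes[, 2] + boxes[, 4], 1), size)
  cbind(x0, y0, pmax(x1 - x0, 1e-3), pmax(y1 - y0, 1e-3))
}

# proposal generation from detached RPN outputs
make_proposals <- function(model, rpn_out, anchors, training) {
  dc <- model$cfg$detector
  dec <- rpn_decode_all(rpn_out, anchors)
  boxes <- clip_boxes(dec$boxes, model$cfg$input_size)
  pre_n <- if (training) dc$pre_nms_train else dc$pre_nms_test
  post_n <- if (training) dc$post_nms_train else dc$post_nms_test
  top <- head(order(-dec$scores), pre_n)
  keep <- nms(boxes[top, , drop = FALSE], dec$scores[top], dc$proposal_nms)
  keep <- head(keep, post_n)
  list(boxes = boxes[top[keep], , drop = FALSE],
       scores = dec$scores[top[keep]])
}

# pooled ROI features (ag) for a set of boxes; returns matrix node rows
pool_rois <- function(model, pyr, boxes, pool, sampling_ratio) {
  rows <- vector("list", nrow(boxes))
  lvls <- roi_to_level(boxes[, 3] * boxes[, 4])
  for (i in seq_len(nrow(boxes))) {
    lvl <- paste0("P", lvls[i])
    stride <- pyramid_strides[[lvl]]
    b <- boxes[i, ] / stride
    roi <- c(b[1], b[2], b[1] + b[3], b[2] + b[4])
    rows[[i]] <- ag_flatten(ag_roi_align(pyr[[lvl]], roi, pool, pool,
                                         sampling_ratio))
  }
  list(mat = ag_stack_rows(rows), levels = lvls)
}
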