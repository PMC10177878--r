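# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code under fixed seeds; nothing is stored on
# disk.

tiny_phantom_config <- function(n_images = 4L, image_size = 96L, seed = 11L,
                                ...) {
  phantom_config(image_size = image_size, n_images = n_images, seed = seed,
                 ...)
}

# naive direct convolution, independent of the im2col kernel
naive_conv2d <- function(x, w, b, stride = 1, pad = 1) {
  K <- dim(w)[1]; C <- dim(w)[3]; O <- dim(w)[4]
  H <- dim(x)[1]; W <- dim(x)[2]
  Ho <- (H + 2 * pad - K) %/% stride + 1
  Wo <- (W + 2 * pad - K) %/% stride + 1
  out <- array(0, c(Ho, Wo, O))
  for (o in seq_len(O)) for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    s <- b[o]
    for (c in seq_len(C)) for (ki in seq_len(K)) for (kj in seq_len(K)) {
      ih <- (i - 1) * stride - pad + ki
      iw <- (j - 1) * stride - pad + kj
      if (ih >= 1 && ih <= H && iw >= 1 && iw <= W)
        s <- s + w[ki, kj, c, o] * x[ih, iw, c]
    }
    out[i, j, o] <- s
  }
  out
}

# brute-force greedy NMS oracle
naive_nms <- function(boxes, scores, thr) {
  n <- nrow(boxes)
  iou <- function(a, b) {
    ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
    iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
    inter <- ix * iy
    inter / (a[3] * a[4] + b[3] * b[4] - inter)
  }
  ord <- order(-scores)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (k in kept) if (iou(boxes[i, ], boxes[k, ]) > thr) { ok <- FALSE; break }
    if (ok) kept <- c(kept, i)
  }
  kept
}

# Independent COCO-protocol AP oracle: per-category greedy matching at each
# threshold on a precomputed IoU list, step-by-step 101-point integration.
# Written against the published protocol, sharing no code with the package
# evaluator.
oracle_ap <- function(dets, gts, thr, iou_fun, range = c(0, Inf),
                      det_area = NULL) {
  sc <- sapply(dets, function(d) d$score)
  ord <- order(-sc)
  gig <- sapply(gts, function(g) g$area <= range[1] || g$area >= range[2])
  n_gt <- sum(!gig)
  taken <- rep(FALSE, length(gts))
  lab <- integer(length(dets))
  for (i in ord) {
    ious <- sapply(seq_along(gts), function(j) {
      if (taken[j] || dets[[i]]$image_id != gts[[j]]$image_id) -1
      else iou_fun(dets[[i]], gts[[j]])
    })
    if (length(ious) == 0) ious <- numeric(0)
    cand <- which(ious >= thr)
    if (length(cand)) {
      un <- cand[!gig[cand]]
      j <- if (length(un)) un[which.max(ious[un])] else cand[which.max(ious[cand])]
      taken[j] <- TRUE
      lab[i] <- if (gig[j]) -1L else 1L
    } else {
      a <- if (is.null(det_area)) dets[[i]]$bbox[3] * dets[[i]]$bbox[4]
           else det_area[i]
      lab[i] <- if (a <= range[1] || a >= range[2]) -1L else 0L
    }
  }
  labs <- lab[ord]
  labs <- labs[labs >= 0]
  if (n_gt == 0) return(NA_real_)
  if (!length(labs)) return(0)
  tp <- cumsum(labs == 1); fp <- cumsum(labs == 0)
  rec <- tp / n_gt; prec <- tp / (tp + fp)
  total <- 0
  for (r in seq(0, 1, by = 0.01)) {
    ok <- rec >= r - 1e-12
    total <- total + (if (any(ok)) max(prec[ok]) else 0)
  }
  total / 101
}

# synthetic detection sets: ground truth from tiny phantoms plus jittered /
# dropped / spurious detections, deterministic under seed
make_eval_case <- function(seed, n_images = 3L, image_size = 96L) {
  set.seed(seed)
  pc <- tiny_phantom_config(n_images = n_images, image_size = image_size,
                            seed = seed)
  gts <- list(); dets <- list()
  for (i in seq_len(n_images)) {
    ph <- generate_phantom(pc, i)
    for (inst in ph$instances) {
      gts[[length(gts) + 1L]] <- list(image_id = i,
                                      category_id = match(inst$category,
                                        uterseg_categories()$name),
                                      bbox = inst$bbox, area = inst$area,
                                      mask = inst$mask)
      if (runif(1) < 0.85) {           # jittered detection
        shift <- round(runif(2, -6, 6))
        mk <- shift_mask(inst$mask, shift[1], shift[2])
        if (sum(mk) == 0) next
        cid <- if (runif(1) < 0.9) match(inst$category,
                                         uterseg_categories()$name)
               else sample(1:3, 1)
        dets[[length(dets) + 1L]] <- list(image_id = i, category_id = cid,
                                          score = runif(1),
                                          bbox = tight_bbox(mk), mask = mk)
      }
    }
    # spurious detections
    for (k in seq_len(sample(0:2, 1))) {
      mk <- matrix(FALSE, image_size, image_size)
      r0 <- sample(image_size - 12, 1); c0 <- sample(image_size - 12, 1)
      mk[r0 + 1:10, c0 + 1:10] <- TRUE
      dets[[length(dets) + 1L]] <- list(image_id = i,
                                        category_id = sample(1:3, 1),
                                        score = runif(1), bbox = tight_bbox(mk),
                                        mask = mk)
    }
  }
  list(dets = dets, gts = gts, image_size = image_size)
}

shift_mask <- function(mask, dy, dx) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(FALSE, H, W)
  src_r <- seq_len(H) - dy; src_c <- seq_len(W) - dx
  ok_r <- src_r >= 1 & src_r <= H; ok_c <- src_c >= 1 & src_c <= W
  out[ok_r, ok_c] <- mask[src_r[ok_r], src_c[ok_c]]
  out
}

mask_iou_ref <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) 0 else sum(a & b) / u
}

box_iou_ref <- function(a, b) {
  ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

# Independent Lloyd clustering oracle under D = 1 - IoU with median
# updates, many restarts; returns the best average IoU found.
oracle_kmeans_iou <- function(boxes, k, restarts = 200, seed = 1) {
  set.seed(seed)
  iou1 <- function(a, b) {
    inter <- min(a[1], b[1]) * min(a[2], b[2])
    inter / (a[1] * a[2] + b[1] * b[2] - inter)
  }
  n <- nrow(boxes)
  best <- -Inf
  for (r in seq_len(restarts)) {
    cent <- boxes[sample(n, k), , drop = FALSE]
    prev <- rep(0L, n)
    for (it in 1:100) {
      asg <- vapply(seq_len(n), function(i) {
        which.max(vapply(seq_len(k), function(j) iou1(boxes[i, ], cent[j, ]),
                         numeric(1)))
      }, integer(1))
      if (all(asg == prev)) break
      prev <- asg
      for (j in seq_len(k)) {
        mem <- boxes[asg == j, , drop = FALSE]
        if (nrow(mem)) cent[j, ] <- apply(mem, 2, median)
      }
    }
    avg <- mean(vapply(seq_len(n), function(i)
      iou1(boxes[i, ], cent[prev[i], ]), numeric(1)))
    if (avg > best) best <- avg
  }
  best
}

# two deterministic overfit samples shared by the training tests
overfit_samples <- function() {
  pc <- phantom_config(image_size = 128, n_images = 2, seed = 7)
  lapply(1:2, function(i) generate_phantom(pc, i))
}

train_eval_report <- function(model, samples) {
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
  evaluate_detections(res, gts, model$cfg$input_size)
}

# pixels within `width` pixels of the mask boundary (dilation minus erosion)
mask_boundary_band <- function(mask, width = 2L) {
  H <- nrow(mask); W <- ncol(mask)
  dil <- mask; ero <- mask
  for (i in seq_len(width)) {
    up <- rbind(dil[-1, ], FALSE); down <- rbind(FALSE, dil[-H, ])
    le <- cbind(dil[, -1], FALSE); ri <- cbind(FALSE, dil[, -W])
    dil <- dil | up | down | le | ri
    upe <- rbind(ero[-1, ], TRUE); downe <- rbind(TRUE, ero[-H, ])
    lee <- cbind(ero[, -1], TRUE); rie <- cbind(TRUE, ero[, -W])
    ero <- ero & upe & downe & lee & rie
  }
  dil & !ero
}
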