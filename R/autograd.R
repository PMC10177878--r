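# Reverse-mode autodiff tape over plain R arrays.
#
# Tensors are environments carrying a value, an accumulated gradient, parent
# links and a node-local backward function.  Heavy kernels (convolution,
# deformable convolution, ROIAlign, resampling) live in src/kernels.cpp; the
# tape only does bookkeeping.  Feature maps are arrays dim c(H, W, C).

new_ag <- function(value, parents = list(), backward = NULL,
                   requires_grad = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  e$requires_grad <- requires_grad ||
    any(vapply(parents, function(p) p$requires_grad, logical(1)))
  class(e) <- "ag_tensor"
  e
}

#' Create a trainable parameter tensor
#' @param value numeric array holding the initial value
#' @return an `ag_tensor` with gradient tracking enabled
#' @keywords internal
ag_param <- function(value) new_ag(value, requires_grad = TRUE)

ag_const <- function(value) new_ag(value)

is_ag <- function(x) inherits(x, "ag_tensor")

ag_value <- function(x) if (is_ag(x)) x$value else x

as_ag <- function(x) if (is_ag(x)) x else ag_const(x)

#' @export
print.ag_tensor <- function(x, ...) {
  cat("<ag_tensor", paste(dim(x$value) %||% length(x$value), collapse = "x"),
      if (x$requires_grad) "grad" else "", ">\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Topologically ordered backward sweep from a scalar loss node.
ag_backward <- function(loss) {
  stopifnot(is_ag(loss), length(loss$value) == 1L)
  order <- list()
  seen <- new.env(parent = emptyenv())
  # iterative DFS; node identity by environment address
  addr <- function(e) format.default(e)
  stack <- list(list(node = loss, phase = 0L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- addr(node)
    if (top$phase == 0L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, phase = 1L)
      for (p in node$parents)
        if (p$requires_grad && is.null(seen[[addr(p)]]))
          stack[[length(stack) + 1L]] <- list(node = p, phase = 0L)
    } else {
      order[[length(order) + 1L]] <- node
    }
  }
  # order is children-after-parents; reverse for backprop
  loss$grad <- 1
  for (i in rev(seq_along(order))) {
    node <- order[[i]]
    if (is.null(node$backward) || is.null(node$grad)) next
    grads <- node$backward(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (!p$requires_grad || is.null(grads[[j]])) next
      p$grad <- if (is.null(p$grad)) grads[[j]] else p$grad + grads[[j]]
    }
  }
  invisible(loss)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ------------------------------------------------------------------ ops -----

ag_conv2d <- function(x, w, b, stride = 1L, pad = 1L) {
  fw <- cpp_conv2d_fwd_cache(x$value, w$value, b$value, stride, pad)
  d <- dim(x$value)
  new_ag(fw$y, list(x, w, b), function(g) {
    r <- cpp_conv2d_bwd_cache(fw$col, d[1], d[2], w$value, g, stride, pad,
                              x$requires_grad)
    list(if (x$requires_grad) r$gx else NULL, r$gw, r$gb)
  })
}

ag_dconv2d <- function(x, w, b, offs, stride = 1L, pad = 1L) {
  y <- cpp_dconv2d_fwd(x$value, w$value, b$value, offs$value, stride, pad)
  new_ag(y, list(x, w, b, offs), function(g) {
    r <- cpp_dconv2d_bwd(x$value, w$value, offs$value, g, stride, pad)
    list(r$gx, r$gw, r$gb, r$goffs)
  })
}

ag_relu <- function(x) {
  m <- x$value > 0
  new_ag(x$value * m, list(x), function(g) list(g * m))
}

ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  new_ag(s, list(x), function(g) list(g * s * (1 - s)))
}

ag_add <- function(x, y) {
  new_ag(x$value + y$value, list(x, y), function(g) list(g, g))
}

ag_mul <- function(x, y) {
  new_ag(x$value * y$value, list(x, y),
         function(g) list(g * y$value, g * x$value))
}

ag_mul_s <- function(x, k) {
  new_ag(x$value * k, list(x), function(g) list(g * k))
}

# x: H x W x C cube; s: length-C vector -> per-channel scaling
ag_scale_channels <- function(x, s) {
  d <- dim(x$value)
  sv <- rep(s$value, each = d[1] * d[2])
  new_ag(x$value * sv, list(x, s), function(g) {
    gs <- vapply(seq_len(d[3]), function(c) sum(g[, , c] * x$value[, , c]),
                 numeric(1))
    list(g * sv, gs)
  })
}

# x: H x W x C cube; m: H x W matrix -> per-pixel scaling
ag_scale_map <- function(x, m) {
  d <- dim(x$value)
  mv <- array(m$value, dim = d)
  new_ag(x$value * mv, list(x, m), function(g) {
    gm <- matrix(0, d[1], d[2])
    for (c in seq_len(d[3])) gm <- gm + g[, , c] * x$value[, , c]
    list(g * mv, gm)
  })
}

ag_concat_c <- function(xs) {
  vals <- lapply(xs, function(x) x$value)
  d1 <- dim(vals[[1]])
  ccounts <- vapply(vals, function(v) dim(v)[3], numeric(1))
  out <- array(unlist(vals), dim = c(d1[1], d1[2], sum(ccounts)))
  new_ag(out, xs, function(g) {
    res <- vector("list", length(xs))
    at <- 0L
    for (i in seq_along(xs)) {
      res[[i]] <- g[, , at + seq_len(ccounts[i]), drop = FALSE]
      at <- at + ccounts[i]
    }
    res
  })
}

ag_upsample2x <- function(x) {
  d <- dim(x$value)
  new_ag(cpp_upsample2x_fwd(x$value), list(x),
         function(g) list(cpp_upsample2x_bwd(g, d[1], d[2])))
}

ag_avgpool2 <- function(x) {
  new_ag(cpp_avgpool2_fwd(x$value), list(x),
         function(g) list(cpp_avgpool2_bwd(g)))
}

# global average pool H x W x C -> C
ag_gap <- function(x) {
  d <- dim(x$value)
  new_ag(apply(x$value, 3, mean), list(x), function(g) {
    list(array(rep(g / (d[1] * d[2]), each = d[1] * d[2]), dim = d))
  })
}

# global max pool H x W x C -> C (first-maximum tie-break)
ag_gmp <- function(x) {
  d <- dim(x$value)
  idx <- integer(d[3])
  out <- numeric(d[3])
  for (c in seq_len(d[3])) {
    sl <- x$value[, , c]
    idx[c] <- which.max(sl)
    out[c] <- sl[idx[c]]
  }
  new_ag(out, list(x), function(g) {
    gx <- array(0, dim = d)
    for (c in seq_len(d[3])) {
      gi <- arrayInd(idx[c], d[1:2])
      gx[gi[1], gi[2], c] <- g[c]
    }
    list(gx)
  })
}

# mean over channels -> H x W x 1
ag_cmean <- function(x) {
  d <- dim(x$value)
  m <- apply(x$value, c(1, 2), mean)
  new_ag(array(m, c(d[1], d[2], 1)), list(x), function(g) {
    list(array(rep(g[, , 1] / d[3], d[3]), dim = d))
  })
}

# max over channels -> H x W x 1 (first-maximum tie-break)
ag_cmax <- function(x) {
  d <- dim(x$value)
  which_c <- apply(x$value, c(1, 2), which.max)
  m <- apply(x$value, c(1, 2), max)
  new_ag(array(m, c(d[1], d[2], 1)), list(x), function(g) {
    gx <- array(0, dim = d)
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
      gx[i, j, which_c[i, j]] <- g[i, j, 1]
    list(gx)
  })
}

# x: N x D matrix (or length-D vector treated as 1 x D); W: D x O; b: O
ag_linear <- function(x, w, b) {
  xv <- x$value
  if (is.null(dim(xv))) xv <- matrix(xv, nrow = 1)
  y <- xv %*% w$value + matrix(b$value, nrow(xv), length(b$value), byrow = TRUE)
  new_ag(y, list(x, w, b), function(g) {
    gx <- g %*% t(w$value)
    if (is.null(dim(x$value))) gx <- as.numeric(gx)
    list(gx, t(xv) %*% g, colSums(g))
  })
}

ag_flatten <- function(x) {
  d <- dim(x$value)
  new_ag(as.numeric(x$value), list(x), function(g) list(array(g, dim = d)))
}

ag_roi_align <- function(x, roi, out_h, out_w, sampling_ratio = 2L) {
  d <- dim(x$value)
  new_ag(cpp_roi_align_fwd(x$value, roi, out_h, out_w, sampling_ratio),
         list(x), function(g) {
           list(cpp_roi_align_bwd(g, roi, d[1], d[2], d[3], sampling_ratio))
         })
}

# pts: N x 2 matrix of normalised (u = x-frac, v = y-frac); -> N x C
ag_point_sample <- function(x, pts) {
  d <- dim(x$value)
  new_ag(cpp_point_sample_fwd(x$value, pts), list(x), function(g) {
    list(cpp_point_sample_bwd(g, pts, d[1], d[2], d[3]))
  })
}

# gather cube entries at an n x 3 (row, col, channel) index matrix -> vector
ag_gather <- function(x, idx) {
  d <- dim(x$value)
  new_ag(x$value[idx], list(x), function(g) {
    gx <- array(0, dim = d)
    gx[idx] <- gx[idx] + g
    list(gx)
  })
}

# select rows of a matrix
ag_rows <- function(x, i) {
  new_ag(x$value[i, , drop = FALSE], list(x), function(g) {
    gx <- matrix(0, nrow(x$value), ncol(x$value))
    gx[i, ] <- gx[i, ] + g
    list(gx)
  })
}

# group normalisation over channel groups of an H x W x C cube
ag_groupnorm <- function(x, gamma, beta, groups, eps = 1e-5) {
  fw <- cpp_groupnorm_fwd(x$value, gamma$value, beta$value, groups, eps)
  new_ag(fw$y, list(x, gamma, beta), function(gr) {
    bw <- cpp_groupnorm_bwd(gr, fw$xhat, fw$invstd, gamma$value, groups)
    list(bw$gx, as.numeric(bw$ggamma), as.numeric(bw$gbeta))
  })
}

init_groupnorm <- function(channels) {
  list(gamma = ag_param(rep(1, channels)), beta = ag_param(numeric(channels)))
}

# concatenate vector nodes
ag_cat_vec <- function(xs) {
  lens <- vapply(xs, function(x) length(x$value), numeric(1))
  new_ag(unlist(lapply(xs, function(x) as.numeric(x$value))), xs, function(g) {
    at <- 0
    lapply(seq_along(xs), function(i) {
      gi <- g[at + seq_len(lens[i])]
      at <<- at + lens[i]
      gi
    })
  })
}

# stack vector nodes as matrix rows
ag_stack_rows <- function(xs) {
  vals <- lapply(xs, function(x) as.numeric(x$value))
  new_ag(do.call(rbind, vals), xs, function(g) {
    lapply(seq_along(xs), function(i) {
      gi <- g[i, ]
      if (!is.null(dim(xs[[i]]$value))) gi <- array(gi, dim = dim(xs[[i]]$value))
      gi
    })
  })
}

# column-bind two matrix nodes
ag_cbind <- function(a, b) {
  ca <- ncol(a$value); cb <- ncol(b$value)
  new_ag(cbind(a$value, b$value), list(a, b), function(g) {
    list(g[, seq_len(ca), drop = FALSE],
         g[, ca + seq_len(cb), drop = FALSE])
  })
}

ag_sum <- function(x) {
  new_ag(sum(x$value), list(x), function(g) {
    v <- x$value
    list(if (is.null(dim(v))) rep(g, length(v)) else array(g, dim = dim(v)))
  })
}

ag_mean <- function(x) ag_mul_s(ag_sum(x), 1 / length(x$value))

# ------------------------------------------------------------- losses -------

# logits: N x K; labels: integer 1..K; weights: length-K class weights.
# L = (1/N) sum_i weights[y_i] * CE_i  (so doubling a class weight doubles
# that sample's contribution).
ag_softmax_ce <- function(logits, labels, weights = NULL) {
  z <- logits$value
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  n <- nrow(z); k <- ncol(z)
  if (is.null(weights)) weights <- rep(1, k)
  zmax <- apply(z, 1, max)
  ez <- exp(z - zmax)
  p <- ez / rowSums(ez)
  wi <- weights[labels]
  li <- -log(pmax(p[cbind(seq_len(n), labels)], 1e-12))
  loss <- sum(wi * li) / n
  new_ag(loss, list(logits), function(g) {
    gz <- p
    gz[cbind(seq_len(n), labels)] <- gz[cbind(seq_len(n), labels)] - 1
    gz <- gz * (wi / n) * g
    if (is.null(dim(logits$value))) gz <- as.numeric(gz)
    list(gz)
  })
}

# mean binary cross entropy on logits; targets in [0,1], same shape
ag_bce_logits <- function(logits, targets) {
  z <- logits$value
  t <- targets
  n <- length(z)
  l <- pmax(z, 0) - z * t + log1p(exp(-abs(z)))
  new_ag(sum(l) / n, list(logits), function(g) {
    s <- 1 / (1 + exp(-z))
    gz <- (s - t) * (g / n)
    list(if (is.null(dim(z))) gz else array(gz, dim = dim(z)))
  })
}

# elementwise smooth-L1 of (pred - target), summed
ag_smooth_l1_sum <- function(pred, target) {
  dlt <- pred$value - target
  sm <- abs(dlt) < 1
  l <- ifelse(sm, 0.5 * dlt^2, abs(dlt) - 0.5)
  new_ag(sum(l), list(pred), function(g) {
    gd <- ifelse(sm, dlt, sign(dlt)) * g
    list(if (is.null(dim(pred$value))) as.numeric(gd) else gd)
  })
}

# ------------------------------------------------------------ optimiser -----

#' Stochastic gradient descent with momentum and weight decay
#'
#' @param params named list of `ag_tensor` parameters
#' @param lr learning rate
#' @param momentum momentum coefficient
#' @param weight_decay L2 coefficient added to the gradient
#' @return an optimiser state object with a `step` closure
#' @keywords internal
sgd_optimizer <- function(params, lr = 0.001, momentum = 0.9,
                          weight_decay = 1e-4, clip_norm = 2) {
  vel <- lapply(params, function(p) {
    v <- p$value
    if (is.null(dim(v))) numeric(length(v)) else array(0, dim = dim(v))
  })
  list(
    params = params,
    step = function() {
      if (is.finite(clip_norm)) {
        gn <- sqrt(sum(vapply(params, function(p)
          if (is.null(p$grad)) 0 else sum(p$grad^2), numeric(1))))
        if (gn > clip_norm) {
          sc <- clip_norm / gn
          for (p in params) if (!is.null(p$grad)) p$grad <- p$grad * sc
        }
      }
      for (i in seq_along(params)) {
        p <- params[[i]]
        if (is.null(p$grad)) next
        g <- p$grad + weight_decay * p$value
        vel[[i]] <<- momentum * vel[[i]] + g
        p$value <- p$value - lr * vel[[i]]
      }
      invisible(NULL)
    },
    set_lr = function(new_lr) lr <<- new_lr
  )
}

# He-style initialisation helpers -------------------------------------------

init_conv <- function(k, c_in, c_out, scale = 1) {
  std <- scale * sqrt(2 / (k * k * c_in))
  list(w = ag_param(array(stats::rnorm(k * k * c_in * c_out, 0, std),
                          dim = c(k, k, c_in, c_out))),
       b = ag_param(numeric(c_out)))
}

init_linear <- function(d_in, d_out, scale = 1) {
  std <- scale * sqrt(2 / d_in)
  list(w = ag_param(matrix(stats::rnorm(d_in * d_out, 0, std), d_in, d_out)),
       b = ag_param(numeric(d_out)))
}

init_conv_zero <- function(k, c_in, c_out) {
  list(w = ag_param(array(0, dim = c(k, k, c_in, c_out))),
       b = ag_param(numeric(c_out)))
}
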