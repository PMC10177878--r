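# Multi-resolution backbone: parallel high/low-resolution branches with
# information exchange at stage boundaries, deformable convolution in the
# final block of each branch, fusion of all branches at the highest
# resolution, stepwise average pooling into a 3-level pyramid (P3/P4/P5 at
# strides 8/16/32) and CBAM attention on each output level.

#' Deformable 3x3 convolution (functional form)
#'
#' Convolution whose kernel sampling positions are displaced by per-location
#' fractional offsets; fractional positions are read by bilinear
#' interpolation and positions outside the image contribute zero.  With all
#' offsets zero this reduces exactly to regular convolution.
#'
#' @param feature H x W x C array
#' @param weights K x K x C x O array
#' @param bias length-O vector
#' @param offsets Ho x Wo x (2*K*K) array; channels (2l, 2l+1) hold the
#'   (dy, dx) displacement of kernel position l = ki + K*kj
#' @param stride,pad convolution geometry
#' @return Ho x Wo x O array
#' @export
deformable_conv <- function(feature, weights, bias = NULL, offsets,
                            stride = 1L, pad = 1L) {
  K <- dim(weights)[1]
  if (is.null(bias)) bias <- numeric(dim(weights)[4])
  if (dim(offsets)[3] != 2 * K * K)
    stop("offsets must have one (dy, dx) pair per kernel position")
  cpp_dconv2d_fwd(feature, weights, bias, offsets, as.integer(stride),
                  as.integer(pad))
}

#' Initialise CBAM parameters for a C-channel feature map
#' @param channels number of channels C
#' @param reduction channel-MLP reduction ratio
#' @param spatial_kernel kernel size of the spatial-attention convolution
#' @return parameter list (`mlp1`, `mlp2`, `sconv`)
#' @export
init_cbam <- function(channels, reduction = 16L, spatial_kernel = 7L) {
  hidden <- max(1L, channels %/% reduction)
  p <- list(mlp1 = init_linear(channels, hidden),
            mlp2 = init_linear(hidden, channels),
            sconv = init_conv(spatial_kernel, 2L, 1L),
            spatial_kernel = spatial_kernel)
  # open-gate initialisation: Mc, Ms start near sigmoid(1) ~ 0.73 so early
  # training is not throttled and attention is learned rather than imposed
  p$mlp2$b$value[] <- 1
  p$sconv$b$value[] <- 1
  p
}

ag_channel_attention <- function(f, pars) {
  avg <- ag_gap(f); mx <- ag_gmp(f)
  mlp <- function(v) ag_linear(ag_relu(ag_linear(v, pars$mlp1$w, pars$mlp1$b)),
                               pars$mlp2$w, pars$mlp2$b)
  s <- ag_add(mlp(avg), mlp(mx))
  ag_sigmoid(new_ag(as.numeric(s$value), list(s), function(g) list(matrix(g, nrow = 1))))
}

ag_spatial_attention <- function(f, pars) {
  stack <- ag_concat_c(list(ag_cmean(f), ag_cmax(f)))
  pad <- (pars$spatial_kernel - 1L) %/% 2L
  lg <- ag_conv2d(stack, pars$sconv$w, pars$sconv$b, 1L, pad)
  ms <- ag_sigmoid(lg)
  # H x W x 1 -> H x W matrix node
  new_ag(ms$value[, , 1], list(ms), function(g) {
    list(array(g, dim = dim(ms$value)))
  })
}

ag_cbam <- function(f, pars) {
  mc <- ag_channel_attention(f, pars)
  f1 <- ag_scale_channels(f, mc)
  ms <- ag_spatial_attention(f1, pars)
  ag_scale_map(f1, ms)
}

#' Channel attention weights of a feature map
#'
#' Global average pooling and global max pooling in parallel, a shared
#' two-layer MLP applied to both pooled vectors, element-wise addition and
#' a sigmoid.
#'
#' @param feature H x W x C array
#' @param params CBAM parameters from [init_cbam()]
#' @return length-C vector of weights in (0, 1)
#' @export
channel_attention <- function(feature, params) {
  as.numeric(ag_channel_attention(ag_const(feature), params)$value)
}

#' Spatial attention map of a feature map
#'
#' Channel-wise average and max pooling stacked into an H x W x 2 map,
#' convolved to one channel and passed through a sigmoid.
#'
#' @inheritParams channel_attention
#' @return H x W matrix of weights in (0, 1)
#' @export
spatial_attention <- function(feature, params) {
  ag_spatial_attention(ag_const(feature), params)$value
}

#' CBAM: channel-then-spatial attention gating
#'
#' F1 = Mc(F) (.) F, then F' = Ms(F1) (.) F1.
#' @inheritParams channel_attention
#' @return gated H x W x C array
#' @export
cbam <- function(feature, params) {
  ag_cbam(ag_const(feature), params)$value
}

# ---- backbone construction -------------------------------------------------

#' Initialise backbone parameters
#'
#' @param widths per-branch channel widths, highest resolution first
#' @param stages number of exchange stages
#' @param dcn use deformable convolution in the final block of each branch
#' @param use_cbam apply CBAM to each pyramid output level
#' @param reduction CBAM channel reduction ratio
#' @param pyramid_channels common channel width of P3/P4/P5
#' @param offset_scale multiplier on predicted deformable offsets; values
#'   below 1 slow offset growth (an offset learning-rate multiplier)
#' @return backbone parameter tree
#' @export
init_backbone <- function(widths = c(8L, 16L, 32L), stages = 2L, dcn = TRUE,
                          use_cbam = TRUE, reduction = 4L,
                          pyramid_channels = 32L, offset_scale = 1,
                          spatial_kernel = 7L) {
  B <- length(widths)
  L <- list(widths = widths, stages = stages, dcn = dcn, use_cbam = use_cbam,
            pyramid_channels = pyramid_channels, offset_scale = offset_scale)
  cn <- function(k, cin, cout) c(init_conv(k, cin, cout),
                                 list(norm = init_groupnorm(cout)))
  L$stem1 <- cn(3, 1, widths[1])
  L$stem2 <- cn(3, widths[1], widths[1])
  if (B > 1)
    L$trans <- lapply(2:B, function(i) cn(3, widths[i - 1], widths[i]))
  L$stage <- lapply(seq_len(stages), function(s) {
    st <- list()
    st$branch <- lapply(seq_len(B), function(i) {
      br <- list(conv = cn(3, widths[i], widths[i]))
      if (dcn && s == stages)
        br$offs <- init_conv_zero(3, widths[i], 18L)   # 2 * 3 * 3 offsets
      br
    })
    st$ex <- lapply(seq_len(B), function(i) {
      lapply(seq_len(B), function(j) {
        if (j == i) NULL
        else if (j < i) cn(3, widths[j], widths[i])   # down: stride 2
        else cn(1, widths[j], widths[i])              # up: 1x1 + ups
      })
    })
    st
  })
  L$fuse <- cn(1, sum(widths), pyramid_channels)
  if (use_cbam)
    L$cbam <- lapply(1:3, function(k) init_cbam(pyramid_channels, reduction,
                                                spatial_kernel))
  L
}

# conv + groupnorm (+ relu) block
cnr <- function(x, ly, stride = 1L, pad = 1L, relu = TRUE) {
  h <- ag_conv2d(x, ly$w, ly$b, stride, pad)
  h <- ag_groupnorm(h, ly$norm$gamma, ly$norm$beta, 8L)
  if (relu) ag_relu(h) else h
}

# forward through the backbone; x is an ag tensor H x W x 1
backbone_forward <- function(bb, x) {
  B <- length(bb$widths)
  h <- cnr(x, bb$stem1, 2L, 1L)
  h <- cnr(h, bb$stem2, 2L, 1L)
  branches <- vector("list", B)
  branches[[1]] <- h
  if (B > 1) for (i in 2:B) {
    branches[[i]] <- cnr(branches[[i - 1]], bb$trans[[i - 1]], 2L, 1L)
  }
  for (s in seq_len(bb$stages)) {
    st <- bb$stage[[s]]
    conv_out <- vector("list", B)
    for (i in seq_len(B)) {
      br <- st$branch[[i]]
      if (!is.null(br$offs)) {
        offs <- ag_conv2d(branches[[i]], br$offs$w, br$offs$b, 1L, 1L)
        if (!is.null(bb$offset_scale) && bb$offset_scale != 1)
          offs <- ag_mul_s(offs, bb$offset_scale)
        h <- ag_dconv2d(branches[[i]], br$conv$w, br$conv$b, offs, 1L, 1L)
        h <- ag_groupnorm(h, br$conv$norm$gamma, br$conv$norm$beta, 8L)
        conv_out[[i]] <- ag_relu(h)
      } else {
        conv_out[[i]] <- cnr(branches[[i]], br$conv, 1L, 1L)
      }
    }
    nb <- vector("list", B)
    for (i in seq_len(B)) {
      acc <- conv_out[[i]]
      for (j in seq_len(B)) {
        if (j == i) next
        ex <- st$ex[[i]][[j]]
        if (j < i) {           # downsample j -> i
          t <- cnr(conv_out[[j]], ex, 2L, 1L, relu = FALSE)
          reps <- i - j - 1L
          while (reps > 0L) { t <- ag_avgpool2(t); reps <- reps - 1L }
        } else {               # upsample j -> i
          t <- cnr(conv_out[[j]], ex, 1L, 0L, relu = FALSE)
          reps <- j - i
          while (reps > 0L) { t <- ag_upsample2x(t); reps <- reps - 1L }
        }
        acc <- ag_add(acc, t)
      }
      nb[[i]] <- ag_relu(acc)
    }
    branches <- nb
  }
  ups <- lapply(seq_len(B), function(i) {
    t <- branches[[i]]
    reps <- i - 1L
    while (reps > 0L) { t <- ag_upsample2x(t); reps <- reps - 1L }
    t
  })
  fused <- cnr(ag_concat_c(ups), bb$fuse, 1L, 0L)
  p3 <- ag_avgpool2(fused)
  p4 <- ag_avgpool2(p3)
  p5 <- ag_avgpool2(p4)
  pyr <- list(P3 = p3, P4 = p4, P5 = p5)
  if (bb$use_cbam)
    pyr <- lapply(1:3, function(k) ag_cbam(pyr[[k]], bb$cbam[[k]]))
  names(pyr) <- c("P3", "P4", "P5")
  pyr
}

#' Extract the 3-level feature pyramid of an image
#'
#' @param model a model from [build_model()] (or a bare backbone parameter
#'   tree from [init_backbone()])
#' @param image square numeric matrix with side divisible by 32
#' @return list of arrays `P3`, `P4`, `P5` at strides 8/16/32
#' @export
extract_pyramid <- function(model, image) {
  bb <- if (!is.null(model$backbone)) model$backbone else model
  if (nrow(image) %% 32 != 0 || ncol(image) != nrow(image))
    stop("input must be square with side divisible by 32; resize first")
  x <- ag_const(array(image, dim = c(nrow(image), ncol(image), 1)))
  lapply(backbone_forward(bb, x), function(t) t$value)
}
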