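# Mask branch: coarse per-class mask prediction on the ROI grid, then
# uncertainty-guided point refinement.  The most ambiguous points -- those
# with predicted foreground probability closest to 0.5 -- are re-predicted
# by a small shared MLP at each bilinear upsampling step.

#' Initialise coarse mask head parameters
#' @param channels ROI feature channels
#' @param n_classes number of foreground classes
#' @return parameter list (two 3x3 convs + 1x1 class conv)
#' @export
init_mask_head <- function(channels, n_classes = 3L) {
  list(c1 = c(init_conv(3, channels, channels),
              list(norm = init_groupnorm(channels))),
       c2 = c(init_conv(3, channels, channels),
              list(norm = init_groupnorm(channels))),
       out = init_conv(1, channels, n_classes, scale = 0.1),
       n_classes = n_classes)
}

ag_coarse_mask <- function(pooled, pars) {
  h <- cnr(pooled, pars$c1, 1L, 1L)
  h <- cnr(h, pars$c2, 1L, 1L)
  ag_conv2d(h, pars$out$w, pars$out$b, 1L, 0L)   # logits G x G x n_classes
}

#' Coarse mask probabilities for one pooled ROI
#'
#' @param roi_features G x G x C pooled ROI feature array
#' @param params parameters from [init_mask_head()]
#' @return G x G x n_classes array of probabilities in [0, 1]
#' @export
coarse_mask_head <- function(roi_features, params) {
  1 / (1 + exp(-ag_coarse_mask(ag_const(roi_features), params)$value))
}

uncertainty <- function(p) abs(p - 0.5)

#' Select training points for the point head
#'
#' kN candidate points are drawn uniformly in the unit square; the beta*N
#' most uncertain of them (probability closest to 0.5 under bilinear
#' interpolation of `prob_grid`) are kept, topped up with (1 - beta)*N
#' fresh uniform points.
#'
#' @param prob_grid G x G matrix of foreground probabilities
#' @param k oversampling factor (> 1)
#' @param beta fraction of uncertainty-ranked points, in [0, 1]
#' @param n_points number of points N to return
#' @param rng optional integer seed; `NULL` uses the current RNG stream
#' @return list: `points` (N x 2 normalised (u, v)), `probability`,
#'   `uncertainty`
#' @export
select_training_points <- function(prob_grid, k = 3, beta = 0.75, n_points,
                                   rng = NULL) {
  stopifnot(k > 1, beta >= 0, beta <= 1)
  if (!all(is.finite(prob_grid))) stop("non-finite probabilities")
  if (!is.null(rng)) {
    old <- .Random.seed_guard(as.numeric(rng) %% 2147483647)
    on.exit(old(), add = TRUE)
  }
  n_cand <- ceiling(k * n_points)
  cand <- cbind(stats::runif(n_cand), stats::runif(n_cand))
  g <- array(prob_grid, dim = c(dim(prob_grid), 1))
  p <- as.numeric(cpp_point_sample_fwd(g, cand))
  n_unc <- round(beta * n_points)
  sel <- if (n_unc > 0) order(uncertainty(p))[seq_len(n_unc)] else integer(0)
  pts <- cand[sel, , drop = FALSE]
  n_rand <- n_points - n_unc
  if (n_rand > 0)
    pts <- rbind(pts, cbind(stats::runif(n_rand), stats::runif(n_rand)))
  pp <- as.numeric(cpp_point_sample_fwd(g, pts))
  list(points = pts, probability = pp, uncertainty = uncertainty(pp),
       candidates = cand, candidate_probability = p, n_uncertain = n_unc)
}

#' Select the most uncertain grid points for inference refinement
#'
#' Picks the `n_points` grid cells whose probability is closest to 0.5,
#' ties broken by row-major cell index.
#'
#' @param prob_grid H x W probability matrix
#' @param n_points number of points to select
#' @return list: `idx` (n x 2 of (row, col), 1-based), `points`
#'   (normalised centre coordinates), `probability`, `uncertainty`
#' @export
select_inference_points <- function(prob_grid, n_points) {
  if (!all(is.finite(prob_grid))) stop("non-finite probabilities")
  H <- nrow(prob_grid); W <- ncol(prob_grid)
  n_points <- min(n_points, H * W)
  rows <- rep(seq_len(H), each = W)
  cols <- rep(seq_len(W), H)
  p <- prob_grid[cbind(rows, cols)]       # row-major traversal
  u <- uncertainty(p)
  sel <- order(u)[seq_len(n_points)]      # order() is stable: row-major ties
  list(idx = cbind(row = rows[sel], col = cols[sel]),
       points = cbind((cols[sel] - 0.5) / W, (rows[sel] - 0.5) / H),
       probability = p[sel], uncertainty = u[sel])
}

#' Point-wise feature vectors: fine features + coarse probabilities
#'
#' Each point's representation is the bilinear sample of the fine feature
#' map concatenated with the bilinear sample of the coarse probability
#' grid at the same normalised location.
#'
#' @param fine_feature_map H x W x C array
#' @param coarse_prob_grid G x G (or G x G x K) probability array
#' @param points N x 2 normalised (u, v) coordinates
#' @return N x (C + K) matrix
#' @export
point_features <- function(fine_feature_map, coarse_prob_grid, points) {
  if (is.matrix(fine_feature_map))
    fine_feature_map <- array(fine_feature_map, dim = c(dim(fine_feature_map), 1))
  if (is.matrix(coarse_prob_grid))
    coarse_prob_grid <- array(coarse_prob_grid, dim = c(dim(coarse_prob_grid), 1))
  cbind(cpp_point_sample_fwd(fine_feature_map, points),
        cpp_point_sample_fwd(coarse_prob_grid, points))
}

#' Initialise the point head MLP
#'
#' A small shared MLP applied independently to every point vector.
#' @param in_dim point feature length
#' @param hidden hidden width (256 at full scale)
#' @param n_layers number of hidden layers (3 at full scale)
#' @param n_classes output classes
#' @return parameter list
#' @export
init_point_head <- function(in_dim, hidden = 256L, n_layers = 3L,
                            n_classes = 3L) {
  dims <- c(in_dim, rep(hidden, n_layers))
  list(hidden = lapply(seq_len(n_layers),
                       function(i) init_linear(dims[i], dims[i + 1])),
       out = init_linear(hidden, n_classes, scale = 0.1),
       n_classes = n_classes)
}

ag_point_head <- function(x, pars) {
  h <- x
  for (ly in pars$hidden) h <- ag_relu(ag_linear(h, ly$w, ly$b))
  ag_linear(h, pars$out$w, pars$out$b)
}

#' Point head foreground probabilities
#'
#' @param per_point N x D matrix of point feature vectors
#' @param params parameters from [init_point_head()]
#' @return N x n_classes matrix of probabilities in (0, 1)
#' @export
point_head <- function(per_point, params) {
  1 / (1 + exp(-ag_point_head(ag_const(per_point), params)$value))
}

#' Iterative uncertainty-guided mask refinement
#'
#' Starting from a coarse probability grid, each step doubles the
#' resolution by bilinear interpolation, selects the `n_per_step` most
#' uncertain grid points and replaces their probabilities with the output
#' of `point_predict`.  All other points keep their interpolated values.
#'
#' @param coarse_grid G x G probability matrix
#' @param steps number of 2x subdivision steps (>= 0)
#' @param n_per_step points re-predicted per step
#' @param point_predict function(points Nx2 normalised) -> N probabilities;
#'   forcing it to return the interpolated values makes refinement a no-op
#' @return (G * 2^steps) square probability matrix
#' @export
iterative_refine <- function(coarse_grid, steps, n_per_step, point_predict) {
  g <- coarse_grid
  if (steps <= 0) return(g)
  for (s in seq_len(steps)) {
    g <- cpp_upsample2x_fwd(array(g, dim = c(dim(g), 1)))[, , 1]
    sel <- select_inference_points(g, n_per_step)
    g[sel$idx] <- point_predict(sel$points)
  }
  g
}
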