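# Composite training loss: weighted cross entropy for classification,
# smooth-L1 on box regression over positive ROIs only, binary cross
# entropy for coarse-grid and point-head mask predictions, combined as
# total = lambda1 * Lcls + lambda2 * Lbbox + lambda3 * Lmask with
# lambda = (1, 1.2, 1).

#' Weighted classification cross entropy
#'
#' L = (1/N) * sum_i w[y_i] * (-log p_i[y_i]); doubling a class weight
#' doubles that class's per-sample contribution.
#'
#' @param pred_probs N x K matrix of predicted class probabilities
#' @param true_labels integer labels in 1..K
#' @param class_weights optional length-K weights (default all 1)
#' @return scalar loss
#' @export
cls_loss <- function(pred_probs, true_labels, class_weights = NULL) {
  p <- matrix(pred_probs, ncol = if (is.matrix(pred_probs)) ncol(pred_probs)
              else length(pred_probs))
  n <- nrow(p)
  if (is.null(class_weights)) class_weights <- rep(1, ncol(p))
  py <- p[cbind(seq_len(n), true_labels)]
  sum(class_weights[true_labels] * -log(pmax(py, 1e-12))) / n
}

#' Smooth-L1 loss
#'
#' Elementwise 0.5 d^2 for |d| < 1 and |d| - 0.5 otherwise, summed over the
#' coordinates of `t - t_pred`.
#'
#' @param t regression target(s)
#' @param t_pred prediction(s), default 0 so `smooth_l1(d)` evaluates the
#'   kernel at a raw difference
#' @return scalar
#' @export
smooth_l1 <- function(t, t_pred = 0) {
  d <- t - t_pred
  sum(ifelse(abs(d) < 1, 0.5 * d^2, abs(d) - 0.5))
}

#' Box regression loss over positive ROIs
#'
#' (1/Nreg) * sum_i P'_i * smoothL1(t_i - t'_i); only positives
#' (P'_i = 1) contribute.
#'
#' @param preds n x 4 predicted regression values
#' @param targets n x 4 targets
#' @param positives length-n 0/1 indicator of positive ROIs
#' @param n_reg normaliser Nreg; defaults to the number of ROIs n
#' @return scalar loss
#' @export
bbox_loss <- function(preds, targets, positives, n_reg = NULL) {
  preds <- matrix(preds, ncol = 4); targets <- matrix(targets, ncol = 4)
  if (is.null(n_reg)) n_reg <- length(positives)
  if (n_reg == 0 || !any(positives == 1)) return(0)
  idx <- which(positives == 1)
  s <- sum(vapply(idx, function(i) smooth_l1(targets[i, ], preds[i, ]),
                  numeric(1)))
  s / n_reg
}

#' Binary cross-entropy mask loss
#'
#' Mean BCE -y log y' - (1-y) log(1-y') over the coarse-grid cells, plus
#' the mean over refinement points when point predictions are supplied.
#'
#' @param y_pred predicted coarse probabilities (any shape)
#' @param y matching ground-truth values in [0, 1]
#' @param point_pred optional point-head probabilities
#' @param point_y optional point ground truth
#' @return scalar loss
#' @export
mask_loss <- function(y_pred, y, point_pred = NULL, point_y = NULL) {
  bce <- function(p, t) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    mean(-t * log(p) - (1 - t) * log(1 - p))
  }
  l <- bce(y_pred, y)
  if (!is.null(point_pred)) l <- l + bce(point_pred, point_y)
  l
}

#' Total multi-task loss
#'
#' total = lambda1 * Lcls + lambda2 * Lbbox + lambda3 * Lmask.
#'
#' @param l_cls,l_bbox,l_mask branch losses
#' @param lambda length-3 branch weights, default c(1, 1.2, 1)
#' @return scalar
#' @export
total_loss <- function(l_cls, l_bbox, l_mask, lambda = c(1, 1.2, 1)) {
  lambda[1] * l_cls + lambda[2] * l_bbox + lambda[3] * l_mask
}

#' Inverse-frequency class weights
#'
#' w_c = T / (C * n_c) with T total instances and C the number of classes;
#' the rarest class receives the largest weight.
#'
#' @param class_counts named or plain vector of per-class instance counts
#' @return weights, same names
#' @export
inverse_frequency_weights <- function(class_counts) {
  total <- sum(class_counts)
  total / (length(class_counts) * class_counts)
}
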