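# Training-time data augmentation: horizontal/vertical flips, small random
# rotation, central crop-and-rescale.  Masks and boxes transform with the
# image; instances whose mask is cropped away entirely are dropped.

rotate_matrix <- function(m, angle_deg, nearest = FALSE) {
  if (angle_deg == 0) return(m)
  H <- nrow(m); W <- ncol(m)
  th <- angle_deg * pi / 180
  cy <- H / 2; cx <- W / 2
  # inverse mapping: output pixel centre -> input position
  xs <- matrix(seq_len(W) - 0.5 - cx, H, W, byrow = TRUE)
  ys <- matrix(seq_len(H) - 0.5 - cy, H, W)
  u <- cos(th) * xs + sin(th) * ys + cx
  v <- -sin(th) * xs + cos(th) * ys + cy
  if (nearest) {
    r <- floor(v) + 1L; c <- floor(u) + 1L
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    out <- matrix(0, H, W)
    out[ok] <- m[cbind(r[ok], c[ok])]
    out
  } else {
    g <- array(m, dim = c(H, W, 1))
    pts <- cbind(as.numeric(u) / W, as.numeric(v) / H)
    inside <- pts[, 1] >= 0 & pts[, 1] <= 1 & pts[, 2] >= 0 & pts[, 2] <= 1
    vals <- as.numeric(cpp_point_sample_fwd(g, pts))
    vals[!inside] <- 0
    matrix(vals, H, W)
  }
}

central_crop_matrix <- function(m, scale, nearest = FALSE) {
  if (scale >= 1) return(m)
  H <- nrow(m); W <- ncol(m)
  side_h <- round(H * scale); side_w <- round(W * scale)
  r0 <- floor((H - side_h) / 2); c0 <- floor((W - side_w) / 2)
  crop <- m[r0 + seq_len(side_h), c0 + seq_len(side_w)]
  rs <- resize_input(crop * 1, masks = if (nearest) list(crop > 0.5) else NULL,
                     target = H)
  if (nearest) rs$masks[[1]] else rs$image
}

#' Deterministic geometric augmentation of one sample
#'
#' @param image numeric matrix
#' @param instances list of instance records (`category`, `mask`)
#' @param hflip,vflip logical flips
#' @param angle rotation in degrees (bilinear image / nearest masks)
#' @param crop_scale central crop fraction in (0, 1]; the crop is resized
#'   back to the original side
#' @return list(image, instances) with refreshed bbox/area; fully cropped
#'   instances dropped
#' @export
augment_sample <- function(image, instances, hflip = FALSE, vflip = FALSE,
                           angle = 0, crop_scale = 1) {
  tf_img <- function(m, nearest) {
    if (hflip) m <- m[, rev(seq_len(ncol(m)))]
    if (vflip) m <- m[rev(seq_len(nrow(m))), ]
    m <- rotate_matrix(m, angle, nearest)
    central_crop_matrix(m, crop_scale, nearest)
  }
  img <- tf_img(image, nearest = FALSE)
  insts <- list()
  for (inst in instances) {
    mk <- tf_img(inst$mask * 1, nearest = TRUE) > 0.5
    if (sum(mk) == 0) next
    insts[[length(insts) + 1L]] <- new_instance(inst$category, mk)
  }
  list(image = img, instances = insts)
}

#' Random augmentation drawing from the configured distributions
#'
#' Flips with probability 0.5 each, rotation uniform in +/-15 degrees,
#' central crop scale uniform in [0.8, 1]; each applied with
#' probability 0.5.
#'
#' @param image,instances sample to augment
#' @param rng optional integer seed; `NULL` uses the current RNG stream
#' @param rotate,crop enable the rotation / central-crop components (the
#'   desk profile keeps flips only)
#' @return augmented list(image, instances)
#' @export
augment <- function(image, instances, rng = NULL, rotate = TRUE,
                    crop = TRUE) {
  if (!is.null(rng)) {
    old <- .Random.seed_guard(as.numeric(rng) %% 2147483647)
    on.exit(old(), add = TRUE)
  }
  augment_sample(image, instances,
                 hflip = stats::runif(1) < 0.5,
                 vflip = stats::runif(1) < 0.5,
                 angle = if (rotate && stats::runif(1) < 0.5)
                   stats::runif(1, -15, 15) else 0,
                 crop_scale = if (crop && stats::runif(1) < 0.5)
                   stats::runif(1, 0.8, 1) else 1)
}
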