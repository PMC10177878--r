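# Synthetic pelvic phantom generator.
#
# Emulates the statistical structure of sagittal T2-weighted uterine MRI:
# a dark annular uterine wall around a bright, very thin uterine cavity,
# dark myoma blobs of widely varying size and position, low-contrast
# distractor structures (bright bladder-like discs, a dark spine-like
# column), a smooth multiplicative bias field, and additive noise.

#' Categories of the uterine-region dataset
#'
#' Fixed COCO category table: id 1 uterine_wall, 2 uterine_cavity, 3 myoma.
#' @return data.frame with columns `id`, `name`
#' @export
uterseg_categories <- function() {
  data.frame(id = 1:3,
             name = c("uterine_wall", "uterine_cavity", "myoma"),
             stringsAsFactors = FALSE)
}

#' Configuration for the synthetic pelvic phantom
#'
#' @param image_size pixels per side of the square image (>= 64)
#' @param n_images number of images in a dataset
#' @param myoma_count_range inclusive integer range of myomas per image
#' @param cavity_thickness_frac cavity half-thickness as a fraction of the
#'   wall's inner radius; the cavity is a thin elongated ellipse
#' @param contrast_levels named mean intensities in [0,1] for
#'   `background`, `wall`, `cavity`, `myoma`; must satisfy
#'   cavity > wall > myoma
#' @param bias_amplitude fractional peak of the smooth multiplicative
#'   bias field (0 disables it)
#' @param noise_sigma standard deviation of additive Gaussian noise
#' @param distractor_count_range integer range of bright distractor discs
#' @param seed RNG seed; identical seed + config gives byte-identical data
#' @return a `phantom_config` list
#' @export
phantom_config <- function(image_size = 512, n_images = 100,
                           myoma_count_range = c(0L, 4L),
                           cavity_thickness_frac = 0.15,
                           contrast_levels = c(background = 0.20, wall = 0.40,
                                               cavity = 0.85, myoma = 0.12),
                           bias_amplitude = 0.15, noise_sigma = 0.02,
                           distractor_count_range = c(1L, 3L), seed = 0L) {
  if (image_size < 64) stop("image_size must be >= 64 to fit the wall annulus")
  cl <- contrast_levels
  need <- c("background", "wall", "cavity", "myoma")
  if (!all(need %in% names(cl))) stop("contrast_levels must name ", paste(need, collapse = ", "))
  if (!(cl["cavity"] > cl["wall"] && cl["wall"] > cl["myoma"]))
    stop("contrast ordering violated: need cavity > wall > myoma")
  if (myoma_count_range[1] < 0 || myoma_count_range[2] < myoma_count_range[1])
    stop("invalid myoma_count_range")
  structure(list(image_size = as.integer(image_size),
                 n_images = as.integer(n_images),
                 myoma_count_range = as.integer(myoma_count_range),
                 cavity_thickness_frac = cavity_thickness_frac,
                 contrast_levels = cl,
                 bias_amplitude = bias_amplitude,
                 noise_sigma = noise_sigma,
                 distractor_count_range = as.integer(distractor_count_range),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# cached pixel-centre coordinate grids, one per image size
.grid_cache <- new.env(parent = emptyenv())

pixel_grids <- function(S) {
  key <- as.character(S)
  g <- .grid_cache[[key]]
  if (is.null(g)) {
    g <- list(xs = matrix(seq_len(S) - 0.5, S, S, byrow = TRUE),
              ys = matrix(seq_len(S) - 0.5, S, S))
    .grid_cache[[key]] <- g
  }
  g
}

# pixel-centre ellipse membership; 0-based continuous coords, theta in rad
ellipse_mask <- function(S, cx, cy, a, b, theta) {
  g <- pixel_grids(S)
  xs <- g$xs; ys <- g$ys
  dx <- xs - cx; dy <- ys - cy
  ct <- cos(theta); st <- sin(theta)
  u <- dx * ct + dy * st
  v <- -dx * st + dy * ct
  (u / a)^2 + (v / b)^2 <= 1
}

tight_bbox <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  # 0-based (x, y, w, h), x/y top-left
  c(cols[1] - 1, rows[1] - 1,
    cols[length(cols)] - cols[1] + 1, rows[length(rows)] - rows[1] + 1)
}

new_instance <- function(category, mask) {
  stopifnot(sum(mask) > 0)
  list(category = category, mask = mask, bbox = tight_bbox(mask),
       area = sum(mask))
}

#' Generate one synthetic phantom image with its instance records
#'
#' @param config a [phantom_config()]
#' @param index image index (1-based); the per-image RNG stream is derived
#'   from `config$seed` and `index`, so each image is individually
#'   reproducible
#' @return list with `image` (matrix of intensities in [0,1]) and
#'   `instances` (list of records with `category`, `mask`, `bbox`, `area`)
#' @export
generate_phantom <- function(config, index = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  S <- config$image_size
  cl <- config$contrast_levels
  old <- .Random.seed_guard((as.numeric(config$seed) * 10007 +
                               as.numeric(index)) %% 2147483647)
  on.exit(old(), add = TRUE)

  img <- matrix(cl["background"], S, S)
  instances <- list()

  # --- distractors (no instance records) -----------------------------------
  n_dis <- sample_range(config$distractor_count_range)
  # uterus geometry drawn first so distractors can avoid it
  cx <- S * stats::runif(1, 0.42, 0.58)
  cy <- S * stats::runif(1, 0.42, 0.58)
  theta <- stats::runif(1, -pi / 4, pi / 4)
  a_out <- S * stats::runif(1, 0.22, 0.30)
  b_out <- S * stats::runif(1, 0.16, 0.24)
  u_in <- stats::runif(1, 0.55, 0.68)
  a_in <- u_in * a_out; b_in <- u_in * b_out

  if (n_dis > 0) {
    for (d in seq_len(n_dis)) {
      for (try in 1:20) {
        dxk <- stats::runif(1, 0.08, 0.92) * S
        dyk <- stats::runif(1, 0.08, 0.92) * S
        rk <- stats::runif(1, 0.03, 0.08) * S
        if (sqrt((dxk - cx)^2 + (dyk - cy)^2) > a_out + rk + 0.02 * S) break
      }
      m <- ellipse_mask(S, dxk, dyk, rk, rk * stats::runif(1, 0.8, 1.2),
                        stats::runif(1, 0, pi))
      img[m] <- cl["cavity"] * stats::runif(1, 0.85, 1.0)
    }
  }
  # dark spine-like vertical column at the left or right margin
  col_x <- if (stats::runif(1) < 0.5) stats::runif(1, 0.03, 0.08) else
    stats::runif(1, 0.92, 0.97)
  col_w <- stats::runif(1, 0.03, 0.05)
  jcols <- which(abs((seq_len(S) - 0.5) / S - col_x) < col_w / 2)
  img[, jcols] <- cl["myoma"] + 0.05

  # --- uterus --------------------------------------------------------------
  outer <- ellipse_mask(S, cx, cy, a_out, b_out, theta)
  inner <- ellipse_mask(S, cx, cy, a_in, b_in, theta)
  wall <- outer & !inner
  junction <- cl["wall"] + 0.15 * (cl["cavity"] - cl["wall"])
  img[inner] <- junction
  img[wall] <- cl["wall"]
  instances[[length(instances) + 1L]] <- new_instance("uterine_wall", wall)

  # cavity: thin elongated ellipse inside the inner region
  b_cav <- max(config$cavity_thickness_frac * b_in, 1.2)
  cavity <- ellipse_mask(S, cx, cy, 0.78 * a_in, b_cav, theta)
  cavity <- cavity & inner

  # --- myomas --------------------------------------------------------------
  n_myo <- sample_range(config$myoma_count_range)
  myo_masks <- list()
  if (n_myo > 0) {
    for (m in seq_len(n_myo)) {
      type <- sample(c("intramural", "submucosal", "subserosal"), 1)
      phi <- stats::runif(1, 0, 2 * pi)
      rho <- switch(type,
                    intramural = 1.0,
                    submucosal = 0.45,
                    subserosal = 1.02)
      aref <- switch(type,
                     intramural = (a_in + a_out) / 2,
                     submucosal = a_in,
                     subserosal = a_out)
      bref <- switch(type,
                     intramural = (b_in + b_out) / 2,
                     submucosal = b_in,
                     subserosal = b_out)
      ex <- rho * aref * cos(phi); ey <- rho * bref * sin(phi)
      mx <- cx + ex * cos(theta) - ey * sin(theta)
      my <- cy + ex * sin(theta) + ey * cos(theta)
      rr <- S * stats::runif(1, 0.04, 0.14)
      mm <- ellipse_mask(S, mx, my, rr, rr * stats::runif(1, 0.8, 1.25),
                         stats::runif(1, 0, pi))
      mm <- mm & !cavity                   # cavity stays visible and bright
      if (sum(mm) == 0) next
      img[mm] <- max(cl["myoma"] + stats::runif(1, -0.03, 0.03), 0.01)
      myo_masks[[length(myo_masks) + 1L]] <- mm
    }
  }
  # cavity painted last so its pixels keep the configured intensity
  img[cavity] <- cl["cavity"]
  instances[[length(instances) + 1L]] <- new_instance("uterine_cavity", cavity)
  for (mm in myo_masks)
    instances[[length(instances) + 1L]] <- new_instance("myoma", mm)

  # --- bias field and noise ------------------------------------------------
  if (config$bias_amplitude > 0) {
    u <- matrix((seq_len(S) - 0.5) / S * 2 - 1, S, S, byrow = TRUE)
    v <- matrix((seq_len(S) - 0.5) / S * 2 - 1, S, S)
    co <- stats::rnorm(5)
    f <- co[1] * u + co[2] * v + co[3] * u * v + co[4] * u^2 + co[5] * v^2
    mx <- max(abs(f))
    if (mx > 0) f <- f / mx * log1p(config$bias_amplitude)
    img <- img * exp(f)
  }
  if (config$noise_sigma > 0)
    img <- img + matrix(stats::rnorm(S * S, 0, config$noise_sigma), S, S)
  img <- pmin(pmax(img, 0), 1)

  list(image = img, instances = instances)
}

sample_range <- function(r) {
  if (r[1] == r[2]) return(r[1])
  sample(seq.int(r[1], r[2]), 1)
}

# Seed the session RNG reproducibly and return a restorer closure.
.Random.seed_guard <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  saved <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", saved, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Generate a COCO-format synthetic dataset on disk
#'
#' Writes `images/{split}/` 16-bit grayscale TIFFs and
#' `annotations/{split}.json` COCO files for splits train/val/test.
#'
#' @param config a [phantom_config()]
#' @param dir output directory (created if missing)
#' @param split_ratio positive weights for (train, val, test); normalised to
#'   sum to one; image counts are the rounded ratio shares
#' @return invisible manifest list: per-split image data.frames and counts
#' @export
generate_dataset <- function(config, dir, split_ratio = c(8, 1, 1)) {
  stopifnot(inherits(config, "phantom_config"))
  if (any(split_ratio <= 0)) stop("split ratios must be positive")
  n <- config$n_images
  if (n < length(split_ratio)) stop("n_images smaller than the number of splits")
  r <- split_ratio / sum(split_ratio)
  counts <- diff(c(0L, round(cumsum(r) * n)))
  splits <- c("train", "val", "test")

  old <- .Random.seed_guard(as.numeric(config$seed) %% 2147483647)
  on.exit(old(), add = TRUE)
  perm <- sample(n)
  assign <- rep(splits, counts)[order(perm)]  # deterministic random split
  old()

  for (s in splits) {
    dir.create(file.path(dir, "images", s), recursive = TRUE,
               showWarnings = FALSE)
  }
  dir.create(file.path(dir, "annotations"), recursive = TRUE,
             showWarnings = FALSE)

  manifest <- list()
  for (s in splits) {
    idxs <- which(assign == s)
    imgs <- data.frame(id = integer(0), file_name = character(0),
                       width = integer(0), height = integer(0))
    anns <- list()
    for (i in idxs) {
      ph <- generate_phantom(config, i)
      fn <- sprintf("img_%05d.tiff", i)
      tiff::writeTIFF(ph$image, file.path(dir, "images", s, fn),
                      bits.per.sample = 16L, compression = "none")
      imgs <- rbind(imgs, data.frame(id = i, file_name = fn,
                                     width = config$image_size,
                                     height = config$image_size))
      for (inst in ph$instances)
        anns[[length(anns) + 1L]] <- c(inst, list(image_id = i))
    }
    write_coco(imgs, anns, file.path(dir, "annotations", paste0(s, ".json")))
    manifest[[s]] <- list(images = imgs, n_instances = length(anns))
  }
  invisible(manifest)
}
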