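# Image preprocessing chain: adaptive histogram equalization -> (optional
# external bias-field correction hook) -> Z-score normalization -> resize.

#' Contrast-limited adaptive histogram equalization
#'
#' Wraps tile-based CLAHE. `clip_limit` is the clipped fraction of a tile's
#' pixel count per histogram bin (skimage convention); internally mapped to
#' the multiple-of-mean-bin-height convention.
#'
#' @param image single-channel numeric matrix with finite values
#' @param clip_limit clipping fraction, default 0.01
#' @param tile_grid number of tiles per image side, default 8
#' @return equalized matrix with values in [0, 1]
#' @export
adaptive_hist_eq <- function(image, clip_limit = 0.01, tile_grid = 8L) {
  if (!all(is.finite(image))) stop("adaptive_hist_eq: non-finite pixel values")
  rng <- range(image)
  if (diff(rng) == 0) return(matrix(0.5, nrow(image), ncol(image)))
  x01 <- (image - rng[1]) / diff(rng)
  bins <- 256L
  tiles <- max(as.integer(tile_grid), 2L)   # CLAHE needs >= 2x2 tiles
  eb <- EBImage::Image(t(x01))
  out <- EBImage::clahe(eb, nx = tiles, ny = tiles, bins = bins,
                        limit = max(clip_limit * bins, 1))
  out <- t(EBImage::imageData(out))
  pmin(pmax(out, 0), 1)
}

#' Z-score intensity normalization
#'
#' Centers to mean 0 and scales to unit population standard deviation.
#' A constant image cannot be scaled and returns all zeros with a warning.
#'
#' @param image numeric matrix
#' @return normalized matrix
#' @export
zscore_normalize <- function(image) {
  mu <- mean(image)
  sd_pop <- sqrt(mean((image - mu)^2))
  if (sd_pop == 0) {
    warning("zscore_normalize: constant image, returning zeros")
    return(matrix(0, nrow(image), ncol(image)))
  }
  (image - mu) / sd_pop
}

#' Resize an image and its instance masks
#'
#' Bilinear interpolation for the image, nearest neighbour for masks; box
#' coordinates are rescaled by the same factor.
#'
#' @param image numeric matrix
#' @param masks optional list of logical matrices
#' @param target output side length (square), >= 32
#' @param boxes optional n x 4 matrix of (x, y, w, h) boxes to rescale
#' @return list with `image`, `masks`, `boxes`
#' @export
resize_input <- function(image, masks = NULL, target, boxes = NULL) {
  stopifnot(target >= 32)
  src <- nrow(image)
  if (src == target && ncol(image) == target) {
    return(list(image = image, masks = masks, boxes = boxes))
  }
  img <- t(EBImage::imageData(EBImage::resize(EBImage::Image(t(image)),
                                              w = target, h = target)))
  out_masks <- NULL
  if (!is.null(masks)) {
    out_masks <- lapply(masks, function(m) {
      r <- EBImage::resize(EBImage::Image(t(m * 1)), w = target, h = target,
                           filter = "none")
      t(EBImage::imageData(r)) > 0.5
    })
  }
  out_boxes <- if (!is.null(boxes)) boxes * (target / src) else NULL
  list(image = img, masks = out_masks, boxes = out_boxes)
}

#' Run the full preprocessing chain on one image
#'
#' Order: adaptive histogram equalization, optional external bias-field
#' correction hook, Z-score normalization, resize.
#'
#' @param image numeric matrix
#' @param target output side length
#' @param clip_limit,tile_grid CLAHE parameters
#' @param bias_hook optional function(matrix) -> matrix applied between
#'   equalization and normalization (e.g. an external N4 correction wrapped
#'   around temporary files); `NULL` skips the step
#' @param masks,boxes optional annotations resized alongside
#' @return list with `image`, `masks`, `boxes`
#' @export
preprocess_image <- function(image, target = nrow(image), clip_limit = 0.01,
                             tile_grid = 8L, bias_hook = NULL,
                             masks = NULL, boxes = NULL) {
  x <- adaptive_hist_eq(image, clip_limit, tile_grid)
  if (!is.null(bias_hook)) x <- bias_hook(x)
  x <- zscore_normalize(x)
  resize_input(x, masks = masks, target = target, boxes = boxes)
}

#' Preprocess a dataset directory
#'
#' Applies the preprocessing chain to every image of every split and writes
#' float TIFFs rescaled to [0, 1] plus a `meta.json` with the affine
#' (slope, intercept) per file so the exact Z-scored values can be
#' reconstructed at load time.
#'
#' @param in_dir dataset directory produced by [generate_dataset()]
#' @param out_dir output directory
#' @param target output side length
#' @param clip_limit,tile_grid,bias_hook see [preprocess_image()]
#' @return invisible list of written files
#' @export
preprocess_dir <- function(in_dir, out_dir, target = 512, clip_limit = 0.01,
                           tile_grid = 8L, bias_hook = NULL) {
  written <- list()
  for (split in c("train", "val", "test")) {
    src <- file.path(in_dir, "images", split)
    if (!dir.exists(src)) next
    dst <- file.path(out_dir, "images", split)
    dir.create(dst, recursive = TRUE, showWarnings = FALSE)
    meta <- list()
    for (fn in list.files(src, pattern = "\\.tiff?$")) {
      img <- load_gray_image(file.path(src, fn))
      pp <- preprocess_image(img, target = target, clip_limit = clip_limit,
                             tile_grid = tile_grid, bias_hook = bias_hook)
      z <- pp$image
      lo <- min(z); hi <- max(z)
      scl <- if (hi > lo) hi - lo else 1
      tiff::writeTIFF((z - lo) / scl, file.path(dst, fn),
                      bits.per.sample = 16L, compression = "none")
      meta[[fn]] <- list(slope = scl, intercept = lo)
      written[[length(written) + 1L]] <- file.path(dst, fn)
    }
    jsonlite::write_json(meta, file.path(dst, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
    ann <- file.path(in_dir, "annotations", paste0(split, ".json"))
    if (file.exists(ann)) {
      dir.create(file.path(out_dir, "annotations"), recursive = TRUE,
                 showWarnings = FALSE)
      file.copy(ann, file.path(out_dir, "annotations", paste0(split, ".json")),
                overwrite = TRUE)
    }
  }
  invisible(written)
}

#' Load a grayscale image file as a numeric matrix
#' @param path TIFF or PNG path
#' @return numeric matrix (rows = y)
#' @export
load_gray_image <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    r <- tiff::readTIFF(path)
    r
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}
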