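# COCO-format annotation I/O.
#
# Masks are encoded as a single polygon traced along pixel edges when the
# region is simply connected (one boundary loop), and as uncompressed
# column-major run-length encoding otherwise (e.g. the annular uterine
# wall).  Both encodings round-trip pixel-for-pixel: polygons follow the
# integer pixel grid and are rasterised by even-odd scanline fill over
# pixel centres.

# ---- boundary tracing ------------------------------------------------------

# Returns a list of closed loops; each loop is a matrix of (x, y) vertices
# on the integer grid, 0-based image coordinates.
mask_boundary_loops <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  core <- pad[2:(H + 1), 2:(W + 1)]
  idx <- which(core)
  if (!length(idx)) return(list())
  rr <- ((idx - 1) %% H) + 1          # 1-based row
  cc <- ((idx - 1) %/% H) + 1         # 1-based col
  x <- cc - 1; y <- rr - 1            # 0-based pixel coords
  vid <- function(vx, vy) vx + (W + 1) * vy + 1   # vertex id on (W+1)x(H+1)

  # pad index: pixel (r, c) -> pad[r+1, c+1]
  up <- !pad[cbind(rr, cc + 1)]
  down <- !pad[cbind(rr + 2, cc + 1)]
  left <- !pad[cbind(rr + 1, cc)]
  right <- !pad[cbind(rr + 1, cc + 2)]

  e1 <- cbind(vid(x[up], y[up]), vid(x[up] + 1, y[up]))             # top
  e2 <- cbind(vid(x[down], y[down] + 1), vid(x[down] + 1, y[down] + 1))
  e3 <- cbind(vid(x[left], y[left]), vid(x[left], y[left] + 1))     # left
  e4 <- cbind(vid(x[right] + 1, y[right]), vid(x[right] + 1, y[right] + 1))
  edges <- rbind(e1, e2, e3, e4)
  ne <- nrow(edges)
  # adjacency: vertex id -> incident edge indices
  verts <- c(edges[, 1], edges[, 2])
  einc <- c(seq_len(ne), seq_len(ne))
  ord <- order(verts)
  verts <- verts[ord]; einc <- einc[ord]
  starts <- c(1L, which(diff(verts) > 0) + 1L)
  uverts <- verts[starts]
  ends <- c(starts[-1L] - 1L, length(verts))
  lookup <- function(v) {
    k <- match(v, uverts)
    einc[starts[k]:ends[k]]
  }
  used <- logical(ne)
  loops <- list()
  for (e0 in seq_len(ne)) {
    if (used[e0]) next
    used[e0] <- TRUE
    start_v <- edges[e0, 1]
    cur_v <- edges[e0, 2]
    loop <- c(start_v, cur_v)
    while (cur_v != start_v) {
      cand <- lookup(cur_v)
      cand <- cand[!used[cand]]
      if (!length(cand)) stop("boundary tracing failed: open chain")
      en <- cand[1]
      used[en] <- TRUE
      cur_v <- if (edges[en, 1] == cur_v) edges[en, 2] else edges[en, 1]
      loop <- c(loop, cur_v)
    }
    loop <- loop[-length(loop)]         # drop repeated start
    lx <- (loop - 1) %% (W + 1)
    ly <- (loop - 1) %/% (W + 1)
    loops[[length(loops) + 1L]] <- cbind(x = lx, y = ly)
  }
  loops
}

#' Encode a binary mask as a COCO segmentation
#'
#' Polygon (single boundary loop) when the region is simply connected,
#' uncompressed column-major RLE otherwise.
#' @param mask logical matrix (rows = y, cols = x)
#' @return a COCO segmentation object
#' @export
mask_to_segmentation <- function(mask) {
  loops <- mask_boundary_loops(mask)
  if (length(loops) == 1L) {
    v <- loops[[1]]
    list(as.numeric(t(v)))              # one polygon, x1,y1,x2,y2,...
  } else {
    mask_to_rle(mask)
  }
}

mask_to_rle <- function(mask) {
  v <- as.integer(mask)                 # column-major == COCO order
  r <- rle(v)
  counts <- r$lengths
  if (r$values[1] == 1L) counts <- c(0L, counts)
  list(size = c(nrow(mask), ncol(mask)), counts = as.integer(counts))
}

rle_to_mask <- function(rle) {
  sz <- as.integer(unlist(rle$size))
  counts <- as.integer(unlist(rle$counts))
  vals <- rep(rep(c(0L, 1L), length.out = length(counts)), counts)
  matrix(as.logical(vals), sz[1], sz[2])
}

#' Decode a COCO segmentation back into a binary mask
#' @param seg segmentation object (polygon list or RLE)
#' @param height,width image dimensions
#' @return logical matrix
#' @export
segmentation_to_mask <- function(seg, height, width) {
  if (!is.null(seg$counts)) return(rle_to_mask(seg))
  out <- matrix(FALSE, height, width)
  for (poly in seg) {
    p <- as.numeric(unlist(poly))
    xs <- p[seq(1, length(p), 2)]
    ys <- p[seq(2, length(p), 2)]
    out <- out | cpp_rasterize_polygon(xs, ys, height, width)
  }
  out
}

# ---- writer / reader -------------------------------------------------------

#' Write a COCO-format annotation file
#'
#' @param images data.frame with columns `id`, `file_name`, `width`, `height`
#' @param instances list of instance records; each needs `image_id`,
#'   `category` (name or COCO id), and either a `mask` matrix or
#'   pre-encoded `segmentation` + `bbox` + `area`
#' @param path output JSON path
#' @return invisible `path`
#' @export
write_coco <- function(images, instances, path) {
  cats <- uterseg_categories()
  ann_list <- vector("list", length(instances))
  for (k in seq_along(instances)) {
    inst <- instances[[k]]
    cid <- if (is.numeric(inst$category)) as.integer(inst$category) else
      cats$id[match(inst$category, cats$name)]
    if (is.na(cid)) stop("unknown category in instance ", k)
    if (!is.null(inst$mask)) {
      seg <- mask_to_segmentation(inst$mask)
      bbox <- if (!is.null(inst$bbox)) inst$bbox else tight_bbox(inst$mask)
      area <- if (!is.null(inst$area)) inst$area else sum(inst$mask)
    } else {
      seg <- inst$segmentation; bbox <- inst$bbox; area <- inst$area
    }
    ann_list[[k]] <- list(id = k, image_id = inst$image_id, category_id = cid,
                          segmentation = seg, area = area,
                          bbox = as.numeric(bbox), iscrowd = 0L)
  }
  obj <- list(
    images = lapply(seq_len(nrow(images)), function(i) {
      list(id = images$id[i], file_name = images$file_name[i],
           width = images$width[i], height = images$height[i])
    }),
    annotations = ann_list,
    categories = lapply(seq_len(nrow(cats)), function(i) {
      list(id = cats$id[i], name = cats$name[i], supercategory = "uterus")
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a COCO-format annotation file
#'
#' @param path JSON path
#' @return list with `images` (data.frame), `annotations` (list of records
#'   keeping `segmentation` objects), `categories` (data.frame)
#' @export
read_coco <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed COCO JSON at ", path,
                                           ": ", conditionMessage(e)))
  imgs <- do.call(rbind, lapply(obj$images, function(im) {
    data.frame(id = im$id, file_name = im$file_name, width = im$width,
               height = im$height, stringsAsFactors = FALSE)
  }))
  anns <- lapply(seq_along(obj$annotations), function(k) {
    a <- obj$annotations[[k]]
    for (f in c("id", "image_id", "category_id", "bbox", "area"))
      if (is.null(a[[f]]))
        stop("malformed COCO annotation record ", k, ": missing field ", f)
    a$bbox <- as.numeric(unlist(a$bbox))
    a$area <- as.numeric(a$area)
    a
  })
  cat_df <- do.call(rbind, lapply(obj$categories, function(ct) {
    data.frame(id = ct$id, name = ct$name, stringsAsFactors = FALSE)
  }))
  list(images = imgs, annotations = anns, categories = cat_df)
}

#' Reconstruct the binary mask of one COCO annotation
#' @param ann annotation record from [read_coco()]
#' @param height,width image dimensions
#' @return logical matrix
#' @export
annotation_mask <- function(ann, height, width) {
  segmentation_to_mask(ann$segmentation, height, width)
}
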