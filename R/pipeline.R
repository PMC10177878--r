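# End-to-end pipeline: generate -> preprocess -> anchors -> train ->
# predict -> evaluate, with a self-describing run directory.

#' Load a dataset split into in-memory samples
#'
#' @param dataset_dir directory written by [generate_dataset()]
#' @param split one of "train", "val", "test"
#' @return list of samples: `image` (matrix), `instances`, `image_id`
#' @export
load_split <- function(dataset_dir, split) {
  ann_path <- file.path(dataset_dir, "annotations", paste0(split, ".json"))
  if (!file.exists(ann_path))
    stop("missing annotations for split '", split,
         "'; run the generate stage first")
  coco <- read_coco(ann_path)
  lapply(seq_len(nrow(coco$images)), function(i) {
    im <- coco$images[i, ]
    img <- load_gray_image(file.path(dataset_dir, "images", split,
                                     im$file_name))
    anns <- Filter(function(a) a$image_id == im$id, coco$annotations)
    insts <- lapply(anns, function(a) {
      mk <- segmentation_to_mask(a$segmentation, im$height, im$width)
      list(category = uterseg_categories()$name[a$category_id],
           mask = mk, bbox = a$bbox, area = a$area)
    })
    list(image = img, instances = insts, image_id = im$id)
  })
}

#' Fit anchors from a dataset's training annotations
#'
#' Collects box statistics, runs IoU k-means with the configured k and
#' assigns the sorted centroids to the pyramid levels.
#'
#' @param coco_path training annotations JSON
#' @param k number of clusters (default 9)
#' @param seed RNG seed
#' @param restarts k-means restarts
#' @return list: `levels` (P3/P4/P5 matrices), `cluster` (the
#'   [kmeans_iou()] result)
#' @export
fit_anchors <- function(coco_path, k = 9L, seed = 0L, restarts = 10L) {
  st <- collect_box_stats(coco_path)
  boxes <- cbind(st$widths, st$heights)
  cl <- kmeans_iou(boxes, k, seed = seed, restarts = restarts)
  list(levels = assign_anchors_to_levels(cl$centroids), cluster = cl)
}

write_anchors_yaml <- function(anchors, path, avg_iou = NULL) {
  obj <- lapply(anchors, function(m) {
    lapply(seq_len(nrow(m)), function(i) list(w = m[i, 1], h = m[i, 2]))
  })
  if (!is.null(avg_iou)) obj$avg_iou <- avg_iou
  yaml::write_yaml(obj, path)
  invisible(path)
}

read_anchors_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  lev <- lapply(c("P3", "P4", "P5"), function(l) {
    do.call(rbind, lapply(obj[[l]], function(a) c(a$w, a$h)))
  })
  names(lev) <- c("P3", "P4", "P5")
  lev
}

#' Run the full pipeline from a configuration
#'
#' Stages in order: phantom dataset generation, anchor fitting, training
#' (with per-epoch validation), prediction on the test split, COCO
#' evaluation.  Every stage's outputs plus the resolved configuration are
#' written to `out_dir`; a rerun with the same config and seed reproduces
#' the dataset and anchors byte-identically.
#'
#' @param config a [model_config()], a named list of overrides, or a YAML
#'   path with fields `profile`, `seed`, `n_images` and optional nested
#'   overrides
#' @param out_dir run directory
#' @param n_images phantom dataset size (overridden by `config$n_images`)
#' @param verbose print progress
#' @return invisible list: `model`, `report`, `history`, paths
#' @export
run_pipeline <- function(config = list(), out_dir, n_images = 40L,
                         verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (inherits(config, "uterseg_config")) {
    cfg <- config
  } else {
    profile <- config$profile %||% "desk"
    extra <- config[setdiff(names(config), c("profile", "n_images"))]
    cfg <- do.call(model_config, c(list(profile = profile), extra))
  }
  if (!is.null(config$n_images)) n_images <- config$n_images
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # stage 1: dataset ---------------------------------------------------------
  ds_dir <- file.path(out_dir, "dataset")
  pcfg <- phantom_config(image_size = cfg$input_size, n_images = n_images,
                         seed = cfg$seed)
  generate_dataset(pcfg, ds_dir)
  if (verbose) message("dataset written to ", ds_dir)

  # stage 2: anchors ---------------------------------------------------------
  train_json <- file.path(ds_dir, "annotations", "train.json")
  if (isTRUE(cfg$anchors$kmeans)) {
    fa <- fit_anchors(train_json, k = cfg$anchors$k, seed = cfg$seed,
                      restarts = cfg$anchors$restarts)
    anchors <- fa$levels
    write_anchors_yaml(anchors, file.path(out_dir, "anchors.yaml"),
                       avg_iou = fa$cluster$avg_iou)
  } else {
    anchors <- default_anchor_levels()
    write_anchors_yaml(anchors, file.path(out_dir, "anchors.yaml"))
  }

  # stage 3: training --------------------------------------------------------
  model <- build_model(cfg, anchors = anchors)
  train_samples <- load_split(ds_dir, "train")
  val_samples <- load_split(ds_dir, "val")
  fit <- train_model(model, train_samples, val_samples = val_samples,
                     log_file = file.path(out_dir, "train_log.jsonl"),
                     verbose = verbose)
  model <- fit$model
  saveRDS(list(cfg = cfg, anchors = anchors,
               params = param_values(model)),
          file.path(out_dir, "checkpoint.rds"))

  # stage 4: prediction on the test split -----------------------------------
  test_samples <- load_split(ds_dir, "test")
  results <- list()
  for (s in test_samples) {
    dets <- predict_model(model, s$image)
    results <- c(results, detections_to_results(dets, s$image_id))
  }
  write_results_json(results, file.path(out_dir, "results_test.json"))

  # stage 5: evaluation ------------------------------------------------------
  report <- evaluate(file.path(out_dir, "results_test.json"),
                     file.path(ds_dir, "annotations", "test.json"))
  report_json <- c(as.list(report$box),
                   stats::setNames(as.list(report$mask),
                                   paste0("mask_", names(report$mask))))
  jsonlite::write_json(report_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)

  # resolved config + code identity
  resolved <- unclass(cfg)
  resolved$n_images <- n_images
  resolved$package_version <- as.character(utils::packageVersion("uterseg"))
  desc <- system.file("DESCRIPTION", package = "uterseg")
  if (nzchar(desc))
    resolved$code_hash <- unname(tools::md5sum(desc))
  yaml::write_yaml(resolved, file.path(out_dir, "config_resolved.yaml"))

  invisible(list(model = model, report = report, history = fit$history,
                 best_val_ap = fit$best_val_ap, dir = out_dir))
}

#' Load a model checkpoint written by [run_pipeline()]
#' @param path checkpoint.rds path
#' @return a restored `uterseg_model`
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$cfg, anchors = ck$anchors)
  restore_params(model, ck$params)
  model
}
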