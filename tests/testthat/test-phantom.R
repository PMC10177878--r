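# Synthetic phantom generator: instance structure, determinism, geometry.

test_that("phantom emits exactly one wall and one cavity plus configured myomas", {
  cfg <- tiny_phantom_config(myoma_count_range = c(0L, 0L))
  ph <- generate_phantom(cfg, 1)
  cats <- vapply(ph$instances, `[[`, character(1), "category")
  expect_length(ph$instances, 2L)
  expect_setequal(cats, c("uterine_wall", "uterine_cavity"))

  cfg2 <- tiny_phantom_config(myoma_count_range = c(2L, 2L))
  for (i in 1:3) {
    cats2 <- vapply(generate_phantom(cfg2, i)$instances, `[[`,
                    character(1), "category")
    expect_equal(sum(cats2 == "myoma"), 2L)
    expect_equal(sum(cats2 == "uterine_wall"), 1L)
    expect_equal(sum(cats2 == "uterine_cavity"), 1L)
  }
})

test_that("identical config and index give identical output; indices differ", {
  cfg <- tiny_phantom_config()
  expect_identical(generate_phantom(cfg, 2), generate_phantom(cfg, 2))
  expect_false(identical(generate_phantom(cfg, 1)$image,
                         generate_phantom(cfg, 2)$image))
})

test_that("with no noise or bias the cavity pixels equal the configured level", {
  cfg <- tiny_phantom_config(noise_sigma = 0, bias_amplitude = 0)
  ph <- generate_phantom(cfg, 3)
  cav <- ph$instances[[which(vapply(ph$instances, `[[`, character(1),
                                    "category") == "uterine_cavity")]]
  expect_true(all(ph$image[cav$mask] == cfg$contrast_levels["cavity"]))
})

test_that("instance records are internally consistent", {
  cfg <- tiny_phantom_config(myoma_count_range = c(1L, 3L))
  for (i in 1:4) {
    ph <- generate_phantom(cfg, i)
    wall <- NULL
    for (inst in ph$instances) {
      expect_gt(inst$area, 0)
      expect_equal(inst$area, sum(inst$mask))
      expect_equal(inst$bbox, tight_bbox(inst$mask))
      if (inst$category == "uterine_wall") wall <- inst
    }
    cav <- ph$instances[[which(vapply(ph$instances, `[[`, character(1),
                                      "category") == "uterine_cavity")]]
    # cavity lies inside the annulus hole: disjoint from the wall ring and
    # its bounding box nested in the wall's
    expect_equal(sum(cav$mask & wall$mask), 0)
    expect_true(cav$bbox[1] > wall$bbox[1] && cav$bbox[2] > wall$bbox[2])
    expect_true(cav$bbox[1] + cav$bbox[3] < wall$bbox[1] + wall$bbox[3])
  }
})

test_that("intramural myomas overlap the wall ring", {
  cfg <- tiny_phantom_config(myoma_count_range = c(3L, 3L), seed = 21L)
  found_overlap <- FALSE
  for (i in 1:6) {
    ph <- generate_phantom(cfg, i)
    wall <- ph$instances[[1]]
    for (inst in ph$instances) {
      if (inst$category == "myoma" && sum(inst$mask & wall$mask) > 0)
        found_overlap <- TRUE
    }
  }
  expect_true(found_overlap)
})

test_that("configuration errors are caught", {
  expect_error(phantom_config(image_size = 32), "image_size")
  expect_error(phantom_config(contrast_levels = c(background = 0.2,
                                                  wall = 0.9, cavity = 0.85,
                                                  myoma = 0.1)),
               "ordering")
  expect_error(phantom_config(myoma_count_range = c(3L, 1L)), "range")
})

test_that("dataset split counts follow rounded ratio shares", {
  dir1 <- withr::local_tempdir()
  m <- generate_dataset(tiny_phantom_config(n_images = 10L), dir1)
  expect_equal(vapply(m, function(s) nrow(s$images), numeric(1)),
               c(train = 8, val = 1, test = 1))
  dir2 <- withr::local_tempdir()
  m2 <- generate_dataset(tiny_phantom_config(n_images = 20L, seed = 2L), dir2,
                         split_ratio = c(0.5, 0.25, 0.25))
  expect_equal(vapply(m2, function(s) nrow(s$images), numeric(1)),
               c(train = 10, val = 5, test = 5))
  expect_error(generate_dataset(tiny_phantom_config(n_images = 2L),
                                withr::local_tempdir()),
               "smaller")
})

test_that("instances are conserved across splits and files exist on disk", {
  dir <- withr::local_tempdir()
  cfg <- tiny_phantom_config(n_images = 8L, seed = 5L)
  m <- generate_dataset(cfg, dir)
  n_direct <- sum(vapply(1:8, function(i)
    length(generate_phantom(cfg, i)$instances), numeric(1)))
  n_split <- sum(vapply(m, `[[`, numeric(1), "n_instances"))
  expect_equal(n_split, n_direct)
  for (s in c("train", "val", "test")) {
    coco <- read_coco(file.path(dir, "annotations", paste0(s, ".json")))
    for (fn in coco$images$file_name)
      expect_true(file.exists(file.path(dir, "images", s, fn)))
  }
})

test_that("box size and aspect-ratio marginals match the clinical profile", {
  # at 512^2: most box sides below 260 px, aspect ratios mostly < 2,
  # mode of the ratio distribution at 1
  cfg <- phantom_config(image_size = 512, n_images = 1, seed = 31)
  ws <- c(); hs <- c(); ar <- c()
  for (i in 1:200) {
    ph <- generate_phantom(cfg, i)
    bb <- t(vapply(ph$instances, function(x) x$bbox, numeric(4)))
    ws <- c(ws, bb[, 3]); hs <- c(hs, bb[, 4])
    ar <- c(ar, bb[, 3] / bb[, 4])
  }
  expect_gt(mean(ws < 260), 0.6)
  expect_gt(mean(hs < 260), 0.6)
  expect_gt(mean(ar < 2), 0.7)
  hb <- hist(ar, breaks = seq(0, max(ar) + 0.5, by = 0.5), plot = FALSE)
  expect_equal(hb$mids[which.max(hb$counts)], 1.25, tolerance = 0.5)
})
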