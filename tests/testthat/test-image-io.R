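test_that("detection files round-trip in both dialects", {
  ps <- pod_set("plant1", "front", c(10, 31.5), c(20, 4), c(50, 40.5),
                c(90, 12), c(3, 1), c(0.91, 0.5), c(7L, 9L))
  for (dialect in c("flat_csv", "coco_json")) {
    f <- tempfile(fileext = if (dialect == "flat_csv") ".csv" else ".json")
    write_detections(ps, f, dialect, image_size = c(400, 300))
    back <- read_detections(f, dialect)
    expect_equal(as.data.frame(back), as.data.frame(ps))
    expect_equal(attr(back, "plant_id"), "plant1")
    expect_equal(attr(back, "view"), "front")
  }
})

test_that("flat CSV rows parse to the documented fields", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("plant_id,view,x_min,y_min,x_max,y_max,class,confidence",
               "plant1,front,10,20,50,90,three,0.91"), f)
  ps <- read_detections(f, "flat_csv")
  expect_equal(nrow(ps), 1)
  expect_equal(ps$pod_class, 3L)
  expect_equal(ps$confidence, 0.91)
  expect_equal(unlist(ps[1, c("x_min", "y_min", "x_max", "y_max")]),
               c(x_min = 10, y_min = 20, x_max = 50, y_max = 90))
})

test_that("COCO [x,y,w,h] boxes convert to half-open corners", {
  ps <- pod_set("p", "rear", 10, 20, 50, 90, 2)
  f <- tempfile(fileext = ".json")
  write_detections(ps, f, "coco_json")
  raw <- jsonlite::fromJSON(f, simplifyDataFrame = FALSE)
  expect_equal(unlist(raw$annotations[[1]]$bbox), c(10, 20, 40, 70))
  back <- read_detections(f, "coco_json")
  expect_equal(back$x_max, 50)
  expect_equal(back$y_max, 90)
})

test_that("malformed detection rows are rejected, empty files are not", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("plant_id,view,x_min,y_min,x_max,y_max,class,confidence",
               "plant1,front,10,20,50,90,five,0.9"), f)
  expect_error(read_detections(f, "flat_csv"), "five")
  writeLines(c("plant_id,view,x_min,y_min,x_max,y_max,class,confidence",
               "plant1,front,NaN,20,50,90,two,0.9"), f)
  expect_error(read_detections(f, "flat_csv"), "row 1")
  writeLines("plant_id,view,x_min,y_min,x_max,y_max,class,confidence", f)
  expect_equal(nrow(read_detections(f, "flat_csv")), 0)
})

test_that("mirror_flip is an involution that reflects columns", {
  set.seed(5)
  img <- array(runif(8 * 10 * 3), c(8, 10, 3))
  expect_equal(mirror_flip(mirror_flip(img)), img)
  expect_equal(mirror_flip(img)[, 10, ], img[, 1, ])
  sym <- img
  sym[] <- sym[, c(1:5, 5:1), ]
  expect_equal(mirror_flip(sym), sym)
  expect_error(mirror_flip(array(0, c(0, 0, 3))), "empty")
})

test_that("flip_boxes reflects x and is an involution", {
  ps <- pod_set("p", "rear", 10, 0, 30, 10, 2)
  fl <- flip_boxes(ps, 100)
  expect_equal(c(fl$x_min, fl$x_max), c(70, 90))
  expect_equal(c(fl$y_min, fl$y_max), c(0, 10))
  expect_equal(as.data.frame(flip_boxes(fl, 100)), as.data.frame(ps))
  centered <- pod_set("p", "rear", 40, 0, 60, 10, 1)
  expect_equal(as.data.frame(flip_boxes(centered, 100)),
               as.data.frame(centered))
  expect_error(flip_boxes(pod_set("p", "rear", 90, 0, 120, 10, 1), 100),
               "outside")
})

test_that("flip_boxes commutes with mirror_flip through cropping", {
  # axis-aligned content at integer scale: crop(flip img, flip box) equals
  # mirror(crop(img, box))
  img <- array(0.2, c(20, 30, 3))
  img[5:10, 4:9, 1] <- 0.9
  ps <- pod_set("p", "front", 3, 4, 9, 10, 1)
  a <- crop_and_resize(mirror_flip(img), flip_boxes(ps, 30)[1, ],
                       pad = 0, side = 6)
  b <- mirror_flip(crop_and_resize(img, ps[1, ], pad = 0, side = 6))
  expect_equal(a, b)
})

test_that("crop_and_resize honors its shape and constancy contracts", {
  img <- array(0.5, c(12, 18, 3))
  det <- pod_set("p", "front", 2, 3, 8, 9, 1)[1, ]
  cr <- crop_and_resize(img, det, pad = 2, side = 105)
  expect_equal(dim(cr), c(105, 105, 3))
  expect_true(all(abs(cr - 0.5) < 1e-12))
  whole <- crop_and_resize(img, pod_set("p", "front", 0, 0, 18, 12, 1)[1, ],
                           pad = 0, side = 7)
  expect_equal(dim(whole), c(7, 7, 3))
  expect_error(crop_and_resize(img, pod_set("p", "front", 30, 30, 40, 40,
                                            1)[1, ]),
               "intersect")
})

test_that("augmentations follow their algebra", {
  set.seed(8)
  crop <- array(runif(10 * 10 * 3, 0.2, 0.8), c(10, 10, 3))
  expect_equal(augment(crop, character(0)), crop)
  expect_equal(augment(augment(crop, "rotate180"), "rotate180"), crop)
  # rotate180 equals two successive mirror axes
  expect_equal(augment(crop, "rotate180"),
               aperm(mirror_flip(aperm(mirror_flip(crop), c(2, 1, 3))),
                     c(2, 1, 3)))
  everything <- augment(crop, "salt_pepper", p = 1, seed = 1)
  expect_true(all(everything %in% c(0, 1)))
  n1 <- augment(crop, "salt_pepper", p = 0.3, seed = 42)
  n2 <- augment(crop, "salt_pepper", p = 0.3, seed = 42)
  expect_identical(n1, n2)
  n3 <- augment(crop, "salt_pepper", p = 0.3, seed = 43)
  expect_false(identical(n1, n3))
})

test_that("dataset augmentation expands fourfold with labels aligned", {
  crops <- list(const_crop(0.3), const_crop(0.6))
  aug <- augment_dataset(crops, c(1L, 2L), seed = 2)
  expect_length(aug$crops, 8)
  expect_equal(aug$labels, rep(c(1L, 2L), each = 4))
  expect_equal(aug$crops[[1]], crops[[1]])
})

test_that("images round-trip through PNG", {
  set.seed(2)
  img <- array(round(runif(6 * 7 * 3), 3), c(6, 7, 3))
  f <- tempfile(fileext = ".png")
  write_image(img, f)
  back <- read_image(f)
  expect_equal(dim(back), dim(img))
  expect_true(max(abs(back - img)) < 1 / 255)
})
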