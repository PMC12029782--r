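test_that("YOLO-seg lines parse classes, confidence and vertices", {
  f <- withr::local_tempfile(lines = "0 0.4 0.4 0.6 0.4 0.5 0.6")
  ann <- read_yolo_seg(f)
  expect_equal(ann$class, "BAC")
  expect_equal(ann$confidence, 1)
  expect_equal(ann$vertices[[1]],
               cbind(x = c(0.4, 0.6, 0.5), y = c(0.4, 0.4, 0.6)))

  # prediction dialect: odd token count after the id = leading confidence
  f2 <- withr::local_tempfile(lines = "1 0.55 0.4 0.4 0.6 0.4 0.5 0.6")
  ann2 <- read_yolo_seg(f2)
  expect_equal(ann2$class, "AS")
  expect_equal(ann2$confidence, 0.55)

  empty <- withr::local_tempfile(lines = character())
  expect_equal(nrow(read_yolo_seg(empty)), 0)
})

test_that("malformed YOLO-seg lines fail with the line number", {
  bad_coord <- withr::local_tempfile(lines = "0 0.4 0.4 1.6 0.4 0.5 0.6")
  expect_error(read_yolo_seg(bad_coord), "line 1.*\\[0, 1\\]")
  too_few <- withr::local_tempfile(lines = c("0 0.1 0.1 0.2 0.2 0.3 0.3",
                                             "0 0.1 0.1 0.2 0.2"))
  expect_error(read_yolo_seg(too_few), "line 2")
  bad_class <- withr::local_tempfile(lines = "7 0.4 0.4 0.6 0.4 0.5 0.6")
  expect_error(read_yolo_seg(bad_class), "class id")
})

test_that("write/read YOLO-seg roundtrips classes, confidence, vertices", {
  set.seed(101)
  ann <- random_annotations(60)
  f <- withr::local_tempfile(fileext = ".txt")
  write_yolo_seg(ann, f)
  back <- read_yolo_seg(f)
  expect_identical(back$class, ann$class)
  expect_equal(back$confidence, ann$confidence)
  for (i in seq_len(nrow(ann))) {
    expect_lt(max(abs(back$vertices[[i]] - ann$vertices[[i]])), 1e-6)
  }
  # empty list -> empty file; boundary coordinate 1.0 survives exactly
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_yolo_seg(annotation_tbl(), f2)
  expect_equal(nrow(read_yolo_seg(f2)), 0)
  edge <- annotation_tbl("BAC", list(cbind(c(0, 1, 1), c(0, 0, 1))))
  write_yolo_seg(edge, f2)
  expect_equal(read_yolo_seg(f2)$vertices[[1]],
               cbind(x = c(0, 1, 1), y = c(0, 0, 1)))
})

test_that("COCO polygon segmentations import with normalization", {
  coco <- list(
    images = list(list(id = 1, width = 200, height = 100)),
    categories = list(list(id = 1, name = "BAC"), list(id = 2, name = "AS")),
    annotations = list(list(id = 1, image_id = 1, category_id = 1,
                            segmentation = list(c(20, 20, 80, 20, 80, 60,
                                                  20, 60)))))
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(coco, f, auto_unbox = TRUE)
  ann <- read_coco_segmentation(f)
  expect_equal(ann$class, "BAC")
  expect_equal(ann$vertices[[1]],
               cbind(x = c(0.1, 0.4, 0.4, 0.1), y = c(0.2, 0.2, 0.6, 0.6)))

  # COCO <-> YOLO conversion preserves the absolute polygon area
  abs_area <- polygon_area(matrix(c(20, 20, 80, 20, 80, 60, 20, 60),
                                  ncol = 2, byrow = TRUE))
  g <- withr::local_tempfile(fileext = ".txt")
  write_yolo_seg(ann, g)
  v <- read_yolo_seg(g)$vertices[[1]]
  back_area <- polygon_area(cbind(v[, 1] * 200, v[, 2] * 100))
  expect_lt(abs(back_area - abs_area) / abs_area, 0.005)
})

test_that("COCO import rejects RLE and unknown categories", {
  base <- list(images = list(list(id = 1, width = 10, height = 10)),
               categories = list(list(id = 1, name = "BAC")))
  rle <- base
  rle$annotations <- list(list(id = 1, image_id = 1, category_id = 1,
                               segmentation = list(counts = "abc",
                                                   size = c(10, 10))))
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(rle, f, auto_unbox = TRUE)
  expect_error(read_coco_segmentation(f), "RLE|not supported")

  badcat <- base
  badcat$categories <- list(list(id = 1, name = "cat"))
  badcat$annotations <- list()
  jsonlite::write_json(badcat, f, auto_unbox = TRUE)
  expect_error(read_coco_segmentation(f), "categories")
})

test_that("the dataset split follows the 75/25 floor rule", {
  s8 <- split_dataset(letters[1:8], 0.75, seed = 2)
  expect_length(s8$train, 6)
  expect_length(s8$test, 2)
  s10 <- split_dataset(letters[1:10], 0.75, seed = 2)
  expect_length(s10$train, 7)
  expect_length(s10$test, 3)
  all_train <- split_dataset(letters[1:5], 1, seed = 2)
  expect_length(all_train$train, 5)
  expect_length(all_train$test, 0)
  expect_error(split_dataset(character()), "at least one")
})

test_that("the split partitions exactly and seeds only permute membership", {
  ids <- sprintf("img_%02d", 1:23)
  for (seed in 1:5) {
    s <- split_dataset(ids, 0.75, seed = seed)
    expect_length(intersect(s$train, s$test), 0)
    expect_setequal(c(s$train, s$test), ids)
    expect_length(s$train, 17) # floor(23 * 0.75)
  }
  expect_identical(split_dataset(ids, seed = 3), split_dataset(ids, seed = 3))
  expect_false(identical(split_dataset(ids, seed = 3)$train,
                         split_dataset(ids, seed = 4)$train))
})

test_that("the class map YAML records both classes", {
  f <- withr::local_tempfile(fileext = ".yaml")
  write_class_map(f)
  y <- yaml::read_yaml(f)
  expect_equal(y$nc, 2)
  expect_equal(y$names[["0"]], "BAC")
  expect_equal(y$names[["1"]], "AS")
})
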