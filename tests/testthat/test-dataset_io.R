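# Annotation and image I/O: YOLO conversions, LabelMe, grayscale, resizing,
# manifests.

test_that("YOLO lines convert to pixel corner boxes and back", {
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines("1 0.5 0.5 0.2 0.1", tf)
  b <- read_yolo_labels(tf, 640, 640, student_class_map())
  expect_equal(b$class, "piglet")
  expect_equal(as.numeric(b[1, c("x_min", "y_min", "x_max", "y_max")]),
               c(256, 288, 384, 352))

  out <- withr::local_tempfile(fileext = ".txt")
  write_yolo_labels(boxes("piglet", 256, 288, 384, 352), 640, 640,
                    student_class_map(), out)
  expect_equal(readLines(out), "1 0.500000 0.500000 0.200000 0.100000")
})

test_that("YOLO read/write round-trips within serialization precision", {
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(), tf)
  expect_equal(nrow(read_yolo_labels(tf, 640, 640, teacher_class_map())), 0)
  write_yolo_labels(boxes(), 640, 640, teacher_class_map(), tf)
  expect_identical(readLines(tf), character(0))

  set.seed(41)
  for (k in 1:5) {
    b <- random_box_set(6, classes = as.character(teacher_class_map()))
    write_yolo_labels(b, 320, 200, teacher_class_map(), tf)
    b2 <- read_yolo_labels(tf, 320, 200, teacher_class_map())
    expect_equal(b2$class, b$class)
    # one quantization step of the 6-decimal normalized serialization
    expect_lt(max(abs(as.matrix(b2[2:5]) - as.matrix(b[2:5]))), 2 * 1e-6 * 320)
  }
})

test_that("YOLO reader rejects malformed lines and unknown class indices", {
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0.5 0.5 0.1 0.1", "oops not a line"), tf)
  expect_error(read_yolo_labels(tf, 64, 64, student_class_map()), "line 2")
  writeLines("7 0.5 0.5 0.1 0.1", tf)
  expect_error(read_yolo_labels(tf, 64, 64, student_class_map()), "index")
  expect_error(write_yolo_labels(boxes("piglet", 1, 1, 5, 5), 64, 64,
                                 class_map("head"), tf), "not present")
})

test_that("degenerate boxes are rejected before serialization", {
  expect_error(boxes("piglet", 10, 10, 10, 20), "degenerate")
  b <- boxes("piglet", 1, 1, 5, 5)
  b$x_max <- b$x_min
  tf <- withr::local_tempfile(fileext = ".txt")
  expect_error(write_yolo_labels(b, 64, 64, student_class_map(), tf), "degenerate")
})

test_that("LabelMe rectangles are read with corner normalization and synonyms", {
  doc <- list(
    imageWidth = 200, imageHeight = 100,
    shapes = list(
      list(label = "piglet", shape_type = "rectangle",
           points = list(list(10, 20), list(50, 60))),
      list(label = "Sow tail", shape_type = "rectangle",
           points = list(list(50, 60), list(10, 20))),
      list(label = "head", shape_type = "rectangle",
           points = list(list(1, 2), list(5, 9)))))
  tf <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, tf, auto_unbox = TRUE)
  got <- read_labelme(tf, teacher_class_map(), synonyms = c("Sow tail" = "tail"))
  expect_equal(got$image_width, 200)
  expect_equal(nrow(got$boxes), 3)
  expect_equal(got$boxes$class, c("piglet", "tail", "head"))
  # reversed corners normalize to the same box
  expect_equal(as.numeric(got$boxes[2, 2:5]), c(10, 20, 50, 60))
  expect_equal(as.numeric(got$boxes[1, 2:5]), c(10, 20, 50, 60))

  doc$shapes[[1]]$shape_type <- "polygon"
  jsonlite::write_json(doc, tf, auto_unbox = TRUE)
  expect_error(read_labelme(tf, teacher_class_map()), "polygon")
  doc$shapes[[1]]$shape_type <- "rectangle"
  doc$shapes[[1]]$label <- "zebra"
  jsonlite::write_json(doc, tf, auto_unbox = TRUE)
  expect_error(read_labelme(tf, teacher_class_map()), "zebra")
})

test_that("grayscale conversion uses BT.601 luma weights", {
  gray <- array(120, dim = c(4, 4, 3))
  expect_true(all(to_grayscale(gray) == 120))
  white <- array(255, dim = c(2, 2, 3))
  expect_true(all(to_grayscale(white) == 255))
  red <- array(0, dim = c(2, 2, 3)); red[, , 1] <- 255
  expect_true(all(to_grayscale(red) == 76))   # round(0.299 * 255)
  expect_error(to_grayscale(array(1, dim = c(2, 2, 2))), "RGB")
})

test_that("bilinear resizing matches closed-form cases", {
  img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  expect_identical(resize_image(img, 8, 8), farrowdet:::quantize8(img))
  expect_true(all(resize_image(matrix(33, 5, 7), 12, 9) == 33))
  checker <- matrix(c(0, 255, 255, 0), 2, 2)
  expect_equal(as.numeric(resize_image(checker, 1, 1)), 128)
})

test_that("PNG round-trip preserves 8-bit pixels exactly", {
  img <- matrix(sample(0:255, 48 * 32, replace = TRUE), 32, 48)
  tf <- withr::local_tempfile(fileext = ".png")
  write_image_png(img, tf)
  expect_identical(unname(read_image_png(tf)[, ]), img + 0)
})

test_that("manifests round-trip and enforce their invariants", {
  td <- withr::local_tempdir()
  m <- tiny_dataset(td, 3, seed = 7)
  m2 <- read_manifest(file.path(td, "manifest.tsv"))
  expect_s3_class(m2, "dataset_manifest")
  expect_equal(nrow(m2$records), 3)
  expect_equal(as.character(m2$class_map), as.character(teacher_class_map()))
  expect_equal(basename(m2$records$image), basename(m$records$image))

  rec <- m$records[c(1, 1), ]
  expect_error(dataset_manifest(rec, teacher_class_map()), "duplicate")
  rec2 <- m$records
  rec2$provenance <- "guessed"
  expect_error(dataset_manifest(rec2, teacher_class_map()), "provenance")
  # missing files surface at load time
  bad <- m$records
  bad$label[1] <- file.path(td, "nope.txt")
  write_manifest(dataset_manifest(bad, teacher_class_map()), file.path(td, "bad.tsv"))
  expect_error(read_manifest(file.path(td, "bad.tsv")), "missing")
})
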