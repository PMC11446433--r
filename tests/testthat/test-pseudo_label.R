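# Pseudo-labeling: confidence filtering, oracle end-to-end consistency,
# student-set construction and the review queue.

test_that("confidence filtering is strict, order-preserving and monotone", {
  det <- boxes(rep("piglet", 4), c(0, 20, 40, 60), c(0, 0, 0, 0),
               c(10, 30, 50, 70), c(10, 10, 10, 10),
               confidence = c(0.95, 0.91, 0.89, 0.30))
  kept <- filter_detections(det, pseudo_label_config(0.9))
  expect_equal(kept$confidence, c(0.95, 0.91))
  expect_equal(nrow(filter_detections(det[0, ], pseudo_label_config(0.9))), 0)

  exact <- det; exact$confidence[1] <- 0.9
  expect_equal(nrow(filter_detections(exact[1, , drop = FALSE],
                                      pseudo_label_config(0.9))), 0)
  expect_equal(nrow(filter_detections(exact[1, , drop = FALSE],
                                      pseudo_label_config(0.9, strict = FALSE))), 1)

  set.seed(4)
  for (k in 1:20) {
    d <- random_box_set(sample(1:8, 1), confidence = TRUE)
    th <- sort(runif(2))
    expect_gte(nrow(filter_detections(d, pseudo_label_config(max(th[1], 0.01)))),
               nrow(filter_detections(d, pseudo_label_config(max(th[2], 0.02)))))
  }
})

test_that("an oracle teacher reproduces the direct ground-truth transformation exactly", {
  sc <- generate_scene(small_params(piglet_count_range = c(3, 6)), 17)
  img <- sc$pixels
  attr(img, "truth") <- sc$boxes
  teacher <- oracle_detector(teacher_class_map())
  pa <- pseudo_annotate_frame(img, teacher, crop = crop_spec(320, 320))
  expect_true(pa$ok)

  # independent path: restrict ground truth to the region, crop, class-reduce
  reg <- region_from_annotations(sc$boxes, ncol(img), nrow(img))
  gt <- reduce_classes(sc$boxes)
  gt <- gt[farrowdet:::boxes_in_region(gt, reg), , drop = FALSE]
  direct <- crop_and_remap(img, gt, reg$crop_window, crop_spec(320, 320))
  expect_identical(pa$image, direct$image)
  expect_equal(pa$boxes$class, direct$boxes$class)
  expect_equal(as.matrix(pa$boxes[2:5]), as.matrix(direct$boxes[2:5]),
               tolerance = 1e-12)
})

test_that("frames without a detectable head/rear pair are skipped with a reason", {
  sc <- generate_scene(small_params(), 23)
  img <- sc$pixels
  attr(img, "truth") <- sc$boxes[sc$boxes$class != "rear", ]
  pa <- pseudo_annotate_frame(img, oracle_detector(teacher_class_map()))
  expect_false(pa$ok)
  expect_equal(pa$reason, "no_region")
})

test_that("all-filtered piglet detections still yield a tail-only label set", {
  # a detector whose piglet detections never clear the confidence filter
  registerS3method("detect_frame", "shy_detector",
                   function(model, image, ...) {
                     b <- attr(image, "truth")
                     b$confidence <- ifelse(b$class == "piglet", 0.5, 1.0)
                     b
                   }, envir = asNamespace("farrowdet"))
  shy <- structure(list(class_map = teacher_class_map()), class = "shy_detector")

  sc <- generate_scene(small_params(piglet_count_range = c(2, 4)), 29)
  img <- sc$pixels
  attr(img, "truth") <- sc$boxes
  pa <- pseudo_annotate_frame(img, shy, pl_config = pseudo_label_config(0.9))
  expect_true(pa$ok)
  expect_true(all(pa$boxes$class == "tail"))
  expect_equal(sum(pa$boxes$class == "piglet"), 0)

  # and with a minimum piglet requirement the frame is excluded instead
  pa2 <- pseudo_annotate_frame(img, shy,
                               pl_config = pseudo_label_config(0.9,
                                                               min_piglet_detections = 1))
  expect_false(pa2$ok)
  expect_equal(pa2$reason, "too_few_piglets")
})

test_that("student dataset construction, review rejection and determinism", {
  td <- withr::local_tempdir()
  pool <- tiny_dataset(file.path(td, "pool"), 10, seed = 3,
                       params = small_params(piglet_count_range = c(2, 6)))
  teacher <- oracle_detector(teacher_class_map())
  out1 <- file.path(td, "student1")
  m1 <- build_student_dataset(pool, teacher, out_dir = out1, crop = crop_spec(320, 320))
  expect_equal(nrow(m1$records), 10)
  expect_true(all(m1$records$provenance == "pseudo"))
  ct <- attr(m1, "counters")
  expect_equal(unname(ct["frames_kept"]), 10)

  # reject two records through the review queue, then finalize
  rq <- attr(m1, "review_queue")
  lines <- readLines(rq)
  lines[c(2, 5)] <- sub("\taccept\t", "\treject\tbad localization", lines[c(2, 5)])
  writeLines(lines, rq)
  m1b <- finalize_student_dataset(m1)
  expect_equal(nrow(m1b$records), 8)

  out2 <- file.path(td, "student2")
  m2 <- build_student_dataset(pool, teacher, out_dir = out2, crop = crop_spec(320, 320))
  for (i in seq_len(nrow(m1$records))) {
    expect_identical(readLines(m1$records$label[i]), readLines(m2$records$label[i]))
  }
})

test_that("every pseudo-box lies inside the output image bounds", {
  td <- withr::local_tempdir()
  pool <- tiny_dataset(file.path(td, "pool"), 6, seed = 8,
                       params = small_params(piglet_count_range = c(2, 6)))
  m <- build_student_dataset(pool, oracle_detector(teacher_class_map()),
                             out_dir = file.path(td, "student"),
                             crop = crop_spec(320, 320))
  for (lp in m$records$label) {
    b <- read_yolo_labels(lp, 320, 320, student_class_map())
    if (!nrow(b)) next
    expect_true(all(b$x_min >= -0.001 & b$y_min >= -0.001 &
                    b$x_max <= 320.001 & b$y_max <= 320.001))
  }
})
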