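# Detection evaluation: IoU, greedy matching vs an exhaustive oracle,
# Recall/Precision/F1 identities, region-restricted model evaluation.

test_that("IoU matches closed-form cases", {
  a <- boxes("piglet", 0, 0, 10, 10)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, boxes("piglet", 20, 20, 30, 30)), 0)
  expect_equal(iou(a, boxes("piglet", 5, 5, 15, 15)), 25 / 175)
})

test_that("greedy matching counts TP/FP/FN with a one-to-one guard", {
  gt <- boxes("piglet", 0, 0, 10, 10)
  det <- boxes("piglet", 1, 0, 11, 10, confidence = 0.9)   # IoU 9/11
  c1 <- match_detections(gt, det)
  expect_equal(unname(c1$pooled), c(1, 0, 0))

  det2 <- rbind(det, boxes("piglet", 0, 1, 10, 11, confidence = 0.8))
  c2 <- match_detections(gt, det2)
  expect_equal(unname(c2$pooled), c(1, 1, 0))

  # class-aware matching refuses a cross-class match
  det3 <- boxes("tail", 0, 0, 10, 10, confidence = 1)
  c3 <- match_detections(gt, det3)
  expect_equal(c3$per_class$FP[c3$per_class$class == "tail"], 1)
  expect_equal(c3$per_class$FN[c3$per_class$class == "piglet"], 1)
  c4 <- match_detections(gt, det3, eval_config(class_aware = FALSE))
  expect_equal(sum(c4$per_class$TP), 1)
})

test_that("greedy matching keeps count invariants and tracks the optimal oracle", {
  set.seed(20240)
  agree <- 0L; n_inst <- 200L
  for (k in seq_len(n_inst)) {
    gt <- random_box_set(sample(0:6, 1))
    det <- random_box_set(sample(0:6, 1), confidence = TRUE)
    cc <- match_detections(gt, det)
    for (cl in cc$per_class$class) {
      row <- cc$per_class[cc$per_class$class == cl, ]
      expect_equal(row$TP + row$FN, sum(gt$class == cl))
      expect_equal(row$TP + row$FP, sum(det$class == cl))
    }
    opt <- optimal_match_count(gt, det)
    expect_lte(unname(cc$pooled["TP"]), opt)
    if (unname(cc$pooled["TP"]) == opt) agree <- agree + 1L
  }
  expect_gte(agree / n_inst, 0.95)
})

test_that("metrics follow the count definitions, including published worked rows", {
  m <- compute_metrics(data.frame(class = "piglet", TP = 441, FP = 4, FN = 249))
  expect_equal(round(m$recall[1], 3), 0.639)
  expect_equal(round(m$precision[1], 3), 0.991)
  expect_equal(round(m$f1[1], 3), 0.777)

  tot <- compute_metrics(data.frame(class = c("piglet", "tail"),
                                    TP = c(666, 186), FP = c(25, 26), FN = c(24, 70)))
  t_row <- tot[tot$class == "Total", ]
  expect_equal(t_row$TP, 852)
  expect_equal(round(t_row$precision, 3), 0.944)
  expect_equal(round(t_row$f1, 3), 0.922)

  z <- compute_metrics(data.frame(class = "piglet", TP = 0, FP = 0, FN = 0))
  expect_true(all(is.na(z[1, c("recall", "precision", "f1")])))
})

test_that("F1 equals both the harmonic-mean and the count form when defined", {
  set.seed(9)
  for (k in 1:50) {
    TP <- sample(0:50, 1); FP <- sample(0:20, 1); FN <- sample(0:20, 1)
    m <- compute_metrics(data.frame(class = "x", TP = TP, FP = FP, FN = FN))[1, ]
    if (!is.na(m$recall) && !is.na(m$precision) && (m$recall + m$precision) > 0) {
      expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall),
                   tolerance = 1e-12)
      expect_equal(m$f1, 2 * TP / (2 * TP + FP + FN), tolerance = 1e-12)
    }
  }
})

test_that("pooled metrics micro-average the counts, not the per-class metrics", {
  cnt <- data.frame(class = c("a", "b"), TP = c(9, 1), FP = c(0, 9), FN = c(1, 0))
  m <- compute_metrics(cnt)
  tot <- m[m$class == "Total", ]
  expect_equal(tot$precision, 10 / 19)
  macro <- mean(m$precision[m$class != "Total"])
  expect_false(isTRUE(all.equal(tot$precision, macro)))
})

test_that("adding detections moves recall and precision monotonically", {
  gt <- rbind(boxes("piglet", 0, 0, 10, 10), boxes("piglet", 30, 30, 40, 40))
  det <- boxes("piglet", 0, 0, 10, 10, confidence = 0.9)
  base <- compute_metrics(match_detections(gt, det))
  # a perfect detection of an unmatched ground-truth box
  more <- rbind(det, boxes("piglet", 30, 30, 40, 40, confidence = 0.8))
  up <- compute_metrics(match_detections(gt, more))
  expect_gte(up[up$class == "Total", "recall"], base[base$class == "Total", "recall"])
  # a spurious detection far from everything
  spur <- rbind(det, boxes("piglet", 70, 70, 80, 80, confidence = 0.5))
  down <- compute_metrics(match_detections(gt, spur))
  expect_lte(down[down$class == "Total", "precision"],
             base[base$class == "Total", "precision"])
})

test_that("an oracle detector evaluates to a perfect score, an empty one to zero recall", {
  td <- withr::local_tempdir()
  m <- tiny_dataset(td, 4, seed = 5, split = "eval")
  perfect <- evaluate_model(oracle_detector(teacher_class_map()), m)
  expect_equal(perfect$n_images, 4)
  expect_true(all(perfect$metrics$recall == 1))
  expect_true(all(perfect$metrics$precision == 1))
  expect_true(all(perfect$metrics$f1 == 1))

  # a student-style oracle sees the remapped crop ground truth
  perfect_s <- evaluate_model(oracle_detector(student_class_map()), m)
  expect_equal(perfect_s$model_style, "student")
  expect_true(all(perfect_s$metrics$f1 == 1))
  # identical region-restricted denominators for both styles
  expect_equal(perfect_s$counts$per_class$TP + perfect_s$counts$per_class$FN,
               perfect$counts$per_class$TP + perfect$counts$per_class$FN)

  registerS3method("detect_frame", "null_detector",
                   function(model, image, ...) farrowdet:::empty_boxes(confidence = TRUE),
                   envir = asNamespace("farrowdet"))
  null_model <- structure(list(class_map = student_class_map()), class = "null_detector")
  nothing <- evaluate_model(null_model, m)
  tot <- nothing$metrics[nothing$metrics$class == "Total", ]
  expect_equal(tot$recall, 0)
  expect_true(is.na(tot$precision))
  expect_equal(tot$FN, sum(perfect$counts$per_class$TP))
})

test_that("accumulated counts equal a single-pass per-image recount", {
  td <- withr::local_tempdir()
  m <- tiny_dataset(td, 5, seed = 77, split = "eval")
  ev <- evaluate_model(oracle_detector(teacher_class_map()), m)
  total <- 0L
  for (i in 1:5) {
    lr <- farrowdet:::load_record(m$records[i, ], m$class_map)
    reg <- region_from_annotations(lr$boxes, ncol(lr$image), nrow(lr$image))
    gt <- reduce_classes(lr$boxes)
    total <- total + sum(farrowdet:::boxes_in_region(gt, reg))
  }
  expect_equal(unname(ev$counts$pooled["TP"]), total)
})

test_that("metric reports render and serialize with 3-decimal formatting", {
  rep <- compute_metrics(data.frame(class = c("piglet", "tail"),
                                    TP = c(441, 90), FP = c(4, 99), FN = c(249, 166)))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_metrics_report(rep, tsv, js)
  tab <- read.delim(tsv, check.names = FALSE)
  expect_equal(names(tab), c("Class", "TP", "FP", "FN", "Recall", "Precision", "F1"))
  expect_equal(tab$Recall[tab$Class == "piglet"], 0.639)
  back <- jsonlite::fromJSON(js)
  expect_equal(back$TP[back$class == "Total"], 531)
})
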