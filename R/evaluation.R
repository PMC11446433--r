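# Region-restricted detection evaluation: IoU matching, per-class and pooled
# (micro-averaged) TP/FP/FN counts, and Recall / Precision / F1.

#' Evaluation configuration
#'
#' @param iou_threshold minimum IoU for a detection to match a ground-truth
#'   box (default 0.5).
#' @param class_aware match detections only to ground truth of the same class
#'   (default TRUE).
#' @param region_restrict `"teacher_style"` keeps only boxes whose center lies
#'   inside the birth region; `"none"` evaluates the full frame.
#' @return list of class `"eval_config"`.
#' @export
eval_config <- function(iou_threshold = 0.5, class_aware = TRUE,
                        region_restrict = c("teacher_style", "none")) {
  if (iou_threshold <= 0 || iou_threshold > 1) stopf("iou_threshold must lie in (0, 1]")
  structure(list(iou_threshold = iou_threshold, class_aware = class_aware,
                 region_restrict = match.arg(region_restrict)),
            class = "eval_config")
}

#' Intersection over union of two boxes
#'
#' @param box_a,box_b single-row box data.frames.
#' @return IoU in `[0, 1]`; 0 for disjoint boxes.
#' @export
iou <- function(box_a, box_b) {
  ix <- min(box_a$x_max, box_b$x_max) - max(box_a$x_min, box_b$x_min)
  iy <- min(box_a$y_max, box_b$y_max) - max(box_a$y_min, box_b$y_min)
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  inter / (box_area(box_a) + box_area(box_b) - inter)
}

# Vectorized IoU matrix between two box tables.
iou_matrix <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(matrix(0, nrow(a), nrow(b)))
  ix <- outer(a$x_max, b$x_max, pmin) - outer(a$x_min, b$x_min, pmax)
  iy <- outer(a$y_max, b$y_max, pmin) - outer(a$y_min, b$y_min, pmax)
  inter <- pmax(ix, 0) * pmax(iy, 0)
  un <- outer(box_area(a), box_area(b), "+") - inter
  out <- inter / un
  out[un <= 0] <- 0
  out
}

#' Match detections to ground truth and count TP/FP/FN
#'
#' Detections are processed in order of decreasing confidence (ties: larger
#' area first, then input order); each is greedily matched one-to-one to the
#' unmatched ground-truth box of the same class (when `class_aware`) with the
#' highest IoU at or above the threshold. Matched detections are TP, unmatched
#' detections FP, unmatched ground truth FN.
#'
#' @param ground_truth box data.frame.
#' @param detections detection data.frame (a missing confidence column is
#'   treated as all ones).
#' @param config an [eval_config()].
#' @param classes class universe for per-class rows (default: classes present).
#' @return object of class `"confusion_counts"`: per-class data.frame plus
#'   pooled totals.
#' @export
match_detections <- function(ground_truth, detections, config = eval_config(),
                             classes = NULL) {
  gt <- ground_truth; det <- detections
  if (is.null(classes)) classes <- sort(unique(c(gt$class, det$class)))
  conf <- if ("confidence" %in% names(det)) det$confidence else rep(1, nrow(det))
  ord <- if (nrow(det)) order(-conf, -box_area(det), seq_len(nrow(det))) else integer()
  gt_matched <- rep(FALSE, nrow(gt))
  det_matched <- rep(FALSE, nrow(det))
  iom <- iou_matrix(det, gt)
  for (i in ord) {
    cand <- which(!gt_matched &
                    (!config$class_aware | gt$class == det$class[i]) &
                    iom[i, ] >= config$iou_threshold)
    if (length(cand)) {
      best <- cand[which.max(iom[i, cand])]
      gt_matched[best] <- TRUE
      det_matched[i] <- TRUE
    }
  }
  per <- if (length(classes)) {
    do.call(rbind, lapply(classes, function(cl) {
      data.frame(class = cl,
                 TP = sum(det_matched & det$class == cl),
                 FP = sum(!det_matched & det$class == cl),
                 FN = sum(!gt_matched & gt$class == cl),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(class = character(), TP = integer(), FP = integer(), FN = integer(),
               stringsAsFactors = FALSE)
  }
  confusion_counts(per)
}

#' Confusion counts container
#'
#' Holds per-class TP/FP/FN rows; pooled totals are their sums
#' (micro-averaging). Counts from several images are combined with `+`.
#'
#' @param per_class data.frame with columns `class`, `TP`, `FP`, `FN`.
#' @return object of class `"confusion_counts"`.
#' @export
confusion_counts <- function(per_class) {
  stopifnot(all(c("class", "TP", "FP", "FN") %in% names(per_class)))
  rownames(per_class) <- NULL
  structure(list(per_class = per_class,
                 pooled = c(TP = sum(per_class$TP), FP = sum(per_class$FP),
                            FN = sum(per_class$FN))),
            class = "confusion_counts")
}

#' @export
`+.confusion_counts` <- function(e1, e2) {
  classes <- union(e1$per_class$class, e2$per_class$class)
  per <- do.call(rbind, lapply(classes, function(cl) {
    a <- e1$per_class[e1$per_class$class == cl, , drop = FALSE]
    b <- e2$per_class[e2$per_class$class == cl, , drop = FALSE]
    data.frame(class = cl,
               TP = sum(a$TP, b$TP), FP = sum(a$FP, b$FP), FN = sum(a$FN, b$FN),
               stringsAsFactors = FALSE)
  }))
  confusion_counts(per)
}

#' @export
print.confusion_counts <- function(x, ...) {
  print(x$per_class)
  cat(sprintf("pooled: TP=%d FP=%d FN=%d\n", x$pooled["TP"], x$pooled["FP"], x$pooled["FN"]))
  invisible(x)
}

metrics_from_triplet <- function(TP, FP, FN) {
  rec <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  prec <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  f1 <- if (2 * TP + FP + FN > 0) 2 * TP / (2 * TP + FP + FN) else NA_real_
  c(recall = rec, precision = prec, f1 = f1)
}

#' Compute Recall, Precision and F1 from confusion counts
#'
#' Recall = TP / (TP + FN), Precision = TP / (TP + FP),
#' F1 = 2 TP / (2 TP + FP + FN). Pooled ("Total") metrics are computed from
#' the pooled counts (micro-averaging), not by averaging per-class metrics.
#' Zero-denominator metrics are reported as `NA` (undefined), never coerced
#' to 0 or 1.
#'
#' @param counts a [confusion_counts()] object, or a data.frame with columns
#'   `class`, `TP`, `FP`, `FN`.
#' @return object of class `"metrics_report"`: data.frame with one row per
#'   class plus a `Total` row.
#' @export
compute_metrics <- function(counts) {
  if (is.data.frame(counts)) counts <- confusion_counts(counts)
  per <- counts$per_class
  rows <- lapply(seq_len(nrow(per)), function(i) {
    m <- metrics_from_triplet(per$TP[i], per$FP[i], per$FN[i])
    cbind(per[i, ], data.frame(recall = m[1], precision = m[2], f1 = m[3]))
  })
  mp <- metrics_from_triplet(counts$pooled["TP"], counts$pooled["FP"], counts$pooled["FN"])
  total <- data.frame(class = "Total",
                      TP = unname(counts$pooled["TP"]), FP = unname(counts$pooled["FP"]),
                      FN = unname(counts$pooled["FN"]),
                      recall = mp[1], precision = mp[2], f1 = mp[3])
  out <- rbind(do.call(rbind, rows), total)
  rownames(out) <- NULL
  structure(out, class = c("metrics_report", "data.frame"))
}

#' @export
print.metrics_report <- function(x, ...) {
  d <- as.data.frame(x)
  d$recall <- fmt3(d$recall); d$precision <- fmt3(d$precision); d$f1 <- fmt3(d$f1)
  print(d, row.names = FALSE)
  invisible(x)
}

#' Write a metrics report as a delimited table and JSON
#'
#' The TSV mirrors the usual results-table layout (Class, TP, FP, FN, Recall,
#' Precision, F1) with 3-decimal half-away-from-zero rounding; the JSON
#' counterpart keeps full precision.
#'
#' @param report a `"metrics_report"`.
#' @param path_tsv,path_json output paths (either may be `NULL`).
#' @export
write_metrics_report <- function(report, path_tsv = NULL, path_json = NULL) {
  d <- as.data.frame(report)
  if (!is.null(path_tsv)) {
    out <- data.frame(Class = d$class, TP = d$TP, FP = d$FP, FN = d$FN,
                      Recall = fmt3(d$recall), Precision = fmt3(d$precision),
                      F1 = fmt3(d$f1))
    utils::write.table(out, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(d, path_json, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(report)
}

#' Evaluate a detector on an annotated evaluation set
#'
#' Per image: the birth region is derived from the manual head/rear
#' annotations; the ground truth is restricted to tail/piglet boxes whose
#' centers fall inside the region. A 4-class (teacher-style) model predicts on
#' the full frame and keeps center-in-region tail/piglet detections; a 2-class
#' (student-style) model predicts on the cropped, rescaled target image, with
#' the ground truth remapped into the same crop frame -- so both model types
#' are scored against the identical region-restricted ground-truth set.
#' Counts are accumulated over all images and reported per class and pooled.
#'
#' @param model a fitted detector.
#' @param eval_manifest manifest annotated with the teacher class map.
#' @param region a [region_params()].
#' @param config an [eval_config()].
#' @param crop a [crop_spec()] (student-style evaluation).
#' @return list of class `"evaluation_result"` with `counts`, `metrics`,
#'   `n_images`, `n_skipped`.
#' @export
evaluate_model <- function(model, eval_manifest, region = region_params(),
                           config = eval_config(), crop = crop_spec()) {
  rec <- eval_manifest$records
  smap <- student_class_map()
  student_style <- !any(c("head", "rear") %in% model$class_map)
  total <- confusion_counts(data.frame(class = as.character(smap),
                                       TP = 0L, FP = 0L, FN = 0L))
  n_used <- 0L; n_skipped <- 0L
  for (i in seq_len(nrow(rec))) {
    lr <- load_record(rec[i, ], eval_manifest$class_map)
    reg <- tryCatch(
      region_from_annotations(lr$boxes, ncol(lr$image), nrow(lr$image), region),
      error = function(e) NULL)
    if (is.null(reg)) {
      warning(sprintf("skipping %s: %s", basename(rec$image[i]),
                      "no usable head/rear annotation"), call. = FALSE)
      n_skipped <- n_skipped + 1L
      next
    }
    gt <- reduce_classes(lr$boxes, smap)
    if (config$region_restrict == "teacher_style" && nrow(gt)) {
      gt <- gt[boxes_in_region(gt, reg), , drop = FALSE]
    }
    if (student_style) {
      cw <- reg$crop_window
      cr_img <- crop_and_remap(lr$image, gt, cw,
                               crop_spec(crop$out_width, crop$out_height,
                                         retention_threshold = 1e-9))
      img <- cr_img$image
      attr(img, "truth") <- cr_img$boxes
      gt_eval <- cr_img$boxes
      det <- reduce_classes(detect_frame(model, img), smap)
      if (config$region_restrict == "teacher_style" && nrow(det)) {
        # same center-in-circle rule as the teacher: map detection centers
        # back into the source frame (the square crop corners lie outside
        # the circular region)
        ctr <- box_center(det)
        sx <- (cw$x_max - cw$x_min) / crop$out_width
        sy <- (cw$y_max - cw$y_min) / crop$out_height
        src <- cbind(cw$x_min + ctr[, 1] * sx, cw$y_min + ctr[, 2] * sy)
        det <- det[point_in_region(src, reg), , drop = FALSE]
      }
    } else {
      gt_eval <- gt
      det <- reduce_classes(detect_frame(model, lr$image), smap)
      if (config$region_restrict == "teacher_style" && nrow(det)) {
        det <- det[boxes_in_region(det, reg), , drop = FALSE]
      }
    }
    total <- total + match_detections(gt_eval, det, config, classes = as.character(smap))
    n_used <- n_used + 1L
  }
  structure(list(counts = total, metrics = compute_metrics(total),
                 n_images = n_used, n_skipped = n_skipped,
                 model_style = if (student_style) "student" else "teacher"),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("evaluation over %d images (%d skipped), %s-style model\n",
              x$n_images, x$n_skipped, x$model_style))
  print(x$metrics)
  invisible(x)
}
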