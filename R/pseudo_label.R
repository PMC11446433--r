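# Pseudo-label generation: run the teacher on unlabeled frames, derive the
# birth region, crop, confidence-filter, and emit student annotations.

#' Pseudo-labeling configuration
#'
#' @param confidence_threshold detections must score above this value to
#'   become pseudo-labels (default 0.9).
#' @param strict use strict `>` ("above the threshold"); set `FALSE` for `>=`.
#' @param require_region keep only detections whose box center lies inside the
#'   derived birth region before cropping (default TRUE).
#' @param min_piglet_detections minimum number of surviving piglet detections
#'   an image needs to enter the student set (default 0: frames with zero
#'   piglets are kept as hard negatives).
#' @return list of class `"pseudo_label_config"`.
#' @export
pseudo_label_config <- function(confidence_threshold = 0.9, strict = TRUE,
                                require_region = TRUE, min_piglet_detections = 0L) {
  if (confidence_threshold <= 0 || confidence_threshold >= 1) {
    stopf("confidence_threshold must lie in (0, 1)")
  }
  structure(list(confidence_threshold = confidence_threshold, strict = strict,
                 require_region = require_region,
                 min_piglet_detections = as.integer(min_piglet_detections)),
            class = "pseudo_label_config")
}

#' Filter detections by confidence
#'
#' Keeps the subset whose confidence lies above the threshold (strict `>` by
#' default), preserving order. Monotone: raising the threshold never increases
#' the kept count.
#'
#' @param detections detection data.frame with a `confidence` column.
#' @param config a [pseudo_label_config()] (or a bare numeric threshold).
#' @return filtered detection data.frame.
#' @export
filter_detections <- function(detections, config = pseudo_label_config()) {
  if (is.numeric(config)) config <- pseudo_label_config(confidence_threshold = config)
  if (!nrow(detections)) return(detections)
  keep <- if (isTRUE(config$strict)) {
    detections$confidence > config$confidence_threshold
  } else {
    detections$confidence >= config$confidence_threshold
  }
  out <- detections[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pseudo-annotate one unlabeled frame
#'
#' Runs the teacher on the full frame, picks the best head/rear pair to derive
#' the birth region, crops and rescales the region window, and returns the
#' confidence-filtered tail/piglet detections remapped into crop coordinates.
#' When no valid head/rear pair is found the frame is skipped
#' (`ok = FALSE`, `reason = "no_region"`).
#'
#' @param image grayscale frame matrix.
#' @param teacher a fitted 4-class detector.
#' @param region a [region_params()].
#' @param pl_config a [pseudo_label_config()].
#' @param crop a [crop_spec()].
#' @param label_model optional 2-class detector applied to the cropped target
#'   image instead of remapping the teacher's full-frame detections (used when
#'   a promoted student, which cannot localize head/rear, provides the labels
#'   in later self-training generations).
#' @return list with `ok`; when `ok`, also `image` (target crop), `boxes`
#'   (pseudo-labels in crop coordinates), `region`.
#' @export
pseudo_annotate_frame <- function(image, teacher, region = region_params(),
                                  pl_config = pseudo_label_config(),
                                  crop = crop_spec(), label_model = NULL) {
  dets <- detect_frame(teacher, image)
  hr <- select_head_rear(dets)
  if (is.null(hr)) {
    return(list(ok = FALSE, reason = "no_region"))
  }
  region <- compute_target_region(hr$head, hr$rear, ncol(image), nrow(image), region)
  if (is.null(label_model)) {
    cand <- reduce_classes(dets)
    cand <- filter_detections(cand, pl_config)
    if (isTRUE(pl_config$require_region) && nrow(cand)) {
      cand <- cand[boxes_in_region(cand, region), , drop = FALSE]
    }
    cr <- crop_and_remap(image, cand, region$crop_window, crop)
    target <- cr$image; pboxes <- cr$boxes
  } else {
    cr <- crop_and_remap(image, empty_boxes(confidence = TRUE), region$crop_window, crop)
    target <- cr$image
    pboxes <- filter_detections(reduce_classes(detect_frame(label_model, target)), pl_config)
  }
  if (sum(pboxes$class == "piglet") < pl_config$min_piglet_detections) {
    return(list(ok = FALSE, reason = "too_few_piglets"))
  }
  rownames(pboxes) <- NULL
  list(ok = TRUE, image = target, boxes = pboxes, region = region)
}

#' Build the pseudo-labeled student dataset
#'
#' Applies [pseudo_annotate_frame()] to every record of an unlabeled manifest,
#' writes target-structure images and YOLO-format pseudo-labels (student class
#' map, provenance `"pseudo"`), and emits a review-queue file for the manual
#' verification hook: one line per record, `record_id<TAB>accept<TAB>`,
#' editable to `reject` before [finalize_student_dataset()].
#'
#' @param unlabeled_manifest a [dataset_manifest()]; only its image paths are
#'   used.
#' @param teacher a fitted 4-class detector.
#' @param region,pl_config,crop stage configurations.
#' @param out_dir output directory.
#' @param label_model see [pseudo_annotate_frame()].
#' @return the student [dataset_manifest()]; skip counters are in the
#'   `"counters"` attribute and the review queue path in `"review_queue"`.
#' @export
build_student_dataset <- function(unlabeled_manifest, teacher,
                                  region = region_params(),
                                  pl_config = pseudo_label_config(),
                                  crop = crop_spec(), out_dir,
                                  label_model = NULL) {
  rec <- unlabeled_manifest$records
  if (!nrow(rec)) stopf("unlabeled manifest is empty")
  img_dir <- file.path(out_dir, "images"); lab_dir <- file.path(out_dir, "labels")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(lab_dir, recursive = TRUE, showWarnings = FALSE)
  smap <- student_class_map()
  out <- list(); ids <- character()
  counters <- c(frames_in = nrow(rec), frames_kept = 0L,
                frames_skipped_no_region = 0L, frames_skipped_too_few = 0L)
  for (i in seq_len(nrow(rec))) {
    # attach ground truth when the pool is annotated, so oracle teachers
    # (consistency checks, smoke runs) can read it; real detectors ignore it
    img <- if (nzchar(rec$label[i]) && file.exists(rec$label[i])) {
      load_record(rec[i, ], unlabeled_manifest$class_map)$image
    } else {
      read_image_png(rec$image[i])
    }
    pa <- pseudo_annotate_frame(img, teacher, region, pl_config, crop, label_model)
    if (!pa$ok) {
      key <- if (pa$reason == "no_region") "frames_skipped_no_region" else "frames_skipped_too_few"
      counters[key] <- counters[key] + 1L
      next
    }
    stem <- sprintf("pseudo_%05d", i)
    ip <- file.path(img_dir, paste0(stem, ".png"))
    lp <- file.path(lab_dir, paste0(stem, ".txt"))
    write_image_png(pa$image, ip)
    write_yolo_labels(pa$boxes, ncol(pa$image), nrow(pa$image), smap, lp)
    counters["frames_kept"] <- counters["frames_kept"] + 1L
    ids <- c(ids, stem)
    out[[length(out) + 1L]] <- data.frame(image = ip, label = lp,
                                          provenance = "pseudo", split = "train",
                                          stringsAsFactors = FALSE)
  }
  if (!length(out)) stopf("no frame yielded a valid birth region; student set is empty")
  m <- dataset_manifest(do.call(rbind, out), smap)
  write_manifest(m, file.path(out_dir, "manifest.tsv"))
  rq <- file.path(out_dir, "review_queue.tsv")
  writeLines(sprintf("%s\taccept\t", ids), rq)
  attr(m, "counters") <- counters
  attr(m, "review_queue") <- rq
  m
}

#' Finalize a student dataset against its review queue
#'
#' Reads the review-queue file (lines `record_id<TAB>accept|reject<TAB>note`)
#' and drops rejected records from the manifest, mirroring the manual removal
#' of incorrectly pseudo-labeled instances.
#'
#' @param manifest the student [dataset_manifest()].
#' @param review_path review queue file (defaults to the one emitted by
#'   [build_student_dataset()]).
#' @return the filtered [dataset_manifest()].
#' @export
finalize_student_dataset <- function(manifest, review_path = attr(manifest, "review_queue")) {
  lines <- readLines(review_path, warn = FALSE)
  f <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
  verdict <- vapply(f, function(x) if (length(x) >= 2) x[2] else "accept", "")
  id <- vapply(f, `[`, "", 1)
  if (!all(verdict %in% c("accept", "reject"))) stopf("review verdicts must be accept or reject")
  rejected <- id[verdict == "reject"]
  stems <- sub("\\.png$", "", basename(manifest$records$image))
  keep <- !(stems %in% rejected)
  dataset_manifest(manifest$records[keep, , drop = FALSE], manifest$class_map)
}
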