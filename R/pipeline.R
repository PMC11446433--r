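# Orchestration of the full noisy-student experiment and the dataset-size
# comparison, with seeded reproducibility and per-stage logging.

#' Pipeline configuration
#'
#' Bundles every stage configuration. Manifests may be given as paths or as
#' [dataset_manifest()] objects.
#'
#' @param teacher_manifest manually labeled full-frame training set (teacher
#'   class map).
#' @param unlabeled_manifest pool of frames to pseudo-label (labels unused).
#' @param eval_manifest evaluation set annotated with the teacher class map.
#' @param out_dir output root for models, datasets and reports.
#' @param region,crop,augment,pseudo,eval_cfg stage configurations.
#' @param teacher_train,student_train [train_config()]s; the student default
#'   activates dropout and mixup noise at rate 0.5 each.
#' @param generations number of self-training generations (default 1); in
#'   generation k+1 the generation-k student provides the tail/piglet labels
#'   on the cropped target images while the original teacher keeps providing
#'   head/rear localization.
#' @param include_manual_in_student also add the transformed manual teacher
#'   annotations to the student set (default FALSE: pseudo-labels only).
#' @param flip_teacher flip-expand the teacher training set by factor four as
#'   well (default TRUE, matching the flip augmentation of both datasets).
#' @param teacher_model optional pre-fitted 4-class detector (e.g. an
#'   [oracle_detector()] for smoke runs); when supplied, teacher training is
#'   skipped and this model anchors the pipeline.
#' @param master_seed integer master seed; all stage seeds derive from it.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(teacher_manifest, unlabeled_manifest, eval_manifest,
                            out_dir,
                            region = region_params(), crop = crop_spec(),
                            augment = augmentation_config(),
                            pseudo = pseudo_label_config(),
                            teacher_train = train_config(noise = noise_config(0, 0)),
                            student_train = train_config(noise = noise_config(0.5, 0.5)),
                            eval_cfg = eval_config(),
                            generations = 1L, include_manual_in_student = FALSE,
                            flip_teacher = TRUE, teacher_model = NULL,
                            master_seed = 1L) {
  if (!is_count(generations) || generations < 1) stopf("generations must be >= 1")
  structure(list(teacher_manifest = teacher_manifest,
                 unlabeled_manifest = unlabeled_manifest,
                 eval_manifest = eval_manifest, out_dir = out_dir,
                 region = region, crop = crop, augment = augment, pseudo = pseudo,
                 teacher_train = teacher_train, student_train = student_train,
                 eval_cfg = eval_cfg, generations = as.integer(generations),
                 include_manual_in_student = include_manual_in_student,
                 flip_teacher = flip_teacher, teacher_model = teacher_model,
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

resolve_manifest <- function(x) {
  if (inherits(x, "dataset_manifest")) x else read_manifest(x)
}

# md5 fingerprint of a manifest's label files (content identity of a dataset)
fingerprint_manifest <- function(manifest) {
  h <- unname(tools::md5sum(manifest$records$label))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(h, tmp)
  unname(tools::md5sum(tmp))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  cfg <- rapply(unclass(config), function(x)
    if (inherits(x, "dataset_manifest")) "<manifest>" else x, how = "replace")
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Materialize the flip expansion of a dataset
#'
#' Writes one image + label pair per enabled flip variant per record (default
#' factor four) and returns the expanded manifest.
#'
#' @param manifest a [dataset_manifest()].
#' @param out_dir output directory.
#' @param config an [augmentation_config()].
#' @return the expanded [dataset_manifest()].
#' @export
materialize_flips <- function(manifest, out_dir, config = augmentation_config()) {
  img_dir <- file.path(out_dir, "images"); lab_dir <- file.path(out_dir, "labels")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(lab_dir, recursive = TRUE, showWarnings = FALSE)
  rec <- manifest$records
  out <- vector("list", nrow(rec) * length(config$flips))
  idx <- 0L
  suffix <- c(identity = "o", horizontal = "h", vertical = "v", both = "b")
  for (i in seq_len(nrow(rec))) {
    lr <- load_record(rec[i, ], manifest$class_map)
    stem <- sub("\\.png$", "", basename(rec$image[i]))
    for (v in flip_expand(lr$image, lr$boxes, config)) {
      idx <- idx + 1L
      s <- sprintf("%s_%s", stem, suffix[[v$flip]])
      ip <- file.path(img_dir, paste0(s, ".png"))
      lp <- file.path(lab_dir, paste0(s, ".txt"))
      write_image_png(v$image, ip)
      write_yolo_labels(v$boxes, ncol(v$image), nrow(v$image), manifest$class_map, lp)
      out[[idx]] <- data.frame(image = ip, label = lp,
                               provenance = rec$provenance[i], split = rec$split[i],
                               stringsAsFactors = FALSE)
    }
  }
  m <- dataset_manifest(do.call(rbind, out[seq_len(idx)]), manifest$class_map)
  write_manifest(m, file.path(out_dir, "manifest.tsv"))
  m
}

#' Class distribution of a dataset
#'
#' Counts annotation instances per class (re-parsing every label file) and
#' reports absolute and percentage frequencies, the usual
#' class-distribution bookkeeping table.
#'
#' @param x a [dataset_manifest()], or a named vector of per-class counts.
#' @return data.frame with columns `class`, `count`, `percent`.
#' @export
class_distribution <- function(x) {
  if (inherits(x, "dataset_manifest")) {
    counts <- stats::setNames(rep(0L, length(x$class_map)), as.character(x$class_map))
    for (i in seq_len(nrow(x$records))) {
      d <- png_dim(x$records$image[i])
      b <- read_yolo_labels(x$records$label[i], d[2], d[1], x$class_map)
      tb <- table(b$class)
      counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
    }
  } else {
    counts <- x
  }
  data.frame(class = names(counts), count = as.integer(counts),
             percent = 100 * as.integer(counts) / sum(counts),
             stringsAsFactors = FALSE)
}

stage_log <- function(log_path, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cat(msg, "\n", sep = "")
  if (!is.null(log_path)) cat(msg, "\n", sep = "", file = log_path, append = TRUE)
  invisible(msg)
}

run_stage <- function(name, log_path, expr) {
  stage_log(log_path, "[stage %s] start", name)
  out <- tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
  stage_log(log_path, "[stage %s] done", name)
  out
}

#' Run the noisy-student experiment
#'
#' Trains the teacher on the manual full-frame labels (four classes),
#' pseudo-labels the unlabeled pool inside derived birth regions, flip-expands
#' the pseudo-labeled target crops, trains the student (two classes) under
#' dropout + mixup noise, evaluates both models region-restricted on the same
#' evaluation set, and writes metrics reports plus a provenance log. With
#' `generations > 1` the student is promoted to label-teacher and the cycle
#' repeats.
#'
#' @param config a [pipeline_config()].
#' @return list of class `"noisy_student_run"` with fitted models, evaluation
#'   results and report paths.
#' @export
run_noisy_student <- function(config) {
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mod_dir <- file.path(out_dir, "models"); rep_dir <- file.path(out_dir, "reports")
  dir.create(mod_dir, showWarnings = FALSE); dir.create(rep_dir, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  cat("", file = log_path)

  tm <- resolve_manifest(config$teacher_manifest)
  um <- resolve_manifest(config$unlabeled_manifest)
  em <- resolve_manifest(config$eval_manifest)
  seed <- config$master_seed

  teacher <- if (!is.null(config$teacher_model)) {
    stage_log(log_path, "[stage train_teacher] skipped (pre-fitted teacher supplied)")
    config$teacher_model
  } else {
    teacher_train_set <- if (config$flip_teacher) {
      run_stage("teacher_flips", log_path,
                materialize_flips(tm, file.path(out_dir, "teacher_aug"), config$augment))
    } else tm
    run_stage("train_teacher", log_path,
              reference_train(teacher_train_set, config$teacher_train,
                              seed = derive_seed(seed, 1)))
  }
  save_detector(teacher, file.path(mod_dir, "teacher.rds"))
  teacher_eval <- run_stage("evaluate_teacher", log_path,
                            evaluate_model(teacher, em, config$region,
                                           config$eval_cfg, config$crop))
  write_metrics_report(teacher_eval$metrics,
                       file.path(rep_dir, "teacher_metrics.tsv"),
                       file.path(rep_dir, "teacher_metrics.json"))

  students <- list(); student_evals <- list()
  label_model <- NULL
  for (g in seq_len(config$generations)) {
    gdir <- file.path(out_dir, sprintf("gen%d", g))
    pseudo_set <- run_stage(sprintf("pseudo_label_gen%d", g), log_path,
                            build_student_dataset(um, teacher, config$region,
                                                  config$pseudo, config$crop,
                                                  file.path(gdir, "student_data"),
                                                  label_model = label_model))
    ct <- attr(pseudo_set, "counters")
    stage_log(log_path, "  pseudo-labeled %d/%d frames (%d no region, %d too few piglets)",
              ct["frames_kept"], ct["frames_in"],
              ct["frames_skipped_no_region"], ct["frames_skipped_too_few"])
    if (config$include_manual_in_student) {
      manual_crops <- run_stage(sprintf("manual_crops_gen%d", g), log_path,
                                transform_manual_set(tm, config$region, config$crop,
                                                     file.path(gdir, "manual_data")))
      pseudo_set <- dataset_manifest(rbind(pseudo_set$records, manual_crops$records),
                                     pseudo_set$class_map)
    }
    student_set <- run_stage(sprintf("student_flips_gen%d", g), log_path,
                             materialize_flips(pseudo_set, file.path(gdir, "student_aug"),
                                               config$augment))
    student <- run_stage(sprintf("train_student_gen%d", g), log_path,
                         reference_train(student_set, config$student_train,
                                         seed = derive_seed(seed, 100 + g)))
    save_detector(student, file.path(mod_dir, sprintf("student_gen%d.rds", g)))
    sev <- run_stage(sprintf("evaluate_student_gen%d", g), log_path,
                     evaluate_model(student, em, config$region,
                                    config$eval_cfg, config$crop))
    write_metrics_report(sev$metrics,
                         file.path(rep_dir, sprintf("student_gen%d_metrics.tsv", g)),
                         file.path(rep_dir, sprintf("student_gen%d_metrics.json", g)))
    students[[g]] <- student
    student_evals[[g]] <- sev
    label_model <- student   # promoted student labels the next generation
  }

  prov <- list(master_seed = seed,
               config_hash = config_hash(config),
               teacher_manifest_md5 = fingerprint_manifest(tm),
               unlabeled_manifest_md5 = fingerprint_manifest(um),
               eval_manifest_md5 = fingerprint_manifest(em))
  yaml::write_yaml(prov, file.path(out_dir, "provenance.yaml"))

  structure(list(teacher = teacher, students = students,
                 teacher_eval = teacher_eval, student_evals = student_evals,
                 report_dir = rep_dir, model_dir = mod_dir, provenance = prov),
            class = "noisy_student_run")
}

# Crop + class-reduce the manual teacher set into target structure (used when
# manual annotations are added to the student set).
transform_manual_set <- function(teacher_manifest, region_params, crop, out_dir) {
  img_dir <- file.path(out_dir, "images"); lab_dir <- file.path(out_dir, "labels")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(lab_dir, recursive = TRUE, showWarnings = FALSE)
  smap <- student_class_map()
  rec <- teacher_manifest$records
  out <- list()
  for (i in seq_len(nrow(rec))) {
    lr <- load_record(rec[i, ], teacher_manifest$class_map)
    region <- tryCatch(region_from_annotations(lr$boxes, ncol(lr$image), nrow(lr$image),
                                               region_params),
                       error = function(e) NULL)
    if (is.null(region)) next
    gt <- reduce_classes(lr$boxes, smap)
    gt <- gt[boxes_in_region(gt, region), , drop = FALSE]
    cr <- crop_and_remap(lr$image, gt, region$crop_window, crop)
    stem <- sprintf("manual_%05d", i)
    ip <- file.path(img_dir, paste0(stem, ".png"))
    lp <- file.path(lab_dir, paste0(stem, ".txt"))
    write_image_png(cr$image, ip)
    write_yolo_labels(cr$boxes, ncol(cr$image), nrow(cr$image), smap, lp)
    out[[length(out) + 1L]] <- data.frame(image = ip, label = lp,
                                          provenance = "manual", split = "train",
                                          stringsAsFactors = FALSE)
  }
  m <- dataset_manifest(do.call(rbind, out), smap)
  write_manifest(m, file.path(out_dir, "manifest.tsv"))
  m
}

#' @export
print.noisy_student_run <- function(x, ...) {
  cat("noisy-student run\n")
  cat("teacher (region-restricted):\n"); print(x$teacher_eval$metrics)
  for (g in seq_along(x$student_evals)) {
    cat(sprintf("student generation %d:\n", g)); print(x$student_evals[[g]]$metrics)
  }
  invisible(x)
}

#' Compare teacher and student across training-set sizes
#'
#' For each requested size (and replicate), trains a fresh teacher on a random
#' subset of the manual set and a fresh student on a random subset of the
#' pseudo-labeled set (both subsets drawn before flip expansion, seeded from
#' the master seed), evaluates both region-restricted on the shared evaluation
#' set, and tabulates pooled Recall/Precision/F1 per model and size.
#'
#' @param config a [pipeline_config()].
#' @param sizes ascending vector of training-set sizes (images before flips).
#' @param replicates replicates per size (default 1).
#' @return data.frame of class `"size_comparison"` with one row per
#'   (model, size, replicate).
#' @export
run_size_comparison <- function(config, sizes, replicates = 1L) {
  if (any(diff(sizes) <= 0) || any(sizes < 1)) stopf("sizes must be positive and ascending")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "size_comparison_log.txt")
  cat("", file = log_path)
  tm <- resolve_manifest(config$teacher_manifest)
  um <- resolve_manifest(config$unlabeled_manifest)
  em <- resolve_manifest(config$eval_manifest)
  if (max(sizes) > nrow(tm$records)) {
    stopf("size %d exceeds the %d available teacher training images",
          max(sizes), nrow(tm$records))
  }
  seed <- config$master_seed

  # one full teacher provides the pseudo-labeled pool all student subsets draw from
  full_teacher_set <- if (config$flip_teacher) {
    materialize_flips(tm, file.path(out_dir, "full_teacher_aug"), config$augment)
  } else tm
  full_teacher <- run_stage("train_full_teacher", log_path,
                            reference_train(full_teacher_set, config$teacher_train,
                                            seed = derive_seed(seed, 11)))
  pseudo_set <- run_stage("pseudo_label_pool", log_path,
                          build_student_dataset(um, full_teacher, config$region,
                                                config$pseudo, config$crop,
                                                file.path(out_dir, "student_pool")))
  if (max(sizes) > nrow(pseudo_set$records)) {
    stopf("size %d exceeds the %d available pseudo-labeled images",
          max(sizes), nrow(pseudo_set$records))
  }

  rows <- list()
  for (s in sizes) {
    for (r in seq_len(replicates)) {
      sub_seed <- derive_seed(seed, 1000 + 17 * s + r)
      t_idx <- with_seed(sub_seed, sample.int(nrow(tm$records), s))
      s_idx <- with_seed(sub_seed + 1L, sample.int(nrow(pseudo_set$records), s))
      tdir <- file.path(out_dir, sprintf("size%d_rep%d", s, r))
      t_sub <- dataset_manifest(tm$records[t_idx, , drop = FALSE], tm$class_map)
      t_set <- if (config$flip_teacher) {
        materialize_flips(t_sub, file.path(tdir, "teacher_aug"), config$augment)
      } else t_sub
      s_sub <- dataset_manifest(pseudo_set$records[s_idx, , drop = FALSE],
                                pseudo_set$class_map)
      s_set <- materialize_flips(s_sub, file.path(tdir, "student_aug"), config$augment)
      teacher_s <- run_stage(sprintf("train_teacher_%d_%d", s, r), log_path,
                             reference_train(t_set, config$teacher_train,
                                             seed = derive_seed(sub_seed, 2)))
      student_s <- run_stage(sprintf("train_student_%d_%d", s, r), log_path,
                             reference_train(s_set, config$student_train,
                                             seed = derive_seed(sub_seed, 3)))
      for (mt in c("teacher", "student")) {
        mdl <- if (mt == "teacher") teacher_s else student_s
        ev <- run_stage(sprintf("evaluate_%s_%d_%d", mt, s, r), log_path,
                        evaluate_model(mdl, em, config$region, config$eval_cfg,
                                       config$crop))
        tot <- ev$metrics[ev$metrics$class == "Total", ]
        rows[[length(rows) + 1L]] <- data.frame(
          model = mt, ds_size = s, replicate = r,
          TP = tot$TP, FP = tot$FP, FN = tot$FN,
          recall = tot$recall, precision = tot$precision, f1 = tot$f1,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.table(
    data.frame(Model = paste(out$model, out$ds_size, sep = "_"),
               `DS Size` = out$ds_size, Recall = fmt3(out$recall),
               Precision = fmt3(out$precision), F1 = fmt3(out$f1),
               check.names = FALSE),
    file.path(out_dir, "size_comparison.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  structure(out, class = c("size_comparison", "data.frame"))
}

#' Plot the dataset-size comparison
#'
#' Line plot of pooled F1 (optionally recall/precision) against training-set
#' size for teacher and student models.
#'
#' @param comparison output of [run_size_comparison()].
#' @param path optional PDF path; when `NULL`, plots to the active device.
#' @export
plot_size_comparison <- function(comparison, path = NULL) {
  if (!is.null(path)) {
    grDevices::pdf(path, width = 7, height = 5)
    on.exit(grDevices::dev.off())
  }
  agg <- stats::aggregate(f1 ~ model + ds_size, data = comparison, FUN = mean)
  sizes <- sort(unique(agg$ds_size))
  te <- agg[agg$model == "teacher", ]; st <- agg[agg$model == "student", ]
  graphics::plot(range(sizes), c(0, 1), type = "n", xlab = "training images",
                 ylab = "pooled F1", main = "Teacher vs student by dataset size")
  graphics::lines(te$ds_size[order(te$ds_size)], te$f1[order(te$ds_size)],
                  type = "b", col = "red3", pch = 16)
  graphics::lines(st$ds_size[order(st$ds_size)], st$f1[order(st$ds_size)],
                  type = "b", col = "blue3", pch = 17)
  graphics::legend("bottomright", legend = c("teacher", "student"),
                   col = c("red3", "blue3"), pch = c(16, 17), lty = 1, bty = "n")
  invisible(comparison)
}
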