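# Detector contract and the CPU-scale trainable reference detector.
#
# Any detector backend satisfies the same seam: a class map, a training entry
# point, a `detect_frame()` method returning confidence-scored boxes, and
# state (de)serialization. The reference detector is a classical
# segmentation-based model: it normalizes image intensities robustly, fits
# per-class intensity bands and blob-feature centroids from the training
# boxes, and at prediction time segments the frame into class layers, labels
# connected components, and classifies each component by nearest feature
# centroid with a softmax-style confidence. It exists so the full pipeline is
# trainable and measurable on one CPU; heavier neural backends (e.g. a YOLO
# family model) can be plugged in behind the same contract using the training
# settings carried in `train_config()`.

#' Noise configuration for student training
#'
#' Dropout is realized for the reference detector as random omission of
#' training boxes during fitting (the contract-level analogue of fitting under
#' perturbation); mixup blends a training sample with another uniformly drawn
#' sample, with the blend weight drawn from a symmetric Beta law.
#'
#' @param dropout_rate probability of omitting a training box (default 0.5).
#' @param mixup_rate probability a training sample is mixup-blended (default 0.5).
#' @param mixup_shape Beta shape parameter for the blend weight (default 1.5).
#' @return list of class `"noise_config"`.
#' @export
noise_config <- function(dropout_rate = 0.5, mixup_rate = 0.5, mixup_shape = 1.5) {
  if (dropout_rate < 0 || dropout_rate > 1) stopf("dropout_rate must lie in [0, 1]")
  if (mixup_rate < 0 || mixup_rate > 1) stopf("mixup_rate must lie in [0, 1]")
  structure(list(dropout_rate = dropout_rate, mixup_rate = mixup_rate,
                 mixup_shape = mixup_shape), class = "noise_config")
}

#' Detector training configuration
#'
#' `epochs`, `batch_size`, `input_size` and `learning_rate` carry the standard
#' settings a gradient-trained backend would consume (defaults 300 / 16 /
#' 640 / 0.01); the reference detector fits in closed form and uses only
#' `min_area` (suppression floor for connected components, in pixels of the
#' analyzed image -- a sensor-noise speckle scale) and `noise`.
#'
#' @param epochs,batch_size,input_size,learning_rate backend training settings.
#' @param min_area minimum connected-component area in pixels (default 25).
#' @param noise a [noise_config()]; use `noise_config(0, 0)` for teachers.
#' @return list of class `"train_config"`.
#' @export
train_config <- function(epochs = 300, batch_size = 16, input_size = 640,
                         learning_rate = 0.01, min_area = 25,
                         noise = noise_config(0, 0)) {
  if (epochs < 1 || batch_size < 1 || input_size < 1 || learning_rate <= 0 || min_area < 1) {
    stopf("train_config values must be positive")
  }
  structure(list(epochs = epochs, batch_size = batch_size, input_size = input_size,
                 learning_rate = learning_rate, min_area = min_area, noise = noise),
            class = "train_config")
}

# Robust intensity normalization: denoise with a 3x3 binomial kernel (sensor
# noise would otherwise flood the segmentation on low-light frames), then
# normalize contrast against the pen floor: the 10% quantile estimates the
# floor level, and with a (near) zero black level every object contrast is
# proportional to it under illumination-gain changes. Unlike upper-quantile
# anchors, the floor estimate does not depend on how much sow or how many
# piglets the view contains, so full-pen frames and target crops map to the
# same intensity units.
normalize_frame <- function(px, passes = 1L) {
  sm <- px
  for (i in seq_len(max(1L, passes))) sm <- smooth3(sm)
  lo <- stats::quantile(sm, 0.10, names = FALSE)
  sc <- max(lo, 1)
  list(norm = (sm - lo) / sc, med = lo, scale = sc)
}

weighted_median <- function(x, w) {
  o <- order(x); x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

# Per-box training observation on one (possibly mixup-blended) frame.
# Intensity is the median of the central 60% of the box.
box_intensity_sample <- function(norm, b) {
  h <- nrow(norm); w <- ncol(norm)
  cx0 <- b$x_min + 0.2 * (b$x_max - b$x_min); cx1 <- b$x_max - 0.2 * (b$x_max - b$x_min)
  cy0 <- b$y_min + 0.2 * (b$y_max - b$y_min); cy1 <- b$y_max - 0.2 * (b$y_max - b$y_min)
  rows <- max(1, floor(cy0) + 1):min(h, ceiling(cy1))
  cols <- max(1, floor(cx0) + 1):min(w, ceiling(cx1))
  stats::median(norm[rows, cols])
}

# Blob features of one component: log-area, bounding-box elongation, median
# normalized intensity, distance to the largest blob (normalized by image
# diagonal).
make_features <- function(area, width, height, intensity, dist, diag) {
  c(log_area = log(area), elongation = max(width, height) / max(1e-9, min(width, height)),
    intensity = intensity, dist_largest = dist / diag)
}

#' Train the reference detector
#'
#' Fits, from a labeled manifest: (a) robust per-class intensity-band centers
#' used to segment frames into class layers, (b) per-class blob-feature
#' centroids (log area, elongation, median intensity, distance to the largest
#' blob) used to classify and score components. Centroids are per-feature
#' weighted medians, which keeps mixup-blended observations from biasing the
#' fit; the confidence bandwidth `sigma` is the median standardized distance
#' of training observations to their own class centroid. Deterministic for a
#' fixed `(manifest, config, seed)`.
#'
#' @param manifest a [dataset_manifest()] with at least one labeled image.
#' @param config a [train_config()].
#' @param seed integer seed (drives dropout/mixup noise realization).
#' @return fitted model of class `"reference_detector"`.
#' @export
reference_train <- function(manifest, config = train_config(), seed = 0L) {
  rec <- manifest$records
  cmap <- manifest$class_map
  if (!nrow(rec)) stopf("manifest has no records")
  n <- nrow(rec)
  labels <- lapply(seq_len(n), function(i) {
    img_dim <- png_dim(rec$image[i])
    read_yolo_labels(rec$label[i], img_dim[2], img_dim[1], cmap)
  })

  # noise plan (fixed before any image is read, so both passes agree)
  plan <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      nb <- nrow(labels[[i]])
      keep <- if (config$noise$dropout_rate > 0 && nb) {
        stats::runif(nb) >= config$noise$dropout_rate
      } else rep(TRUE, nb)
      mix <- n > 1 && config$noise$mixup_rate > 0 &&
        stats::runif(1) < config$noise$mixup_rate
      partner <- if (mix) sample.int(n - 1L, 1L) else NA_integer_
      if (mix && partner >= i) partner <- partner + 1L
      lam <- if (mix) stats::rbeta(1, config$noise$mixup_shape, config$noise$mixup_shape) else 1
      list(keep = keep, partner = partner, lambda = lam)
    })
  })

  # assemble the effective training frame for record i under the noise plan
  frame_for <- function(i) {
    li <- load_record(rec[i, ], cmap)
    bi <- li$boxes[plan[[i]]$keep, , drop = FALSE]
    if (!is.na(plan[[i]]$partner)) {
      j <- plan[[i]]$partner
      lj <- load_record(rec[j, ], cmap)
      bj <- lj$boxes[plan[[j]]$keep, , drop = FALSE]
      if (all(dim(lj$image) == dim(li$image))) {
        mp <- mixup_pair(li$image, bi, lj$image, bj, plan[[i]]$lambda)
        return(mp)
      }
    }
    bi$weight <- rep(1, nrow(bi))
    list(image = li$image, boxes = bi)
  }

  # single image pass: collect per-box padded subimages (in normalized
  # intensity units) plus background samples; features are derived from the
  # cached subimages once the intensity bands are known.
  obs <- list(); bg_samples <- numeric()
  for (i in seq_len(n)) {
    fr <- frame_for(i)
    nf <- normalize_frame(fr$image)
    b <- fr$boxes
    bg_samples <- c(bg_samples,
                    sample_background(nf$norm, b, 400L, seed = derive_seed(seed, i)))
    if (!nrow(b)) next
    h <- nrow(fr$image); w <- ncol(fr$image)
    diag_len <- sqrt(h^2 + w^2)
    largest <- box_center(b[which.max(box_area(b)), , drop = FALSE])[1, ]
    for (k in seq_len(nrow(b))) {
      bb <- b[k, , drop = FALSE]
      r0 <- max(1, floor(bb$y_min) - 2); r1 <- min(h, ceiling(bb$y_max) + 2)
      c0 <- max(1, floor(bb$x_min) - 2); c1 <- min(w, ceiling(bb$x_max) + 2)
      bl <- bb
      bl$x_min <- bb$x_min - (c0 - 1); bl$x_max <- bb$x_max - (c0 - 1)
      bl$y_min <- bb$y_min - (r0 - 1); bl$y_max <- bb$y_max - (r0 - 1)
      obs[[length(obs) + 1L]] <- list(
        class = bb$class, w = bb$weight,
        sub = nf$norm[r0:r1, c0:c1, drop = FALSE], box = bl,
        dist = sqrt(sum((box_center(bb)[1, ] - largest)^2)), diag = diag_len,
        ival = box_intensity_sample(nf$norm, bb))
    }
  }
  if (!length(obs)) stopf("no training boxes of any mapped class")
  ocls <- vapply(obs, `[[`, "", "class")
  ow <- vapply(obs, `[[`, 0, "w")
  # multi-modal background: non-box pixels include any unannotated structure
  # (in target crops, most of the sow body), so several levels are fitted
  bg <- bg_levels(bg_samples, k = 3L)
  intensity <- stats::setNames(bg, paste0(".background", seq_along(bg)))
  for (cl in cmap) {
    s <- ocls == cl
    if (any(s)) {
      intensity[cl] <- weighted_median(vapply(obs[s], `[[`, 0, "ival"), ow[s])
    } else {
      warning(sprintf("no training boxes for class '%s'; class will never be predicted", cl),
              call. = FALSE)
    }
  }

  feats <- lapply(obs, function(o) {
    fe <- box_features(o$sub, o$box, intensity, o$dist, o$diag)
    data.frame(class = o$class, t(fe), w = o$w)
  })
  fm <- do.call(rbind, feats)
  fnames <- c("log_area", "elongation", "intensity", "dist_largest")
  pooled_med <- vapply(fnames, function(f) weighted_median(fm[[f]], fm$w), 0)
  feat_scale <- vapply(fnames, function(f) {
    s <- weighted_median(abs(fm[[f]] - pooled_med[[f]]), fm$w)
    max(s, 0.05)
  }, 0)
  centroids <- t(vapply(as.character(cmap), function(cl) {
    s <- fm[fm$class == cl, , drop = FALSE]
    if (!nrow(s)) return(rep(NA_real_, 4))
    vapply(fnames, function(f) weighted_median(s[[f]], s$w), 0)
  }, numeric(4)))
  colnames(centroids) <- fnames

  dist_own <- vapply(seq_len(nrow(fm)), function(r) {
    ct <- centroids[fm$class[r], ]
    if (anyNA(ct)) return(NA_real_)
    sqrt(sum(((as.numeric(fm[r, fnames]) - ct) / feat_scale)^2))
  }, 0)
  sigma <- weighted_median(dist_own[!is.na(dist_own)], fm$w[!is.na(dist_own)])
  sigma <- max(sigma, 0.3)

  # object-scale prior: the model works at the scale of its training blobs;
  # per class, components far below the class's typical area (15% of its
  # robust median) are suppressed, never below the configured speckle floor
  min_area <- stats::setNames(vapply(as.character(cmap), function(cl) {
    la <- centroids[cl, "log_area"]
    if (is.na(la)) config$min_area else max(config$min_area, 0.15 * exp(la))
  }, 0), as.character(cmap))

  # denoising bandwidth matched to the object scale: models fitted on larger
  # blobs (e.g. upscaled target crops) smooth more aggressively at prediction
  obj_scale <- sqrt(min(exp(centroids[, "log_area"]), na.rm = TRUE))
  smooth_passes <- max(1L, min(4L, as.integer(round(obj_scale / 10))))

  structure(list(class_map = cmap, intensity = intensity, centroids = centroids,
                 feat_scale = feat_scale, sigma = sigma,
                 min_area = min_area, smooth_passes = smooth_passes, n_train = n,
                 config = config, version = 1L),
            class = "reference_detector")
}

# (height, width) from the PNG IHDR chunk without decoding the image
png_dim <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- as.integer(readBin(con, "raw", 24L))
  c(sum(hdr[21:24] * 256^(3:0)), sum(hdr[17:20] * 256^(3:0)))
}

sample_background <- function(norm, b, n_px, seed) {
  h <- nrow(norm); w <- ncol(norm)
  with_seed(seed, {
    idx <- sample.int(h * w, min(n_px * 3L, h * w))
    rr <- (idx - 1L) %% h + 1L; cc <- (idx - 1L) %/% h + 1L
    if (nrow(b)) {
      inside <- rep(FALSE, length(idx))
      for (k in seq_len(nrow(b))) {
        inside <- inside | (cc - 0.5 > b$x_min[k] & cc - 0.5 < b$x_max[k] &
                            rr - 0.5 > b$y_min[k] & rr - 0.5 < b$y_max[k])
      }
      rr <- rr[!inside]; cc <- cc[!inside]
    }
    utils::head(norm[cbind(rr, cc)], n_px)
  })
}

# Features of the blob backing one training box: segment the padded box
# subimage (normalized units) by nearest intensity center, take the largest
# component of the box's class (fallback: the box geometry itself).
box_features <- function(sub, b, intensity, dist, diag_len) {
  lvl <- intensity[!is.na(intensity)]
  if (b$class %in% names(lvl)) {
    assign_idx <- nearest_level(sub, lvl)
    mask <- clean_mask(matrix(names(lvl)[assign_idx] == b$class, nrow(sub), ncol(sub)))
    lab <- EBImage::bwlabel(mask)
    if (max(lab) > 0) {
      areas <- tabulate(lab[lab > 0])
      kbest <- which.max(areas)
      pix <- which(lab == kbest, arr.ind = TRUE)
      bw <- diff(range(pix[, 2])) + 1; bh <- diff(range(pix[, 1])) + 1
      return(make_features(areas[kbest], bw, bh, stats::median(sub[lab == kbest]),
                           dist, diag_len))
    }
  }
  make_features(max(1, box_area(b)), b$x_max - b$x_min, b$y_max - b$y_min,
                box_intensity_sample(sub, b), dist, diag_len)
}

# index of nearest intensity level per pixel
nearest_level <- function(norm, lvl) {
  v <- as.vector(norm)
  d <- abs(outer(v, unname(lvl), "-"))
  max.col(-d, ties.method = "first")
}

# k background intensity levels from non-box pixel samples: quantile-seeded
# 1-d Lloyd iterations with median updates (deterministic).
bg_levels <- function(x, k = 3L, iters = 10L) {
  ctr <- stats::quantile(x, probs = seq(0.15, 0.85, length.out = k), names = FALSE)
  for (it in seq_len(iters)) {
    idx <- max.col(-abs(outer(x, ctr, "-")), ties.method = "first")
    for (j in seq_len(k)) {
      if (any(idx == j)) ctr[j] <- stats::median(x[idx == j])
    }
    ctr <- sort(ctr)
  }
  unique(ctr)
}

# 3x3 morphological opening of a logical mask: removes speckle and the thin
# transition rings left around blob boundaries by optical blur.
clean_mask <- function(mask) {
  EBImage::opening(mask, matrix(1L, 3, 3)) > 0
}

#' Run a detector on a grayscale frame
#'
#' Generic seam shared by all backends: returns a detection table (boxes with
#' a `confidence` column in `[0, 1]`) in the frame's pixel coordinates,
#' deterministically for a fixed model and input.
#'
#' @param model a fitted detector (e.g. from [reference_train()]).
#' @param image grayscale matrix, 0-255.
#' @param ... backend-specific arguments.
#' @return data.frame of detections.
#' @export
detect_frame <- function(model, image, ...) UseMethod("detect_frame")

#' @rdname detect_frame
#' @export
detect_frame.reference_detector <- function(model, image, ...) {
  nf <- normalize_frame(image, if (is.null(model$smooth_passes)) 1L else model$smooth_passes)
  lvl <- model$intensity[!is.na(model$intensity)]
  classes <- names(lvl)[!startsWith(names(lvl), ".background")]
  classes <- classes[!apply(model$centroids[classes, , drop = FALSE], 1, anyNA)]
  if (!length(classes)) return(empty_boxes(confidence = TRUE))
  assign_idx <- nearest_level(nf$norm, lvl)
  assign_name <- names(lvl)[assign_idx]
  h <- nrow(image); w <- ncol(image)
  comp <- list()
  for (cl in classes) {
    mask <- matrix(assign_name == cl, h, w)
    if (!any(mask)) next
    lab <- EBImage::bwlabel(clean_mask(mask))
    pos <- which(lab > 0)
    if (!length(pos)) next
    lv <- as.integer(lab[pos])
    areas <- tabulate(lv)
    ma <- if (length(model$min_area) > 1) model$min_area[[cl]] else model$min_area
    keep <- which(areas >= ma)
    if (!length(keep)) next
    sel <- lv %in% keep
    f <- factor(lv[sel], levels = keep)
    rr <- (pos[sel] - 1L) %% h + 1L
    cc <- (pos[sel] - 1L) %/% h + 1L
    vals <- nf$norm[pos[sel]]
    r0 <- tapply(rr, f, min); r1 <- tapply(rr, f, max)
    c0 <- tapply(cc, f, min); c1 <- tapply(cc, f, max)
    med <- tapply(vals, f, stats::median)
    for (j in seq_along(keep)) {
      comp[[length(comp) + 1L]] <- list(
        layer = cl, area = areas[keep[j]],
        r0 = r0[[j]], r1 = r1[[j]], c0 = c0[[j]], c1 = c1[[j]],
        intensity = med[[j]])
    }
  }
  if (!length(comp)) return(empty_boxes(confidence = TRUE))
  areas <- vapply(comp, `[[`, 0, "area")
  big <- comp[[which.max(areas)]]
  big_ctr <- c((big$c0 + big$c1) / 2 - 0.5, (big$r0 + big$r1) / 2 - 0.5)
  diag_len <- sqrt(h^2 + w^2)
  out <- vector("list", length(comp))
  for (i in seq_along(comp)) {
    cm <- comp[[i]]
    ctr <- c((cm$c0 + cm$c1) / 2 - 0.5, (cm$r0 + cm$r1) / 2 - 0.5)
    fe <- make_features(cm$area, cm$c1 - cm$c0 + 1, cm$r1 - cm$r0 + 1, cm$intensity,
                        sqrt(sum((ctr - big_ctr)^2)), diag_len)
    d2 <- vapply(classes, function(cl) {
      sum(((fe - model$centroids[cl, ]) / model$feat_scale)^2)
    }, 0)
    if (length(d2) > 1) {
      lik <- exp(-(d2 - min(d2)) / (2 * model$sigma^2))
      conf <- lik / sum(lik)
    } else {
      # degenerate single-class model: fall back to the raw likelihood so the
      # score still reflects how typical the blob is of the class
      conf <- exp(-d2 / (2 * (3 * model$sigma)^2))
    }
    best <- which.max(conf)
    # boxes are the tight bounds of the segmented component; optical blur
    # pulls the contour slightly inside the true edge, a scale-dependent
    # localization bias that small objects feel most
    out[[i]] <- data.frame(class = classes[best],
                           x_min = cm$c0 - 1, y_min = cm$r0 - 1,
                           x_max = cm$c1, y_max = cm$r1,
                           confidence = unname(conf[best]),
                           stringsAsFactors = FALSE)
  }
  b <- do.call(rbind, out)
  rownames(b) <- NULL
  b
}

#' @export
predict.reference_detector <- function(object, image, ...) detect_frame(object, image, ...)

#' @export
print.reference_detector <- function(x, ...) {
  cat(sprintf("reference_detector: %d classes (%s), trained on %d images\n",
              length(x$class_map), paste(x$class_map, collapse = ", "), x$n_train))
  cat(sprintf("  sigma = %.3f, min_area = %s px\n", x$sigma,
              paste(as.integer(x$min_area), collapse = "/")))
  invisible(x)
}

#' @export
summary.reference_detector <- function(object, ...) {
  print(object)
  cat("  intensity bands (normalized units):\n")
  for (nm in names(object$intensity)) {
    cat(sprintf("    %-12s %.3f\n", nm, object$intensity[[nm]]))
  }
  cat("  feature centroids:\n")
  print(round(object$centroids, 3))
  invisible(object)
}

#' Serialize / restore a fitted detector
#'
#' @param model a fitted detector.
#' @param path state file path.
#' @export
save_detector <- function(model, path) {
  saveRDS(model, path, version = 2)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, c("reference_detector", "oracle_detector"))) {
    stopf("not a detector state file: %s", path)
  }
  m
}

#' Ground-truth oracle detector
#'
#' A detector-contract fixture that returns the ground-truth boxes attached to
#' a frame (the `"truth"` attribute set by the package's loaders) with
#' confidence 1.0, filtered to its class map. Used for end-to-end consistency
#' checks and the pipeline's oracle smoke mode.
#'
#' @param class_map a [class_map()].
#' @return object of classes `"oracle_detector"`.
#' @export
oracle_detector <- function(class_map = teacher_class_map()) {
  structure(list(class_map = class_map), class = "oracle_detector")
}

#' @rdname detect_frame
#' @export
detect_frame.oracle_detector <- function(model, image, ...) {
  b <- attr(image, "truth")
  if (is.null(b)) return(empty_boxes(confidence = TRUE))
  b <- b[b$class %in% model$class_map, , drop = FALSE]
  b$confidence <- rep(1, nrow(b))
  rownames(b) <- NULL
  b
}
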