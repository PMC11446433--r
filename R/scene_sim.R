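# Seeded synthetic farrowing-pen scenes with pixel-accurate ground truth.
#
# A scene holds one sow rendered as two overlapping filled ellipses (head lobe
# and rear lobe along the head-to-rear axis), a short dark tail mark at the
# rear apex, and 0-20 small piglet ellipses whose centers are sampled with
# elevated density behind the sow's rear. Piglets flagged as occluded are
# drawn below the sow (or below another piglet), so parts of their ground-truth
# boxes are covered by the occluder -- boxes are the tight bounds of each
# rendered shape before occlusion compositing, matching the annotation
# practice of boxing partially visible animals.

# Flat rendering intensities per class layer (8-bit scene units, before the
# illumination model is applied).
.scene_intensity <- c(background = 70, head = 140, rear = 180, piglet = 230, tail = 25)

#' Scene generator parameters
#'
#' @param image_width,image_height frame dimensions in pixels (default 640).
#' @param sow_length_range nose-to-rump sow length range in pixels.
#' @param piglet_count_range integer interval for the number of piglets,
#'   within `[0, 20]`.
#' @param piglet_axis_range piglet body length (major axis) range in pixels.
#' @param occlusion_rate probability that a piglet is drawn partially under
#'   the sow or under another piglet.
#' @param illumination subset of `c("day", "night")`; when both are given each
#'   scene draws its condition uniformly. Day uses full gain and mild sensor
#'   noise, night halved gain, a small offset and stronger noise.
#' @param background_texture_std intensity SD of the coarse floor texture.
#' @param day,night illumination models: lists with `gain`, `offset`,
#'   `noise_sd` (intensity units).
#' @return list of class `"scene_params"`.
#' @export
scene_params <- function(image_width = 640, image_height = 640,
                         sow_length_range = c(260, 340),
                         piglet_count_range = c(0, 14),
                         piglet_axis_range = c(12, 20),
                         occlusion_rate = 0.3,
                         illumination = c("day", "night"),
                         background_texture_std = 6,
                         day = list(gain = 1, offset = 0, noise_sd = 5),
                         night = list(gain = 0.5, offset = 4, noise_sd = 9)) {
  p <- structure(list(image_width = as.integer(image_width),
                      image_height = as.integer(image_height),
                      sow_length_range = as.numeric(sow_length_range),
                      piglet_count_range = as.integer(piglet_count_range),
                      piglet_axis_range = as.numeric(piglet_axis_range),
                      occlusion_rate = occlusion_rate,
                      illumination = illumination,
                      background_texture_std = background_texture_std,
                      day = day, night = night),
                 class = "scene_params")
  validate_scene_params(p)
  p
}

validate_scene_params <- function(p) {
  if (p$image_width < 32 || p$image_height < 32) stopf("image dimensions too small")
  if (any(p$sow_length_range <= 0) || p$sow_length_range[1] > p$sow_length_range[2]) {
    stopf("sow_length_range must be a positive, ordered interval")
  }
  if (any(p$piglet_count_range < 0) || any(p$piglet_count_range > 20) ||
      p$piglet_count_range[1] > p$piglet_count_range[2]) {
    stopf("piglet_count_range must be an ordered interval within [0, 20]")
  }
  if (any(p$piglet_axis_range <= 0) || p$piglet_axis_range[1] > p$piglet_axis_range[2]) {
    stopf("piglet_axis_range must be a positive, ordered interval")
  }
  if (p$occlusion_rate < 0 || p$occlusion_rate > 1) stopf("occlusion_rate must lie in [0, 1]")
  if (!all(p$illumination %in% c("day", "night")) || !length(p$illumination)) {
    stopf("illumination must be a non-empty subset of c('day', 'night')")
  }
  invisible(p)
}

# Pixel set of a rotated filled ellipse; returns NULL when fully outside.
ellipse_mask <- function(cx, cy, a, b, theta, width, height) {
  hx <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
  hy <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
  cols <- max(1L, floor(cx - hx)) : min(width, ceiling(cx + hx))
  rows <- max(1L, floor(cy - hy)) : min(height, ceiling(cy + hy))
  if (!length(cols) || !length(rows) || cols[1] > cols[length(cols)]) return(NULL)
  px <- rep(cols, each = length(rows)) - 0.5 - cx
  py <- rep(rows, times = length(cols)) - 0.5 - cy
  u <- (px * cos(theta) + py * sin(theta)) / a
  v <- (-px * sin(theta) + py * cos(theta)) / b
  inside <- u * u + v * v <= 1
  if (!any(inside)) return(NULL)
  list(rows = rep(rows, times = length(cols))[inside],
       cols = rep(cols, each = length(rows))[inside])
}

mask_box <- function(class, mask) {
  data.frame(class = class,
             x_min = min(mask$cols) - 1, y_min = min(mask$rows) - 1,
             x_max = max(mask$cols), y_max = max(mask$rows),
             stringsAsFactors = FALSE)
}

boxes_disjoint <- function(b, others, gap = 2) {
  if (!nrow(others)) return(TRUE)
  !any(b$x_min - gap < others$x_max & b$x_max + gap > others$x_min &
       b$y_min - gap < others$y_max & b$y_max + gap > others$y_min)
}

#' Generate one synthetic farrowing scene
#'
#' Deterministic for a fixed `(params, seed)` pair. The returned annotation
#' contains exactly one head, one rear and one tail box plus one box per
#' piglet; boxes are tight bounds of each rendered shape before occlusion.
#'
#' @param params a [scene_params()].
#' @param seed integer seed.
#' @return list of class `"annotated_scene"` with `pixels` (8-bit grayscale
#'   matrix), `boxes`, `source_id` and `meta` (illumination, sow pose,
#'   piglet count).
#' @export
generate_scene <- function(params = scene_params(), seed = 1L) {
  validate_scene_params(params)
  with_seed(seed, {
    W <- params$image_width; H <- params$image_height
    L <- runif(1, params$sow_length_range[1], params$sow_length_range[2])
    inset <- 0.52 * L + 12
    if (2 * inset >= W || 2 * inset >= H) {
      stopf("image too small for sow_length_range (need > %.0f px)", 2 * inset)
    }
    theta <- runif(1, 0, 2 * pi)
    u <- c(cos(theta), sin(theta))
    mid <- c(runif(1, inset, W - inset), runif(1, inset, H - inset))
    d <- 0.5 * L
    head_c <- mid - (d / 2) * u
    rear_c <- mid + (d / 2) * u
    # lobe semi-axes as fractions of the sow length
    head_ax <- c(0.22, 0.145) * L
    rear_ax <- c(0.26, 0.170) * L
    tail_c <- rear_c + rear_ax[1] * u      # tail mark centered on the rear apex
    tail_ax <- c(6, 3)

    head_mask <- ellipse_mask(head_c[1], head_c[2], head_ax[1], head_ax[2], theta, W, H)
    rear_mask <- ellipse_mask(rear_c[1], rear_c[2], rear_ax[1], rear_ax[2], theta, W, H)
    tail_mask <- ellipse_mask(tail_c[1], tail_c[2], tail_ax[1], tail_ax[2], theta, W, H)
    if (is.null(head_mask) || is.null(rear_mask) || is.null(tail_mask)) {
      stopf("internal: sow rendering left the image")
    }
    sow_boxes <- rbind(mask_box("head", head_mask),
                       mask_box("rear", rear_mask),
                       mask_box("tail", tail_mask))

    # --- piglets ------------------------------------------------------------
    cr <- params$piglet_count_range
    n <- cr[1] + sample.int(cr[2] - cr[1] + 1L, 1L) - 1L
    bias_center <- rear_c + 0.15 * d * u
    bias_radius <- 0.5 * d
    piglets <- list()   # each: list(cx, cy, a, b, th, box, occluded, pos)
    for (k in seq_len(n)) {
      occluded <- runif(1) < params$occlusion_rate
      placed <- FALSE
      for (attempt in 1:400) {
        len <- runif(1, params$piglet_axis_range[1], params$piglet_axis_range[2])
        a <- len / 2; b <- 0.275 * len
        th <- runif(1, 0, 2 * pi)
        insert_at <- length(piglets) + 1L
        if (occluded && length(piglets) && runif(1) < 0.3) {
          # partially under an already placed piglet
          j <- sample.int(length(piglets), 1L)
          dir <- runif(1, 0, 2 * pi)
          ctr <- c(piglets[[j]]$cx, piglets[[j]]$cy) + 0.6 * len * c(cos(dir), sin(dir))
          insert_at <- j
        } else if (occluded) {
          # centered on the rear-lobe outline, drawn below the sow
          phi <- runif(1, 0, 2 * pi)
          ctr <- rear_c + c(rear_ax[1] * cos(phi) * cos(theta) - rear_ax[2] * sin(phi) * sin(theta),
                            rear_ax[1] * cos(phi) * sin(theta) + rear_ax[2] * sin(phi) * cos(theta))
        } else if (runif(1) < 0.8) {
          rr <- bias_radius * sqrt(runif(1)); aa <- runif(1, 0, 2 * pi)
          ctr <- bias_center + rr * c(cos(aa), sin(aa))
        } else {
          ctr <- c(runif(1, 12, W - 12), runif(1, 12, H - 12))
        }
        hx <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
        hy <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
        cand <- data.frame(x_min = ctr[1] - hx, y_min = ctr[2] - hy,
                           x_max = ctr[1] + hx, y_max = ctr[2] + hy)
        if (cand$x_min < 2 || cand$y_min < 2 || cand$x_max > W - 2 || cand$y_max > H - 2) next
        if (!occluded && length(piglets)) {
          prev <- do.call(rbind, lapply(piglets, function(p) p$box[, c("x_min", "y_min", "x_max", "y_max")]))
          if (!boxes_disjoint(cand, prev, gap = 2)) next
        }
        entry <- list(cx = ctr[1], cy = ctr[2], a = a, b = b, th = th,
                      box = cbind(data.frame(class = "piglet", stringsAsFactors = FALSE), cand),
                      occluded = occluded, under_sow = occluded && insert_at > length(piglets))
        piglets <- append(piglets, list(entry), after = insert_at - 1L)
        placed <- TRUE
        break
      }
      if (!placed) stopf("could not place piglet %d; image too crowded for the requested counts", k)
    }

    # --- compositing (z-order: under-sow piglets < sow < tail < piglets) ----
    # coarse floor texture: a low-resolution Gaussian field upsampled
    # bilinearly (smooth intensity variation, no hard patch edges)
    tex_cell <- 16L
    tw <- ceiling(W / tex_cell) + 1L; th_ <- ceiling(H / tex_cell) + 1L
    tex <- matrix(rnorm(tw * th_, 0, params$background_texture_std), th_, tw)
    xs <- (seq_len(W) - 0.5) * tw / W
    ys <- (seq_len(H) - 0.5) * th_ / H
    scene <- .scene_intensity[["background"]] +
      matrix(bilinear_sample(tex, rep(xs, each = H), rep(ys, times = W)), H, W)

    paint <- function(mask, value) scene[cbind(mask$rows, mask$cols)] <<- value
    piglet_masks <- lapply(piglets, function(p)
      ellipse_mask(p$cx, p$cy, p$a, p$b, p$th, W, H))
    for (i in seq_along(piglets)) {
      if (piglets[[i]]$under_sow) paint(piglet_masks[[i]], .scene_intensity[["piglet"]])
    }
    paint(head_mask, .scene_intensity[["head"]])
    paint(rear_mask, .scene_intensity[["rear"]])
    paint(tail_mask, .scene_intensity[["tail"]])
    for (i in seq_along(piglets)) {
      if (!piglets[[i]]$under_sow) paint(piglet_masks[[i]], .scene_intensity[["piglet"]])
    }

    illum <- if (length(params$illumination) == 1) params$illumination else
      params$illumination[sample.int(length(params$illumination), 1L)]
    im <- params[[illum]]
    out <- smooth3(scene) * im$gain + im$offset +
      matrix(rnorm(W * H, 0, im$noise_sd), H, W)
    pixels <- quantize8(out)

    piglet_boxes <- if (length(piglets)) {
      do.call(rbind, lapply(piglets, function(p) {
        m <- ellipse_mask(p$cx, p$cy, p$a, p$b, p$th, W, H)
        mask_box("piglet", m)
      }))
    } else empty_boxes()
    all_boxes <- rbind(sow_boxes, piglet_boxes)
    rownames(all_boxes) <- NULL

    structure(list(pixels = pixels, boxes = all_boxes,
                   source_id = sprintf("scene_%d", as.integer(seed)),
                   meta = list(illumination = illum, n_piglets = n,
                               head_center = head_c, rear_center = rear_c,
                               sow_length = L, theta = theta)),
              class = "annotated_scene")
  })
}

#' @export
print.annotated_scene <- function(x, ...) {
  cat(sprintf("annotated_scene %s: %dx%d px, %s, %d piglets, %d boxes\n",
              x$source_id, ncol(x$pixels), nrow(x$pixels),
              x$meta$illumination, x$meta$n_piglets, nrow(x$boxes)))
  invisible(x)
}

#' Generate a dataset of synthetic scenes on disk
#'
#' Writes `n_images` grayscale PNGs with YOLO-format label files (teacher
#' class map) and a manifest. Per-image seeds are derived reproducibly from
#' the master seed, so two runs with the same arguments produce identical
#' files.
#'
#' @param params a [scene_params()].
#' @param n_images number of scenes (>= 1).
#' @param seed master seed.
#' @param out_dir output directory (created if needed).
#' @param split `"train"` or `"eval"` tag recorded in the manifest.
#' @param prefix filename prefix.
#' @return the [dataset_manifest()], with per-scene piglet counts in the
#'   `"piglet_counts"` attribute.
#' @export
generate_dataset <- function(params, n_images, seed, out_dir,
                             split = "train", prefix = "scene") {
  if (!is_count(n_images) || n_images < 1) stopf("n_images must be >= 1")
  img_dir <- file.path(out_dir, "images"); lab_dir <- file.path(out_dir, "labels")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(lab_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir)) stopf("cannot create output directory %s", img_dir)
  cmap <- teacher_class_map()
  rec <- vector("list", n_images)
  counts <- integer(n_images)
  for (i in seq_len(n_images)) {
    sc <- generate_scene(params, derive_seed(seed, i))
    stem <- sprintf("%s_%05d", prefix, i)
    ip <- file.path(img_dir, paste0(stem, ".png"))
    lp <- file.path(lab_dir, paste0(stem, ".txt"))
    write_image_png(sc$pixels, ip)
    write_yolo_labels(sc$boxes, params$image_width, params$image_height, cmap, lp)
    counts[i] <- sc$meta$n_piglets
    rec[[i]] <- data.frame(image = ip, label = lp, provenance = "manual",
                           split = split, stringsAsFactors = FALSE)
  }
  m <- dataset_manifest(do.call(rbind, rec), cmap)
  write_manifest(m, file.path(out_dir, "manifest.tsv"))
  attr(m, "piglet_counts") <- counts
  m
}
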