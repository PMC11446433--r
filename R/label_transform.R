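# Target-image construction and augmentation: crop + rescale + class
# reduction, flip expansion, mixup blending.

#' Crop specification
#'
#' @param out_width,out_height output dimensions of the cropped target image
#'   (default 640 x 640).
#' @param retention_threshold minimum fraction of a box's area that must fall
#'   inside the crop window for the box to be kept (default 0.5); kept boxes
#'   are clipped to the window.
#' @return list of class `"crop_spec"`.
#' @export
crop_spec <- function(out_width = 640, out_height = 640, retention_threshold = 0.5) {
  if (retention_threshold <= 0 || retention_threshold > 1) {
    stopf("retention_threshold must lie in (0, 1]")
  }
  if (out_width < 1 || out_height < 1) stopf("output dimensions must be positive")
  structure(list(out_width = as.integer(out_width), out_height = as.integer(out_height),
                 retention_threshold = retention_threshold),
            class = "crop_spec")
}

#' Crop a window out of an image and remap its annotations
#'
#' The window contents are bilinearly resampled to the output size. Each box is
#' intersected with the window and kept iff the intersection covers at least
#' `retention_threshold` of its original area; kept boxes are clipped,
#' translated to window coordinates and scaled per-axis to the output size.
#' Extra box columns (confidence, weight) are preserved.
#'
#' @param image grayscale pixel matrix.
#' @param boxes data.frame of boxes in the source frame.
#' @param window single-row box data.frame: the crop window in source pixels.
#' @param spec a [crop_spec()].
#' @return list with `image` (resampled window) and `boxes` (remapped).
#' @export
crop_and_remap <- function(image, boxes, window, spec = crop_spec()) {
  x0 <- window$x_min[1]; y0 <- window$y_min[1]
  x1 <- window$x_max[1]; y1 <- window$y_max[1]
  if (!(x1 > x0 && y1 > y0)) stopf("crop window has non-positive area")
  if (x1 <= 0 || y1 <= 0 || x0 >= ncol(image) || y0 >= nrow(image)) {
    stopf("crop window lies outside the image")
  }
  out <- crop_pixels(image, x0, y0, x1, y1, spec$out_width, spec$out_height)
  sx <- spec$out_width / (x1 - x0)
  sy <- spec$out_height / (y1 - y0)
  if (nrow(boxes)) {
    ix_min <- pmax(boxes$x_min, x0); iy_min <- pmax(boxes$y_min, y0)
    ix_max <- pmin(boxes$x_max, x1); iy_max <- pmin(boxes$y_max, y1)
    inter <- pmax(0, ix_max - ix_min) * pmax(0, iy_max - iy_min)
    keep <- inter >= spec$retention_threshold * box_area(boxes) & inter > 0
    b <- boxes[keep, , drop = FALSE]
    if (nrow(b)) {
      b$x_min <- (pmax(b$x_min, x0) - x0) * sx
      b$x_max <- (pmin(b$x_max, x1) - x0) * sx
      b$y_min <- (pmax(b$y_min, y0) - y0) * sy
      b$y_max <- (pmin(b$y_max, y1) - y0) * sy
    }
    rownames(b) <- NULL
  } else {
    b <- boxes
  }
  list(image = out, boxes = b)
}

#' Reduce annotations to the student class space
#'
#' Drops head and rear boxes; tail/piglet boxes are kept in their original
#' order. Idempotent on inputs already restricted to student classes.
#'
#' @param boxes data.frame of boxes.
#' @param student_map a [class_map()] (default [student_class_map()]).
#' @return data.frame of boxes with classes drawn from `student_map`.
#' @export
reduce_classes <- function(boxes, student_map = student_class_map()) {
  b <- boxes[boxes$class %in% student_map, , drop = FALSE]
  rownames(b) <- NULL
  b
}

#' Augmentation configuration
#'
#' @param flips character subset of `c("identity", "horizontal", "vertical",
#'   "both")`; the default enables all four, multiplying a dataset by four.
#' @param mixup_rate probability that a student training sample is replaced by
#'   a mixup pair (default 0.5).
#' @param mixup_shape shape parameter of the symmetric Beta law the mixup
#'   weight is drawn from (default 1.5).
#' @param seed integer seed for augmentation randomness.
#' @return list of class `"augmentation_config"`.
#' @export
augmentation_config <- function(flips = c("identity", "horizontal", "vertical", "both"),
                                mixup_rate = 0.5, mixup_shape = 1.5, seed = 0L) {
  flips <- match.arg(flips, c("identity", "horizontal", "vertical", "both"),
                     several.ok = TRUE)
  if (mixup_rate < 0 || mixup_rate > 1) stopf("mixup_rate must lie in [0, 1]")
  if (mixup_shape <= 0) stopf("mixup_shape must be positive")
  structure(list(flips = flips, mixup_rate = mixup_rate,
                 mixup_shape = mixup_shape, seed = as.integer(seed)),
            class = "augmentation_config")
}

# Flip an image+boxes pair. mode in identity/horizontal/vertical/both.
flip_one <- function(image, boxes, mode) {
  h <- nrow(image); w <- ncol(image)
  b <- boxes
  if (mode %in% c("horizontal", "both")) {
    image <- image[, rev(seq_len(w)), drop = FALSE]
    if (nrow(b)) {
      x0 <- w - b$x_max; x1 <- w - b$x_min
      b$x_min <- x0; b$x_max <- x1
    }
  }
  if (mode %in% c("vertical", "both")) {
    image <- image[rev(seq_len(h)), , drop = FALSE]
    if (nrow(b)) {
      y0 <- h - b$y_max; y1 <- h - b$y_min
      b$y_min <- y0; b$y_max <- y1
    }
  }
  list(image = image, boxes = b, flip = mode)
}

#' Expand a sample into its flip variants
#'
#' Produces one output per enabled flip variant (default four: identity,
#' horizontal, vertical, both), the factor-four dataset expansion. A corner
#' (x, y) maps to (W - x, y) under horizontal and (x, H - y) under vertical
#' flips, with min/max corners re-normalized.
#'
#' @inheritParams crop_and_remap
#' @param config an [augmentation_config()].
#' @return list of `list(image, boxes, flip)` entries.
#' @export
flip_expand <- function(image, boxes, config = augmentation_config()) {
  lapply(config$flips, function(m) flip_one(image, boxes, m))
}

#' Mixup-blend two annotated images
#'
#' Pixels are interpolated as `lambda * A + (1 - lambda) * B` in real
#' arithmetic and quantized once; the box list is the concatenation of both
#' inputs, each tagged with its source weight in a `weight` column (for loss
#' weighting by trainable backends).
#'
#' @param image_a,image_b grayscale matrices of identical dimensions.
#' @param boxes_a,boxes_b box data.frames in the respective image frames.
#' @param lambda mixing weight in `[0, 1]` applied to sample A.
#' @return list with `image` and `boxes`.
#' @export
mixup_pair <- function(image_a, boxes_a, image_b, boxes_b, lambda) {
  if (!all(dim(image_a) == dim(image_b))) stopf("mixup images must share dimensions")
  if (lambda < 0 || lambda > 1) stopf("lambda must lie in [0, 1]")
  img <- quantize8(lambda * image_a + (1 - lambda) * image_b)
  ba <- boxes_a; bb <- boxes_b
  ba$weight <- rep(lambda, nrow(ba)); bb$weight <- rep(1 - lambda, nrow(bb))
  common <- union(names(ba), names(bb))
  for (nm in setdiff(common, names(ba))) ba[[nm]] <- rep(NA, nrow(ba))
  for (nm in setdiff(common, names(bb))) bb[[nm]] <- rep(NA, nrow(bb))
  b <- rbind(ba[common], bb[common])
  rownames(b) <- NULL
  list(image = img, boxes = b)
}
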