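# Annotation and image I/O: YOLO label files, LabelMe JSON, 8-bit grayscale
# PNG images, dataset manifests.

#' Read a YOLO-format label file
#'
#' Each line holds `class_index cx cy w h` with center/size normalized to
#' `[0, 1]` relative to the image dimensions. Coordinates are converted to
#' pixel min/max corners using per-axis scale factors (aspect distortion is
#' permitted); line order is preserved.
#'
#' @param path label file path.
#' @param image_width,image_height image dimensions in pixels.
#' @param class_map a [class_map()] giving the index-to-name mapping.
#' @return data.frame of boxes (see [boxes()]).
#' @export
read_yolo_labels <- function(path, image_width, image_height, class_map) {
  if (!file.exists(path)) stopf("label file does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_boxes())
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  out <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- suppressWarnings(as.numeric(parts[[i]]))
    if (length(p) != 5 || anyNA(p)) {
      stopf("malformed YOLO label line %d in %s", i, path)
    }
    cls <- class_name(class_map, p[1])
    cx <- p[2] * image_width;  w <- p[4] * image_width
    cy <- p[3] * image_height; h <- p[5] * image_height
    out[[i]] <- data.frame(class = cls,
                           x_min = cx - w / 2, y_min = cy - h / 2,
                           x_max = cx + w / 2, y_max = cy + h / 2,
                           stringsAsFactors = FALSE)
  }
  b <- do.call(rbind, out)
  validate_boxes(b)
  b
}

#' Write boxes as a YOLO-format label file
#'
#' Inverse of [read_yolo_labels()]; coordinates are serialized in normalized
#' center format at fixed 6-decimal precision.
#'
#' @inheritParams read_yolo_labels
#' @param boxes data.frame of boxes in pixel corner coordinates.
#' @return `path`, invisibly.
#' @export
write_yolo_labels <- function(boxes, image_width, image_height, class_map, path) {
  validate_boxes(boxes)
  if (!nrow(boxes)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  idx <- class_index(class_map, boxes$class)
  cx <- (boxes$x_min + boxes$x_max) / 2 / image_width
  cy <- (boxes$y_min + boxes$y_max) / 2 / image_height
  w <- (boxes$x_max - boxes$x_min) / image_width
  h <- (boxes$y_max - boxes$y_min) / image_height
  writeLines(sprintf("%d %.6f %.6f %.6f %.6f", idx, cx, cy, w, h), path)
  invisible(path)
}

#' Read a LabelMe JSON annotation file
#'
#' Supports rectangle shapes only. Corner points are normalized to
#' (min, max) order regardless of how they were stored. Labels may be mapped
#' onto canonical class names through `synonyms` (e.g. `c("Sow tail" = "tail")`).
#'
#' @param path LabelMe JSON path.
#' @param class_map a [class_map()]; labels (after synonym mapping) must be
#'   members of it.
#' @param synonyms optional named character vector mapping file labels to
#'   class-map names.
#' @return list with `image_width`, `image_height` and `boxes`.
#' @export
read_labelme <- function(path, class_map, synonyms = NULL) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  shapes <- doc$shapes
  out <- vector("list", length(shapes))
  for (i in seq_along(shapes)) {
    s <- shapes[[i]]
    if (!identical(s$shape_type, "rectangle")) {
      stopf("unsupported LabelMe shape '%s' (rectangles only)", s$shape_type)
    }
    lab <- s$label
    if (!is.null(synonyms) && lab %in% names(synonyms)) lab <- unname(synonyms[[lab]])
    if (!lab %in% class_map) stopf("unknown LabelMe label '%s'", s$label)
    p1 <- as.numeric(s$points[[1]]); p2 <- as.numeric(s$points[[2]])
    out[[i]] <- data.frame(class = lab,
                           x_min = min(p1[1], p2[1]), y_min = min(p1[2], p2[2]),
                           x_max = max(p1[1], p2[1]), y_max = max(p1[2], p2[2]),
                           stringsAsFactors = FALSE)
  }
  b <- if (length(out)) do.call(rbind, out) else empty_boxes()
  validate_boxes(b)
  list(image_width = doc$imageWidth, image_height = doc$imageHeight, boxes = b)
}

#' Convert an RGB image to 8-bit grayscale
#'
#' Uses the BT.601 luma weights (0.299, 0.587, 0.114).
#'
#' @param pixels_rgb numeric array `[height, width, 3]` with values in 0–255.
#' @return numeric matrix `[height, width]`, quantized to 0–255.
#' @export
to_grayscale <- function(pixels_rgb) {
  d <- dim(pixels_rgb)
  if (length(d) == 2) return(quantize8(pixels_rgb))
  if (length(d) != 3 || d[3] < 3) stopf("expected a [height, width, 3] RGB array")
  quantize8(0.299 * pixels_rgb[, , 1] + 0.587 * pixels_rgb[, , 2] + 0.114 * pixels_rgb[, , 3])
}

#' Resize a grayscale image by bilinear interpolation
#'
#' Pixel-center aligned bilinear resampling with per-axis scale factors
#' (aspect distortion permitted), quantized to 8-bit with round-half-to-even.
#'
#' @param pixels numeric matrix `[height, width]`, 0–255.
#' @param target_width,target_height output dimensions in pixels.
#' @return numeric matrix `[target_height, target_width]`.
#' @export
resize_image <- function(pixels, target_width, target_height) {
  if (!is_count(target_width) || !is_count(target_height) ||
      target_width < 1 || target_height < 1) {
    stopf("target dimensions must be positive integers")
  }
  if (target_width == ncol(pixels) && target_height == nrow(pixels)) {
    return(quantize8(pixels))
  }
  crop_pixels(pixels, 0, 0, ncol(pixels), nrow(pixels), target_width, target_height)
}

# Resample the window [x0,x1]x[y0,y1] of `pixels` onto an out_w x out_h grid.
crop_pixels <- function(pixels, x0, y0, x1, y1, out_w, out_h) {
  xs <- x0 + (seq_len(out_w) - 0.5) * (x1 - x0) / out_w
  ys <- y0 + (seq_len(out_h) - 0.5) * (y1 - y0) / out_h
  xm <- matrix(rep(xs, each = out_h), nrow = out_h)
  ym <- matrix(rep(ys, times = out_w), nrow = out_h)
  quantize8(matrix(bilinear_sample(pixels, as.vector(xm), as.vector(ym)), nrow = out_h))
}

#' Read / write 8-bit grayscale PNG images
#'
#' Images are numeric matrices `[height, width]` with intensities 0–255.
#' Color PNGs are converted on read via [to_grayscale()]. The read image
#' carries its source path in the `"source"` attribute.
#'
#' @param path PNG file path.
#' @return `read_image_png()`: the pixel matrix; `write_image_png()`: `path`.
#' @export
read_image_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) {
    px <- to_grayscale(px[, , 1:3] * 255)
  } else {
    px <- quantize8(px * 255)
  }
  attr(px, "source") <- path
  px
}

#' @rdname read_image_png
#' @param pixels numeric matrix `[height, width]`, 0–255.
#' @export
write_image_png <- function(pixels, path) {
  png::writePNG(quantize8(pixels) / 255, path)
  invisible(path)
}

# ---- dataset manifests ------------------------------------------------------

#' Dataset manifests
#'
#' A manifest lists (image, label, provenance, split) records together with the
#' class map its label files are indexed by. Provenance is `"manual"` for
#' human-annotated (or simulator ground-truth) labels and `"pseudo"` for
#' teacher-generated labels.
#'
#' @param records data.frame with columns `image`, `label`, `provenance`
#'   (`manual`/`pseudo`), `split` (`train`/`eval`).
#' @param class_map a [class_map()].
#' @return object of class `"dataset_manifest"`.
#' @export
dataset_manifest <- function(records, class_map) {
  need <- c("image", "label", "provenance", "split")
  if (!all(need %in% names(records))) {
    stopf("manifest records need columns: %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(records$image)) stopf("duplicate image paths in manifest")
  if (!all(records$provenance %in% c("manual", "pseudo"))) {
    stopf("provenance must be 'manual' or 'pseudo'")
  }
  rownames(records) <- NULL
  structure(list(records = records[need], class_map = class_map),
            class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("dataset_manifest: %d records (%s); classes: %s\n",
              nrow(x$records),
              paste(sprintf("%s=%d", names(table(x$records$provenance)),
                            as.integer(table(x$records$provenance))), collapse = ", "),
              paste(x$class_map, collapse = ", ")))
  invisible(x)
}

#' Write / read a dataset manifest
#'
#' Plain-text TSV with a `#classes` header line; paths are stored relative to
#' the manifest file and resolved on read.
#'
#' @param manifest a [dataset_manifest()].
#' @param path file path for the manifest (`.tsv`).
#' @return `write_manifest()`: `path`; `read_manifest()`: the manifest with
#'   absolute paths.
#' @export
write_manifest <- function(manifest, path) {
  dir <- dirname(normalizePath(path, mustWork = FALSE))
  rec <- manifest$records
  rel <- function(p) {
    p <- normalizePath(p, mustWork = FALSE)
    sub(paste0("^", gsub("([][{}()+*^$.|\\\\?])", "\\\\\\1", dir), "/?"), "", p)
  }
  rec$image <- vapply(rec$image, rel, character(1))
  rec$label <- vapply(rec$label, rel, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#classes\t", paste(manifest$class_map, collapse = ",")), con)
  writeLines("image\tlabel\tprovenance\tsplit", con)
  if (nrow(rec)) {
    writeLines(sprintf("%s\t%s\t%s\t%s", rec$image, rec$label, rec$provenance, rec$split), con)
  }
  invisible(path)
}

#' @rdname write_manifest
#' @param check_files verify that every referenced file exists.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "#classes\t")) {
    stopf("not a manifest file (missing #classes header): %s", path)
  }
  cmap <- class_map(strsplit(sub("^#classes\t", "", lines[1]), ",", fixed = TRUE)[[1]])
  body <- lines[-(1:2)]
  dir <- dirname(normalizePath(path))
  if (length(body)) {
    f <- strsplit(body, "\t", fixed = TRUE)
    rec <- data.frame(image = vapply(f, `[`, "", 1), label = vapply(f, `[`, "", 2),
                      provenance = vapply(f, `[`, "", 3), split = vapply(f, `[`, "", 4),
                      stringsAsFactors = FALSE)
    abs <- function(p) ifelse(startsWith(p, "/"), p, file.path(dir, p))
    rec$image <- abs(rec$image); rec$label <- abs(rec$label)
  } else {
    rec <- data.frame(image = character(), label = character(),
                      provenance = character(), split = character())
  }
  if (check_files && nrow(rec)) {
    missing <- c(rec$image, rec$label)[!file.exists(c(rec$image, rec$label))]
    if (length(missing)) stopf("manifest references missing file: %s", missing[1])
  }
  dataset_manifest(rec, cmap)
}

# Load one manifest record: image matrix (with "source" + "truth" attributes)
# and its ground-truth boxes.
load_record <- function(record, class_map) {
  img <- read_image_png(record$image)
  b <- read_yolo_labels(record$label, ncol(img), nrow(img), class_map)
  attr(img, "truth") <- b
  list(image = img, boxes = b)
}
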