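# Bounding boxes and class maps.
#
# Boxes live in continuous pixel coordinates: origin at the top-left corner of
# the pixel grid, x rightward, y downward. A box is a row of a data.frame with
# columns class, x_min, y_min, x_max, y_max; detections carry an extra
# `confidence` column, mixup-weighted boxes a `weight` column.

#' Construct a bounding-box table
#'
#' @param class character vector of class names.
#' @param x_min,y_min,x_max,y_max numeric vectors of box corners in pixel
#'   coordinates (origin top-left, x rightward, y downward).
#' @param confidence optional numeric vector in `[0, 1]`; when supplied the
#'   result is a detection table.
#' @return data.frame with one row per box.
#' @examples
#' boxes(c("piglet", "tail"), c(10, 40), c(10, 40), c(30, 52), c(22, 46))
#' @export
boxes <- function(class = character(), x_min = numeric(), y_min = numeric(),
                  x_max = numeric(), y_max = numeric(), confidence = NULL) {
  b <- data.frame(class = as.character(class),
                  x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                  x_max = as.numeric(x_max), y_max = as.numeric(y_max),
                  stringsAsFactors = FALSE)
  if (!is.null(confidence)) b$confidence <- as.numeric(confidence)
  validate_boxes(b)
  b
}

#' Validate a bounding-box table
#'
#' Checks required columns, strict corner ordering (`x_min < x_max`,
#' `y_min < y_max`) and, when present, confidences in `[0, 1]`.
#' @param b data.frame of boxes.
#' @return `b`, invisibly.
#' @export
validate_boxes <- function(b) {
  need <- c("class", "x_min", "y_min", "x_max", "y_max")
  if (!all(need %in% names(b))) {
    stopf("box table must have columns: %s", paste(need, collapse = ", "))
  }
  if (nrow(b)) {
    bad <- which(!(b$x_min < b$x_max & b$y_min < b$y_max))
    if (length(bad)) stopf("degenerate box (zero or negative extent) at row %d", bad[1])
    if ("confidence" %in% names(b) &&
        any(b$confidence < 0 | b$confidence > 1 | !is.finite(b$confidence))) {
      stopf("detection confidences must lie in [0, 1]")
    }
  }
  invisible(b)
}

empty_boxes <- function(confidence = FALSE) {
  b <- data.frame(class = character(), x_min = numeric(), y_min = numeric(),
                  x_max = numeric(), y_max = numeric(), stringsAsFactors = FALSE)
  if (confidence) b$confidence <- numeric()
  b
}

box_area <- function(b) pmax(0, b$x_max - b$x_min) * pmax(0, b$y_max - b$y_min)

box_center <- function(b) cbind(x = (b$x_min + b$x_max) / 2, y = (b$y_min + b$y_max) / 2)

# Clip boxes to [0,W]x[0,H]; rows reduced to zero area are dropped.
clip_boxes <- function(b, width, height) {
  if (!nrow(b)) return(b)
  b$x_min <- pmax(b$x_min, 0); b$y_min <- pmax(b$y_min, 0)
  b$x_max <- pmin(b$x_max, width); b$y_max <- pmin(b$y_max, height)
  b[b$x_min < b$x_max & b$y_min < b$y_max, , drop = FALSE]
}

#' Class maps
#'
#' A class map is an ordered character vector of class names; the YOLO integer
#' index of a class is its position minus one. The teacher dialect covers the
#' four annotated classes of the full-pen images, the student dialect the two
#' classes kept inside the birth region.
#'
#' @param names character vector of unique class names.
#' @return character vector of class `"class_map"`.
#' @examples
#' teacher_class_map()
#' student_class_map()
#' @export
class_map <- function(names) {
  names <- as.character(names)
  if (!length(names) || anyDuplicated(names)) stopf("class names must be non-empty and unique")
  structure(names, class = "class_map")
}

#' @rdname class_map
#' @export
teacher_class_map <- function() class_map(c("head", "rear", "tail", "piglet"))

#' @rdname class_map
#' @export
student_class_map <- function() class_map(c("tail", "piglet"))

class_index <- function(map, class) {
  idx <- match(class, map)
  if (anyNA(idx)) stopf("class '%s' not present in class map", class[which(is.na(idx))[1]])
  idx - 1L
}

class_name <- function(map, index) {
  index <- as.integer(index)
  if (any(index < 0 | index >= length(map))) {
    stopf("class index %d out of range for a %d-class map",
          index[which(index < 0 | index >= length(map))[1]], length(map))
  }
  unclass(map)[index + 1L]
}
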