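# Restricted birth region: the circular area behind the sow's rear derived
# from the head and rear boxes, plus the square crop window bounding it.

#' Parameters of the restricted birth region
#'
#' The region is a circle placed on the sow's head-to-rear axis. With `d` the
#' head-to-rear center distance, the circle center sits
#' `center_offset_alpha * d` beyond the rear center along the axis and the
#' radius is `max(radius_beta * d, min_radius_px)`.
#'
#' @param center_offset_alpha dimensionless axial offset fraction (default 0.15).
#' @param radius_beta dimensionless radius fraction (default 0.45).
#' @param min_radius_px radius floor in pixels (default 16).
#' @return list of class `"region_params"`.
#' @export
region_params <- function(center_offset_alpha = 0.15, radius_beta = 0.45,
                          min_radius_px = 16) {
  if (radius_beta <= 0) stopf("radius_beta must be positive")
  if (min_radius_px < 1) stopf("min_radius_px must be >= 1")
  structure(list(center_offset_alpha = center_offset_alpha,
                 radius_beta = radius_beta, min_radius_px = min_radius_px),
            class = "region_params")
}

#' Compute the restricted birth region from head and rear boxes
#'
#' The sow axis is the unit vector from the head box center to the rear box
#' center. The crop window is the axis-aligned square of side `2 * radius`
#' centered on the circle, clipped to the image bounds.
#'
#' @param head_box,rear_box single-row box data.frames (see [boxes()]).
#' @param image_width,image_height image dimensions in pixels.
#' @param params a [region_params()].
#' @return object of class `"target_region"`: list with `center`, `radius`,
#'   `axis` (head-to-rear unit vector), `crop_window` (clipped) and
#'   `window_unclipped`.
#' @export
compute_target_region <- function(head_box, rear_box, image_width, image_height,
                                  params = region_params()) {
  hc <- as.numeric(box_center(head_box)[1, ])
  rc <- as.numeric(box_center(rear_box)[1, ])
  delta <- rc - hc
  d <- sqrt(sum(delta^2))
  if (d == 0) stopf("degenerate sow pose: head and rear centers coincide")
  axis <- delta / d
  center <- rc + params$center_offset_alpha * d * axis
  radius <- max(params$radius_beta * d, params$min_radius_px)
  win <- data.frame(class = "window",
                    x_min = center[1] - radius, y_min = center[2] - radius,
                    x_max = center[1] + radius, y_max = center[2] + radius,
                    stringsAsFactors = FALSE)
  clipped <- clip_boxes(win, image_width, image_height)
  if (!nrow(clipped)) stopf("birth region falls entirely outside the image")
  structure(list(center = center, radius = radius, axis = axis,
                 crop_window = clipped, window_unclipped = win),
            class = "target_region")
}

#' @export
print.target_region <- function(x, ...) {
  cat(sprintf("target_region: center (%.1f, %.1f), radius %.1f px\n",
              x$center[1], x$center[2], x$radius))
  invisible(x)
}

#' Test whether points fall inside the birth region
#'
#' Membership is inclusive: points at distance exactly `radius` are inside.
#'
#' @param point numeric vector `c(x, y)` or a two-column matrix of points.
#' @param region a `"target_region"`.
#' @return logical vector.
#' @export
point_in_region <- function(point, region) {
  p <- if (is.matrix(point)) point else matrix(point, ncol = 2)
  (p[, 1] - region$center[1])^2 + (p[, 2] - region$center[2])^2 <= region$radius^2
}

# Region membership for boxes: decided by the box center point.
boxes_in_region <- function(b, region) {
  if (!nrow(b)) return(logical(0))
  point_in_region(box_center(b), region)
}

#' Derive the birth region from an annotation set
#'
#' Requires exactly one head and one rear box; delegates to
#' [compute_target_region()].
#'
#' @param boxes data.frame of boxes containing one `head` and one `rear` row.
#' @inheritParams compute_target_region
#' @export
region_from_annotations <- function(boxes, image_width, image_height,
                                    params = region_params()) {
  h <- boxes[boxes$class == "head", , drop = FALSE]
  r <- boxes[boxes$class == "rear", , drop = FALSE]
  if (nrow(h) != 1) stopf("annotation set must contain exactly one head box (found %d)", nrow(h))
  if (nrow(r) != 1) stopf("annotation set must contain exactly one rear box (found %d)", nrow(r))
  compute_target_region(h, r, image_width, image_height, params)
}

# Pick the single best head and rear detection: highest confidence, ties
# broken by larger area. Returns NULL when either class is absent.
select_head_rear <- function(detections) {
  pick <- function(cls) {
    d <- detections[detections$class == cls, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    conf <- if ("confidence" %in% names(d)) d$confidence else rep(1, nrow(d))
    d[order(-conf, -box_area(d))[1], , drop = FALSE]
  }
  h <- pick("head"); r <- pick("rear")
  if (is.null(h) || is.null(r)) return(NULL)
  list(head = h, rear = r)
}

#' Render the region over an image for visual QA
#'
#' Draws the sow axis, the region circle and the crop window into a copy of
#' the image (bright overlay), mirroring the usual debug view of the
#' transformation.
#'
#' @param image grayscale matrix.
#' @param region a `"target_region"`.
#' @param value overlay intensity (default 255).
#' @return the annotated pixel matrix.
#' @export
draw_region_debug <- function(image, region, value = 255) {
  h <- nrow(image); w <- ncol(image)
  th <- seq(0, 2 * pi, length.out = 360)
  cx <- region$center[1] + region$radius * cos(th)
  cy <- region$center[2] + region$radius * sin(th)
  put <- function(x, y) {
    r <- ceiling(y); c <- ceiling(x)
    ok <- r >= 1 & r <= h & c >= 1 & c <= w
    image[cbind(r[ok], c[ok])] <<- value
  }
  put(cx, cy)
  t <- seq(0, 1, length.out = 200)
  a0 <- region$center - region$radius * region$axis
  put(a0[1] + t * 2 * region$radius * region$axis[1],
      a0[2] + t * 2 * region$radius * region$axis[2])
  wn <- region$crop_window
  put(seq(wn$x_min, wn$x_max, length.out = 200), rep(wn$y_min, 200))
  put(seq(wn$x_min, wn$x_max, length.out = 200), rep(wn$y_max, 200))
  put(rep(wn$x_min, 200), seq(wn$y_min, wn$y_max, length.out = 200))
  put(rep(wn$x_max, 200), seq(wn$y_min, wn$y_max, length.out = 200))
  image
}
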