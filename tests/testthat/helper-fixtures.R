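# Shared fixtures: desk-scale scene parameters and a brute-force optimal
# matching oracle used to validate the greedy matcher.

# Small frames keep the unit tests fast; proportions mirror the default
# benchmark scenes.
small_params <- function(...) {
  defaults <- list(image_width = 224, image_height = 224,
                   sow_length_range = c(85, 105),
                   piglet_count_range = c(1, 6),
                   piglet_axis_range = c(10, 16))
  do.call(scene_params, utils::modifyList(defaults, list(...)))
}

tiny_dataset <- function(dir, n, seed, params = small_params(), split = "train") {
  generate_dataset(params, n, seed, dir, split = split)
}

random_box <- function(cls, width = 100, height = 100) {
  x0 <- runif(1, 0, max(width - 12, 1)); y0 <- runif(1, 0, max(height - 12, 1))
  w <- runif(1, 2, max(4, width * 0.3)); h <- runif(1, 2, max(4, height * 0.3))
  boxes(cls, x0, y0, x0 + w, y0 + h)
}

random_box_set <- function(n, classes = c("tail", "piglet"), confidence = FALSE,
                           width = 100, height = 100) {
  if (n == 0) {
    b <- boxes()
    if (confidence) b$confidence <- numeric()
    return(b)
  }
  b <- do.call(rbind, lapply(seq_len(n), function(i)
    random_box(sample(classes, 1), width, height)))
  if (confidence) b$confidence <- runif(n)
  b
}

# Exhaustive optimal one-to-one matching: maximizes the number of matched
# (same-class, IoU >= threshold) pairs by recursive enumeration. Independent
# of the greedy implementation.
optimal_match_count <- function(gt, det, iou_threshold = 0.5, class_aware = TRUE) {
  if (!nrow(gt) || !nrow(det)) return(0L)
  feas <- matrix(FALSE, nrow(det), nrow(gt))
  for (i in seq_len(nrow(det))) {
    for (j in seq_len(nrow(gt))) {
      ok <- !class_aware || det$class[i] == gt$class[j]
      feas[i, j] <- ok && iou(det[i, ], gt[j, ]) >= iou_threshold
    }
  }
  best <- 0L
  recurse <- function(i, used, matched) {
    if (matched + (nrow(det) - i + 1) <= best) return()
    if (i > nrow(det)) {
      best <<- max(best, matched)
      return()
    }
    for (j in which(feas[i, ] & !used)) {
      used[j] <- TRUE
      recurse(i + 1L, used, matched + 1L)
      used[j] <- FALSE
    }
    recurse(i + 1L, used, matched)
  }
  recurse(1L, rep(FALSE, nrow(gt)), 0L)
  best
}
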