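# Birth-region geometry: closed-form cases, rigid-motion equivariance,
# membership.

axis_case_head <- boxes("head", -2, -2, 2, 2)
axis_case_rear <- boxes("rear", 8, -2, 12, 2)

test_that("axis-aligned region cases match hand-computed geometry", {
  r <- compute_target_region(axis_case_head, axis_case_rear, 200, 200,
                             region_params(center_offset_alpha = 0,
                                           radius_beta = 0.5, min_radius_px = 1))
  expect_equal(r$center, c(10, 0))
  expect_equal(r$radius, 5)
  expect_equal(r$axis, c(1, 0))
  expect_equal(as.numeric(r$window_unclipped[1, 2:5]), c(5, -5, 15, 5))
  # clipped to the image at y = 0
  expect_equal(as.numeric(r$crop_window[1, 2:5]), c(5, 0, 15, 5))

  r2 <- compute_target_region(axis_case_head, axis_case_rear, 200, 200,
                              region_params(center_offset_alpha = 0.2,
                                            radius_beta = 0.5, min_radius_px = 1))
  expect_equal(r2$center, c(12, 0))

  r3 <- compute_target_region(boxes("head", -1, -1, 1, 1), boxes("rear", 5, 7, 7, 9),
                              200, 200,
                              region_params(0, 0.5, 1))
  expect_equal(r3$center, c(6, 8))   # d = 10 along (0.6, 0.8)
  expect_equal(r3$radius, 5)
})

test_that("region center and radius are equivariant under rigid motions", {
  p <- region_params(center_offset_alpha = 0.15, radius_beta = 0.45, min_radius_px = 1)
  h0 <- c(40, 50); r0 <- c(70, 58)
  base <- compute_target_region(boxes("head", h0[1] - 2, h0[2] - 2, h0[1] + 2, h0[2] + 2),
                                boxes("rear", r0[1] - 2, r0[2] - 2, r0[1] + 2, r0[2] + 2),
                                1e4, 1e4, p)
  for (ang in seq(0, 2 * pi, length.out = 13)[-13]) {
    for (k in 1:3) {
      tr <- c(4000 + 37 * k, 5000 + 11 * k)
      rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
      h <- as.numeric(rot %*% h0) + tr
      r <- as.numeric(rot %*% r0) + tr
      got <- compute_target_region(boxes("head", h[1] - 2, h[2] - 2, h[1] + 2, h[2] + 2),
                                   boxes("rear", r[1] - 2, r[2] - 2, r[1] + 2, r[2] + 2),
                                   1e4, 1e4, p)
      expect_equal(got$center, as.numeric(rot %*% base$center) + tr, tolerance = 1e-9)
      expect_equal(got$radius, base$radius, tolerance = 1e-9)
    }
  }
})

test_that("scaling the head-rear separation scales the radius above the floor", {
  p <- region_params(0, 0.5, min_radius_px = 4)
  mk <- function(s) compute_target_region(boxes("head", -1, -1, 1, 1),
                                          boxes("rear", 10 * s - 1, -1, 10 * s + 1, 1),
                                          1e4, 1e4, p)
  expect_equal(mk(3)$radius, 3 * mk(1)$radius)
  # below the floor the minimum radius applies
  tiny <- compute_target_region(boxes("head", -1, -1, 1, 1),
                                boxes("rear", 1, -1, 3, 1), 1e4, 1e4, p)
  expect_equal(tiny$radius, 4)
})

test_that("the unclipped window always contains the full circle", {
  set.seed(7)
  for (k in 1:50) {
    h <- runif(2, 50, 150); r <- h + runif(2, -40, 40)
    if (all(h == r)) next
    reg <- compute_target_region(boxes("head", h[1] - 2, h[2] - 2, h[1] + 2, h[2] + 2),
                                 boxes("rear", r[1] - 2, r[2] - 2, r[1] + 2, r[2] + 2),
                                 1e4, 1e4, region_params())
    w <- reg$window_unclipped
    expect_lte(w$x_min, reg$center[1] - reg$radius + 1e-12)
    expect_gte(w$x_max, reg$center[1] + reg$radius - 1e-12)
    expect_lte(w$y_min, reg$center[2] - reg$radius + 1e-12)
    expect_gte(w$y_max, reg$center[2] + reg$radius - 1e-12)
  }
})

test_that("point membership matches the brute-force distance check, boundary inclusive", {
  reg <- compute_target_region(axis_case_head, axis_case_rear, 500, 500,
                               region_params(0, 0.5, 1))
  expect_true(point_in_region(reg$center, reg))
  expect_true(point_in_region(reg$center + c(reg$radius, 0), reg))
  expect_false(point_in_region(reg$center + c(reg$radius + 1e-9, 0), reg))
  set.seed(13)
  pts <- cbind(runif(10000, -20, 40), runif(10000, -30, 30))
  got <- point_in_region(pts, reg)
  want <- sqrt((pts[, 1] - reg$center[1])^2 + (pts[, 2] - reg$center[2])^2) <= reg$radius
  expect_identical(got, want)
})

test_that("region_from_annotations delegates and enforces the head/rear contract", {
  sc <- generate_scene(small_params(), 3)
  reg <- region_from_annotations(sc$boxes, 224, 224)
  h <- sc$boxes[sc$boxes$class == "head", ]
  r <- sc$boxes[sc$boxes$class == "rear", ]
  direct <- compute_target_region(h, r, 224, 224)
  expect_equal(reg$center, direct$center)
  expect_equal(reg$radius, direct$radius)

  expect_error(region_from_annotations(rbind(sc$boxes, h), 224, 224), "exactly one head")
  expect_error(region_from_annotations(sc$boxes[sc$boxes$class != "rear", ], 224, 224),
               "exactly one rear")
  # coincident centers are a degenerate pose
  expect_error(compute_target_region(boxes("head", 0, 0, 4, 4), boxes("rear", 0, 0, 4, 4),
                                     100, 100), "degenerate")
})

test_that("the debug renderer marks the region without resizing the image", {
  sc <- generate_scene(small_params(), 9)
  reg <- region_from_annotations(sc$boxes, 224, 224)
  dbg <- draw_region_debug(sc$pixels, reg)
  expect_equal(dim(dbg), dim(sc$pixels))
  expect_gt(sum(dbg == 255), sum(sc$pixels == 255))
})
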