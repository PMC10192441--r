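test_that("the eye mask is the dilated filled polygon", {
  f <- render_eye()
  cfg <- gaze_config()
  m <- build_eye_mask(f$image, f$landmarks, cfg)
  poly <- polygon_mask(ncol(f$image), nrow(f$image),
                       f$landmarks[, "x"], f$landmarks[, "y"])
  expect_gte(sum(m$mask), sum(poly)) # dilation is extensive
  expect_true(all(m$mask[poly]))     # and contains the polygon
  m1 <- build_eye_mask(f$image, f$landmarks, gaze_config(dilation_kernel_size = 1))
  expect_identical(sum(m1$mask), sum(poly)) # identity structuring element
})

test_that("degenerate eye polygons are rejected", {
  closed <- render_eye(open_fraction = 0)
  expect_error(build_eye_mask(closed$image, closed$landmarks),
               class = "eyespeak_degenerate_eye")
  f <- render_eye()
  outside <- f$landmarks
  outside[, "x"] <- outside[, "x"] + 1000
  expect_error(build_eye_mask(f$image, outside), class = "eyespeak_input_error")
})

test_that("segmentation locates a rendered pupil within 2 px", {
  f <- render_eye(gx = 0.25, gy = 0.5, size = 96)
  m <- build_eye_mask(f$image, f$landmarks)
  p <- segment_eyeball(f$image, m)
  W <- max(f$landmarks[, "x"]) - min(f$landmarks[, "x"])
  h <- max(f$landmarks[, "y"]) - min(f$landmarks[, "y"])
  truth_cx <- min(f$landmarks[, "x"]) + 0.25 * W
  truth_cy <- min(f$landmarks[, "y"]) + 0.5 * h
  expect_lt(abs(p$centroid["x"] - truth_cx), 2)
  expect_lt(abs(p$centroid["y"] - truth_cy), 2)
  expect_gte(p$contour_area, gaze_config()$min_contour_area)
})

test_that("segmentation fails cleanly when no pupil is present", {
  f <- render_eye()
  img <- f$image
  img[img <= 70] <- 200 # repaint the pupil: uniform light eye region
  m <- build_eye_mask(img, f$landmarks)
  expect_error(segment_eyeball(img, m), class = "eyespeak_no_pupil")
})

test_that("the largest dark contour wins", {
  f <- render_eye(gx = 0.7, gy = 0.5) # real pupil, area ~48 px
  img <- f$image
  # add a smaller dark blob inside the eye polygon on the other side
  cx <- min(f$landmarks[, "x"]) + 0.2 * (max(f$landmarks[, "x"]) - min(f$landmarks[, "x"]))
  cy <- mean(range(f$landmarks[, "y"]))
  for (dx in -1:1) for (dy in -1:1) img[round(cy) + dy + 1L, round(cx) + dx + 1L] <- 40L
  m <- build_eye_mask(img, f$landmarks)
  p <- segment_eyeball(img, m)
  expect_gt(p$gx, 0.5) # centroid tracks the big blob, not the 9 px one
})

test_that("direction mapping follows the subject convention with UP precedence", {
  cfg <- gaze_config()
  loc <- function(gx, gy) list(gx = gx, gy = gy)
  expect_identical(classify_direction(loc(0.85, 0.5), cfg), "LEFT")
  expect_identical(classify_direction(loc(0.15, 0.5), cfg), "RIGHT")
  expect_identical(classify_direction(loc(0.5, 0.2), cfg), "UP")
  expect_identical(classify_direction(loc(0.85, 0.2), cfg), "UP") # vertical first
  expect_identical(classify_direction(loc(0.5, 0.5), cfg), "CENTER")
  viewer <- gaze_config(mirror_convention = "viewer")
  expect_identical(classify_direction(loc(0.15, 0.5), viewer), "LEFT")
  expect_identical(classify_direction(loc(0.85, 0.5), viewer), "RIGHT")
})

test_that("a down state is never produced", {
  cfg <- gaze_config()
  for (gy in seq(0.1, 0.95, by = 0.05)) {
    for (gx in c(0.1, 0.5, 0.9)) {
      expect_true(classify_direction(list(gx = gx, gy = gy), cfg) %in%
                    c("LEFT", "RIGHT", "UP", "CENTER"))
    }
  }
})

test_that("pushing the pupil further past a margin never reverts to CENTER", {
  classify_render <- function(gx, gy) {
    f <- render_eye(gx = gx, gy = gy)
    m <- build_eye_mask(f$image, f$landmarks)
    classify_direction(segment_eyeball(f$image, m))
  }
  for (gx in seq(0.38, 0.12, by = -0.02)) {
    expect_identical(classify_render(gx, 0.5), "RIGHT")
  }
  for (gx in seq(0.62, 0.88, by = 0.02)) {
    expect_identical(classify_render(gx, 0.5), "LEFT")
  }
  for (gy in seq(0.33, 0.15, by = -0.02)) {
    expect_identical(classify_render(0.5, gy), "UP")
  }
})

test_that("gaze configuration validates its ranges", {
  expect_error(gaze_config(horizontal_margins = c(0.6, 0.4)), class = "eyespeak_config_error")
  expect_error(gaze_config(binarize_threshold = 300), class = "eyespeak_config_error")
  expect_error(gaze_config(vertical_up_threshold = 1.5), class = "eyespeak_config_error")
  expect_error(gaze_config(min_contour_area = 0), class = "eyespeak_config_error")
})
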