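# Gaze classification by pupil segmentation.
#
# Procedure (per frame, per eye): draw the filled 6-point eye polygon in
# white on a black mask of frame dimensions; grow it with one binary
# dilation; extract the eye by masking the grayscale frame; turn the zeroed
# background white so the pupil is the only dark region left; binarise at a
# fixed threshold; take the largest dark contour as the eyeball and compute
# its centroid. The centroid's normalised position inside the eye landmark
# bounding box maps to a direction: up first, then left/right by horizontal
# margins, else centre.

#' Gaze-classification configuration
#'
#' @param binarize_threshold Fixed 8-bit binarisation threshold separating
#'   the dark pupil from sclera and skin (default 70).
#' @param horizontal_margins Normalised `(low, high)` pupil-position margins;
#'   beyond them the gaze is lateral (default `c(0.40, 0.60)`).
#' @param vertical_up_threshold Normalised vertical position below which the
#'   gaze is UP (default 0.35; image y grows downward).
#' @param min_contour_area Minimum dark-contour area in pixels accepted as a
#'   pupil (default 9).
#' @param dilation_kernel_size Odd side length of the square structuring
#'   element used to grow the eye mask (default 5).
#' @param mirror_convention `"subject"` (default) expresses directions in the
#'   patient's frame: in an un-mirrored camera image the subject's LEFT is
#'   the image's right half. `"viewer"` uses image-frame naming instead.
#' @return A list of class `gaze_config`.
#' @export
gaze_config <- function(binarize_threshold = 70,
                        horizontal_margins = c(0.40, 0.60),
                        vertical_up_threshold = 0.35,
                        min_contour_area = 9,
                        dilation_kernel_size = 5,
                        mirror_convention = c("subject", "viewer")) {
  mirror_convention <- match.arg(mirror_convention)
  if (!is_scalar_number(binarize_threshold) || binarize_threshold <= 0 || binarize_threshold >= 255) {
    abort_config("binarize_threshold must lie in (0, 255)")
  }
  if (length(horizontal_margins) != 2 ||
      !(0 < horizontal_margins[1] && horizontal_margins[1] < horizontal_margins[2] &&
        horizontal_margins[2] < 1)) {
    abort_config("horizontal_margins must satisfy 0 < low < high < 1")
  }
  if (!is_scalar_number(vertical_up_threshold) ||
      vertical_up_threshold <= 0 || vertical_up_threshold >= 1) {
    abort_config("vertical_up_threshold must lie in (0, 1)")
  }
  if (!is_scalar_number(min_contour_area) || min_contour_area < 1) {
    abort_config("min_contour_area must be >= 1")
  }
  structure(list(binarize_threshold = binarize_threshold,
                 horizontal_margins = horizontal_margins,
                 vertical_up_threshold = vertical_up_threshold,
                 min_contour_area = min_contour_area,
                 dilation_kernel_size = as.integer(dilation_kernel_size),
                 mirror_convention = mirror_convention),
            class = "gaze_config")
}

#' Build the dilated eye-region mask
#'
#' The filled 6-point eye polygon is drawn white on a black mask of the
#' frame's dimensions and grown once by the configured square structuring
#' element.
#'
#' @param frame Grayscale image matrix (or synthetic frame).
#' @param eye 6 x 2 matrix of p1..p6 eye landmarks.
#' @param cfg A [gaze_config()].
#' @return A list of class `eye_mask`: `mask` (logical, frame-sized), `eye`
#'   (the landmarks), `kernel` (structuring-element size), `bbox` (0-based
#'   `c(x0, y0, x1, y1)` of the dilated region).
#' @export
build_eye_mask <- function(frame, eye, cfg = gaze_config()) {
  img <- frame_image(frame)
  eye <- validate_eye(eye)
  if (any(eye[, "x"] < 0) || any(eye[, "y"] < 0) ||
      any(eye[, "x"] > ncol(img) - 1) || any(eye[, "y"] > nrow(img) - 1)) {
    abort_input("eye landmarks lie outside the frame")
  }
  if (abs(polygon_area(eye[, "x"], eye[, "y"])) < 1e-9) {
    abort_degenerate_eye("degenerate eye polygon (zero area): eye closed or collinear landmarks")
  }
  r <- (cfg$dilation_kernel_size - 1L) %/% 2L
  # compute on a padded crop, then place into the full-frame mask
  x0 <- max(0L, as.integer(floor(min(eye[, "x"]))) - r - 1L)
  x1 <- min(ncol(img) - 1L, as.integer(ceiling(max(eye[, "x"]))) + r + 1L)
  y0 <- max(0L, as.integer(floor(min(eye[, "y"]))) - r - 1L)
  y1 <- min(nrow(img) - 1L, as.integer(ceiling(max(eye[, "y"]))) + r + 1L)
  crop <- polygon_mask(x1 - x0 + 1L, y1 - y0 + 1L, eye[, "x"] - x0, eye[, "y"] - y0)
  crop <- dilate_mask(crop, cfg$dilation_kernel_size)
  mask <- matrix(FALSE, nrow = nrow(img), ncol = ncol(img))
  mask[(y0:y1) + 1L, (x0:x1) + 1L] <- crop
  structure(list(mask = mask, eye = eye, kernel = cfg$dilation_kernel_size,
                 bbox = c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)),
            class = "eye_mask")
}

#' Segment the eyeball and locate the pupil
#'
#' Applies the bitwise extraction with the eye mask, converts the zeroed
#' pixels outside the mask to 255 so the pupil is the only dark region,
#' binarises at the fixed threshold, and keeps the largest dark contour of
#' sufficient area. The centroid is reported both in pixels and normalised
#' to the eye landmark bounding box.
#'
#' @param frame Grayscale image matrix (or synthetic frame).
#' @param mask An `eye_mask` from [build_eye_mask()].
#' @param cfg A [gaze_config()].
#' @return A list of class `pupil_location`: `centroid` (`c(x, y)` pixels),
#'   `gx`, `gy` (normalised position in `[0, 1]`), `contour_area` (pixels).
#' @export
segment_eyeball <- function(frame, mask, cfg = gaze_config()) {
  img <- frame_image(frame)
  if (!inherits(mask, "eye_mask")) abort_input("'mask' must come from build_eye_mask()")
  bb <- mask$bbox
  rows <- (bb["y0"]:bb["y1"]) + 1L
  cols <- (bb["x0"]:bb["x1"]) + 1L
  work <- img[rows, cols, drop = FALSE]
  inside <- mask$mask[rows, cols, drop = FALSE]
  work[!inside] <- 0L          # bitwise-and with the mask
  work[work == 0L] <- 255L     # zeros -> 255: background becomes white
  dark <- work <= cfg$binarize_threshold
  comps <- label_components(dark)
  comps <- comps[vapply(comps, length, integer(1)) >= cfg$min_contour_area]
  if (length(comps) == 0) {
    abort_no_pupil("no dark contour of sufficient area: pupil not found in eye region")
  }
  cells <- comps[[1]]
  cen <- component_centroid(cells, nrow(work))
  cen <- c(x = unname(cen["x"]) + unname(bb["x0"]), y = unname(cen["y"]) + unname(bb["y0"]))
  ex <- range(mask$eye[, "x"])
  ey <- range(mask$eye[, "y"])
  gx <- (cen["x"] - ex[1]) / max(ex[2] - ex[1], .Machine$double.eps)
  gy <- (cen["y"] - ey[1]) / max(ey[2] - ey[1], .Machine$double.eps)
  structure(list(centroid = cen,
                 gx = unname(pmin(pmax(gx, 0), 1)),
                 gy = unname(pmin(pmax(gy, 0), 1)),
                 contour_area = length(cells)),
            class = "pupil_location")
}

#' Map a pupil location to a gaze direction
#'
#' Vertical test first: `gy < vertical_up_threshold` is UP (an up-gaze also
#' perturbs `gx`, so it takes precedence). Otherwise the pupil is lateral
#' when `gx` passes a horizontal margin — under the subject convention a
#' pupil in the image's right half (`gx > high`) is the subject's LEFT —
#' else CENTER. A down state is never produced (it conflicts with blinking
#' and is not part of the language).
#'
#' @param p A `pupil_location` (or any list with `gx`, `gy`).
#' @param cfg A [gaze_config()].
#' @return One of `"LEFT"`, `"RIGHT"`, `"UP"`, `"CENTER"`.
#' @export
classify_direction <- function(p, cfg = gaze_config()) {
  gx <- p$gx; gy <- p$gy
  if (!is_scalar_number(gx) || !is_scalar_number(gy)) {
    abort_input("pupil location needs scalar gx and gy")
  }
  if (gy < cfg$vertical_up_threshold) return("UP")
  lo <- cfg$horizontal_margins[1]; hi <- cfg$horizontal_margins[2]
  if (cfg$mirror_convention == "subject") {
    if (gx > hi) return("LEFT")
    if (gx < lo) return("RIGHT")
  } else {
    if (gx < lo) return("LEFT")
    if (gx > hi) return("RIGHT")
  }
  "CENTER"
}

# Full per-eye classification for one frame; returns direction or UNKNOWN
# (no pupil / degenerate eye), plus the pupil location when found.
classify_eye_direction <- function(frame, eye, cfg = gaze_config()) {
  res <- tryCatch({
    m <- build_eye_mask(frame, eye, cfg)
    p <- segment_eyeball(frame, m, cfg)
    list(direction = classify_direction(p, cfg), pupil = p)
  },
  eyespeak_no_pupil = function(e) list(direction = "UNKNOWN", pupil = NULL),
  eyespeak_degenerate_eye = function(e) list(direction = "UNKNOWN", pupil = NULL))
  res
}
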