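# Landmark frontend: 68-point facial landmark sets, the two 6-point eye
# slices, face detection, and the landmark-stream CSV dialect.
#
# The 68-point layout follows the iBUG 300-W annotation scheme (0-based):
# indices 36-41 are the eye imaged on the viewer's LEFT (the subject's right
# eye), 42-47 the viewer's RIGHT. Within each eye the points are re-ordered to
# the p1..p6 convention used by the eye aspect ratio: p1 the temporal (outer)
# corner, p4 the opposite corner, p2/p3 on the upper lid, p5/p6 on the lower.

#' Coerce to a 68-point landmark set
#'
#' @param x A 68 x 2 numeric matrix (columns x, y), or a data frame with
#'   columns `x` and `y` in point order 0..67.
#' @return A 68 x 2 numeric matrix with columns `x`, `y`.
#' @export
as_landmarks <- function(x) {
  if (is.data.frame(x)) x <- cbind(x$x, x$y)
  if (!is.matrix(x) || ncol(x) != 2 || !is.numeric(x)) {
    abort_validation("landmarks must be a 68 x 2 numeric matrix or a data frame with x, y")
  }
  if (nrow(x) != 68) {
    abort_validation(paste0("a landmark set has exactly 68 points, got ", nrow(x)))
  }
  if (!all(is.finite(x))) abort_validation("landmark coordinates must all be finite")
  colnames(x) <- c("x", "y")
  x
}

# iBUG 0-based index slices for the two eyes
ibug_eye_indices <- function(side = c("left", "right")) {
  side <- match.arg(side)
  if (side == "left") 36:41 else 42:47
}

#' Extract the two 6-point eye landmark sets
#'
#' Slices the iBUG eye indices (36-41 viewer-left, 42-47 viewer-right) out of
#' a 68-point landmark set and re-orders each to the p1..p6 convention (p1 =
#' temporal corner, p2/p3 upper lid, p4 = opposite corner, p5/p6 lower lid).
#' For the viewer-left eye the stored order already is p1..p6; the
#' viewer-right eye is reversed so that p1 is again the temporal corner.
#'
#' @param lm A 68-point landmark set (see [as_landmarks()]).
#' @return A list with elements `left` and `right` (sides in the image/viewer
#'   frame), each a 6 x 2 matrix with rows p1..p6.
#' @export
extract_eyes <- function(lm) {
  lm <- as_landmarks(lm)
  left <- lm[ibug_eye_indices("left") + 1L, , drop = FALSE]
  r <- lm[ibug_eye_indices("right") + 1L, , drop = FALSE]
  # stored order 42..47 = (nasal corner, upper x2, temporal corner, lower x2);
  # re-ordered so p1 = temporal corner, p2/p3 upper, p5/p6 lower
  right <- r[c(4L, 3L, 2L, 1L, 6L, 5L), , drop = FALSE]
  rownames(left) <- rownames(right) <- paste0("p", 1:6)
  list(left = left, right = right)
}

validate_eye <- function(eye) {
  if (is.data.frame(eye)) eye <- cbind(eye$x, eye$y)
  if (!is.matrix(eye) || !is.numeric(eye) || ncol(eye) != 2) {
    abort_validation("an eye is a 6 x 2 numeric matrix of p1..p6 coordinates")
  }
  if (nrow(eye) != 6) {
    abort_validation(paste0("an eye has exactly 6 landmark points, got ", nrow(eye)))
  }
  if (!all(is.finite(eye))) abort_validation("eye coordinates must all be finite")
  colnames(eye) <- c("x", "y")
  eye
}

#' Detect the face bounding box in a frame
#'
#' Backends:
#' * `"pixel"` — a contrast detector for synthetic frames: the face is the
#'   bounding box of pixels that differ from the dominant border intensity.
#'   Returns the largest such region, ties broken leftmost-topmost.
#' * `"synthetic"` — replays the generator's ground-truth box attached to a
#'   synthetic frame.
#' * `"pretrained"` — placeholder for a HOG+SVM detector; unavailable in this
#'   installation and raises a configuration error explaining that.
#'
#' @param frame A grayscale image matrix or a synthetic frame object.
#' @param backend One of `"pixel"`, `"synthetic"`, `"pretrained"`.
#' @return A named numeric vector `c(left, top, right, bottom)` in 0-based
#'   pixel coordinates, or `NULL` when no face is found.
#' @export
detect_face <- function(frame, backend = c("pixel", "synthetic", "pretrained")) {
  backend <- match.arg(backend)
  img <- frame_image(frame)
  if (length(img) == 0 || nrow(img) == 0 || ncol(img) == 0) {
    abort_input("empty image: cannot detect a face")
  }
  if (backend == "synthetic") {
    if (!inherits(frame, "synth_frame") || is.null(frame$face_box)) {
      abort_config("synthetic face backend requires a synthetic frame carrying a ground-truth box")
    }
    return(frame$face_box)
  }
  if (backend == "pretrained") {
    abort_config(paste0(
      "the pretrained HOG+SVM face detector is not installed; ",
      "use backend = 'pixel' or 'synthetic', or run the upstream dlib pipeline ",
      "and feed its landmark CSV stream instead"
    ))
  }
  border <- c(img[1, ], img[nrow(img), ], img[, 1], img[, ncol(img)])
  bg <- as.integer(names(sort(table(border), decreasing = TRUE))[1])
  fg <- abs(img - bg) > 20
  comps <- label_components(fg)
  if (length(comps) == 0) return(NULL)
  # largest component; require it to be plausibly face-sized
  cells <- comps[[1]]
  if (length(cells) < 0.02 * length(img)) return(NULL)
  nr <- nrow(img)
  ys <- (cells - 1L) %% nr
  xs <- (cells - 1L) %/% nr
  c(left = min(xs), top = min(ys), right = max(xs), bottom = max(ys))
}

#' Predict 68 facial landmarks for a detected face
#'
#' Backends mirror [detect_face()]: `"synthetic"` replays the generator's
#' ground truth (used throughout the test suite), `"pretrained"` documents
#' how a real shape predictor would slot in and raises a configuration error
#' here because the dlib model is not installed.
#'
#' @param frame Image matrix or synthetic frame.
#' @param box Face box from [detect_face()].
#' @param backend `"synthetic"` or `"pretrained"`.
#' @return A 68 x 2 landmark matrix, clamped to frame bounds.
#' @export
predict_landmarks <- function(frame, box, backend = c("synthetic", "pretrained")) {
  backend <- match.arg(backend)
  img <- frame_image(frame)
  if (!is.numeric(box) || length(box) != 4) abort_input("'box' must be c(left, top, right, bottom)")
  if (box[1] < 0 || box[2] < 0 || box[3] > ncol(img) - 1 || box[4] > nrow(img) - 1 ||
      box[3] <= box[1] || box[4] <= box[2]) {
    abort_input("face box lies outside the frame")
  }
  if (backend == "pretrained") {
    abort_config(paste0(
      "no 68-point shape-predictor model is installed in this R environment; ",
      "either inject landmarks from a CSV stream (read_landmark_csv) or use the ",
      "synthetic backend on generated frames"
    ))
  }
  if (!inherits(frame, "synth_frame") || is.null(frame$landmarks)) {
    abort_config("synthetic landmark backend requires a synthetic frame carrying ground truth")
  }
  lm <- as_landmarks(frame$landmarks)
  lm[, "x"] <- pmin(pmax(lm[, "x"], 0), ncol(img) - 1)
  lm[, "y"] <- pmin(pmax(lm[, "y"], 0), nrow(img) - 1)
  lm
}

frame_image <- function(frame) {
  if (inherits(frame, "synth_frame")) frame$image else frame
}

#' Write a landmark stream CSV
#'
#' One row per frame: `frame,timestamp,x0,y0,...,x67,y67`, header required.
#'
#' @param landmarks A list of 68 x 2 landmark matrices, one per frame.
#' @param path Output CSV path.
#' @param fps Frame rate used to fill timestamps (seconds = frame / fps).
#' @param frames Optional integer frame indices (default `0:(n-1)`).
#' @return `path`, invisibly.
#' @export
write_landmark_csv <- function(landmarks, path, fps = 25, frames = NULL) {
  n <- length(landmarks)
  frames <- frames %||% (seq_len(n) - 1L)
  rows <- purrr::map2(landmarks, frames, function(lm, f) {
    lm <- as_landmarks(lm)
    v <- as.numeric(t(lm))
    setNames(c(f, f / fps, v),
             c("frame", "timestamp", paste0(c("x", "y"), rep(0:67, each = 2))))
  })
  df <- as_tibble(do.call(rbind, rows))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a landmark stream CSV
#'
#' @param path CSV with columns `frame,timestamp,x0,y0,...,x67,y67`.
#' @return A list with `frames` (integer vector), `timestamps`, and
#'   `landmarks` (list of 68 x 2 matrices).
#' @export
read_landmark_csv <- function(path) {
  if (!file.exists(path)) abort_io(paste0("landmark CSV not found: ", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                        progress = FALSE)
  want <- c("frame", "timestamp", paste0(c("x", "y"), rep(0:67, each = 2)))
  if (!identical(names(df), want)) {
    abort_validation("landmark CSV must have columns frame,timestamp,x0,y0,...,x67,y67")
  }
  lms <- purrr::map(seq_len(nrow(df)), function(i) {
    v <- as.numeric(df[i, -(1:2)])
    m <- matrix(v, ncol = 2, byrow = TRUE)
    as_landmarks(m)
  })
  list(frames = as.integer(df$frame), timestamps = df$timestamp, landmarks = lms)
}
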