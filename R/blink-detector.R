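# Blink detection from the eye aspect ratio (EAR).
#
# EAR = (||p2 - p6|| + ||p3 - p5||) / (2 ||p1 - p4||): near-constant while the
# eye is open, approximately zero when closed. A frame is CLOSED when
# EAR <= t (threshold t = 0.2 by default, boundary inclusive). A maximal run
# of CLOSED frames is one blink; at 25 fps a run of >= 13 frames (~520 ms) is
# an intentional language blink (deliberate closures last ~800 ms), while
# shorter runs are natural blinks (100-400 ms).

#' Blink-detection configuration
#'
#' @param threshold_t EAR open/closed threshold (dimensionless, default 0.2).
#' @param min_intentional_frames Minimum CLOSED-run length for an intentional
#'   blink. Default 13 frames at 25 fps; when `fps` differs and no explicit
#'   value is given, the default rescales as `round(13 * fps / 25)` so the
#'   duration criterion (~520 ms) is preserved.
#' @param fps Capture frame rate, frames per second.
#' @return A list of class `blink_config`.
#' @examples
#' blink_config()
#' blink_config(fps = 50) # min_intentional_frames rescales to 26
#' @export
blink_config <- function(threshold_t = 0.2, min_intentional_frames = NULL, fps = 25) {
  if (!is_scalar_number(threshold_t) || threshold_t <= 0 || threshold_t >= 1) {
    abort_config("threshold_t must lie strictly between 0 and 1")
  }
  if (!is_scalar_number(fps) || fps <= 0) abort_config("fps must be positive")
  if (is.null(min_intentional_frames)) {
    min_intentional_frames <- max(1L, as.integer(round(13 * fps / 25)))
  }
  if (!is_scalar_number(min_intentional_frames) || min_intentional_frames < 1) {
    abort_config("min_intentional_frames must be >= 1")
  }
  structure(list(threshold_t = threshold_t,
                 min_intentional_frames = as.integer(round(min_intentional_frames)),
                 fps = fps),
            class = "blink_config")
}

#' Eye aspect ratio of a 6-point eye
#'
#' \deqn{EAR = \frac{\|p_2 - p_6\| + \|p_3 - p_5\|}{2 \|p_1 - p_4\|}}
#' Euclidean norms throughout, so the ratio is invariant under translation,
#' rotation and uniform scaling of the six points.
#'
#' @param eye A 6 x 2 matrix of p1..p6 coordinates (rows in order).
#' @return The EAR, a dimensionless ratio `>= 0`.
#' @examples
#' eye <- rbind(c(0, 0), c(1, 1), c(3, 1), c(4, 0), c(3, -1), c(1, -1))
#' compute_ear(eye) # 0.5
#' @export
compute_ear <- function(eye) {
  eye <- validate_eye(eye)
  d <- function(i, j) sqrt(sum((eye[i, ] - eye[j, ])^2))
  width <- d(1, 4)
  if (width == 0) abort_degenerate_eye("degenerate eye: p1 == p4 (zero horizontal width)")
  (d(2, 6) + d(3, 5)) / (2 * width)
}

#' Classify one frame open or closed from its EAR
#'
#' The closed state includes the boundary: `EAR <= t` is CLOSED, `EAR > t`
#' is OPEN.
#'
#' @param ear EAR value, `>= 0`.
#' @param cfg A [blink_config()].
#' @return `"CLOSED"` or `"OPEN"`.
#' @export
classify_frame_open <- function(ear, cfg = blink_config()) {
  if (!is.numeric(ear) || any(!is.finite(ear)) || any(ear < 0)) {
    abort_input("EAR must be finite and non-negative")
  }
  ifelse(ear <= cfg$threshold_t, "CLOSED", "OPEN")
}

#' Detect blink events in an EAR trace
#'
#' Scans the mean EAR for maximal runs of CLOSED frames. Each run is one
#' blink event; a run of at least `min_intentional_frames` frames is an
#' INTENTIONAL language blink, shorter runs are NATURAL. Runs touching the
#' first or last row of the trace are reported with `at_boundary = TRUE`
#' (their true duration is unknowable) but still classified.
#'
#' @param trace A data frame with column `frame` (strictly increasing) and
#'   either `ear_mean` or both `ear_left` and `ear_right`.
#' @param cfg A [blink_config()].
#' @return A tibble of blink events: `start_frame`, `end_frame`,
#'   `duration_frames`, `duration_ms`, `kind` (`"NATURAL"`/`"INTENTIONAL"`),
#'   `at_boundary`.
#' @export
detect_blinks <- function(trace, cfg = blink_config()) {
  empty <- tibble(start_frame = integer(), end_frame = integer(),
                  duration_frames = integer(), duration_ms = double(),
                  kind = character(), at_boundary = logical(),
                  at_start = logical(), at_end = logical())
  if (is.null(trace) || nrow(trace) == 0) return(empty)
  if (!"frame" %in% names(trace)) abort_input("trace needs a 'frame' column")
  if (any(diff(trace$frame) <= 0)) abort_input("trace frame indices must be strictly increasing")
  ear <- if ("ear_mean" %in% names(trace)) {
    trace$ear_mean
  } else if (all(c("ear_left", "ear_right") %in% names(trace))) {
    (trace$ear_left + trace$ear_right) / 2
  } else {
    abort_input("trace needs 'ear_mean' or both 'ear_left' and 'ear_right'")
  }
  closed <- classify_frame_open(ear, cfg) == "CLOSED"
  r <- rle(closed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs) == 0) return(empty)
  purrr::map(runs, function(i) {
    s <- starts[i]; e <- ends[i]
    dur <- e - s + 1L
    tibble(
      start_frame = as.integer(trace$frame[s]),
      end_frame = as.integer(trace$frame[e]),
      duration_frames = dur,
      duration_ms = dur * 1000 / cfg$fps,
      kind = if (dur >= cfg$min_intentional_frames) "INTENTIONAL" else "NATURAL",
      at_boundary = s == 1L || e == nrow(trace),
      at_start = s == 1L,
      at_end = e == nrow(trace)
    )
  }) |> bind_rows()
}

#' Export blink events as JSON lines
#' @param events Tibble from [detect_blinks()].
#' @param path Output file; one JSON object per line.
#' @return `path`, invisibly.
#' @export
write_blink_jsonl <- function(events, path) {
  lines <- purrr::map_chr(seq_len(nrow(events)), function(i) {
    jsonlite::toJSON(as.list(events[i, ]), auto_unbox = TRUE)
  })
  writeLines(lines, path)
  invisible(path)
}
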