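# Decoder pipeline: per-frame classification -> debounced gesture events ->
# three-state tracking list -> phrases, plus the streaming queue contract and
# the analytic communication-speed model.

#' Pipeline configuration
#'
#' @param gesture_debounce_frames Consecutive frames a lateral/up gaze must
#'   persist to register one gesture (default 10, ~400 ms at 25 fps).
#' @param error_window_seconds After an unrecognised interval the patient has
#'   this long to produce a valid state before the pending tracking list is
#'   cleared (default 5 s).
#' @param queue_capacity Bounded frame-buffer capacity for streaming use.
#' @param fps Frame rate, frames per second.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(gesture_debounce_frames = 10, error_window_seconds = 5,
                            queue_capacity = 32, fps = 25) {
  vals <- c(gesture_debounce_frames, error_window_seconds, queue_capacity, fps)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort_config("all pipeline_config values must be positive")
  }
  structure(list(gesture_debounce_frames = as.integer(gesture_debounce_frames),
                 error_window_seconds = error_window_seconds,
                 queue_capacity = as.integer(queue_capacity), fps = fps),
            class = "pipeline_config")
}

#' Classify every frame of a clip
#'
#' For each frame: extract the two 6-point eyes from the landmark set,
#' compute per-eye EARs, and either mark the frame CLOSED (mean EAR at or
#' below the blink threshold) or segment both pupils and classify gaze. The
#' two eyes must agree on a direction; disagreement or a missing pupil yields
#' UNKNOWN.
#'
#' @param frames List of grayscale images or `synth_frame` objects.
#' @param landmarks Optional list of 68 x 2 landmark matrices (one per
#'   frame), e.g. from [read_landmark_csv()]; defaults to the ground truth
#'   carried by synthetic frames.
#' @param blink_cfg A [blink_config()].
#' @param gaze_cfg A [gaze_config()].
#' @return A tibble with one row per frame: `frame`, `ear_left`, `ear_right`,
#'   `ear_mean`, `eye_open`, `gx`, `gy`, `state`.
#' @export
classify_frames <- function(frames, landmarks = NULL,
                            blink_cfg = blink_config(), gaze_cfg = gaze_config()) {
  n <- length(frames)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- frames[[i]]
    img <- frame_image(fr)
    lm <- if (!is.null(landmarks)) landmarks[[i]] else fr$landmarks
    if (is.null(lm)) abort_input("no landmarks available: supply 'landmarks' or synthetic frames")
    idx <- if (inherits(fr, "synth_frame") && !is.null(fr$frame_index)) fr$frame_index else i - 1L
    eyes <- extract_eyes(lm)
    ear_l <- tryCatch(compute_ear(eyes$left), eyespeak_degenerate_eye = function(e) NA_real_)
    ear_r <- tryCatch(compute_ear(eyes$right), eyespeak_degenerate_eye = function(e) NA_real_)
    ear_m <- mean(c(ear_l, ear_r), na.rm = TRUE)
    if (!is.finite(ear_m)) {
      out[[i]] <- tibble(frame = idx, ear_left = ear_l, ear_right = ear_r,
                         ear_mean = NA_real_, eye_open = NA, gx = NA_real_,
                         gy = NA_real_, state = "UNKNOWN")
      next
    }
    open <- classify_frame_open(ear_m, blink_cfg) == "OPEN"
    if (!open) {
      out[[i]] <- tibble(frame = idx, ear_left = ear_l, ear_right = ear_r,
                         ear_mean = ear_m, eye_open = FALSE, gx = NA_real_,
                         gy = NA_real_, state = "CLOSED")
      next
    }
    cl <- classify_eye_direction(img, eyes$left, gaze_cfg)
    cr <- classify_eye_direction(img, eyes$right, gaze_cfg)
    state <- if (cl$direction == cr$direction) cl$direction else "UNKNOWN"
    gxs <- purrr::map_dbl(list(cl$pupil, cr$pupil), ~ if (is.null(.x)) NA_real_ else .x$gx)
    gys <- purrr::map_dbl(list(cl$pupil, cr$pupil), ~ if (is.null(.x)) NA_real_ else .x$gy)
    out[[i]] <- tibble(frame = idx, ear_left = ear_l, ear_right = ear_r,
                       ear_mean = ear_m, eye_open = TRUE,
                       gx = mean(gxs, na.rm = TRUE), gy = mean(gys, na.rm = TRUE),
                       state = state)
  }
  bind_rows(out)
}

#' Register debounced gesture events
#'
#' A lateral/up gaze registers once it persists for
#' `gesture_debounce_frames` consecutive frames, and at most once per
#' excursion from CENTER (return-to-centre delimits repeated identical
#' gestures). Intentional blink events register as BLINK gestures. Natural
#' blinks and UNKNOWN frames register nothing and do not end an excursion.
#'
#' Runs truncated at the start of the recording are ignored (their duration
#' is unknowable). By default a blink run flagged at the END of a finite
#' recording is still accepted: the recording closed while the eye was held
#' shut and the observed run length already satisfies the intentional rule.
#'
#' @param frame_states Tibble from [classify_frames()] (needs `frame`,
#'   `state`).
#' @param blink_events Tibble from [detect_blinks()], or `NULL`.
#' @param cfg A [pipeline_config()].
#' @param boundary One of `"end"` (default: accept end-of-recording blink
#'   runs), `"none"` (drop all boundary-flagged runs), `"all"` (accept both).
#' @return A tibble of gesture events: `state`, `start_frame`, `end_frame`,
#'   `registered_at` (seconds).
#' @export
register_gestures <- function(frame_states, blink_events = NULL,
                              cfg = pipeline_config(),
                              boundary = c("end", "none", "all")) {
  boundary <- match.arg(boundary)
  events <- list()
  if (!is.null(frame_states) && nrow(frame_states) > 0) {
    r <- rle(frame_states$state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    emitted <- FALSE
    for (k in seq_along(r$values)) {
      st <- r$values[k]
      if (st == "CENTER") {
        emitted <- FALSE
      } else if (st %in% c("LEFT", "RIGHT", "UP")) {
        if (!emitted && r$lengths[k] >= cfg$gesture_debounce_frames) {
          s <- starts[k]; e <- ends[k]
          events[[length(events) + 1L]] <- tibble(
            state = st,
            start_frame = as.integer(frame_states$frame[s]),
            end_frame = as.integer(frame_states$frame[e]),
            registered_at = frame_states$frame[e] / cfg$fps)
          emitted <- TRUE
        }
      }
      # CLOSED and UNKNOWN are transparent: they neither emit nor reset
    }
  }
  if (!is.null(blink_events) && nrow(blink_events) > 0) {
    keep <- blink_events$kind == "INTENTIONAL"
    keep <- keep & switch(boundary,
      all = TRUE,
      none = !blink_events$at_boundary,
      end = !blink_events$at_start)
    be <- blink_events[keep, , drop = FALSE]
    if (nrow(be) > 0) {
      events[[length(events) + 1L]] <- tibble(
        state = "BLINK",
        start_frame = be$start_frame,
        end_frame = be$end_frame,
        registered_at = be$end_frame / cfg$fps)
    }
  }
  if (length(events) == 0) {
    return(tibble(state = character(), start_frame = integer(),
                  end_frame = integer(), registered_at = double()))
  }
  bind_rows(events) |> arrange(.data$start_frame)
}

#' Decode a gesture-event stream into phrases
#'
#' Events are accumulated in arrival order in a tracking list of at most
#' three; each full triple emits its dictionary phrase and clears the list.
#' A trailing incomplete group emits nothing. If the silence after the last
#' event exceeds `error_window_seconds` before the next valid state arrives,
#' the pending list is cleared (the patient's correction window expired);
#' within the window the pending gestures are preserved.
#'
#' @param events Tibble from [register_gestures()].
#' @param dict A `phrase_dictionary`.
#' @param cfg A [pipeline_config()].
#' @return A transcript tibble: `code`, `phrase`, `start_frame`,
#'   `end_frame`, `t` (seconds of emission).
#' @export
decode_stream <- function(events, dict = load_dictionary(), cfg = pipeline_config()) {
  stopifnot_dictionary(dict)
  transcript <- list()
  pending <- list()
  last_t <- NULL
  n <- if (is.null(events)) 0L else nrow(events)
  for (i in seq_len(n)) {
    ev <- events[i, ]
    if (!is.null(last_t) && length(pending) > 0 &&
        ev$registered_at - last_t > cfg$error_window_seconds) {
      pending <- list() # correction window expired: reset the tracking list
    }
    pending[[length(pending) + 1L]] <- ev
    last_t <- ev$registered_at
    if (length(pending) == 3L) {
      code <- paste(unname(eye_states()[purrr::map_chr(pending, "state")]), collapse = "")
      transcript[[length(transcript) + 1L]] <- tibble(
        code = code,
        phrase = decode_code(code, dict),
        start_frame = pending[[1]]$start_frame,
        end_frame = pending[[3]]$end_frame,
        t = pending[[3]]$registered_at)
      pending <- list()
    }
  }
  if (length(transcript) == 0) {
    return(tibble(code = character(), phrase = character(),
                  start_frame = integer(), end_frame = integer(), t = double()))
  }
  bind_rows(transcript)
}

#' Run the full decoding pipeline
#'
#' Composes landmark extraction, EAR blink detection, gaze classification,
#' gesture registration and stream decoding over a frame sequence.
#'
#' @param input A `synthetic_clip`, a list of `synth_frame` objects, or a
#'   fixture-bundle directory path (frames + optional `landmarks.csv`).
#' @param dict A `phrase_dictionary`.
#' @param landmarks Optional list of landmark matrices overriding the input's
#'   own (the "CSV route").
#' @param blink_cfg,gaze_cfg,pipe_cfg Module configurations.
#' @return A list of class `eyespeak_result`: `transcript`, `events`,
#'   `blinks`, `diagnostics` (per-frame tibble), `dropped_frames`.
#' @export
run_pipeline <- function(input, dict = load_dictionary(), landmarks = NULL,
                         blink_cfg = blink_config(), gaze_cfg = gaze_config(),
                         pipe_cfg = pipeline_config()) {
  stopifnot_dictionary(dict)
  if (is.character(input) && length(input) == 1) {
    bundle <- read_fixture_bundle(input)
    frames <- bundle$images
    landmarks <- landmarks %||% bundle$landmarks
    if (is.null(landmarks)) abort_config("frame directory carries no landmarks.csv and no landmark backend is available")
  } else if (inherits(input, "synthetic_clip")) {
    frames <- input$frames
    landmarks <- landmarks %||% input$landmarks
  } else if (is.list(input)) {
    frames <- input
  } else {
    abort_input("unsupported input to run_pipeline()")
  }
  if (length(frames) == 0) {
    return(structure(list(transcript = decode_stream(NULL, dict, pipe_cfg),
                          events = register_gestures(NULL, NULL, pipe_cfg),
                          blinks = detect_blinks(NULL, blink_cfg),
                          diagnostics = tibble(), dropped_frames = 0L),
                     class = "eyespeak_result"))
  }
  diag <- classify_frames(frames, landmarks, blink_cfg, gaze_cfg)
  blinks <- detect_blinks(diag[is.finite(diag$ear_mean), c("frame", "ear_mean")], blink_cfg)
  events <- register_gestures(diag, blinks, pipe_cfg)
  transcript <- decode_stream(events, dict, pipe_cfg)
  structure(list(transcript = transcript, events = events, blinks = blinks,
                 diagnostics = diag, dropped_frames = 0L),
            class = "eyespeak_result")
}

#' @export
print.eyespeak_result <- function(x, ...) {
  cat("<eyespeak_result>\n")
  cat("  frames:", nrow(x$diagnostics), " gestures:", nrow(x$events),
      " phrases:", nrow(x$transcript), " dropped:", x$dropped_frames, "\n")
  if (nrow(x$transcript)) {
    cat("  transcript:\n")
    for (i in seq_len(nrow(x$transcript))) {
      cat(sprintf("    %s  %s\n", x$transcript$code[i], x$transcript$phrase[i]))
    }
  }
  invisible(x)
}

#' Write a transcript as JSON lines
#' @param transcript Transcript tibble from [decode_stream()].
#' @param path Output path; one record per phrase.
#' @return `path`, invisibly.
#' @export
write_transcript_jsonl <- function(transcript, path) {
  lines <- purrr::map_chr(seq_len(nrow(transcript)), function(i) {
    jsonlite::toJSON(as.list(transcript[i, ]), auto_unbox = TRUE)
  })
  writeLines(lines, path)
  invisible(path)
}
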