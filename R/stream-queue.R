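# Bounded drop-oldest frame queue and an in-process receive/process session.
#
# In deployment the mobile client streams frames to the backend over a
# two-way socket; when frames arrive faster than face/eye processing drains
# them, a bounded buffer drops the oldest frames so the stream stays current.
# The session object below is the in-process double of that transport: tests
# interleave receive() and process() calls to emulate concurrency.

#' Create a bounded frame queue
#'
#' @param capacity Maximum number of buffered frames (positive integer).
#' @return A queue object (environment) of class `frame_queue`.
#' @export
frame_queue <- function(capacity) {
  if (!is_scalar_number(capacity) || capacity < 1 || capacity != round(capacity)) {
    abort_config("queue capacity must be a positive integer")
  }
  q <- new.env(parent = emptyenv())
  q$items <- vector("list", 0)
  q$capacity <- as.integer(capacity)
  q$drops <- 0L
  q$accepted <- 0L
  class(q) <- "frame_queue"
  q
}

#' Enqueue a frame, dropping the oldest when full
#'
#' @param q A [frame_queue()].
#' @param frame Any object (typically an image or `synth_frame`).
#' @return `"accepted"` when the queue had room, `"dropped_oldest"` when the
#'   oldest buffered frame was evicted to make room.
#' @export
queue_push <- function(q, frame) {
  stopifnot(inherits(q, "frame_queue"))
  dropped <- length(q$items) >= q$capacity
  if (dropped) {
    q$items <- q$items[-1]
    q$drops <- q$drops + 1L
  }
  q$items[[length(q$items) + 1L]] <- frame
  q$accepted <- q$accepted + 1L
  if (dropped) "dropped_oldest" else "accepted"
}

#' Pop the oldest buffered frame
#' @param q A [frame_queue()].
#' @return The oldest frame, or `NULL` when the queue is empty.
#' @export
queue_pop <- function(q) {
  stopifnot(inherits(q, "frame_queue"))
  if (length(q$items) == 0) return(NULL)
  out <- q$items[[1]]
  q$items <- q$items[-1]
  out
}

#' Queue occupancy and drop statistics
#' @param q A [frame_queue()].
#' @return A one-row tibble: `size`, `capacity`, `drops`, `received`.
#' @export
queue_stats <- function(q) {
  stopifnot(inherits(q, "frame_queue"))
  tibble(size = length(q$items), capacity = q$capacity,
         drops = q$drops, received = q$accepted)
}

#' Open an in-process streaming session
#'
#' The session pairs a bounded queue with a list of processed frames;
#' [session_receive()] and [session_process()] emulate the concurrent
#' receive/process methods of the deployed service.
#'
#' @param queue_capacity Bounded-buffer capacity.
#' @return A `stream_session` environment.
#' @export
stream_session <- function(queue_capacity = 32) {
  s <- new.env(parent = emptyenv())
  s$queue <- frame_queue(queue_capacity)
  s$processed <- vector("list", 0)
  s$landmarks <- vector("list", 0)
  class(s) <- "stream_session"
  s
}

#' Receive one frame into the session buffer
#' @param s A [stream_session()].
#' @param frame Frame object (image or `synth_frame`).
#' @param landmarks Optional landmark matrix travelling with the frame.
#' @return The enqueue outcome (`"accepted"` / `"dropped_oldest"`).
#' @export
session_receive <- function(s, frame, landmarks = NULL) {
  stopifnot(inherits(s, "stream_session"))
  queue_push(s$queue, list(frame = frame, landmarks = landmarks))
}

#' Process up to `n` buffered frames
#' @param s A [stream_session()].
#' @param n Maximum number of frames to drain (default: all buffered).
#' @return Number of frames processed in this call.
#' @export
session_process <- function(s, n = Inf) {
  stopifnot(inherits(s, "stream_session"))
  done <- 0L
  while (done < n) {
    item <- queue_pop(s$queue)
    if (is.null(item)) break
    s$processed[[length(s$processed) + 1L]] <- item$frame
    s$landmarks[[length(s$landmarks) + 1L]] <- item$landmarks
    done <- done + 1L
  }
  done
}

#' Decode everything the session has processed
#' @param s A [stream_session()].
#' @param dict A `phrase_dictionary`.
#' @param ... Passed to [run_pipeline()].
#' @return An `eyespeak_result`; its `dropped_frames` reflects queue drops.
#' @export
session_decode <- function(s, dict = load_dictionary(), ...) {
  stopifnot(inherits(s, "stream_session"))
  lms <- if (all(purrr::map_lgl(s$landmarks, is.null))) NULL else s$landmarks
  res <- run_pipeline(s$processed, dict = dict, landmarks = lms, ...)
  res$dropped_frames <- s$queue$drops
  res
}
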