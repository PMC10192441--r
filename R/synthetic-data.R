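# Synthetic fixtures: rendered eye regions and full-face frames with exact
# ground truth. Landmarks are authored first and the image is rendered from
# them, so pixel processing and landmark-stream processing share one truth.
# The eye is a hexagon p1..p6 with horizontal extent W and lid opening h;
# by construction EAR = h / W, and h = open_fraction * 0.3 * W, so the
# ground-truth EAR is exactly 0.3 * open_fraction.

EAR_OPEN <- 0.3 # fully-open EAR of the synthetic geometry

# p1..p6 hexagon; steep corner edges (top/bottom points at W/6 and 5W/6)
# keep an off-centre pupil from being clipped too hard by the lid polygon
eye_hexagon <- function(x0, yc, W, h) {
  m <- rbind(
    p1 = c(x0,             yc),
    p2 = c(x0 + W / 6,     yc - h / 2),
    p3 = c(x0 + 5 * W / 6, yc - h / 2),
    p4 = c(x0 + W,         yc),
    p5 = c(x0 + 5 * W / 6, yc + h / 2),
    p6 = c(x0 + W / 6,     yc + h / 2)
  )
  colnames(m) <- c("x", "y")
  m
}

# seeded RNG scoped to one call, leaving the session RNG untouched
local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

INTENSITY <- list(background = 60L, skin = 180L, sclera = 245L, pupil = 30L,
                  feature = 120L)

# paint one eye (polygon sclera + pupil disc clipped to the polygon) onto
# img; all raster work happens on the eye bounding-box crop
paint_eye <- function(img, hex, gx, gy, pupil_r) {
  h <- hex["p6", "y"] - hex["p2", "y"]
  if (h <= 0) return(img) # closed: lids cover everything, skin only
  W <- hex["p4", "x"] - hex["p1", "x"]
  x0 <- hex["p1", "x"]
  top <- hex["p2", "y"]
  bx0 <- max(0L, as.integer(floor(min(hex[, "x"]))))
  bx1 <- min(ncol(img) - 1L, as.integer(ceiling(max(hex[, "x"]))))
  by0 <- max(0L, as.integer(floor(min(hex[, "y"]))))
  by1 <- min(nrow(img) - 1L, as.integer(ceiling(max(hex[, "y"]))))
  cw <- bx1 - bx0 + 1L
  ch <- by1 - by0 + 1L
  sel <- polygon_mask(cw, ch, hex[, "x"] - bx0, hex[, "y"] - by0)
  crop <- img[(by0:by1) + 1L, (bx0:bx1) + 1L, drop = FALSE]
  crop[sel] <- INTENSITY$sclera
  cx <- x0 + gx * W
  cy <- top + gy * h
  pup <- disc_mask(cw, ch, cx - bx0, cy - by0, pupil_r) & sel
  crop[pup] <- INTENSITY$pupil
  img[(by0:by1) + 1L, (bx0:bx1) + 1L] <- crop
  img
}

truth_direction <- function(gx, gy, open_fraction) {
  if (open_fraction == 0) return("CLOSED")
  if (gy < 0.35) return("UP")
  if (gx > 0.60) return("LEFT")   # image-right = subject's left
  if (gx < 0.40) return("RIGHT")
  "CENTER"
}

#' Render a synthetic eye region with known ground truth
#'
#' Draws a light sclera hexagon on a skin-tone background with a dark pupil
#' disc at normalised position `(gx, gy)` of the eye box, lids open to
#' `open_fraction`. The six ground-truth landmarks are constructed so the
#' eye aspect ratio equals exactly `0.3 * open_fraction`.
#'
#' @param gx,gy Normalised pupil position in the eye box, each in `[0, 1]`
#'   (`gy` grows downward; `gy < 0.35` reads as an up-gaze).
#' @param open_fraction Lid opening in `[0, 1]`; 0 renders a closed eye.
#' @param size Image width in pixels (minimum 24).
#' @param seed Unused for the clean render; kept for interface symmetry.
#' @return A `synth_frame`: `image`, `landmarks` (6 x 2, p1..p6),
#'   `truth_pupil`, `truth_state`, `ear` (ground-truth EAR).
#' @examples
#' f <- render_eye(gx = 0.85, gy = 0.5)
#' f$truth_state # "LEFT" (subject frame)
#' @export
render_eye <- function(gx = 0.5, gy = 0.5, open_fraction = 1, size = 96, seed = NULL) {
  if (!is_scalar_number(size) || size < 24) {
    abort_param("size too small to render an eye region (minimum 24 px)")
  }
  if (gx < 0 || gx > 1 || gy < 0 || gy > 1) abort_param("gx and gy must lie in [0, 1]")
  if (open_fraction < 0 || open_fraction > 1) abort_param("open_fraction must lie in [0, 1]")
  width <- as.integer(round(size))
  height <- as.integer(round(0.75 * size))
  W <- size / 2
  x0 <- size / 4
  yc <- height / 2
  h <- open_fraction * EAR_OPEN * W
  hex <- eye_hexagon(x0, yc, W, h)
  img <- new_image(width, height, INTENSITY$skin)
  img <- paint_eye(img, hex, gx, gy, pupil_r = max(2, round(W / 12)))
  structure(list(image = img, landmarks = hex, kind = "eye",
                 truth_pupil = c(gx = gx, gy = gy),
                 truth_state = truth_direction(gx, gy, open_fraction),
                 ear = open_fraction * EAR_OPEN),
            class = "synth_frame")
}

# Static 68-point template around animated eyes. Only the eye indices move;
# the rest (jaw, brows, nose, mouth) exists to exercise the 68-point slicing.
face_template <- function(frame_width = 160, frame_height = 128) {
  cx <- frame_width / 2
  fy <- frame_height * 0.52
  rx <- frame_width * 0.34
  ry <- frame_height * 0.45
  eye_w <- frame_width * 0.19
  eye_gap <- frame_width * 0.0625
  eye_y <- frame_height * 0.41
  left_x0 <- cx - eye_gap / 2 - eye_w
  right_x0 <- cx + eye_gap / 2
  lm <- matrix(NA_real_, nrow = 68, ncol = 2, dimnames = list(NULL, c("x", "y")))
  th <- seq(pi, 2 * pi, length.out = 17)
  lm[1:17, ] <- cbind(cx + rx * cos(th), fy - ry * sin(th)) # jaw arc, chin down
  lm[18:22, ] <- cbind(seq(left_x0, left_x0 + eye_w, length.out = 5), eye_y - 12)
  lm[23:27, ] <- cbind(seq(right_x0, right_x0 + eye_w, length.out = 5), eye_y - 12)
  lm[28:31, ] <- cbind(cx, seq(eye_y, eye_y + 14, length.out = 4))
  lm[32:36, ] <- cbind(seq(cx - 8, cx + 8, length.out = 5), eye_y + 18)
  mo <- seq(0, 2 * pi, length.out = 13)[-13]
  lm[49:60, ] <- cbind(cx + 16 * cos(mo), fy + ry * 0.55 + 7 * sin(mo))
  mi <- seq(0, 2 * pi, length.out = 9)[-9]
  lm[61:68, ] <- cbind(cx + 10 * cos(mi), fy + ry * 0.55 + 3.5 * sin(mi))
  # base image: background, face ellipse, light feature strokes
  img <- new_image(frame_width, frame_height, INTENSITY$background)
  xs <- matrix(rep(0:(frame_width - 1L), each = frame_height), nrow = frame_height)
  ys <- matrix(rep(0:(frame_height - 1L), times = frame_width), nrow = frame_height)
  face <- ((xs - cx) / rx)^2 + ((ys - fy) / ry)^2 <= 1
  img[face] <- INTENSITY$skin
  brow_rows <- (round(eye_y - 13):round(eye_y - 11)) + 1L
  img[brow_rows, (round(left_x0):round(left_x0 + eye_w)) + 1L] <- INTENSITY$feature
  img[brow_rows, (round(right_x0):round(right_x0 + eye_w)) + 1L] <- INTENSITY$feature
  mouth_rows <- (round(fy + ry * 0.55 - 1):round(fy + ry * 0.55 + 1)) + 1L
  img[mouth_rows, (round(cx - 16):round(cx + 16)) + 1L] <- INTENSITY$feature
  list(landmarks = lm, base = img,
       eyes = list(left = list(x0 = left_x0, yc = eye_y, W = eye_w),
                   right = list(x0 = right_x0, yc = eye_y, W = eye_w)),
       face_box = c(left = cx - rx, top = fy - ry, right = cx + rx, bottom = fy + ry),
       pupil_r = max(2, round(eye_w / 10)))
}

# one full-face frame; both eyes share (gx, gy, open_fraction)
render_face_frame <- function(template, gx, gy, open_fraction, frame_index = 0L) {
  img <- template$base
  lm <- template$landmarks
  h_open <- EAR_OPEN # as a fraction of W below
  hexes <- list()
  for (side in c("left", "right")) {
    g <- template$eyes[[side]]
    h <- open_fraction * EAR_OPEN * g$W
    hex <- eye_hexagon(g$x0, g$yc, g$W, h)
    img <- paint_eye(img, hex, gx, gy, template$pupil_r)
    hexes[[side]] <- hex
  }
  # iBUG storage order: viewer-left eye 36..41 is already p1..p6 (its
  # temporal corner has the smallest x, which is the hexagon's first vertex);
  # the viewer-right eye stores nasal corner first, i.e. the hexagon rows in
  # their natural order, and extract_eyes() undoes that
  lm[36:41 + 1L, ] <- hexes$left
  lm[42:47 + 1L, ] <- hexes$right
  structure(list(image = img, landmarks = lm, kind = "face",
                 frame_index = as.integer(frame_index),
                 truth_pupil = c(gx = gx, gy = gy),
                 truth_state = truth_direction(gx, gy, open_fraction),
                 ear = open_fraction * EAR_OPEN,
                 face_box = template$face_box),
            class = "synth_frame")
}

gesture_render_params <- function(state) {
  switch(state,
    LEFT   = list(gx = 0.85, gy = 0.5, open = 1),
    RIGHT  = list(gx = 0.15, gy = 0.5, open = 1),
    UP     = list(gx = 0.5,  gy = 0.2, open = 1),
    BLINK  = list(gx = 0.5,  gy = 0.5, open = 0),
    CENTER = list(gx = 0.5,  gy = 0.5, open = 1),
    abort_param(paste0("unknown gesture state: ", state))
  )
}

#' Define a scripted gesture sequence
#'
#' A script is the stated world for an end-to-end test: each gesture is
#' preceded by `gap_frames` neutral (CENTER) frames and held for
#' `hold_frames` frames, emulating 25 fps capture. Blink gestures must be
#' held at least as long as the intentional-blink rule (13 frames at 25 fps)
#' or the script would not mean what it says.
#'
#' @param gestures Character vector of gesture letters (`"L"`, `"R"`, `"U"`,
#'   `"B"`) or full state names.
#' @param hold_frames Frames each gesture is held (default 20, i.e. 800 ms).
#' @param gap_frames CENTER frames before each gesture (default 10).
#' @param fps Frame rate (default 25).
#' @param seed Seed for landmark jitter.
#' @param noise_px Uniform landmark jitter amplitude in pixels (default 0).
#' @return A list of class `synthetic_script`.
#' @export
synthetic_script <- function(gestures, hold_frames = 20, gap_frames = 10,
                             fps = 25, seed = 1, noise_px = 0) {
  states <- eye_states()
  gestures <- as.character(gestures)
  up <- toupper(gestures)
  full <- ifelse(up %in% names(states), up, names(states)[match(up, states)])
  bad <- which(is.na(full))
  if (length(bad)) {
    abort_param(paste0("invalid gesture letter '", gestures[bad[1]],
                       "' at position ", bad[1], " (expected L, R, U or B)"))
  }
  if (hold_frames < 1 || gap_frames < 1) abort_param("hold_frames and gap_frames must be >= 1")
  min_blink <- max(1L, as.integer(round(13 * fps / 25)))
  if (any(full == "BLINK") && hold_frames < min_blink) {
    abort_param(paste0("BLINK gestures need hold_frames >= ", min_blink,
                       " at ", fps, " fps to count as intentional"))
  }
  structure(list(gestures = full, hold_frames = as.integer(hold_frames),
                 gap_frames = as.integer(gap_frames), fps = fps,
                 seed = seed, noise_px = noise_px),
            class = "synthetic_script")
}

#' Render a script into frames with ground truth
#'
#' @param script A [synthetic_script()].
#' @param frame_width,frame_height Frame dimensions in pixels.
#' @return A list of class `synthetic_clip`: `frames` (list of
#'   `synth_frame`), `landmarks` (list of 68 x 2 matrices, jittered when
#'   `noise_px > 0`), `truth` (per-frame tibble: `frame`, `state`, `gx`,
#'   `gy`, `open_fraction`), `codes` (complete gesture triples), `script`.
#' @export
script_to_frames <- function(script, frame_width = 160, frame_height = 128) {
  stopifnot(inherits(script, "synthetic_script"))
  template <- face_template(frame_width, frame_height)
  states <- purrr::map(script$gestures, function(g) {
    c(rep("CENTER", script$gap_frames), rep(g, script$hold_frames))
  }) |> unlist()
  n <- length(states)
  frames <- vector("list", n)
  truth <- vector("list", n)
  if (n > 0) {
    for (i in seq_len(n)) {
      p <- gesture_render_params(states[i])
      frames[[i]] <- render_face_frame(template, p$gx, p$gy, p$open, frame_index = i - 1L)
      truth[[i]] <- tibble(frame = i - 1L, state = frames[[i]]$truth_state,
                           gx = p$gx, gy = p$gy, open_fraction = p$open)
    }
  }
  lms <- purrr::map(frames, "landmarks")
  if (script$noise_px > 0 && n > 0) {
    lms <- local_seed(script$seed, purrr::map(lms, function(lm) {
      lm + matrix(runif(length(lm), -script$noise_px, script$noise_px), ncol = 2)
    }))
  }
  letters <- unname(eye_states()[script$gestures])
  n_full <- length(letters) %/% 3L
  codes <- if (n_full > 0) {
    vapply(seq_len(n_full), function(i) paste(letters[(3 * i - 2):(3 * i)], collapse = ""),
           character(1))
  } else character(0)
  structure(list(frames = frames, landmarks = lms,
                 truth = if (n > 0) bind_rows(truth) else
                   tibble(frame = integer(), state = character(), gx = double(),
                          gy = double(), open_fraction = double()),
                 codes = codes, script = script),
            class = "synthetic_clip")
}

#' Generate a synthetic EAR trace with scripted dips
#'
#' Piecewise-constant trace at `base_ear` with sub-threshold dips to
#' `dip_ear`, plus optional seeded Gaussian noise. Reproducible for a fixed
#' seed.
#'
#' @param dips List of `c(start_frame, run_length)` pairs (0-based starts),
#'   or a 2-column matrix; must be non-overlapping and inside the trace.
#' @param length Trace length in frames.
#' @param base_ear Open-eye EAR level (default 0.3).
#' @param dip_ear In-blink EAR level (default 0.05).
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param seed RNG seed for the noise.
#' @param fps Frame rate for timestamps.
#' @return A tibble: `frame`, `timestamp`, `ear_left`, `ear_right`,
#'   `ear_mean`.
#' @export
make_ear_trace <- function(dips = list(), length, base_ear = 0.3, dip_ear = 0.05,
                           noise_sd = 0, seed = NULL, fps = 25) {
  if (is.matrix(dips) || is.data.frame(dips)) {
    dips <- purrr::map(seq_len(nrow(dips)), function(i) as.numeric(dips[i, ]))
  }
  occupied <- integer(0)
  for (d in dips) {
    if (length(d) != 2 || d[2] < 1) abort_param("each dip is c(start_frame, run_length) with run >= 1")
    span <- d[1]:(d[1] + d[2] - 1)
    if (d[1] < 0 || max(span) >= length) abort_param("dip lies outside the trace")
    if (any(span %in% occupied)) abort_param("dips must not overlap")
    occupied <- c(occupied, span)
  }
  ear <- rep(base_ear, length)
  ear[occupied + 1L] <- dip_ear
  if (noise_sd > 0) {
    ear <- local_seed(seed, ear + rnorm(length, sd = noise_sd))
    ear <- pmax(ear, 0)
  }
  f <- seq_len(length) - 1L
  tibble(frame = f, timestamp = f / fps,
         ear_left = ear, ear_right = ear, ear_mean = ear)
}

#' Persist a rendered clip as a fixture bundle
#'
#' Writes zero-padded plain-PGM frames, the landmark stream CSV, and a
#' `truth.jsonl` with one record per frame plus a final transcript record.
#'
#' @param clip A `synthetic_clip` from [script_to_frames()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(clip, dir) {
  stopifnot(inherits(clip, "synthetic_clip"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(clip$frames)) {
    write_pgm(clip$frames[[i]]$image, file.path(dir, sprintf("frame_%05d.pgm", i - 1L)))
  }
  write_landmark_csv(clip$landmarks, file.path(dir, "landmarks.csv"),
                     fps = clip$script$fps)
  lines <- purrr::map_chr(seq_len(nrow(clip$truth)), function(i) {
    jsonlite::toJSON(as.list(clip$truth[i, ]), auto_unbox = TRUE)
  })
  lines <- c(lines, as.character(jsonlite::toJSON(
    list(type = "transcript", codes = clip$codes), auto_unbox = TRUE)))
  writeLines(lines, file.path(dir, "truth.jsonl"))
  invisible(dir)
}

#' Read a fixture bundle written by [write_fixture_bundle()]
#'
#' @param dir Bundle directory.
#' @return A list: `images` (list of matrices in frame order), `landmarks`
#'   (list of 68 x 2 matrices or `NULL`), `frames` (indices), `truth_codes`
#'   (expected transcript codes or `NULL`).
#' @export
read_fixture_bundle <- function(dir) {
  if (!dir.exists(dir)) abort_io(paste0("no such fixture directory: ", dir))
  pgms <- sort(list.files(dir, pattern = "\\.pgm$", full.names = TRUE))
  images <- purrr::map(pgms, read_pgm)
  lm_path <- file.path(dir, "landmarks.csv")
  lm <- if (file.exists(lm_path)) read_landmark_csv(lm_path) else NULL
  truth_path <- file.path(dir, "truth.jsonl")
  codes <- NULL
  if (file.exists(truth_path)) {
    recs <- purrr::map(readLines(truth_path), jsonlite::fromJSON)
    tr <- purrr::detect(recs, ~ identical(.x$type, "transcript"))
    if (!is.null(tr)) codes <- as.character(tr$codes)
  }
  list(images = images,
       landmarks = if (!is.null(lm)) lm$landmarks else NULL,
       frames = if (!is.null(lm)) lm$frames else seq_along(images) - 1L,
       truth_codes = codes)
}
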