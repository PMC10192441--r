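frames_of <- function(states) {
  tibble::tibble(frame = seq_along(states) - 1L, state = states)
}

test_that("directional gestures debounce and register once per excursion", {
  cfg <- pipeline_config()
  ev <- register_gestures(frames_of(c(rep("CENTER", 5), rep("LEFT", 30), rep("CENTER", 5))),
                          cfg = cfg)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$state, "LEFT")
  expect_identical(ev$start_frame, 5L)

  two <- register_gestures(frames_of(c(rep("LEFT", 15), rep("CENTER", 5), rep("LEFT", 15))),
                           cfg = cfg)
  expect_identical(nrow(two), 2L)
  expect_identical(two$state, c("LEFT", "LEFT"))

  none <- register_gestures(frames_of(c(rep("CENTER", 5), rep("LEFT", 8), rep("CENTER", 5))),
                            cfg = cfg)
  expect_identical(nrow(none), 0L) # below the 10-frame debounce

  # UNKNOWN frames are transparent: they do not end the excursion
  nox <- register_gestures(frames_of(c(rep("LEFT", 15), rep("UNKNOWN", 3), rep("LEFT", 15))),
                           cfg = cfg)
  expect_identical(nrow(nox), 1L)
})

test_that("intentional blinks become BLINK gestures; natural ones do not", {
  cfg <- pipeline_config()
  tr <- make_ear_trace(list(c(10, 15), c(40, 5)), length = 80)
  blinks <- detect_blinks(tr)
  states <- ifelse(tr$ear_mean <= 0.2, "CLOSED", "CENTER")
  ev <- register_gestures(frames_of(states), blinks, cfg)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$state, "BLINK")
  expect_identical(ev$start_frame, 10L)

  # a blink run truncated at the START of the recording is ignored...
  head_tr <- make_ear_trace(list(c(0, 15)), length = 40)
  hb <- detect_blinks(head_tr)
  expect_identical(nrow(register_gestures(frames_of(rep("CENTER", 40)), hb, cfg)), 0L)
  # ...but one running into the END of a finite recording is accepted
  tail_tr <- make_ear_trace(list(c(25, 15)), length = 40)
  tb <- detect_blinks(tail_tr)
  expect_identical(register_gestures(frames_of(rep("CENTER", 40)), tb, cfg)$state, "BLINK")
  expect_identical(nrow(register_gestures(frames_of(rep("CENTER", 40)), tb, cfg,
                                          boundary = "none")), 0L)
})

test_that("decode_stream groups events in threes and clears the list", {
  d <- load_dictionary()
  cfg <- pipeline_config()
  expect_identical(decode_stream(make_events(c("LEFT", "LEFT", "LEFT")), d, cfg)$phrase,
                   "Water")
  six <- decode_stream(make_events(c("LEFT", "LEFT", "LEFT", "BLINK", "BLINK", "UP")), d, cfg)
  expect_identical(six$phrase, c("Water", "Thank You"))
  expect_identical(six$code, c("LLL", "BBU"))
  expect_identical(nrow(decode_stream(make_events(c("LEFT", "LEFT")), d, cfg)), 0L)
  expect_identical(nrow(decode_stream(NULL, d, cfg)), 0L)
})

test_that("phrase count is conserved: floor(gestures / 3) on uninterrupted streams", {
  d <- load_dictionary()
  cfg <- pipeline_config()
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(0:10, 1)
    states <- sample(c("LEFT", "RIGHT", "UP", "BLINK"), n, replace = TRUE)
    out <- decode_stream(make_events(states), d, cfg)
    expect_identical(nrow(out), n %/% 3L)
  }
})

test_that("the five-second correction window clears stale pending gestures", {
  d <- load_dictionary()
  cfg <- pipeline_config()
  ev <- make_events(c("LEFT", "LEFT", "RIGHT", "RIGHT", "RIGHT"), dt = 1)
  # delay the last three events by 8 s: the two pending LEFTs expire
  ev$registered_at[3:5] <- ev$registered_at[3:5] + 8
  out <- decode_stream(ev, d, cfg)
  expect_identical(out$phrase, "Food") # RRR, not LLR + trailing
  # within the window nothing is cleared
  ok <- decode_stream(make_events(c("LEFT", "LEFT", "RIGHT"), dt = 4), d, cfg)
  expect_identical(ok$code, "LLR")
})

test_that("run_pipeline decodes scripted clips end to end", {
  d <- load_dictionary()
  res <- run_pipeline(script_to_frames(synthetic_script(c("L", "L", "L"))), d)
  expect_identical(res$transcript$phrase, "Water")
  res2 <- run_pipeline(script_to_frames(synthetic_script(c("B", "R", "U"))), d)
  expect_identical(res2$transcript$phrase, "I Want to Pray")
  empty <- run_pipeline(script_to_frames(synthetic_script(character(0))), d)
  expect_identical(nrow(empty$transcript), 0L)
  expect_identical(nrow(empty$diagnostics), 0L)
})

test_that("per-frame diagnostics track the scripted truth states", {
  clip <- script_to_frames(synthetic_script(c("U", "B", "R")))
  res <- run_pipeline(clip)
  merged <- dplyr::inner_join(res$diagnostics, clip$truth, by = "frame")
  # every held-gesture frame must classify as its scripted state
  held <- merged[merged$state.y != "CENTER", ]
  expect_true(all(held$state.x == held$state.y))
  expect_true(all(res$diagnostics$state %in%
                    c("LEFT", "RIGHT", "UP", "CENTER", "CLOSED", "UNKNOWN")))
})

test_that("the landmark-CSV route and the in-memory route decode identically", {
  clip <- script_to_frames(synthetic_script(c("L", "U", "B"), seed = 5))
  dir <- file.path(tempdir(), "route-test")
  unlink(dir, recursive = TRUE)
  write_fixture_bundle(clip, dir)
  d <- load_dictionary()
  via_memory <- run_pipeline(clip, d)
  via_disk <- run_pipeline(dir, d) # frames + landmarks.csv re-read from disk
  expect_identical(via_disk$transcript$code, via_memory$transcript$code)
  expect_identical(via_disk$transcript$phrase, via_memory$transcript$phrase)
  unlink(dir, recursive = TRUE)
})

test_that("bounded queue drops oldest and keeps exact counts", {
  q <- frame_queue(3)
  outcomes <- vapply(1:5, function(i) queue_push(q, i), character(1))
  expect_identical(outcomes, c("accepted", "accepted", "accepted",
                               "dropped_oldest", "dropped_oldest"))
  st <- queue_stats(q)
  expect_identical(st$size, 3L)
  expect_identical(st$drops, 2L)
  expect_identical(unlist(q$items), 3:5) # newest three retained

  q1 <- frame_queue(1)
  for (i in 1:4) queue_push(q1, i)
  expect_identical(unlist(q1$items), 4L) # always the most recent frame
  expect_error(frame_queue(0), class = "eyespeak_config_error")
})

test_that("receive/process decoupling preserves the transcript when drops hit gaps", {
  clip <- script_to_frames(synthetic_script(c("L", "R", "B"), hold_frames = 20,
                                            gap_frames = 10))
  s <- stream_session(queue_capacity = 8)
  max_seen <- 0L
  for (i in seq_along(clip$frames)) {
    session_receive(s, clip$frames[[i]], clip$landmarks[[i]])
    max_seen <- max(max_seen, queue_stats(s$queue)$size)
    # the consumer keeps up during gestures but stalls during neutral gaps,
    # so the bursty overflow only ever drops CENTER frames
    if (clip$truth$state[i] != "CENTER") session_process(s, n = Inf)
  }
  session_process(s, n = Inf)
  expect_lte(max_seen, 8L)
  expect_gt(s$queue$drops, 0L)
  res <- session_decode(s)
  expect_identical(res$transcript$code, "LRB")
  expect_identical(res$transcript$phrase, "I am not Okay")
  expect_identical(res$dropped_frames, s$queue$drops)
})

test_that("the speed model completes the equation chain", {
  m <- communication_speed(D = 2, FR = 25, R = 1e4, N = 1e6, P = 3.5)
  expect_equal(m$F, 50)
  expect_equal(m$X, 5e5)
  expect_equal(m$B, 4e6)
  expect_equal(m$T, 4)
  expect_equal(m$CS, 7.5)

  degenerate <- communication_speed(D = 0, FR = 25, R = 1e4, N = 1e6, P = 3.5)
  expect_equal(degenerate$F, 0)
  expect_equal(degenerate$T, 0)
  expect_equal(degenerate$CS, degenerate$P)

  expect_error(communication_speed(D = 2, FR = 25, R = 1e4, N = 0, P = 3.5),
               class = "eyespeak_input_error")
  expect_error(communication_speed(D = -1, FR = 25, R = 1e4, N = 1, P = 0),
               class = "eyespeak_input_error")
})

test_that("tidy and glance summarise the speed model", {
  m <- communication_speed(D = 2, FR = 25, R = 1e4, N = 1e6, P = 3.5)
  td <- tidy(m)
  expect_identical(td$term, c("D", "FR", "F", "R", "X", "B", "N", "P", "T", "CS"))
  expect_identical(td$value[td$term == "CS"], 7.5)
  expect_true(all(nzchar(td$unit)))
  g <- glance(m)
  expect_equal(g$transmission_share, 4 / 7.5)
  expect_s3_class(autoplot(m), "ggplot")
})

test_that("plot helpers return ggplot objects", {
  tr <- make_ear_trace(list(c(10, 15)), length = 50)
  expect_s3_class(plot_ear_trace(tr, detect_blinks(tr)), "ggplot")
  res <- run_pipeline(script_to_frames(synthetic_script(c("L", "L", "L"),
                                                        hold_frames = 13, gap_frames = 5)))
  expect_s3_class(plot_gaze_path(res$diagnostics), "ggplot")
  expect_s3_class(autoplot(res), "ggplot")
})
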