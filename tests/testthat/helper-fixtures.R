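# Shared fixtures built in code; nothing here touches the network or disk
# outside tempdir().

# the hand-checkable 6-point eye: width 4, both vertical gaps 2 => EAR 0.5
hand_eye <- function() {
  rbind(p1 = c(0, 0), p2 = c(1, 1), p3 = c(3, 1),
        p4 = c(4, 0), p5 = c(3, -1), p6 = c(1, -1))
}

rotate_points <- function(pts, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  t(R %*% t(pts))
}

jaccard_box <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  area <- function(z) (z[3] - z[1]) * (z[4] - z[2])
  inter / (area(a) + area(b) - inter)
}

# a gesture-event tibble without running the pipeline, spaced dt seconds apart
make_events <- function(states, dt = 1, fps = 25) {
  n <- length(states)
  tibble::tibble(
    state = states,
    start_frame = as.integer((seq_len(n) - 1) * dt * fps),
    end_frame = as.integer((seq_len(n) - 1) * dt * fps + 5),
    registered_at = (seq_len(n) - 1) * dt + 5 / fps)
}

# write a dictionary TSV from a code->phrase tibble
write_dict_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path, progress = FALSE)
  path
}
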