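# Analytic communication-speed model.
#
# End-to-end communication speed CS is server processing time P plus
# transmission time T. T follows from the video parameters:
#   F = D * FR      total frames in the inspected clip
#   X = F * R       total pixels (R = frame resolution, pixels/frame)
#   B = X * 8       total bits (8 bits per grayscale pixel)
#   T = B / N       transmission time over bandwidth N (bits/second)
#   CS = P + T
# P is measured, not modelled: the deployed backend needed three to four
# seconds per three-gesture sequence, so it enters as an input.

#' Complete the communication-speed model
#'
#' @param D Video clip duration, seconds (`>= 0`).
#' @param FR Frame rate, frames/second (`> 0`).
#' @param R Frame resolution, pixels/frame (`> 0`).
#' @param N Network bandwidth, bits/second (`> 0`).
#' @param P Server processing time, seconds (`>= 0`); measured empirically.
#' @return A one-row tibble of class `speed_model` with columns
#'   `D, FR, F, R, X, B, N, P, T, CS`.
#' @examples
#' m <- communication_speed(D = 2, FR = 25, R = 1e4, N = 1e6, P = 3.5)
#' m$CS # 7.5 seconds
#' @export
communication_speed <- function(D, FR, R, N, P) {
  for (nm in c("D", "FR", "R", "N", "P")) {
    v <- get(nm)
    if (!is_scalar_number(v)) abort_input(paste0(nm, " must be a finite number"))
  }
  if (D < 0) abort_input("D (duration) must be >= 0")
  if (FR <= 0 || R <= 0) abort_input("FR and R must be positive")
  if (N <= 0) abort_input("N (bandwidth) must be positive: transmission time is B / N")
  if (P < 0) abort_input("P (processing time) must be >= 0")
  F <- D * FR
  X <- F * R
  B <- X * 8
  T <- B / N
  CS <- P + T
  out <- tibble(D = D, FR = FR, F = F, R = R, X = X, B = B, N = N, P = P,
                T = T, CS = CS)
  class(out) <- c("speed_model", class(out))
  out
}

speed_model_units <- c(
  D = "s", FR = "frames/s", F = "frames", R = "pixels/frame", X = "pixels",
  B = "bits", N = "bits/s", P = "s", T = "s", CS = "s")

speed_model_descriptions <- c(
  D = "video clip duration", FR = "frame rate", F = "total frames",
  R = "frame resolution", X = "total pixels", B = "total bits",
  N = "network bandwidth", P = "server processing time",
  T = "transmission time", CS = "communication speed")

#' Tidy a speed model into term/value/unit rows
#' @param x A `speed_model`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `value`, `unit`, `description`.
#' @method tidy speed_model
#' @export
tidy.speed_model <- function(x, ...) {
  terms <- names(speed_model_units)
  tibble(term = terms,
         value = purrr::map_dbl(terms, ~ x[[.x]]),
         unit = unname(speed_model_units),
         description = unname(speed_model_descriptions))
}

#' One-row summary of a speed model
#' @param x A `speed_model`.
#' @param ... Unused.
#' @return A tibble with `CS`, `P`, `T` and the share of time spent in
#'   transmission.
#' @method glance speed_model
#' @export
glance.speed_model <- function(x, ...) {
  tibble(CS = x$CS, P = x$P, T = x$T,
         transmission_share = if (x$CS > 0) x$T / x$CS else 0)
}

#' Plot the processing/transmission split of a speed model
#' @param object A `speed_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot speed_model
#' @export
autoplot.speed_model <- function(object, ...) {
  d <- tibble(component = factor(c("processing (P)", "transmission (T)"),
                                 levels = c("transmission (T)", "processing (P)")),
              seconds = c(object$P, object$T))
  ggplot2::ggplot(d, ggplot2::aes(x = "CS", y = .data$seconds, fill = .data$component)) +
    ggplot2::geom_col(width = 0.5) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "seconds",
                  title = sprintf("Communication speed: %.2f s", object$CS)) +
    ggplot2::theme_minimal()
}

# independent re-check used by tests: do the five relations hold?
speed_model_consistent <- function(m, tol = 1e-9) {
  abs(m$F - m$D * m$FR) <= tol * max(1, abs(m$F)) &&
    abs(m$X - m$F * m$R) <= tol * max(1, abs(m$X)) &&
    abs(m$B - m$X * 8) <= tol * max(1, abs(m$B)) &&
    abs(m$T - m$B / m$N) <= tol * max(1, abs(m$T)) &&
    abs(m$CS - (m$P + m$T)) <= tol * max(1, abs(m$CS))
}
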