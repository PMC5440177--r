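# Frame timing for the dynamic acquisition.

#' Decay constant of carbon-11
#'
#' @return The decay constant of the 11C isotope in s^-1 (half-life ~20.4 min).
#' @export
lambda_c11 <- function() 0.0005663

#' Default 24-frame dynamic acquisition layout
#'
#' The 90.5-min protocol used throughout the package: 1x30 s, 4x15 s, 4x60 s,
#' 2x150 s, 10x300 s and 3x600 s frames (5430 s in total), tracer injected as
#' a bolus 30 s after scan start.
#'
#' @return A tibble with columns `count` and `duration_s`.
#' @export
default_frame_spec <- function() {
  tibble(
    count      = c(1L, 4L, 4L, 2L, 10L, 3L),
    duration_s = c(30, 15, 60, 150, 300, 600)
  )
}

#' Build a frame schedule
#'
#' Expands a compact `(count, duration)` layout into a contiguous per-frame
#' schedule starting at time 0 (scan start). All model fitting in the package
#' evaluates curves at the frame midpoints of this schedule.
#'
#' @param spec A data frame with columns `count` and `duration_s`; defaults to
#'   [default_frame_spec()].
#' @param injection_time Seconds from scan start at which the tracer bolus is
#'   given (default 30 s).
#' @param decay_constant Isotope decay constant in s^-1 (default 11C).
#' @return A `frame_schedule`: a tibble with columns `frame` (1-based),
#'   `t_start`, `t_end`, `duration` (all seconds) and attributes
#'   `injection_time` and `decay_constant`.
#' @export
#' @examples
#' sched <- frame_schedule()
#' nrow(sched)                 # 24
#' max(sched$t_end)            # 5430 s = 90.5 min
frame_schedule <- function(spec = default_frame_spec(),
                           injection_time = 30,
                           decay_constant = lambda_c11()) {
  if (!is.data.frame(spec) || !all(c("count", "duration_s") %in% names(spec)) ||
      nrow(spec) == 0L) {
    abort("`spec` must be a non-empty data frame with columns `count` and `duration_s`.")
  }
  if (any(spec$count < 1) || any(spec$count != round(spec$count))) {
    abort("Frame counts must be positive integers.")
  }
  if (any(spec$duration_s <= 0)) {
    abort("Frame durations must be positive.")
  }
  check_number(decay_constant, "decay_constant", lower = 0, strict_lower = TRUE)
  durations <- rep(spec$duration_s, spec$count)
  t_end <- cumsum(durations)
  out <- tibble(
    frame    = seq_along(durations),
    t_start  = t_end - durations,
    t_end    = t_end,
    duration = durations
  )
  structure(out,
    injection_time = injection_time,
    decay_constant = decay_constant,
    class = c("frame_schedule", class(out))
  )
}

n_frames <- function(schedule) nrow(schedule)

#' Frame midpoints of a schedule
#'
#' @param schedule A [frame_schedule()].
#' @return Numeric vector of frame midpoint times in seconds.
#' @export
frame_midpoints <- function(schedule) {
  (schedule$t_start + schedule$t_end) / 2
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf(
    "<frame_schedule> %d frames, %.0f s total, injection at %.0f s, lambda = %g s^-1\n",
    nrow(x), max(x$t_end), attr(x, "injection_time"), attr(x, "decay_constant")
  ))
  NextMethod()
}

assert_schedule <- function(schedule) {
  if (!inherits(schedule, "frame_schedule")) {
    abort("Expected a `frame_schedule` object (see `frame_schedule()`).")
  }
  invisible(schedule)
}
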