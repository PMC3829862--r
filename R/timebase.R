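#' Imaging timebase for a single well
#'
#' A `timebase` records the frame acquisition times of one well's time-lapse
#' together with the position of the agonist dispense. Frames `1..n_pre` are
#' pre-dispense (baseline); the agonist is injected immediately after the last
#' pre-dispense frame, so frames `n_pre + 1` onwards carry the evoked
#' transient. `dispense_index` is the 0-based index of the first post-dispense
#' frame and therefore always equals `n_pre`; the 0-based convention is the one
#' used in sidecar files and matches the frame-axis origin documented there.
#'
#' @param times numeric vector of acquisition times in seconds, strictly
#'   increasing, starting at 0.
#' @param n_pre number of pre-dispense frames (>= 1).
#' @return An object of class `timebase` with fields `times`, `n_pre`,
#'   `dispense_index` (0-based, equal to `n_pre`) and `dispense_time` (the
#'   time of injection, taken as the time of the last pre-dispense frame).
#' @export
timebase <- function(times, n_pre) {
  times <- as.numeric(times)
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("`times` must be strictly increasing with at least 2 frames")
  if (times[1] != 0)
    stop("`times` must start at 0")
  n_pre <- as.integer(n_pre)
  if (n_pre < 1L || n_pre >= length(times))
    stop("`n_pre` must satisfy 1 <= n_pre < number of frames")
  structure(
    list(times = times, n_pre = n_pre, dispense_index = n_pre,
         dispense_time = times[n_pre]),
    class = "timebase")
}

#' Canonical 13-frame acquisition timebase
#'
#' The default protocol images each well for 23.5 s in total: a 5 s baseline
#' window sampled at 2.5 s intervals (frames at t = 0, 2.5, 5 s), agonist
#' dispensed immediately after the third frame, then 5 s at 1 s intervals
#' (t = 6..10 s) to capture the fast calcium rise, and finally 12.5 s at 2.5 s
#' intervals (t = 12.5..22.5 s) for the decay — 13 frames altogether.
#'
#' @return A [timebase] with 13 frames and `n_pre = 3`.
#' @export
default_timebase <- function() {
  timebase(c(0, 2.5, 5, 6:10, seq(12.5, 22.5, by = 2.5)), n_pre = 3L)
}

#' @export
print.timebase <- function(x, ...) {
  cat(sprintf("timebase: %d frames, %d pre-dispense, dispense at t = %.1f s, last frame t = %.1f s\n",
              length(x$times), x$n_pre, x$dispense_time, max(x$times)))
  invisible(x)
}

#' Indices of post-dispense frames (1-based)
#' @param tb a [timebase]
#' @return integer vector of frame indices at/after agonist dispense.
#' @export
post_dispense_frames <- function(tb) {
  seq.int(tb$n_pre + 1L, length(tb$times))
}
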