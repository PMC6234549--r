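#' PET frame schedule
#'
#' The acquisition time grid of a dynamic scan: contiguous frames described by
#' start times and durations in seconds. Frame-averaged model predictions and
#' the noise/weight models are defined on this grid.
#'
#' @param duration_s frame durations in seconds (all `> 0`).
#' @param start_s optional frame start times in seconds; when omitted the
#'   frames are laid out contiguously from zero. When given, the first frame
#'   must start at zero and `start[i+1] == start[i] + duration[i]`.
#' @return an object of class `frame_schedule`: a data frame with columns
#'   `start_s` and `dur_s`.
#' @examples
#' sch <- default_frame_schedule()
#' nrow(sch)            # 19 frames
#' sum(sch$dur_s)       # 3600 s
#' @export
frame_schedule <- function(duration_s, start_s = NULL) {
  duration_s <- as.numeric(duration_s)
  if (length(duration_s) < 1L || anyNA(duration_s) || any(duration_s <= 0))
    stop("frame durations must be positive and non-missing")
  if (is.null(start_s)) {
    start_s <- cumsum(c(0, duration_s[-length(duration_s)]))
  } else {
    start_s <- as.numeric(start_s)
    if (length(start_s) != length(duration_s))
      stop("start_s and duration_s lengths differ")
    if (abs(start_s[1]) > 1e-9) stop("first frame must start at time zero")
    gap <- start_s[-1] - (start_s[-length(start_s)] + duration_s[-length(duration_s)])
    if (any(abs(gap) > 1e-6)) {
      bad <- which(abs(gap) > 1e-6)[1] + 1L
      stop(sprintf("frames must be contiguous: frame %d starts at %g s but frame %d ends at %g s",
                   bad, start_s[bad], bad - 1L,
                   start_s[bad - 1L] + duration_s[bad - 1L]))
    }
  }
  structure(data.frame(start_s = start_s, dur_s = duration_s),
            class = c("frame_schedule", "data.frame"))
}

#' Default 60-min, 19-frame acquisition schedule
#'
#' The standard dynamic rebinning used throughout the package:
#' 1 x 15, 3 x 5, 3 x 10, 4 x 60, 2 x 150, 2 x 300 and 4 x 600 s frames,
#' totalling 3600 s.
#'
#' @return a [frame_schedule] with 19 frames.
#' @export
default_frame_schedule <- function() {
  frame_schedule(rep(c(15, 5, 10, 60, 150, 300, 600), c(1, 3, 3, 4, 2, 2, 4)))
}

#' Frame midpoints
#'
#' @param schedule a [frame_schedule].
#' @param unit `"s"` or `"min"`.
#' @return numeric vector of frame midpoint times.
#' @export
frame_mid <- function(schedule, unit = c("s", "min")) {
  stopifnot(inherits(schedule, "frame_schedule"))
  unit <- match.arg(unit)
  mid <- schedule$start_s + schedule$dur_s / 2
  if (unit == "min") mid / 60 else mid
}

frame_end_s <- function(schedule) schedule$start_s + schedule$dur_s

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("frame schedule: %d frames, %.0f s total\n", nrow(x), sum(x$dur_s)))
  NextMethod()
}
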