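#' Frame schedule of a dynamic PET acquisition
#'
#' A frame schedule holds the start and end times, in minutes, of the
#' time frames into which a dynamic scan is binned. Frames must be
#' non-overlapping and ascending, with the first start at or after
#' injection (time 0).
#'
#' @param start numeric vector of frame start times (minutes).
#' @param end numeric vector of frame end times (minutes), same length.
#' @return An object of class `frame_schedule` with elements `start` and
#'   `end`.
#' @examples
#' sch <- frame_schedule(c(0, 1, 2), c(1, 2, 5))
#' frame_midpoints(sch)
#' @export
frame_schedule <- function(start, end) {
  if (length(start) != length(end)) {
    stop("frame start and end vectors must have the same length", call. = FALSE)
  }
  if (length(start) == 0L) stop("schedule must contain at least one frame", call. = FALSE)
  if (any(!is.finite(start)) || any(!is.finite(end))) {
    stop("frame times must be finite", call. = FALSE)
  }
  if (start[1L] < 0) stop("first frame must start at or after time 0", call. = FALSE)
  if (any(end <= start)) {
    i <- which(end <= start)[1L]
    stop(sprintf("frame %d has end <= start (%g <= %g)", i, end[i], start[i]),
         call. = FALSE)
  }
  if (length(start) > 1L && any(start[-1L] < end[-length(end)] - 1e-9)) {
    stop("frames must be non-overlapping and ascending", call. = FALSE)
  }
  structure(list(start = as.numeric(start), end = as.numeric(end)),
            class = "frame_schedule")
}

#' Default dynamic framing for a 90- or 120-minute scan
#'
#' Early frames are short to resolve the arterial peak (6 x 1 min,
#' 5 x 2 min, 4 x 5 min), followed by 6-minute frames to the end of the
#' scan.
#'
#' @param total_min scan duration in minutes; must be 36 + a multiple of 6.
#' @return A [frame_schedule()].
#' @export
default_frame_schedule <- function(total_min = 120) {
  assert_scalar_num(total_min, "total_min", lower = 42)
  if ((total_min - 36) %% 6 != 0) {
    stop("total_min must be 36 plus a multiple of 6 minutes", call. = FALSE)
  }
  dur <- c(rep(1, 6), rep(2, 5), rep(5, 4), rep(6, (total_min - 36) / 6))
  e <- cumsum(dur)
  frame_schedule(c(0, head(e, -1)), e)
}

#' @rdname frame_schedule
#' @param schedule a `frame_schedule`.
#' @export
frame_midpoints <- function(schedule) (schedule$start + schedule$end) / 2

#' @rdname frame_schedule
#' @export
frame_durations <- function(schedule) schedule$end - schedule$start

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %g-%g min\n",
              length(x$start), x$start[1L], x$end[length(x$end)]))
  invisible(x)
}

n_frames <- function(schedule) length(schedule$start)
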