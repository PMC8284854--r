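#' Build a PET acquisition frame schedule
#'
#' A frame schedule is the sequence of acquisition time frames of a dynamic
#' PET study.  It is specified, as on a scanner console, by a run-length
#' list of (count, duration) pairs, e.g. `list(c(15, 2), c(12, 10))` for
#' fifteen 2-second frames followed by twelve 10-second frames.
#'
#' @param spec list of `c(count, duration_seconds)` pairs (or a 2-column
#'   matrix with one row per block).
#' @param origin start time of the first frame, in seconds (default 0).
#' @return An object of class `frame_schedule`: a data frame with columns
#'   `start_s` and `duration_s` (one row per frame) and attributes
#'   `n_frames` (number of frames) and `end_min` (end of acquisition,
#'   minutes after time zero).
#' @examples
#' # a typical radiowater acquisition: 57 frames over 8.75 minutes
#' sch <- frame_schedule(list(c(1, 60), c(15, 2), c(15, 5),
#'                            c(12, 10), c(8, 15), c(6, 20)))
#' n_frames(sch)
#' schedule_end(sch)
#' @export
frame_schedule <- function(spec, origin = 0) {
  if (is.matrix(spec)) spec <- lapply(seq_len(nrow(spec)), function(i) spec[i, ])
  if (!is.list(spec) || length(spec) == 0L)
    stop("'spec' must be a non-empty list of (count, duration) pairs")
  counts <- vapply(spec, function(p) p[[1]], numeric(1))
  durs <- vapply(spec, function(p) p[[2]], numeric(1))
  if (any(counts < 1) || any(counts != round(counts)))
    stop("frame counts must be positive integers")
  if (any(durs <= 0)) stop("frame durations must be positive")
  duration_s <- rep(durs, times = counts)
  start_s <- origin + cumsum(c(0, duration_s[-length(duration_s)]))
  out <- data.frame(start_s = start_s, duration_s = duration_s)
  class(out) <- c("frame_schedule", "data.frame")
  attr(out, "n_frames") <- nrow(out)
  attr(out, "end_min") <- (start_s[length(start_s)] +
                             duration_s[length(duration_s)]) / 60
  out
}

#' @rdname frame_schedule
#' @param x a `frame_schedule`.
#' @export
n_frames <- function(x) nrow(x)

#' @rdname frame_schedule
#' @export
schedule_end <- function(x) {
  (x$start_s[nrow(x)] + x$duration_s[nrow(x)]) / 60
}

#' Frame midpoints, starts and ends in minutes
#' @param x a `frame_schedule`.
#' @return numeric vector, minutes.
#' @export
frame_mid_min <- function(x) (x$start_s + x$duration_s / 2) / 60

#' @rdname frame_mid_min
#' @export
frame_start_min <- function(x) x$start_s / 60

#' @rdname frame_mid_min
#' @export
frame_end_min <- function(x) (x$start_s + x$duration_s) / 60

#' Concatenate frame schedules back-to-back
#'
#' Later schedules are shifted so each begins where the previous one ends;
#' used to assemble multi-injection acquisition protocols.
#'
#' @param ... `frame_schedule` objects.
#' @return A single `frame_schedule`.
#' @export
concat_schedules <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "frame_schedule")) parts <- parts[[1]]
  offset <- 0
  rows <- lapply(parts, function(p) {
    stopifnot(inherits(p, "frame_schedule"))
    r <- data.frame(start_s = p$start_s - p$start_s[1] + offset,
                    duration_s = p$duration_s)
    offset <<- r$start_s[nrow(r)] + r$duration_s[nrow(r)]
    r
  })
  out <- do.call(rbind, rows)
  class(out) <- c("frame_schedule", "data.frame")
  attr(out, "n_frames") <- nrow(out)
  attr(out, "end_min") <- (out$start_s[nrow(out)] +
                             out$duration_s[nrow(out)]) / 60
  out
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("Frame schedule: %d frames, %.4g min total\n",
              nrow(x), schedule_end(x) - x$start_s[1] / 60))
  invisible(x)
}

#' Read/write frame schedules as CSV
#'
#' CSV layout: one row per frame, columns `start_s`, `duration_s`.
#'
#' @param x a `frame_schedule`.
#' @param file path.
#' @export
write_schedule_csv <- function(x, file) {
  utils::write.csv(as.data.frame(x), file, row.names = FALSE)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(file) {
  d <- utils::read.csv(file)
  if (!all(c("start_s", "duration_s") %in% names(d)))
    stop("schedule CSV needs columns start_s, duration_s")
  if (any(d$duration_s <= 0)) stop("frame durations must be positive")
  if (any(diff(d$start_s) <= 0)) stop("frame starts must be increasing")
  if (any(d$start_s[-1] < (d$start_s + d$duration_s)[-nrow(d)] - 1e-9))
    stop("frames overlap")
  out <- data.frame(start_s = d$start_s, duration_s = d$duration_s)
  class(out) <- c("frame_schedule", "data.frame")
  attr(out, "n_frames") <- nrow(out)
  attr(out, "end_min") <- (out$start_s[nrow(out)] +
                             out$duration_s[nrow(out)]) / 60
  out
}

#' Standard acquisition sequences for the bundled study designs
#'
#' `h2o_schedule()` is a 57-frame 8.75-minute bolus-water protocol
#' (1x1 min pre-injection, 15x2 s, 15x5 s, 12x10 s, 8x15 s, 6x20 s);
#' `fdg_schedule()` is a 25-frame 61-minute FDG protocol (1x1 min
#' pre-injection, 4x20 s, 4x40 s, 4x1 min, 4x3 min, 8x5 min).
#'
#' @param origin start of the first frame in seconds.
#' @return A `frame_schedule`.
#' @export
h2o_schedule <- function(origin = 0) {
  frame_schedule(list(c(1, 60), c(15, 2), c(15, 5),
                      c(12, 10), c(8, 15), c(6, 20)), origin = origin)
}

#' @rdname h2o_schedule
#' @export
fdg_schedule <- function(origin = 0) {
  frame_schedule(list(c(1, 60), c(4, 20), c(4, 40),
                      c(4, 60), c(4, 180), c(8, 300)), origin = origin)
}
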