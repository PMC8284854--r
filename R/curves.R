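#' Sampled time-activity curves
#'
#' Container for a sampled concentration curve: an arterial input function
#' (AIF, C_p), a venous injection-site signal (C_IV) or a tissue
#' time-activity curve (TAC).  Times are minutes; values are activity
#' concentrations (MBq/cc).
#'
#' @param time_min sample times, minutes, strictly increasing.
#' @param value activity concentration at each time.
#' @param label optional character label (e.g. "Cp", "TAC").
#' @param require_nonneg if TRUE (default) negative values are an error,
#'   as appropriate for input functions.
#' @return An object of class `sampled_curve` (data frame with columns
#'   `time_min`, `value`).
#' @export
sampled_curve <- function(time_min, value, label = "curve",
                          require_nonneg = TRUE) {
  if (length(time_min) != length(value))
    stop("time and value lengths differ")
  if (length(time_min) < 1L) stop("empty curve")
  if (any(diff(time_min) <= 0)) stop("sample times must be increasing")
  if (require_nonneg && any(value < 0))
    stop("negative values in a non-negative curve")
  out <- data.frame(time_min = as.numeric(time_min),
                    value = as.numeric(value))
  attr(out, "label") <- label
  class(out) <- c("sampled_curve", "data.frame")
  out
}

#' Evaluate a sampled curve at arbitrary times
#'
#' Linear interpolation between samples; zero before the first sample
#' (curves represent tracer signals that are zero pre-injection) and the
#' last sampled value after the final sample.
#'
#' @param curve a `sampled_curve`.
#' @param t times (minutes).
#' @export
curve_at <- function(curve, t) {
  if (nrow(curve) == 1L)
    return(ifelse(t < curve$time_min[1], 0, curve$value[1]))
  stats::approx(curve$time_min, curve$value, xout = t,
                yleft = 0, yright = curve$value[nrow(curve)])$y
}

#' Running integral of a curve (trapezoid), evaluated at given times
#' @param curve a `sampled_curve`.
#' @param t times (minutes).
#' @return integral of the curve from 0 (or its first support) to each `t`.
#' @export
curve_integral_at <- function(curve, t) {
  grid <- sort(unique(c(0, curve$time_min, t)))
  v <- curve_at(curve, grid)
  cumint <- c(0, cumsum(diff(grid) * (v[-1] + v[-length(v)]) / 2))
  stats::approx(grid, cumint, xout = t, yleft = 0,
                yright = cumint[length(cumint)])$y
}

#' @export
print.sampled_curve <- function(x, ...) {
  cat(sprintf("Sampled curve '%s': %d samples on [%.3g, %.3g] min, peak %.4g\n",
              attr(x, "label"), nrow(x), x$time_min[1],
              x$time_min[nrow(x)], max(x$value)))
  invisible(x)
}

#' Read/write sampled curves as CSV (columns time_min, value)
#' @param x a `sampled_curve`.
#' @param file path.
#' @export
write_curve_csv <- function(x, file) {
  utils::write.csv(data.frame(time_min = x$time_min, value = x$value),
                   file, row.names = FALSE)
}

#' @rdname write_curve_csv
#' @param label label for the curve read from file.
#' @export
read_curve_csv <- function(file, label = "curve") {
  d <- utils::read.csv(file)
  sampled_curve(d$time_min, d$value, label = label, require_nonneg = FALSE)
}

#' Average a finely sampled function over the frames of a schedule
#'
#' PET frames record counts integrated over the frame interval, so model
#' curves are compared with data through their frame averages rather than
#' midpoint values.
#'
#' @param tgrid fine time grid, minutes, uniform spacing.
#' @param values function values on `tgrid`.
#' @param schedule a `frame_schedule`.
#' @return numeric vector of frame averages, length `n_frames(schedule)`.
#' @export
frame_average <- function(tgrid, values, schedule) {
  starts <- frame_start_min(schedule)
  ends <- frame_end_min(schedule)
  n <- length(tgrid)
  # trapezoid cumulative integral at the grid points
  cumint <- c(0, cumsum(diff(tgrid) * (values[-1] + values[-n]) / 2))
  Iat <- function(t) stats::approx(tgrid, cumint, xout = t, yleft = 0,
                                   yright = cumint[n])$y
  (Iat(ends) - Iat(starts)) / (ends - starts)
}
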