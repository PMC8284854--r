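# Synthetic arterial input functions.  The bolus shape is a gamma-variate
# -- the standard parametric form for a first-pass arterial bolus -- with
# an optional recirculation tail; infusion inputs convolve the bolus with
# a rectangular pump profile.

gamma_variate <- function(t, onset, peak_delay, shape, amplitude) {
  u <- (t - onset) / peak_delay
  v <- ifelse(u > 0, amplitude * u^shape * exp(shape * (1 - u)), 0)
  v[!is.finite(v)] <- 0
  v
}

#' Synthetic arterial input function
#'
#' `h2o_bolus`: a sharp gamma-variate bolus (peak `peak_delay` minutes
#' after `onset`, amplitude at the peak) plus a small recirculation tail.
#' `fdg_infusion`: the same gamma-variate shape convolved with a
#' rectangular constant-rate infusion of duration `infusion_min`
#' (default 2 minutes) plus a slow washout tail.  As the infusion
#' duration goes to zero the infusion input converges to the bolus.
#'
#' @param tracer_kind `"h2o_bolus"` or `"fdg_infusion"`.
#' @param onset injection time, minutes (global study time).
#' @param peak_delay bolus time-to-peak, minutes (default 0.6 for the
#'   bolus: a peak roughly 30-60 s after injection).
#' @param shape gamma-variate shape parameter (> 0; larger = sharper).
#' @param amplitude peak amplitude of the underlying bolus (MBq/cc).
#' @param tail_frac recirculation/washout tail amplitude as a fraction of
#'   the bolus peak.
#' @param tail_rate tail decay rate, 1/min.
#' @param infusion_min infusion duration (infusion kind only), minutes.
#' @param grid time grid for the returned curve, minutes; defaults to
#'   0.5 s sampling over `[0, t_end]`.
#' @param t_end end of the returned support, minutes.
#' @return A `sampled_curve` (non-negative, zero before `onset`).
#' @export
synth_aif <- function(tracer_kind = c("h2o_bolus", "fdg_infusion"),
                      onset = 1, peak_delay = 0.6, shape = 3,
                      amplitude = 1, tail_frac = 0.08, tail_rate = 0.25,
                      infusion_min = 2, grid = NULL, t_end = 10) {
  tracer_kind <- match.arg(tracer_kind)
  if (peak_delay <= 0 || shape <= 0 || amplitude < 0 ||
      tail_frac < 0 || tail_rate < 0 || infusion_min < 0)
    stop("negative or zero shape parameters")
  if (is.null(grid)) grid <- seq(0, t_end, by = 1 / 120)
  bolus <- gamma_variate(grid, onset, peak_delay, shape, amplitude)
  if (tracer_kind == "fdg_infusion" && infusion_min > 0) {
    # convolve the bolus with a unit-mass boxcar of width infusion_min
    dt <- grid[2] - grid[1]
    nbox <- max(1L, round(infusion_min / dt))
    box <- rep(1 / (nbox * dt), nbox)
    main <- stats::convolve(bolus, rev(box),
                            type = "open")[seq_along(grid)] * dt
  } else main <- bolus
  tail <- tail_frac * amplitude *
    ifelse(grid > onset,
           (1 - exp(-(grid - onset) / max(peak_delay, 1e-6))) *
             exp(-tail_rate * (grid - onset)), 0)
  sampled_curve(grid, pmax(main + tail, 0),
                label = tracer_kind)
}
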