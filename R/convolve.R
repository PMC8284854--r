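# Convolution of residues / compartmental impulse responses with an AIF,
# evaluated as frame averages on an acquisition schedule.  All model-vs-data
# comparisons go through frame averages because PET frames record integrated
# counts over the frame interval.

#' Internal fine time grid for convolution quadrature
#' @param T_E end of scan, minutes.
#' @param dt grid step, minutes (default 0.1 s).
#' @keywords internal
conv_grid <- function(T_E, dt = 1 / 600) seq(0, T_E, by = dt)

# causal discrete convolution dt * sum_{m<=n} x[m] y[n-m+1] via FFT,
# zero-padded to a power of two (unpadded lengths can be prime and slow)
causal_conv <- function(x, y, dt) {
  n <- length(x)
  L <- stats::nextn(2 * n - 1, 2)
  X <- stats::fft(c(x, rep(0, L - n)))
  Y <- stats::fft(c(y, rep(0, L - n)))
  Re(stats::fft(X * Y, inverse = TRUE))[seq_len(n)] / L * dt
}

#' Convolve a residue function with an arterial input function
#'
#' Computes the model tissue curve R * C_p(t - delay) on a fine uniform
#' grid and averages it over the frames of the acquisition schedule.  A
#' spike residue reproduces the (shifted) AIF; a constant residue
#' reproduces the running integral of the AIF (the Patlak limit).
#'
#' @param R a `residue_fn`.
#' @param Cp the arterial input function, a `sampled_curve` sampled
#'   densely relative to the schedule.
#' @param delay arrival delay, minutes.
#' @param schedule a `frame_schedule`.
#' @param dt quadrature step, minutes (default 0.1 s).
#' @return A `sampled_curve` of frame-averaged model values at the frame
#'   midpoints (one value per frame).
#' @export
convolve_residue_aif <- function(R, Cp, delay = 0, schedule,
                                 dt = 1 / 600) {
  T_E <- schedule_end(schedule)
  if (delay >= T_E)
    stop("delay pushes the input function outside the scan window")
  tgrid <- conv_grid(T_E, dt)
  r <- residue_at(R, tgrid)
  cshift <- curve_at(Cp, tgrid - delay)
  conv <- causal_conv(r, cshift, dt)
  sampled_curve(frame_mid_min(schedule),
                frame_average(tgrid, conv, schedule),
                label = "model TAC", require_nonneg = FALSE)
}

#' Two-compartment model parameters
#'
#' The standard two-compartment tissue model with fractional blood volume
#' and delay: eta(t) = f_b C_p(t - delta) +
#' sum_m A_m int_0^t exp(-lambda_m (t-s)) C_p(s - delta) ds.
#' All parameters except the delay are constrained non-negative.
#'
#' @param delta arrival delay, minutes (unconstrained).
#' @param f_b fractional blood volume contribution (>= 0).
#' @param A_1,A_2 exponential amplitudes (>= 0).
#' @param lambda_1,lambda_2 exponential rates, 1/min (>= 0).
#' @export
two_compartment_params <- function(delta = 0, f_b = 0, A_1 = 0, A_2 = 0,
                                   lambda_1 = 0, lambda_2 = 0) {
  v <- c(f_b = f_b, A_1 = A_1, A_2 = A_2,
         lambda_1 = lambda_1, lambda_2 = lambda_2)
  if (any(v < 0))
    stop("all two-compartment parameters except the delay must be >= 0")
  out <- list(delta = delta, f_b = f_b, A_1 = A_1, A_2 = A_2,
              lambda_1 = lambda_1, lambda_2 = lambda_2)
  class(out) <- "two_compartment_params"
  out
}

#' Two-compartment model tissue curve on a frame schedule
#'
#' @param params a `two_compartment_params`.
#' @param Cp arterial input function (`sampled_curve`).
#' @param schedule a `frame_schedule`.
#' @param dt quadrature step, minutes.
#' @return A `sampled_curve` of frame-averaged model values.
#' @export
two_compartment_tac <- function(params, Cp, schedule, dt = 1 / 600) {
  stopifnot(inherits(params, "two_compartment_params"))
  T_E <- schedule_end(schedule)
  tgrid <- conv_grid(T_E, dt)
  cshift <- curve_at(Cp, tgrid - params$delta)
  out <- params$f_b * cshift
  for (m in 1:2) {
    A <- params[[paste0("A_", m)]]
    lam <- params[[paste0("lambda_", m)]]
    if (A > 0)
      out <- out + A * causal_conv(exp(-lam * tgrid), cshift, dt)
  }
  sampled_curve(frame_mid_min(schedule),
                frame_average(tgrid, out, schedule),
                label = "2C TAC", require_nonneg = FALSE)
}

#' Fit the two-compartment model to a tissue curve
#'
#' Weighted least squares with positivity constraints on
#' (f_b, A_1, A_2, lambda_1, lambda_2) and a grid search over the delay.
#' For fixed delay and rates the model is linear in (f_b, A_1, A_2), so
#' those are profiled out by non-negative least squares (variable
#' projection); the rates are optimised on the log scale by Nelder-Mead
#' from a small set of starting values.
#'
#' @param tac observed tissue curve: a `sampled_curve` with one value per
#'   frame, or a numeric vector of length `n_frames(schedule)`.
#' @param weights positive frame weights (e.g. 1/sigma^2); default equal.
#' @param Cp arterial input function.
#' @param schedule a `frame_schedule`.
#' @param delta_grid delay grid, minutes; default -10 s to +30 s in 2 s
#'   steps.
#' @param lambda_starts starting values for the two rates (1/min).
#' @param dt quadrature step, minutes.
#' @return A `two_compartment_params` with attributes `sse` (weighted
#'   residual sum of squares) and `fitted` (frame-averaged fit).
#' @export
fit_two_compartment <- function(tac, weights = NULL, Cp, schedule,
                                delta_grid = seq(-10, 30, by = 2) / 60,
                                lambda_starts = list(c(0.1, 2), c(0.01, 0.5)),
                                dt = 1 / 600) {
  z <- if (inherits(tac, "sampled_curve")) tac$value else as.numeric(tac)
  NT <- n_frames(schedule)
  if (length(z) != NT) stop("tac length must equal the number of frames")
  if (is.null(weights)) weights <- rep(1, NT)
  if (all(weights <= 0)) stop("weights must include positive entries")
  if (NT < 6) stop("fewer frames than parameters")
  sw <- sqrt(weights)
  T_E <- schedule_end(schedule)
  tgrid <- conv_grid(T_E, dt)

  design_fit <- function(delta, loglam) {
    lam <- exp(loglam)
    cshift <- curve_at(Cp, tgrid - delta)
    X <- cbind(frame_average(tgrid, cshift, schedule),
               frame_average(tgrid, causal_conv(exp(-lam[1] * tgrid),
                                                cshift, dt), schedule),
               frame_average(tgrid, causal_conv(exp(-lam[2] * tgrid),
                                                cshift, dt), schedule))
    fit <- wnnls(sw * X, sw * z)
    list(coef = fit$x, sse = fit$sse, fitted = drop(X %*% fit$x))
  }

  best <- NULL
  for (delta in delta_grid) {
    for (st in lambda_starts) {
      opt <- stats::optim(log(st),
                          function(ll) design_fit(delta, ll)$sse,
                          method = "Nelder-Mead",
                          control = list(maxit = 200, reltol = 1e-10))
      if (is.null(best) || opt$value < best$sse) {
        f <- design_fit(delta, opt$par)
        best <- list(delta = delta, lam = exp(opt$par), coef = f$coef,
                     sse = f$sse, fitted = f$fitted)
      }
    }
  }
  out <- two_compartment_params(delta = best$delta, f_b = best$coef[1],
                                A_1 = best$coef[2], A_2 = best$coef[3],
                                lambda_1 = best$lam[1],
                                lambda_2 = best$lam[2])
  attr(out, "sse") <- best$sse
  attr(out, "fitted") <- best$fitted
  out
}
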