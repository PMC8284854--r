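#' Piecewise-linear tissue residue functions
#'
#' The residue function R(t) gives the fraction-weighted amount of tracer
#' remaining in a tissue element t minutes after an idealised unit arterial
#' bolus.  Indicator-dilution theory requires it to be non-negative and
#' monotone non-increasing; here it is represented non-parametrically as a
#' piecewise-linear function on a knot grid over the scan interval
#' [0, T_E].  R(0) carries the flow scale (mL/mL/min).
#'
#' @param knot_times knot locations, minutes, starting at 0, increasing.
#' @param knot_values residue values at the knots; non-negative and
#'   non-increasing.
#' @param tol tolerance for the monotonicity/non-negativity checks.
#' @return An object of class `residue_fn`.
#' @export
residue_fn <- function(knot_times, knot_values, tol = 1e-9) {
  if (length(knot_times) != length(knot_values))
    stop("knot time/value lengths differ")
  if (knot_times[1] != 0) stop("knot grid must start at t = 0")
  if (any(diff(knot_times) <= 0)) stop("knot times must be increasing")
  if (any(knot_values < -tol)) stop("residue values must be non-negative")
  if (any(diff(knot_values) > tol)) stop("residue must be non-increasing")
  out <- list(knot_times = as.numeric(knot_times),
              knot_values = pmax(as.numeric(knot_values), 0))
  class(out) <- "residue_fn"
  out
}

#' Evaluate a residue function
#'
#' Linear interpolation between knots; constant extrapolation of the last
#' knot value beyond the grid and of the first value before t = 0.
#'
#' @param R a `residue_fn`.
#' @param t times, minutes.
#' @export
residue_at <- function(R, t) {
  if (length(R$knot_times) == 1L) return(rep(R$knot_values, length(t)))
  stats::approx(R$knot_times, R$knot_values, xout = t, rule = 2)$y
}

#' Exact integral of a piecewise-linear residue over [0, t]
#' @param R a `residue_fn`.
#' @param t upper limit, minutes.
#' @export
residue_integral <- function(R, t) {
  grid <- sort(unique(c(R$knot_times, t)))
  grid <- grid[grid <= max(c(R$knot_times, t))]
  v <- residue_at(R, grid)
  cumint <- c(0, cumsum(diff(grid) * (v[-1] + v[-length(v)]) / 2))
  stats::approx(grid, cumint, xout = t, rule = 2)$y
}

#' Linear combination of residue functions on a merged knot grid
#' @param Rs list of `residue_fn`.
#' @param coefs non-negative coefficients, one per residue.
#' @return A `residue_fn` on the union of the knot grids.
#' @export
residue_combine <- function(Rs, coefs) {
  stopifnot(length(Rs) == length(coefs), all(coefs >= 0))
  knots <- sort(unique(unlist(lapply(Rs, function(r) r$knot_times))))
  vals <- rowSums(mapply(function(r, a) a * residue_at(r, knots), Rs, coefs))
  residue_fn(knots, vals, tol = 1e-7)
}

#' @export
print.residue_fn <- function(x, ...) {
  cat(sprintf("Residue function: %d knots on [0, %.4g] min, R(0) = %.4g\n",
              length(x$knot_times), max(x$knot_times), x$knot_values[1]))
  invisible(x)
}

#' Decompose a residue into vascular, in-distribution and extracted parts
#'
#' Any residue measured over the scan interval [0, T_E] splits additively
#' as R = R_B + R_D + R_E, where the extracted part R_E(t) = R(T_E) is the
#' tracer still retained at the end of scanning, the large-vessel
#' (vascular) part R_B(t) = R(t) - R(T_B) for t in [0, T_B] and 0 after,
#' and the in-distribution part R_D absorbs the remainder.  T_B is an
#' upper bound on the large-vessel transit time of tracer atoms; 15 s is a
#' physiologically reasonable default for common PET tracers.
#'
#' @param R a `residue_fn`.
#' @param T_B large-vessel transit-time bound, minutes (default 0.25,
#'   i.e. 15 seconds).
#' @param T_E end of the scan interval, minutes; defaults to the last knot.
#' @return An object of class `residue_decomposition`: list with
#'   `R_B`, `R_D`, `R_E` (each a `residue_fn` on a common knot grid),
#'   `T_B` and `T_E`.
#' @export
residue_decompose <- function(R, T_B = 0.25, T_E = max(R$knot_times)) {
  if (!(T_B > 0 && T_B < T_E)) stop("T_B must lie in (0, T_E)")
  knots <- sort(unique(c(R$knot_times[R$knot_times <= T_E], T_B, T_E)))
  r <- residue_at(R, knots)
  rTB <- residue_at(R, T_B)
  rTE <- residue_at(R, T_E)
  vB <- ifelse(knots <= T_B, pmax(r - rTB, 0), 0)
  vE <- rep(rTE, length(knots))
  vD <- pmax(r - vB - vE, 0)
  out <- list(R_B = residue_fn(knots, vB, tol = 1e-7),
              R_D = residue_fn(knots, vD, tol = 1e-7),
              R_E = residue_fn(knots, vE, tol = 1e-7),
              T_B = T_B, T_E = T_E)
  class(out) <- "residue_decomposition"
  out
}

#' Kinetic summaries of a decomposed residue
#'
#' From the decomposition R = R_B + R_D + R_E over [0, T_E]:
#' large-vessel blood volume V_B = integral of R_B, in-distribution
#' volume V_D = integral of R_D, non-large-vessel flow K_D = R_D(0),
#' apparent flux (retention) K_i = R_E(0), overall flow K_1 = K_D + K_i,
#' extraction K_i/K_1, and mean transit time MTT = V_D/K_D + delay by the
#' central volume theorem.  All volumes and flows are linear in the
#' residue.
#'
#' @param dec a `residue_decomposition`.
#' @param delay arrival delay of tracer at the tissue, minutes (added to
#'   the transit-time ratio).
#' @return An object of class `kinetic_summaries`: list with fields `V_B`,
#'   `V_D`, `K_D`, `K_i`, `K_1`, `extraction`, `MTT`, `delay`, and flags
#'   `MTT_defined` (FALSE when K_D = 0) and `extraction_defined` (FALSE
#'   when K_1 = 0).
#' @export
residue_summaries <- function(dec, delay = 0) {
  stopifnot(inherits(dec, "residue_decomposition"))
  V_B <- residue_integral(dec$R_B, dec$T_B)
  V_D <- residue_integral(dec$R_D, dec$T_E)
  K_D <- dec$R_D$knot_values[1]
  K_i <- dec$R_E$knot_values[1]
  K_1 <- K_D + K_i
  ext_def <- K_1 > 0
  mtt_def <- K_D > 0
  out <- list(V_B = V_B, V_D = V_D, K_D = K_D, K_i = K_i, K_1 = K_1,
              extraction = if (ext_def) K_i / K_1 else NA_real_,
              MTT = if (mtt_def) V_D / K_D + delay else NA_real_,
              delay = delay,
              MTT_defined = mtt_def, extraction_defined = ext_def)
  class(out) <- "kinetic_summaries"
  out
}

#' @export
print.kinetic_summaries <- function(x, ...) {
  cat(sprintf(
    "V_B=%.4g V_D=%.4g K_D=%.4g K_i=%.4g K_1=%.4g extraction=%.4g MTT=%s\n",
    x$V_B, x$V_D, x$K_D, x$K_i, x$K_1,
    ifelse(x$extraction_defined, x$extraction, NA),
    if (x$MTT_defined) sprintf("%.4g", x$MTT) else "undefined"))
  invisible(x)
}

#' One-compartment (Kety-Schmidt) residue
#'
#' The single-compartment model has residue K_1 exp(-k_2 t): tracer enters
#' at flow K_1 (mL/mL/min) and washes out at rate k_2 (1/min).  Returned
#' as a piecewise-linear `residue_fn` on a grid dense enough that the
#' interpolation error is below 0.5% of K_1.
#'
#' @param K_1 delivery flow, mL/mL/min, non-negative.
#' @param k_2 clearance rate, 1/min, non-negative.
#' @param T_E end of support, minutes.
#' @param n_knots minimum number of knots (grid is refined automatically
#'   for fast clearance rates).
#' @export
kety_residue <- function(K_1, k_2, T_E, n_knots = 40) {
  if (K_1 < 0 || k_2 < 0) stop("K_1 and k_2 must be non-negative")
  if (k_2 == 0 || K_1 == 0)
    return(residue_fn(c(0, T_E), c(K_1, K_1)))
  # piecewise-linear interpolation error of exp(-k2 t) on a step h placed
  # at t is ~ exp(-k2 t) (k2 h)^2 / 8; keep every step under 0.5% of K_1
  knots <- 0
  while (knots[length(knots)] < T_E) {
    t <- knots[length(knots)]
    h <- sqrt(8 * 0.005 * exp(k_2 * t)) / k_2
    knots <- c(knots, min(t + h, T_E))
  }
  if (length(knots) < n_knots)
    knots <- sort(unique(c(knots, residue_knots(T_E, n_knots))))
  residue_fn(knots, K_1 * exp(-k_2 * knots))
}

#' Default knot grid for fitted residues
#'
#' Geometric spacing, dense at early times where residues change fastest
#' and sparse late, spanning [0, T_E].
#'
#' @param T_E end of scan, minutes.
#' @param n number of knots.
#' @param rate geometric growth factor controlling early density.
#' @export
residue_knots <- function(T_E, n = 12, rate = 3) {
  u <- seq(0, 1, length.out = n)
  k <- T_E * (exp(rate * u) - 1) / (exp(rate) - 1)
  k[1] <- 0
  k[n] <- T_E
  k
}
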