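# Combined versus separate estimation for multiple-injection studies:
# voxel fitting over the full time course versus per-injection windows,
# the weighted squared-error assessment of estimated sources, MSE
# summaries, the theoretical variance-pooling ratio, and the
# meta-analysis regressions of scaled MSE.

#' Combined and separate voxel coefficient estimates
#'
#' The combined estimate fits each voxel's full time course against the
#' basis; the separate estimate for injection j uses only the frames in
#' that injection's window (with the basis rows restricted accordingly).
#' Both fits are non-negative least squares.
#'
#' @param Z reconstructed dynamic image, voxels x N_T.
#' @param basis a `subtac_basis` or N_T x K matrix.
#' @param windows list of `c(start, end)` injection windows, minutes.
#' @param schedule the acquisition `frame_schedule`.
#' @param weights optional frame weights.
#' @return list with `alpha_C` (voxels x K) and `alpha_S` (list per
#'   injection of voxels x K matrices).
#' @export
fit_combined_and_separate <- function(Z, basis, windows, schedule,
                                      weights = NULL) {
  X <- if (inherits(basis, "subtac_basis")) basis$X else as.matrix(basis)
  Z <- as.matrix(Z)
  nv <- nrow(Z)
  K <- ncol(X)
  if (is.null(weights)) weights <- rep(1, nrow(X))
  sw <- sqrt(weights)
  alpha_C <- t(vapply(seq_len(nv), function(i)
    pracma::lsqnonneg(sw * X, sw * Z[i, ])$x, numeric(K)))
  alpha_S <- lapply(windows, function(w) {
    idx <- frames_in_window(schedule, w)
    if (length(idx) == 0) stop("empty injection window")
    Xw <- X[idx, , drop = FALSE]
    sww <- sw[idx]
    keep <- colSums(abs(Xw)) > 0
    out <- matrix(0, nv, K)
    out[, keep] <- t(vapply(seq_len(nv), function(i)
      pracma::lsqnonneg(sww * Xw[, keep, drop = FALSE],
                        sww * Z[i, idx])$x,
      numeric(sum(keep))))
    out
  })
  list(alpha_C = alpha_C, alpha_S = alpha_S)
}

#' Weighted squared-error assessment of an estimated source
#'
#' Per-injection time-integrated squared error between the estimated and
#' true source, weighted by 1/(D_j lambda_bar_j^2) where D_j is the
#' window duration and lambda_bar_j the maximum true intensity within the
#' window, averaged over voxels (so values are comparable across grid
#' sizes).  Time integrals use frame-duration weighting.
#'
#' @param lambda_hat estimated source, voxels x N_T.
#' @param lambda true source, voxels x N_T.
#' @param schedule the acquisition `frame_schedule`.
#' @param windows list of injection windows, minutes.
#' @param intensity how the window maximum intensity is measured:
#'   `"max"` (default) or `"p99"` (99th percentile).
#' @return scalar squared-error assessment `Se`.
#' @export
assess_error <- function(lambda_hat, lambda, schedule, windows,
                         intensity = c("max", "p99")) {
  intensity <- match.arg(intensity)
  lambda_hat <- as.matrix(lambda_hat)
  lambda <- as.matrix(lambda)
  if (!all(dim(lambda_hat) == dim(lambda))) stop("grid mismatch")
  durations <- schedule$duration_s / 60
  se <- 0
  for (w in windows) {
    idx <- frames_in_window(schedule, w)
    lam_w <- lambda[, idx, drop = FALSE]
    lbar <- if (intensity == "max") max(lam_w)
            else stats::quantile(lam_w, 0.99, names = FALSE)
    if (lbar <= 0) stop("window has zero maximum intensity")
    D_j <- sum(durations[idx])
    err2 <- (lambda_hat[, idx, drop = FALSE] - lam_w)^2
    tint <- err2 %*% durations[idx]          # per-voxel time integral
    se <- se + mean(tint) / (D_j * lbar^2)
  }
  se
}

#' Replicate MSE summary and percent improvement
#'
#' @param se_C per-replicate squared-error values for the combined fit.
#' @param se_S per-replicate values for the separate fit (same length,
#'   paired by replicate).
#' @return An object of class `mse_summary`: `MSE_C`, `MSE_S`, their
#'   Monte-Carlo standard errors, `improvement` (percent,
#'   (MSE_S/MSE_C - 1) x 100) and its delta-method standard error.
#' @export
summarize_mse <- function(se_C, se_S) {
  n <- length(se_C)
  if (n < 2 || length(se_S) != n)
    stop("need >= 2 paired replicates")
  m_C <- mean(se_C); m_S <- mean(se_S)
  v_C <- stats::var(se_C) / n
  v_S <- stats::var(se_S) / n
  cv <- stats::cov(se_C, se_S) / n
  ratio <- m_S / m_C
  var_ratio <- ratio^2 * (v_S / m_S^2 + v_C / m_C^2 - 2 * cv / (m_S * m_C))
  out <- list(MSE_C = m_C, MSE_S = m_S,
              se_MSE_C = sqrt(v_C), se_MSE_S = sqrt(v_S),
              improvement = (ratio - 1) * 100,
              se_improvement = 100 * sqrt(max(var_ratio, 0)),
              n = n)
  class(out) <- "mse_summary"
  out
}

#' @export
print.mse_summary <- function(x, ...) {
  cat(sprintf(
    "MSE_C = %.4g (SE %.2g), MSE_S = %.4g (SE %.2g), improvement = %.2f%% (SE %.2g)\n",
    x$MSE_C, x$se_MSE_C, x$MSE_S, x$se_MSE_S,
    x$improvement, x$se_improvement))
  invisible(x)
}

#' Theoretical MSE ratio of combined to separate estimation
#'
#' Under Gaussian approximation, pooling J injections gives a combined
#' estimator whose MSE relative to the separate estimator from injection
#' j alone is sigma_j^-2 / (sigma_1^-2 + ... + sigma_J^-2): never above
#' 1, and exactly 1/J when all injections are equally informative.
#'
#' @param sigmas per-injection kinetic-parameter standard deviations
#'   (positive).
#' @param j index of the target injection.
#' @export
theory_mse_ratio <- function(sigmas, j = 1) {
  if (any(sigmas <= 0)) stop("sigmas must be positive")
  if (j < 1 || j > length(sigmas)) stop("invalid injection index")
  sigmas[j]^-2 / sum(sigmas^-2)
}

#' Percent-improvement implied by a log-scale method coefficient
#'
#' The meta-regressions model log MSE, so a method-indicator coefficient
#' c converts to a percent improvement 100 (e^c - 1).
#'
#' @param coef coefficient on the log scale.
#' @export
coef_to_improvement <- function(coef) 100 * (exp(coef) - 1)

#' Meta-regression of scaled MSE on design covariates
#'
#' Ordinary least squares for log(MSE/sigma_z2) on the method indicator
#' plus the dose ratio (`design = "h2o_fdg"`), or on the method
#' indicator, number of injections and their interaction
#' (`design = "repeat"`).  The method indicator is 1 for separate
#' analysis, so a positive coefficient measures the combined-analysis
#' improvement on the log scale.
#'
#' @param tab data frame with columns `mse`, `sigma2_z`, `method`
#'   ("combined"/"separate"), and `DR` (dose ratio) or `J` (number of
#'   injections); a `dose` column, when present, can be included as a
#'   check covariate via `with_dose`.
#' @param design `"h2o_fdg"` or `"repeat"`.
#' @param with_dose add log(dose) as a covariate.
#' @return An object of class `meta_regression`: the `lm` fit plus
#'   `coefficients` (with standard errors) and `implied_improvement`
#'   (percent, from the method coefficient).
#' @export
fit_scaled_mse <- function(tab, design = c("h2o_fdg", "repeat"),
                           with_dose = FALSE) {
  design <- match.arg(design)
  tab$I <- as.numeric(tab$method == "separate")
  tab$y <- log(tab$mse / tab$sigma2_z)
  fm <- if (design == "h2o_fdg") y ~ I + DR else y ~ I * J
  if (with_dose) fm <- stats::update(fm, . ~ . + log(dose))
  fit <- stats::lm(fm, data = tab)
  qrr <- qr(stats::model.matrix(fit))
  if (qrr$rank < ncol(stats::model.matrix(fit)))
    stop("rank-deficient design")
  sm <- summary(fit)
  out <- list(fit = fit, coefficients = sm$coefficients,
              implied_improvement =
                coef_to_improvement(stats::coef(fit)[["I"]]),
              design = design)
  class(out) <- "meta_regression"
  out
}

#' Dose-decay model for total-uptake reconstruction error
#'
#' OLS of log(sigma_z2) on log dose and the secondary design factor M
#' (dose ratio or number of injections); the dose coefficient is
#' reported as the positive decay exponent gamma_tau (MSE ~ tau^-gamma).
#'
#' @param tab data frame with columns `sigma2_z`, `tau` and optionally
#'   `M`.
#' @return An object of class `meta_regression` with `gamma_tau` and its
#'   standard error.
#' @export
fit_dose_model <- function(tab, ...) {
  if (length(unique(tab$tau)) < 2) stop("need at least two dose levels")
  fm <- if (!is.null(tab$M) && length(unique(tab$M)) > 1)
    log(sigma2_z) ~ log(tau) + M else log(sigma2_z) ~ log(tau)
  fit <- stats::lm(fm, data = tab)
  sm <- summary(fit)
  out <- list(fit = fit, coefficients = sm$coefficients,
              gamma_tau = -stats::coef(fit)[["log(tau)"]],
              se_gamma_tau = sm$coefficients["log(tau)", "Std. Error"],
              design = "dose")
  class(out) <- "meta_regression"
  out
}

#' @export
print.meta_regression <- function(x, ...) {
  if (!is.null(x$gamma_tau))
    cat(sprintf("Dose model: gamma_tau = %.3f (SE %.3f)\n",
                x$gamma_tau, x$se_gamma_tau))
  else
    cat(sprintf("Scaled-MSE model (%s): implied improvement %.2f%%\n",
                x$design, x$implied_improvement))
  stats::printCoefmat(x$coefficients)
  invisible(x)
}

#' Dose increase equivalent to an MSE improvement
#'
#' With reconstruction MSE decaying as tau^-gamma, matching a fractional
#' MSE improvement by dose alone requires a percent dose increase of
#' 100 ((1 + improvement)^(1/gamma) - 1).
#'
#' @param improvement fractional MSE improvement (e.g. 0.10 for 10%).
#' @param gamma_tau positive dose-decay exponent.
#' @return percent dose increase.
#' @export
dose_equivalence <- function(improvement, gamma_tau) {
  if (gamma_tau <= 0) stop("gamma_tau must be positive")
  if (improvement <= -1) stop("improvement must exceed -100%")
  100 * ((1 + improvement)^(1 / gamma_tau) - 1)
}

#' Relative RMSE between two mapping methods, and local-error slopes
#'
#' `relative_rmse` averages the per-cell RMSE ratio of a comparison
#' method to a reference method for each kinetic parameter.
#' `local_error_slopes` regresses log relative kinetic RMSE on the log
#' relative local error (reconstruction or model error), per parameter.
#'
#' @param tab data frame with columns `param`, `rmse_num` (comparison
#'   method), `rmse_den` (reference method), one row per
#'   voxel/dose cell.
#' @return data frame with `param`, `e_hat` (mean ratio), `se`.
#' @export
relative_rmse <- function(tab) {
  if (any(tab$rmse_den <= 0)) stop("zero denominator RMSE")
  sp <- split(tab, tab$param)
  out <- do.call(rbind, lapply(names(sp), function(p) {
    r <- sp[[p]]$rmse_num / sp[[p]]$rmse_den
    data.frame(param = p, e_hat = mean(r),
               se = stats::sd(r) / sqrt(length(r)))
  }))
  rownames(out) <- NULL
  out
}

#' @rdname relative_rmse
#' @param rmse kinetic-parameter RMSE per cell (positive).
#' @param theta true parameter magnitude per cell (positive scale).
#' @param sigma local error per cell (reconstruction error sigma_i or
#'   model error sigma_i^lambda).
#' @param param parameter label per cell.
#' @return for `local_error_slopes`: data frame with `param`, `slope`,
#'   `intercept`, `r_squared`.
#' @export
local_error_slopes <- function(rmse, sigma, theta, param) {
  d <- data.frame(rmse = rmse, sigma = sigma, theta = theta,
                  param = param)
  d <- d[d$rmse > 0 & d$sigma > 0 & d$theta > 0, ]
  sp <- split(d, d$param)
  out <- do.call(rbind, lapply(names(sp), function(p) {
    x <- log(sp[[p]]$sigma / sp[[p]]$theta)
    y <- log(sp[[p]]$rmse / sp[[p]]$theta)
    f <- stats::lm(y ~ x)
    data.frame(param = p, slope = stats::coef(f)[[2]],
               intercept = stats::coef(f)[[1]],
               r_squared = summary(f)$r.squared)
  }))
  rownames(out) <- NULL
  out
}
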