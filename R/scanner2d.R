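# 2-D attenuated parallel-beam Radon scanning model with filtered
# backprojection.  The image lives on a 128 x 128 grid over the unit
# square (pixel centres, coordinates centred at the origin); the sinogram
# is 183 distances over [-2, 2] by 181 angles over [0, pi).

#' Configuration of the 2-D scanning model
#'
#' @param n_pix image grid size (n_pix x n_pix over the unit square).
#' @param n_s number of radial (distance) samples.
#' @param n_theta number of angles over [0, pi).
#' @param s_range radial range (default [-2, 2]).
#' @param attenuation_map positive attenuation coefficient map
#'   (n_pix x n_pix); default a uniform mild attenuator whose ray factors
#'   fall in about [0.7, 1].
#' @param tau expected total counts (dose).
#' @param h Gaussian post-smoothing bandwidth in pixels (0 = none).
#' @param hann apply a Hann window to the ramp filter (off by default:
#'   the Gaussian post-smoother is the noise-control mechanism, and an
#'   unwindowed ramp keeps the noiseless round trip sharp).
#' @return An object of class `scanner_2d_config`, with the attenuation
#'   sinogram (ray exponentials) precomputed.
#' @export
scanner_2d_config <- function(n_pix = 128, n_s = 183, n_theta = 181,
                              s_range = c(-2, 2), attenuation_map = NULL,
                              tau = 1e7, h = 0, hann = FALSE) {
  if (tau <= 0) stop("tau must be positive")
  if (is.null(attenuation_map))
    attenuation_map <- matrix(0.3, n_pix, n_pix)
  if (!all(dim(attenuation_map) == c(n_pix, n_pix)) ||
      any(attenuation_map <= 0))
    stop("attenuation map must be positive with matching dimensions")
  out <- list(n_pix = n_pix, n_s = n_s, n_theta = n_theta,
              s_grid = seq(s_range[1], s_range[2], length.out = n_s),
              theta_grid = seq(0, pi, length.out = n_theta + 1)[1:n_theta],
              tau = tau, h = h, hann = hann,
              attenuation_map = attenuation_map)
  class(out) <- "scanner_2d_config"
  out$attenuation_sino <- exp(-radon_2d(attenuation_map, out))
  out
}

# bilinear interpolation of a matrix image at continuous coordinates
# (x, y) in the centred unit square; zero outside the support
bilinear_at <- function(img, x, y) {
  n <- nrow(img)
  fx <- (x + 0.5) * n + 0.5   # fractional row index (pixel centres)
  fy <- (y + 0.5) * n + 0.5
  i0 <- floor(fx); j0 <- floor(fy)
  wx <- fx - i0; wy <- fy - j0
  val <- numeric(length(x))
  pick <- function(i, j) {
    ok <- i >= 1 & i <= n & j >= 1 & j <= n
    v <- numeric(length(i))
    v[ok] <- img[cbind(i[ok], j[ok])]
    v
  }
  (1 - wx) * (1 - wy) * pick(i0, j0) +
    wx * (1 - wy) * pick(i0 + 1, j0) +
    (1 - wx) * wy * pick(i0, j0 + 1) +
    wx * wy * pick(i0 + 1, j0 + 1)
}

#' Discrete parallel-beam Radon transform
#'
#' Line integrals of the image along rays indexed by (distance s, angle
#' theta), by sampling each ray at pixel resolution with bilinear
#' interpolation.
#'
#' @param img image matrix (n_pix x n_pix).
#' @param cfg a `scanner_2d_config` (or list with the grid fields).
#' @return sinogram matrix, n_s x n_theta.
#' @export
radon_2d <- function(img, cfg) {
  n <- cfg$n_pix
  if (!all(dim(img) == c(n, n))) stop("image has wrong dimensions")
  dt <- 0.5 / n   # half-pixel ray sampling
  tgrid <- seq(-0.75, 0.75, by = dt)
  sino <- matrix(0, cfg$n_s, cfg$n_theta)
  grid <- expand.grid(s = cfg$s_grid, t = tgrid)
  for (k in seq_along(cfg$theta_grid)) {
    th <- cfg$theta_grid[k]
    x <- grid$s * cos(th) - grid$t * sin(th)
    y <- grid$s * sin(th) + grid$t * cos(th)
    v <- bilinear_at(img, x, y)
    sino[, k] <- rowSums(matrix(v, cfg$n_s, length(tgrid))) * dt
  }
  sino
}

#' Expected-count projection of a source frame (attenuated Radon)
#'
#' @param frame_image non-negative source image (n_pix x n_pix).
#' @param cfg a `scanner_2d_config`.
#' @param scale count scale for this frame (study scale x duration).
#' @return expected-count sinogram, n_s x n_theta.
#' @export
project_2d <- function(frame_image, cfg, scale = 1) {
  if (!all(dim(frame_image) == c(cfg$n_pix, cfg$n_pix)))
    stop("image has wrong dimensions")
  if (any(frame_image < 0)) stop("negative source values")
  scale * cfg$attenuation_sino * radon_2d(frame_image, cfg)
}

#' Study-level count scale for the 2-D scanner
#'
#' @param lambda_frames list (or 3-d array, third index = frame) of source
#'   images.
#' @param durations_min frame durations, minutes.
#' @param cfg a `scanner_2d_config`.
#' @export
study_scale_2d <- function(lambda_frames, durations_min, cfg) {
  if (is.array(lambda_frames) && length(dim(lambda_frames)) == 3)
    lambda_frames <- lapply(seq_len(dim(lambda_frames)[3]),
                            function(l) lambda_frames[, , l])
  tot <- 0
  for (l in seq_along(lambda_frames))
    tot <- tot + durations_min[l] *
      sum(cfg$attenuation_sino * radon_2d(lambda_frames[[l]], cfg))
  cfg$tau / tot
}

#' Separable Gaussian smoothing of an image
#'
#' @param img image matrix.
#' @param h Gaussian bandwidth in pixels; 0 returns the image unchanged.
#' @export
gauss_smooth_2d <- function(img, h) {
  if (h <= 0) return(img)
  r <- ceiling(4 * h)
  g <- exp(-0.5 * ((-r):r / h)^2)
  g <- g / sum(g)
  pad_conv <- function(M) {
    n <- nrow(M)
    out <- matrix(0, n, ncol(M))
    Mp <- rbind(matrix(0, r, ncol(M)), M, matrix(0, r, ncol(M)))
    for (i in seq_len(n))
      out[i, ] <- crossprod(g, Mp[i:(i + 2 * r), , drop = FALSE])
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

#' Filtered backprojection reconstruction of a 2-D sinogram
#'
#' Attenuation-corrects the counts, ramp-filters each angular profile in
#' the radial frequency domain (optionally Hann-apodised) and
#' backprojects with linear interpolation; an optional Gaussian
#' post-smoother is applied in image space.  The operator is linear in
#' the sinogram.
#'
#' @param sino count (or expected-count) sinogram, n_s x n_theta.
#' @param cfg a `scanner_2d_config`.
#' @param scale the count scale used in projection.
#' @param h post-smoothing bandwidth (pixels); default `cfg$h`.
#' @return reconstructed image, n_pix x n_pix.
#' @export
recon_fbp_2d <- function(sino, cfg, scale = 1, h = cfg$h) {
  if (!all(dim(sino) == c(cfg$n_s, cfg$n_theta)))
    stop("sinogram has wrong dimensions")
  q <- sino / (scale * cfg$attenuation_sino)
  ds <- cfg$s_grid[2] - cfg$s_grid[1]
  n_pad <- 2^ceiling(log2(2 * cfg$n_s))
  freq_idx <- c(0:(n_pad / 2), (n_pad / 2 - 1):1)
  omega <- freq_idx / (n_pad * ds)            # cycles per unit length
  filt <- omega
  if (cfg$hann) {
    w <- rep(0, n_pad)
    nz <- freq_idx <= n_pad / 2
    w[nz] <- 0.5 * (1 + cos(pi * freq_idx[nz] / (n_pad / 2)))
    filt <- filt * w
  }
  qf <- matrix(0, cfg$n_s, cfg$n_theta)
  for (k in seq_len(cfg$n_theta)) {
    qp <- c(q[, k], rep(0, n_pad - cfg$n_s))
    f <- Re(stats::fft(stats::fft(qp) * filt, inverse = TRUE)) / n_pad
    qf[, k] <- f[seq_len(cfg$n_s)]
  }
  n <- cfg$n_pix
  xs <- ((seq_len(n) - 0.5) / n) - 0.5
  px <- matrix(xs, n, n)
  py <- matrix(xs, n, n, byrow = TRUE)
  img <- matrix(0, n, n)
  dtheta <- pi / cfg$n_theta
  for (k in seq_along(cfg$theta_grid)) {
    th <- cfg$theta_grid[k]
    s <- px * cos(th) + py * sin(th)
    v <- stats::approx(cfg$s_grid, qf[, k], xout = as.numeric(s),
                       yleft = 0, yright = 0)$y
    img <- img + matrix(v, n, n)
  }
  img <- img * dtheta
  gauss_smooth_2d(img, h)
}

#' Simulate one frame (or study) of 2-D scanning
#'
#' @param lambda_frames list of source images (or a single image).
#' @param durations_min frame durations, minutes.
#' @param cfg a `scanner_2d_config`.
#' @param recon reconstruct each frame by FBP (`TRUE`) or return counts
#'   only.
#' @param h smoothing bandwidth; default `cfg$h`.
#' @return list with `counts`, `expected` (lists of sinograms), `recon`
#'   (list of images or NULL) and `scale`.
#' @export
simulate_study_2d <- function(lambda_frames, durations_min, cfg,
                              recon = TRUE, h = cfg$h) {
  if (is.matrix(lambda_frames)) lambda_frames <- list(lambda_frames)
  sc <- study_scale_2d(lambda_frames, durations_min, cfg)
  expected <- lapply(seq_along(lambda_frames), function(l)
    project_2d(lambda_frames[[l]], cfg, scale = sc * durations_min[l]))
  counts <- lapply(expected, sample_counts)
  Z <- NULL
  if (recon)
    Z <- lapply(seq_along(counts), function(l)
      recon_fbp_2d(counts[[l]], cfg, scale = sc * durations_min[l], h = h))
  list(counts = counts, expected = expected, recon = Z, scale = sc)
}
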