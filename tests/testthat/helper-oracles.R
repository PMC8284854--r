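# Independent oracles used across the suite.

# Exhaustive-support non-negative least squares: solve the unconstrained
# problem on every subset of columns, keep solutions that are feasible
# (coefficients >= 0) and pick the one with smallest residual sum of
# squares.  Exact for small K; independent of the Lawson-Hanson path.
nnls_enum <- function(X, z) {
  K <- ncol(X)
  best <- list(sse = sum(z^2), x = rep(0, K))
  for (mask in seq_len(2^K - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(K) - 1)) > 0)
    XS <- X[, S, drop = FALSE]
    b <- tryCatch(qr.solve(crossprod(XS), crossprod(XS, z)),
                  error = function(e) NULL)
    if (is.null(b) || any(b < 0)) next
    r <- z - XS %*% b
    sse <- sum(r^2)
    if (sse < best$sse - 1e-12) {
      x <- rep(0, K)
      x[S] <- b
      best <- list(sse = sse, x = x)
    }
  }
  best
}

# Direct Riemann causal convolution on a uniform grid (quadratic cost).
brute_conv <- function(r, cvals, dt) {
  n <- length(r)
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- sum(r[seq_len(i)] * cvals[i:1]) * dt
  out
}

# Direct circular convolution by the spatial kernel matrix.
brute_project_1d <- function(src, cfg, scale = 1) {
  N <- cfg$N
  kap <- kernel_fourier_1d(cfg)
  ksp <- Re(stats::fft(kap, inverse = TRUE)) / N
  out <- numeric(N)
  for (n in seq_len(N))
    out[n] <- sum(ksp[((n - seq_len(N)) %% N) + 1] * src)
  scale * cfg$attenuation * out
}

# Ray-sum Radon oracle at matched discretisation for a single pixel.
pixel_center <- function(i, n) (i - 0.5) / n - 0.5
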