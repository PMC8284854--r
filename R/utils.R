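# shared internal helpers

# non-negative least squares returning the coefficient vector and the
# residual sum of squares; thin wrapper around the Lawson-Hanson solver.
# Exactly collinear columns (e.g. duplicated candidate sub-TACs) can make
# the active-set normal equations singular; retry with a tiny ridge.
wnnls <- function(X, z) {
  z <- as.numeric(z)
  fit <- tryCatch(pracma::lsqnonneg(X, z), error = function(e) NULL)
  if (is.null(fit)) {
    eps <- 1e-8 * max(abs(X))
    Xa <- rbind(X, diag(eps, ncol(X)))
    fit <- pracma::lsqnonneg(Xa, c(z, rep(0, ncol(X))))
  }
  r <- z - drop(X %*% fit$x)
  list(x = fit$x, sse = sum(r^2))
}
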