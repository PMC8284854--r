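test_that("projection matches the spatial-domain circular convolution oracle", {
  cfg <- scanner_1d_config(tau = 1e5)
  src <- smooth_source_1d()
  expect_lt(max(abs(project_1d(src, cfg, scale = 37) -
                      brute_project_1d(src, cfg, scale = 37))), 1e-9)

  # near-zero exponent: the kernel is the identity
  cfg_id <- scanner_1d_config(beta = 1e-9, attenuation = rep(1, 128))
  expect_equal(project_1d(src, cfg_id, 1), src, tolerance = 1e-6)

  # constant source: DC preserved (kappa_0 = 1)
  cfg1 <- scanner_1d_config(attenuation = rep(1, 128))
  expect_equal(project_1d(rep(2, 128), cfg1, scale = 3), rep(6, 128),
               tolerance = 1e-12)

  expect_error(project_1d(-src, cfg), "negative")
  expect_error(project_1d(src[1:10], cfg), "length")
})

test_that("count sampling is Poisson with the requested mean", {
  expect_equal(sample_counts(rep(0, 50)), rep(0L, 50))
  set.seed(41)
  y <- sample_counts(rep(5, 1e4))
  se <- sqrt(5 / 1e4)
  expect_lt(abs(mean(y) - 5), 3 * se)
  expect_lt(abs(stats::var(y) - 5), 3 * sqrt(2 * 25 / 1e4 + 5 / 1e4))
  expect_error(sample_counts(c(-2, 1)), "negative")
})

test_that("study scaling delivers the requested expected total counts", {
  cfg <- scanner_1d_config(tau = 2e5)
  lam <- cbind(smooth_source_1d(), 2 * smooth_source_1d(),
               0.5 * smooth_source_1d())
  dur <- c(0.5, 1, 2)
  set.seed(42)
  sim <- simulate_study_1d(lam, dur, cfg, recon = "none")
  expect_equal(sum(sim$expected), 2e5, tolerance = 1e-10)
  expect_lt(abs(sum(sim$counts) - 2e5) / 2e5, 5 / sqrt(2e5))
})

test_that("direct reconstruction inverts the projection exactly on noiseless data", {
  cfg <- scanner_1d_config(tau = 1e5)
  src <- smooth_source_1d()
  expected <- project_1d(src, cfg, scale = 37)
  z <- recon_fbp_1d(expected, cfg, scale = 37, h = 0)
  expect_lt(max(abs(z - src)) / max(src), 1e-10)

  # h = 0 leaves the raw reconstruction untouched
  set.seed(43)
  y <- sample_counts(expected)
  expect_equal(as.numeric(recon_fbp_1d(y, cfg, scale = 37, h = 0)),
               as.numeric(recon_fbp_1d(y, cfg, scale = 37)))
})

test_that("reconstruction MSE decreases with dose", {
  cfg <- scanner_1d_config()
  src <- smooth_source_1d()
  mse_at <- function(scale, nrep) {
    expected <- project_1d(src, cfg, scale = scale)
    mean(vapply(seq_len(nrep), function(r)
      mean((as.numeric(recon_fbp_1d(sample_counts(expected), cfg,
                                    scale = scale, h = 0)) - src)^2),
      numeric(1)))
  }
  set.seed(44)
  expect_lt(mse_at(400, 100), mse_at(100, 100))
})

test_that("ML reconstruction solves exact data, stays non-negative, and descends", {
  # small grid keeps the IRLS iterations cheap
  cfg <- scanner_1d_config(N = 32, tau = 1e4)
  x <- seq_len(32)
  src <- 0.3 + exp(-((x - 12) / 4)^2) + 0.6 * exp(-((x - 24) / 5)^2)
  expected <- project_1d(src, cfg, scale = 50)

  # zero counts give the zero image
  z0 <- recon_ml_1d(rep(0, 32), cfg, scale = 50, h = 0)
  expect_equal(max(abs(z0)), 0)

  # fixed point on exact expected data from a flat start
  zml <- recon_ml_1d(expected, cfg, scale = 50, h = 0, init = "flat")
  expect_lt(max(abs(zml - src)) / max(src), 0.01)

  # non-negativity and monotone deviance across random realizations
  set.seed(45)
  for (i in 1:25) {
    y <- sample_counts(expected)
    z <- recon_ml_1d(y, cfg, scale = 50, h = 0)
    expect_true(all(z >= 0))
    expect_true(all(diff(attr(z, "deviance")) <= 1e-9))
  }
})

test_that("ML forward projections match observed total counts at convergence", {
  cfg <- scanner_1d_config(N = 32, tau = 1e4)
  x <- seq_len(32)
  src <- 0.3 + exp(-((x - 12) / 4)^2)
  expected <- project_1d(src, cfg, scale = 80)
  set.seed(46)
  y <- sample_counts(expected)
  z <- recon_ml_1d(y, cfg, scale = 80, h = 0)
  m <- brute_project_1d(as.numeric(z), cfg, scale = 80)
  expect_lt(abs(sum(m) - sum(y)) / sum(y), 1e-3)
})

test_that("bandwidth selection minimises estimated uptake MSE", {
  cfg <- scanner_1d_config()
  src <- smooth_source_1d()
  h_grid <- seq(0, 4, by = 0.5)

  # zero noise: no smoothing wins
  expected <- project_1d(src, cfg, scale = 200)
  clean <- as.numeric(recon_fbp_1d(expected, cfg, scale = 200, h = 0))
  expect_equal(as.numeric(select_bandwidth(clean, src, h_grid)), 0)

  # flat truth: smoothing is bias-free, the largest bandwidth wins
  flat <- rep(1, 128)
  exp_flat <- project_1d(flat, cfg, scale = 50)
  set.seed(47)
  raw <- vapply(1:20, function(r)
    as.numeric(recon_fbp_1d(sample_counts(exp_flat), cfg, scale = 50,
                            h = 0)), numeric(128))
  expect_equal(as.numeric(select_bandwidth(raw, flat, h_grid)),
               max(h_grid))

  # the selected point attains the minimum of its own MSE curve
  set.seed(48)
  raw2 <- vapply(1:10, function(r)
    as.numeric(recon_fbp_1d(sample_counts(expected), cfg, scale = 200,
                            h = 0)), numeric(128))
  h <- select_bandwidth(raw2, src, h_grid)
  expect_equal(min(attr(h, "mse")),
               attr(h, "mse")[match(as.numeric(h), h_grid)])
  expect_error(select_bandwidth(raw2, src, numeric(0)), "empty")
})

test_that("unbiased-risk bandwidth selection tracks the truth-based choice", {
  cfg <- scanner_1d_config()
  src <- smooth_source_1d()
  expected <- project_1d(src, cfg, scale = 60)
  h_grid <- seq(0, 4, by = 0.5)
  set.seed(49)
  diffs <- replicate(10, {
    y <- sample_counts(expected)
    h_s <- select_bandwidth_sure(y, cfg, scale = 60, h_grid)
    raw <- as.numeric(recon_fbp_1d(y, cfg, scale = 60, h = 0))
    h_t <- select_bandwidth(raw, src, h_grid)
    abs(as.numeric(h_s) - as.numeric(h_t))
  })
  expect_lte(mean(diffs), 1)
})
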