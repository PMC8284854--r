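cfg2_plain <- scanner_2d_config(tau = 1e6,
                                attenuation_map = matrix(1e-9, 128, 128))

test_that("projection of a centred disk is rotationally symmetric", {
  n <- 128
  xs <- (seq_len(n) - 0.5) / n - 0.5
  disk <- outer(xs, xs, function(x, y) as.numeric(x^2 + y^2 < 0.3^2))
  sino <- radon_2d(disk, cfg2_plain)
  ref <- rowMeans(sino)
  # edge bins carry the pixelisation error; RMS over the sinogram stays
  # inside the discretization tolerance
  expect_lt(sqrt(mean((sino - ref)^2)) / max(ref), 0.005)
})

test_that("zero images project to zero sinograms", {
  expect_equal(max(abs(project_2d(matrix(0, 128, 128), cfg2_plain, 1))), 0)
  expect_error(project_2d(matrix(-1, 128, 128), cfg2_plain), "negative")
  expect_error(project_2d(matrix(0, 64, 64), cfg2_plain), "dimensions")
})

test_that("a single bright pixel traces a sinusoid and matches the ray-sum oracle", {
  n <- 128
  img <- matrix(0, n, n)
  img[40, 88] <- 1
  sino <- radon_2d(img, cfg2_plain)
  px <- pixel_center(40, n)
  py <- pixel_center(88, n)
  ds <- cfg2_plain$s_grid[2] - cfg2_plain$s_grid[1]

  # independent ray-sum oracle: fine Riemann integration of the bilinear
  # tent of the pixel along each ray, at the same (s, theta) grid
  tent_line <- function(s, th, dt = 1e-4) {
    t <- seq(-0.75, 0.75, by = dt)
    x <- s * cos(th) - t * sin(th)
    y <- s * sin(th) + t * cos(th)
    v <- pmax(0, 1 - abs(x - px) * n) * pmax(0, 1 - abs(y - py) * n)
    sum(v) * dt
  }
  for (k in seq(1, cfg2_plain$n_theta, by = 30)) {
    th <- cfg2_plain$theta_grid[k]
    oracle <- vapply(cfg2_plain$s_grid, tent_line, numeric(1), th = th)
    expect_lt(max(abs(sino[, k] - oracle)),
              0.05 * max(max(oracle), n^-1.5))
    if (max(sino[, k]) > 1e-6) {
      # the ridge follows s = x cos(theta) + y sin(theta)
      s_obs <- cfg2_plain$s_grid[which.max(sino[, k])]
      expect_lt(abs(s_obs - (px * cos(th) + py * sin(th))), 2 * ds)
    }
  }
})

test_that("filtered backprojection round-trips a smooth phantom within 5%", {
  n <- 128
  xs <- (seq_len(n) - 0.5) / n - 0.5
  img <- outer(xs, xs, function(x, y)
    exp(-(x^2 + y^2) / (2 * 0.12^2)) +
      0.6 * exp(-((x - 0.15)^2 + (y + 0.1)^2) / (2 * 0.07^2)))
  cfg <- scanner_2d_config(tau = 1e6)
  rec <- recon_fbp_2d(project_2d(img, cfg, 1), cfg, scale = 1, h = 0)
  expect_lt(sqrt(mean((rec - img)^2)) / sqrt(mean(img^2)), 0.05)
  expect_error(recon_fbp_2d(matrix(0, 10, 10), cfg), "dimensions")
})

test_that("reconstruction is linear in the sinogram", {
  set.seed(51)
  cfg <- scanner_2d_config(tau = 1e6)
  s1 <- matrix(stats::rexp(183 * 181), 183, 181)
  s2 <- matrix(stats::rexp(183 * 181), 183, 181)
  r12 <- recon_fbp_2d(s1 + s2, cfg, scale = 1, h = 0)
  r1 <- recon_fbp_2d(s1, cfg, scale = 1, h = 0)
  r2 <- recon_fbp_2d(s2, cfg, scale = 1, h = 0)
  expect_lt(max(abs(r12 - (r1 + r2))), 1e-10 * max(abs(r12)))
})

test_that("backprojection is translation-equivariant on the pixel grid", {
  n <- 128
  xs <- (seq_len(n) - 0.5) / n - 0.5
  blob <- function(cx, cy) outer(xs, xs, function(x, y)
    exp(-((x - cx)^2 + (y - cy)^2) / (2 * 0.08^2)))
  cfg <- scanner_2d_config(tau = 1e6)
  shift <- 16
  r0 <- recon_fbp_2d(project_2d(blob(0, 0), cfg, 1), cfg, 1, h = 0)
  r1 <- recon_fbp_2d(project_2d(blob(shift / n, 0), cfg, 1), cfg, 1,
                     h = 0)
  inner <- 33:96   # compare away from the borders
  expect_lt(max(abs(r1[inner + shift, inner] - r0[inner, inner])),
            0.02 * max(r0))
})

test_that("doubling the dose halves replicate-averaged voxel variance", {
  n <- 128
  xs <- (seq_len(n) - 0.5) / n - 0.5
  img <- outer(xs, xs, function(x, y) exp(-(x^2 + y^2) / (2 * 0.15^2)))
  cfg <- scanner_2d_config(tau = 5e5)
  sino_unit <- radon_2d(img, cfg) * cfg$attenuation_sino
  var_at <- function(tau, nrep) {
    sc <- tau / sum(sino_unit)
    recs <- vapply(seq_len(nrep), function(r)
      as.numeric(recon_fbp_2d(sample_counts(sino_unit * sc), cfg,
                              scale = sc, h = 0)), numeric(n * n))
    mean(apply(recs, 1, stats::var))
  }
  set.seed(52)
  ratio <- var_at(5e5, 40) / var_at(1e6, 40)
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.4)
})

test_that("the 2-D dose exponent of uptake MSE lies in the 1-D band", {
  des <- make_study("h2o_fdg", dose = 1, ratio_or_J = 25, N_R = 2,
                    seed = 5)
  src1 <- default_source(des)
  map2 <- default_phantom_2d()
  dur <- des$schedule$duration_s / 60
  upt <- as.numeric(t(map2$alpha) %*% (src1$mu_frames %*% dur))
  img <- matrix(upt / max(upt), 128, 128)
  cfg <- scanner_2d_config(tau = 2e6)
  sino_unit <- radon_2d(img, cfg) * cfg$attenuation_sino
  set.seed(53)
  tab <- NULL
  for (dose in c(0.3, 0.7, 1.5, 3.2)) {
    tau <- 2e6 * dose
    sc <- tau / sum(sino_unit)
    raws <- lapply(1:15, function(r)
      recon_fbp_2d(sample_counts(sino_unit * sc), cfg, scale = sc,
                   h = 0))
    mses <- vapply(seq(0, 3, 0.5), function(h)
      mean(vapply(raws, function(z)
        mean((gauss_smooth_2d(z, h) - img)^2), numeric(1))), numeric(1))
    tab <- rbind(tab, data.frame(tau = tau, sigma2_z = min(mses)))
  }
  gamma <- fit_dose_model(tab)$gamma_tau
  expect_gt(gamma, 0.30)
  expect_lt(gamma, 0.55)
})
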