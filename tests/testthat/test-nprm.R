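test_that("segmentation recovers proportional groups exactly in the noise-free case", {
  set.seed(31)
  NT <- 30
  t <- seq(0.1, 3, length.out = NT)
  shapes <- rbind(exp(-t), t * exp(-t), 1 - exp(-2 * t))
  Z <- do.call(rbind, lapply(1:3, function(g)
    t(sapply(1:20, function(i) stats::runif(1, 0.5, 2) * shapes[g, ]))))
  DS <- segment_image(Z, S_target = 10)
  expect_equal(DS$S, 3)
  # each recovered segment is one true group
  truth <- rep(1:3, each = 20)
  expect_equal(length(unique(paste(DS$labels, truth))), 3)
  expect_true(all(DS$sds > 0))

  # single voxel: one segment with a floored SD
  one <- segment_image(Z[1, , drop = FALSE], S_target = 1)
  expect_equal(one$S, 1)
  expect_equal(one$means[1, ], Z[1, ])
  expect_true(all(one$sds > 0))

  # identical voxels collapse to one segment regardless of the ceiling
  same <- matrix(rep(shapes[1, ], each = 15), 15, NT)
  expect_equal(segment_image(same, S_target = 5)$S, 1)

  expect_error(segment_image(Z, S_target = 100), "exceeds")
})

test_that("noiseless sub-TAC fitting recovers the residue and its delay on the grid", {
  TE <- schedule_end(h2o_sch)
  kn <- residue_knots(TE, 10)
  Rtrue <- residue_fn(kn, 0.5 * exp(-0.4 * kn))
  mu <- convolve_residue_aif(Rtrue, h2o_cp, 10 / 60, h2o_sch)$value
  st <- fit_subtac(mu, rep(0.01 * max(mu), length(mu)), list(h2o_inj),
                   h2o_sch, "residue",
                   delta_grid = seq(-10, 30, by = 2) / 60, knots_n = 10)
  expect_equal(st$delays, 10 / 60)
  expect_lt(max(abs(st$curve - mu)) / max(mu), 1e-8)
  expect_true(all(st$curve >= -1e-12))

  # zero data give a zero-amplitude sub-TAC
  z0 <- fit_subtac(rep(0, n_frames(h2o_sch)),
                   rep(1, n_frames(h2o_sch)), list(h2o_inj), h2o_sch,
                   "residue", delta_grid = 0, knots_n = 6)
  expect_equal(max(abs(z0$curve)), 0)

  # Patlak-type data: fitted residue is constant (no active constraint)
  muP <- convolve_residue_aif(residue_fn(c(0, TE), c(0.3, 0.3)),
                              h2o_cp, 0, h2o_sch)$value
  stP <- fit_subtac(muP, rep(0.01 * max(muP), length(muP)),
                    list(h2o_inj), h2o_sch, "residue",
                    delta_grid = 0, knots_n = 8)
  expect_equal(stP$residues[[1]]$knot_values,
               rep(0.3, length(stP$residues[[1]]$knot_values)),
               tolerance = 1e-6)

  expect_error(fit_subtac(mu, rep(0, length(mu)), list(h2o_inj),
                          h2o_sch, "residue"), "positive")
  expect_error(fit_subtac(mu, rep(1, length(mu)), list(h2o_inj),
                          h2o_sch, "residue", delta_grid = numeric(0)),
               "empty delay grid")
})

test_that("model-kind selection keeps the residue unless an alternative clearly wins", {
  TE <- schedule_end(h2o_sch)
  R <- kety_residue(0.6, 0.4, TE)
  mu <- convolve_residue_aif(R, h2o_cp, 0, h2o_sch)$value
  sel <- select_segment_model(mu, rep(0.01 * max(mu), length(mu)),
                              list(h2o_inj), h2o_sch,
                              delta_grid = seq(0, 12, 4) / 60,
                              knots_n = 8)
  expect_equal(sel$kind, "residue")

  # data that are exactly a scaled shifted injection-site signal
  tg <- seq(0, TE, by = 1 / 600)
  ziv <- frame_average(tg, 2.5 * curve_at(h2o_cp, tg - 10 / 60), h2o_sch)
  sel2 <- select_segment_model(ziv, rep(0.005 * max(ziv), length(ziv)),
                               list(h2o_inj), h2o_sch,
                               delta_grid = seq(0, 20, 2) / 60,
                               knots_n = 8)
  expect_equal(sel2$kind, "iv_site")
  expect_equal(sel2$scale, 2.5, tolerance = 1e-3)

  # tie within threshold: Patlak data fit equally by residue and
  # distribution kinds; the residue kind is retained
  muP <- convolve_residue_aif(residue_fn(c(0, TE), c(0.3, 0.3)),
                              h2o_cp, 0, h2o_sch)$value
  sel3 <- select_segment_model(muP, rep(0.01 * max(muP), length(muP)),
                               list(h2o_inj), h2o_sch,
                               delta_grid = 0, knots_n = 8)
  expect_equal(sel3$kind, "residue")
})

test_that("basis elimination drops redundancy but spans the generating sub-TACs", {
  TE <- schedule_end(h2o_sch)
  set.seed(32)
  gen <- lapply(c(0.2, 0.8, 2.5), function(k2)
    convolve_residue_aif(kety_residue(0.7, k2, TE), h2o_cp, 0,
                         h2o_sch)$value)
  NT <- n_frames(h2o_sch)
  # segments generated from the 3 shapes (plus mild noise), candidate
  # set padded with near-duplicates
  S <- 9
  means <- matrix(0, S, NT)
  for (s in 1:S) {
    w <- c(stats::runif(1, 0, 2), stats::runif(1, 0, 1),
           stats::runif(1, 0, 0.5))
    means[s, ] <- w[1] * gen[[1]] + w[2] * gen[[2]] + w[3] * gen[[3]]
  }
  means <- means + stats::rnorm(length(means), sd = 0.002 * max(means))
  means <- pmax(means, 0)
  DS <- list(means = means, sds = matrix(0.01 * max(means), S, NT),
             sizes = rep(10, S), labels = rep(1:S, each = 10), S = S)
  class(DS) <- "reduced_dataset"
  cands <- lapply(c(gen, gen, gen), function(g)
    subtac_known(list(kety_residue(0.7, 1, TE)), 0, g))
  B <- build_basis(cands, DS, list(h2o_inj), h2o_sch, tol = 0.02)
  expect_lte(ncol(B$X), 6)
  # the reduced dataset is still fit to within the noise floor
  for (s in 1:S) {
    f <- fit_voxel(means[s, ], B)
    expect_lt(f$resid_rms, 0.01 * max(means))
  }

  # single candidate retained
  B1 <- build_basis(cands[1], DS, list(h2o_inj), h2o_sch)
  expect_gte(ncol(B1$X), 1)

  # an all-zero candidate column is dropped immediately
  zero <- subtac_known(list(kety_residue(0, 0, TE)), 0, rep(0, NT))
  B2 <- build_basis(c(cands[1:3], list(zero)), DS, list(h2o_inj),
                    h2o_sch, tol = 0.02)
  expect_false(any(colSums(abs(B2$X)) == 0))
})

test_that("voxel fitting matches the exhaustive-support NNLS oracle", {
  set.seed(33)
  # exact representation
  X <- cbind(c(1, 2, 3, 1), c(0, 1, 0, 2))
  f <- fit_voxel(X %*% c(2, 3), X)
  expect_equal(f$alpha, c(2, 3), tolerance = 1e-10)
  expect_equal(fit_voxel(rep(0, 4), X)$alpha, c(0, 0))

  # oracle equivalence over random small problems
  for (i in 1:1000) {
    K <- sample(2:4, 1)
    NT <- sample(6:20, 1)
    X <- matrix(stats::rnorm(NT * K), NT, K)
    z <- stats::rnorm(NT)
    f <- fit_voxel(z, X)
    o <- nnls_enum(X, z)
    expect_lt(abs(f$sse - o$sse), 1e-8)
    expect_lt(max(abs(f$alpha - o$x)), 1e-6)
  }

  X4 <- cbind(c(1, 2, 3, 1), c(0, 1, 0, 2))
  expect_error(fit_voxel(1:3, X4), "length")
  expect_error(fit_voxel(c(1, NA, 2, 3), X4), "non-finite")
})

test_that("adding noise-free replicate columns never worsens the voxel fit", {
  set.seed(34)
  for (i in 1:50) {
    NT <- 15
    X <- matrix(abs(stats::rnorm(NT * 3)), NT, 3)
    z <- abs(stats::rnorm(NT))
    base <- fit_voxel(z, X)$sse
    Xdup <- cbind(X, X[, sample(3, 1)])
    expect_lte(fit_voxel(z, Xdup)$sse, base + 1e-9)
  }
})

test_that("voxel kinetic mapping weights delays by flow and is linear", {
  TE <- schedule_end(h2o_sch)
  R1 <- kety_residue(0.5, 0.3, TE)
  mu1 <- convolve_residue_aif(R1, h2o_cp, 6 / 60, h2o_sch)$value
  b1 <- basis_from_subtacs(list(subtac_known(list(R1), 6 / 60, mu1)),
                           list(h2o_inj), h2o_sch)
  k1 <- map_voxel_kinetics(c(1), b1)
  expect_equal(k1[[1]]$delay, 6 / 60)

  # two components with equal alpha * K_D and delays 0, 10 s
  R2 <- kety_residue(0.5, 0.8, TE)
  mu2 <- convolve_residue_aif(R2, h2o_cp, 10 / 60, h2o_sch)$value
  b2 <- basis_from_subtacs(list(
    subtac_known(list(R1), 0, mu1),
    subtac_known(list(R2), 10 / 60, mu2)), list(h2o_inj), h2o_sch)
  kd1 <- residue_summaries(residue_decompose(R1, 0.25))$K_D
  kd2 <- residue_summaries(residue_decompose(R2, 0.25))$K_D
  k2 <- map_voxel_kinetics(c(1, kd1 / kd2), b2)
  expect_equal(k2[[1]]$delay, 5 / 60, tolerance = 1e-10)

  # linearity: mapped summaries equal summaries of the summed residue
  R3 <- kety_residue(0.9, 1.5, TE)
  mu3 <- convolve_residue_aif(R3, h2o_cp, 0, h2o_sch)$value
  b3 <- basis_from_subtacs(list(
    subtac_known(list(R1), 0, mu1), subtac_known(list(R2), 0, mu2),
    subtac_known(list(R3), 0, mu3)), list(h2o_inj), h2o_sch)
  a <- c(0.4, 1.2, 0.3)
  k3 <- map_voxel_kinetics(a, b3)
  oracle <- residue_summaries(residue_decompose(
    residue_combine(list(R1, R2, R3), a), 0.25))
  for (p in c("V_B", "V_D", "K_D", "K_i", "K_1"))
    expect_equal(k3[[1]][[p]], oracle[[p]], tolerance = 1e-9)

  # a basis with no residue columns flags zero summaries
  bs <- basis_from_subtacs(list(
    list(kind = "aif_spike", delays = 0, residues = NULL, curve = mu1,
         coef = NULL, sse = NA)), list(h2o_inj), h2o_sch)
  kz <- map_voxel_kinetics(c(1), bs)
  expect_false(attr(kz, "has_residue"))
  expect_equal(kz[[1]]$K_1, 0)
})
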