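test_that("infusion input converges to the bolus as the pump duration shrinks", {
  grid <- seq(0, 10, by = 1 / 120)
  bolus <- synth_aif("h2o_bolus", onset = 1, tail_frac = 0, grid = grid)
  inf_short <- synth_aif("fdg_infusion", onset = 1, tail_frac = 0,
                         infusion_min = 1 / 120, grid = grid)
  expect_lt(max(abs(inf_short$value - bolus$value)) / max(bolus$value),
            0.02)
  inf2 <- synth_aif("fdg_infusion", onset = 1, infusion_min = 2,
                    grid = grid)
  expect_lt(max(inf2$value), max(bolus$value))  # pump spreads the peak
})

test_that("input-function area scales with amplitude and the peak sits where asked", {
  grid <- seq(0, 12, by = 1 / 120)
  a1 <- synth_aif("h2o_bolus", onset = 1, amplitude = 1, grid = grid)
  a2 <- synth_aif("h2o_bolus", onset = 1, amplitude = 2, grid = grid)
  expect_equal(curve_integral_at(a2, 12), 2 * curve_integral_at(a1, 12),
               tolerance = 1e-10)

  pk <- synth_aif("h2o_bolus", onset = 1, peak_delay = 0.6,
                  tail_frac = 0, grid = grid)
  expect_equal(grid[which.max(pk$value)], 1.6, tolerance = 1 / 60)

  # width at half maximum matches the closed-form gamma-variate
  shape <- 3
  gv <- function(t) ifelse(t > 0, (t / 0.6)^shape *
                             exp(shape * (1 - t / 0.6)), 0)
  tfine <- seq(0, 11, by = 1e-4)
  ref <- gv(tfine)
  fw_ref <- diff(range(tfine[ref >= 0.5]))
  obs <- pk$value / max(pk$value)
  fw_obs <- diff(range(grid[obs >= 0.5]))
  expect_equal(fw_obs, fw_ref, tolerance = 0.02)

  expect_error(synth_aif("h2o_bolus", peak_delay = -1), "shape")
})

test_that("1-D phantoms cover the axis with non-negative profiles", {
  map <- default_phantom_1d()
  expect_equal(nrow(map$alpha), 6)
  expect_true(all(map$alpha >= 0))
  expect_true(all(colSums(map$alpha) > 0))
  expect_setequal(map$names,
                  c("spleen", "tumour", "myocardium", "normal_breast",
                    "liver", "lv"))

  expect_error(build_phantom_1d(list()), "empty")
  one <- build_phantom_1d(list(list(name = "all", center = 64.5,
                                    width = 128, amplitude = 1,
                                    shape = "plateau")))
  expect_equal(one$alpha[1, ], rep(1, 128))

  expect_error(build_phantom_1d(list(
    list(name = "a", center = 30, width = 20, amplitude = 1,
         shape = "plateau"),
    list(name = "b", center = 35, width = 20, amplitude = 1,
         shape = "plateau"))), "overlapping")
})

test_that("source assembly superposes injections and stays non-negative", {
  des <- make_study("repeat_h2o", dose = 1, ratio_or_J = 2, N_R = 2,
                    seed = 61)
  map <- build_phantom_1d(list(list(name = "grey", center = 60,
                                    width = 30, amplitude = 1)))
  kin <- list(list(list(kind = "kety", K_1 = 0.5, k_2 = 0.6),
                   list(kind = "kety", K_1 = 0.5, k_2 = 0.6)))
  src <- build_source(map, kin, des$injections, des$schedule)

  # superposition: the two-injection curve is the sum of single-injection
  # responses to each injection's input alone
  per_inj <- lapply(seq_along(des$injections), function(j)
    convolve_residue_aif(src$residues[[1]][[j]],
                         des$injections[[j]]$aif, 0,
                         des$schedule)$value)
  expect_equal(src$mu_frames[1, ], per_inj[[1]] + per_inj[[2]],
               tolerance = 1e-8)

  # zero-flow region contributes nothing
  kin0 <- list(list(list(kind = "kety", K_1 = 0, k_2 = 0),
                    list(kind = "kety", K_1 = 0, k_2 = 0)))
  src0 <- build_source(map, kin0, des$injections, des$schedule)
  expect_equal(max(abs(src0$lambda_frames)), 0)

  expect_error(build_source(map, list(), des$injections, des$schedule),
               "per region")
})

test_that("random phantoms always produce non-negative sources", {
  set.seed(62)
  des <- make_study("repeat_h2o", dose = 1, ratio_or_J = 2, N_R = 2,
                    seed = 62)
  for (i in 1:30) {
    spec <- lapply(1:3, function(k)
      list(name = paste0("r", k), center = stats::runif(1, 10, 118),
           width = stats::runif(1, 6, 40),
           amplitude = stats::runif(1, 0.2, 1.5)))
    map <- build_phantom_1d(spec)
    kin <- lapply(1:3, function(k) lapply(1:2, function(j)
      list(kind = "kety", K_1 = stats::runif(1, 0.1, 1),
           k_2 = stats::runif(1, 0.2, 2))))
    src <- build_source(map, kin, des$injections, des$schedule,
                        dt = 1 / 120)
    expect_true(all(src$lambda_frames >= 0))
  }
})

test_that("study designs are replicable and enforce their grids", {
  expect_error(make_study("h2o_fdg", N_R = 0), "N_R")
  expect_error(make_study("h2o_fdg", dose = 0.9), "grid")
  expect_error(make_study("h2o_fdg", ratio_or_J = 7), "ratio")
  expect_error(make_study("repeat_h2o", ratio_or_J = 3), "injections")
  expect_silent(make_study("h2o_fdg", dose = 0.9, strict = FALSE))

  d <- make_study("h2o_fdg", dose = 1, ratio_or_J = 25, N_R = 5,
                  seed = 63)
  expect_equal(d$tau_split / d$tau, c(25, 1) / 26)
  expect_equal(length(d$seeds), 5)

  # bit-identical counts under the same seed
  src <- default_source(d)
  cfg <- scanner_1d_config(tau = d$tau)
  run_counts <- function() {
    set.seed(d$seeds[1])
    simulate_study_1d(src$lambda_frames, d$schedule$duration_s / 60,
                      cfg, recon = "none")$counts
  }
  expect_identical(run_counts(), run_counts())
})

test_that("simulated voxel noise at the reference dose sits in the calibrated band", {
  des <- make_study("h2o_fdg", dose = 1, ratio_or_J = 25, N_R = 2,
                    seed = 64)
  rel_sd <- calibrate_noise(des)
  expect_gt(rel_sd, 0.05)
  expect_lt(rel_sd, 0.40)
})

test_that("true kinetic maps follow the region mixtures", {
  des <- make_study("fdg", dose = 1, N_R = 2, seed = 65)
  src <- default_source(des, map = roi_phantom_1d())
  tr <- true_kinetic_maps(src)
  expect_equal(dim(tr[[1]]), c(128, 7))
  # plateau phantom: voxels inside the tumour ROI carry tumour kinetics
  reg <- apply(src$alpha, 2, which.max)
  i_t <- which(reg == 2 & colSums(src$alpha) > 0)[3]
  Rt <- src$residues[[2]][[1]]
  amp <- src$alpha[2, i_t]
  s <- residue_summaries(residue_decompose(Rt, 0.25))
  expect_equal(unname(tr[[1]][i_t, "K_1"]), amp * s$K_1,
               tolerance = 1e-8)
})
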