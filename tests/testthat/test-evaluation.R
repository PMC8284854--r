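test_that("combined and separate fits coincide for a single injection and recover noiseless truth", {
  set.seed(71)
  NT <- 20
  X <- matrix(abs(stats::rnorm(NT * 3)), NT, 3)
  sch <- frame_schedule(list(c(NT, 60)))
  truth <- matrix(abs(stats::rnorm(10 * 3)), 10, 3)
  Z <- truth %*% t(X)
  f <- fit_combined_and_separate(Z, X, list(c(0, NT)), sch)
  expect_equal(f$alpha_C, truth, tolerance = 1e-8)
  expect_equal(f$alpha_S[[1]], f$alpha_C, tolerance = 1e-10)
  expect_error(fit_combined_and_separate(Z, X, list(c(100, 200)), sch),
               "empty")
})

test_that("the squared-error assessment matches hand evaluation and scales quadratically", {
  sch1 <- frame_schedule(list(c(1, 60)))
  lam <- matrix(2, 1, 1)
  lam_hat <- matrix(3, 1, 1)
  se <- assess_error(lam_hat, lam, sch1, list(c(0, 1)))
  expect_equal(se, 0.25)    # (3-2)^2 / (1 * 2^2)

  expect_equal(assess_error(lam, lam, sch1, list(c(0, 1))), 0)

  set.seed(72)
  lam2 <- matrix(abs(stats::rnorm(5 * 10)) + 0.5, 5, 10)
  sch10 <- frame_schedule(list(c(10, 30)))
  base <- assess_error(lam2 + 1, lam2, sch10, list(c(0, 5)))
  expect_equal(assess_error(lam2 + 3, lam2, sch10, list(c(0, 5))),
               9 * base, tolerance = 1e-10)
  expect_error(assess_error(lam2[, 1:5], lam2, sch10, list(c(0, 5))),
               "mismatch")
})

test_that("MSE summaries and percent improvement follow the ratio definition", {
  expect_equal(summarize_mse(c(1, 1, 1), c(1, 1, 1))$improvement, 0)
  expect_equal(summarize_mse(c(1, 2, 3), 2 * c(1, 2, 3))$improvement, 100)
  set.seed(73)
  a <- stats::runif(50, 0.9, 1.1)
  s <- summarize_mse(a, 1.2085 * a)
  expect_equal(s$improvement, 20.85, tolerance = 1e-10)
  expect_error(summarize_mse(1, 2), "replicates")
})

test_that("the variance-pooling ratio formula holds and is verified by Monte Carlo", {
  expect_equal(theory_mse_ratio(rep(2, 4), 1), 0.25)
  expect_equal(theory_mse_ratio(3, 1), 1)
  expect_equal(theory_mse_ratio(c(1, 2), 1), 0.8)
  expect_error(theory_mse_ratio(c(0, 1)), "positive")
  expect_error(theory_mse_ratio(c(1, 2), 5), "index")

  mc <- mc_pooling_ratio(J = 2, n_per = 15, p = 3, n_rep = 1500,
                         seed = 74)
  expect_true(all(abs(mc$mc_ratio - mc$formula_ratio) <= 3 * mc$mc_se))
  expect_true(all(mc$formula_ratio <= 1))
})

test_that("scaled-MSE regression recovers exact coefficients and converts to percent", {
  expect_equal(coef_to_improvement(0), 0)
  expect_equal(round(coef_to_improvement(0.19)), 21)

  # noiseless synthetic table built from the model itself
  tab <- expand.grid(method = c("combined", "separate"),
                     DR = c(16, 25, 64), dose = c(0.5, 1))
  a <- c(-6.3, 0.19, 0.015)
  tab$sigma2_z <- 1e-6
  tab$mse <- tab$sigma2_z *
    exp(a[1] + a[2] * (tab$method == "separate") + a[3] * tab$DR)
  fit <- fit_scaled_mse(tab, "h2o_fdg")
  expect_equal(unname(stats::coef(fit$fit)), a, tolerance = 1e-10)
  expect_equal(fit$implied_improvement, coef_to_improvement(0.19),
               tolerance = 1e-8)

  tab2 <- expand.grid(method = c("combined", "separate"),
                      J = c(2, 4, 6, 8))
  b <- c(1.8, 0.44, -0.45, 0.32)
  tab2$sigma2_z <- 1
  tab2$mse <- exp(b[1] + b[2] * (tab2$method == "separate") +
                    b[3] * tab2$J +
                    b[4] * (tab2$method == "separate") * tab2$J)
  fit2 <- fit_scaled_mse(tab2, "repeat")
  expect_equal(unname(stats::coef(fit2$fit)), b, tolerance = 1e-10)

  bad <- tab
  bad$DR <- 25
  expect_error(fit_scaled_mse(bad, "h2o_fdg"), "rank-deficient")
})

test_that("the dose-decay exponent is recovered exactly from log-linear tables", {
  tab <- data.frame(tau = c(3e5, 5e5, 1e6, 2e6),
                    sigma2_z = 7 * c(3e5, 5e5, 1e6, 2e6)^(-0.42))
  expect_equal(fit_dose_model(tab)$gamma_tau, 0.42, tolerance = 1e-12)
  flat <- data.frame(tau = c(1e5, 1e6), sigma2_z = c(2, 2))
  expect_equal(fit_dose_model(flat)$gamma_tau, 0, tolerance = 1e-12)
  expect_error(fit_dose_model(data.frame(tau = 1e5, sigma2_z = 1)),
               "two dose levels")
})

test_that("dose equivalence converts improvements into percent dose increases", {
  expect_equal(round(dose_equivalence(0.10, 0.42)), 25)
  expect_equal(dose_equivalence(0, 0.8), 0)
  expect_equal(dose_equivalence(0.10, 1), 10, tolerance = 1e-12)
  expect_error(dose_equivalence(0.1, 0), "positive")
  expect_error(dose_equivalence(-1, 0.42), "exceed")
})

test_that("relative RMSE ratios and local-error slopes behave on constructed tables", {
  tab <- data.frame(param = rep(c("K_D", "K_i"), each = 4),
                    rmse_num = c(1, 2, 3, 4, 2, 4, 6, 8),
                    rmse_den = c(1, 2, 3, 4, 1, 2, 3, 4))
  rr <- relative_rmse(tab)
  expect_equal(rr$e_hat[rr$param == "K_D"], 1)
  expect_equal(rr$e_hat[rr$param == "K_i"], 2)

  # hand-computed mean of a small ratio table
  tab2 <- data.frame(param = "p", rmse_num = c(1.2, 0.9, 1.5),
                     rmse_den = c(1, 1, 1))
  expect_equal(relative_rmse(tab2)$e_hat, mean(c(1.2, 0.9, 1.5)))
  expect_error(relative_rmse(data.frame(param = "p", rmse_num = 1,
                                        rmse_den = 0)), "denominator")

  # exact proportionality gives slope 1 with perfect fit
  set.seed(75)
  sig <- stats::rexp(40) + 0.1
  th <- stats::rexp(40) + 0.5
  sl <- local_error_slopes(rmse = 0.7 * sig, sigma = sig, theta = th,
                           param = rep("K_1", 40))
  expect_equal(sl$slope, 1, tolerance = 1e-10)
  expect_equal(sl$r_squared, 1, tolerance = 1e-10)
})

test_that("array containers round-trip with their JSON sidecars", {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(c(f, paste0(f, ".json"))))
  x <- matrix(stats::rnorm(12), 3, 4)
  write_array_csv(x, f, meta = list(kind = "test", n = 3))
  back <- read_array_csv(f)
  expect_equal(back, x, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(back, "meta")$kind, "test")
})
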