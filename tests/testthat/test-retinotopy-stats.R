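# Design matrix, prewhitened GLM, F/z statistics, thresholding and the
# retinotopic phase estimator.

test_that("task regressors follow the quadrature convention", {
  x <- task_regressors(120, 9, "clockwise")
  expect_equal(unname(x[1, ]), c(0, -1))            # t = 0: sin 0, cos 0
  xc <- task_regressors(120, 9, "counterclockwise")
  expect_equal(xc[, 1], -x[, 1])
  expect_equal(xc[, 2], x[, 2])
  expect_lt(abs(sum(x[, 1] * x[, 2])), 1e-9)        # quadrature orthogonality
  expect_error(task_regressors(120, 0), "positive")
})

test_that("the design matrix is 240 x 20 and block-diagonal", {
  d <- fx_design120()
  expect_equal(dim(d$X), c(240L, 20L))
  expect_true(all(d$X[1:120, 11:20] == 0))
  expect_true(all(d$X[121:240, 1:10] == 0))
  expect_equal(unname(d$X[1:120, 9]), 0:119)        # drift column = t
  expect_true(all(d$X[1:120, 10] == 1))             # baseline
  expect_error(build_design(120, 2.4, 32, motion1 = matrix(0, 50, 6)),
               "Nvol x 6")
})

test_that("the prewhitened GLM recovers exact and noisy coefficients", {
  d <- fx_design120()
  # noiseless interpolation
  set.seed(1)
  beta <- matrix(rnorm(20 * 5), 20, 5)
  Y <- d$X %*% beta
  fit <- fit_glm(Y, d)
  expect_lt(max(abs(coef(fit) - beta)), 1e-8)
  # residuals orthogonal to the whitened design
  expect_lt(max(abs(crossprod(fit$Xw, residuals(fit)))), 1e-6)
  expect_equal(fit$dof, 240 - 20)

  # adding a constant moves only the baseline coefficients
  fit2 <- fit_glm(Y + 7, d)
  delta <- coef(fit2) - coef(fit)
  expect_equal(unname(delta[10, ]), rep(7, 5), tolerance = 1e-8)
  expect_equal(unname(delta[20, ]), rep(7, 5), tolerance = 1e-8)
  expect_lt(max(abs(delta[-c(10, 20), ])), 1e-8)

  # AR(1) recovery at the nominal value
  set.seed(3)
  Yn <- rbind(ar1_series(120, 0.4, 1, ncol = 500),
              ar1_series(120, 0.4, 1, ncol = 500))
  fitn <- fit_glm(Yn, d)
  expect_equal(fitn$ar1_hat, 0.4, tolerance = 0.05)

  # absent motion leaves aliased columns: dropped by default, error on demand
  d0 <- build_design(120, 2.4, 32)
  fit0 <- fit_glm(Y[, 1, drop = FALSE], d0)
  expect_equal(fit0$rank, 8)
  expect_error(fit_glm(Y[, 1, drop = FALSE], d0, on_deficient = "error"),
               "mot")
})

test_that("GLM methods expose the classic modelling interface", {
  d <- fx_design120()
  set.seed(2)
  Y <- d$X %*% matrix(rnorm(20 * 3), 20, 3) + matrix(rnorm(240 * 3), 240, 3)
  fit <- fit_glm(Y, d)
  expect_output(print(fit), "AR\\(1\\)")
  expect_output(print(summary(fit)), "residual dof")
  expect_equal(dim(coef(fit)), c(20L, 3L))
  expect_equal(dim(residuals(fit)), c(240L, 3L))
  expect_equal(dim(fitted(fit)), c(240L, 3L))
  sim <- simulate(fit, nsim = 1, seed = 4)
  expect_equal(dim(sim), c(240L, 3L))
  expect_identical(sim, simulate(fit, nsim = 1, seed = 4))
})

test_that("effect-of-interest F has the printed degrees of freedom and null law", {
  d <- fx_design120()
  set.seed(3)
  Y0 <- matrix(rnorm(240 * 2000), 240, 2000)
  fit <- fit_glm(Y0, d)
  eoi <- effect_of_interest(fit, "paper")
  expect_equal(eoi$nu1, 16)
  expect_equal(eoi$nu2, 220)
  # central F mean under the null: nu2 / (nu2 - 2), within 3 SE
  expect_equal(mean(eoi$F), 220 / 218,
               tolerance = 3 * sd(eoi$F) / sqrt(2000) / (220 / 218))

  conv <- effect_of_interest(fit, "conventional")
  expect_equal(conv$nu1, 4)
  expect_equal(mean(conv$F), 220 / 218,
               tolerance = 3 * sd(conv$F) / sqrt(2000) / (220 / 218))

  raw <- effect_of_interest(fit, "paper", statistic = "paper_raw")
  expect_equal(raw$F_raw, eoi$F * 16 / 220, tolerance = 1e-12)

  # a voxel with a huge task effect and tiny noise is overwhelming
  sig <- d$X[, c(1, 2, 11, 12)] %*% c(50, 30, -40, 20) + rnorm(240, sd = 0.01)
  fit1 <- fit_glm(cbind(sig), d)
  expect_lt(effect_of_interest(fit1, "conventional")$p, 1e-10)
})

test_that("task z maps are null-calibrated, signed, and t-like at high dof", {
  d <- fx_design120()
  set.seed(4)
  Y0 <- matrix(rnorm(240 * 2000), 240, 2000)
  fit <- fit_glm(Y0, d)
  tz <- task_z_maps(fit)
  expect_equal(mean(tz$z), 0, tolerance = 3 / sqrt(4 * 2000))
  expect_true(all(sign(tz$z) == sign(tz$beta) | tz$z == 0))
  # with dof = 220 the z conversion barely moves moderate t values
  expect_equal(tz$z[abs(tz$t) < 3], tz$t[abs(tz$t) < 3], tolerance = 0.01)
})

test_that("the three thresholding strategies behave as specified", {
  # BH step-up oracle on a small list
  expect_equal(sum(threshold_map(c(0.001, 0.01, 0.02, 0.5), "i")), 3)
  # strategy ii is the z > 3.09 rule
  expect_equal(round(qnorm(1 - 0.001), 2), 3.09)
  p <- c(0.0005, 0.002, 0.5)
  expect_equal(as.vector(threshold_map(p, "ii")), c(TRUE, FALSE, FALSE))
  # BH rejections never decrease as q grows
  set.seed(5)
  pv <- runif(500)^2
  r1 <- sum(threshold_map(pv, "i", q = 0.01))
  r2 <- sum(threshold_map(pv, "i", q = 0.05))
  r3 <- sum(threshold_map(pv, "i", q = 0.2))
  expect_true(r1 <= r2 && r2 <= r3)

  # strategy iii: a 4-voxel cluster dies, a 5-voxel cluster survives
  parr <- array(1, c(12, 12))
  parr[2:5, 2] <- 1e-4          # 4 voxels
  parr[8:12, 8] <- 1e-4         # 5 voxels
  m <- threshold_map(parr, "iii")
  expect_equal(sum(m[2:5, 2]), 0)
  expect_equal(sum(m[8:12, 8]), 5)
  expect_error(threshold_map(p, "iv"))
})

test_that("null false-positive rate of strategy ii is calibrated on 50k voxels", {
  d <- fx_design120()
  set.seed(6)
  Y0 <- matrix(rnorm(240 * 50000), 240, 50000)
  fit <- fit_glm(Y0, d)
  eoi <- effect_of_interest(fit, "paper")
  fpr <- mean(threshold_map(eoi$p, "ii"))
  expect_equal(fpr, 0.001, tolerance = 3 * sqrt(0.001 * 0.999 / 50000) / 0.001)
})

test_that("phase estimation is exact on noiseless runs and accurate under noise", {
  ph <- fx_phantom32()
  d <- fx_design120()
  rim <- ph$roi[ph$support]
  truth <- ph$phi_v[ph$support][rim]

  # keystone: noiseless two-run round trip recovers phi_v and d_h exactly
  nz <- noise_spec(sigma = 0, ar1 = 0, drift_slope = 0.01)
  runs <- list(simulate_bold_series(ph, retinotopy_spec(), nz, "clockwise"),
               simulate_bold_series(ph, retinotopy_spec(), nz,
                                    "counterclockwise"))
  fit <- fit_glm(runs, d)
  tz <- task_z_maps(fit)
  pm <- phase_maps(tz$beta[1, ], tz$beta[2, ], tz$beta[3, ], tz$beta[4, ])
  expect_lt(max(circ_diff(pm$phi[rim], truth)), 1e-6)
  expect_lt(max(abs(pm$d_h[rim] - pi / 4)), 1e-6)

  # Eq-style arithmetic: phi_clock = pi/3, phi_cclock = pi/6
  one <- phase_maps(-sin(pi / 3), -cos(pi / 3), -sin(pi / 6), cos(pi / 6))
  expect_equal(one$phi_clock, pi / 3)
  expect_equal(one$phi_cclock, pi / 6)
  expect_equal(one$d_h, pi / 4)
  expect_equal(one$phi, pi / 12)

  # z1 = z3, z2 = -z4 (with positive session phase) collapses phi to 0
  two <- phase_maps(-0.3, -0.8, -0.3, 0.8)
  expect_equal(two$phi, 0)

  # undefined voxels are flagged
  three <- phase_maps(0, 0, 1, 1)
  expect_true(three$undefined)

  # noisy recovery at temporal SNR ~ 50: circular RMSE < 0.2 rad
  nn <- noise_spec(sigma = 2, ar1 = 0.3)
  runs_n <- list(simulate_bold_series(ph, retinotopy_spec(), nn, "clockwise",
                                      seed = 21),
                 simulate_bold_series(ph, retinotopy_spec(), nn,
                                      "counterclockwise", seed = 22))
  fitn <- fit_glm(runs_n, d)
  tzn <- task_z_maps(fitn)
  pmn <- phase_maps(tzn$beta[1, ], tzn$beta[2, ], tzn$beta[3, ], tzn$beta[4, ])
  err <- circ_diff(pmn$phi[rim], truth)
  expect_lt(sqrt(mean(err^2)), 0.2)
  # mirrored hemifields keep mirrored recovered phases
  expect_gt(cor(sin(pmn$phi[rim]), sin(truth)), 0.9)
})

test_that("F is invariant to invertible reparameterization of nuisance columns", {
  d <- fx_design120()
  set.seed(7)
  Y <- matrix(rnorm(240 * 200), 240, 200)
  f1 <- effect_of_interest(fit_glm(Y, d), "conventional")
  d2 <- d
  nuis <- setdiff(seq_len(20), d$task_cols)
  A <- diag(length(nuis)) + matrix(0.1, length(nuis), length(nuis))
  d2$X[, nuis] <- d$X[, nuis] %*% A
  f2 <- effect_of_interest(fit_glm(Y, d2), "conventional")
  expect_equal(f1$F, f2$F, tolerance = 1e-6)
})

test_that("Gaussian smoothing preserves mass and matches the FWHM sigma", {
  expect_equal(2 / (2 * sqrt(2 * log(2))), 0.8493, tolerance = 1e-4)
  set.seed(8)
  x <- array(rnorm(48 * 48)^2, c(48, 48))
  s <- gaussian_smooth(x, fwhm_mm = 2, voxel_mm = 1)
  expect_equal(sum(s), sum(x), tolerance = 1e-6)
  expect_identical(gaussian_smooth(x, 0), x)
  # masked smoothing never bleeds outside the mask
  mask <- array(FALSE, c(48, 48)); mask[10:30, 10:30] <- TRUE
  sm <- gaussian_smooth(x, 2, mask = mask)
  expect_true(all(sm[!mask] == 0))
  # kernel width: smoothing a delta gives the expected half width
  dlt <- array(0, c(48, 48)); dlt[25, 25] <- 1   # the origin voxel
  sd_emp <- sqrt(sum(gaussian_smooth(dlt, 4) *
                       (centered_grid(c(48, 48))[, 1] + 0)^2))
  expect_equal(sd_emp, 4 / 2.3548, tolerance = 0.02)
})
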