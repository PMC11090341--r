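# Wavelet transform, soft thresholding, POGM compressed sensing and the
# linear comparator reconstructions.

test_that("soft thresholding shrinks magnitudes and preserves phase", {
  expect_equal(soft_threshold(0 + 0i, 1), 0 + 0i)
  x <- 0.5 * exp(1i * 0.7)
  expect_equal(soft_threshold(x, 0.6), 0 + 0i)
  x2 <- 2 * exp(1i * 1.2)
  out <- soft_threshold(x2, 1)
  expect_equal(Mod(out), 1, tolerance = 1e-12)
  expect_equal(Arg(out), 1.2, tolerance = 1e-12)
  expect_error(soft_threshold(x2, -1), "tau")
})

test_that("wavelet transform is orthonormal and round-trips exactly", {
  set.seed(1)
  for (shape in list(c(64, 64), c(16, 16, 16))) {
    x <- array(rnorm(prod(shape)), shape)
    w <- dwt(x, 3)
    expect_lt(max(abs(idwt(w) - x)), 1e-10)
    expect_equal(sum(w^2), sum(x^2), tolerance = 1e-10)   # Parseval
  }
  xc <- array(complex(real = rnorm(1024), imaginary = rnorm(1024)), c(32, 32))
  expect_lt(max(Mod(idwt(dwt(xc, 3)) - xc)), 1e-10)
  expect_error(dwt(array(0, c(20, 20)), 3), "divisible")
})

test_that("POGM with lambda = 0 on fully sampled data solves the inverse FFT", {
  shape <- c(32, 32)
  full <- epi_sampling_mask(shape, 1, 1, 1)
  op <- encoding_operator(full, shape)
  m <- fx_phantom32()$t2s_image + 0i
  y <- encode(m, op)
  rec <- cs_reconstruct(y, op, recon_config(lambda = 0, n_iter = 10))
  expect_lt(max(Mod(rec$image - m)), 1e-5)
})

test_that("huge lambda suppresses every detail coefficient", {
  shape <- c(32, 32)
  K <- pattern_points(fx_pattern_small())
  op <- encoding_operator(K, shape)
  y <- op$forward(fx_phantom32()$t2s_image + 0i)
  rec <- cs_reconstruct(y, op, recon_config(lambda = 10, n_iter = 15))
  w <- dwt(rec$image, rec$levels)
  coarse <- sparkfmri:::.coarse_mask(shape, rec$levels)
  expect_lt(max(Mod(w[!coarse])), 1e-8 * max(Mod(w)))
})

test_that("CS beats the density-compensated adjoint on the undersampled fixture", {
  set.seed(1)
  shape <- c(64, 64)
  ph <- fx_phantom64()
  truth <- ph$t2s_image
  hw <- fx_hw()
  K <- optimize_pattern(init_radial_pattern(8, 64, d = 2, hw = hw, seed = 5),
                        fx_density2d(), n_iter = 60)
  coils <- make_coil_profiles(4, shape, seed = 3)
  op <- encoding_operator(K, shape, coils)
  y <- op$forward(truth + 0i)
  sd_n <- sqrt(mean(Mod(y)^2) * 10^(-30 / 10) / 2)   # 30 dB SNR
  y <- y + matrix(complex(real = rnorm(length(y), sd = sd_n),
                          imaginary = rnorm(length(y), sd = sd_n)), nrow(y))

  adj <- op$adjoint(y * dcf_weights(op$points))
  rec <- cs_reconstruct(y, op, recon_config(lambda = 5e-3, n_iter = 40))

  # compare on a common least-squares intensity scale (linear recon scale
  # is arbitrary under undersampling)
  rescale <- function(est) {
    s <- sum(Mod(est) * truth) / sum(Mod(est)^2)
    Mod(est) * s
  }
  psnr_adj <- psnr(rescale(adj), truth)
  psnr_cs <- psnr(rescale(rec$image), truth)
  expect_gt(psnr_cs, psnr_adj)

  # objective decreases monotonically after the burn-in iterations
  tr <- rec$objective
  expect_true(all(diff(tr[-(1:5)]) <= 1e-8 * abs(tr[1])))

  # determinism
  rec2 <- cs_reconstruct(y, op, recon_config(lambda = 5e-3, n_iter = 40))
  expect_identical(rec$image, rec2$image)
})

test_that("linear reconstruction recovers full data and ghosts aliased data", {
  shape <- c(32, 32)
  full <- epi_sampling_mask(shape, 1, 1, 1)
  op <- encoding_operator(full, shape)
  m <- fx_phantom32()$t2s_image + 0i
  rec <- linear_reconstruct(encode(m, op), op, "zero_filled")
  expect_lt(max(Mod(rec - m)), 1e-6)

  # every-2nd-line mask: impulse replicates at a FOV/2 shift
  em2 <- epi_sampling_mask(shape, r_phase = 2, r_partition = 1, pf = 1)
  op2 <- encoding_operator(em2, shape)
  imp <- array(0 + 0i, shape); imp[17, 13] <- 1
  zf <- Mod(linear_reconstruct(encode(imp, op2), op2, "zero_filled"))
  pk <- arrayInd(order(zf, decreasing = TRUE)[1:2], shape)
  expect_setequal(pk[, 2], c(13, 29))

  # zero data -> zero image, both methods
  zero <- matrix(0 + 0i, op2$M, 1)
  expect_equal(max(Mod(linear_reconstruct(zero, op2, "zero_filled"))), 0)
  expect_equal(max(Mod(linear_reconstruct(zero, op2, "least_squares"))), 0)

  # least squares undoes moderate undersampling with multiple coils
  coils <- make_coil_profiles(4, shape, seed = 3)
  em <- epi_sampling_mask(shape, r_phase = 2, r_partition = 1, pf = 6 / 8)
  opc <- encoding_operator(em, shape, coils)
  ls <- linear_reconstruct(opc$forward(m), opc, "least_squares", n_iter = 30)
  expect_gt(psnr(ls, Mod(m)), 25)
})

test_that("lambda line search returns the audit table and an interior choice", {
  set.seed(5)
  shape <- c(32, 32)
  ph <- fx_phantom32()
  # hardware with enough dwell for 48-sample shots to span all of k-space
  hw <- hardware_constraints(dt = 5e-4, Kmax = 1 / (2 * 0.006))
  K <- init_radial_pattern(8, 48, d = 2, hw = hw, seed = 5)
  coils <- make_coil_profiles(4, shape, seed = 3)
  op <- encoding_operator(K, shape, coils)
  spec <- retinotopy_spec(Nvol = 40)
  st <- simulate_kspace_study(ph, spec, noise_spec(sigma = 2, ar1 = 0.3),
                              op, snr_db = 30, seed = 7)
  yl <- st$sessions$clockwise[1:6]
  truth <- lapply(1:6, function(t) st$truth$clockwise$data[, , t])
  grid <- c(1e-4, 3e-3, 2e-2, 0.3)
  ls <- lambda_line_search(yl, op, lambdas = grid, truth = truth,
                           mask = ph$support,
                           cfg = recon_config(n_iter = 12))
  expect_equal(nrow(ls$table), 4)
  expect_true(ls$lambda %in% grid[-c(1, length(grid))])  # interior
  # single-element grid returns that element
  one <- lambda_line_search(yl[1:3], op, lambdas = 0.01,
                            mask = ph$support,
                            cfg = recon_config(n_iter = 5))
  expect_equal(one$lambda, 0.01)
  expect_error(lambda_line_search(yl, op, numeric(0)), "empty")
})
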