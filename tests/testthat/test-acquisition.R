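# Encoding operator: DFT convention, adjointness, off-resonance handling,
# EPI mask and sample timing.

test_that("unit impulse at the origin has a flat spectrum of modulus 1/sqrt(N)", {
  set.seed(2)
  shape <- c(16, 16)
  K <- matrix(runif(60, -1, 1), 30, 2)
  op <- encoding_operator(K, shape)
  m <- array(0 + 0i, shape)
  m[floor(16 / 2) + 1, floor(16 / 2) + 1] <- 1
  y <- encode(m, op)
  expect_true(all(abs(Mod(y$samples) - 1 / sqrt(prod(shape))) < 1e-12))
})

test_that("encode and encode_adjoint are exact adjoints and linear", {
  set.seed(3)
  shape <- c(12, 12, 8)
  coils <- make_coil_profiles(4, shape, seed = 2)
  fmap <- make_field_map(shape, max_hz = 40, seed = 3)
  K <- matrix(runif(3 * 200, -1, 1), 200, 3)
  times <- seq(0, 25e-3, length.out = 200) + 15e-3

  for (op in list(encoding_operator(K, shape, coils),
                  encoding_operator(K, shape, coils, fmap, times = times),
                  encoding_operator(K, shape, coils, fmap, times = times,
                                    method = "exact"),
                  encoding_operator(epi_sampling_mask(shape, 2, 2, 6 / 8),
                                    shape, coils, fmap))) {
    expect_lt(adjointness_error(op), 1e-6)
  }

  # linearity in the image argument
  op <- encoding_operator(K, shape, coils)
  N <- prod(shape)
  x1 <- array(complex(real = rnorm(N), imaginary = rnorm(N)), shape)
  x2 <- array(complex(real = rnorm(N), imaginary = rnorm(N)), shape)
  lhs <- op$forward(2 * x1 - 3i * x2)
  rhs <- 2 * op$forward(x1) - 3i * op$forward(x2)
  expect_lt(max(Mod(lhs - rhs)), 1e-10)

  # zero data -> zero volume
  expect_equal(max(Mod(op$adjoint(matrix(0 + 0i, 200, 4)))), 0)
})

test_that("fully sampled Cartesian encoding is unitary", {
  shape <- c(16, 16)
  full <- epi_sampling_mask(shape, 1, 1, 1)
  op <- encoding_operator(full, shape)
  set.seed(9)
  x <- array(complex(real = rnorm(256), imaginary = rnorm(256)), shape)
  expect_lt(max(Mod(op$adjoint(op$forward(x)) - x)), 1e-6)

  # FFT backend agrees with the NDFT at the grid frequencies
  opn <- encoding_operator(full$points, shape)
  expect_lt(max(Mod(op$forward(x) - opn$forward(x))), 1e-10)
})

test_that("time segmentation tracks the brute-force off-resonance model", {
  set.seed(4)
  shape <- c(8, 8, 8)
  fmap <- make_field_map(shape, max_hz = 50, seed = 3)
  coils <- make_coil_profiles(4, shape, seed = 2)
  K <- matrix(runif(3 * 300, -1, 1), 300, 3)
  times <- seq(0, 26.88e-3, length.out = 300) + 20e-3
  x <- array(complex(real = rnorm(512), imaginary = rnorm(512)), shape)
  op_seg <- encoding_operator(K, shape, coils, fmap, times = times,
                              n_segments = 8)
  op_ex <- encoding_operator(K, shape, coils, fmap, times = times,
                             method = "exact")
  ys <- op_seg$forward(x); ye <- op_ex$forward(x)
  expect_lt(sqrt(sum(Mod(ys - ye)^2) / sum(Mod(ye)^2)), 1e-3)

  # constant offset factorizes into a global per-sample phase
  fconst <- fmap; fconst$delta_b0 <- array(7, shape)
  op0 <- encoding_operator(K, shape, coils)
  opc <- encoding_operator(K, shape, coils, fconst, times = times,
                           method = "exact")
  expect_lt(max(Mod(opc$forward(x) -
                      op0$forward(x) * exp(-1i * 2 * pi * 7 * times))), 1e-9)
})

test_that("EPI mask keeps the prescribed fraction inside the partial-Fourier window", {
  em <- epi_sampling_mask(c(64, 64, 32), r_phase = 4, r_partition = 2,
                          pf = 6 / 8)
  expect_equal(length(em$idx) / prod(c(64, 64, 32)),
               (1 / 4) * (1 / 2) * (6 / 8) * (6 / 8))
  # contained in the partial-Fourier window along both phase axes
  sub <- arrayInd(em$idx, c(64, 64, 32))
  expect_true(all(sub[, 2] > (1 - 6 / 8) * 64))
  expect_true(all(sub[, 3] > (1 - 6 / 8) * 32))

  full <- epi_sampling_mask(c(16, 16), 1, 1, 1)
  expect_equal(length(full$idx), 256)
  expect_error(epi_sampling_mask(c(30, 30), r_phase = 4), "divisible")
})

test_that("sample times are anchored at TE and match the readout preset", {
  K <- fx_pattern_small()
  tm <- sample_times(K, dt = 1e-4, te = 20e-3)
  per_shot <- matrix(tm, K$Ns, K$Nc)
  expect_equal(per_shot[K$te_index, 1], 20e-3)
  expect_true(all(diff(per_shot[, 1]) > 0))
  expect_equal(max(per_shot[, 1]) - min(per_shot[, 1]), (K$Ns - 1) * 1e-4)

  # paper-scale preset: (Ns - 1) dt reproduces the 26.88 ms readout
  preset <- paper_scale_preset()
  expect_equal((preset$Ns - 1) * preset$dt, 26.88e-3, tolerance = 0.1e-3 / 26.88e-3)
})

test_that("density-compensation weights cap at the plateau and normalize", {
  pts <- rbind(c(0, 0), c(0.1, 0), c(0.5, 0), c(0.9, 0))
  w <- dcf_weights(pts, C = 0.25, D = 2)
  expect_equal(mean(w), 1)
  expect_equal(w[1], w[2])          # inside the plateau
  expect_gt(w[4], w[3])             # grows outward with |k|
})
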