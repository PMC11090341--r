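# Variable-density target, attraction-repulsion energy, constraint
# projection and pattern optimization.

test_that("target density has the plateau/decay shape and unit mass", {
  rho <- target_density(0.25, 2, c(32, 32, 32))
  expect_equal(sum(rho$grid) * rho$cell_volume, 1, tolerance = 1e-9)

  # plateau value inside C, power-law decay outside: value ratio at
  # |x| = 0.5 vs the plateau is (C/0.5)^D = 0.25
  r <- as.vector(rho$radius)
  v <- as.vector(rho$grid)
  plateau <- mean(v[r < 0.2])
  at_half <- v[which.min(abs(r - 0.5))]
  expect_equal(at_half / plateau, 0.25, tolerance = 0.02)

  # radially non-increasing beyond C
  o <- order(r)
  vo <- v[o][r[o] >= 0.25]
  expect_true(all(diff(vo) <= 1e-9))

  # D = 0 gives a uniform density
  u <- target_density(0.4, 0, c(16, 16))
  expect_lt(diff(range(u$grid)), 1e-12)

  expect_error(target_density(0, 2, c(32, 32)), "C must")
  expect_error(target_density(0.25, 2, c(4, 4)), ">= 8")
})

test_that("energy matches the brute-force double sums", {
  rho <- target_density(0.25, 2, c(16, 16, 16))
  # repulsion: p = 2, points at distance 1 -> Fr = (1/(2*4)) * 2 = 0.25
  pts <- rbind(c(0, 0, 0), c(1, 0, 0))
  e <- sparkling_energy(pts, rho)
  expect_equal(e$Fr, 0.25, tolerance = 1e-12)

  # attraction oracle: independent Riemann double sum
  set.seed(1)
  pts2 <- matrix(runif(5 * 3, -0.8, 0.8), 5, 3)
  w <- as.vector(rho$grid) * rho$cell_volume
  fa_brute <- mean(vapply(seq_len(nrow(pts2)), function(i) {
    sum(sqrt(colSums((t(rho$coords) - pts2[i, ])^2)) * w)
  }, 0))
  e2 <- sparkling_energy(pts2, rho)
  expect_equal(e2$Fa, fa_brute, tolerance = 1e-10)

  # repulsion oracle + translation invariance
  fr_brute <- 0
  for (i in 1:5) for (j in 1:5)
    fr_brute <- fr_brute + sqrt(sum((pts2[i, ] - pts2[j, ])^2))
  fr_brute <- fr_brute / (2 * 25)
  expect_equal(e2$Fr, fr_brute, tolerance = 1e-12)
  # translation invariance (tolerance reflects the cancellation error of
  # the fast pairwise-distance evaluation, ~sqrt(machine eps))
  shifted <- sweep(pts2, 2, c(0.1, -0.05, 0.02), "+")
  expect_equal(sparkling_energy(shifted, rho)$Fr, e2$Fr, tolerance = 1e-7)

  expect_error(sparkling_energy(matrix(0, 0, 3), rho), "empty")
})

test_that("speed/acceleration bounds follow the hardware formulas", {
  # independent unit-tracking oracle in Hz/T (gamma_bar = gamma / 2pi):
  # alpha = min(gamma_bar * Gmax, 1/(FOV dt)) / Kmax, beta = gamma_bar *
  # Smax / Kmax
  gamma_bar <- 42.576e6
  Gmax <- 40e-3; Smax <- 180; FOV <- 0.192; dt <- 2e-6; Kmax <- 1 / (2 * 0.001)
  oracle_alpha <- min(gamma_bar * Gmax, 1 / (FOV * dt)) / Kmax
  oracle_beta <- gamma_bar * Smax / Kmax
  ab <- speed_accel_bounds(Gmax, Smax, gamma = 2 * pi * gamma_bar,
                           dt = dt, FOV = FOV, Kmax = Kmax)
  expect_equal(ab$alpha, oracle_alpha, tolerance = 1e-12)
  expect_equal(ab$beta, oracle_beta, tolerance = 1e-12)

  # Gmax -> Inf collapses the min to the sampling-rate limit
  ab_inf <- speed_accel_bounds(1e9, Smax, dt = dt, FOV = FOV, Kmax = Kmax)
  expect_equal(ab_inf$alpha, 1 / (Kmax * FOV * dt), tolerance = 1e-12)
  # doubling Smax doubles beta
  ab2 <- speed_accel_bounds(Gmax, 2 * Smax, dt = dt, FOV = FOV, Kmax = Kmax)
  expect_equal(ab2$beta, 2 * ab$beta, tolerance = 1e-12)
  expect_error(speed_accel_bounds(-1, Smax, dt = dt, FOV = FOV, Kmax = Kmax),
               "positive")
})

test_that("projection enforces TE crossing and derivative bounds", {
  hw <- fx_hw()
  te <- 25
  # feasible straight shot is a fixed point
  u <- c(cos(0.3), sin(0.3))
  shot <- outer((seq_len(48) - te) * hw$step_max * 0.5, u)
  proj <- project_shot(shot, te, hw)
  expect_lt(max(abs(proj - shot)), 1e-12)

  # TE offset is removed exactly
  shifted <- sweep(shot, 2, c(0.3, 0), "+")
  proj2 <- project_shot(shifted, te, hw)
  expect_lt(sqrt(sum(proj2[te, ]^2)), 1e-9)

  # random infeasible shots: independent finite-difference audit
  set.seed(4)
  for (rep in 1:5) {
    bad <- matrix(runif(48 * 2, -1, 1), 48, 2)
    pr <- project_shot(bad, te, hw, tol = 1e-3)
    d1 <- diff(pr); d2 <- diff(d1)
    expect_lt(sqrt(sum(pr[te, ]^2)), 1e-9)
    expect_lte(max(sqrt(rowSums(d1^2))), hw$step_max * (1 + 1e-3))
    expect_lte(max(sqrt(rowSums(d2^2))), hw$accel_max * (1 + 1e-3))
    expect_lte(max(abs(pr)), 1 + 1e-12)
  }
  bad_hw <- fx_hw(); bad_hw$step_max <- 0
  expect_error(project_shot(shot, te, bad_hw), "infeasible")
})

test_that("optimization descends, fits the density better, and stays feasible", {
  hw <- fx_hw()
  rho <- fx_density2d()
  K0 <- init_radial_pattern(8, 64, d = 2, hw = hw, seed = 5)
  e0 <- sparkling_energy(K0, rho)$F
  K <- optimize_pattern(K0, rho, n_iter = 40)
  trace <- attr(K, "energy_trace")

  expect_lte(sparkling_energy(K, rho)$F, e0)
  expect_true(all(diff(trace) <= 1e-12))

  ks0 <- radial_ks_distance(pattern_points(K0), rho)
  ks1 <- radial_ks_distance(pattern_points(K), rho)
  expect_lt(ks1, ks0)

  # constraint audit on every optimized shot
  aud <- pattern_audit(K)
  expect_lt(aud$te, 1e-9)
  expect_lte(aud$speed, 1e-3)
  expect_lte(aud$accel, 1e-3)

  # determinism: identical seeds give bitwise-identical patterns
  K0b <- init_radial_pattern(8, 64, d = 2, hw = hw, seed = 5)
  Kb <- optimize_pattern(K0b, rho, n_iter = 40)
  expect_identical(pattern_points(K), pattern_points(Kb))

  # the paper-scale shot count is accepted
  K48 <- init_radial_pattern(48, 16, d = 2, hw = hw, seed = 1)
  expect_equal(K48$Nc, 48)
})

test_that("attraction is minimized at the density's center of mass", {
  rho <- target_density(0.5, 1, c(32, 32))
  w <- as.vector(rho$grid) * rho$cell_volume
  # grid search over single-point patterns
  cand <- as.matrix(expand.grid(seq(-0.6, 0.6, 0.2), seq(-0.6, 0.6, 0.2)))
  fa <- apply(cand, 1, function(p) sparkling_energy(rbind(p), rho)$Fa)
  best <- cand[which.min(fa), ]
  com <- colSums(rho$coords * w)
  expect_lt(sqrt(sum((best - com)^2)), 0.3)
  # point mass exactly at a lattice site: Fa = 0
  rho_pt <- rho
  rho_pt$grid[] <- 0
  idx <- which.min(rowSums((rho$coords)^2))
  rho_pt$grid[idx] <- 1 / rho_pt$cell_volume
  expect_lt(sparkling_energy(rbind(rho$coords[idx, ]), rho_pt)$Fa, 1e-12)
})

test_that("gradient waveforms invert exactly and respect limits", {
  hw <- fx_hw()
  K <- fx_pattern_small()
  s <- K$shots[[3]]
  wf <- gradient_waveforms(s, hw)
  back <- integrate_waveforms(wf, hw)
  expect_lt(max(abs(back - s)), 1e-9)
  expect_lte(max(abs(wf$G / 1e3)), hw$Gmax + 1e-12)

  # constant-velocity straight shot -> constant gradient
  u <- c(1, 0)
  straight <- outer((1:20) * 0.01, u)
  wfs <- gradient_waveforms(straight, hw)
  expect_lt(diff(range(wfs$G[, 1])), 1e-12)

  # slew audit: discrete diff of the waveform bounded by Smax * dt
  d <- diff(wf$G / 1e3)
  expect_lte(max(sqrt(rowSums(d^2))), hw$Smax * hw$dt * (1 + 1e-3))
})

test_that("PSF of full Cartesian sampling is a unit-width peak at the origin", {
  full <- epi_sampling_mask(c(32, 32), 1, 1, 1)
  pr <- psf_report(full$points, c(32, 32))
  expect_equal(pr$fwhm, c(1, 1), tolerance = 0.1)
  expect_equal(pr$peak, floor(c(32, 32) / 2) + 1)
  expect_gte(pr$mslr, 1)

  # undersampled non-Cartesian pattern cannot beat the fully sampled FWHM
  K <- fx_pattern_small()
  pr2 <- psf_report(K, c(32, 32))
  expect_true(all(pr2$fwhm >= pr$fwhm - 0.1))
  expect_gte(pr2$mslr, 1)

  expect_error(psf_report(matrix(0, 0, 2), c(16, 16)), "empty")
})

test_that("patterns export to plain text with one sample per line", {
  K <- fx_pattern_small()
  f <- tempfile(fileext = ".csv")
  export_pattern(K, f)
  df <- read.csv(f)
  expect_equal(nrow(df), K$p)
  expect_equal(names(df), c("shot", "sample", "kx", "ky"))
  expect_equal(max(df$shot), K$Nc)
  unlink(f)
})
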