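# Shared fixtures, built lazily and cached for the session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# hardware with a desk-scale dwell so 64-sample shots can span k-space
fx_hw <- function() fixture("hw", function() {
  hardware_constraints(dt = 5e-4, Kmax = 1 / (2 * 0.003))
})

fx_density2d <- function() fixture("rho2d", function() {
  target_density(0.25, 2, c(64, 64))
})

fx_phantom32 <- function() fixture("ph32", function() make_phantom(c(32, 32), seed = 2))

fx_phantom64 <- function() fixture("ph64", function() {
  make_phantom(c(64, 64), voxel_mm = 3, seed = 2)
})

fx_pattern_small <- function() fixture("pat_small", function() {
  init_radial_pattern(8, 48, d = 2, hw = fx_hw(), seed = 5)
})

# two-session design with smooth non-degenerate motion regressors
fx_design120 <- function() fixture("design120", function() {
  build_design(120, 2.4, 32,
               motion1 = simulate_motion(120, seed = 11),
               motion2 = simulate_motion(120, seed = 12))
})

# helper: relative inner-product adjointness error of an operator
adjointness_error <- function(op, seed = 1) {
  set.seed(seed)
  N <- prod(op$shape)
  x <- array(complex(real = rnorm(N), imaginary = rnorm(N)), op$shape)
  y <- matrix(complex(real = rnorm(op$M * op$n_coils),
                      imaginary = rnorm(op$M * op$n_coils)),
              op$M, op$n_coils)
  lhs <- sum(Conj(op$forward(x)) * y)
  rhs <- sum(Conj(x) * op$adjoint(y))
  Mod(lhs - rhs) / Mod(lhs)
}
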