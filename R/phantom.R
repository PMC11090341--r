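# Brain-like numerical phantom with tissue maps and a retinotopically
# organized visual ROI.

#' Build a brain-like phantom
#'
#' Deterministic (given `seed`) concentric smoothed compartments: a CSF
#' shell, a gray-matter ribbon and a white-matter core inside an elliptical
#' support, plus a posterior "visual cortex" patch of GM-dominant voxels
#' carrying polar angles arranged as mirrored hemifields (the angle of a
#' ROI voxel is its geometric polar angle around the occipital pole, so
#' left- and right-hemisphere voxels carry angles of opposite sign).
#'
#' @param shape Lattice dimensions (length 2 or 3), each >= 24.
#' @param voxel_mm Voxel size in mm (default 3).
#' @param seed Seed for the smooth boundary perturbation.
#' @return Object of class `phantom` with fields `gm`, `wm`, `csf`
#'   (probability arrays), `support` (logical), `roi` (logical),
#'   `phi_v` (polar angle array, NA outside the ROI), `t2s_image`
#'   (baseline anatomical-contrast image), `shape`, `voxel_mm`.
#' @export
make_phantom <- function(shape, voxel_mm = 3, seed = 1) {
  shape <- as.integer(shape)
  d <- length(shape)
  if (d < 2 || d > 3) stop_param("shape must have 2 or 3 entries")
  if (any(shape < 24)) stop_param("each dimension must be >= 24")

  grid <- centered_grid(shape)
  semi <- shape / 2 * 0.9
  # normalized elliptical radius, seeded smooth angular perturbation
  re <- sqrt(rowSums(sweep(grid, 2, semi, "/")^2))
  ang <- atan2(grid[, 2], grid[, 1])
  pert <- with_seed(seed, {
    a <- stats::rnorm(3, sd = 0.02)
    b <- stats::rnorm(3, sd = 0.02)
    a[1] * cos(ang) + a[2] * cos(2 * ang) + a[3] * cos(3 * ang) +
      b[1] * sin(ang) + b[2] * sin(2 * ang) + b[3] * sin(3 * ang)
  })
  re <- re + pert

  support <- array(re <= 1, dim = shape)
  # soft radial memberships (logistic bands), then clipped so sums <= 1
  band <- function(lo, hi, s = 0.04) {
    1 / (1 + exp(-(re - lo) / s)) * (1 - 1 / (1 + exp(-(re - hi) / s)))
  }
  wm <- 1 - 1 / (1 + exp(-(re - 0.55) / 0.04))
  gm <- band(0.55, 0.80)
  csf <- band(0.80, 1.00)
  tot <- wm + gm + csf
  sc <- ifelse(tot > 1, 1 / tot, 1)
  wm <- array(wm * sc * support, dim = shape)
  gm <- array(gm * sc * support, dim = shape)
  csf <- array(csf * sc * support, dim = shape)

  # posterior visual ROI: GM-dominant voxels near the occipital pole
  # (posterior = negative axis-2 direction), angles measured around it
  pole <- c(0, -semi[2] * 0.675, if (d == 3) 0)
  rel <- sweep(grid[, seq_len(min(d, 3)), drop = FALSE], 2, pole[seq_len(d)], "-")
  dist_pole <- sqrt(rowSums(sweep(rel, 2, c(1, 1, 2)[seq_len(d)] / min(semi), "*")^2)) * min(semi)
  roi_vec <- gm > 0.5 & gm >= wm & gm >= csf & dist_pole <= 0.30 * min(semi)
  roi <- array(roi_vec, dim = shape)
  phi <- array(NA_real_, dim = shape)
  # mirrored hemifields: angle of the voxel around the pole, in-plane
  phi[roi] <- atan2(rel[roi_vec, 1], -rel[roi_vec, 2])

  t2s <- 0.25 * wm + 0.75 * gm + 1.0 * csf

  structure(list(gm = gm, wm = wm, csf = csf, support = support,
                 roi = roi, phi_v = phi, t2s_image = t2s,
                 shape = shape, voxel_mm = voxel_mm, seed = seed),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("Phantom %s (%g mm voxels): %d support voxels, %d ROI voxels\n",
              paste(x$shape, collapse = "x"), x$voxel_mm,
              sum(x$support), sum(x$roi)))
  invisible(x)
}

#' Smooth multi-coil sensitivity profiles
#'
#' Gaussian-lobed complex profiles centered on a ring around the object,
#' normalized so the root-sum-of-squares magnitude is 1 at every voxel
#' inside the support mask.  `n_coils = 1` yields a single uniform
#' all-ones profile.
#'
#' @param n_coils Number of coils.
#' @param shape Lattice dimensions.
#' @param support Optional logical support mask (default: everywhere).
#' @param seed Seed for the coil phase offsets.
#' @return Object of class `coil_profiles` with `maps` (list of complex
#'   arrays) and `n_coils`.
#' @export
make_coil_profiles <- function(n_coils, shape, support = NULL, seed = 1) {
  shape <- as.integer(shape)
  d <- length(shape)
  if (n_coils == 1) {
    return(structure(list(maps = list(array(1 + 0i, dim = shape)),
                          n_coils = 1L), class = "coil_profiles"))
  }
  grid <- centered_grid(shape)
  radius <- max(shape) * 0.6
  width <- max(shape) * 0.6
  phases <- with_seed(seed, stats::runif(n_coils, -pi, pi))
  maps <- lapply(seq_len(n_coils), function(c) {
    th <- 2 * pi * (c - 1) / n_coils
    center <- c(radius * cos(th), radius * sin(th), if (d == 3) 0)
    d2 <- rowSums(sweep(grid, 2, center[seq_len(d)], "-")^2)
    mag <- exp(-d2 / (2 * width^2))
    array(mag * exp(1i * phases[c]), dim = shape)
  })
  rss <- sqrt(Reduce(`+`, lapply(maps, function(m) Mod(m)^2)))
  rss[rss == 0] <- 1
  maps <- lapply(maps, function(m) m / rss)
  if (!is.null(support)) maps <- lapply(maps, function(m) m * support)
  structure(list(maps = maps, n_coils = as.integer(n_coils)),
            class = "coil_profiles")
}

#' Smooth off-resonance field map
#'
#' Band-limited smooth field (a low-order sum of slowly varying spatial
#' harmonics) scaled so the maximum magnitude equals `max_hz`, and zeroed
#' outside the support mask.
#'
#' @param shape Lattice dimensions.
#' @param max_hz Maximum off-resonance magnitude in Hz.
#' @param support Optional logical support mask.
#' @param seed Seed for the harmonic coefficients.
#' @return Object of class `field_map` with `delta_b0` (Hz array) and
#'   `omega0 = 2 * pi * delta_b0` (rad/s).
#' @export
make_field_map <- function(shape, max_hz = 30, support = NULL, seed = 1) {
  shape <- as.integer(shape)
  d <- length(shape)
  grid <- centered_grid(shape)
  u <- sweep(grid, 2, shape / 2, "/")      # in [-1, 1]
  f <- with_seed(seed, {
    co <- stats::rnorm(7)
    val <- co[1] * u[, 1] + co[2] * u[, 2] +
      co[3] * cos(pi * u[, 1]) + co[4] * sin(pi * u[, 2]) +
      co[5] * u[, 1] * u[, 2]
    if (d == 3) val <- val + co[6] * u[, 3] + co[7] * cos(pi * u[, 3])
    val
  })
  if (max(abs(f)) > 0) f <- f / max(abs(f)) * max_hz
  b0 <- array(f, dim = shape)
  if (!is.null(support)) b0 <- b0 * support
  structure(list(delta_b0 = b0, omega0 = 2 * pi * b0, max_hz = max_hz),
            class = "field_map")
}
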