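# Synthetic retinotopic BOLD time series.

#' Retinotopy stimulation specification
#'
#' Defaults reproduce the study conditions: two runs of 120 volumes at a
#' volumetric TR of 2.4 s with a 32 s wedge period, i.e.
#' `ncyc = Nvol * TR / Pcyc = 9` full stimulus cycles per run.  The BOLD
#' response is modeled as a phase-delayed cosine: the analysis estimates
#' and removes exactly one haemodynamic phase delay `d_h`, so a delayed
#' cosine is sufficient and exactly identifiable.
#'
#' @param Nvol Volumes per run (default 120).
#' @param TR Volumetric repetition time in s (default 2.4).
#' @param Pcyc Wedge rotation period in s (default 32).
#' @param amplitude BOLD amplitude as percent signal change (default 2).
#' @param d_h Haemodynamic phase delay in rad (default pi/4, in [0, pi)).
#' @param baseline Baseline signal level (default 100).
#' @return List of class `retinotopy_spec`; `ncyc` is computed and must be
#'   a whole number of cycles.
#' @export
retinotopy_spec <- function(Nvol = 120, TR = 2.4, Pcyc = 32,
                            amplitude = 2, d_h = pi / 4, baseline = 100) {
  ncyc <- Nvol * TR / Pcyc
  if (abs(ncyc - round(ncyc)) > 1e-9)
    stop_param("Nvol * TR / Pcyc must be a whole number of cycles (got %g)", ncyc)
  if (amplitude < 0) stop_param("amplitude must be >= 0")
  structure(list(Nvol = as.integer(Nvol), TR = TR, Pcyc = Pcyc,
                 ncyc = round(ncyc), amplitude = amplitude,
                 d_h = d_h, baseline = baseline),
            class = "retinotopy_spec")
}

#' Noise specification for BOLD series
#'
#' @param sigma Marginal noise SD in signal units (default 2, i.e. a
#'   temporal SNR near 50 at the default baseline of 100).
#' @param ar1 Lag-1 autocorrelation of the AR(1) noise, |ar1| < 1
#'   (default 0.3).
#' @param drift_slope Linear drift in signal units per volume (default 0.01).
#' @param seed RNG seed.
#' @return List of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 2, ar1 = 0.3, drift_slope = 0.01, seed = 1) {
  if (abs(ar1) >= 1) stop_param("|ar1| must be < 1")
  if (sigma < 0) stop_param("sigma must be >= 0")
  structure(list(sigma = sigma, ar1 = ar1, drift_slope = drift_slope,
                 seed = seed), class = "noise_spec")
}

#' Stationary AR(1) series
#'
#' First-order autoregressive Gaussian noise with marginal standard
#' deviation `sigma` (the innovation SD is `sigma * sqrt(1 - ar1^2)`); the
#' first sample is drawn from the stationary distribution.
#'
#' @param n Length of the series.
#' @param ar1 Lag-1 autocorrelation.
#' @param sigma Marginal SD.
#' @param seed RNG seed (NULL = use current RNG state).
#' @param ncol Number of independent series (returns a matrix if > 1).
#' @return Numeric vector (or n x ncol matrix).
#' @export
ar1_series <- function(n, ar1, sigma, seed = NULL, ncol = 1) {
  if (abs(ar1) >= 1) stop_param("|ar1| must be < 1")
  gen <- function() {
    if (sigma == 0) return(matrix(0, n, ncol))
    e <- matrix(stats::rnorm(n * ncol), n, ncol)
    out <- matrix(0, n, ncol)
    out[1, ] <- e[1, ] * sigma
    if (n > 1) {
      innov_sd <- sigma * sqrt(1 - ar1^2)
      for (t in 2:n) out[t, ] <- ar1 * out[t - 1, ] + innov_sd * e[t, ]
    }
    out
  }
  out <- if (is.null(seed)) gen() else with_seed(seed, gen())
  if (ncol == 1) drop(out) else out
}

#' Simulate a retinotopic BOLD run
#'
#' Voxelwise signal model: for ROI voxels
#' \deqn{y(t) = baseline + drift\cdot t + a \cos(2\pi n_{cyc} t / N_{vol}
#'   - s\,\varphi_v - d_h + \psi_s) + \epsilon(t)}
#' with `s = +1` for the clockwise and `s = -1` for the counter-clockwise
#' wedge, `a = amplitude/100 * baseline`, and AR(1) Gaussian noise
#' \eqn{\epsilon}.  Non-ROI support voxels carry baseline, drift and noise
#' only.  The session phase origin \eqn{\psi_s} (0 for clockwise, \eqn{\pi}
#' for counter-clockwise) fixes where the wedge starts; it is chosen so
#' that the standard regressor pair and phase-map estimator recover
#' \eqn{\varphi_v} exactly on noiseless data, and is recorded in the
#' series metadata.
#'
#' @param ph A [make_phantom()] object.
#' @param spec A [retinotopy_spec()].
#' @param noise A [noise_spec()].
#' @param session `"clockwise"` or `"counterclockwise"`.
#' @param motion Optional Nvol x 6 motion-regressor matrix; when given, a
#'   motion-coupled signal component `motion %*% motion_coef` is added to
#'   every support voxel.
#' @param motion_coef Coupling coefficients (length 6, default 0.5 signal
#'   units per unit regressor).
#' @param seed RNG seed for the noise (defaults to `noise$seed`).
#' @return Object of class `bold_series`: `data` (array shape x Nvol),
#'   `TR`, `session`, `mask` (phantom support), `spec`, and the phase
#'   origin `psi`.
#' @export
simulate_bold_series <- function(ph, spec = retinotopy_spec(),
                                 noise = noise_spec(),
                                 session = c("clockwise", "counterclockwise"),
                                 motion = NULL, motion_coef = rep(0.5, 6),
                                 seed = noise$seed) {
  session <- match.arg(session)
  s_sign <- if (session == "clockwise") 1 else -1
  psi <- if (session == "clockwise") 0 else pi
  Nvol <- spec$Nvol
  tt <- seq_len(Nvol) - 1
  omega <- 2 * pi * spec$ncyc / Nvol
  amp <- spec$amplitude / 100 * spec$baseline

  mask_idx <- which(ph$support)
  V <- length(mask_idx)
  noise_mat <- ar1_series(Nvol, noise$ar1, noise$sigma, seed = seed, ncol = V)
  if (V == 1) noise_mat <- matrix(noise_mat, ncol = 1)

  base_t <- spec$baseline + noise$drift_slope * tt
  sig <- matrix(base_t, Nvol, V) + noise_mat

  roi_in_mask <- which(ph$roi[mask_idx])
  if (length(roi_in_mask) > 0 && amp > 0) {
    phis <- ph$phi_v[mask_idx[roi_in_mask]]
    task <- outer(omega * tt, rep(1, length(phis)))
    task <- sweep(task, 2, s_sign * phis + spec$d_h - psi, "-")
    sig[, roi_in_mask] <- sig[, roi_in_mask] + amp * cos(task)
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != Nvol) stop_param("motion series length mismatch")
    sig <- sig + as.vector(motion %*% motion_coef[seq_len(ncol(motion))])
  }

  data <- array(0, dim = c(ph$shape, Nvol))
  flat <- matrix(data, prod(ph$shape), Nvol)
  flat[mask_idx, ] <- t(sig)
  data <- array(flat, dim = c(ph$shape, Nvol))

  structure(list(data = data, TR = spec$TR, session = session,
                 mask = ph$support, spec = spec, psi = psi,
                 motion = motion), class = "bold_series")
}

#' Simulate rigid-body motion regressor series
#'
#' Six smooth low-amplitude series (three translations in mm, three
#' rotations in rad) modeled as slow AR(1) random walks, the standard
#' shape of realignment-parameter traces.  Needed to exercise the full
#' 20-column design: absent motion leaves all-zero columns and a
#' rank-deficient model.
#'
#' @param Nvol Number of volumes.
#' @param scale Marginal SD of each series (default 0.05).
#' @param seed RNG seed.
#' @return Nvol x 6 matrix.
#' @export
simulate_motion <- function(Nvol, scale = 0.05, seed = 1) {
  m <- ar1_series(Nvol, 0.95, scale, seed = seed, ncol = 6)
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("BOLD series (%s): %s x %d volumes, TR = %g s\n",
              x$session, paste(d[-length(d)], collapse = "x"),
              d[length(d)], x$TR))
  invisible(x)
}
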