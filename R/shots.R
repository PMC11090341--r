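# Single-shot feasibility: echo-time crossing, speed and slew projection,
# gradient waveforms.

#' Audit the hardware feasibility of a shot
#'
#' Independent finite-difference check of the constraint set: the sample at
#' `te_index` must sit at the k-space origin, consecutive sample steps must
#' not exceed `alpha * dt`, discrete second differences must not exceed
#' `beta * dt^2`, and every sample must lie in `[-1, 1]^d`.
#'
#' @param samples Ns x d matrix of normalized k-space samples.
#' @param te_index Index (1-based) of the sample pinned to the origin.
#' @param hw A [hardware_constraints()] object.
#' @return Named list of worst-case violations: `te` (distance of the TE
#'   sample from the origin), `speed` and `accel` (relative excess over the
#'   bounds, <= 0 when satisfied), `box` (excess over the domain boundary).
#' @export
shot_audit <- function(samples, te_index, hw) {
  samples <- as.matrix(samples)
  d1 <- diff(samples)
  d2 <- diff(d1)
  list(
    te = sqrt(sum(samples[te_index, ]^2)),
    speed = if (nrow(d1) > 0) max(row_norms(d1)) / hw$step_max - 1 else -1,
    accel = if (nrow(d2) > 0) max(row_norms(d2)) / hw$accel_max - 1 else -1,
    box = max(abs(samples)) - 1
  )
}

# column-wise cumulative sum that always returns a matrix
.colcumsum <- function(m) {
  out <- apply(m, 2, cumsum)
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(m))
  out
}

# rebuild sample positions from first differences so that samples[te] = 0
.rebuild_from_diffs <- function(d1, te_index, ns, dims) {
  k <- matrix(0, ns, dims)
  if (ns > 1) k[-1, ] <- .colcumsum(d1)
  sweep(k, 2, k[te_index, ], "-")
}

#' Project a shot onto the constraint set
#'
#' Cyclic projection enforcing, in turn: the box `[-1, 1]^d`, the echo-time
#' crossing (`samples[te_index] = 0`, by translation, which leaves all
#' discrete differences unchanged), the speed bound (first differences
#' clipped to `alpha * dt`), and the slew bound (second differences clipped
#' to `beta * dt^2`).  The cycle is iterated until the worst relative
#' violation is below `tol` or `max_iter` cycles have run.  A feasible input
#' is returned unchanged.
#'
#' @param samples Ns x d matrix of normalized k-space samples.
#' @param te_index Index of the echo-time sample.
#' @param hw A [hardware_constraints()] object.
#' @param tol Relative violation tolerance (default 1e-3).
#' @param max_iter Maximum number of projection cycles (default 50).
#' @return Projected Ns x d matrix.
#' @export
project_shot <- function(samples, te_index, hw, tol = 1e-3, max_iter = 50) {
  if (hw$step_max <= 0 || hw$accel_max <= 0)
    stop_param("infeasible constraints: alpha and beta must be positive")
  k <- as.matrix(samples)
  if (any(!is.finite(k))) stop_param("shot contains non-finite coordinates")
  ns <- nrow(k); dims <- ncol(k)
  if (te_index < 1 || te_index > ns) stop_param("te_index out of range")

  feasible <- function(k) {
    a <- shot_audit(k, te_index, hw)
    a$te <= 1e-12 && a$speed <= tol && a$accel <= tol && a$box <= 1e-12
  }
  if (feasible(k)) return(k)

  for (it in seq_len(max_iter)) {
    # box
    k <- pmin(pmax(k, -1), 1)
    # TE crossing by translation (preserves differences)
    k <- sweep(k, 2, k[te_index, ], "-")
    # speed: clip first differences
    if (ns > 1) {
      d1 <- diff(k)
      nrm <- row_norms(d1)
      sc <- pmin(1, hw$step_max / pmax(nrm, .Machine$double.eps))
      d1 <- d1 * sc
      k <- .rebuild_from_diffs(d1, te_index, ns, dims)
    }
    # slew: clip second differences, rebuild differences then positions
    if (ns > 2) {
      d1 <- diff(k)
      d2 <- diff(d1)
      nrm <- row_norms(d2)
      sc <- pmin(1, hw$accel_max / pmax(nrm, .Machine$double.eps))
      d2 <- d2 * sc
      d1_new <- matrix(0, ns - 1, dims)
      d1_new[1, ] <- d1[1, ]
      d1_new[-1, ] <- sweep(.colcumsum(d2), 2, d1[1, ], "+")
      k <- .rebuild_from_diffs(d1_new, te_index, ns, dims)
    }
    if (feasible(k)) break
  }
  # final exact TE anchoring
  sweep(k, 2, k[te_index, ], "-")
}

#' Gradient waveforms realizing a shot
#'
#' Converts the discrete k-space steps of a feasible shot into the gradient
#' amplitudes that drive them, using \eqn{k(t) = (\gamma/2\pi)\int G\,d\tau}
#' in physical units and the normalization by `Kmax`.  The waveform has
#' `Ns - 1` entries, one per sample-to-sample transition; integrating it
#' (cumulative sum scaled by \eqn{\gamma \delta t / 2\pi} and de-normalized
#' by `Kmax`) from the first sample reproduces the shot exactly.
#'
#' @param samples Ns x d matrix of normalized k-space samples.
#' @param hw A [hardware_constraints()] object.
#' @return List with `G` ((Ns-1) x d gradient amplitudes in mT/m), `k0`
#'   (first sample, the integration anchor) and `dt`.
#' @export
gradient_waveforms <- function(samples, hw) {
  samples <- as.matrix(samples)
  gamma_bar <- hw$gamma / (2 * pi)               # Hz/T
  d1 <- diff(samples)                            # normalized k steps
  # normalized step = gamma_bar * G * dt / Kmax  =>  G in T/m
  G <- d1 * hw$Kmax / (gamma_bar * hw$dt)
  list(G = G * 1e3, k0 = samples[1, ], dt = hw$dt)
}

#' Integrate gradient waveforms back to k-space samples
#'
#' Inverse of [gradient_waveforms()]; used to audit the round trip.
#'
#' @param wf List as returned by [gradient_waveforms()].
#' @param hw A [hardware_constraints()] object.
#' @return Ns x d matrix of normalized k-space samples.
#' @export
integrate_waveforms <- function(wf, hw) {
  gamma_bar <- hw$gamma / (2 * pi)
  d1 <- (wf$G / 1e3) * gamma_bar * hw$dt / hw$Kmax
  ns <- nrow(d1) + 1
  k <- matrix(0, ns, ncol(d1))
  k[1, ] <- wf$k0
  if (ns > 1) k[-1, ] <- sweep(.colcumsum(d1), 2, wf$k0, "+")
  k
}
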