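# Gradient-hardware constraints expressed in normalized k-space units.

#' Speed and acceleration bounds from gradient hardware limits
#'
#' Converts physical gradient system limits into bounds on the k-space
#' velocity and acceleration of a shot, in normalized units (k-space scaled
#' to `[-1, 1]` by `Kmax`) per second.  With the gyromagnetic ratio
#' \eqn{\gamma} in rad/s/T, the velocity bound is
#' \deqn{\alpha = \frac{1}{K_{max}}\min\left(\frac{\gamma G_{max}}{2\pi},
#'   \frac{1}{FOV\,\delta t}\right)}
#' (the first term is the gradient-amplitude limit, the second the
#' sampling-rate/Nyquist limit), and the acceleration bound is
#' \deqn{\beta = \frac{\gamma S_{max}}{2\pi K_{max}}.}
#'
#' @param Gmax Maximum gradient amplitude (T/m).
#' @param Smax Maximum slew rate (T/m/s).
#' @param gamma Gyromagnetic ratio (rad/s/T); default is the proton value
#'   \eqn{2\pi \times 42.576\times 10^{6}}.
#' @param dt Dwell (raster) time between consecutive samples (s).
#' @param FOV Field of view per axis (m).
#' @param Kmax k-space extent per axis (1/m); defaults to `1 / (2 * res)`
#'   where `res` is the voxel size implied by `FOV` and is not needed if
#'   `Kmax` is given directly.
#' @return Named list with `alpha` and `beta` (normalized units per second
#'   and per second squared).
#' @export
speed_accel_bounds <- function(Gmax, Smax, gamma = 2 * pi * 42.576e6,
                               dt, FOV, Kmax) {
  vals <- c(Gmax = Gmax, Smax = Smax, gamma = gamma, dt = dt,
            FOV = FOV, Kmax = Kmax)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_param("all hardware parameters must be positive and finite")
  }
  alpha <- (1 / Kmax) * min(gamma * Gmax / (2 * pi), 1 / (FOV * dt))
  beta <- gamma * Smax / (2 * pi * Kmax)
  list(alpha = alpha, beta = beta)
}

#' Hardware constraint set for trajectory design
#'
#' Bundles the physical gradient limits with their normalized-unit
#' counterparts.  `alpha` and `beta` bound the norm of the first and second
#' time derivatives of a shot in normalized k-space; the per-sample discrete
#' bounds used by the projection are `alpha * dt` and `beta * dt^2`.
#'
#' @inheritParams speed_accel_bounds
#' @return Object of class `hardware_constraints`.
#' @examples
#' hw <- hardware_constraints(Gmax = 40e-3, Smax = 180, dt = 2e-6,
#'                            FOV = 0.192, Kmax = 500)
#' hw$alpha
#' @export
hardware_constraints <- function(Gmax = 40e-3, Smax = 180,
                                 gamma = 2 * pi * 42.576e6,
                                 dt = 2e-6, FOV = 0.192,
                                 Kmax = 1 / (2 * 0.001)) {
  ab <- speed_accel_bounds(Gmax, Smax, gamma, dt, FOV, Kmax)
  structure(list(
    Gmax = Gmax, Smax = Smax, gamma = gamma, dt = dt, FOV = FOV, Kmax = Kmax,
    alpha = ab$alpha, beta = ab$beta,
    step_max = ab$alpha * dt,        # max sample-to-sample k step
    accel_max = ab$beta * dt^2       # max discrete second difference
  ), class = "hardware_constraints")
}

#' Full-scale acquisition preset
#'
#' The acquisition geometry of the 7T protocol the package emulates at
#' reduced scale: 48 shots per volume at a 50 ms unitary TR (volumetric
#' TR `48 * 0.050 = 2.4` s), echo time 20 ms, and a readout of 26.88 ms
#' realized here as `Ns = 385` samples at a 70 us dwell
#' (`(Ns - 1) * dt = 26.88` ms).  The matrix/FOV give 1 mm isotropic
#' voxels (`Kmax = 500` 1/m).
#'
#' @return Named list: `Nc`, `Ns`, `dt`, `tr_unit`, `te`, `volumetric_tr`,
#'   `FOV`, `Kmax`, `C`, `D`.
#' @export
paper_scale_preset <- function() {
  list(Nc = 48L, Ns = 385L, dt = 70e-6, tr_unit = 50e-3, te = 20e-3,
       volumetric_tr = 48 * 50e-3, FOV = 0.192, Kmax = 1 / (2 * 0.001),
       C = 0.25, D = 2)
}

#' @export
print.hardware_constraints <- function(x, ...) {
  cat("Hardware constraints (normalized k-space in [-1,1]):\n")
  cat(sprintf("  Gmax = %g mT/m, Smax = %g T/m/s, dt = %g us\n",
              x$Gmax * 1e3, x$Smax, x$dt * 1e6))
  cat(sprintf("  FOV = %g mm, Kmax = %g 1/m\n", x$FOV * 1e3, x$Kmax))
  cat(sprintf("  alpha = %.4g /s (step <= %.4g per sample)\n",
              x$alpha, x$step_max))
  cat(sprintf("  beta  = %.4g /s^2 (2nd diff <= %.4g per sample^2)\n",
              x$beta, x$accel_max))
  invisible(x)
}
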