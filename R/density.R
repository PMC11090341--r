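# Variable-density sampling targets on the normalized k-space cube.

#' Radially decaying target sampling density
#'
#' Builds the plateau-and-power-law density
#' \deqn{\pi_{C,D}(x) = \kappa \quad (|x| < C), \qquad
#'       \pi_{C,D}(x) = \kappa (C/|x|)^D \quad (|x| \ge C)}
#' sampled on a regular lattice over \eqn{\Omega = [-1,1]^d} and discretely
#' normalized so that the Riemann sum `sum(grid) * cell_volume` equals 1.
#' `C` controls the radius of the fully sampled plateau and `D` how fast the
#' density decays towards the k-space periphery.
#'
#' @param C Cutoff radius in normalized k-space units, in (0, 1].
#' @param D Decay exponent, >= 0 (D = 0 gives a uniform density).
#' @param grid_shape Integer vector of lattice dimensions (length 2 or 3),
#'   all >= 8.
#' @return Object of class `target_density` with fields `grid` (the density
#'   values), `C`, `D`, `kappa` (normalizing constant), `cell_volume`,
#'   `radius` (lattice radii) and `coords`.
#' @examples
#' rho <- target_density(0.25, 2, c(32, 32))
#' sum(rho$grid) * rho$cell_volume  # 1
#' @export
target_density <- function(C, D, grid_shape) {
  if (!is.numeric(C) || length(C) != 1 || C <= 0 || C > 1)
    stop_param("C must be a scalar in (0, 1]")
  if (!is.numeric(D) || length(D) != 1 || D < 0)
    stop_param("D must be a scalar >= 0")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) < 2 || length(grid_shape) > 3 || any(grid_shape < 8))
    stop_param("grid_shape must have 2 or 3 entries, all >= 8")

  d <- length(grid_shape)
  # lattice of cell centers covering [-1, 1]^d
  axes <- lapply(grid_shape, function(n) -1 + (2 * (seq_len(n) - 0.5)) / n)
  coords <- as.matrix(do.call(expand.grid, axes))
  colnames(coords) <- c("x", "y", "z")[seq_len(d)]
  r <- sqrt(rowSums(coords^2))
  cell_volume <- prod(2 / grid_shape)

  val <- ifelse(r < C, 1, (C / pmax(r, .Machine$double.eps))^D)
  kappa <- 1 / (sum(val) * cell_volume)
  grid <- array(val * kappa, dim = grid_shape)

  structure(list(grid = grid, C = C, D = D, kappa = kappa,
                 cell_volume = cell_volume,
                 radius = array(r, dim = grid_shape),
                 coords = coords, dim = d),
            class = "target_density")
}

#' @export
print.target_density <- function(x, ...) {
  cat(sprintf("Target sampling density pi_{C,D}: C = %g, D = %g on %s lattice\n",
              x$C, x$D, paste(dim(x$grid), collapse = "x")))
  cat(sprintf("  kappa = %.6g, discrete mass = %.9f\n",
              x$kappa, sum(x$grid) * x$cell_volume))
  invisible(x)
}

#' Radial cumulative distribution of a target density
#'
#' Numerically accumulates the density mass inside radius `r`, used to
#' compare an optimized point set against its target by a Kolmogorov
#' distance in the radial coordinate.
#'
#' @param rho A `target_density`.
#' @return A function `F(r)` returning the target probability mass at radii
#'   `<= r` (vectorized).
#' @export
radial_cdf <- function(rho) {
  stopifnot(inherits(rho, "target_density"))
  r <- as.vector(rho$radius)
  w <- as.vector(rho$grid) * rho$cell_volume
  o <- order(r)
  r_sorted <- r[o]
  cw <- cumsum(w[o])
  function(q) {
    idx <- findInterval(q, r_sorted)
    out <- numeric(length(q))
    out[idx > 0] <- cw[idx[idx > 0]]
    out
  }
}

#' Kolmogorov distance between point radii and the target radial law
#'
#' @param points Matrix of points (rows) in normalized k-space.
#' @param rho A `target_density`.
#' @return The sup-distance between the empirical CDF of the point radii and
#'   the target radial CDF, evaluated at the pooled radii.
#' @export
radial_ks_distance <- function(points, rho) {
  Fr <- radial_cdf(rho)
  r <- sqrt(rowSums(points^2))
  n <- length(r)
  rs <- sort(r)
  emp_hi <- seq_len(n) / n
  emp_lo <- (seq_len(n) - 1) / n
  tgt <- Fr(rs)
  max(abs(emp_hi - tgt), abs(emp_lo - tgt))
}
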