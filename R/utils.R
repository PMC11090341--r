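# Internal helpers shared across the package.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library functions never perturb user-level randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

#' Wrap angles to (-pi, pi]
#'
#' @param x Numeric vector of angles in radians.
#' @return Angles wrapped to the half-open interval (-pi, pi].
#' @export
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  # map -pi back to +pi so the interval is half-open on the left
  y[y <= -pi + 1e-15] <- pi
  y
}

#' Circular absolute difference between two angles
#'
#' @param a,b Angles in radians.
#' @return Absolute circular difference in `[0, pi]`.
#' @export
circ_diff <- function(a, b) {
  abs(wrap_angle(a - b))
}

# round half away from zero (printed-table convention)
round_half_away <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Peak signal-to-noise ratio between two images
#'
#' @param x Estimate (numeric or complex array; magnitude is used).
#' @param ref Reference image of the same shape.
#' @return PSNR in dB, with the reference dynamic range as the peak.
#' @export
psnr <- function(x, ref) {
  stopifnot(length(x) == length(ref))
  x <- abs(x); ref <- abs(ref)
  mse <- mean((x - ref)^2)
  if (mse == 0) return(Inf)
  peak <- max(ref) - min(ref)
  10 * log10(peak^2 / mse)
}

# centered voxel coordinates for one axis of length n: 0:(n-1) - floor(n/2)
centered_axis <- function(n) seq_len(n) - 1 - floor(n / 2)

# grid of centered voxel coordinates, one row per voxel, one column per axis
centered_grid <- function(shape) {
  axes <- lapply(shape, centered_axis)
  as.matrix(do.call(expand.grid, axes))
}

# fftshift / ifftshift for vectors and 1-3D arrays
.shift_idx <- function(n, h) {
  if (h >= n) return(seq_len(n))
  c((h + 1):n, seq_len(h))
}

fftshift <- function(x) {
  d <- dim(x)
  if (is.null(d)) return(x[.shift_idx(length(x), ceiling(length(x) / 2))])
  idx <- lapply(d, function(n) .shift_idx(n, ceiling(n / 2)))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

ifftshift <- function(x) {
  d <- dim(x)
  if (is.null(d)) return(x[.shift_idx(length(x), floor(length(x) / 2))])
  idx <- lapply(d, function(n) .shift_idx(n, floor(n / 2)))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# n-dimensional FFT helpers on centered grids; unitary scaling.
# Image lattice is centered at 0, frequencies are the centered DFT bins.
fft_centered <- function(x) {
  d <- dim(x)
  out <- fftshift(array(stats::fft(ifftshift(x)), dim = d))
  out / sqrt(length(x))
}

ifft_centered <- function(x) {
  d <- dim(x)
  out <- fftshift(array(stats::fft(ifftshift(x), inverse = TRUE), dim = d))
  out / sqrt(length(x))
}

# matrix of |x|^2 summed over rows -> squared row norms
row_norms <- function(m) sqrt(rowSums(m^2))

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
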