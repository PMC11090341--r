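# Periodized orthonormal discrete wavelet transform (Daubechies 4-tap),
# separable in 2D/3D, exact-adjoint so the l1 proximal step is exact.

# Daubechies D4 analysis filters (orthonormal QMF pair)
.D4_H <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
.D4_G <- c(.D4_H[4], -.D4_H[3], .D4_H[2], -.D4_H[1])

# one analysis step along the first dimension of a matrix (n x m), periodic
.dwt_step_mat <- function(x) {
  n <- nrow(x)
  k <- seq_len(n / 2)
  a <- 0; d <- 0
  for (j in 0:3) {
    idx <- ((2 * (k - 1) + j) %% n) + 1
    a <- a + .D4_H[j + 1] * x[idx, , drop = FALSE]
    d <- d + .D4_G[j + 1] * x[idx, , drop = FALSE]
  }
  rbind(a, d)
}

# transpose (= inverse, by orthonormality) of .dwt_step_mat
.idwt_step_mat <- function(y) {
  n <- nrow(y)
  h <- n / 2
  a <- y[seq_len(h), , drop = FALSE]
  d <- y[h + seq_len(h), , drop = FALSE]
  x <- matrix(0, n, ncol(y))
  if (is.complex(y)) x <- matrix(0 + 0i, n, ncol(y))
  k <- seq_len(h)
  for (j in 0:3) {
    idx <- ((2 * (k - 1) + j) %% n) + 1
    x[idx, ] <- x[idx, ] + .D4_H[j + 1] * a + .D4_G[j + 1] * d
  }
  x
}

# apply a matrix operation along one axis of an array
.along_axis <- function(x, axis, fun) {
  d <- dim(x)
  nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  m <- fun(matrix(xp, nrow = dp[1]))
  out <- array(m, dim = dp)
  aperm(out, order(perm))
}

#' Orthonormal multilevel wavelet decomposition
#'
#' Separable periodized Daubechies 4-tap transform in the Mallat layout:
#' after each level the approximation block occupies the low-index corner
#' and is recursed on.  The transform is orthonormal, so
#' `idwt(dwt(x)) == x` to machine precision and Parseval holds.
#'
#' @param x Numeric or complex array (each dimension divisible by
#'   `2^levels`).
#' @param levels Number of decomposition levels (default 3).
#' @return Coefficient array of the same shape, with attribute `levels`.
#' @export
dwt <- function(x, levels = 3) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  if (any(d %% 2^levels != 0))
    stop_param("every dimension must be divisible by 2^levels")
  out <- x
  sub <- d
  for (l in seq_len(levels)) {
    blk_idx <- lapply(sub, seq_len)
    blk <- do.call(`[`, c(list(out), blk_idx, list(drop = FALSE)))
    for (ax in seq_along(sub)) blk <- .along_axis(blk, ax, .dwt_step_mat)
    out <- do.call(`[<-`, c(list(out), blk_idx, list(blk)))
    sub <- sub %/% 2L
  }
  attr(out, "levels") <- levels
  out
}

#' Inverse orthonormal wavelet reconstruction
#'
#' @param w Coefficient array from [dwt()] (or with matching layout).
#' @param levels Number of levels (defaults to the `levels` attribute).
#' @return The reconstructed array.
#' @export
idwt <- function(w, levels = attr(w, "levels")) {
  d <- dim(w)
  if (is.null(d)) d <- length(w)
  out <- w
  for (l in rev(seq_len(levels))) {
    sub <- d %/% (2L^(l - 1L))
    blk_idx <- lapply(sub, seq_len)
    blk <- do.call(`[`, c(list(out), blk_idx, list(drop = FALSE)))
    for (ax in rev(seq_along(sub))) blk <- .along_axis(blk, ax, .idwt_step_mat)
    out <- do.call(`[<-`, c(list(out), blk_idx, list(blk)))
  }
  attributes(out)$levels <- NULL
  dim(out) <- d
  out
}

# logical mask of the coarse approximation block (excluded from the l1
# penalty so the image mean is never shrunk)
.coarse_mask <- function(shape, levels) {
  m <- array(FALSE, shape)
  idx <- lapply(shape %/% (2L^levels), seq_len)
  do.call(`[<-`, c(list(m), idx, list(TRUE)))
}
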