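# Point spread function of a sampling pattern.

#' Point spread function report
#'
#' Computes the PSF of a sampling pattern as the adjoint of the sampling
#' operator applied to unit weights on the image lattice, then measures the
#' full width at half maximum of the main lobe along each axis (by linear
#' interpolation of the half-maximum crossings) and the main-to-sidelobe
#' ratio (main-lobe peak over the largest magnitude outside the connected
#' above-half-maximum region containing the peak).
#'
#' @param K A `sampling_pattern`, or a p x d matrix of k-space points.
#' @param grid_shape Image lattice dimensions (length d).
#' @return Object of class `psf_report` with `fwhm` (voxels, per axis),
#'   `mslr`, and the PSF magnitude array `psf`.
#' @export
psf_report <- function(K, grid_shape) {
  pts <- if (inherits(K, "sampling_pattern")) pattern_points(K) else as.matrix(K)
  if (nrow(pts) == 0) stop_param("empty sampling pattern")
  grid_shape <- as.integer(grid_shape)
  psf <- ndft_adjoint(pts, rep(1 + 0i, nrow(pts)), grid_shape)
  psf <- abs(psf)
  if (max(psf) <= 0) stop_param("degenerate all-zero PSF")
  psf <- psf / max(psf)

  center <- floor(grid_shape / 2) + 1L
  # ties between the main lobe and replication ghosts resolve to the origin
  peak_idx <- if (psf[matrix(center, 1)] >= max(psf) - 1e-12) {
    matrix(center, 1)
  } else arrayInd(which.max(psf), grid_shape)
  fwhm <- vapply(seq_along(grid_shape), function(ax) {
    idx <- as.list(peak_idx[1, ])
    prof <- do.call(`[`, c(list(psf), replace(idx, ax, list(seq_len(grid_shape[ax])))))
    .fwhm_1d(as.numeric(prof), peak_idx[1, ax])
  }, 0)

  main <- .above_half_component(psf >= 0.5, peak_idx[1, ])
  outside <- psf[!main]
  mslr <- if (length(outside) == 0 || max(outside) == 0) Inf else 1 / max(outside)

  structure(list(fwhm = fwhm, mslr = mslr, psf = psf, peak = peak_idx[1, ],
                 center = center), class = "psf_report")
}

#' @export
print.psf_report <- function(x, ...) {
  cat(sprintf("PSF: FWHM = %s voxels, main-to-sidelobe ratio = %.3g\n",
              paste(sprintf("%.2f", x$fwhm), collapse = " x "), x$mslr))
  invisible(x)
}

# FWHM of a 1D profile around index `peak` by linear interpolation of the
# half-maximum crossings on each side.
.fwhm_1d <- function(prof, peak) {
  half <- prof[peak] / 2
  left <- peak
  while (left > 1 && prof[left - 1] >= half) left <- left - 1
  right <- peak
  n <- length(prof)
  while (right < n && prof[right + 1] >= half) right <- right + 1
  xl <- if (left == 1) left else {
    left - (prof[left] - half) / (prof[left] - prof[left - 1])
  }
  xr <- if (right == n) right else {
    right + (prof[right] - half) / (prof[right] - prof[right + 1])
  }
  xr - xl
}

# connected component (4/6-neighbour) of `mask` containing `start`
.above_half_component <- function(mask, start) {
  shape <- dim(mask)
  d <- length(shape)
  comp <- array(FALSE, shape)
  queue <- matrix(start, nrow = 1)
  comp[matrix(start, 1)] <- TRUE
  offs <- NULL
  for (ax in seq_len(d)) {
    for (sgn in c(-1L, 1L)) {
      o <- integer(d); o[ax] <- sgn
      offs <- rbind(offs, o)
    }
  }
  head <- 1L
  while (head <= nrow(queue)) {
    cur <- queue[head, ]; head <- head + 1L
    for (r in seq_len(nrow(offs))) {
      nb <- cur + offs[r, ]
      if (any(nb < 1) || any(nb > shape)) next
      nbm <- matrix(nb, 1)
      if (mask[nbm] && !comp[nbm]) {
        comp[nbm] <- TRUE
        queue <- rbind(queue, nb)
      }
    }
  }
  comp
}
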