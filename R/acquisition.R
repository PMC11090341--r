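# Multi-coil, off-resonance-aware encoding operator (forward / adjoint)
# for arbitrary sampling patterns, and the accelerated Cartesian EPI mask.
#
# DFT convention: the image lattice is centered at 0 (voxel coordinates
# 0:(n-1) - floor(n/2) per axis) and k-space is normalized to [-1, 1] per
# axis, with k = 1 the Nyquist edge (0.5 cycles/voxel).  The forward model
# for a unit coil and no off-resonance is
#   y_j = N^{-1/2} sum_x m(x) exp(-i pi k_j . x),
# so full Cartesian sampling at the centered DFT bins k = 2*(idx - n/2)/n
# is the unitary DFT and a unit impulse at the origin voxel has flat
# spectrum of modulus N^{-1/2}.

# ---- non-uniform DFT kernels (chunked to bound memory) ------------------

# apply the NDFT matrix E (M x N) to columns X (N x c): returns M x c
ndft_forward_mat <- function(pts, shape, X) {
  grid <- centered_grid(shape)
  N <- nrow(grid); M <- nrow(pts)
  X <- as.matrix(X)
  out <- matrix(0 + 0i, M, ncol(X))
  chunk <- max(1L, floor(4e6 / N))
  i0 <- 1L
  while (i0 <= M) {
    i1 <- min(M, i0 + chunk - 1L)
    E <- exp(-1i * pi * tcrossprod(pts[i0:i1, , drop = FALSE], grid))
    out[i0:i1, ] <- E %*% X
    i0 <- i1 + 1L
  }
  out / sqrt(N)
}

# apply E^H to columns Y (M x c): returns N x c
ndft_adjoint_mat <- function(pts, shape, Y) {
  grid <- centered_grid(shape)
  N <- nrow(grid); M <- nrow(pts)
  Y <- as.matrix(Y)
  out <- matrix(0 + 0i, N, ncol(Y))
  chunk <- max(1L, floor(4e6 / N))
  i0 <- 1L
  while (i0 <= M) {
    i1 <- min(M, i0 + chunk - 1L)
    E <- exp(-1i * pi * tcrossprod(pts[i0:i1, , drop = FALSE], grid))
    out <- out + crossprod(Conj(E), Y[i0:i1, , drop = FALSE])
    i0 <- i1 + 1L
  }
  out / sqrt(N)
}

#' Adjoint non-uniform DFT of weighted samples
#'
#' @param pts M x d matrix of normalized k-space points.
#' @param w Complex weights, length M.
#' @param shape Image lattice dimensions.
#' @return Complex array of dimension `shape`.
#' @export
ndft_adjoint <- function(pts, w, shape) {
  array(ndft_adjoint_mat(pts, shape, matrix(w, ncol = 1)), dim = shape)
}

# ---- sample timing ------------------------------------------------------

#' Acquisition time of every sample of a pattern
#'
#' Within each shot, sample `j` is acquired at
#' `t_j = (j - te_index) * dt + TE`, so the echo-time sample is acquired
#' exactly at TE and times are monotone within a shot.
#'
#' @param K A `sampling_pattern`.
#' @param dt Dwell time (s); defaults to the pattern's hardware dwell.
#' @param te Echo time TE (s).
#' @return Numeric vector of length `K$p`, ordered like [pattern_points()].
#' @export
sample_times <- function(K, dt = K$hw$dt, te = 20e-3) {
  if (dt <= 0) stop_param("dt must be positive")
  per_shot <- (seq_len(K$Ns) - K$te_index) * dt + te
  rep(per_shot, times = K$Nc)
}

# ---- EPI Cartesian comparator mask --------------------------------------

#' Accelerated Cartesian EPI sampling mask
#'
#' Keeps every `r_phase`-th phase-encode line (axis 2) and every
#' `r_partition`-th partition (axis 3, when present), then removes the
#' early `1 - pf` fraction of lines along each phase-encode axis (partial
#' Fourier).  Timing assigns one readout train per excitation (one
#' partition in 3D, the whole plane in 2D): kept phase-encode lines are
#' traversed in order with an even echo spacing spanning `readout_dur`,
#' and the central line is acquired at `te`.
#'
#' @param grid_shape Lattice dimensions (length 2 or 3).
#' @param r_phase Phase-encode acceleration factor (default 4).
#' @param r_partition Partition acceleration factor (default 2; ignored in 2D).
#' @param pf Partial Fourier fraction (default 6/8).
#' @param te Echo time (s).
#' @param readout_dur Duration of one readout train (s).
#' @return Object of class `cartesian_mask` with fields `mask` (logical
#'   array in centered layout), `idx` (linear indices of kept points),
#'   `points` (kept normalized k-space locations), `times`, `shape`.
#' @export
epi_sampling_mask <- function(grid_shape, r_phase = 4, r_partition = 2,
                              pf = 6 / 8, te = 20e-3, readout_dur = 26.33e-3) {
  grid_shape <- as.integer(grid_shape)
  d <- length(grid_shape)
  if (d < 2 || d > 3) stop_param("grid_shape must have 2 or 3 entries")
  if (grid_shape[2] %% r_phase != 0)
    stop_param("phase-encode dimension not divisible by r_phase")
  if (d == 3 && grid_shape[3] %% r_partition != 0)
    stop_param("partition dimension not divisible by r_partition")

  keep_lines <- function(n, r, pf) {
    start0 <- round((1 - pf) * n)            # 0-based first kept index
    off <- start0 %% r
    idx0 <- seq.int(start0 - (start0 %% r) + off, n - 1, by = r)
    idx0 <- idx0[idx0 >= start0]
    idx0 + 1L
  }
  ky <- keep_lines(grid_shape[2], r_phase, pf)
  mask <- array(FALSE, grid_shape)
  if (d == 2) {
    mask[, ky] <- TRUE
  } else {
    kz <- keep_lines(grid_shape[3], r_partition, pf)
    mask[, ky, kz] <- TRUE
  }

  idx <- which(mask)
  sub <- arrayInd(idx, grid_shape)
  # normalized k locations of the kept grid points
  points <- vapply(seq_len(d), function(ax) {
    2 * (sub[, ax] - 1 - floor(grid_shape[ax] / 2)) / grid_shape[ax]
  }, numeric(length(idx)))

  # timing: one train per excitation along the kept ky lines
  n_lines <- length(ky)
  esp <- if (n_lines > 1) readout_dur / (n_lines - 1) else 0
  center_pos <- which.min(abs(ky - (floor(grid_shape[2] / 2) + 1)))
  line_time <- te + (seq_len(n_lines) - center_pos) * esp
  times <- line_time[match(sub[, 2], ky)]

  structure(list(mask = mask, idx = idx, points = points, times = times,
                 shape = grid_shape, r_phase = r_phase,
                 r_partition = if (d == 3) r_partition else 1L, pf = pf,
                 te = te, readout_dur = readout_dur),
            class = "cartesian_mask")
}

#' @export
print.cartesian_mask <- function(x, ...) {
  cat(sprintf("Cartesian EPI mask %s: R = %dx%d, partial Fourier %.3g, %d/%d points kept (%.1f%%)\n",
              paste(x$shape, collapse = "x"), x$r_phase, x$r_partition, x$pf,
              length(x$idx), prod(x$shape), 100 * length(x$idx) / prod(x$shape)))
  invisible(x)
}

# ---- off-resonance temporal basis ---------------------------------------

# SVD-derived time-segmentation basis: approximates the per-voxel phase
# accrual exp(-i * omega_x * t_j) by sum_l B[j, l] * Cseg[x, l] with L
# temporal segments.  B is fit on a spread of representative off-resonance
# values; Cseg is the exact projection of each voxel's phase history onto
# the basis, so the approximation error is the basis truncation error only.
.b0_basis <- function(times, omega, L) {
  uo <- unique(as.vector(omega))
  qs <- stats::quantile(as.vector(omega), probs = seq(0, 1, length.out = min(96, max(2L, length(uo)))),
                        names = FALSE, type = 7)
  qs <- unique(qs)
  P <- exp(-1i * outer(times, qs))
  L <- min(L, ncol(P), nrow(P))
  B <- svd(P, nu = L, nv = 0)$u              # M x L orthonormal
  B
}

# exact per-voxel coefficients Cseg (N x L) = P_x^T conj(B) chunked
.b0_coeffs <- function(times, omega, B) {
  M <- length(times); N <- length(omega); L <- ncol(B)
  out <- matrix(0 + 0i, N, L)
  chunk <- max(1L, floor(4e6 / M))
  i0 <- 1L
  while (i0 <= N) {
    i1 <- min(N, i0 + chunk - 1L)
    P <- exp(-1i * outer(times, omega[i0:i1]))   # M x chunk
    out[i0:i1, ] <- crossprod(P, Conj(B))        # (chunk x M) %*% (M x L)
    i0 <- i1 + 1L
  }
  out
}

# ---- the encoding operator ----------------------------------------------

#' Build the multi-coil off-resonance-aware encoding operator
#'
#' Defines the linear forward model
#' \deqn{y_c(j) = N^{-1/2} \sum_x S_c(x)\, m(x)\, e^{-i 2\pi k_j \cdot x}\,
#'       e^{-i \delta\omega_0(x) t_j}}
#' and its exact adjoint.  Off-resonance is handled by time segmentation
#' with an SVD-derived temporal basis of `n_segments` components (the
#' adjoint is the exact adjoint of the segmented forward operator), or
#' exactly per sample with `method = "exact"` (the brute-force oracle,
#' only practical on small problems).  Cartesian masks use FFT kernels;
#' arbitrary patterns use the non-uniform DFT.
#'
#' @param traj A `sampling_pattern`, a `cartesian_mask`, or an M x d matrix
#'   of normalized k-space points.
#' @param shape Image lattice dimensions.
#' @param coils A `coil_profiles` object (NULL = single uniform coil).
#' @param fieldmap A `field_map` object (NULL = no off-resonance).
#' @param times Acquisition time per sample (s); required when `fieldmap`
#'   is given, defaulted from the trajectory when possible.
#' @param n_segments Number of temporal segments (default 8).
#' @param method `"segmented"` (default) or `"exact"`.
#' @return Object of class `encoding_op` with `$forward(m)` mapping an
#'   image (array or vector) to an M x n_coils complex matrix, and
#'   `$adjoint(y)` mapping samples back to an image array.
#' @export
encoding_operator <- function(traj, shape, coils = NULL, fieldmap = NULL,
                              times = NULL, n_segments = 8,
                              method = c("segmented", "exact")) {
  method <- match.arg(method)
  shape <- as.integer(shape)
  N <- prod(shape)
  cartesian <- inherits(traj, "cartesian_mask")
  if (cartesian) {
    pts <- traj$points
    if (is.null(times)) times <- traj$times
  } else if (inherits(traj, "sampling_pattern")) {
    pts <- pattern_points(traj)
    if (is.null(times)) times <- sample_times(traj)
  } else {
    pts <- as.matrix(traj)
  }
  M <- nrow(pts)

  S <- if (is.null(coils)) matrix(1 + 0i, N, 1) else {
    matrix(vapply(coils$maps, as.vector, complex(N)), N, coils$n_coils)
  }
  n_coils <- ncol(S)

  omega <- if (is.null(fieldmap)) NULL else 2 * pi * as.vector(fieldmap$delta_b0)
  use_b0 <- !is.null(omega) && any(omega != 0)
  if (use_b0 && is.null(times))
    stop_param("sample times are required when a field map is supplied")

  if (use_b0 && method == "segmented") {
    B <- .b0_basis(times, omega, n_segments)
    Cs <- .b0_coeffs(times, omega, B)
    L <- ncol(B)
  } else if (!use_b0) {
    B <- matrix(1 + 0i, M, 1)
    Cs <- matrix(1 + 0i, N, 1)
    L <- 1L
  } else {
    L <- 0L   # exact per-sample phase, no segmentation
  }

  if (method == "exact" && use_b0) {
    forward <- function(m) {
      m <- as.vector(m)
      X <- S * m                               # N x n_coils
      out <- matrix(0 + 0i, M, n_coils)
      grid <- centered_grid(shape)
      chunk <- max(1L, floor(4e6 / N))
      i0 <- 1L
      while (i0 <= M) {
        i1 <- min(M, i0 + chunk - 1L)
        E <- exp(-1i * pi * tcrossprod(pts[i0:i1, , drop = FALSE], grid) -
                   1i * outer(times[i0:i1], omega))
        out[i0:i1, ] <- E %*% X
        i0 <- i1 + 1L
      }
      out / sqrt(N)
    }
    adjoint <- function(y) {
      y <- as.matrix(y)
      acc <- matrix(0 + 0i, N, n_coils)
      grid <- centered_grid(shape)
      chunk <- max(1L, floor(4e6 / N))
      i0 <- 1L
      while (i0 <= M) {
        i1 <- min(M, i0 + chunk - 1L)
        E <- exp(-1i * pi * tcrossprod(pts[i0:i1, , drop = FALSE], grid) -
                   1i * outer(times[i0:i1], omega))
        acc <- acc + crossprod(Conj(E), y[i0:i1, , drop = FALSE])
        i0 <- i1 + 1L
      }
      array(rowSums(Conj(S) * acc) / sqrt(N), dim = shape)
    }
  } else if (cartesian) {
    idx <- traj$idx
    forward <- function(m) {
      m <- as.vector(m)
      out <- matrix(0 + 0i, M, n_coils)
      for (l in seq_len(L)) {
        X <- S * (Cs[, l] * m)
        for (c in seq_len(n_coils)) {
          Fc <- fft_centered(array(X[, c], dim = shape))
          out[, c] <- out[, c] + B[, l] * Fc[idx]
        }
      }
      out
    }
    adjoint <- function(y) {
      y <- as.matrix(y)
      img <- rep(0 + 0i, N)
      for (l in seq_len(L)) {
        yl <- Conj(B[, l]) * y                 # M x n_coils
        part <- rep(0 + 0i, N)
        for (c in seq_len(n_coils)) {
          grid_full <- array(0 + 0i, dim = shape)
          grid_full[idx] <- yl[, c]
          part <- part + Conj(S[, c]) * as.vector(ifft_centered(grid_full))
        }
        img <- img + Conj(Cs[, l]) * part
      }
      array(img, dim = shape)
    }
  } else {
    # cache the full NDFT matrix when it fits comfortably in memory
    E <- if (as.double(M) * N <= 8e6) {
      exp(-1i * pi * tcrossprod(pts, centered_grid(shape))) / sqrt(N)
    } else NULL
    forward <- function(m) {
      m <- as.vector(m)
      out <- matrix(0 + 0i, M, n_coils)
      for (l in seq_len(L)) {
        X <- S * (Cs[, l] * m)                 # N x n_coils
        proj <- if (is.null(E)) ndft_forward_mat(pts, shape, X) else E %*% X
        out <- out + B[, l] * proj
      }
      out
    }
    adjoint <- function(y) {
      y <- as.matrix(y)
      img <- rep(0 + 0i, N)
      for (l in seq_len(L)) {
        yl <- Conj(B[, l]) * y
        back <- if (is.null(E)) ndft_adjoint_mat(pts, shape, yl)
                else crossprod(Conj(E), yl)    # N x n_coils
        img <- img + Conj(Cs[, l]) * rowSums(Conj(S) * back)
      }
      array(img, dim = shape)
    }
  }

  structure(list(forward = forward, adjoint = adjoint, shape = shape,
                 M = M, n_coils = n_coils, points = pts, times = times,
                 cartesian = cartesian,
                 n_segments = if (use_b0 && method == "segmented") L else 0L,
                 method = method),
            class = "encoding_op")
}

#' @export
print.encoding_op <- function(x, ...) {
  cat(sprintf("Encoding operator: %d samples x %d coils on %s image (%s%s)\n",
              x$M, x$n_coils, paste(x$shape, collapse = "x"),
              if (x$cartesian) "Cartesian FFT" else "NUFFT",
              if (x$n_segments > 0) sprintf(", %d B0 segments", x$n_segments) else ""))
  invisible(x)
}

#' Apply the encoding operator to an image
#'
#' @param image Complex (or numeric) image array matching the operator.
#' @param op An [encoding_operator()].
#' @return Object of class `kspace_data`: list with `samples` (M x n_coils
#'   complex), `times`, and the operator's trajectory metadata.
#' @export
encode <- function(image, op) {
  stopifnot(inherits(op, "encoding_op"))
  if (length(image) != prod(op$shape)) stop_param("image shape mismatch")
  if (any(!is.finite(image))) stop_param("image contains non-finite values")
  structure(list(samples = op$forward(image), times = op$times,
                 shape = op$shape, n_coils = op$n_coils),
            class = "kspace_data")
}

#' Apply the adjoint encoding operator to k-space data
#'
#' Coil combination is the conjugate-weighted sum built into the adjoint.
#'
#' @param y A `kspace_data` object or an M x n_coils complex matrix.
#' @param op An [encoding_operator()].
#' @return Complex image array.
#' @export
encode_adjoint <- function(y, op) {
  stopifnot(inherits(op, "encoding_op"))
  samples <- if (inherits(y, "kspace_data")) y$samples else as.matrix(y)
  op$adjoint(samples)
}

#' Density-compensation weights for adjoint-based images
#'
#' Radial approximation `w ~ max(|k|, C)^min(D, d-1)` (the plateau caps the
#' weight at low frequencies), normalized to unit mean.  Used only to
#' sharpen adjoint-based initial images, never inside the iterative
#' reconstruction.
#'
#' @param pts M x d matrix of k-space points.
#' @param C Density plateau cutoff.
#' @param D Density decay exponent.
#' @return Numeric weights of length M with mean 1.
#' @export
dcf_weights <- function(pts, C = 0.25, D = 2) {
  d <- ncol(pts)
  r <- sqrt(rowSums(pts^2))
  w <- pmax(r, C)^min(D, d - 1)
  w / mean(w)
}
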