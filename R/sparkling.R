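# Attraction-repulsion optimization of variable-density sampling patterns.

#' Sampling pattern container
#'
#' A multi-shot sampling pattern over the normalized k-space cube
#' \eqn{\Omega = [-1,1]^d}: `Nc` shots of `Ns` ordered samples each, with
#' the echo-time sample of every shot pinned to the origin.
#'
#' @param shots List of Ns x d sample matrices.
#' @param te_index Echo-time sample index shared by all shots.
#' @param hw A [hardware_constraints()] object.
#' @param seed Seed used for initialization (stored for provenance).
#' @return Object of class `sampling_pattern`.
#' @export
sampling_pattern <- function(shots, te_index, hw, seed = NULL) {
  stopifnot(length(shots) > 0)
  d <- ncol(shots[[1]])
  ns <- nrow(shots[[1]])
  structure(list(shots = shots, te_index = te_index, hw = hw,
                 Nc = length(shots), Ns = ns, d = d,
                 p = length(shots) * ns, seed = seed),
            class = "sampling_pattern")
}

#' @export
print.sampling_pattern <- function(x, ...) {
  cat(sprintf("Sampling pattern: %d shots x %d samples (p = %d) in %dD\n",
              x$Nc, x$Ns, x$p, x$d))
  a <- pattern_audit(x)
  cat(sprintf("  worst TE offset %.2e, speed excess %.2e, accel excess %.2e\n",
              a$te, a$speed, a$accel))
  invisible(x)
}

#' Flatten a pattern to a p x d point matrix
#' @param K A `sampling_pattern`.
#' @return Matrix of all sample locations.
#' @export
pattern_points <- function(K) do.call(rbind, K$shots)

#' Audit every shot of a pattern
#'
#' @param K A `sampling_pattern`.
#' @return Worst-case violations across shots (see [shot_audit()]).
#' @export
pattern_audit <- function(K) {
  audits <- lapply(K$shots, shot_audit, te_index = K$te_index, hw = K$hw)
  list(te = max(vapply(audits, `[[`, 0, "te")),
       speed = max(vapply(audits, `[[`, 0, "speed")),
       accel = max(vapply(audits, `[[`, 0, "accel")),
       box = max(vapply(audits, `[[`, 0, "box")))
}

#' Attraction-repulsion energy of a sampling pattern
#'
#' Evaluates the variable-density energy
#' \deqn{F(K) = F_a(K) - F_r(K)}
#' with attraction
#' \eqn{F_a = \frac1p \sum_i \int_\Omega \|x - K_i\| \rho(x) dx}
#' (discretized as a Riemann sum on the density lattice) and repulsion
#' \eqn{F_r = \frac{1}{2p^2} \sum_{i,j} \|K_i - K_j\|}.
#' Minimizing F draws points towards high-density regions while spreading
#' them locally uniformly.
#'
#' @param K A `sampling_pattern` or a p x d point matrix.
#' @param rho A [target_density()].
#' @return List with `Fa`, `Fr` and `F = Fa - Fr`.
#' @export
sparkling_energy <- function(K, rho) {
  pts <- if (inherits(K, "sampling_pattern")) pattern_points(K) else as.matrix(K)
  if (nrow(pts) == 0) stop_param("empty sampling pattern")
  if (max(abs(pts)) > 1 + 1e-9) stop_param("points outside [-1,1]^d")
  w <- as.vector(rho$grid) * rho$cell_volume
  p <- nrow(pts)

  Fa <- 0
  # chunk the lattice to bound memory on 3D grids
  chunk <- max(1L, floor(2e6 / p))
  g <- nrow(rho$coords)
  i0 <- 1L
  while (i0 <= g) {
    i1 <- min(g, i0 + chunk - 1L)
    dmat <- .cross_dist(pts, rho$coords[i0:i1, , drop = FALSE])
    Fa <- Fa + sum(dmat %*% w[i0:i1])
    i0 <- i1 + 1L
  }
  Fa <- Fa / p

  Dpp <- .cross_dist(pts, pts)
  Fr <- sum(Dpp) / (2 * p^2)
  list(Fa = Fa, Fr = Fr, F = Fa - Fr)
}

# Euclidean distance matrix between row sets (m x d, n x d) -> m x n
.cross_dist <- function(a, b) {
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# gradient of F = Fa - Fr w.r.t. every point; smoothed norm avoids the
# non-differentiability of ||.|| at coincident points
.sparkling_grad <- function(pts, rho, eps = 1e-8) {
  p <- nrow(pts); d <- ncol(pts)
  w <- as.vector(rho$grid) * rho$cell_volume
  grad <- matrix(0, p, d)

  chunk <- max(1L, floor(2e6 / p))
  g <- nrow(rho$coords)
  i0 <- 1L
  while (i0 <= g) {
    i1 <- min(g, i0 + chunk - 1L)
    co <- rho$coords[i0:i1, , drop = FALSE]
    dmat <- .cross_dist(pts, co)
    inv <- 1 / sqrt(dmat^2 + eps^2)
    ww <- w[i0:i1]
    # d/dK_i sum_l w_l ||x_l - K_i||  = sum_l w_l (K_i - x_l)/dist
    wi <- inv * rep(ww, each = p)       # p x chunk
    s <- rowSums(wi)                    # sum_l w_l / dist
    grad <- grad + (pts * s - wi %*% co)
    i0 <- i1 + 1L
  }
  grad <- grad / p

  # repulsion gradient: (1/p^2) sum_j (K_i - K_j)/dist
  Dpp <- .cross_dist(pts, pts)
  invp <- 1 / sqrt(Dpp^2 + eps^2)
  diag(invp) <- 0
  sr <- rowSums(invp)
  grad_r <- (pts * sr - invp %*% pts) / p^2
  grad - grad_r
}

#' Initialize a pattern as jittered radial spokes
#'
#' Each shot is a straight line through the k-space origin with a seeded
#' random orientation (evenly spaced base angles plus jitter in 2D, random
#' directions on the sphere in 3D).  Straight constant-step spokes are
#' feasible by construction; one projection pass is applied regardless.
#'
#' @param Nc Number of shots.
#' @param Ns Samples per shot.
#' @param d Dimension (2 or 3).
#' @param hw A [hardware_constraints()] object.
#' @param seed RNG seed.
#' @return A `sampling_pattern`.
#' @export
init_radial_pattern <- function(Nc, Ns, d = 2, hw = hardware_constraints(),
                                seed = 1) {
  te <- floor((Ns + 1) / 2)
  # keep the spokes clearly inside the speed bound so the optimizer has
  # slack to deform them before the projection clips
  reach <- min(1, hw$step_max * (Ns - 1) / 2 * 0.8)
  shots <- with_seed(seed, {
    lapply(seq_len(Nc), function(i) {
      if (d == 2) {
        theta <- 2 * pi * (i - 1) / Nc + stats::runif(1, -pi / Nc, pi / Nc)
        u <- c(cos(theta), sin(theta))
      } else {
        u <- stats::rnorm(d)
        u <- u / sqrt(sum(u^2))
      }
      tpos <- (seq_len(Ns) - te) / max(1, (Ns - te))
      outer(tpos * reach, u)
    })
  })
  K <- sampling_pattern(shots, te, hw, seed = seed)
  K$shots <- lapply(K$shots, project_shot, te_index = te, hw = hw)
  K
}

#' Optimize a sampling pattern by projected gradient descent
#'
#' Minimizes the attraction-repulsion energy of [sparkling_energy()] over
#' the hardware constraint set: at each iteration a gradient step on all
#' points is followed by the per-shot projection of [project_shot()]; the
#' step is halved (backtracking, up to `max_halvings`) until the projected
#' iterate does not increase the energy, so the recorded energy trace is
#' non-increasing by construction.
#'
#' @param init A `sampling_pattern` (feasible after one projection pass).
#' @param rho A [target_density()].
#' @param n_iter Number of iterations (default 200).
#' @param step Base step size in normalized units (default 0.2).
#' @param max_halvings Backtracking budget per iteration (default 20).
#' @param tol Projection tolerance passed to [project_shot()].
#' @return The optimized `sampling_pattern` with an `energy_trace`
#'   attribute (numeric vector, first entry = initial energy).
#' @export
optimize_pattern <- function(init, rho, n_iter = 200, step = 0.2,
                             max_halvings = 20, tol = 1e-3) {
  stopifnot(inherits(init, "sampling_pattern"))
  K <- init
  te <- K$te_index; hw <- K$hw
  project_all <- function(pts) {
    shots <- split.data.frame(pts, rep(seq_len(K$Nc), each = K$Ns))
    lapply(shots, function(s) project_shot(as.matrix(s), te, hw, tol = tol))
  }
  K$shots <- project_all(pattern_points(K))

  pts <- pattern_points(K)
  e <- sparkling_energy(pts, rho)$F
  trace <- numeric(n_iter + 1)
  trace[1] <- e

  p <- nrow(pts)
  for (it in seq_len(n_iter)) {
    # gradients of the per-point mean energy scale as 1/p; rescale so
    # `step` is quoted as a typical per-point displacement
    gr <- .sparkling_grad(pts, rho) * p
    s <- step
    accepted <- FALSE
    for (h in seq_len(max_halvings)) {
      cand <- pts - s * gr
      cand <- pmin(pmax(cand, -1), 1)
      shots_cand <- project_all(cand)
      cand_pts <- do.call(rbind, shots_cand)
      e_cand <- sparkling_energy(cand_pts, rho)$F
      if (e_cand <= e) {
        pts <- cand_pts
        K$shots <- shots_cand
        e <- e_cand
        accepted <- TRUE
        break
      }
      s <- s / 2
    }
    trace[it + 1] <- e
    if (!accepted && it > 1 && trace[it] == trace[it - 1]) {
      # stalled twice: no descent direction within the backtracking budget
      trace <- trace[seq_len(it + 1)]
      break
    }
  }
  attr(K, "energy_trace") <- trace
  K
}

#' Export a pattern as plain text
#'
#' One sample per line: `shot_index, sample_index, kx, ky[, kz]`.
#'
#' @param K A `sampling_pattern`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
export_pattern <- function(K, file) {
  pts <- pattern_points(K)
  df <- data.frame(shot = rep(seq_len(K$Nc), each = K$Ns),
                   sample = rep(seq_len(K$Ns), K$Nc))
  df <- cbind(df, as.data.frame(pts))
  names(df)[-(1:2)] <- c("kx", "ky", "kz")[seq_len(K$d)]
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
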