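# Quality metrics: temporal SNR, Dice overlap, tissue specificity,
# distribution-shift tests, residual normality.

#' Temporal SNR map
#'
#' Voxelwise temporal mean divided by temporal standard deviation, after
#' optional removal of a linear trend (default on).  Voxels with zero
#' temporal SD get the value 0 and are flagged.
#'
#' @param series 4D (or 3D in 2D imaging) array with time as the last
#'   dimension, or a `bold_series`.
#' @param detrend Remove a linear trend before computing the SD
#'   (default TRUE).
#' @return Array of tSNR values with attribute `flagged` (logical array of
#'   zero-variance voxels).
#' @export
tsnr_map <- function(series, detrend = TRUE) {
  if (inherits(series, "bold_series")) series <- series$data
  d <- dim(series)
  nt <- d[length(d)]
  if (nt < 3) stop_param("need at least 3 time points")
  flat <- matrix(series, prod(d[-length(d)]), nt)
  mu <- rowMeans(flat)
  # population SD so a +-1 alternation around the mean gives SD exactly 1
  if (detrend) {
    tt <- seq_len(nt) - (nt + 1) / 2
    slope <- as.vector(flat %*% tt) / sum(tt^2)
    resid <- flat - mu - outer(slope, tt)
    sdv <- sqrt(rowMeans(resid^2))
  } else {
    sdv <- sqrt(rowMeans((flat - mu)^2))
  }
  flagged <- sdv <= 1e-12 * pmax(abs(mu), 1)
  out <- ifelse(flagged, 0, mu / ifelse(flagged, 1, sdv))
  structure(array(out, dim = d[-length(d)]),
            flagged = array(flagged, dim = d[-length(d)]))
}

#' Dice overlap between two binary masks
#'
#' `2 |A ∩ B| / (|A| + |B|)`; two empty masks are defined as perfectly
#' overlapping (1, with a warning).
#'
#' @param maskA,maskB Logical vectors/arrays of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(maskA, maskB) {
  a <- as.logical(maskA); b <- as.logical(maskB)
  stopifnot(length(a) == length(b))
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) {
    warning("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(a & b) / (na + nb)
}

#' Tissue composition of an activation mask
#'
#' Assigns every activated voxel to its maximum-probability tissue (gray
#' matter, white matter, CSF); voxels whose top probability ties or falls
#' below `floor_prob` are counted as "other".  Percentages are relative to
#' the total number of activated voxels.
#'
#' @param mask Logical activation mask.
#' @param gm,wm,csf Tissue probability arrays.
#' @param floor_prob Minimum probability for a tissue assignment
#'   (default 0.34).
#' @return Named numeric vector `c(GM, WM, CSF, other)` summing to 100.
#' @export
activation_tissue_table <- function(mask, gm, wm, csf, floor_prob = 0.34) {
  idx <- which(mask)
  if (length(idx) == 0) stop_param("empty activation mask")
  probs <- cbind(GM = as.vector(gm)[idx], WM = as.vector(wm)[idx],
                 CSF = as.vector(csf)[idx])
  top <- max.col(probs, ties.method = "first")
  pmaxv <- probs[cbind(seq_along(idx), top)]
  # ties between the top two tissues, or too-low probability -> other
  sorted2 <- apply(probs, 1, function(r) sort(r, decreasing = TRUE)[2])
  other <- pmaxv < floor_prob | pmaxv == sorted2
  counts <- c(tabulate(top[!other], nbins = 3), sum(other))
  names(counts) <- c("GM", "WM", "CSF", "other")
  100 * counts / length(idx)
}

#' Average a table of per-subject tissue percentages
#'
#' Arithmetic mean across subjects per column, rounded half away from
#' zero to 2 decimals (the printed-table convention).
#'
#' @param tables Matrix or data.frame with one row per subject.
#' @return Named numeric vector of column averages.
#' @export
average_specificity_table <- function(tables) {
  m <- as.matrix(tables)
  round_half_away(colMeans(m), 2)
}

#' One-sided two-sample Kolmogorov-Smirnov comparison
#'
#' Compares the upper tails of two z-score samples after restricting both
#' to values `>= z_threshold`.  `direction = "right"` tests the
#' alternative that `zB` is stochastically larger than `zA` (its
#' distribution shifted to the right), using the signed supremum
#' `D = max(ECDF_A - ECDF_B)`; `direction = "left"` tests the opposite
#' shift.  The p-value is the asymptotic one-sided bound
#' `exp(-2 m D^2)` with `m = n1 n2 / (n1 + n2)`.
#'
#' @param zA,zB Numeric samples.
#' @param z_threshold Lower restriction (default 3.09; use -Inf to keep
#'   all values).
#' @param direction `"right"` or `"left"`.
#' @return List with `D`, `p`, `n1`, `n2`, `direction`.
#' @export
ks_compare <- function(zA, zB, z_threshold = 3.09,
                       direction = c("right", "left")) {
  direction <- match.arg(direction)
  a <- zA[zA >= z_threshold]
  b <- zB[zB >= z_threshold]
  if (length(a) == 0 || length(b) == 0)
    stop_param("no suprathreshold values in one of the samples")
  grid <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(grid)
  Fb <- stats::ecdf(b)(grid)
  D <- if (direction == "right") max(Fa - Fb) else max(Fb - Fa)
  D <- max(D, 0)
  m <- length(a) * length(b) / (length(a) + length(b))
  p <- min(1, exp(-2 * m * D^2))
  list(D = D, p = p, n1 = length(a), n2 = length(b), direction = direction)
}

#' Fraction of voxels with normal-looking residuals
#'
#' Per-voxel Shapiro-Wilk test of the temporal residuals; returns the
#' fraction of voxels whose normality hypothesis is not rejected at
#' `level`.
#'
#' @param residuals T x V matrix of temporal residuals (or a
#'   [fit_glm()] object).
#' @param level Test level (default 0.01).
#' @return Fraction in `[0, 1]`.
#' @export
residual_normality <- function(residuals, level = 0.01) {
  if (inherits(residuals, "retino_glm")) residuals <- residuals$residuals
  residuals <- as.matrix(residuals)
  if (ncol(residuals) == 0) stop_param("no voxels to test")
  pvals <- apply(residuals, 2, function(r) stats::shapiro.test(r)$p.value)
  mean(pvals >= level)
}
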