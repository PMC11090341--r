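# Activation thresholding strategies and connected-component cluster
# filtering.

#' Label connected components of a binary mask
#'
#' Face-connectivity labeling (4-neighbour in 2D, 6-neighbour in 3D) by
#' iterative flood fill.
#'
#' @param mask Logical array (2D or 3D).
#' @return Integer array of component labels (0 = background).
#' @export
label_components <- function(mask) {
  shape <- dim(mask)
  d <- length(shape)
  n <- prod(shape)
  labels <- integer(n)
  maskv <- as.vector(mask)
  # precompute neighbour linear offsets with boundary guards via subscripts
  strides <- cumprod(c(1, shape[-d]))
  sub <- arrayInd(seq_len(n), shape)
  lab <- 0L
  for (start in which(maskv & labels == 0L)) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    stack <- start
    labels[start] <- lab
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (ax in seq_len(d)) {
        for (sgn in c(-1L, 1L)) {
          s <- sub[cur, ax] + sgn
          if (s < 1 || s > shape[ax]) next
          nb <- cur + sgn * strides[ax]
          if (maskv[nb] && labels[nb] == 0L) {
            labels[nb] <- lab
            stack <- c(stack, nb)
          }
        }
      }
    }
  }
  array(labels, dim = shape)
}

#' Threshold a statistical map into a binary activation mask
#'
#' Three strategies: (i) Benjamini-Hochberg false discovery rate control
#' at `q = 0.05`; (ii) `p < 0.001` uncorrected, equivalently `z > 3.09`
#' (the upper 0.001 standard-normal quantile); (iii) `p < 0.05`
#' uncorrected followed by removal of face-connected clusters smaller
#' than `cluster_min` voxels.
#'
#' @param p Vector or array of p-values over the analysis mask.
#' @param strategy `"i"`, `"ii"` or `"iii"`.
#' @param q FDR level for strategy i (default 0.05).
#' @param p_unc Uncorrected level for strategy ii (default 0.001).
#' @param p_clu Uncorrected level for strategy iii (default 0.05).
#' @param cluster_min Minimum cluster size for strategy iii (default 5).
#' @param shape Array dimensions for cluster labeling when `p` is a
#'   vector restricted to `mask`.
#' @param mask Optional logical array locating the entries of `p`.
#' @return Logical vector (or array when `p` is an array / `mask` given)
#'   marking suprathreshold voxels.
#' @export
threshold_map <- function(p, strategy = c("i", "ii", "iii"),
                          q = 0.05, p_unc = 0.001, p_clu = 0.05,
                          cluster_min = 5, shape = NULL, mask = NULL) {
  strategy <- match.arg(strategy)
  pv <- as.vector(p)
  if (strategy == "i") {
    keep <- stats::p.adjust(pv, method = "BH") <= q
  } else if (strategy == "ii") {
    keep <- pv < p_unc
  } else {
    keep <- pv < p_clu
    # embed into an array for connectivity
    if (!is.null(mask)) {
      arr <- array(FALSE, dim = dim(mask))
      arr[mask] <- keep
    } else {
      if (is.null(dim(p)) && is.null(shape))
        stop_param("strategy iii needs array-shaped input (or shape/mask)")
      arr <- array(keep, dim = if (!is.null(shape)) shape else dim(p))
    }
    labs <- label_components(arr)
    sizes <- tabulate(labs[labs > 0])
    small <- which(sizes < cluster_min)
    arr[labs %in% small] <- FALSE
    keep <- if (!is.null(mask)) arr[mask] else as.vector(arr)
  }
  if (!is.null(mask)) {
    out <- array(FALSE, dim = dim(mask))
    out[mask] <- keep
    return(out)
  }
  if (!is.null(dim(p))) return(array(keep, dim = dim(p)))
  keep
}
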