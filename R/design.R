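# Two-session block-diagonal design matrix for the retinotopic GLM.

#' Task regressors for one wedge session
#'
#' The quadrature pair capturing a traveling-wave response at `ncyc`
#' cycles per run.  Clockwise:
#' `x1(t) = -sin(2 ncyc t pi / Nvol)`, `x2(t) = -cos(2 ncyc t pi / Nvol)`;
#' counter-clockwise: `x1` is negated (the wedge turns the other way) and
#' `x2` is unchanged.  `t = 0, ..., Nvol - 1`.
#'
#' @param Nvol Volumes per run.
#' @param ncyc Stimulus cycles per run (> 0).
#' @param session `"clockwise"` or `"counterclockwise"`.
#' @return Nvol x 2 matrix with columns `task1`, `task2`.
#' @export
task_regressors <- function(Nvol, ncyc,
                            session = c("clockwise", "counterclockwise")) {
  session <- match.arg(session)
  if (ncyc <= 0) stop_param("ncyc must be positive")
  tt <- seq_len(Nvol) - 1
  w <- 2 * ncyc * pi / Nvol
  x1 <- -sin(w * tt)
  x2 <- -cos(w * tt)
  if (session == "counterclockwise") x1 <- -x1
  cbind(task1 = x1, task2 = x2)
}

#' Two-session block-diagonal design matrix
#'
#' Per session the block holds `[task x2, motion x6, drift t, baseline 1]`
#' (Q/2 = 10 columns); the two blocks are stacked block-diagonally so rows
#' of session 1 are exactly zero on session-2 columns and vice versa
#' (Q = 20 columns, 2 Nvol rows at defaults).
#'
#' @param Nvol Volumes per run (default 120).
#' @param TR Volumetric TR in s (default 2.4).
#' @param Pcyc Wedge period in s (default 32).
#' @param motion1,motion2 Optional Nvol x 6 motion-regressor matrices per
#'   session (zeros when absent).
#' @return Object of class `design_matrix`: `X` (2Nvol x Q), `labels`,
#'   `task_cols` (indices of the four task columns), `session` (row
#'   session index), `Nvol`, `ncyc`.
#' @export
build_design <- function(Nvol = 120, TR = 2.4, Pcyc = 32,
                         motion1 = NULL, motion2 = NULL) {
  ncyc <- Nvol * TR / Pcyc
  if (abs(ncyc - round(ncyc)) > 1e-9)
    stop_param("Nvol * TR / Pcyc must be a whole number of cycles")
  ncyc <- round(ncyc)
  tt <- seq_len(Nvol) - 1

  block <- function(session, motion) {
    task <- task_regressors(Nvol, ncyc, session)
    if (is.null(motion)) motion <- matrix(0, Nvol, 6)
    motion <- as.matrix(motion)
    if (nrow(motion) != Nvol || ncol(motion) != 6)
      stop_param("motion regressors must be Nvol x 6")
    cbind(task, motion, drift = tt, baseline = 1)
  }
  X1 <- block("clockwise", motion1)
  X2 <- block("counterclockwise", motion2)
  q2 <- ncol(X1)
  X <- rbind(cbind(X1, matrix(0, Nvol, q2)),
             cbind(matrix(0, Nvol, q2), X2))
  labels <- c(paste0("s1_", c("task1", "task2", paste0("mot", 1:6), "drift", "baseline")),
              paste0("s2_", c("task1", "task2", paste0("mot", 1:6), "drift", "baseline")))
  colnames(X) <- labels
  structure(list(X = X, labels = labels,
                 task_cols = c(1L, 2L, q2 + 1L, q2 + 2L),
                 session = rep(1:2, each = Nvol),
                 Nvol = as.integer(Nvol), ncyc = ncyc, Q = 2L * q2),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("Design matrix: %d rows x %d columns (2 sessions of %d volumes, %d cycles/run)\n",
              nrow(x$X), ncol(x$X), x$Nvol, x$ncyc))
  invisible(x)
}
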