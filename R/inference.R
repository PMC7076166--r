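## Estimation procedures: exhaustive-search diameter fitting with a
## 1%-of-minimum plausibility interval, and a minimal DTI/FA fit.

#' Exhaustive-search cylinder diameter fit
#'
#' Computes the RMAE between the input signal and the analytic GPD cylinder
#' signal for every diameter on a grid (default 0.4 to 8 um in 0.01 um
#' steps). The best diameter is the argmin (ties broken toward the smaller
#' diameter); the plausible interval is the contiguous grid run containing
#' the argmin whose RMAE stays within \code{threshold} (default 1%) of the
#' minimum fitting error.
#'
#' @param signal a \code{signal_set} or numeric vector (intra-axonal,
#'   normalized).
#' @param p the acquisition \code{pgse_protocol} (defaults to the signal's).
#' @param D diffusivity used for the analytic signals (m^2/s).
#' @param axis assumed cylinder axis.
#' @param grid diameter grid in meters, ascending.
#' @param threshold fractional tolerance above the minimum RMAE defining
#'   the plausible range.
#' @return a \code{diameter_fit} with \code{best_diameter},
#'   \code{plausible_interval}, \code{min_rmae} (%), and the per-grid
#'   \code{rmae} profile.
#' @export
fit_diameter_exhaustive <- function(signal, p = NULL, D = 0.6e-9,
                                    axis = c(0, 0, 1),
                                    grid = seq(0.4e-6, 8.0e-6, by = 0.01e-6),
                                    threshold = 0.01) {
  if (inherits(signal, "signal_set") && is.null(p)) p <- signal$protocol
  if (is.null(p)) stop("a protocol is required")
  s <- signal_values(signal)
  if (any(!is.finite(s))) stop("non-finite signal values")
  stopifnot(!is.unsorted(grid), all(grid > 0))
  S <- cylinder_signal_matrix(grid / 2, axis, D, p)
  err <- 100 * colMeans(abs(s - S) / abs(s))
  best <- which.min(err)               # which.min takes the first = smallest
  lim <- err[best] * (1 + threshold)
  lo <- best
  while (lo > 1 && err[lo - 1] <= lim) lo <- lo - 1
  hi <- best
  while (hi < length(grid) && err[hi + 1] <= lim) hi <- hi + 1
  structure(list(best_diameter = grid[best],
                 plausible_interval = c(grid[lo], grid[hi]),
                 min_rmae = err[best],
                 rmae = err, grid = grid, threshold = threshold),
            class = "diameter_fit")
}

#' @export
print.diameter_fit <- function(x, ...) {
  cat(sprintf("diameter_fit: best %.2f um [%.2f, %.2f], min RMAE %.3f%%\n",
              x$best_diameter * 1e6, x$plausible_interval[1] * 1e6,
              x$plausible_interval[2] * 1e6, x$min_rmae))
  invisible(x)
}

#' Ordinary least-squares diffusion tensor fit
#'
#' Fits \eqn{-\ln(S/S_0) = b\, g^T D g} by OLS on the selected measurements
#' and derives MD, FA and the principal eigenvector. Intended as a masking
#' and visualization aid (voxels are diameter-fitted only where FA exceeds
#' a threshold), not as a microstructure model.
#'
#' @param signal \code{signal_set} or numeric vector.
#' @param p protocol (defaults to the signal's).
#' @param shell b-value (s/mm^2) selecting the shell to fit (nearest unique
#'   protocol b-value), or \code{NULL} to use all measurements with G > 0.
#' @return a \code{tensor_fit}: \code{tensor} (3 x 3, m^2/s), \code{md},
#'   \code{fa}, \code{evals}, \code{principal} plus a
#'   \code{negative_eigenvalues} flag (clamped to zero).
#' @export
fit_dti <- function(signal, p = NULL, shell = NULL) {
  if (inherits(signal, "signal_set") && is.null(p)) p <- signal$protocol
  s <- signal_values(signal)
  b <- protocol_bvalues(p) * 1e6            # s/m^2
  keep <- p$table$G > 0
  if (!is.null(shell)) {
    ub <- unique(round(protocol_bvalues(p)))
    target <- ub[which.min(abs(ub - shell))]
    keep <- keep & (abs(protocol_bvalues(p) - target) < 1)
  }
  if (any(s[keep] <= 0)) stop("non-positive signal in the selected shell")
  g <- as.matrix(p$table[keep, c("gx", "gy", "gz")])
  X <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  X <- X * b[keep]
  if (qr(X)$rank < 6)
    stop("rank-deficient tensor design: need >= 6 non-collinear directions")
  y <- -log(s[keep])
  beta <- solve(crossprod(X), crossprod(X, y))
  Dt <- matrix(c(beta[1], beta[4], beta[5],
                 beta[4], beta[2], beta[6],
                 beta[5], beta[6], beta[3]), 3, 3)
  e <- eigen(Dt, symmetric = TRUE)
  neg <- any(e$values < 0)
  ev <- pmax(e$values, 0)
  md <- mean(ev)
  fa <- if (sum(ev^2) == 0) 0 else
    sqrt(3 / 2) * sqrt(sum((ev - md)^2) / sum(ev^2))
  structure(list(tensor = Dt, md = md, fa = min(fa, 1), evals = ev,
                 principal = e$vectors[, 1],
                 negative_eigenvalues = neg),
            class = "tensor_fit")
}

#' @export
print.tensor_fit <- function(x, ...) {
  cat(sprintf("tensor_fit: MD %.3g m^2/s, FA %.3f, e1 = (%.3f, %.3f, %.3f)\n",
              x$md, x$fa, x$principal[1], x$principal[2], x$principal[3]))
  invisible(x)
}

#' FA mask for diameter fitting
#'
#' Diameter fitting on voxel maps is applied only where FA exceeds the
#' threshold (default 0.25), separating coherent white-matter-like voxels
#' from mixed ones.
#'
#' @param fa numeric FA values.
#' @param threshold FA cutoff.
#' @return logical mask.
#' @export
fa_mask <- function(fa, threshold = 0.25) fa > threshold
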