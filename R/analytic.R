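## Closed-form reference signals and scalar formulas.

.mcdsim_env <- new.env(parent = emptyenv())

## Roots of J1'(x) = 0 (derivative of the order-1 Bessel function of the
## first kind), used by the Gaussian-phase-distribution cylinder series.
## Computed once by bracketed bisection on a sign-change scan and cached.
## J1'(x) = J0(x) - J1(x)/x.
bessel_j1prime_roots <- function(n = 1024L) {
  cached <- .mcdsim_env$j1p_roots
  if (!is.null(cached) && length(cached) >= n) return(cached[seq_len(n)])
  f <- function(x) besselJ(x, 0) - besselJ(x, 1) / x
  ## roots are interlaced ~pi apart; first is ~1.8412
  roots <- numeric(n)
  lo <- 0.5
  for (m in seq_len(n)) {
    hi <- lo + 0.05
    while (sign(f(lo)) == sign(f(hi))) {
      lo <- hi
      hi <- hi + 0.05
      if (hi > 10 + n * 4) stop("failed to bracket Bessel root ", m)
    }
    r <- uniroot(f, c(lo, hi), tol = 1e-14)$root
    roots[m] <- r
    lo <- r + 1.0
  }
  .mcdsim_env$j1p_roots <- roots
  roots
}

## Dimensionless-in-G part of the GPD log-attenuation for a cylinder of
## radius R (m): ln(S_perp/S0) = -2 * gamma^2 * Gperp^2 * series_sum.
## Vectorized over R. Series truncated when the next term contributes
## < 1e-10 relative; errors if the root table is exhausted first.
gpd_series_sum <- function(R, D, delta, Delta, n_roots = 1024L) {
  mu <- bessel_j1prime_roots(n_roots)
  out <- numeric(length(R))
  for (i in seq_along(R)) {
    a2 <- (mu / R[i])^2                      # alpha_m^2, 1/m^2
    x <- D * a2
    num <- 2 * x * delta - 2 +
      2 * exp(-x * delta) + 2 * exp(-x * Delta) -
      exp(-x * (Delta - delta)) - exp(-x * (Delta + delta))
    terms <- num / (D^2 * a2^3 * (mu^2 - 1))
    cs <- cumsum(terms)
    rel <- abs(terms) / pmax(abs(cs), .Machine$double.xmin)
    k <- which(rel < 1e-10)[1]
    if (is.na(k))
      stop("GPD series did not converge within ", n_roots,
           " Bessel roots (R = ", signif(R[i], 4),
           " m); increase n_roots")
    out[i] <- cs[k]
  }
  out
}

#' GPD perpendicular attenuation of a cylinder
#'
#' Signal attenuation \eqn{S_\perp/S_0} of spins restricted in an infinite
#' impermeable cylinder for the gradient component perpendicular to the
#' cylinder axis, under the Gaussian Phase Distribution approximation
#' (Van Gelderen series over the roots of \eqn{J_1'}).
#'
#' @param R cylinder radius (m); may be a vector.
#' @param D diffusivity (m^2/s).
#' @param Gperp perpendicular gradient magnitude (T/m).
#' @param delta pulse duration (s).
#' @param Delta pulse separation (s).
#' @param gamma gyromagnetic ratio (rad s^-1 T^-1).
#' @param n_roots size of the precomputed Bessel-root table.
#' @return attenuation(s) in (0, 1].
#' @export
gpd_perpendicular_attenuation <- function(R, D, Gperp, delta, Delta,
                                          gamma = GYROMAGNETIC_RATIO,
                                          n_roots = 1024L) {
  stopifnot(all(R > 0), D >= 0)
  if (Gperp == 0 || D == 0) return(rep(1, length(R)))
  exp(-2 * gamma^2 * Gperp^2 * gpd_series_sum(R, D, delta, Delta, n_roots))
}

#' Cylinder specification
#' @param radius cylinder radius (m).
#' @param axis unit 3-vector (default +z).
#' @return a \code{cylinder_spec}.
#' @export
cylinder_spec <- function(radius, axis = c(0, 0, 1)) {
  axis <- as.numeric(axis)
  stopifnot(radius > 0, length(axis) == 3)
  nrm <- sqrt(sum(axis^2))
  stopifnot(abs(nrm - 1) < 1e-8)
  structure(list(radius = radius, axis = axis / nrm), class = "cylinder_spec")
}

#' Construct a signal set
#'
#' Normalized diffusion-weighted signals \eqn{S/S_0}, one per protocol
#' measurement, optionally with per-compartment sub-signals and weights.
#'
#' @param values numeric vector of \eqn{S/S_0}.
#' @param protocol the generating \code{pgse_protocol}.
#' @param sub optional named list of compartment sub-signal vectors.
#' @param weights optional named compartment weights (sum to 1).
#' @return a \code{signal_set}.
#' @export
signal_set <- function(values, protocol, sub = NULL, weights = NULL) {
  values <- as.numeric(values)
  if (length(values) != n_measurements(protocol))
    stop("signal length (", length(values), ") != protocol length (",
         n_measurements(protocol), ")")
  if (any(values < 0)) stop("signal values must be non-negative")
  structure(list(values = values, protocol = protocol,
                 sub = sub, weights = weights),
            class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  cat(sprintf("signal_set: %d measurements, S/S0 in [%.4f, %.4f]\n",
              length(x$values), min(x$values), max(x$values)))
  if (!is.null(x$sub))
    cat("  compartments:", paste(names(x$sub), collapse = ", "), "\n")
  invisible(x)
}

signal_values <- function(s) if (inherits(s, "signal_set")) s$values else as.numeric(s)

#' Analytic PGSE signal of a straight cylinder
#'
#' Per measurement, the gradient is decomposed into components parallel and
#' perpendicular to the cylinder axis. The parallel (unrestricted) component
#' attenuates as \eqn{\exp(-b_\parallel D)}; the perpendicular component by
#' the GPD series. The product is returned.
#'
#' @param cyl a \code{cylinder_spec} (or radius in m, axis +z).
#' @param D diffusivity (m^2/s).
#' @param p a \code{pgse_protocol}.
#' @param gamma gyromagnetic ratio.
#' @return a \code{signal_set}.
#' @export
cylinder_signal <- function(cyl, D, p, gamma = GYROMAGNETIC_RATIO) {
  if (is.numeric(cyl)) cyl <- cylinder_spec(cyl)
  sig <- cylinder_signal_matrix(cyl$radius, cyl$axis, D, p, gamma)[, 1]
  signal_set(sig, p)
}

## Signal matrix (n_measurements x n_radii) for straight cylinders sharing
## one axis; the GPD series is evaluated once per (shell, radius).
cylinder_signal_matrix <- function(radii, axis, D, p,
                                   gamma = GYROMAGNETIC_RATIO) {
  sh <- protocol_shells(p)
  tab <- p$table
  gvec <- cbind(tab$gx, tab$gy, tab$gz) * tab$G
  gpar <- as.numeric(gvec %*% axis)
  gperp2 <- pmax(tab$G^2 - gpar^2, 0)
  out <- matrix(NA_real_, nrow(tab), length(radii))
  for (s in seq_len(nrow(sh$shells))) {
    idx <- which(sh$shell_id == s)
    del <- sh$shells$delta[s]; Del <- sh$shells$Delta[s]
    if (sh$shells$G[s] == 0 || D == 0) {
      out[idx, ] <- 1
      next
    }
    csum <- gpd_series_sum(radii, D, del, Del)
    bpar_si <- gamma^2 * gpar[idx]^2 * del^2 * (Del - del / 3)  # s/m^2
    for (j in seq_along(radii)) {
      out[idx, j] <- exp(-bpar_si * D) *
        exp(-2 * gamma^2 * gperp2[idx] * csum[j])
    }
  }
  out
}

#' Volume-weighted mixture signal of parallel cylinders
#'
#' The intra-axonal signal of a set of parallel cylinders is the
#' volume-weighted average of the per-cylinder analytic signals; for a
#' common length the volumes reduce to cross-sectional areas
#' \eqn{\pi r_j^2}.
#'
#' @param cylinders list of \code{cylinder_spec}, or numeric radii (m)
#'   with a common axis.
#' @param D diffusivity (m^2/s).
#' @param p a \code{pgse_protocol}.
#' @param axis common axis when \code{cylinders} is numeric.
#' @param gamma gyromagnetic ratio.
#' @return a \code{signal_set}; attribute \code{"weights"} holds the
#'   normalized volume weights.
#' @export
mixture_signal <- function(cylinders, D, p, axis = c(0, 0, 1),
                           gamma = GYROMAGNETIC_RATIO) {
  if (length(cylinders) == 0) stop("empty cylinder list")
  if (is.list(cylinders)) {
    radii <- vapply(cylinders, function(c) c$radius, numeric(1))
    axes <- vapply(cylinders, function(c) c$axis, numeric(3))
    if (max(apply(axes, 1, function(r) diff(range(r)))) > 1e-12)
      stop("mixture_signal requires a common cylinder axis")
    axis <- axes[, 1]
  } else radii <- as.numeric(cylinders)
  stopifnot(all(radii > 0))
  w <- radii^2 / sum(radii^2)
  ur <- unique(radii)
  S <- cylinder_signal_matrix(ur, axis, D, p, gamma)
  vals <- as.numeric(S[, match(radii, ur), drop = FALSE] %*% w)
  out <- signal_set(vals, p)
  attr(out, "weights") <- w
  out
}

#' Relative mean absolute error between two signal sets
#'
#' \eqn{\mathrm{RMAE} = \frac{100}{N}\sum_i |S_{gt}(i)-S_c(i)|/|S_{gt}(i)|},
#' in percent, with the first argument as ground truth.
#'
#' @param s_gt ground-truth signals (\code{signal_set} or numeric).
#' @param s_c compared signals.
#' @return RMAE in percent.
#' @export
rmae <- function(s_gt, s_c) {
  a <- signal_values(s_gt); b <- signal_values(s_c)
  if (length(a) != length(b))
    stop("signal length mismatch: ", length(a), " vs ", length(b))
  if (any(abs(a) <= 1e-12))
    stop("ground-truth signal has entries below 1e-12; ",
         "RMAE requires a normalized positive reference")
  100 * mean(abs(a - b) / abs(a))
}

#' Minimum differentiable cylinder diameter
#'
#' Resolution limit of single-shell PGSE diameter estimation,
#' \eqn{d_{min} = (768\,\sigma D / (7\gamma^2\delta |G|^2))^{1/4}}.
#'
#' @param sigma significance level as a fraction (minimum tolerated
#'   fractional signal change), e.g. 0.01.
#' @param D diffusivity (m^2/s).
#' @param delta pulse duration (s).
#' @param G gradient magnitude (T/m).
#' @param gamma gyromagnetic ratio (rad s^-1 T^-1).
#' @return minimum differentiable diameter in meters.
#' @export
resolution_limit <- function(sigma, D, delta, G, gamma = GYROMAGNETIC_RATIO) {
  stopifnot(sigma > 0, D > 0, delta > 0, G > 0, gamma > 0)
  (768 * sigma * D / (7 * gamma^2 * delta * G^2))^(1 / 4)
}

#' Tortuosity of a helical undulation
#'
#' \eqn{\lambda = \sqrt{(2\pi A/L)^2 + 1}}: arc length per unit axial
#' length of the helix with amplitude \code{A} and wavelength \code{L}.
#'
#' @param A undulation amplitude (m).
#' @param L undulation wavelength (m).
#' @return tortuosity factor (>= 1).
#' @export
tortuosity <- function(A, L) {
  stopifnot(all(L > 0), all(A >= 0))
  sqrt((2 * pi * A / L)^2 + 1)
}

#' Effective apparent radius of a radius ensemble
#'
#' \eqn{r_{eff} = (\langle r^6\rangle/\langle r^2\rangle)^{1/4}}, the
#' MR-visible (tail-weighted) apparent radius of a distribution of radii.
#'
#' @param radii positive radii (m).
#' @return effective radius (m).
#' @export
effective_radius <- function(radii) {
  if (length(radii) == 0) stop("empty radius list")
  stopifnot(all(radii > 0))
  (mean(radii^6) / mean(radii^2))^(1 / 4)
}

#' Protocol sensitivity matrix over a diameter grid
#'
#' Entry (i, j) is the RMAE of the analytic cylinder signal of
#' \code{diameters[j]} against that of \code{diameters[i]} taken as ground
#' truth. The matrix is generally asymmetric (the denominator is the
#' ground-truth signal). A logical mask marks entries at or below
#' \code{level} percent, whose boundary is the protocol's discrimination
#' level curve.
#'
#' @param diameters ascending diameter grid (m).
#' @param D diffusivity (m^2/s).
#' @param p a \code{pgse_protocol}.
#' @param level level-set threshold in percent (default 1).
#' @param axis cylinder axis.
#' @return list with \code{rmae} (matrix, percent), \code{mask}
#'   (logical matrix, RMAE <= level) and \code{diameters}.
#' @export
sensitivity_matrix <- function(diameters, D, p, level = 1, axis = c(0, 0, 1)) {
  stopifnot(!is.unsorted(diameters), all(diameters > 0))
  S <- cylinder_signal_matrix(diameters / 2, axis, D, p)
  n <- length(diameters)
  M <- matrix(0, n, n, dimnames = list(gt = signif(diameters * 1e6, 6),
                                       cmp = signif(diameters * 1e6, 6)))
  for (i in seq_len(n)) {
    M[i, ] <- 100 * colMeans(abs(S - S[, i]) / abs(S[, i]))
  }
  list(rmae = M, mask = M <= level, diameters = diameters)
}
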