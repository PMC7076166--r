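## Crossing-substrate framework: strands (polylines with radius), an
## overlap/curvature/length energy, a greedy stochastic optimizer, gamma
## sub-strand subdivision, and tube meshing.

#' Strand: a polyline with constant radius
#'
#' @param control_points n x 3 matrix of backbone points (m), n >= 2,
#'   consecutive points distinct.
#' @param radius strand radius (m).
#' @return a \code{strand}.
#' @export
strand <- function(control_points, radius) {
  cp <- matrix(as.numeric(control_points), ncol = 3)
  stopifnot(nrow(cp) >= 2, radius > 0)
  if (any(rowSums(diff(cp)^2) == 0))
    stop("consecutive control points must be distinct")
  structure(list(control_points = cp, radius = radius), class = "strand")
}

#' Strand system with energy weights
#'
#' @param strands list of \code{strand}.
#' @param w_o,w_c,w_l non-negative weights of the overlap, curvature and
#'   length penalties. Overlap dominates by default (zero overlap is a hard
#'   requirement of the generated substrates).
#' @param box optional 2 x 3 bounding box (rows: lower, upper corners, m).
#' @return a \code{strand_system}.
#' @export
strand_system <- function(strands, w_o = 1e3, w_c = 1, w_l = 1, box = NULL) {
  stopifnot(length(strands) >= 1, w_o >= 0, w_c >= 0, w_l >= 0)
  if (!is.null(box)) {
    box <- matrix(as.numeric(box), 2, 3)
    for (s in strands) {
      cp <- s$control_points
      if (any(t(cp) < box[1, ] - 1e-12) || any(t(cp) > box[2, ] + 1e-12))
        stop("control point outside the bounding volume")
    }
  }
  structure(list(strands = strands, w_o = w_o, w_c = w_c, w_l = w_l,
                 box = box),
            class = "strand_system")
}

#' @export
print.strand_system <- function(x, ...) {
  e <- strand_energy(x)
  cat(sprintf("strand_system: %d strands, E = %.4g (Jo %.3g, Jc %.3g, Jl %.3g)\n",
              length(x$strands), e$E, e$J_o, e$J_c, e$J_l))
  invisible(x)
}

## minimum distance between segments p1-p2 and q1-q2 (clamped closed form)
segment_distance <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1; r <- p1 - q1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a <= 1e-300 && e <= 1e-300) return(sqrt(sum(r * r)))
  if (a <= 1e-300) {
    s <- 0; t <- min(max(f / e, 0), 1)
  } else {
    c_ <- sum(d1 * r)
    if (e <= 1e-300) {
      t <- 0; s <- min(max(-c_ / a, 0), 1)
    } else {
      b <- sum(d1 * d2)
      den <- a * e - b * b
      s <- if (den > 0) min(max((b * f - c_ * e) / den, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-c_ / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - c_) / a, 0), 1) }
    }
  }
  cp <- p1 + s * d1; cq <- q1 + t * d2
  sqrt(sum((cp - cq)^2))
}

#' Total penetration depth between two strands
#'
#' Capsule-capsule test: for every pair of backbone segments, the
#' penetration is \code{max(0, r_a + r_b - d)} with \code{d} the minimum
#' segment-segment distance; the total over pairs is returned.
#'
#' @param a,b \code{strand} objects.
#' @return total penetration depth (m); 0 when the strands do not overlap.
#' @export
strand_overlap <- function(a, b) {
  pa <- a$control_points; pb <- b$control_points
  rr <- a$radius + b$radius
  tot <- 0
  for (i in seq_len(nrow(pa) - 1)) {
    ## bbox prefilter
    lo <- pmin(pa[i, ], pa[i + 1, ]) - rr
    hi <- pmax(pa[i, ], pa[i + 1, ]) + rr
    for (j in seq_len(nrow(pb) - 1)) {
      if (any(pmax(pb[j, ], pb[j + 1, ]) < lo) ||
          any(pmin(pb[j, ], pb[j + 1, ]) > hi)) next
      d <- segment_distance(pa[i, ], pa[i + 1, ], pb[j, ], pb[j + 1, ])
      if (d < rr) tot <- tot + (rr - d)
    }
  }
  tot
}

strand_curvature_energy <- function(s) {
  cp <- s$control_points
  n <- nrow(cp)
  if (n < 3) return(0)
  a <- cp[2:(n - 1), , drop = FALSE] - cp[1:(n - 2), , drop = FALSE]
  b <- cp[3:n, , drop = FALSE] - cp[2:(n - 1), , drop = FALSE]
  cosang <- rowSums(a * b) /
    (sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)))
  sum(acos(pmin(1, pmax(-1, cosang)))^2)
}

strand_length_energy <- function(s) {
  cp <- s$control_points
  arc <- sum(sqrt(rowSums(diff(cp)^2)))
  chord <- sqrt(sum((cp[nrow(cp), ] - cp[1, ])^2))
  if (chord == 0) return(Inf)
  arc / chord - 1
}

#' Energy of a strand system
#'
#' \eqn{E = w_o J_o + w_c J_c + w_l J_l} with all three terms
#' dimensionless so the weights compare like with like: \eqn{J_o} sums,
#' over strand pairs, the squared penetration depth normalized by the
#' pair's radius sum; \eqn{J_c} the squared turn angles at interior control
#' points; \eqn{J_l} the relative excess of polyline length over the
#' endpoint chord.
#'
#' @param sys a \code{strand_system}.
#' @return list with \code{E} and the \code{J_o}, \code{J_c}, \code{J_l}
#'   breakdown (unweighted).
#' @export
strand_energy <- function(sys) {
  n <- length(sys$strands)
  J_o <- 0
  if (n > 1)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      J_o <- J_o + (strand_overlap(sys$strands[[i]], sys$strands[[j]]) /
                      (sys$strands[[i]]$radius + sys$strands[[j]]$radius))^2
  J_c <- sum(vapply(sys$strands, strand_curvature_energy, numeric(1)))
  J_l <- sum(vapply(sys$strands, strand_length_energy, numeric(1)))
  list(E = sys$w_o * J_o + sys$w_c * J_c + sys$w_l * J_l,
       J_o = J_o, J_c = J_c, J_l = J_l)
}

#' Optimize a strand system by greedy stochastic descent
#'
#' Repeatedly perturbs one random interior control point by a Gaussian step
#' and accepts the move only if the total energy decreases. Endpoints are
#' fixed (they pin the strands to the entry/exit faces of the bounding
#' volume). The energy sequence is non-increasing; a final positive overlap
#' is reported via the \code{converged} flag, not an error.
#'
#' @param sys a \code{strand_system}.
#' @param iterations number of proposals.
#' @param step_scale standard deviation of the perturbation (m).
#' @param seed RNG seed (deterministic optimization).
#' @return the optimized \code{strand_system}; attributes
#'   \code{energy_trace} (accepted energies), \code{final_energy},
#'   \code{converged} (TRUE iff final J_o == 0).
#' @export
optimize_strands <- function(sys, iterations = 2000L, step_scale = NULL,
                             seed = 1L) {
  set.seed(seed)
  strands <- sys$strands
  n <- length(strands)
  if (is.null(step_scale))
    step_scale <- mean(vapply(strands, function(s) s$radius, numeric(1))) / 2
  ## cache pairwise overlaps and per-strand terms for delta updates
  radii <- vapply(strands, function(s) s$radius, numeric(1))
  rsum <- outer(radii, radii, "+")
  ov <- matrix(0, n, n)          # normalized penetrations
  if (n > 1)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      ov[i, j] <- ov[j, i] <- strand_overlap(strands[[i]], strands[[j]]) /
        rsum[i, j]
  jc <- vapply(strands, strand_curvature_energy, numeric(1))
  jl <- vapply(strands, strand_length_energy, numeric(1))
  E <- sys$w_o * sum(ov[upper.tri(ov)]^2) + sys$w_c * sum(jc) +
    sys$w_l * sum(jl)
  trace <- E
  movable <- which(vapply(strands, function(s) nrow(s$control_points) > 2,
                          logical(1)))
  if (length(movable)) {
    for (it in seq_len(iterations)) {
      i <- movable[sample.int(length(movable), 1)]
      s <- strands[[i]]
      interior <- 2:(nrow(s$control_points) - 1)
      k <- interior[sample.int(length(interior), 1)]
      cand <- s
      cand$control_points[k, ] <- s$control_points[k, ] +
        rnorm(3, sd = step_scale)
      if (!is.null(sys$box) &&
          (any(cand$control_points[k, ] < sys$box[1, ]) ||
           any(cand$control_points[k, ] > sys$box[2, ]))) next
      if (any(rowSums(diff(cand$control_points)^2) == 0)) next
      ov_new <- ov[i, ]
      for (j in seq_len(n)) if (j != i)
        ov_new[j] <- strand_overlap(cand, strands[[j]]) / rsum[i, j]
      jc_new <- strand_curvature_energy(cand)
      jl_new <- strand_length_energy(cand)
      dE <- sys$w_o * (sum(ov_new^2) - sum(ov[i, ]^2)) +
        sys$w_c * (jc_new - jc[i]) + sys$w_l * (jl_new - jl[i])
      if (dE < 0) {
        strands[[i]] <- cand
        ov[i, ] <- ov_new; ov[, i] <- ov_new
        jc[i] <- jc_new; jl[i] <- jl_new
        E <- E + dE
        trace <- c(trace, E)
      }
    }
  }
  out <- sys
  out$strands <- strands
  attr(out, "energy_trace") <- trace
  attr(out, "final_energy") <- E
  attr(out, "converged") <- sum(ov[upper.tri(ov)]) == 0
  out
}

#' Subdivide a strand into gamma-distributed sub-strands
#'
#' Sub-strand diameters are drawn from the truncated gamma law; their
#' cross-section disks are packed inside the parent disk by random
#' sequential addition in descending radius order, and each sub-strand is
#' swept along the parent trajectory with the parent's parallel-transport
#' frame (so sub-strands follow the backbone without twisting).
#'
#' @param s the parent \code{strand}.
#' @param gamma_spec a \code{gamma_radii_spec} (diameters; \code{count} =
#'   number of sub-strands to attempt).
#' @param seed RNG seed for the disk packing.
#' @param max_attempts placement attempts per disk.
#' @return list of \code{strand}; attribute \code{"offsets"} holds the
#'   in-disk (u, v) offsets.
#' @export
subdivide_strand <- function(s, gamma_spec, seed = 1L, max_attempts = 2000L) {
  if (s$radius <= gamma_spec$min_diameter / 2)
    stop("parent radius must exceed the sub-strand minimum radius")
  dia <- sample_gamma_diameters(gamma_spec)
  radii <- sort(dia / 2, decreasing = TRUE)
  radii <- radii[radii < s$radius]
  if (length(radii) == 0) stop("no sub-strand disk fits the parent radius")
  set.seed(seed)
  placed_u <- numeric(0); placed_v <- numeric(0); placed_r <- numeric(0)
  for (r in radii) {
    rmax_off <- s$radius - r
    done <- FALSE
    for (att in seq_len(max_attempts)) {
      ang <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1)) * rmax_off
      u <- rad * cos(ang); v <- rad * sin(ang)
      if (length(placed_r) == 0 ||
          all((placed_u - u)^2 + (placed_v - v)^2 >= (placed_r + r)^2)) {
        placed_u <- c(placed_u, u); placed_v <- c(placed_v, v)
        placed_r <- c(placed_r, r)
        done <- TRUE
        break
      }
    }
    if (!done) next  # disk does not fit; skip (tail under-representation)
  }
  if (length(placed_r) == 0) stop("no sub-strand disk could be placed")
  fr <- parallel_transport_frames(s$control_points)
  subs <- vector("list", length(placed_r))
  for (i in seq_along(placed_r)) {
    off <- outer(rep(placed_u[i], nrow(fr$u)), c(1, 1, 1)) * fr$u +
      outer(rep(placed_v[i], nrow(fr$v)), c(1, 1, 1)) * fr$v
    subs[[i]] <- strand(s$control_points + off, placed_r[i])
  }
  attr(subs, "offsets") <- cbind(u = placed_u, v = placed_v, r = placed_r)
  subs
}

#' Mesh a set of strands as capped tubes
#'
#' One watertight tube shell per strand (shells are disjoint when the
#' strands do not overlap). Self-intersecting tubes (radius exceeding the
#' backbone's radius of curvature) raise an error naming the strand.
#'
#' @param strands list of \code{strand}.
#' @param n_theta ring vertices per cross-section.
#' @return a \code{trimesh}; attribute \code{"shell"} gives the strand
#'   index of each face.
#' @export
strands_to_mesh <- function(strands, n_theta = 16L) {
  verts <- NULL; faces <- NULL; shell <- integer(0)
  for (i in seq_along(strands)) {
    s <- strands[[i]]
    m <- tryCatch(sweep_tube(s$control_points, s$radius, n_theta),
                  error = function(e)
                    stop("strand ", i, ": ", conditionMessage(e)))
    off <- if (is.null(verts)) 0L else nrow(verts)
    verts <- rbind(verts, m$vertices)
    faces <- rbind(faces, m$faces + off)
    shell <- c(shell, rep(i, nrow(m$faces)))
  }
  out <- trimesh(verts, faces)
  attr(out, "shell") <- shell
  out
}
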