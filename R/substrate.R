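## Substrate generation: gamma-distributed diameters, periodically packed
## parallel cylinders sized to a target ICVF, and swept-tube triangle meshes.

#' Gamma radii specification
#'
#' Parameters of a (optionally truncated) gamma law for axon diameters:
#' shape \code{kappa}, scale \code{theta} (m), a minimum diameter enforced
#' by rejection, a count and a seed.
#'
#' @param kappa gamma shape (dimensionless, > 0).
#' @param theta gamma scale in meters (> 0).
#' @param min_diameter truncation floor in meters (>= 0); draws below it
#'   are rejected and re-sampled.
#' @param count number of diameters to draw.
#' @param seed RNG seed.
#' @return a \code{gamma_radii_spec}.
#' @export
gamma_radii_spec <- function(kappa, theta, min_diameter = 0, count = 1L,
                             seed = 1L) {
  stopifnot(kappa > 0, theta > 0, min_diameter >= 0, count >= 1)
  structure(list(kappa = kappa, theta = theta, min_diameter = min_diameter,
                 count = as.integer(count), seed = as.integer(seed)),
            class = "gamma_radii_spec")
}

#' Sample gamma-distributed axon diameters
#'
#' I.i.d. draws from Gamma(kappa, theta); draws below the truncation floor
#' are re-sampled (rejection, preserving the distribution shape above the
#' floor). Deterministic for a fixed seed.
#'
#' @param spec a \code{gamma_radii_spec}.
#' @return numeric vector of diameters (m), length \code{spec$count}.
#' @export
sample_gamma_diameters <- function(spec) {
  acc <- 1 - pgamma(spec$min_diameter, shape = spec$kappa, scale = spec$theta)
  if (acc < 1e-3)
    stop("truncation floor ", spec$min_diameter,
         " m leaves acceptance rate ", signif(acc, 3), " (< 1e-3)")
  set.seed(spec$seed)
  out <- numeric(0)
  while (length(out) < spec$count) {
    need <- spec$count - length(out)
    d <- rgamma(ceiling(need / acc * 1.1) + 16, shape = spec$kappa,
                scale = spec$theta)
    out <- c(out, d[d >= spec$min_diameter])
  }
  out[seq_len(spec$count)]
}

#' Voxel side length achieving a target intra-axonal volume fraction
#'
#' For parallel cylinders of the given radii in a square-cross-section
#' periodic voxel, the side such that \eqn{\sum \pi r_i^2 / side^2} equals
#' the requested ICVF.
#'
#' @param radii cylinder radii (m).
#' @param icvf target intra-axonal volume fraction in (0, 1).
#' @return voxel side (m).
#' @export
voxel_side_for_icvf <- function(radii, icvf) {
  stopifnot(icvf > 0, icvf < 1, all(radii > 0))
  sqrt(sum(pi * radii^2) / icvf)
}

#' Cylinder population in a periodic voxel
#'
#' Parallel cylinders (axis +z) defined by 2D centers in the square voxel
#' cross-section, radii, the voxel side, and a periodicity flag.
#'
#' @param centers n x 2 matrix of centers (m).
#' @param radii length-n radii (m).
#' @param voxel_side square cross-section side (m).
#' @param periodic logical; minimum-image periodicity at the boundaries.
#' @param axis cylinder axis (currently +z only).
#' @return a \code{cylinder_population}.
#' @export
cylinder_population <- function(centers, radii, voxel_side, periodic = TRUE,
                                axis = c(0, 0, 1)) {
  centers <- matrix(as.numeric(centers), ncol = 2)
  stopifnot(nrow(centers) == length(radii), all(radii > 0), voxel_side > 0)
  if (any(abs(axis - c(0, 0, 1)) > 1e-12))
    stop("only the +z cylinder axis is supported")
  structure(list(centers = centers, radii = as.numeric(radii),
                 voxel_side = voxel_side, periodic = isTRUE(periodic),
                 axis = c(0, 0, 1)),
            class = "cylinder_population")
}

#' @export
print.cylinder_population <- function(x, ...) {
  cat(sprintf(
    "cylinder_population: %d cylinders, voxel %.3g x %.3g um, ICVF %.3f%s\n",
    length(x$radii), x$voxel_side * 1e6, x$voxel_side * 1e6,
    sum(pi * x$radii^2) / x$voxel_side^2,
    if (x$periodic) " (periodic)" else ""))
  invisible(x)
}

#' Analytic ICVF of a cylinder population
#' @param pop a \code{cylinder_population}.
#' @return \eqn{\sum \pi r_i^2 / side^2}.
#' @export
population_icvf <- function(pop) sum(pi * pop$radii^2) / pop$voxel_side^2

## Minimum-image pairwise overlap test used by the packer and its tests.
## Returns the count of overlapping pairs.
count_periodic_overlaps <- function(centers, radii, side, tol = 0) {
  n <- nrow(centers)
  if (n < 2) return(0L)
  cnt <- 0L
  for (i in seq_len(n - 1)) {
    dx <- centers[(i + 1):n, 1] - centers[i, 1]
    dy <- centers[(i + 1):n, 2] - centers[i, 2]
    dx <- dx - side * round(dx / side)
    dy <- dy - side * round(dy / side)
    rr <- radii[(i + 1):n] + radii[i]
    cnt <- cnt + sum(dx * dx + dy * dy < (rr - tol)^2)
  }
  cnt
}

#' Pack parallel cylinders into a periodic voxel at a target ICVF
#'
#' Random sequential addition in descending radius order: the voxel side is
#' fixed by \code{\link{voxel_side_for_icvf}}, then each cylinder is placed
#' uniformly at random and accepted if it overlaps no previously placed
#' cylinder under the minimum-image convention (periodic boundaries).
#' Deterministic for a fixed seed.
#'
#' @param diameters cylinder diameters (m).
#' @param icvf target intra-axonal volume fraction (<= 0.7; RSA cannot
#'   reliably reach denser packings).
#' @param seed RNG seed.
#' @param max_attempts placement attempts per cylinder before giving up.
#' @return a \code{cylinder_population}.
#' @export
pack_parallel_cylinders <- function(diameters, icvf = 0.6, seed = 1L,
                                    max_attempts = 10000L) {
  stopifnot(icvf > 0)
  if (icvf > 0.7) stop("requested ICVF ", icvf, " exceeds the 0.7 ceiling ",
                       "attainable by random sequential addition")
  radii <- sort(as.numeric(diameters) / 2, decreasing = TRUE)
  side <- voxel_side_for_icvf(radii, icvf)
  n <- length(radii)
  cx <- numeric(n); cy <- numeric(n)
  set.seed(seed)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      x <- runif(1, 0, side); y <- runif(1, 0, side)
      if (i == 1) { ok <- TRUE } else {
        dx <- cx[seq_len(i - 1)] - x
        dy <- cy[seq_len(i - 1)] - y
        dx <- dx - side * round(dx / side)
        dy <- dy - side * round(dy / side)
        rr <- radii[seq_len(i - 1)] + radii[i]
        ok <- all(dx * dx + dy * dy >= rr * rr)
      }
      if (ok) { cx[i] <- x; cy[i] <- y; placed <- TRUE; break }
    }
    if (!placed)
      stop("packing failed: placed ", i - 1, " of ", n,
           " cylinders at ICVF ", icvf,
           " (", max_attempts, " attempts for cylinder ", i, ")")
  }
  cylinder_population(cbind(cx, cy), radii, side, periodic = TRUE)
}

## ---------------------------------------------------------------------------
## Triangle meshes

#' Triangle mesh substrate
#'
#' A triangle soup intended to be a watertight, consistently outward-oriented
#' barrier set. Validity (watertightness, orientation, non-degeneracy) is
#' checked by \code{\link{mesh_is_watertight}}; readers flag rather than
#' reject non-watertight input.
#'
#' @param vertices n x 3 numeric matrix (m).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return a \code{trimesh}.
#' @export
trimesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (any(faces < 1) || any(faces > nrow(vertices)))
    stop("face index out of range")
  structure(list(vertices = vertices, faces = faces), class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("trimesh: %d vertices, %d faces, bbox %.3g x %.3g x %.3g um\n",
              nrow(x$vertices), nrow(x$faces),
              diff(bb[, 1]) * 1e6, diff(bb[, 2]) * 1e6, diff(bb[, 3]) * 1e6))
  invisible(x)
}

face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Signed enclosed volume of a mesh
#'
#' Divergence-theorem volume \eqn{\sum \det(v_1, v_2, v_3)/6}; positive for
#' consistently outward-oriented watertight meshes.
#'
#' @param mesh a \code{trimesh}.
#' @return signed volume (m^3).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
      p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

#' Watertightness and orientation check
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces, and consistently oriented when every directed edge appears exactly
#' once.
#'
#' @param mesh a \code{trimesh}.
#' @return logical; attributes \code{oriented} and \code{degenerate_faces}.
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  dir_key <- paste(e[, 1], e[, 2])
  und_key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  watertight <- all(table(und_key) == 2)
  oriented <- !anyDuplicated(dir_key) && watertight
  res <- watertight
  attr(res, "oriented") <- oriented
  attr(res, "degenerate_faces") <- sum(face_areas(mesh) <= 0)
  res
}

## Parallel-transport frames along a polyline: returns list(u, v) of
## n x 3 matrices spanning the plane normal to each segment-averaged tangent.
parallel_transport_frames <- function(pts) {
  n <- nrow(pts)
  seg <- diff(pts)
  seg <- seg / sqrt(rowSums(seg^2))
  tang <- rbind(seg[1, , drop = FALSE],
                (seg[-nrow(seg), , drop = FALSE] + seg[-1, , drop = FALSE]),
                seg[nrow(seg), , drop = FALSE])
  tang <- tang / sqrt(rowSums(tang^2))
  u <- matrix(0, n, 3); v <- matrix(0, n, 3)
  ref <- if (abs(tang[1, 3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u0 <- ref - sum(ref * tang[1, ]) * tang[1, ]
  u[1, ] <- u0 / sqrt(sum(u0^2))
  v[1, ] <- crossv(tang[1, ], u[1, ])
  for (i in 2:n) {
    ## rotate previous frame by the rotation taking tang[i-1] to tang[i]
    a <- tang[i - 1, ]; b <- tang[i, ]
    c_ <- sum(a * b)
    if (c_ > 1 - 1e-14) {
      u[i, ] <- u[i - 1, ]
    } else {
      ax <- crossv(a, b)
      s <- sqrt(sum(ax^2))
      ax <- ax / s
      u[i, ] <- rodrigues(u[i - 1, ], ax, s, c_)
    }
    ## re-orthogonalize against accumulated drift
    ui <- u[i, ] - sum(u[i, ] * b) * b
    u[i, ] <- ui / sqrt(sum(ui^2))
    v[i, ] <- crossv(b, u[i, ])
  }
  list(u = u, v = v, tangent = tang)
}

crossv <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

rodrigues <- function(p, axis, s, c_) {
  p * c_ + crossv(axis, p) * s + axis * sum(axis * p) * (1 - c_)
}

## Discrete curvature (1/m) at interior points of a polyline.
polyline_curvature <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(numeric(0))
  a <- pts[2:(n - 1), , drop = FALSE] - pts[1:(n - 2), , drop = FALSE]
  b <- pts[3:n, , drop = FALSE] - pts[2:(n - 1), , drop = FALSE]
  la <- sqrt(rowSums(a^2)); lb <- sqrt(rowSums(b^2))
  cosang <- pmin(1, pmax(-1, rowSums(a * b) / (la * lb)))
  2 * sin(acos(cosang) / 2) / ((la + lb) / 2)
}

#' Sweep a circular tube along a polyline
#'
#' Closed (end-capped) tube of the given radius around the centerline, using
#' a parallel-transport frame (no frame flips on helices). Errors when the
#' tube would locally self-intersect (radius exceeding the centerline's
#' radius of curvature).
#'
#' @param centerline n x 3 matrix of centerline points (m).
#' @param radius tube radius (m).
#' @param n_theta number of vertices per cross-section ring (>= 8).
#' @return a watertight \code{trimesh} with outward orientation.
#' @export
sweep_tube <- function(centerline, radius, n_theta = 32L) {
  centerline <- matrix(as.numeric(centerline), ncol = 3)
  n <- nrow(centerline)
  stopifnot(n >= 2, radius > 0, n_theta >= 8)
  kap <- polyline_curvature(centerline)
  if (length(kap) && max(kap) * radius >= 1)
    stop("tube self-intersection: radius ", signif(radius, 4),
         " m exceeds minimum radius of curvature ",
         signif(1 / max(kap), 4), " m")
  fr <- parallel_transport_frames(centerline)
  th <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  ct <- cos(th); st <- sin(th)
  nv <- n * n_theta
  verts <- matrix(0, nv + 2, 3)
  for (i in seq_len(n)) {
    ring <- (i - 1) * n_theta + seq_len(n_theta)
    verts[ring, ] <- rep(centerline[i, ], each = n_theta) +
      radius * (outer(ct, fr$u[i, ]) + outer(st, fr$v[i, ]))
  }
  verts[nv + 1, ] <- centerline[1, ]     # start cap center
  verts[nv + 2, ] <- centerline[n, ]     # end cap center
  faces <- matrix(0L, 2 * (n - 1) * n_theta + 2 * n_theta, 3)
  k <- 0L
  for (i in seq_len(n - 1)) {
    a <- (i - 1) * n_theta
    b <- i * n_theta
    for (j in seq_len(n_theta)) {
      jn <- if (j == n_theta) 1L else j + 1L
      faces[k + 1, ] <- c(a + j, b + j, b + jn)
      faces[k + 2, ] <- c(a + j, b + jn, a + jn)
      k <- k + 2L
    }
  }
  for (j in seq_len(n_theta)) {          # start cap (inward tangent side)
    jn <- if (j == n_theta) 1L else j + 1L
    faces[k + 1, ] <- c(nv + 1L, j + 0L, jn + 0L)
    k <- k + 1L
  }
  last <- (n - 1) * n_theta
  for (j in seq_len(n_theta)) {          # end cap
    jn <- if (j == n_theta) 1L else j + 1L
    faces[k + 1, ] <- c(nv + 2L, last + jn, last + j)
    k <- k + 1L
  }
  m <- trimesh(verts, faces)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Helical undulating axon mesh
#'
#' Tube of circular cross-section swept along the helical centerline
#' \eqn{U(z) = (A\cos(2\pi z/L), A\sin(2\pi z/L), z)} with equal x/y
#' amplitudes (helical undulation), wavelength \code{L} and total axial
#' extent \code{length}.
#'
#' @param diameter tube diameter (m).
#' @param A undulation amplitude (m); 0 gives a straight cylinder.
#' @param L undulation wavelength (m).
#' @param length axial extent (m).
#' @param n_theta ring vertices (default 32).
#' @param n_per_wavelength centerline segments per wavelength (default 64).
#' @return a watertight \code{trimesh}; attribute \code{"centerline"} holds
#'   the swept polyline.
#' @export
undulating_mesh <- function(diameter, A, L, length, n_theta = 32L,
                            n_per_wavelength = 64L) {
  stopifnot(diameter > 0, A >= 0, L > 0, length > 0, n_theta >= 8)
  n_seg <- max(8L, as.integer(ceiling(length / L * n_per_wavelength)))
  z <- seq(0, length, length.out = n_seg + 1)
  ctr <- cbind(A * cos(2 * pi * z / L), A * sin(2 * pi * z / L), z)
  m <- sweep_tube(ctr, diameter / 2, n_theta)
  attr(m, "centerline") <- ctr
  m
}

#' Arc length of the helical centerline
#' @param A amplitude (m); @param L wavelength (m); @param length axial
#'   extent (m).
#' @return arc length (m), \code{length * tortuosity(A, L)}.
#' @export
helix_arc_length <- function(A, L, length) length * tortuosity(A, L)

## ---------------------------------------------------------------------------
## Mesh I/O (ASCII OFF and PLY)

#' Write a triangle mesh
#'
#' ASCII OFF or PLY. Coordinates are written with 12 significant digits; a
#' write/read roundtrip preserves them to at least 9 significant digits and
#' the face topology exactly.
#'
#' @param mesh a \code{trimesh}.
#' @param path output path.
#' @param format \code{"off"} or \code{"ply"}; default from the extension.
#' @return \code{path}, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "off", "ply")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "off"
  v <- mesh$vertices; f <- mesh$faces - 1L
  vl <- apply(v, 1, function(r) paste(formatC(r, format = "g", digits = 12),
                                      collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "off") {
    writeLines("OFF", con)
    writeLines(sprintf("%d %d 0", nrow(v), nrow(f)), con)
    writeLines(vl, con)
    writeLines(sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices",
                 "end_header"), con)
    writeLines(vl, con)
    writeLines(sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}

#' Read a triangle mesh (ASCII OFF or PLY)
#'
#' Non-watertight input is accepted with a warning and the result carries
#' \code{attr(mesh, "watertight") = FALSE}.
#'
#' @param path input path.
#' @param format \code{"off"}, \code{"ply"} or \code{"auto"} (extension).
#' @return a \code{trimesh}.
#' @export
read_mesh <- function(path, format = c("auto", "off", "ply")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("mesh file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "off"
  lines <- readLines(path, warn = FALSE)
  toknum <- function(s) suppressWarnings(as.numeric(strsplit(trimws(s), "\\s+")[[1]]))
  if (format == "off") {
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    if (length(lines) < 2 || toupper(trimws(lines[1])) != "OFF")
      stop("not an OFF file: ", path)
    hdr <- toknum(lines[2])
    if (length(hdr) < 2 || anyNA(hdr[1:2])) stop("malformed OFF header in ", path)
    nv <- hdr[1]; nf <- hdr[2]
    if (length(lines) < 2 + nv + nf) stop("truncated OFF file: ", path)
    v <- t(vapply(lines[3:(2 + nv)], function(s) toknum(s)[1:3], numeric(3)))
    fl <- lapply(lines[(3 + nv):(2 + nv + nf)], toknum)
  } else {
    if (trimws(lines[1]) != "ply") stop("not a PLY file: ", path)
    endh <- which(trimws(lines) == "end_header")[1]
    if (is.na(endh)) stop("malformed PLY header (no end_header) in ", path)
    hdr <- lines[1:endh]
    if (!any(grepl("format\\s+ascii", hdr)))
      stop("only ASCII PLY is supported: ", path)
    nv <- as.integer(sub(".*element\\s+vertex\\s+(\\d+).*", "\\1",
                         grep("element\\s+vertex", hdr, value = TRUE)[1]))
    nf <- as.integer(sub(".*element\\s+face\\s+(\\d+).*", "\\1",
                         grep("element\\s+face", hdr, value = TRUE)[1]))
    if (length(lines) < endh + nv + nf) stop("truncated PLY file: ", path)
    v <- t(vapply(lines[endh + seq_len(nv)], function(s) toknum(s)[1:3],
                  numeric(3)))
    fl <- lapply(lines[endh + nv + seq_len(nf)], toknum)
  }
  if (anyNA(v)) stop("non-numeric vertex data in ", path)
  bad <- which(vapply(fl, function(x) length(x) < 4 || x[1] != 3 || anyNA(x),
                      logical(1)))
  if (length(bad))
    stop("malformed/non-triangular face record ", bad[1], " in ", path)
  f <- t(vapply(fl, function(x) x[2:4], numeric(3))) + 1L
  m <- trimesh(v, f)
  wt <- mesh_is_watertight(m)
  if (!wt) warning("mesh ", path, " is not watertight")
  attr(m, "watertight") <- as.logical(wt)
  rownames(m$vertices) <- NULL
  m
}
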