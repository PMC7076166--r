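#' @useDynLib mcdsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rgamma runif rnorm sd setNames coef lm pgamma ks.test
#' @importFrom utils read.table write.table
NULL

#' Gyromagnetic ratio of the proton
#'
#' Default gyromagnetic ratio used throughout the package,
#' 2.6751525e8 rad s^-1 T^-1.
#' @export
GYROMAGNETIC_RATIO <- 2.6751525e8

#' Construct a PGSE measurement
#'
#' A single pulsed-gradient spin-echo (PGSE) measurement: a gradient
#' direction, gradient magnitude \code{G} (T/m), pulse duration \code{delta}
#' (s), pulse separation \code{Delta} (s) and echo time \code{TE} (s).
#' All quantities are SI.
#'
#' @param direction numeric length-3 gradient direction; normalized unless
#'   \code{G = 0}, in which case it may be zero.
#' @param G gradient magnitude in T/m (non-negative).
#' @param delta gradient pulse duration in seconds.
#' @param Delta gradient pulse separation in seconds.
#' @param TE echo time in seconds.
#' @return a \code{pgse_measurement} (named list).
#' @export
pgse_measurement <- function(direction, G, delta, Delta, TE) {
  direction <- as.numeric(direction)
  stopifnot(length(direction) == 3, is.finite(direction))
  m <- structure(list(direction = direction, G = as.numeric(G),
                      delta = as.numeric(delta), Delta = as.numeric(Delta),
                      TE = as.numeric(TE)),
                 class = "pgse_measurement")
  validate_measurement(m)
  m
}

validate_measurement <- function(m, where = NULL) {
  tag <- if (is.null(where)) "" else sprintf(" (measurement %s)", where)
  if (m$G < 0) stop("gradient magnitude G must be >= 0", tag)
  if (m$G > 0) {
    nrm <- sqrt(sum(m$direction^2))
    if (abs(nrm - 1) > 1e-6)
      stop(sprintf("gradient direction must be unit-norm when G > 0%s; got |g| = %.8g",
                   tag, nrm))
    if (m$delta <= 0 || m$Delta <= 0 || m$TE <= 0)
      stop(sprintf("delta, Delta and TE must be strictly positive when G > 0%s", tag))
  }
  if (m$delta > m$Delta)
    stop(sprintf("invalid PGSE timing%s: delta (%.6g s) exceeds Delta (%.6g s)",
                 tag, m$delta, m$Delta))
  if (m$Delta + m$delta > m$TE + 1e-12)
    stop(sprintf("invalid PGSE timing%s: Delta + delta (%.6g s) exceeds TE (%.6g s)",
                 tag, m$Delta + m$delta, m$TE))
  invisible(m)
}

#' Construct a PGSE protocol
#'
#' An ordered set of PGSE measurements. Internally stored as a data frame
#' with columns \code{gx, gy, gz, G, Delta, delta, TE} (SI units), matching
#' the on-disk scheme layout.
#'
#' @param measurements a list of \code{pgse_measurement}, or a data frame
#'   with the columns above.
#' @param label free-text label.
#' @return a \code{pgse_protocol} object.
#' @export
pgse_protocol <- function(measurements, label = "") {
  if (is.data.frame(measurements)) {
    tab <- measurements
    need <- c("gx", "gy", "gz", "G", "Delta", "delta", "TE")
    if (!all(need %in% names(tab))) stop("protocol data frame lacks columns: ",
                                         paste(setdiff(need, names(tab)), collapse = ", "))
    tab <- tab[need]
  } else {
    stopifnot(is.list(measurements), length(measurements) > 0)
    tab <- do.call(rbind, lapply(measurements, function(m) {
      data.frame(gx = m$direction[1], gy = m$direction[2], gz = m$direction[3],
                 G = m$G, Delta = m$Delta, delta = m$delta, TE = m$TE)
    }))
  }
  if (nrow(tab) == 0) stop("a protocol must contain at least one measurement")
  p <- structure(list(table = tab, label = label), class = "pgse_protocol")
  for (i in seq_len(nrow(tab))) validate_measurement(protocol_measurement(p, i), i)
  p
}

#' Number of measurements in a protocol
#' @param p a \code{pgse_protocol}.
#' @return integer count.
#' @export
n_measurements <- function(p) nrow(p$table)

#' Extract one measurement from a protocol
#' @param p a \code{pgse_protocol}.
#' @param i measurement index.
#' @return a \code{pgse_measurement}.
#' @export
protocol_measurement <- function(p, i) {
  r <- p$table[i, ]
  structure(list(direction = c(r$gx, r$gy, r$gz), G = r$G,
                 delta = r$delta, Delta = r$Delta, TE = r$TE),
            class = "pgse_measurement")
}

#' @export
print.pgse_protocol <- function(x, ...) {
  te <- unique(signif(x$table$TE, 6))
  cat(sprintf("PGSE protocol%s: %d measurements, TE = %s s\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              nrow(x$table), paste(te, collapse = ", ")))
  sh <- unique(x$table[c("G", "delta", "Delta")])
  cat(sprintf("  %d unique (G, delta, Delta) shell(s); b = %s s/mm^2\n",
              nrow(sh),
              paste(round(bvalue_stejskal_tanner(sh$G, sh$delta, sh$Delta)),
                    collapse = ", ")))
  invisible(x)
}

#' Stejskal-Tanner b-value
#'
#' \eqn{b = \gamma^2 G^2 \delta^2 (\Delta - \delta/3)}, returned in the
#' conventional s/mm^2 (the SI value in s/m^2 divided by 1e6).
#'
#' @param G gradient magnitude (T/m); vectorized.
#' @param delta pulse duration (s).
#' @param Delta pulse separation (s).
#' @param gamma gyromagnetic ratio (rad s^-1 T^-1).
#' @return b-value(s) in s/mm^2.
#' @export
bvalue_stejskal_tanner <- function(G, delta, Delta, gamma = GYROMAGNETIC_RATIO) {
  gamma^2 * G^2 * delta^2 * (Delta - delta / 3) / 1e6
}

#' b-value of a PGSE measurement
#' @param m a \code{pgse_measurement}.
#' @param gamma gyromagnetic ratio (rad s^-1 T^-1).
#' @return b-value in s/mm^2.
#' @export
bvalue <- function(m, gamma = GYROMAGNETIC_RATIO) {
  bvalue_stejskal_tanner(m$G, m$delta, m$Delta, gamma)
}

#' b-values of all measurements of a protocol
#' @param p a \code{pgse_protocol}.
#' @param gamma gyromagnetic ratio.
#' @return numeric vector, s/mm^2.
#' @export
protocol_bvalues <- function(p, gamma = GYROMAGNETIC_RATIO) {
  bvalue_stejskal_tanner(p$table$G, p$table$delta, p$table$Delta, gamma)
}

#' Read a PGSE scheme file
#'
#' Reads the Camino-style STEJSKALTANNER text dialect: an optional header
#' line starting with \code{VERSION}, then one measurement per line with 7
#' whitespace-separated numbers \code{gx gy gz |G| Delta delta TE} in SI
#' units (T/m and s).
#'
#' @param path path to the scheme file.
#' @return a \code{pgse_protocol}.
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines) & !grepl("^\\s*VERSION", lines, ignore.case = TRUE)
  lines_idx <- which(keep)
  if (length(lines_idx) == 0) stop("scheme file contains no measurement lines: ", path)
  rows <- vector("list", length(lines_idx))
  for (k in seq_along(lines_idx)) {
    i <- lines_idx[k]
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) != 7)
      stop(sprintf("parse error in %s line %d: expected 7 fields, found %d",
                   path, i, length(toks)))
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals))
      stop(sprintf("parse error in %s line %d: non-numeric token '%s'",
                   path, i, toks[which(is.na(vals))[1]]))
    rows[[k]] <- vals
  }
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- c("gx", "gy", "gz", "G", "Delta", "delta", "TE")
  pgse_protocol(tab, label = basename(path))
}

#' Write a PGSE scheme file
#'
#' Inverse of \code{\link{read_scheme}}; values are written with 12
#' significant digits so that a write/read roundtrip is lossless in practice.
#'
#' @param p a \code{pgse_protocol}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_scheme <- function(p, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("VERSION: STEJSKALTANNER", con)
  apply(p$table, 1, function(r)
    writeLines(paste(formatC(r, format = "g", digits = 12), collapse = " "), con))
  invisible(path)
}

## Electrostatic-repulsion direction sets ------------------------------------

## Minimize Coulomb energy of antipodal point pairs on the sphere by
## projected gradient descent. Deterministic: own scrambled-sequence init,
## no dependence on the R RNG state.
repulsion_directions <- function(n, iterations = 200L, seed = 42L) {
  ## low-discrepancy init (golden-spiral) perturbed by a seeded LCG so that
  ## distinct seeds give distinct, reproducible sets
  idx <- seq_len(n)
  lcg <- (as.numeric(seed) * 69069 + idx * 104729) %% 2147483647
  u <- ((idx - 0.5) / n + lcg / 2147483647 * 1e-3) %% 1
  phi <- 2 * pi * ((idx * 0.6180339887498949) %% 1)
  z <- 1 - 2 * u
  r <- sqrt(pmax(0, 1 - z^2))
  P <- cbind(r * cos(phi), r * sin(phi), z)
  step <- 0.05
  for (it in seq_len(iterations)) {
    F <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      d1 <- sweep(P[-i, , drop = FALSE], 2, P[i, ])      # towards others
      d2 <- sweep(-P[-i, , drop = FALSE], 2, P[i, ])     # towards antipodes
      w1 <- 1 / pmax(rowSums(d1^2), 1e-6)^1.5
      w2 <- 1 / pmax(rowSums(d2^2), 1e-6)^1.5
      F[i, ] <- -colSums(d1 * w1) - colSums(d2 * w2)
    }
    P <- P + step * F / sqrt(pmax(rowSums(F^2), 1e-12))
    P <- P / sqrt(rowSums(P^2))
  }
  P
}

radial_xy_directions <- function(n = 180L) {
  ang <- (seq_len(n) - 1) * pi / n   # antipodally non-redundant half-circle
  cbind(cos(ang), sin(ang), 0)
}

shells_to_protocol <- function(shells, dirs, TE, label) {
  tab <- do.call(rbind, lapply(seq_len(nrow(shells)), function(s) {
    data.frame(gx = dirs[, 1], gy = dirs[, 2], gz = dirs[, 3],
               G = shells$G[s], Delta = shells$Delta[s],
               delta = shells$delta[s], TE = TE)
  }))
  pgse_protocol(tab, label = label)
}

#' Built-in acquisition protocols
#'
#' Three protocols used throughout the package studies, with pulse
#' parameters as published:
#' \describe{
#'   \item{\code{activeax_exvivo}}{the optimized ex-vivo ActiveAx protocol:
#'     4 shells x 90 directions, TE = 0.054 s, shells
#'     (G, delta, Delta) = (0.140, 0.010, 0.016), (0.140, 0.010, 0.016),
#'     (0.131, 0.007, 0.045), (0.140, 0.017, 0.035) in (T/m, s, s). The
#'     first two shells are published identical and are kept so.}
#'   \item{\code{dyrby_exvivo}}{optimized ex-vivo diameter-estimation
#'     protocol: 3 shells x 90 directions, TE = 0.0359 s, shells
#'     (0.300, 0.0056, 0.0121), (0.219, 0.0070, 0.0204),
#'     (0.300, 0.0105, 0.0169).}
#'   \item{\code{radial_xy}}{radial extra-axonal probe: G = 0.3 T/m,
#'     delta = 0.010 s, a configurable list of Delta values, 180 directions
#'     evenly distributed in the xy-plane, TE = 0.075 s.}
#' }
#' Direction sets are electrostatic-repulsion point sets generated with a
#' fixed internal seed (the published direction tables are not available).
#'
#' @param name one of \code{"activeax_exvivo"}, \code{"dyrby_exvivo"},
#'   \code{"radial_xy"}.
#' @param Deltas for \code{radial_xy}: Delta values in seconds (default 10
#'   evenly spaced values in [0.015, 0.060]).
#' @param n_directions number of directions per shell.
#' @return a \code{pgse_protocol}.
#' @export
builtin_protocol <- function(name,
                             Deltas = seq(0.015, 0.060, length.out = 10),
                             n_directions = NULL) {
  valid <- c("activeax_exvivo", "dyrby_exvivo", "radial_xy")
  if (!name %in% valid)
    stop("unknown protocol '", name, "'; valid names: ",
         paste(valid, collapse = ", "))
  if (name == "activeax_exvivo") {
    nd <- if (is.null(n_directions)) 90L else n_directions
    dirs <- repulsion_directions(nd)
    shells <- data.frame(G = c(0.140, 0.140, 0.131, 0.140),
                         delta = c(0.010, 0.010, 0.007, 0.017),
                         Delta = c(0.016, 0.016, 0.045, 0.035))
    shells_to_protocol(shells, dirs, TE = 0.054, label = "activeax_exvivo")
  } else if (name == "dyrby_exvivo") {
    nd <- if (is.null(n_directions)) 90L else n_directions
    dirs <- repulsion_directions(nd)
    shells <- data.frame(G = c(0.300, 0.219, 0.300),
                         delta = c(0.0056, 0.0070, 0.0105),
                         Delta = c(0.0121, 0.0204, 0.0169))
    shells_to_protocol(shells, dirs, TE = 0.0359, label = "dyrby_exvivo")
  } else {
    nd <- if (is.null(n_directions)) 180L else n_directions
    dirs <- radial_xy_directions(nd)
    shells <- data.frame(G = 0.3, delta = 0.010, Delta = Deltas)
    shells_to_protocol(shells, dirs, TE = 0.075, label = "radial_xy")
  }
}

## Group the measurements of a protocol into shells sharing (G, delta, Delta).
## Returns list(shells = data.frame(G, delta, Delta), shell_id = int vector).
protocol_shells <- function(p) {
  key <- paste(p$table$G, p$table$delta, p$table$Delta)
  uk <- unique(key)
  id <- match(key, uk)
  first <- match(uk, key)
  list(shells = data.frame(G = p$table$G[first], delta = p$table$delta[first],
                           Delta = p$table$Delta[first]),
       shell_id = id)
}

protocol_te <- function(p) {
  te <- unique(p$table$TE)
  if (length(te) > 1)
    stop("protocol mixes echo times (", paste(signif(te, 6), collapse = ", "),
         " s); a single simulation run requires one TE")
  te
}
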