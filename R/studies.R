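## Study drivers: reproducibility with respect to particle/step counts,
## undulation-induced diameter bias, and extra-axonal voxel-size convergence.
## All drivers derive per-cell seeds from one master seed and are fully
## reproducible from (configuration, master seed).

derive_seed <- function(master, index) {
  ## splittable counter scheme; stays within 32-bit signed range
  (as.numeric(master) * 48271 + as.numeric(index) * 16807) %% 2147483647
}

#' Signal-error confidence study over particle and step counts
#'
#' For every (particles, steps) cell and repetition, one simulation with a
#' distinct derived seed is run on the substrate; the RMAE against a ground
#' truth (the analytic volume-weighted intra-axonal mixture, or a
#' high-count simulated gold standard) quantifies the reproducibility of
#' the simulated signal at that budget.
#'
#' @param substrate a \code{cylinder_population}.
#' @param protocol a \code{pgse_protocol}.
#' @param particle_counts,step_counts vectors of simulation sizes.
#' @param n_reps repetitions per cell.
#' @param gt_mode \code{"analytic_intra"} (GPD mixture, intra-only walkers)
#'   or \code{"simulated_gold"} (high-count reference run, same init mode as
#'   \code{init_mode}).
#' @param seed master seed.
#' @param D diffusivity (m^2/s).
#' @param init_mode walker placement for the simulations (forced to
#'   \code{"intra_only"} for the analytic ground truth).
#' @param gold_particles,gold_steps size of the gold-standard run.
#' @return a \code{confidence_table}: data frame of per-repetition RMAEs
#'   plus a \code{means} matrix (particle x step cells).
#' @export
confidence_study <- function(substrate, protocol, particle_counts,
                             step_counts, n_reps = 10L,
                             gt_mode = c("analytic_intra", "simulated_gold"),
                             seed = 1L, D = 0.6e-9,
                             init_mode = "intra_only",
                             gold_particles = NULL, gold_steps = NULL) {
  gt_mode <- match.arg(gt_mode)
  if (gt_mode == "analytic_intra") {
    init_mode <- "intra_only"
    gt <- mixture_signal(substrate$radii, D, protocol)
    pick <- function(s) s$sub$intra
  } else {
    gp <- if (is.null(gold_particles)) max(particle_counts) * 10 else gold_particles
    gs <- if (is.null(gold_steps)) max(step_counts) else gold_steps
    gcfg <- simulation_config(gp, gs, D, seed = derive_seed(seed, 0),
                              init_mode = init_mode)
    gsig <- run_simulation(substrate, protocol, gcfg)
    pick <- function(s) {
      if (init_mode == "extra_only") s$sub$extra
      else if (init_mode == "intra_only") s$sub$intra
      else s$values
    }
    gt <- pick(gsig)
  }
  rows <- expand.grid(rep = seq_len(n_reps), steps = step_counts,
                      particles = particle_counts)
  rows$rmae <- NA_real_
  for (r in seq_len(nrow(rows))) {
    cfg <- simulation_config(rows$particles[r], rows$steps[r], D,
                             seed = derive_seed(seed, r),
                             init_mode = init_mode)
    s <- run_simulation(substrate, protocol, cfg)
    rows$rmae[r] <- rmae(gt, pick(s))
  }
  means <- tapply(rows$rmae, list(factor(rows$particles, particle_counts),
                                  factor(rows$steps, step_counts)), mean)
  structure(list(table = rows, means = means,
                 particle_counts = particle_counts,
                 step_counts = step_counts, n_reps = n_reps,
                 gt_mode = gt_mode),
            class = "confidence_table")
}

#' @export
print.confidence_table <- function(x, ...) {
  cat("confidence_table: mean RMAE (%) per (particles x steps) cell,",
      x$n_reps, "repetitions\n")
  print(round(x$means, 3))
  invisible(x)
}

#' Undulation diameter-bias study
#'
#' For each (diameter, amplitude, wavelength) cell: build the helical
#' undulating mesh, simulate intra-axonal walkers, and fit the diameter by
#' exhaustive search. Cells whose tube cannot be meshed (amplitude too
#' large for the wavelength at that diameter) are recorded as skipped.
#'
#' @param diameters,amplitudes,wavelengths grids (m).
#' @param protocol a \code{pgse_protocol}.
#' @param n_particles,n_steps simulation size per cell.
#' @param D diffusivity (m^2/s).
#' @param length axial extent of each mesh (m); default 8 wavelengths.
#' @param seed master seed.
#' @param grid fitting grid (m).
#' @return data frame with one row per cell: nominal parameters,
#'   \code{tortuosity}, fitted diameter, plausible interval, min RMAE and a
#'   \code{skipped} flag.
#' @export
undulation_study <- function(diameters, amplitudes, wavelengths, protocol,
                             n_particles = 5000L, n_steps = 2000L,
                             D = 0.6e-9, length = NULL, seed = 1L,
                             grid = seq(0.4e-6, 8.0e-6, by = 0.01e-6)) {
  cells <- expand.grid(diameter = diameters, amplitude = amplitudes,
                       wavelength = wavelengths)
  out <- cells
  out$tortuosity <- tortuosity(cells$amplitude, cells$wavelength)
  out$fitted <- out$fit_lo <- out$fit_hi <- out$min_rmae <- NA_real_
  out$skipped <- FALSE
  for (r in seq_len(nrow(cells))) {
    d <- cells$diameter[r]; A <- cells$amplitude[r]; L <- cells$wavelength[r]
    len <- if (is.null(length)) 8 * L else length
    mesh <- tryCatch(undulating_mesh(d, A, L, len),
                     error = function(e) NULL)
    if (is.null(mesh)) { out$skipped[r] <- TRUE; next }
    cfg <- simulation_config(n_particles, n_steps, D,
                             seed = derive_seed(seed, r),
                             init_mode = "intra_only")
    s <- run_simulation(mesh, protocol, cfg)
    fit <- fit_diameter_exhaustive(s$sub$intra, protocol, D, grid = grid)
    out$fitted[r] <- fit$best_diameter
    out$fit_lo[r] <- fit$plausible_interval[1]
    out$fit_hi[r] <- fit$plausible_interval[2]
    out$min_rmae[r] <- fit$min_rmae
  }
  out
}

#' Radial signal anisotropy (std/mean)
#'
#' Deviation of a radial signal profile from perfect rotational symmetry:
#' the sample standard deviation divided by the mean.
#'
#' @param values signal values over directions at one diffusion time.
#' @return std/mean (0 for a perfectly isotropic profile).
#' @export
radial_anisotropy <- function(values) {
  if (length(values) < 2) return(0)
  stats::sd(values) / mean(values)
}

#' Extra-axonal voxel-size convergence study
#'
#' For each cylinder count: sample gamma diameters, pack a periodic
#' substrate at the target ICVF, simulate extra-axonal walkers with the
#' radial (xy-plane) protocol, and summarize each diffusion time Delta by
#' the mean radial signal and its anisotropy (std/mean). Small substrates
#' produce anisotropic, downward-biased radial profiles; convergence with
#' substrate size is the object of interest.
#'
#' @param cylinder_counts ascending counts of sampled cylinders.
#' @param gamma_spec a \code{gamma_radii_spec} (its \code{count} field is
#'   overridden per cell).
#' @param icvf target intra-axonal volume fraction.
#' @param protocol a radial \code{pgse_protocol}
#'   (\code{builtin_protocol("radial_xy")}).
#' @param n_particles,n_steps simulation size per substrate.
#' @param D extra-axonal diffusivity (m^2/s). The default 0.6e-10 keeps the
#'   long-Delta radial shells of the probe (b up to ~36,500 s/mm^2 at
#'   G = 0.3 T/m) in a measurable attenuation range.
#' @param seed master seed.
#' @return a \code{radial_convergence}: data frame with one row per
#'   (count, Delta): mean signal, sd, anisotropy, voxel side.
#' @export
voxel_size_study <- function(cylinder_counts, gamma_spec, icvf = 0.6,
                             protocol = builtin_protocol("radial_xy"),
                             n_particles = 20000L, n_steps = 1000L,
                             D = 0.6e-10, seed = 1L) {
  stopifnot(!is.unsorted(cylinder_counts))
  sh <- protocol_shells(protocol)
  res <- NULL
  for (ci in seq_along(cylinder_counts)) {
    n <- cylinder_counts[ci]
    spec <- gamma_spec
    spec$count <- as.integer(n)
    spec$seed <- as.integer(derive_seed(seed, 1000 + ci) %% 2^31)
    dia <- sample_gamma_diameters(spec)
    pop <- pack_parallel_cylinders(dia, icvf,
                                   seed = derive_seed(seed, 2000 + ci))
    cfg <- simulation_config(n_particles, n_steps, D,
                             seed = derive_seed(seed, 3000 + ci),
                             init_mode = "extra_only")
    s <- run_simulation(pop, protocol, cfg)
    vals <- s$sub$extra
    for (k in seq_len(nrow(sh$shells))) {
      v <- vals[sh$shell_id == k]
      res <- rbind(res, data.frame(
        count = n, Delta = sh$shells$Delta[k], voxel_side = pop$voxel_side,
        mean_signal = mean(v), sd_signal = stats::sd(v),
        anisotropy = radial_anisotropy(v)))
    }
  }
  structure(list(table = res, cylinder_counts = cylinder_counts),
            class = "radial_convergence")
}

#' @export
print.radial_convergence <- function(x, ...) {
  cat("radial_convergence: anisotropy (std/mean) per (count x Delta)\n")
  print(round(with(x$table, tapply(anisotropy,
                                   list(factor(count, x$cylinder_counts),
                                        factor(Delta)), mean)), 4))
  invisible(x)
}
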