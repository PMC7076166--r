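## R surface of the Monte-Carlo random-walk engine.

#' Simulation configuration
#'
#' @param n_particles number of random walkers (spins).
#' @param n_steps number of time steps; the step duration is
#'   \code{duration / n_steps} and the fixed step length follows Einstein's
#'   relation \code{sqrt(6 * D * dt)}.
#' @param diffusivity diffusion coefficient D (m^2/s).
#' @param seed master seed; simulations are bitwise reproducible for a
#'   fixed seed (counter-seeded per-particle random streams).
#' @param init_mode \code{"all"} (uniform over the voxel, compartment
#'   proportions follow the volume fractions), \code{"intra_only"} or
#'   \code{"extra_only"} (rejection-sampled).
#' @param max_bounces_per_step reflections allowed within one step before
#'   the walker keeps its last safe position (counted, never an error).
#' @param duration total diffusion time (s); defaults to the protocol TE
#'   at run time.
#' @return a \code{simulation_config}.
#' @export
simulation_config <- function(n_particles, n_steps, diffusivity,
                              seed = 1L,
                              init_mode = c("all", "intra_only", "extra_only"),
                              max_bounces_per_step = 100L,
                              duration = NULL) {
  init_mode <- match.arg(init_mode)
  stopifnot(n_particles >= 1, n_steps >= 1, diffusivity >= 0)
  structure(list(n_particles = as.integer(n_particles),
                 n_steps = as.integer(n_steps),
                 diffusivity = diffusivity, seed = seed,
                 init_mode = init_mode,
                 max_bounces_per_step = as.integer(max_bounces_per_step),
                 duration = duration),
            class = "simulation_config")
}

#' Fixed step length from Einstein's relation
#'
#' \eqn{r = \sqrt{6 D\, dt}}: the expected root-mean-square displacement per
#' step in three dimensions.
#'
#' @param D diffusivity (m^2/s).
#' @param dt step duration (s).
#' @return step length (m).
#' @export
step_length <- function(D, dt) {
  stopifnot(D >= 0, dt > 0)
  sqrt(6 * D * dt)
}

#' Free-diffusion substrate (no barriers)
#' @return a \code{free_substrate} marker object.
#' @export
free_substrate <- function() structure(list(), class = "free_substrate")

substrate_code <- function(substrate) {
  if (is.null(substrate) || inherits(substrate, "free_substrate")) {
    list(type = 0L, data = list())
  } else if (inherits(substrate, "cylinder_population")) {
    list(type = 1L,
         data = list(centers = substrate$centers, radii = substrate$radii,
                     voxel_side = substrate$voxel_side,
                     periodic = substrate$periodic))
  } else if (inherits(substrate, "trimesh")) {
    list(type = 2L,
         data = list(vertices = substrate$vertices, faces = substrate$faces))
  } else stop("unsupported substrate class: ",
              paste(class(substrate), collapse = "/"))
}

init_mode_code <- function(mode) {
  match(mode, c("all", "intra_only", "extra_only")) - 1L
}

#' Run a Monte-Carlo diffusion simulation
#'
#' Walkers are placed uniformly (or rejection-sampled into one compartment),
#' diffuse with fixed-length steps and specular reflection against the
#' substrate's impermeable barriers, and accumulate PGSE phase per
#' measurement: the per-step increment is the signed gradient-on time of the
#' step multiplied by \eqn{\gamma\,G\cdot x(t)} with \eqn{x(t)} the
#' unwrapped displacement from the start. The signal is the modulus of the
#' complex ensemble mean of \eqn{e^{-i\phi}}; per-compartment signals are
#' computed from the (constant) walker labels.
#'
#' @param substrate a \code{cylinder_population}, \code{trimesh},
#'   \code{free_substrate} or \code{NULL}.
#' @param protocol a \code{pgse_protocol} with a single TE.
#' @param config a \code{simulation_config}.
#' @param gamma gyromagnetic ratio.
#' @param return_positions include initial positions/labels in the result.
#' @param return_msd include mean-squared-displacement checkpoints.
#' @return a \code{signal_set} with per-compartment sub-signals and an
#'   attribute \code{"run"} holding counters (bounce overflows, compartment
#'   counts, step length).
#' @export
run_simulation <- function(substrate, protocol, config,
                           gamma = GYROMAGNETIC_RATIO,
                           return_positions = FALSE, return_msd = FALSE) {
  te <- protocol_te(protocol)
  duration <- if (is.null(config$duration)) te else config$duration
  if (abs(duration - te) > 1e-12)
    stop("config duration (", duration, " s) != protocol TE (", te, " s)")
  sub <- substrate_code(substrate)
  sh <- protocol_shells(protocol)
  dirs <- as.matrix(protocol$table[c("gx", "gy", "gz")])
  res <- cpp_run_simulation(sub$type, sub$data, dirs, sh$shell_id,
                            as.matrix(sh$shells), te,
                            config$diffusivity, config$n_particles,
                            config$n_steps, gamma,
                            init_mode_code(config$init_mode),
                            as.numeric(config$seed),
                            config$max_bounces_per_step,
                            return_positions, return_msd)
  subsig <- list()
  if (res$n_intra > 0) subsig$intra <- res$signal_intra
  if (res$n_extra > 0) subsig$extra <- res$signal_extra
  w <- c(intra = res$n_intra, extra = res$n_extra) / config$n_particles
  out <- signal_set(res$signal, protocol, sub = subsig, weights = w)
  attr(out, "run") <- res[c("n_intra", "n_extra", "bounce_overflows",
                            "max_penetration", "step_length")]
  if (return_msd) attr(out, "msd") <- res[c("msd", "msd_times")]
  if (return_positions) {
    attr(out, "init_positions") <- res$init_positions
    attr(out, "labels") <- res$labels
  }
  out
}

#' Initialize walkers without running a simulation
#'
#' Places walkers (uniform or rejection-sampled per \code{init_mode}) and
#' labels them by point-in-geometry tests. Used for inspection and for ICVF
#' estimates from particle labels.
#'
#' @param substrate substrate object.
#' @param config a \code{simulation_config} (only \code{n_particles},
#'   \code{seed} and \code{init_mode} are used).
#' @return list with \code{positions} (n x 3, m) and \code{labels}
#'   (intra compartment index, 0-based, or -1 for extra).
#' @export
init_walkers <- function(substrate, config) {
  sub <- substrate_code(substrate)
  dirs <- matrix(c(0, 0, 1), 1, 3)
  shells <- matrix(c(0, 0.001, 0.002), 1, 3)
  res <- cpp_run_simulation(sub$type, sub$data, dirs, 1L, shells, 0.003,
                            0.0, config$n_particles, 1L, GYROMAGNETIC_RATIO,
                            init_mode_code(config$init_mode),
                            as.numeric(config$seed),
                            config$max_bounces_per_step, TRUE, FALSE)
  list(positions = res$init_positions, labels = res$labels,
       n_intra = res$n_intra, n_extra = res$n_extra)
}

#' Estimate the intra-cellular volume fraction by uniform sampling
#'
#' Uniform random points are labeled inside/outside the substrate; the
#' inside fraction estimates the ICVF. For a voxel grid, one fraction per
#' cell is returned.
#'
#' @param substrate a \code{cylinder_population} or \code{trimesh}.
#' @param n_samples number of uniform points.
#' @param seed RNG seed.
#' @param grid_dims optional integer vector (length 2 for cylinder
#'   cross-sections, 3 for meshes) of cells per axis; returns an array of
#'   per-cell fractions.
#' @return a fraction, or an array of per-cell fractions.
#' @export
estimate_icvf <- function(substrate, n_samples = 100000L, seed = 1L,
                          grid_dims = NULL) {
  stopifnot(n_samples >= 1)
  set.seed(seed)
  if (inherits(substrate, "cylinder_population")) {
    s <- substrate$voxel_side
    pts <- cbind(runif(n_samples, 0, s), runif(n_samples, 0, s))
    if (length(substrate$radii) == 0) {
      inside <- rep(FALSE, n_samples)
    } else {
      lab <- cpp_points_in_cylinders(substrate$centers, substrate$radii,
                                     s, substrate$periodic, pts)
      inside <- lab >= 0
    }
    if (is.null(grid_dims)) return(mean(inside))
    ix <- pmin(grid_dims[1], 1L + floor(pts[, 1] / s * grid_dims[1]))
    iy <- pmin(grid_dims[2], 1L + floor(pts[, 2] / s * grid_dims[2]))
    tapply(inside, list(factor(ix, 1:grid_dims[1]), factor(iy, 1:grid_dims[2])),
           mean, default = 0)
  } else if (inherits(substrate, "trimesh")) {
    bb <- apply(substrate$vertices, 2, range)
    pts <- cbind(runif(n_samples, bb[1, 1], bb[2, 1]),
                 runif(n_samples, bb[1, 2], bb[2, 2]),
                 runif(n_samples, bb[1, 3], bb[2, 3]))
    inside <- cpp_points_in_mesh(substrate$vertices, substrate$faces, pts)
    if (is.null(grid_dims)) return(mean(inside))
    idx <- lapply(1:3, function(d)
      factor(pmin(grid_dims[d],
                  1L + floor((pts[, d] - bb[1, d]) / (bb[2, d] - bb[1, d]) *
                             grid_dims[d])), seq_len(grid_dims[d])))
    tapply(inside, idx, mean, default = 0)
  } else stop("estimate_icvf needs a cylinder_population or trimesh")
}

#' Advance one walker by one step with specular reflection
#'
#' Exposes the engine's collision kernel for a single proposed step: at each
#' barrier hit the residual step is mirrored about the surface normal until
#' its full length is consumed.
#'
#' @param position length-3 position (m).
#' @param step length-3 proposed step vector (m).
#' @param substrate \code{cylinder_population} or \code{trimesh}.
#' @param label compartment of the walker: intra cylinder index (0-based)
#'   or -1 for extra-cellular; meshes take -1 (outside) or 0 (inside).
#' @param max_bounces reflection budget.
#' @return list(position, displacement, bounces); \code{bounces = -1} means
#'   the budget was exceeded and the walker kept its starting position.
#' @export
advance_walker <- function(position, step, substrate, label = -1L,
                           max_bounces = 100L) {
  if (inherits(substrate, "cylinder_population")) {
    cpp_advance_cylinders_once(as.numeric(position), as.numeric(step),
                               substrate$centers, substrate$radii,
                               substrate$voxel_side, substrate$periodic,
                               as.integer(label), as.integer(max_bounces))
  } else if (inherits(substrate, "trimesh")) {
    cpp_advance_mesh_once(as.numeric(position), as.numeric(step),
                          substrate$vertices, substrate$faces,
                          FALSE, as.integer(max_bounces))
  } else stop("unsupported substrate")
}
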