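test_that("step length follows Einstein's relation", {
  expect_equal(step_length(0.6e-9, 1e-5), sqrt(6 * 0.6e-9 * 1e-5))
  expect_equal(step_length(0.6e-9, 1e-5), 1.897e-7, tolerance = 1e-3)
  expect_equal(step_length(0, 1e-5), 0)
  expect_equal(step_length(0.6e-9, 4e-5), 2 * step_length(0.6e-9, 1e-5),
               tolerance = 1e-14)
})

test_that("per-step gradient weights refocus a static spin exactly", {
  for (Nt in c(7, 100, 1001)) {
    w <- mcdsim:::cpp_shell_weights(0.007, 0.0204, 0.0359, Nt)
    expect_lt(abs(sum(w)), 1e-15)                 # antisymmetry of a(t)
    expect_lt(abs(sum(w[w > 0]) - 0.007), 1e-15)  # full pulse covered
  }
})

test_that("zero gradient and frozen spins give S/S0 = 1 exactly", {
  tab <- rbind(data.frame(gx = 0, gy = 0, gz = 0, G = 0, Delta = 0.02,
                          delta = 0.01, TE = 0.05),
               data.frame(gx = 1, gy = 0, gz = 0, G = 0.14, Delta = 0.02,
                          delta = 0.01, TE = 0.05))
  p <- pgse_protocol(tab)
  s <- run_simulation(free_substrate(), p,
                      simulation_config(500, 50, 0.6e-9, seed = 2))
  expect_identical(s$values[1], 1)                       # G = 0
  s0 <- run_simulation(free_substrate(), p,
                       simulation_config(500, 50, 0, seed = 2))
  expect_identical(s0$values, c(1, 1))                   # D = 0: refocused
})

test_that("free walkers satisfy the Einstein MSD relation at checkpoints", {
  p <- tiny_protocol(2)
  cfg <- simulation_config(20000, 200, 0.6e-9, seed = 4)
  s <- run_simulation(free_substrate(), p, cfg, return_msd = TRUE)
  m <- attr(s, "msd")
  se <- sqrt(2 / 3 / 20000) * 6 * 0.6e-9 * m$msd_times  # var(|x|^2)=2/3 mu^2 /N
  expect_true(all(abs(m$msd - 6 * 0.6e-9 * m$msd_times) < 3.5 * se))
})

test_that("free diffusion reproduces exp(-bD) within sampling error", {
  p <- tiny_protocol(6)
  Ns <- 20000
  s <- run_simulation(free_substrate(), p,
                      simulation_config(Ns, 1000, 0.6e-9, seed = 5))
  exact <- exp(-protocol_bvalues(p) * 1e6 * 0.6e-9)
  se <- sqrt((1 - exact^2) / (2 * Ns))
  expect_true(all(abs(s$values - exact) < 3.5 * se))
})

test_that("specular reflection preserves speed and flips only the normal", {
  ## head-on wall hit inside a cube: normal component reversed, tangential
  ## preserved
  m <- cube_mesh(2e-6)
  pos <- c(1e-6, 1e-6, 1.8e-6)
  step <- c(0.2e-6, 0.1e-6, 0.4e-6)      # crosses the z = 2e-6 face
  r <- advance_walker(pos, step, m, label = 0)
  expect_equal(r$bounces, 1)
  ## tangential components preserved; the 1e-12 m surface nudge bounds the
  ## tolerance
  expect_lt(max(abs(r$displacement[1:2] - step[1:2])), 1e-11)
  ## z: travels 0.2e-6 up to the wall, reflects, 0.2e-6 back down
  expect_lt(abs(r$position[3] - 1.8e-6), 1e-11)

  ## cylinder wall from inside, radial approach: full reversal of xy motion
  pop <- single_cylinder(1e-6)
  c0 <- c(pop$voxel_side / 2, pop$voxel_side / 2, 0)
  r2 <- advance_walker(c0, c(1.5e-6, 0, 0), pop, label = 0)
  expect_equal(r2$bounces, 1)
  expect_lt(abs(r2$position[1] - (c0[1] + 0.5e-6)), 1e-11)

  ## no barrier on the path: position + step
  r3 <- advance_walker(c0, c(0.5e-7, 0, 1e-6), pop, label = 0)
  expect_equal(r3$bounces, 0)
  expect_equal(as.numeric(r3$position), c0 + c(0.5e-7, 0, 1e-6))
})

test_that("intra walkers never leave their cylinder over many steps", {
  pop <- single_cylinder(1e-6)
  p <- tiny_protocol(2)
  cfg <- simulation_config(50, 10000, 0.6e-9, seed = 6,
                           init_mode = "intra_only")
  s <- run_simulation(pop, p, cfg)
  run <- attr(s, "run")
  expect_lte(run$max_penetration, 1e-12)
  expect_equal(run$n_intra, 50)
})

test_that("uniform initialization respects volume fractions and bounds", {
  dia <- sample_gamma_diameters(gamma_radii_spec(4, 4.5e-7, count = 60,
                                                 seed = 13))
  pop <- pack_parallel_cylinders(dia, 0.60, seed = 14)
  cfg <- simulation_config(20000, 1, 0.6e-9, seed = 15)
  w <- init_walkers(pop, cfg)
  frac <- w$n_intra / 20000
  se <- sqrt(0.6 * 0.4 / 20000)
  expect_lt(abs(frac - 0.60), 3 * se)
  expect_true(all(w$positions >= 0 & w$positions <= pop$voxel_side))
  wi <- init_walkers(pop, simulation_config(500, 1, 0.6e-9, seed = 16,
                                            init_mode = "intra_only"))
  expect_equal(wi$n_intra, 500)
  expect_true(all(wi$labels >= 0))
})

test_that("simulation is reproducible for a fixed seed", {
  pop <- single_cylinder(1.5e-6)
  p <- tiny_protocol(4)
  cfg <- simulation_config(300, 100, 0.6e-9, seed = 17,
                           init_mode = "intra_only")
  s1 <- run_simulation(pop, p, cfg)
  s2 <- run_simulation(pop, p, cfg)
  expect_identical(s1$values, s2$values)
  cfg2 <- cfg; cfg2$seed <- 18
  expect_false(identical(run_simulation(pop, p, cfg2)$values, s1$values))
})

test_that("signal never exceeds 1 and compartments mix exactly", {
  dia <- rep(1.6e-6, 9)
  pop <- pack_parallel_cylinders(dia, 0.45, seed = 19)
  p <- tiny_protocol(6)
  cfg <- simulation_config(4000, 300, 0.6e-9, seed = 20)
  s <- run_simulation(pop, p, cfg)
  expect_true(all(s$values <= 1 + 1e-12))
  expect_true(all(s$sub$intra <= 1 + 1e-12))
  ## total complex mean = label-weighted mixture of compartment complex means
  sub <- mcdsim:::substrate_code(pop)
  sh <- mcdsim:::protocol_shells(p)
  res <- mcdsim:::cpp_run_simulation(sub$type, sub$data,
    as.matrix(p$table[c("gx", "gy", "gz")]), sh$shell_id,
    as.matrix(sh$shells), 0.054, 0.6e-9, 4000L, 300L, GYROMAGNETIC_RATIO,
    0L, 20, 100L, FALSE, FALSE)
  w <- c(res$n_intra, res$n_extra) / 4000
  mix_re <- res$complex_re[, 2] * w[1] + res$complex_re[, 3] * w[2]
  mix_im <- res$complex_im[, 2] * w[1] + res$complex_im[, 3] * w[2]
  expect_equal(mix_re, res$complex_re[, 1], tolerance = 1e-14)
  expect_equal(mix_im, res$complex_im[, 1], tolerance = 1e-14)
})

test_that("TE mismatch between protocol and config is refused", {
  p <- tiny_protocol(2)
  cfg <- simulation_config(10, 10, 0.6e-9, duration = 0.03)
  expect_error(run_simulation(free_substrate(), p, cfg), "TE")
})

test_that("ICVF estimation matches analytic areas and handles edge cases", {
  ## empty substrate
  empty <- cylinder_population(matrix(numeric(0), 0, 2), numeric(0),
                               voxel_side = 1e-5)
  expect_equal(estimate_icvf(empty, 1000, seed = 1), 0)
  ## substrate filling the whole voxel
  side <- 1e-5
  full <- cylinder_population(matrix(c(side / 2, side / 2), 1, 2),
                              side, voxel_side = side, periodic = FALSE)
  expect_equal(estimate_icvf(full, 1000, seed = 1), 1)
  ## one cylinder of known radius in a known box
  one <- cylinder_population(matrix(c(side / 2, side / 2), 1, 2),
                             2e-6, voxel_side = side, periodic = FALSE)
  a <- pi * (2e-6)^2 / side^2
  est <- estimate_icvf(one, 1e5, seed = 2)
  expect_lt(abs(est - a), 3 * sqrt(a * (1 - a) / 1e5))
  ## mesh: cube of half the bbox volume
  m <- cube_mesh(2e-6)
  expect_gt(estimate_icvf(m, 2000, seed = 3), 0.999)
})

test_that("gridded ICVF maps average to the global fraction", {
  side <- 1e-5
  one <- cylinder_population(matrix(c(side / 2, side / 2), 1, 2),
                             2e-6, voxel_side = side, periodic = FALSE)
  g <- estimate_icvf(one, 4e4, seed = 5, grid_dims = c(2, 2))
  expect_equal(dim(g), c(2, 2))
  a <- pi * (2e-6)^2 / side^2
  expect_lt(abs(mean(g) - a), 0.01)
  ## the cylinder is centered: the four quadrants see equal fractions
  expect_lt(diff(range(g)), 0.02)
})

test_that("point-in-mesh parity vote classifies cube interior correctly", {
  m <- cube_mesh(2e-6)
  pts <- rbind(c(1e-6, 1e-6, 1e-6),       # center
               c(3e-6, 1e-6, 1e-6),       # outside
               c(1.9e-6, 1.9e-6, 1.9e-6)) # near corner, inside
  inside <- mcdsim:::cpp_points_in_mesh(m$vertices, m$faces, pts)
  expect_identical(as.logical(inside), c(TRUE, FALSE, TRUE))
})
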