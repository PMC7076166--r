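test_that("gamma sampler reproduces the target law and honors truncation", {
  d <- sample_gamma_diameters(gamma_radii_spec(4.0, 4.5e-7, count = 1e5,
                                               seed = 11))
  expect_equal(mean(d), 1.8e-6, tolerance = 0.02)
  expect_equal(sd(d), 0.9e-6, tolerance = 0.02)
  ## distributional agreement with the analytic CDF (untruncated)
  ks <- suppressWarnings(
    ks.test(d, function(q) pgamma(q, shape = 4, scale = 4.5e-7)))
  expect_lt(unname(ks$statistic), 0.01)

  dt <- sample_gamma_diameters(gamma_radii_spec(1.2, 1.5e-6,
                                                min_diameter = 0.2e-6,
                                                count = 1e5, seed = 12))
  expect_true(all(dt >= 0.2e-6))
  expect_equal(sd(dt), 1.6e-6, tolerance = 0.03)

  ## determinism and impossible truncations
  d2 <- sample_gamma_diameters(gamma_radii_spec(4.0, 4.5e-7, count = 100,
                                                seed = 11))
  expect_identical(d2, d[seq_len(100)])
  expect_error(sample_gamma_diameters(
    gamma_radii_spec(4.0, 4.5e-7, min_diameter = 2e-5, count = 10)),
    "acceptance")
})

test_that("voxel sizing matches the analytic area budget", {
  r <- c(1e-6, 2e-6, 0.5e-6)
  side <- voxel_side_for_icvf(r, 0.3)
  expect_equal(sum(pi * r^2) / side^2, 0.3, tolerance = 1e-12)
  expect_equal(voxel_side_for_icvf(r, 0.6), side / sqrt(2), tolerance = 1e-12)
})

test_that("packing is overlap-free (incl. periodic images) and deterministic", {
  dia <- sample_gamma_diameters(gamma_radii_spec(4, 4.5e-7, count = 120,
                                                 seed = 3))
  pop <- pack_parallel_cylinders(dia, 0.55, seed = 7)
  expect_equal(mcdsim:::count_periodic_overlaps(pop$centers, pop$radii,
                                                pop$voxel_side), 0L)
  expect_equal(population_icvf(pop), 0.55, tolerance = 1e-12)
  pop2 <- pack_parallel_cylinders(dia, 0.55, seed = 7)
  expect_identical(pop$centers, pop2$centers)
  expect_error(pack_parallel_cylinders(dia, 0.75), "0.7")
})

test_that("Monte-Carlo area estimate agrees with the requested ICVF", {
  dia <- rep(2e-6, 10)
  pop <- pack_parallel_cylinders(dia, 0.30, seed = 5)
  est <- estimate_icvf(pop, n_samples = 2e5, seed = 9)
  se <- sqrt(0.3 * 0.7 / 2e5)
  expect_lt(abs(est - 0.30), max(3 * se, 0.01))
})

test_that("undulating mesh matches the helix equation and its volume oracle", {
  A <- 1e-6; L <- 8e-6; len <- 32e-6; d <- 2e-6
  m <- undulating_mesh(d, A, L, len)
  expect_true(mesh_is_watertight(m))
  expect_true(attr(mesh_is_watertight(m), "oriented"))
  ctr <- attr(m, "centerline")
  z <- ctr[, 3]
  expect_equal(ctr[, 1], A * cos(2 * pi * z / L), tolerance = 1e-12)
  expect_equal(ctr[, 2], A * sin(2 * pi * z / L), tolerance = 1e-12)
  ## volume oracle: pi r^2 x numeric arc length of the centerline
  arc <- sum(sqrt(rowSums(diff(ctr)^2)))
  expect_equal(mesh_volume(m), pi * (d / 2)^2 * arc, tolerance = 0.02)
  ## degenerate helix: straight cylinder volume
  ms <- undulating_mesh(d, 0, L, len)
  expect_equal(mesh_volume(ms), pi * (d / 2)^2 * len, tolerance = 0.01)
  ## unmeshable: radius beyond the centerline's radius of curvature
  expect_error(undulating_mesh(6e-6, 2.6e-6, 4e-6, 16e-6),
               "self-intersection")
})

test_that("mesh I/O roundtrips both formats and rejects broken files", {
  m <- cube_mesh(2e-6)
  expect_true(mesh_is_watertight(m))
  for (fmt in c("off", "ply")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_mesh(m, f)
    m2 <- read_mesh(f)
    expect_identical(m2$faces, m$faces)
    expect_equal(m2$vertices, m$vertices, tolerance = 1e-9)
    expect_equal(nrow(m2$vertices), 8)
    expect_equal(nrow(m2$faces), 12)
  }
  ## truncated file
  f <- withr::local_tempfile(fileext = ".off")
  full <- {
    write_mesh(m, f)
    readLines(f)
  }
  writeLines(full[1:5], f)
  expect_error(read_mesh(f), "truncated")
  ## non-watertight input: warn and flag
  g <- withr::local_tempfile(fileext = ".off")
  open_mesh <- trimesh(m$vertices, m$faces[-1, ])
  write_mesh(open_mesh, g)
  expect_warning(m3 <- read_mesh(g), "watertight")
  expect_false(attr(m3, "watertight"))
})

test_that("swept tubes have the predicted vertex count per shell", {
  ctr <- cbind(0, 0, seq(0, 10e-6, length.out = 7))
  tube <- sweep_tube(ctr, 1e-6, n_theta = 12)
  expect_equal(nrow(tube$vertices), 12 * 7 + 2)
  expect_true(mesh_is_watertight(tube))
})
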