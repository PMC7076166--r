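test_that("capsule overlap matches hand geometry", {
  ## parallel unit-separated segments
  a <- strand(rbind(c(0, 0, 0), c(1, 0, 0)), 0.4)
  b <- strand(rbind(c(0, 1, 0), c(1, 1, 0)), 0.4)
  expect_equal(strand_overlap(a, b), 0)
  a6 <- strand(rbind(c(0, 0, 0), c(1, 0, 0)), 0.6)
  b6 <- strand(rbind(c(0, 1, 0), c(1, 1, 0)), 0.6)
  expect_equal(strand_overlap(a6, b6), 0.2, tolerance = 1e-12)
  ## perpendicular intersecting segments: penetration = r_a + r_b
  pa <- strand(rbind(c(-1, 0, 0), c(1, 0, 0)), 0.3)
  pb <- strand(rbind(c(0, -1, 0), c(0, 1, 0)), 0.5)
  expect_equal(strand_overlap(pa, pb), 0.8, tolerance = 1e-12)
})

test_that("segment distance agrees with a dense-sampling oracle", {
  set.seed(30)
  for (k in 1:25) {
    p <- matrix(runif(6, -1, 1), 2, 3, byrow = TRUE)
    q <- matrix(runif(6, -1, 1), 2, 3, byrow = TRUE)
    t <- seq(0, 1, length.out = 201)
    A <- outer(1 - t, p[1, ]) + outer(t, p[2, ])
    B <- outer(1 - t, q[1, ]) + outer(t, q[2, ])
    brute <- sqrt(min(outer(rowSums(A^2), rowSums(B^2), "+") -
                        2 * A %*% t(B)))
    d <- mcdsim:::segment_distance(p[1, ], p[2, ], q[1, ], q[2, ])
    ## the sampled minimum is an upper bound with O(grid spacing) error
    expect_lte(d, brute + 1e-12)
    expect_lt(brute - d, 0.02)
  }
})

test_that("strand energy terms vanish for straight, disjoint systems and add", {
  s1 <- strand(rbind(c(0, 0, 0), c(0, 0, 5e-6), c(0, 0, 10e-6)), 1e-6)
  expect_equal(mcdsim:::strand_curvature_energy(s1), 0)
  expect_equal(mcdsim:::strand_length_energy(s1), 0, tolerance = 1e-12)
  s2 <- strand(rbind(c(5e-6, 0, 0), c(5e-6, 0, 10e-6)), 1e-6)
  sys <- strand_system(list(s1, s2))
  e <- strand_energy(sys)
  expect_equal(e$J_o, 0)
  ## additivity over far-apart subsystems
  far <- function(shift) list(
    strand(rbind(c(0, 0, 0), c(0, 1e-6, 5e-6)) + shift, 0.5e-6),
    strand(rbind(c(0.5e-6, 0, 0), c(0.5e-6, 0, 5e-6)) + shift, 0.4e-6))
  sysA <- strand_system(far(0))
  sysB <- strand_system(far(1e-3))
  sysAB <- strand_system(c(sysA$strands, sysB$strands))
  eA <- strand_energy(sysA); eB <- strand_energy(sysB)
  eAB <- strand_energy(sysAB)
  expect_equal(eAB$E, eA$E + eB$E, tolerance = 1e-9)
})

test_that("optimization removes overlap on a feasible crossing and never
          increases the energy", {
  s1 <- strand(rbind(c(-10e-6, 0, 0), c(0, 0, 0), c(10e-6, 0, 0)), 1e-6)
  s2 <- strand(rbind(c(0, -10e-6, 0.5e-6), c(0, 0, 0.5e-6),
                     c(0, 10e-6, 0.5e-6)), 1e-6)
  sys <- strand_system(list(s1, s2),
                       box = rbind(c(-11e-6, -11e-6, -6e-6),
                                   c(11e-6, 11e-6, 6e-6)))
  e0 <- strand_energy(sys)
  expect_gt(e0$J_o, 0)
  opt <- optimize_strands(sys, iterations = 4000, seed = 5)
  e1 <- strand_energy(opt)
  expect_equal(e1$J_o, 0)
  expect_true(attr(opt, "converged"))
  expect_true(all(diff(attr(opt, "energy_trace")) <= 0))
  ## endpoints pinned
  expect_identical(opt$strands[[1]]$control_points[c(1, 3), ],
                   s1$control_points[c(1, 3), ])
  ## already-optimal straight non-overlapping system is left unchanged
  flat <- strand_system(list(
    strand(rbind(c(0, 0, 0), c(0, 0, 10e-6)), 1e-6),
    strand(rbind(c(5e-6, 0, 0), c(5e-6, 0, 10e-6)), 1e-6)))
  opt2 <- optimize_strands(flat, iterations = 200, seed = 6)
  expect_equal(attr(opt2, "final_energy"), strand_energy(flat)$E)
})

test_that("gamma subdivision keeps sub-strands inside the parent", {
  par <- strand(rbind(c(0, 0, 0), c(0, 0, 40e-6)), 5e-6)
  spec <- gamma_radii_spec(1.2, 1.5e-6, min_diameter = 0.2e-6, count = 40,
                           seed = 6)
  subs <- subdivide_strand(par, spec, seed = 7)
  off <- attr(subs, "offsets")
  ## containment: center offset + radius within the parent radius
  expect_true(all(sqrt(off[, "u"]^2 + off[, "v"]^2) + off[, "r"] <=
                    par$radius + 1e-15))
  ## all diameters honor the truncation floor
  radii <- vapply(subs, function(s) s$radius, numeric(1))
  expect_true(all(2 * radii >= 0.2e-6))
  ## area bookkeeping: sub-areas never exceed the parent area
  expect_lte(sum(pi * radii^2), pi * par$radius^2)
  ## sub-strands do not overlap each other (interdigitation prerequisite)
  for (i in seq_along(subs)[-1])
    for (j in seq_len(i - 1))
      expect_equal(strand_overlap(subs[[i]], subs[[j]]), 0)
  expect_error(subdivide_strand(strand(rbind(c(0, 0, 0), c(0, 0, 1e-6)),
                                       0.05e-6), spec),
               "parent radius")
})

test_that("strand meshes are watertight closed tubes with known volume", {
  s <- strand(rbind(c(0, 0, 0), c(0, 0, 20e-6)), 1.5e-6)
  m <- strands_to_mesh(list(s), n_theta = 24)
  expect_true(mesh_is_watertight(m))
  expect_equal(mesh_volume(m), pi * (1.5e-6)^2 * 20e-6, tolerance = 0.02)
  ## vertex count: n_theta per ring x control points + 2 cap centers
  expect_equal(nrow(m$vertices), 24 * 2 + 2)
})

test_that("a crossing of subdivided bundles interdigitates without overlap", {
  ## two perpendicular parent strands with clearance, each subdivided
  pa <- strand(rbind(c(-20e-6, 0, 0), c(20e-6, 0, 0)), 3e-6)
  pb <- strand(rbind(c(0, -20e-6, 6.2e-6), c(0, 20e-6, 6.2e-6)), 3e-6)
  spec <- gamma_radii_spec(1.2, 1.5e-6, min_diameter = 0.2e-6, count = 12,
                           seed = 8)
  sa <- subdivide_strand(pa, spec, seed = 9)
  sb <- subdivide_strand(pb, spec, seed = 10)
  for (x in sa) for (y in sb)
    expect_equal(strand_overlap(x, y), 0)
  m <- strands_to_mesh(c(sa, sb), n_theta = 12)
  expect_true(mesh_is_watertight(m))
  ## meshed ICVF consistent with the analytic tube volume in the bbox
  bb <- apply(m$vertices, 2, range)
  vol_box <- prod(bb[2, ] - bb[1, ])
  vol_tubes <- sum(vapply(c(sa, sb), function(s) {
    arc <- sum(sqrt(rowSums(diff(s$control_points)^2)))
    pi * s$radius^2 * arc
  }, numeric(1)))
  est <- estimate_icvf(m, 4e4, seed = 11)
  p0 <- vol_tubes / vol_box
  expect_lt(abs(est - p0), 3 * sqrt(p0 * (1 - p0) / 4e4) + 0.01)
})
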