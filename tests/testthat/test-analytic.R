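test_that("GPD attenuation has the right limits", {
  ## no gradient -> no attenuation, exactly
  expect_identical(gpd_perpendicular_attenuation(2e-6, 0.6e-9, 0, 0.01, 0.016),
                   1)
  ## vanishing radius -> fully restricted, no dephasing
  expect_equal(gpd_perpendicular_attenuation(1e-9, 0.6e-9, 0.14, 0.01, 0.016),
               1, tolerance = 1e-9)
  ## huge cylinder -> free diffusion at a moderate b (boundary-layer
  ## corrections scale with b*D and are negligible here)
  att <- gpd_perpendicular_attenuation(500e-6, 0.6e-9, 0.14, 0.010, 0.016)
  b_si <- GYROMAGNETIC_RATIO^2 * 0.14^2 * 0.010^2 * (0.016 - 0.010 / 3)
  expect_equal(att, exp(-b_si * 0.6e-9), tolerance = 0.01)
})

test_that("GPD series is stable under root-count doubling", {
  s1 <- mcdsim:::gpd_series_sum(2e-6, 0.6e-9, 0.010, 0.016, n_roots = 512L)
  s2 <- mcdsim:::gpd_series_sum(2e-6, 0.6e-9, 0.010, 0.016, n_roots = 1024L)
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("Bessel J1' roots match the classical values", {
  mu <- mcdsim:::bessel_j1prime_roots(5)
  expect_equal(mu, c(1.8411838, 5.3314428, 8.5363164, 11.7060049, 14.8635886),
               tolerance = 1e-6)
  ## they are roots: |J1'| tiny
  j1p <- besselJ(mu, 0) - besselJ(mu, 1) / mu
  expect_lt(max(abs(j1p)), 1e-12)
})

test_that("cylinder signal decomposes into parallel and perpendicular parts", {
  p <- tiny_protocol()
  D <- 0.6e-9
  cyl <- cylinder_spec(1.5e-6)
  s <- cylinder_signal(cyl, D, p)
  b_si <- protocol_bvalues(p) * 1e6
  for (i in seq_len(n_measurements(p))) {
    m <- protocol_measurement(p, i)
    gpar <- sum(m$direction * cyl$axis) * m$G
    gperp <- sqrt(max(m$G^2 - gpar^2, 0))
    bpar <- GYROMAGNETIC_RATIO^2 * gpar^2 * m$delta^2 * (m$Delta - m$delta / 3)
    oracle <- exp(-bpar * D) *
      gpd_perpendicular_attenuation(cyl$radius, D, gperp, m$delta, m$Delta)
    expect_equal(s$values[i], oracle, tolerance = 1e-12)
  }
  ## exactly parallel gradient: free attenuation, no restriction
  tab <- data.frame(gx = 0, gy = 0, gz = 1, G = 0.14, Delta = 0.016,
                    delta = 0.010, TE = 0.054)
  ppar <- pgse_protocol(tab)
  expect_equal(cylinder_signal(cyl, D, ppar)$values,
               exp(-protocol_bvalues(ppar) * 1e6 * D), tolerance = 1e-12)
  ## exactly perpendicular: the GPD term alone
  tabp <- data.frame(gx = 1, gy = 0, gz = 0, G = 0.14, Delta = 0.016,
                     delta = 0.010, TE = 0.054)
  pper <- pgse_protocol(tabp)
  expect_equal(cylinder_signal(cyl, D, pper)$values,
               gpd_perpendicular_attenuation(cyl$radius, D, 0.14, 0.010, 0.016),
               tolerance = 1e-12)
})

test_that("cylinder signal is non-increasing in radius per measurement", {
  p <- tiny_protocol(4)
  radii <- seq(0.2e-6, 4e-6, by = 0.2e-6)
  S <- mcdsim:::cylinder_signal_matrix(radii, c(0, 0, 1), 0.6e-9, p)
  for (i in seq_len(nrow(S))) expect_true(all(diff(S[i, ]) <= 1e-12))
})

test_that("mixture signal is the volume-weighted cylinder average", {
  p <- tiny_protocol()
  D <- 0.6e-9
  s1 <- cylinder_signal(cylinder_spec(1e-6), D, p)$values
  s2 <- cylinder_signal(cylinder_spec(2e-6), D, p)$values
  ## radii 1 and 2 um: area weights 1/5 and 4/5
  mix <- mixture_signal(c(1e-6, 2e-6), D, p)
  expect_equal(attr(mix, "weights"), c(1 / 5, 4 / 5))
  expect_equal(mix$values, s1 / 5 + 4 * s2 / 5, tolerance = 1e-12)
  ## single cylinder and n identical cylinders reduce to the same signal
  expect_equal(mixture_signal(1e-6, D, p)$values, s1, tolerance = 1e-14)
  expect_equal(mixture_signal(rep(2e-6, 7), D, p)$values, s2,
               tolerance = 1e-12)
  expect_error(mixture_signal(numeric(0), D, p), "empty")
})

test_that("RMAE matches hand arithmetic and rejects bad references", {
  p <- tiny_protocol(2)
  a <- signal_set(c(0.5, 0.8), p)
  b <- signal_set(c(0.45, 0.84), p)
  expect_equal(rmae(a, b), 100 * (0.1 + 0.05) / 2)
  expect_equal(rmae(a, a), 0)
  expect_equal(rmae(c(0.4, 0.9), 1.01 * c(0.4, 0.9)), 1.0, tolerance = 1e-12)
  expect_error(rmae(c(0.5), c(0.5, 0.6)), "mismatch")
  expect_error(rmae(c(0.5, 1e-13), c(0.5, 0.5)), "1e-12")
  ## non-negativity with equality iff identical
  set.seed(1)
  for (k in 1:20) {
    x <- runif(5, 0.1, 1); y <- x + rnorm(5, sd = 0.01)
    expect_gte(rmae(x, y), 0)
    if (any(x != y)) expect_gt(rmae(x, y), 0)
  }
})

test_that("resolution limit reproduces the published values and scaling", {
  d1 <- resolution_limit(0.01, 0.6e-9, 0.017, 0.140)
  d2 <- resolution_limit(0.01, 0.6e-9, 0.0105, 0.300)
  expect_equal(round(d1 * 1e6, 2), 2.29)
  expect_equal(d2 * 1e6, 1.766, tolerance = 0.01)
  ## d_min ~ G^(-1/2): quadrupling G halves d_min
  expect_equal(resolution_limit(0.01, 0.6e-9, 0.017, 4 * 0.140),
               d1 / 2, tolerance = 1e-12)
})

test_that("tortuosity and effective radius follow their closed forms", {
  expect_equal(tortuosity(0, 4e-6), 1)
  expect_equal(tortuosity(4e-6 / (2 * pi), 4e-6), sqrt(2))
  expect_equal(tortuosity(2.6e-6, 4e-6), sqrt((2 * pi * 2.6 / 4)^2 + 1),
               tolerance = 1e-12)
  expect_equal(round(tortuosity(2.6e-6, 4e-6), 3), 4.205)

  expect_equal(effective_radius(rep(1.3e-6, 5)), 1.3e-6)
  expect_equal(effective_radius(c(1, 2)), (65 / 5)^(1 / 4), tolerance = 1e-12)
  set.seed(2)
  for (k in 1:10) {
    r <- runif(20, 0.2, 5)
    expect_gte(effective_radius(r), sqrt(mean(r^2)) - 1e-12)
  }
  expect_error(effective_radius(numeric(0)), "empty")
})

test_that("sensitivity matrix has a zero diagonal and is asymmetric", {
  p <- tiny_protocol(8)
  dg <- seq(1e-6, 4e-6, by = 0.5e-6)
  sm <- sensitivity_matrix(dg, 0.6e-9, p)
  expect_equal(unname(diag(sm$rmae)), rep(0, length(dg)))
  expect_true(all(sm$rmae >= 0))
  ## denominator is the ground-truth signal: generally asymmetric
  expect_gt(abs(sm$rmae[1, 7] - sm$rmae[7, 1]), 1e-6)
  expect_true(all(diag(sm$mask)))
})

test_that("small diameters are indistinguishable under the ActiveAx protocol", {
  p <- builtin_protocol("activeax_exvivo", n_directions = 20)
  sm <- sensitivity_matrix(c(1e-6, 2e-6), 0.6e-9, p)
  expect_lt(sm$rmae[1, 2], 1)
  expect_lt(sm$rmae[2, 1], 1)
})
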