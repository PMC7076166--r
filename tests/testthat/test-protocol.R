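test_that("scheme write/parse roundtrip is lossless and order-preserving", {
  p <- builtin_protocol("dyrby_exvivo", n_directions = 5)
  f <- withr::local_tempfile(fileext = ".scheme")
  write_scheme(p, f)
  q <- read_scheme(f)
  expect_equal(n_measurements(q), n_measurements(p))
  expect_equal(as.matrix(q$table), as.matrix(p$table), tolerance = 1e-12)
})

test_that("malformed scheme lines are rejected with a line number", {
  f <- withr::local_tempfile(fileext = ".scheme")
  writeLines(c("VERSION: STEJSKALTANNER",
               "0 0 1 0.1 0.02 0.01 0.05",
               "0 1 0 0.1 0.02 0.01"), f)          # 6 tokens
  expect_error(read_scheme(f), "line 3")
  writeLines(c("0 0 1 0.1 0.02 0.01 0.05",
               "0 x 0 0.1 0.02 0.01 0.05"), f)     # non-numeric
  expect_error(read_scheme(f), "line 2")
})

test_that("measurement invariants reject impossible timings", {
  expect_error(pgse_measurement(c(0, 0, 1), 0.1, delta = 0.03, Delta = 0.02,
                                TE = 0.06), "delta")
  expect_error(pgse_measurement(c(0, 0, 1), 0.1, delta = 0.01, Delta = 0.05,
                                TE = 0.055), "TE")
  expect_error(pgse_measurement(c(0, 0, 2), 0.1, delta = 0.01, Delta = 0.02,
                                TE = 0.06), "unit-norm")
  ## zero-gradient measurement does not need a direction
  m <- pgse_measurement(c(0, 0, 0), 0, delta = 0.01, Delta = 0.02, TE = 0.06)
  expect_equal(bvalue(m), 0)
})

test_that("b-value follows the Stejskal-Tanner form and its scaling laws", {
  m <- pgse_measurement(c(1, 0, 0), G = 0.219, delta = 0.007, Delta = 0.0204,
                        TE = 0.0359)
  ## hand-computed gamma^2 G^2 delta^2 (Delta - delta/3) / 1e6
  oracle <- GYROMAGNETIC_RATIO^2 * 0.219^2 * 0.007^2 *
    (0.0204 - 0.007 / 3) / 1e6
  expect_equal(bvalue(m), oracle, tolerance = 1e-14)
  expect_equal(bvalue_stejskal_tanner(2 * 0.219, 0.007, 0.0204),
               4 * bvalue_stejskal_tanner(0.219, 0.007, 0.0204),
               tolerance = 1e-14)
  expect_equal(bvalue_stejskal_tanner(0, 0.007, 0.0204), 0)
})

test_that("built-in protocols match their published shell parameters", {
  a <- builtin_protocol("activeax_exvivo")
  expect_equal(n_measurements(a), 360)
  expect_true(all(a$table$TE == 0.054))
  ## shells as printed, incl. the duplicated shells (i) and (ii); each
  ## shell is a 90-measurement block
  blocks <- a$table[c(1, 91, 181, 271), ]
  expect_equal(blocks$G, c(0.140, 0.140, 0.131, 0.140))
  expect_equal(blocks$delta, c(0.010, 0.010, 0.007, 0.017))
  expect_equal(blocks$Delta, c(0.016, 0.016, 0.045, 0.035))

  d <- builtin_protocol("dyrby_exvivo")
  expect_equal(n_measurements(d), 270)
  expect_true(all(d$table$TE == 0.0359))

  r <- builtin_protocol("radial_xy")
  expect_equal(n_measurements(r), 1800)
  expect_true(all(r$table$gz == 0))
  expect_equal(sqrt(r$table$gx^2 + r$table$gy^2), rep(1, 1800),
               tolerance = 1e-12)

  expect_error(builtin_protocol("nope"), "activeax_exvivo")
})

test_that("every built-in protocol passes the measurement invariants", {
  for (nm in c("activeax_exvivo", "dyrby_exvivo", "radial_xy")) {
    p <- builtin_protocol(nm, n_directions = 12)
    for (i in seq_len(n_measurements(p)))
      expect_silent(mcdsim:::validate_measurement(protocol_measurement(p, i)))
  }
})

test_that("direction sets are unit-norm and reproducible", {
  d1 <- mcdsim:::repulsion_directions(30)
  d2 <- mcdsim:::repulsion_directions(30)
  expect_identical(d1, d2)
  expect_equal(sqrt(rowSums(d1^2)), rep(1, 30), tolerance = 1e-12)
  ## repulsion spreads points: min pairwise angle well above random clumping
  ang <- acos(pmin(abs(d1 %*% t(d1)), 1))
  diag(ang) <- Inf
  expect_gt(min(ang), 0.15)
})

test_that("mixed echo times are refused for a single run", {
  tab <- rbind(data.frame(gx = 0, gy = 0, gz = 1, G = 0.1, Delta = 0.02,
                          delta = 0.01, TE = 0.05),
               data.frame(gx = 0, gy = 0, gz = 1, G = 0.1, Delta = 0.02,
                          delta = 0.01, TE = 0.06))
  p <- pgse_protocol(tab)
  expect_error(mcdsim:::protocol_te(p), "echo time")
})
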