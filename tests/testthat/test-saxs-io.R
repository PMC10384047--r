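test_that("q_from_angle implements the Bragg relation and its limits", {
  expect_identical(q_from_angle(0, 0.1542), 0)
  # algebraic identity: sin(theta/2) = lambda/(4 pi) gives q = 1
  lam <- 0.1542
  theta <- 2 * asin(lam / (4 * pi))
  expect_equal(q_from_angle(theta, lam), 1, tolerance = 1e-12)
  # direct high-precision evaluation
  expect_equal(q_from_angle(0.049105, 0.1542),
               4 * pi / 0.1542 * sin(0.049105 / 2), tolerance = 1e-12)
  expect_equal(q_from_angle(0.049105, 0.1542), 2.0007, tolerance = 1e-4)
  # strictly monotone on a grid
  th <- seq(1e-4, pi - 1e-4, length.out = 200)
  expect_true(all(diff(q_from_angle(th, lam)) > 0))
  expect_error(q_from_angle(0.1, -1), class = "ampchem_invalid_parameter")
  expect_error(q_from_angle(pi, 0.1542), class = "ampchem_invalid_parameter")
})

test_that("background subtraction is pointwise with quadrature sigma", {
  q <- seq(0.2, 2, length.out = 10)
  s <- scattering_curve(q, 2 + 3 * q, sigma = rep(3, 10))
  b <- scattering_curve(q, rep(2, 10), sigma = rep(4, 10))
  d <- subtract_background(s, b)
  expect_equal(d$intensity, 3 * q)
  expect_equal(d$sigma, rep(5, 10))  # sqrt(9 + 16)
  # self-subtraction
  z <- subtract_background(s, s)
  expect_equal(z$intensity, rep(0, 10))
  # grid mismatch is an error, never silent interpolation
  b2 <- scattering_curve(q + 0.01, rep(2, 10))
  expect_error(subtract_background(s, b2), class = "ampchem_grid_mismatch")
})

test_that("absolute scaling is linear, guarded, and commutes with subtraction", {
  cur <- flat_curve(level = 0.1)
  abs1 <- scale_to_absolute(cur, water_level = 0.1, water_xs = 0.01632)
  expect_equal(abs1$intensity, rep(0.01632, 10))
  expect_identical(abs1$meta$scale, "absolute")
  # doubling the water level halves the output
  abs2 <- scale_to_absolute(cur, water_level = 0.2, water_xs = 0.01632)
  expect_equal(abs2$intensity, abs1$intensity / 2)
  # multiplier is the direct ratio
  expect_equal(abs1$intensity[1] / cur$intensity[1], 0.1632)
  # scaling twice is an error
  expect_error(scale_to_absolute(abs1, 0.1),
               class = "ampchem_invalid_calibration")
  expect_error(scale_to_absolute(cur, 0),
               class = "ampchem_invalid_calibration")
  # linearity: subtract-then-scale == scale-both-then-subtract
  q <- seq(0.2, 2, length.out = 10)
  s <- scattering_curve(q, 1 + q^2, sigma = 0.01 * (1 + q^2))
  b <- scattering_curve(q, rep(0.3, 10), sigma = rep(0.01, 10))
  r1 <- scale_to_absolute(subtract_background(s, b), 0.25)
  r2 <- subtract_background(scale_to_absolute(s, 0.25),
                            scale_to_absolute(b, 0.25))
  expect_equal(r1$intensity, r2$intensity, tolerance = 1e-12)
  expect_equal(r1$sigma, r2$sigma, tolerance = 1e-12)
})

test_that("curve text I/O round-trips losslessly and rejects bad input", {
  q <- sort(runif(20, 0.3, 5))
  cur <- scattering_curve(q, exp(-q), sigma = 0.02 * exp(-q),
                          meta = list(temperature = 25, scale = "absolute"))
  f <- withr::local_tempfile(fileext = ".dat")
  write_curve(cur, f)
  back <- read_curve(f)
  expect_identical(back$q, cur$q)          # bitwise
  expect_equal(back$intensity, cur$intensity, tolerance = 1e-14)
  expect_equal(back$sigma, cur$sigma, tolerance = 1e-14)
  expect_equal(back$meta$temperature, 25)
  # 2-column file has no sigma; comma dialect accepted
  f2 <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# exposure: 1200", "0.2,1.0", "0.4,0.8", "0.6,0.7",
               "0.8,0.65", "1.0,0.6"), f2)
  c2 <- read_curve(f2)
  expect_null(c2$sigma)
  expect_equal(c2$meta$exposure, 1200)
  # angstrom dialect multiplies q by 10
  f3 <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0.02 1", "0.04 2", "0.06 3", "0.08 4", "0.10 5"), f3)
  expect_equal(read_curve(f3, dialect = "angstrom")$q,
               c(0.2, 0.4, 0.6, 0.8, 1.0))
  # parse errors carry the offending row
  f4 <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0.2 1", "0.4 x", "0.6 3", "0.8 4", "1.0 5"), f4)
  expect_error(read_curve(f4), "row 2", class = "ampchem_parse_error")
  # non-monotone q rejected
  f5 <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0.2 1", "0.6 2", "0.4 3", "0.8 4", "1.0 5"), f5)
  expect_error(read_curve(f5), class = "ampchem_parse_error")
})
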