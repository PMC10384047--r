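test_that("noiseless piecewise-linear data give the exact breakpoint", {
  ser <- gen_conductivity(1.72, slope_below = 80, slope_ratio = 0.74,
                          noise_frac = 0, seed = 1)
  r <- cmc_from_conductivity(ser, n_boot = 0)
  expect_equal(r$cmc, 1.72, tolerance = 1e-10)
  expect_equal(r$alpha, 0.74, tolerance = 1e-10)
  expect_equal(r$beta, 0.26, tolerance = 1e-10)
  # beta + alpha = 1 exactly
  expect_identical(r$beta, 1 - r$alpha)
})

test_that("a single straight line has no breakpoint", {
  c_ <- seq(0.5, 3, length.out = 20)
  ser <- concentration_series(c_, 80 * c_, kind = "conductivity")
  expect_error(cmc_from_conductivity(ser, n_boot = 0),
               class = "ampchem_no_breakpoint")
})

test_that("the conductivity CMC is equivariant under affine response maps", {
  ser <- gen_conductivity(1.2, slope_below = 60, slope_ratio = 0.6,
                          noise_frac = 0.004, seed = 7)
  r0 <- cmc_from_conductivity(ser, n_boot = 0)
  aff <- concentration_series(ser$concentration,
                              2.5 * ser$response + 40,
                              kind = "conductivity")
  r1 <- cmc_from_conductivity(aff, n_boot = 0)
  expect_equal(r1$cmc, r0$cmc, tolerance = 1e-10)
  # pure scaling (b = 0) leaves alpha unchanged too
  sc <- concentration_series(ser$concentration, 2.5 * ser$response,
                             kind = "conductivity")
  expect_equal(cmc_from_conductivity(sc, n_boot = 0)$alpha, r0$alpha,
               tolerance = 1e-10)
})

test_that("noisy breakpoints are recovered with calibrated intervals", {
  hits <- 0L
  cmcs <- numeric(0)
  for (s in 1:20) {
    ser <- gen_conductivity(1.72, slope_below = 80, slope_ratio = 0.74,
                            noise_frac = 0.005, seed = s)
    r <- cmc_from_conductivity(ser, n_boot = 150, seed = s)
    cmcs <- c(cmcs, r$cmc)
    if (abs(r$cmc - 1.72) <= r$cmc_ci) hits <- hits + 1L
  }
  expect_lt(abs(mean(cmcs) - 1.72) / 1.72, 0.02)
  expect_gte(hits / 20, 0.9)
})

test_that("recovery holds across the published conductivity table", {
  tab <- ref_micellization()
  tab <- tab[!is.na(tab$cmc_cond_mM) & !is.na(tab$beta), ]
  rel_err <- vapply(seq_len(nrow(tab)), function(i) {
    res <- replay_cmc_conductivity(tab$cmc_cond_mM[i], 1 - tab$beta[i],
                                   seeds = 1:8)
    abs(mean(res$cmc) - tab$cmc_cond_mM[i]) / tab$cmc_cond_mM[i]
  }, numeric(1))
  expect_lt(mean(rel_err), 0.03)
})

test_that("fluorescence sigmoids recover the midpoint and reject flats", {
  ser <- gen_fluorescence(3.0, A1 = 1.6, A2 = 1.2, noise_sd = 0, seed = 1)
  r <- cmc_from_fluorescence(ser)
  expect_equal(r$cmc, 3.0, tolerance = 1e-3)
  expect_true(is.na(r$beta))
  flat <- concentration_series(10^seq(-2, 1, length.out = 12),
                               rep(1.6, 12), kind = "fluorescence")
  expect_error(cmc_from_fluorescence(flat), class = "ampchem_no_transition")
  # relabeling A1 <-> A2 with reversed response gives the same midpoint
  rev <- concentration_series(ser$concentration,
                              (1.6 + 1.2) - ser$response,
                              kind = "fluorescence")
  expect_equal(cmc_from_fluorescence(rev)$cmc, r$cmc, tolerance = 1e-6)
})

test_that("kind mismatches are rejected", {
  ser <- gen_fluorescence(1.0, noise_sd = 0, seed = 1)
  expect_error(cmc_from_conductivity(ser), class = "ampchem_invalid_series")
  ser2 <- gen_conductivity(1.0, noise_frac = 0, seed = 1)
  expect_error(cmc_from_fluorescence(ser2), class = "ampchem_invalid_series")
})
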