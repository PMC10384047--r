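test_that("generators are deterministic and persist their truth", {
  m <- ref_bilayer_truth("C12TC3NH3Cl", 0)
  a <- gen_saxs(m, noise_frac = 0.02, seed = 11)
  b <- gen_saxs(m, noise_frac = 0.02, seed = 11)
  expect_identical(a$intensity, b$intensity)
  expect_false(identical(a$intensity,
                         gen_saxs(m, noise_frac = 0.02, seed = 12)$intensity))
  expect_named(attr(a, "truth"), c("model", "family", "noise_frac",
                                   "floor", "seed"))
  s1 <- gen_conductivity(1.72, seed = 5)
  s2 <- gen_conductivity(1.72, seed = 5)
  expect_identical(s1$response, s2$response)
  expect_equal(attr(s1, "truth")$beta, 0.26)
  f1 <- gen_fluorescence(0.67, seed = 3)
  expect_identical(f1$response, gen_fluorescence(0.67, seed = 3)$response)
  t1 <- gen_titration(7.95, seed = 2)
  expect_identical(t1$pH, gen_titration(7.95, seed = 2)$pH)
  expect_equal(attr(t1, "truth")$v_equiv, 1.5)
  # generators leave the caller's RNG stream untouched
  withr::with_seed(99, {
    before <- runif(1)
  })
  withr::with_seed(99, {
    invisible(gen_conductivity(1.0, seed = 123))
    expect_identical(runif(1), before)
  })
})

test_that("zero noise reproduces the forward models exactly", {
  m <- ref_micelle_truth("C14TC3NH3Cl")$model
  cur <- gen_saxs(m, noise_frac = 0, seed = 1)
  expect_equal(cur$intensity, cylinder_intensity(m, cur$q), tolerance = 1e-14)
  fl <- gen_fluorescence(3.0, noise_sd = 0, seed = 1)
  x <- log10(fl$concentration)
  expect_equal(fl$response,
               1.2 + 0.4 / (1 + exp((x - log10(3)) / 0.1)),
               tolerance = 1e-14)
})

test_that("synthetic noise matches the stored uncertainties", {
  # mean over many replicates converges to the model (law of large numbers)
  m <- ref_bilayer_truth("C12TC3NH3Cl", 0)
  q <- seq(0.5, 2, length.out = 5)
  i_model <- bilayer_intensity(m, q)
  sims <- vapply(1:300, function(s)
    gen_saxs(m, q_grid = q, noise_frac = 0.05, seed = 5000 + s)$intensity,
    numeric(5))
  se <- 0.05 * i_model / sqrt(300)
  expect_true(all(abs(rowMeans(sims) - i_model) < 3.5 * se))
  # sigma column equals the promised max(noise_frac * I, floor)
  cur <- gen_saxs(m, q_grid = q, noise_frac = 0.02, floor = 1e-3, seed = 1)
  expect_equal(cur$sigma, pmax(0.02 * i_model, 1e-3))
})

test_that("degenerate generator settings propagate downstream", {
  # equal slopes: no breakpoint for the estimator to find
  expect_warning(ser <- gen_conductivity(1.0, slope_ratio = 1,
                                         noise_frac = 0, seed = 1),
                 class = "ampchem_unusual_slope_ratio")
  expect_error(cmc_from_conductivity(ser, n_boot = 0),
               class = "ampchem_no_breakpoint")
})

test_that("activity-table generation snaps and censors correctly", {
  rec <- gen_activity_table("cmpA", c("s1", "s2"), matrix(c(7, 600), 1),
                            mbc_factor = 2)
  expect_identical(rec[[1]]$mic$value, 8)
  expect_identical(rec[[1]]$mbc$value, 16)
  expect_identical(rec[[2]]$mic$censor, "gt")
  expect_identical(attr(rec, "truth")$mbc_factor, 2)
})
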