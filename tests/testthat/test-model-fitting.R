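test_that("reduced chi-squared follows its definition", {
  q <- seq(0.2, 2, length.out = 10)
  cur <- scattering_curve(q, exp(-q), sigma = rep(0.1, 10))
  expect_equal(reduced_chi_squared(cur, exp(-q), 3), 0)
  # residuals all equal to sigma -> N / (N - p)
  expect_equal(reduced_chi_squared(cur, exp(-q) + 0.1, 4), 10 / 6)
  expect_error(reduced_chi_squared(cur, exp(-q), 10),
               class = "ampchem_degrees_of_freedom")
})

test_that("a zero-residual start converges immediately", {
  m <- ref_bilayer_truth("C12TC3NH3Cl", 0)
  cur <- gen_saxs(m, noise_frac = 0, seed = 1)
  start <- unlist(m[c("Zh", "sigma_h", "drho_h", "sigma_c", "drho_c",
                      "scale", "bkg")])
  f <- fit_curve(fit_problem("bilayer", cur, start), n_starts = 1)
  expect_lt(f$chi2_red, 1e-10)
  expect_lte(f$n_iter, 2)
  expect_true(f$converged)
})

test_that("noiseless synthetic curves are recovered from perturbed starts", {
  # cylinder
  m <- ref_micelle_truth("C12TC3NH3Cl")$model
  cur <- gen_saxs(m, noise_frac = 0, seed = 1)
  truth <- unlist(m[c("Rc", "Rh", "Lc", "rho_c", "rho_h", "rho_solv",
                      "phi", "bkg")])
  start <- truth
  start[c("Rc", "Rh", "Lc", "rho_h")] <-
    start[c("Rc", "Rh", "Lc", "rho_h")] * c(1.15, 0.85, 1.2, 1.1)
  f <- fit_curve(fit_problem("cylinder", cur, start), n_starts = 4,
                 stop_at_chi2 = 1e-6)
  for (nm in c("Rc", "Rh", "Lc", "rho_h"))
    expect_equal(f$estimates[[nm]], truth[[nm]], tolerance = 1e-3,
                 label = nm)
  # bilayer
  b <- ref_bilayer_truth("C12TC3NH3Cl", 0)
  curb <- gen_saxs(b, noise_frac = 0, seed = 1)
  truthb <- unlist(b[c("Zh", "sigma_h", "drho_h", "sigma_c", "drho_c",
                       "scale", "bkg")])
  startb <- truthb
  startb[c("Zh", "sigma_h", "drho_h", "sigma_c", "scale")] <-
    startb[c("Zh", "sigma_h", "drho_h", "sigma_c", "scale")] *
    c(1.1, 0.9, 1.15, 0.85, 1.2)
  fb <- fit_curve(fit_problem("bilayer", curb, startb), n_starts = 4,
                  stop_at_chi2 = 1e-6)
  expect_equal(fb$estimates[["Zh"]], truthb[["Zh"]], tolerance = 1e-3)
})

test_that("chi2_red of correctly specified fits concentrates near 1", {
  m <- ref_bilayer_truth("C12TC3NH3Cl", 0)
  start <- unlist(m[c("Zh", "sigma_h", "drho_h", "sigma_c", "drho_c",
                      "scale", "bkg")])
  ch <- vapply(1:30, function(s) {
    cur <- gen_saxs(m, noise_frac = 0.02, seed = 300 + s)
    fit_curve(fit_problem("bilayer", cur, start), n_starts = 1)$chi2_red
  }, numeric(1))
  n <- 200; p <- 5
  expect_lt(abs(mean(ch) - 1), 3 * sqrt(2 / (n - p)) / sqrt(30) * 5 + 0.05)
  expect_true(all(ch > 0.5 & ch < 1.6))
})

test_that("missing sigma triggers the unit-weight warning", {
  q <- seq(0.2, 6, length.out = 30)
  m <- ref_bilayer_truth("C12TC3NH3Cl", 0)
  cur <- scattering_curve(q, bilayer_intensity(m, q))
  start <- unlist(m[c("Zh", "sigma_h", "drho_h", "sigma_c", "drho_c",
                      "scale", "bkg")])
  expect_warning(fit_problem("bilayer", cur, start),
                 class = "ampchem_unit_weights")
})

test_that("geometry selection recovers the generating family", {
  spec12 <- surfactant_spec(12, concentration = 10)
  cyl <- ref_micelle_truth("C12TC3NH3Cl")$model
  cur_c <- gen_saxs(cyl, noise_frac = 0.02, seed = 3)
  sel_c <- suppressWarnings(select_geometry(cur_c, spec12, n_starts = 4))
  expect_identical(sel_c$family, "cylinder")
  sph <- core_shell_sphere(Rc = 1.5, Rh = 0.8, rho_c = 275, rho_h = 371,
                           phi = 0.00187, bkg = 1e-4)
  cur_s <- gen_saxs(sph, noise_frac = 0.02, seed = 4)
  sel_s <- suppressWarnings(select_geometry(cur_s, spec12, n_starts = 4))
  expect_identical(sel_s$family, "sphere")
  expect_s3_class(sel_c$cylinder, "fit_result")
  expect_s3_class(sel_c$sphere, "fit_result")
})
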