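test_that("Tanford chain geometry matches the group-additive formulas", {
  expect_equal(tanford_chain_volume(0), 0.0274)
  expect_equal(tanford_chain_volume(11), 0.3233)
  expect_equal(tanford_chain_volume(13), 0.3771)
  expect_equal(tanford_max_length(0), 0.154)
  # the dodecanoyl/tetradecanoyl tails round to the conventional 1.4/1.7 nm
  expect_equal(round(tanford_max_length(10), 1), 1.4)
  expect_equal(round(tanford_max_length(12), 1), 1.7)
  expect_error(tanford_chain_volume(-1), class = "ampchem_invalid_parameter")
  expect_error(tanford_max_length(-2), class = "ampchem_invalid_parameter")
})

test_that("cylinder intensity handles degenerate contrast and shell limits", {
  q <- seq(0.2, 6, length.out = 40)
  # zero contrast everywhere -> flat background
  m0 <- core_shell_cylinder(Rc = 1, Rh = 0.5, Lc = 6, rho_c = 334,
                            rho_h = 334, rho_solv = 334, phi = 0.002,
                            bkg = 0.03)
  expect_equal(cylinder_intensity(m0, q), rep(0.03, 40), tolerance = 1e-12)
  # vanishing shell reduces to a solid cylinder of core contrast
  mthin <- core_shell_cylinder(Rc = 1.04, Rh = 1e-9, Lc = 5.9, rho_c = 274,
                               rho_h = 371, phi = 0.00187, bkg = 0)
  msolid <- list(Rc = 1.04, Rh = 0, Lc = 5.9, rho_c = 274, rho_h = 334,
                 rho_solv = 334, phi = 0.00187, bkg = 0)
  # oracle with the shell term cancelled: solid cylinder, contrast rho_c-rho_solv
  solid <- cyl_oracle(list(Rc = 1.04, Rh = 1e-12, Lc = 5.9, rho_c = 274,
                           rho_h = 334, rho_solv = 334, phi = 0.00187,
                           bkg = 0), q, n = 2e4)
  expect_equal(cylinder_intensity(mthin, q), solid, tolerance = 1e-3)
  expect_error(cylinder_intensity(m0, c(0, 1)), class = "ampchem_domain_error")
  expect_error(core_shell_cylinder(-1, 0.5, 6, 274, 371, phi = 0.002),
               class = "ampchem_invalid_model")
})

test_that("forward models match independent quadrature oracles", {
  # spot check here on a coarse grid; the full published-parameter sweep
  # runs in the acceptance suite
  q <- seq(0.2, 6, length.out = 12)
  m <- ref_micelle_truth("C12TC3NH3Cl")$model
  expect_equal(cylinder_intensity(m, q), cyl_oracle(m, q, n = 5e4),
               tolerance = 1e-4)
  b <- ref_bilayer_truth("C12TC3NH3Cl", 0)
  expect_equal(bilayer_intensity(b, q), bil_oracle(b, q), tolerance = 1e-6)
})

test_that("bilayer intensity scales quadratically and stays above background", {
  q <- seq(0.2, 6, length.out = 50)
  b <- ref_bilayer_truth("C14TC3NH3Cl", 40, scale = 1e-4, bkg = 5e-4)
  i1 <- bilayer_intensity(b, q)
  expect_true(all(i1 >= b$bkg))
  b2 <- gaussian_bilayer(b$Zh, b$sigma_h, 2 * b$drho_h, b$sigma_c,
                         2 * b$drho_c, scale = b$scale, bkg = b$bkg)
  i2 <- bilayer_intensity(b2, q)
  expect_equal(i2 - b$bkg, 4 * (i1 - b$bkg), tolerance = 1e-12)
  # zero contrast -> flat background
  b0 <- gaussian_bilayer(1.87, 0.47, 0, 0.43, 0, scale = 1, bkg = 0.02)
  expect_equal(bilayer_intensity(b0, q), rep(0.02, 50))
  # cylinder intensity also bounded below by background for real contrasts
  m <- ref_micelle_truth("C14TC3NH3Cl")$model
  expect_true(all(cylinder_intensity(m, q) >= m$bkg))
})

test_that("electron density profile is even and pointwise correct", {
  b <- ref_bilayer_truth("C12TC3NH3Cl", 0)
  z <- runif(25, -4, 4)
  expect_equal(electron_density_profile(b, z),
               electron_density_profile(b, -z), tolerance = 1e-12)
  # direct evaluation at the headgroup centre
  at_zh <- b$drho_h * (1 + exp(-2 * b$Zh^2 / b$sigma_h^2)) +
    b$drho_c * exp(-b$Zh^2 / (2 * b$sigma_c^2))
  expect_equal(electron_density_profile(b, b$Zh), at_zh, tolerance = 1e-12)
  # headgroup maximum is dominated by the first Gaussian (~ drho_h = 107)
  expect_gt(electron_density_profile(b, b$Zh), 100)
})

test_that("derived micellar quantities reproduce the published geometry", {
  tab <- ref_micelle_fits()
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    m <- core_shell_cylinder(r$Rc_nm, r$Rh_nm, r$Lc_nm, r$rho_c, r$rho_h,
                             phi = r$phi, bkg = 0)
    spec <- surfactant_spec(r$n_tail_carbons, concentration = 10)
    d <- derive_micelle_params(m, spec)
    # N_agg within the +/-5 of the first column or 3% relative
    expect_true(abs(d$N_agg - r$N_agg) <= 5 ||
                  abs(d$N_agg - r$N_agg) / r$N_agg <= 0.03,
                label = sprintf("%s N_agg", r$compound))
    # A_m from printed R_c, L_c, N_agg reproduces the printed row exactly
    expect_equal(round(2 * pi * r$Rc_nm * r$Lc_nm / r$N_agg, 2), r$A_m_nm2,
                 label = sprintf("%s A_m", r$compound))
  }
  # degenerate cylinder guarded
  mm <- core_shell_cylinder(1.04, 0.8, 1e-13, 274, 371, phi = 0.00187)
  expect_error(derive_micelle_params(mm, surfactant_spec(12)),
               class = "ampchem_division_guard")
  # head volume exceeding the shell allocation clamps with a warning
  m2 <- core_shell_cylinder(1.04, 0.1, 5.9, 274, 371, phi = 0.00187)
  expect_warning(d2 <- derive_micelle_params(
    m2, surfactant_spec(12, head_dry_volume = 1.0)),
    class = "ampchem_negative_hydration")
  expect_identical(d2$N_H2O, 0)
})

test_that("volume fraction is linear in concentration", {
  s10 <- surfactant_spec(12, concentration = 10)
  s20 <- surfactant_spec(12, concentration = 20)
  expect_equal(volume_fraction(s10), 0.00195, tolerance = 2e-3)
  expect_equal(volume_fraction(s20), 2 * volume_fraction(s10))
})
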