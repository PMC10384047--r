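# Every generator draws from one seeded stream (withr::with_seed, so the
# caller's RNG state is untouched) and attaches the generating truth as
# attr(x, "truth") - the basis of all recovery tests.

#' Synthetic SAXS curve from a forward model
#'
#' Applies multiplicative Gaussian noise to a forward-model curve:
#' `I_obs = I_model * (1 + eps)`, `eps ~ N(0, noise_frac)`. The stored
#' per-point uncertainty is `max(noise_frac * I_model, floor)`, so refits of
#' correctly specified models have reduced chi-squared near 1.
#'
#' @param model A [core_shell_cylinder()], [core_shell_sphere()] or
#'   [gaussian_bilayer()].
#' @param q_grid Scattering vectors \[nm^-1\].
#' @param noise_frac Relative noise level (0.02 mirrors laboratory-source
#'   measurement scatter).
#' @param floor Additive sigma floor \[cm^-1\], keeping uncertainties
#'   positive on noiseless curves.
#' @param seed Integer seed.
#' @return A [scattering_curve()] with `attr(, "truth")` holding the model
#'   and noise settings.
#' @export
gen_saxs <- function(model, q_grid = seq(0.2, 6, length.out = 200),
                     noise_frac = 0.02, floor = 1e-8, seed = 1L) {
  stopifnot(inherits(model, "saxs_model"))
  if (noise_frac < 0)
    .stop_ampchem("noise_frac must be >= 0", "ampchem_invalid_parameter")
  i_model <- if (inherits(model, "core_shell_cylinder"))
    cylinder_intensity(model, q_grid)
  else if (inherits(model, "core_shell_sphere"))
    sphere_intensity(model, q_grid)
  else bilayer_intensity(model, q_grid)
  eps <- withr::with_seed(seed, rnorm(length(q_grid), 0, noise_frac))
  sigma <- pmax(noise_frac * i_model, floor)
  out <- scattering_curve(q_grid, i_model * (1 + eps), sigma = sigma,
                          meta = list(scale = "absolute", synthetic = TRUE))
  attr(out, "truth") <- list(model = unclass(model),
                             family = class(model)[1],
                             noise_frac = noise_frac, floor = floor,
                             seed = seed)
  out
}

#' Synthetic conductivity scan with a micellization breakpoint
#'
#' Piecewise-linear conductivity `kappa = S1 * c` below the CMC and
#' `kappa(cmc) + S1 * slope_ratio * (c - cmc)` above, with optional
#' quadratic rounding of the kink over `+/- rounding_width` and
#' multiplicative Gaussian noise.
#'
#' @param cmc_mM Breakpoint \[mM\].
#' @param slope_below Pre-CMC slope S1 \[uS cm^-1 mM^-1\].
#' @param slope_ratio Post/pre slope ratio (the degree of ionization alpha);
#'   values >= 1 are permitted with a warning.
#' @param c_grid Concentrations \[mM\].
#' @param noise_frac Relative noise (0.005 mirrors triplicate conductivity
#'   repeatability).
#' @param rounding_width Half-width \[mM\] of the smoothed kink; 0 keeps it
#'   sharp.
#' @param seed Integer seed.
#' @return A conductivity [concentration_series()] with generating truth in
#'   `attr(, "truth")`.
#' @export
gen_conductivity <- function(cmc_mM, slope_below = 80, slope_ratio = 0.74,
                             c_grid = seq(0.2, 2, length.out = 25) * cmc_mM,
                             noise_frac = 0.005, rounding_width = 0,
                             seed = 1L) {
  if (slope_ratio >= 1)
    .warn_ampchem("slope_ratio >= 1: conductivity increases faster above the CMC",
                  "ampchem_unusual_slope_ratio")
  s1 <- slope_below
  s2 <- slope_below * slope_ratio
  kappa <- ifelse(c_grid <= cmc_mM, s1 * c_grid,
                  s1 * cmc_mM + s2 * (c_grid - cmc_mM))
  if (rounding_width > 0) {
    # quadratic blend matching value and slope at cmc +/- w
    w <- rounding_width
    inb <- abs(c_grid - cmc_mM) < w
    x <- c_grid[inb]
    kappa[inb] <- s1 * x + (s2 - s1) * (x - cmc_mM + w)^2 / (4 * w)
  }
  noisy <- withr::with_seed(seed,
    kappa * (1 + rnorm(length(c_grid), 0, noise_frac)))
  out <- concentration_series(c_grid, noisy, kind = "conductivity")
  attr(out, "truth") <- list(cmc = cmc_mM, slope_below = slope_below,
                             slope_ratio = slope_ratio, beta = 1 - slope_ratio,
                             noise_frac = noise_frac,
                             rounding_width = rounding_width, seed = seed)
  out
}

#' Synthetic pyrene I1/I3 fluorescence series
#'
#' Boltzmann sigmoid on the log10 concentration axis between the aqueous
#' plateau (about 1.6, the pyrene ratio in pure water) and the micellar
#' plateau, with additive Gaussian noise.
#'
#' @param cmc_mM Transition midpoint \[mM\].
#' @param A1,A2 Low- and high-concentration plateaus (`A1 > A2`).
#' @param dx_decades Transition width in decades of concentration.
#' @param c_grid Concentrations \[mM\].
#' @param noise_sd Additive noise standard deviation.
#' @param seed Integer seed.
#' @return A fluorescence [concentration_series()] with generating truth in
#'   `attr(, "truth")`.
#' @export
gen_fluorescence <- function(cmc_mM, A1 = 1.6, A2 = 1.2, dx_decades = 0.1,
                             c_grid = 10^seq(log10(cmc_mM) - 2,
                                             log10(cmc_mM) + 1,
                                             length.out = 30),
                             noise_sd = 0.01, seed = 1L) {
  if (A1 <= A2)
    .stop_ampchem("A1 must exceed A2 (polarity drops inside micelles)",
                  "ampchem_invalid_parameter")
  x <- log10(c_grid)
  y <- A2 + (A1 - A2) / (1 + exp((x - log10(cmc_mM)) / dx_decades))
  noisy <- withr::with_seed(seed, y + rnorm(length(y), 0, noise_sd))
  out <- concentration_series(c_grid, noisy, kind = "fluorescence")
  attr(out, "truth") <- list(cmc = cmc_mM, A1 = A1, A2 = A2,
                             dx_decades = dx_decades, noise_sd = noise_sd,
                             seed = seed)
  out
}

#' Synthetic potentiometric titration
#'
#' Exact charge-balance titration curve (see [simulate_titration()]) under
#' the standard conditions (30 umol analyte in 15 mL, 20 mM NaOH) plus
#' additive Gaussian pH noise.
#'
#' @inheritParams simulate_titration
#' @param n_points Number of volume points, spanning 0 to
#'   `2 * v_equiv`.
#' @param pH_noise_sd Additive pH noise (0.02 mirrors a glass electrode).
#' @param seed Integer seed.
#' @return A [titration_curve()] with truth (including the stoichiometric
#'   `v_equiv = acid_umol / titrant_mM`) in `attr(, "truth")`.
#' @export
gen_titration <- function(pKa, acid_umol = 30, V0_mL = 15, titrant_mM = 20,
                          n_points = 200L, pH_noise_sd = 0.02, seed = 1L,
                          direction = "forward_NaOH") {
  v_eq <- acid_umol / titrant_mM
  volumes <- seq(0, 2 * v_eq, length.out = n_points)
  curve <- simulate_titration(acid_umol, V0_mL, pKa, titrant_mM, volumes,
                              direction = direction)
  if (pH_noise_sd > 0) {
    noisy <- withr::with_seed(seed,
      curve$pH + rnorm(n_points, 0, pH_noise_sd))
    noisy <- pmin(pmax(noisy, 1e-6), 14 - 1e-6)
    curve <- titration_curve(volumes, noisy, direction = curve$direction,
                             meta = curve$meta)
  }
  attr(curve, "truth") <- list(pKa = pKa, acid_umol = acid_umol,
                               V0_mL = V0_mL, titrant_mM = titrant_mM,
                               v_equiv = v_eq, pH_noise_sd = pH_noise_sd,
                               seed = seed)
  curve
}

#' Synthetic serial-dilution activity table
#'
#' Reported MICs are the true endpoints snapped upward onto the two-fold
#' dilution grid; endpoints above the grid top are censored.
#'
#' @param compounds,strains Label vectors; records are generated for every
#'   combination.
#' @param true_mic_uM Matrix (compounds x strains) or single value of true
#'   endpoints \[uM\].
#' @param dilution_grid Descending two-fold grid \[uM\].
#' @param mbc_factor MBC is reported as the snapped `mbc_factor *` true
#'   endpoint (1 or 2 reproduce bactericidal behaviour).
#' @param seed Integer seed (kept for interface uniformity; snapping is
#'   deterministic).
#' @return List of [activity_record()]s with truth in `attr(, "truth")`.
#' @export
gen_activity_table <- function(compounds, strains, true_mic_uM,
                               dilution_grid = c(500, 250, 125, 62, 31, 16,
                                                 8, 4, 2),
                               mbc_factor = 2, seed = 1L) {
  true_mic_uM <- matrix(true_mic_uM, nrow = length(compounds),
                        ncol = length(strains))
  records <- list()
  for (i in seq_along(compounds)) {
    for (j in seq_along(strains)) {
      mic <- snap_to_dilution(true_mic_uM[i, j], dilution_grid)
      mbc <- snap_to_dilution(true_mic_uM[i, j] * mbc_factor, dilution_grid)
      records[[length(records) + 1L]] <-
        activity_record(compounds[i], strains[j], "positive",
                        mic = mic, mbc = mbc)
    }
  }
  attr(records, "truth") <- list(true_mic_uM = true_mic_uM,
                                 dilution_grid = dilution_grid,
                                 mbc_factor = mbc_factor, seed = seed)
  records
}
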