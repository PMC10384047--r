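# Replay batteries: generate synthetic data at the published parameter
# values and score the estimators on recovering them. These are the
# package's standard self-validation experiments; tests and the acceptance
# script both run them.

#' Micelle-fit recovery battery
#'
#' For each seed, generates a core-shell cylinder SAXS curve at the
#' published parameters of `compound` (2% multiplicative noise by default),
#' perturbs the free parameters (core radius, shell thickness, length,
#' headgroup density) by up to +/- `perturb` relative, and refits with the
#' hydrophobic density fixed. The fit uses physically motivated box bounds -
#' the cylinder length within the window the q range can resolve, the
#' hydrated headgroup denser than water - and the early-stopping multistart
#' of [fit_curve()].
#'
#' @param compound Compound name from [ref_micelle_fits()].
#' @param seeds Integer vector of noise seeds; the start perturbation for
#'   seed `s` is drawn under seed `1000 + s` (a stream distinct from the
#'   noise).
#' @param noise_frac Relative noise of the generated curves.
#' @param perturb Relative start perturbation.
#' @param q_grid Scattering vectors of the generated curves \[nm^-1\].
#' @return Data frame with one row per seed: `seed`, the refitted `Rc`,
#'   `Rh`, `Lc`, `rho_h`, their 95% half-widths (`*_ci`), and `chi2_red`.
#'   The generating truth is attached as `attr(, "truth")`.
#' @export
replay_micelle_fit <- function(compound = "C12TC3NH3Cl", seeds = 1:10,
                               noise_frac = 0.02, perturb = 0.2,
                               q_grid = seq(0.2, 6, length.out = 200)) {
  tr <- ref_micelle_truth(compound)
  truth <- unlist(tr$model[c("Rc", "Rh", "Lc", "rho_c", "rho_h",
                             "rho_solv", "phi", "bkg")])
  freep <- c("Rc", "Rh", "Lc", "rho_h")
  rows <- lapply(seeds, function(s) {
    curve <- gen_saxs(tr$model, q_grid = q_grid, noise_frac = noise_frac,
                      seed = s)
    start <- truth
    pert <- withr::with_seed(1000L + s,
                             runif(length(freep), -perturb, perturb))
    start[freep] <- start[freep] * (1 + pert)
    start["rho_h"] <- max(start[["rho_h"]], 345)
    pr <- fit_problem("cylinder", curve, start,
                      lower = c(Lc = 1, rho_h = 340),
                      upper = c(Lc = 60, rho_h = 500))
    f <- fit_curve(pr, n_starts = 16L, seed = s, stop_at_chi2 = 2)
    data.frame(seed = s, Rc = f$estimates[["Rc"]], Rh = f$estimates[["Rh"]],
               Lc = f$estimates[["Lc"]], rho_h = f$estimates[["rho_h"]],
               Rc_ci = f$ci95[["Rc"]], Rh_ci = f$ci95[["Rh"]],
               Lc_ci = f$ci95[["Lc"]], rho_h_ci = f$ci95[["rho_h"]],
               chi2_red = f$chi2_red, converged = f$converged)
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- as.list(truth)
  out
}

#' Bilayer-fit recovery battery
#'
#' Same protocol as [replay_micelle_fit()] for the Gaussian bilayer model:
#' curves are generated at the published parameters of one DPPC/surfactant
#' composition, the free parameters (headgroup position, widths, headgroup
#' amplitude, scale) are perturbed by up to +/- `perturb`, and the model is
#' refit. The central trough amplitude follows the default coupling
#' `drho_c = -drho_h` evaluated at the start.
#'
#' @param series Mixture series, see [ref_bilayer_fits()].
#' @param surfactant_pct Composition (mol% surfactant; 0 = pure DPPC).
#' @inheritParams replay_micelle_fit
#' @return Data frame with one row per seed: `seed`, `Zh`, `sigma_h`,
#'   `drho_h`, `sigma_c`, `Zh_ci`, `chi2_red`, `converged`; truth in
#'   `attr(, "truth")`.
#' @export
replay_bilayer_fit <- function(series = "C12TC3NH3Cl", surfactant_pct = 0,
                               seeds = 1:10, noise_frac = 0.02,
                               perturb = 0.2,
                               q_grid = seq(0.2, 6, length.out = 200)) {
  model <- ref_bilayer_truth(series, surfactant_pct)
  truth <- unlist(model[c("Zh", "sigma_h", "drho_h", "sigma_c", "drho_c",
                          "scale", "bkg")])
  freep <- c("Zh", "sigma_h", "drho_h", "sigma_c", "scale")
  rows <- lapply(seeds, function(s) {
    curve <- gen_saxs(model, q_grid = q_grid, noise_frac = noise_frac,
                      seed = s)
    start <- truth
    pert <- withr::with_seed(2000L + s,
                             runif(length(freep), -perturb, perturb))
    start[freep] <- start[freep] * (1 + pert)
    start["drho_c"] <- -start[["drho_h"]]
    pr <- fit_problem("bilayer", curve, start)
    f <- fit_curve(pr, n_starts = 8L, seed = s, stop_at_chi2 = 2)
    data.frame(seed = s, Zh = f$estimates[["Zh"]],
               sigma_h = f$estimates[["sigma_h"]],
               drho_h = f$estimates[["drho_h"]],
               sigma_c = f$estimates[["sigma_c"]],
               Zh_ci = f$ci95[["Zh"]], chi2_red = f$chi2_red,
               converged = f$converged)
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- as.list(truth)
  out
}

#' CMC recovery battery from synthetic conductivity scans
#'
#' Generates two-segment conductivity series at a given breakpoint and
#' slope ratio and scores [cmc_from_conductivity()] on recovering them.
#'
#' @param cmc_mM Generating breakpoint \[mM\].
#' @param slope_ratio Generating post/pre slope ratio (`1 - beta`).
#' @param slope_below Pre-break slope \[uS cm^-1 mM^-1\].
#' @param seeds Integer seeds.
#' @param noise_frac Relative noise.
#' @param n_points Points per series, spanning 0.2x to 2x the breakpoint.
#' @return Data frame with `seed`, `cmc`, `alpha`, `beta`.
#' @export
replay_cmc_conductivity <- function(cmc_mM, slope_ratio, slope_below = 80,
                                    seeds = 1:20, noise_frac = 0.005,
                                    n_points = 25L) {
  rows <- lapply(seeds, function(s) {
    ser <- gen_conductivity(cmc_mM, slope_below = slope_below,
                            slope_ratio = slope_ratio,
                            c_grid = seq(0.2, 2,
                                         length.out = n_points) * cmc_mM,
                            noise_frac = noise_frac, seed = s)
    r <- cmc_from_conductivity(ser, n_boot = 0L)
    data.frame(seed = s, cmc = r$cmc, alpha = r$alpha, beta = r$beta)
  })
  do.call(rbind, rows)
}

#' CMC recovery battery from synthetic fluorescence scans
#'
#' Generates pyrene I1/I3 sigmoids at a given midpoint and scores
#' [cmc_from_fluorescence()] on recovering it.
#'
#' @param cmc_mM Generating midpoint \[mM\].
#' @param c_grid Concentration grid \[mM\].
#' @param seeds Integer seeds.
#' @param noise_sd Additive noise standard deviation.
#' @param ... Passed to [gen_fluorescence()] (plateaus, width).
#' @return Data frame with `seed`, `cmc`.
#' @export
replay_cmc_fluorescence <- function(cmc_mM,
                                    c_grid = 10^seq(log10(0.03), log10(30),
                                                    length.out = 30),
                                    seeds = 1:20, noise_sd = 0.01, ...) {
  rows <- lapply(seeds, function(s) {
    ser <- gen_fluorescence(cmc_mM, c_grid = c_grid, noise_sd = noise_sd,
                            seed = s, ...)
    data.frame(seed = s, cmc = cmc_from_fluorescence(ser)$cmc)
  })
  do.call(rbind, rows)
}
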