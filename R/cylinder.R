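#' Core-shell cylinder micelle model
#'
#' Parameter set of the core-shell cylinder form factor used for the
#' wormlike/rodlike micelles of single-chain cationic surfactants: a
#' hydrocarbon core of radius `Rc` and length `Lc` wrapped in a hydrated
#' headgroup shell of uniform thickness `Rh` covering the lateral surface and
#' both end caps (total outer length `Lc + 2 Rh`).
#'
#' @param Rc Core radius \[nm\].
#' @param Rh Shell (hydrophilic) thickness \[nm\].
#' @param Lc Core cylinder length \[nm\].
#' @param rho_c Core electron density \[e/nm^3\]; for saturated chains this
#'   is fixed from Tanford volumes rather than fitted.
#' @param rho_h Shell electron density \[e/nm^3\].
#' @param rho_solv Solvent electron density \[e/nm^3\]; 334 for water.
#' @param phi Hydrocarbon volume fraction of the solution (dimensionless,
#'   `0 < phi < 0.05`).
#' @param bkg Flat background \[cm^-1\].
#' @return An object of class `core_shell_cylinder`.
#' @export
core_shell_cylinder <- function(Rc, Rh, Lc, rho_c, rho_h,
                                rho_solv = .rho_water, phi, bkg = 0) {
  m <- structure(list(Rc = Rc, Rh = Rh, Lc = Lc, rho_c = rho_c,
                      rho_h = rho_h, rho_solv = rho_solv, phi = phi,
                      bkg = bkg),
                 class = c("core_shell_cylinder", "saxs_model"))
  validate_model(m)
  m
}

#' Core-shell sphere micelle model
#'
#' Spherical analogue of [core_shell_cylinder()]: a hydrocarbon core of
#' radius `Rc` with a concentric shell of thickness `Rh`. Retained for
#' geometry plausibility selection; spheres systematically over-estimate the
#' headgroup region for these surfactants when forced onto absolute-scale
#' data.
#'
#' @inheritParams core_shell_cylinder
#' @return An object of class `core_shell_sphere`.
#' @export
core_shell_sphere <- function(Rc, Rh, rho_c, rho_h, rho_solv = .rho_water,
                              phi, bkg = 0) {
  m <- structure(list(Rc = Rc, Rh = Rh, rho_c = rho_c, rho_h = rho_h,
                      rho_solv = rho_solv, phi = phi, bkg = bkg),
                 class = c("core_shell_sphere", "saxs_model"))
  validate_model(m)
  m
}

#' Validate a SAXS model parameter set
#'
#' @param model A `saxs_model` object.
#' @return The model, invisibly; errors on invalid parameters.
#' @export
validate_model <- function(model) UseMethod("validate_model")

#' @export
validate_model.core_shell_cylinder <- function(model) {
  with(model, {
    if (!all(vapply(list(Rc, Rh, Lc, rho_c, rho_h, rho_solv, phi, bkg),
                    .is_number, logical(1))))
      .stop_ampchem("all cylinder parameters must be finite scalars",
                    "ampchem_invalid_model")
    if (Rc <= 0 || Rh <= 0 || Lc <= 0)
      .stop_ampchem("Rc, Rh, Lc must be > 0", "ampchem_invalid_model")
    if (rho_c <= 150 || rho_c >= 700 || rho_h <= 150 || rho_h >= 700)
      .stop_ampchem("electron densities must lie in (150, 700) e/nm^3",
                    "ampchem_invalid_model")
    if (phi <= 0 || phi >= 0.05)
      .stop_ampchem("phi must lie in (0, 0.05)", "ampchem_invalid_model")
  })
  invisible(model)
}

#' @export
validate_model.core_shell_sphere <- function(model) {
  with(model, {
    if (Rc <= 0 || Rh <= 0)
      .stop_ampchem("Rc, Rh must be > 0", "ampchem_invalid_model")
    if (rho_c <= 150 || rho_c >= 700 || rho_h <= 150 || rho_h >= 700)
      .stop_ampchem("electron densities must lie in (150, 700) e/nm^3",
                    "ampchem_invalid_model")
    if (phi <= 0 || phi >= 0.05)
      .stop_ampchem("phi must lie in (0, 0.05)", "ampchem_invalid_model")
  })
  invisible(model)
}

# sin(x)/x with the removable singularity handled by series; preserves dim
.sinc <- function(x) {
  out <- x
  big <- abs(x) > 1e-5
  out[big] <- sin(x[big]) / x[big]
  out[!big] <- 1 - x[!big]^2 / 6
  out
}

# 2 J1(x)/x with the removable singularity handled by series
.j1c <- function(x) {
  out <- x
  big <- abs(x) > 1e-5
  out[big] <- 2 * besselJ(x[big], 1) / x[big]
  out[!big] <- 1 - x[!big]^2 / 8
  out
}

# Single-orientation cylinder amplitude factor Lambda(q, R, L, alpha):
# sinc(q L cos(a) / 2) * 2 J1(q R sin(a)) / (q R sin(a)).
# q and alpha may be vectors; an outer product matrix is returned
# (rows = q, cols = alpha).
.cyl_lambda <- function(q, R, L, alpha) {
  ca <- cos(alpha); sa <- sin(alpha)
  .sinc(outer(q, ca) * (L / 2)) * .j1c(outer(q, sa) * R)
}

#' Forward intensity of a core-shell cylinder
#'
#' Orientation-averaged single-particle intensity
#' `I(q) = (phi / V_total) * P(q) + bkg` with
#' `P(q) = int_0^(pi/2) |A(q, a)|^2 sin(a) da` and amplitude
#' `A = (rho_c - rho_h) V_core L(q, Rc, Lc, a) + (rho_h - rho_solv) V_total
#' L(q, Rc + Rh, Lc + 2 Rh, a)`. The conversion from electron units to
#' absolute cm^-1 uses the Thomson scattering length. No structure factor is
#' applied (dilute regime, S(q) = 1).
#'
#' The orientation average uses fixed-order Gauss-Legendre quadrature; the
#' order grows with `q_max * (Lc + 2 Rh)` so that long cylinders (whose
#' integrand oscillates rapidly in `cos a`) stay below 1e-4 relative error.
#'
#' @param model A [core_shell_cylinder()].
#' @param q Scattering vector moduli \[nm^-1\], all > 0.
#' @param n_nodes Gauss-Legendre order; `NULL` (default) chooses
#'   automatically.
#' @return Intensity \[cm^-1\] at each `q`.
#' @export
cylinder_intensity <- function(model, q, n_nodes = NULL) {
  validate_model(model)
  if (any(!is.finite(q)) || any(q <= 0))
    .stop_ampchem("q must be finite and > 0", "ampchem_domain_error")
  .cyl_raw(model, q, n_nodes)
}

# Gauss-Legendre nodes on (0, pi/2) are reused across evaluations of the
# same order (the node computation is an eigendecomposition and would
# otherwise dominate fitting time).
.gl_cache <- new.env(parent = emptyenv())
.gl_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]]))
    .gl_cache[[key]] <- pracma::gaussLegendre(n, 1e-8, pi / 2 - 1e-8)
  .gl_cache[[key]]
}

# validation-free evaluator shared with the fitting engine
.cyl_raw <- function(p, q, n_nodes = NULL) {
  with(p, {
    Lt <- Lc + 2 * Rh
    Rt <- Rc + Rh
    if (is.null(n_nodes)) {
      # enough nodes to resolve the sinc oscillations of long cylinders,
      # quantized to limit cache churn and capped against runaway lengths
      n_nodes <- max(128L, ceiling(0.8 * max(q) * Lt) + 32L)
      n_nodes <- min(32L * ceiling(n_nodes / 32L), 1024L)
    }
    gl <- .gl_nodes(n_nodes)
    v_core <- pi * Rc^2 * Lc
    v_tot <- pi * Rt^2 * Lt
    amp <- (rho_c - rho_h) * v_core * .cyl_lambda(q, Rc, Lc, gl$x) +
      (rho_h - rho_solv) * v_tot * .cyl_lambda(q, Rt, Lt, gl$x)
    p_q <- as.vector(amp^2 %*% (gl$w * sin(gl$x)))
    (phi / v_tot) * p_q * .re2_nm3_to_cm + bkg
  })
}

# Sphere amplitude factor 3 (sin x - x cos x) / x^3
.sphc <- function(x) {
  out <- x
  big <- abs(x) > 1e-4
  xb <- x[big]
  out[big] <- 3 * (sin(xb) - xb * cos(xb)) / xb^3
  out[!big] <- 1 - x[!big]^2 / 10
  out
}

#' Forward intensity of a core-shell sphere
#'
#' `I(q) = (phi / V_total) * F(q)^2 + bkg` with the standard two-shell
#' amplitude `F = (rho_c - rho_h) V_c Phi(q Rc) + (rho_h - rho_solv) V_t
#' Phi(q (Rc + Rh))`, `Phi(x) = 3 (sin x - x cos x) / x^3`. Same contrast
#' and absolute-unit conventions as [cylinder_intensity()].
#'
#' @param model A [core_shell_sphere()].
#' @inheritParams cylinder_intensity
#' @return Intensity \[cm^-1\] at each `q`.
#' @export
sphere_intensity <- function(model, q) {
  validate_model(model)
  if (any(!is.finite(q)) || any(q <= 0))
    .stop_ampchem("q must be finite and > 0", "ampchem_domain_error")
  .sph_raw(model, q)
}

.sph_raw <- function(p, q) {
  with(p, {
    Rt <- Rc + Rh
    v_c <- 4 / 3 * pi * Rc^3
    v_t <- 4 / 3 * pi * Rt^3
    f <- (rho_c - rho_h) * v_c * .sphc(q * Rc) +
      (rho_h - rho_solv) * v_t * .sphc(q * Rt)
    (phi / v_t) * f^2 * .re2_nm3_to_cm + bkg
  })
}

#' Derived micellar quantities from a fitted geometry
#'
#' Converts a fitted core-shell geometry plus the chemical specification of
#' the surfactant into aggregation number, area per molecule at the
#' hydrophilic/hydrophobic interface, headgroup hydration and the volumetric
#' headgroup electron density:
#' \itemize{
#'   \item `N_agg = V_core / v_chain` (Tanford chain volume),
#'   \item `A_m = (lateral core area) / N_agg`,
#'   \item `N_H2O = (V_shell / N_agg - v_head) / v_water` with the shell
#'     volume taken over the lateral surface only,
#'   \item `rho_h_volumetric = (head electrons + 10 N_H2O) /
#'     (v_head + N_H2O v_water)`.
#' }
#'
#' @param model A fitted `core_shell_cylinder` or `core_shell_sphere`.
#' @param spec A [surfactant_spec()].
#' @return A list of class `micelle_derived` with elements `N_agg`, `A_m`
#'   \[nm^2\], `N_H2O` and `rho_h_volumetric` \[e/nm^3\].
#' @export
derive_micelle_params <- function(model, spec) UseMethod("derive_micelle_params")

.micelle_derived <- function(N_agg, A_m, N_H2O, rho_h_vol) {
  if (N_H2O < 0) {
    .warn_ampchem("head volume exceeds shell allocation; N_H2O clamped to 0",
                  "ampchem_negative_hydration")
    N_H2O <- 0
  }
  structure(list(N_agg = N_agg, A_m = A_m, N_H2O = N_H2O,
                 rho_h_volumetric = rho_h_vol),
            class = "micelle_derived")
}

#' @export
derive_micelle_params.core_shell_cylinder <- function(model, spec) {
  stopifnot(inherits(spec, "surfactant_spec"))
  v_chain <- tanford_chain_volume(spec$n_formula_carbons)
  with(model, {
    if (Lc <= 1e-12)
      .stop_ampchem("degenerate cylinder: Lc ~ 0", "ampchem_division_guard")
    v_core <- pi * Rc^2 * Lc
    n_agg <- v_core / v_chain
    a_m <- 2 * pi * Rc * Lc / n_agg
    v_shell <- pi * ((Rc + Rh)^2 - Rc^2) * Lc
    n_h2o <- (v_shell / n_agg - spec$head_dry_volume) / .v_water
    rho_vol <- (spec$head_electrons + .e_water * max(n_h2o, 0)) /
      (spec$head_dry_volume + max(n_h2o, 0) * .v_water)
    .micelle_derived(n_agg, a_m, n_h2o, rho_vol)
  })
}

#' @export
derive_micelle_params.core_shell_sphere <- function(model, spec) {
  stopifnot(inherits(spec, "surfactant_spec"))
  v_chain <- tanford_chain_volume(spec$n_formula_carbons)
  with(model, {
    v_core <- 4 / 3 * pi * Rc^3
    n_agg <- v_core / v_chain
    a_m <- 4 * pi * Rc^2 / n_agg
    v_shell <- 4 / 3 * pi * ((Rc + Rh)^3 - Rc^3)
    n_h2o <- (v_shell / n_agg - spec$head_dry_volume) / .v_water
    rho_vol <- (spec$head_electrons + .e_water * max(n_h2o, 0)) /
      (spec$head_dry_volume + max(n_h2o, 0) * .v_water)
    .micelle_derived(n_agg, a_m, n_h2o, rho_vol)
  })
}
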