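#' Symmetric Gaussian bilayer model
#'
#' Electron-density contrast profile of a symmetric lipid bilayer described
#' by three Gaussians: two positive headgroup Gaussians centred at `+/- Zh`
#' (width `sigma_h`, amplitude `drho_h`) and one negative central Gaussian at
#' the midplane (width `sigma_c`, amplitude `drho_c <= 0`) for the terminal
#' methyl trough:
#' `drho(z) = drho_h * [g(z; Zh, sigma_h) + g(z; -Zh, sigma_h)] +
#' drho_c * g(z; 0, sigma_c)` with unnormalized Gaussians
#' `g(z; Z, s) = exp(-(z - Z)^2 / (2 s^2))`.
#'
#' @param Zh Headgroup Gaussian centre distance from the midplane \[nm\].
#' @param sigma_h Headgroup Gaussian width \[nm\]; must satisfy
#'   `sigma_h < Zh` (heads outside the midplane).
#' @param drho_h Headgroup contrast amplitude \[e/nm^3\], > 0.
#' @param sigma_c Central (chain trough) Gaussian width \[nm\].
#' @param drho_c Central contrast amplitude \[e/nm^3\], <= 0. Defaults to
#'   `-drho_h`: scattering curves constrain the trough amplitude only weakly,
#'   so by default it is coupled to the headgroup amplitude; the coupling is
#'   recorded in fit metadata when used.
#' @param scale Overall scale factor absorbing sheet number density and unit
#'   conversion \[cm^-1 nm^2-equivalent\].
#' @param bkg Flat background \[cm^-1\].
#' @return An object of class `gaussian_bilayer`.
#' @export
gaussian_bilayer <- function(Zh, sigma_h, drho_h, sigma_c, drho_c = -drho_h,
                             scale = 1, bkg = 0) {
  m <- structure(list(Zh = Zh, sigma_h = sigma_h, drho_h = drho_h,
                      sigma_c = sigma_c, drho_c = drho_c, scale = scale,
                      bkg = bkg),
                 class = c("gaussian_bilayer", "saxs_model"))
  validate_model(m)
  m
}

#' @export
validate_model.gaussian_bilayer <- function(model) {
  with(model, {
    if (!all(vapply(list(Zh, sigma_h, drho_h, sigma_c, drho_c, scale, bkg),
                    .is_number, logical(1))))
      .stop_ampchem("all bilayer parameters must be finite scalars",
                    "ampchem_invalid_model")
    if (Zh <= 0 || sigma_h <= 0 || sigma_c <= 0)
      .stop_ampchem("Zh, sigma_h, sigma_c must be > 0",
                    "ampchem_invalid_model")
    if (drho_h < 0)
      .stop_ampchem("drho_h must be >= 0", "ampchem_invalid_model")
    if (drho_c > 0)
      .stop_ampchem("drho_c must be <= 0 (methyl trough)",
                    "ampchem_invalid_model")
    if (sigma_h >= Zh)
      .stop_ampchem("sigma_h must be < Zh (heads outside midplane)",
                    "ampchem_invalid_model")
  })
  invisible(model)
}

#' Forward intensity of a Gaussian bilayer
#'
#' The scattering amplitude is the cosine transform of the symmetric contrast
#' profile,
#' `F(q) = sqrt(2 pi) * [2 sigma_h drho_h cos(q Zh) exp(-sigma_h^2 q^2 / 2) +
#' sigma_c drho_c exp(-sigma_c^2 q^2 / 2)]`,
#' and the intensity of randomly oriented flat unilamellar sheets carries the
#' Lorentz factor `1/q^2`:
#' `I(q) = scale * F(q)^2 / q^2 + bkg`.
#'
#' @param model A [gaussian_bilayer()].
#' @param q Scattering vector moduli \[nm^-1\], all > 0.
#' @return Intensity \[cm^-1\] at each `q`.
#' @export
bilayer_intensity <- function(model, q) {
  validate_model(model)
  if (any(!is.finite(q)) || any(q <= 0))
    .stop_ampchem("q must be finite and > 0", "ampchem_domain_error")
  .bil_raw(model, q)
}

.bil_raw <- function(p, q) {
  with(p, {
    f <- sqrt(2 * pi) *
      (2 * sigma_h * drho_h * cos(q * Zh) * exp(-sigma_h^2 * q^2 / 2) +
         sigma_c * drho_c * exp(-sigma_c^2 * q^2 / 2))
    scale * f^2 / q^2 + bkg
  })
}

#' Electron-density contrast profile of a Gaussian bilayer
#'
#' Evaluates the three-Gaussian contrast profile `drho(z)` across the
#' bilayer; an even function of the distance `z` from the midplane.
#'
#' @param model A [gaussian_bilayer()].
#' @param z Distances from the bilayer midplane \[nm\].
#' @return Contrast \[e/nm^3\] at each `z`.
#' @export
electron_density_profile <- function(model, z) {
  validate_model(model)
  with(model, {
    drho_h * (exp(-(z - Zh)^2 / (2 * sigma_h^2)) +
                exp(-(z + Zh)^2 / (2 * sigma_h^2))) +
      drho_c * exp(-z^2 / (2 * sigma_c^2))
  })
}
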