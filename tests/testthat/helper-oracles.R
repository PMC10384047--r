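# Independent brute-force oracles for the forward models. These share no
# code with the package evaluators: the cylinder oracle is a trapezoid
# orientation average on a dense alpha grid, the bilayer oracle a numerical
# cosine transform of the real-space profile.

cyl_oracle <- function(m, q, n = 1e5) {
  a <- seq(1e-9, pi / 2 - 1e-9, length.out = n)
  Lt <- m$Lc + 2 * m$Rh
  Rt <- m$Rc + m$Rh
  vc <- pi * m$Rc^2 * m$Lc
  vt <- pi * Rt^2 * Lt
  re2 <- (2.8179403262e-13)^2 * 1e21
  sinc <- function(x) ifelse(abs(x) < 1e-8, 1, sin(x) / x)
  j1c <- function(x) ifelse(abs(x) < 1e-8, 1, 2 * besselJ(x, 1) / x)
  vapply(q, function(qq) {
    A <- (m$rho_c - m$rho_h) * vc *
      sinc(qq * cos(a) * m$Lc / 2) * j1c(qq * sin(a) * m$Rc) +
      (m$rho_h - m$rho_solv) * vt *
        sinc(qq * cos(a) * Lt / 2) * j1c(qq * sin(a) * Rt)
    p <- pracma::trapz(a, A^2 * sin(a))
    (m$phi / vt) * p * re2 + m$bkg
  }, numeric(1))
}

bil_oracle <- function(m, q) {
  vapply(q, function(qq) {
    f <- integrate(function(z) electron_density_profile(m, z) * cos(qq * z),
                   -Inf, Inf, rel.tol = 1e-11)$value
    m$scale * f^2 / qq^2 + m$bkg
  }, numeric(1))
}

# a plain scattering curve for container-level tests
flat_curve <- function(n = 10, level = 1, sigma = NULL) {
  scattering_curve(seq(0.2, 2, length.out = n), rep(level, n), sigma = sigma)
}
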