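#' Scattering curve container
#'
#' A `scattering_curve` holds a one-dimensional small-angle scattering trace:
#' the scattering-vector moduli `q` (nm^-1), the scattered intensities
#' (cm^-1 once absolutely scaled, arbitrary units otherwise) and, optionally,
#' per-point uncertainties.
#'
#' @param q Numeric vector of scattering-vector moduli \[nm^-1\], strictly
#'   increasing and positive.
#' @param intensity Numeric vector of intensities, same length as `q`.
#' @param sigma Optional numeric vector of per-point standard uncertainties,
#'   strictly positive where present.
#' @param meta Named list of free-form metadata (temperature, exposure,
#'   scaling state, ...).
#' @return An object of class `scattering_curve`: a list with elements `q`,
#'   `intensity`, `sigma` (possibly `NULL`) and `meta`.
#' @examples
#' sc <- scattering_curve(q = seq(0.2, 6, length.out = 50),
#'                        intensity = rep(1, 50))
#' @export
scattering_curve <- function(q, intensity, sigma = NULL, meta = list()) {
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  if (length(q) < 5L)
    .stop_ampchem("a scattering curve needs at least 5 points",
                  "ampchem_invalid_curve")
  if (length(intensity) != length(q))
    .stop_ampchem("q and intensity must have equal length",
                  "ampchem_invalid_curve")
  if (any(!is.finite(q)) || any(q <= 0))
    .stop_ampchem("all q must be finite and > 0", "ampchem_invalid_curve")
  if (any(diff(q) <= 0))
    .stop_ampchem("q must be strictly increasing", "ampchem_invalid_curve")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q))
      .stop_ampchem("sigma must match q in length", "ampchem_invalid_curve")
    if (any(!is.finite(sigma)) || any(sigma <= 0))
      .stop_ampchem("sigma must be finite and > 0 wherever present",
                    "ampchem_invalid_curve")
  }
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 meta = as.list(meta)),
            class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("<scattering_curve: %d points, q in [%.4g, %.4g] nm^-1%s%s>\n",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) ", no sigma" else ", with sigma",
              if (identical(x$meta$scale, "absolute"))
                ", absolute units" else ""))
  invisible(x)
}

#' @export
as.data.frame.scattering_curve <- function(x, ...) {
  d <- data.frame(q = x$q, intensity = x$intensity)
  if (!is.null(x$sigma)) d$sigma <- x$sigma
  d
}

#' Scattering vector modulus from scattering angle
#'
#' Converts a scattering angle to the scattering-vector modulus
#' `q = (4 * pi / lambda) * sin(theta / 2)`.
#'
#' @param theta Scattering angle \[rad\], in `[0, pi)`.
#' @param wavelength X-ray wavelength \[nm\]; 0.1542 nm is the Cu K-alpha
#'   line used on laboratory sources.
#' @return Scattering vector modulus \[nm^-1\], same shape as `theta`.
#' @examples
#' q_from_angle(0.049105, 0.1542)
#' @export
q_from_angle <- function(theta, wavelength = 0.1542) {
  if (!.is_number(wavelength) || wavelength <= 0)
    .stop_ampchem("wavelength must be a positive number",
                  "ampchem_invalid_parameter")
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta >= pi))
    .stop_ampchem("theta must lie in [0, pi)", "ampchem_invalid_parameter")
  (4 * pi / wavelength) * sin(theta / 2)
}

#' Subtract a background curve
#'
#' Pointwise subtraction of a background (typically water) measurement from a
#' sample measurement. The two curves must share the same q grid; no
#' interpolation is attempted. Uncertainties, when present on both operands,
#' combine in quadrature.
#'
#' @param sample,background `scattering_curve` objects on identical q grids
#'   (relative tolerance 1e-9).
#' @return A `scattering_curve` with the difference intensities.
#' @export
subtract_background <- function(sample, background) {
  stopifnot(inherits(sample, "scattering_curve"),
            inherits(background, "scattering_curve"))
  if (length(sample$q) != length(background$q) ||
      any(abs(sample$q - background$q) >
          1e-9 * pmax(abs(sample$q), abs(background$q))))
    .stop_ampchem("sample and background q grids differ; resample upstream",
                  "ampchem_grid_mismatch")
  s_abs <- identical(sample$meta$scale, "absolute")
  b_abs <- identical(background$meta$scale, "absolute")
  if (s_abs != b_abs)
    .stop_ampchem("cannot mix absolutely scaled and unscaled curves",
                  "ampchem_grid_mismatch")
  sigma <- NULL
  if (!is.null(sample$sigma) && !is.null(background$sigma))
    sigma <- sqrt(sample$sigma^2 + background$sigma^2)
  else if (!is.null(sample$sigma))
    sigma <- sample$sigma
  meta <- sample$meta
  meta$background_subtracted <- TRUE
  out <- sample
  out$intensity <- sample$intensity - background$intensity
  out$sigma <- sigma
  out$meta <- meta
  out
}

#' Scale a curve to absolute intensity
#'
#' Calibrates intensities to absolute units (cm^-1) by comparison with the
#' flat scattering level of pure water, whose differential cross section at
#' 25 degC is known. The multiplier is `water_xs / water_level`. Scaling an
#' already-absolute curve is an error (the operation is not idempotent by
#' design).
#'
#' @param curve A `scattering_curve`.
#' @param water_level Measured flat water intensity in the same arbitrary
#'   units as `curve`; must be > 0.
#' @param water_xs Absolute water cross section \[cm^-1\]. The default
#'   0.01632 cm^-1 is the standard literature value at 25 degC; it is an
#'   assumption recorded in the output metadata.
#' @return The calibrated `scattering_curve` with `meta$scale = "absolute"`.
#' @export
scale_to_absolute <- function(curve, water_level, water_xs = 0.01632) {
  stopifnot(inherits(curve, "scattering_curve"))
  if (!.is_number(water_level) || water_level <= 0)
    .stop_ampchem("water_level must be a positive number",
                  "ampchem_invalid_calibration")
  if (!.is_number(water_xs) || water_xs <= 0)
    .stop_ampchem("water_xs must be a positive number",
                  "ampchem_invalid_calibration")
  if (identical(curve$meta$scale, "absolute"))
    .stop_ampchem("curve is already on the absolute scale",
                  "ampchem_invalid_calibration")
  mult <- water_xs / water_level
  out <- curve
  out$intensity <- curve$intensity * mult
  if (!is.null(curve$sigma)) out$sigma <- curve$sigma * mult
  out$meta$scale <- "absolute"
  out$meta$water_xs <- water_xs
  out$meta$water_xs_assumed <- missing(water_xs)
  out
}

#' Read and write scattering curves as plain text
#'
#' Curves are stored as 2- or 3-column whitespace- or comma-delimited text
#' (`q`, `intensity`\[, `sigma`\]) with `#`-prefixed comment lines; comment
#' lines of the form `# key: value` are parsed into metadata. `dialect`
#' selects the q unit of the file: `"nm"` (nm^-1, the internal unit) or
#' `"angstrom"` (A^-1, multiplied by 10 on input, divided by 10 on output).
#'
#' @param path File path.
#' @param dialect `"nm"` or `"angstrom"`.
#' @return `read_curve` returns a `scattering_curve`; `write_curve` invisibly
#'   returns `path`.
#' @export
read_curve <- function(path, dialect = c("nm", "angstrom")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  meta <- list()
  is_comment <- grepl("^\\s*#", lines)
  for (cl in lines[is_comment]) {
    m <- regmatches(cl, regexec("^\\s*#\\s*([^:]+?)\\s*:\\s*(.*\\S)\\s*$", cl))[[1]]
    if (length(m) == 3L) {
      val <- suppressWarnings(as.numeric(m[3]))
      meta[[m[2]]] <- if (is.na(val)) m[3] else val
    }
  }
  body <- lines[!is_comment & nzchar(trimws(lines))]
  if (length(body) == 0L)
    .stop_ampchem("no data rows found", "ampchem_parse_error")
  rows <- strsplit(trimws(body), "[,[:space:]]+")
  ncol <- unique(lengths(rows))
  if (length(ncol) != 1L || !(ncol %in% c(2L, 3L)))
    .stop_ampchem("expected 2 or 3 numeric columns on every row",
                  "ampchem_parse_error")
  mat <- suppressWarnings(
    matrix(as.numeric(unlist(rows)), ncol = ncol, byrow = TRUE))
  bad <- which(apply(mat, 1L, function(r) any(is.na(r))))
  if (length(bad))
    .stop_ampchem(sprintf("non-numeric value in data row %d", bad[1]),
                  "ampchem_parse_error")
  q <- mat[, 1]
  if (dialect == "angstrom") q <- q * 10
  if (any(diff(q) <= 0))
    .stop_ampchem("q column is not strictly increasing",
                  "ampchem_parse_error")
  scattering_curve(q, mat[, 2],
                   sigma = if (ncol == 3L) mat[, 3] else NULL,
                   meta = meta)
}

#' @rdname read_curve
#' @param curve A `scattering_curve` to write.
#' @export
write_curve <- function(curve, path, dialect = c("nm", "angstrom")) {
  stopifnot(inherits(curve, "scattering_curve"))
  dialect <- match.arg(dialect)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(curve$meta)) {
    v <- curve$meta[[k]]
    if (is.numeric(v)) v <- format(v, digits = 17)
    writeLines(sprintf("# %s: %s", k, paste(v, collapse = " ")), con)
  }
  q <- if (dialect == "angstrom") curve$q / 10 else curve$q
  cols <- list(format(q, digits = 17),
               format(curve$intensity, digits = 17))
  if (!is.null(curve$sigma)) cols <- c(cols, list(format(curve$sigma, digits = 17)))
  writeLines(do.call(paste, cols), con)
  invisible(path)
}
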