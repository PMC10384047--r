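#' Concentration-response series
#'
#' Container for conductivity (kappa vs c) or pyrene I1/I3 fluorescence
#' (ratio vs c) titration-free concentration scans used for CMC
#' determination.
#'
#' @param concentration Concentrations \[mM\], strictly positive, sorted
#'   ascending within each replicate.
#' @param response Conductivity \[uS/cm\] or I1/I3 ratio (dimensionless).
#' @param kind `"conductivity"` or `"fluorescence"`.
#' @param replicate_id Optional integer replicate labels per point.
#' @return An object of class `concentration_series`.
#' @export
concentration_series <- function(concentration, response,
                                 kind = c("conductivity", "fluorescence"),
                                 replicate_id = NULL) {
  kind <- match.arg(kind)
  concentration <- as.numeric(concentration)
  response <- as.numeric(response)
  if (length(concentration) < 8L || length(response) != length(concentration))
    .stop_ampchem("need >= 8 points with equal-length arrays",
                  "ampchem_invalid_series")
  if (any(!is.finite(concentration)) || any(concentration <= 0))
    .stop_ampchem("concentrations must be finite and > 0",
                  "ampchem_invalid_series")
  if (is.null(replicate_id)) replicate_id <- rep(1L, length(concentration))
  for (r in unique(replicate_id)) {
    if (is.unsorted(concentration[replicate_id == r], strictly = FALSE))
      .stop_ampchem("concentrations must be ascending within replicate",
                    "ampchem_invalid_series")
  }
  structure(list(concentration = concentration, response = response,
                 kind = kind, replicate_id = as.integer(replicate_id)),
            class = "concentration_series")
}

.cmc_result <- function(cmc, cmc_ci, method, slope_below = NA_real_,
                        slope_above = NA_real_, fit_quality = NA_real_,
                        extra = list()) {
  alpha <- if (is.na(slope_below)) NA_real_ else slope_above / slope_below
  res <- list(cmc = cmc, cmc_ci = cmc_ci, method = method,
              slope_below = slope_below, slope_above = slope_above,
              alpha = alpha,
              beta = if (is.na(alpha)) NA_real_ else 1 - alpha,
              fit_quality = fit_quality)
  structure(c(res, extra), class = "cmc_result")
}

#' @export
print.cmc_result <- function(x, ...) {
  cat(sprintf("<cmc_result [%s]: CMC = %.4g mM (ci %.2g)%s>\n",
              x$method, x$cmc, x$cmc_ci,
              if (!is.na(x$beta))
                sprintf(", alpha = %.3f, beta = %.3f", x$alpha, x$beta)
              else ""))
  invisible(x)
}

# fast simple-regression line: intercept, slope, SSE, slope SE, R^2
.line_fit <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  m <- sum((x - mx) * (y - my)) / sxx
  a <- my - m * mx
  r <- y - a - m * x
  sse <- sum(r^2)
  se <- if (n > 2L) sqrt(sse / (n - 2L) / sxx) else 0
  syy <- sum((y - my)^2)
  r2 <- if (syy > 0) 1 - sse / syy else 1
  list(a = a, m = m, sse = sse, se = se, r2 = r2)
}

.conductivity_breakpoint <- function(c_, k_, exclude_k = 0L) {
  n <- length(c_)
  cand <- seq.int(4L, n - 4L)
  if (length(cand) == 0L)
    .stop_ampchem("too few points for a two-segment fit",
                  "ampchem_invalid_series")
  best <- NULL
  for (i in cand) {
    if (i - exclude_k < 2L || i + 2L + exclude_k > n) next
    lo <- .line_fit(c_[seq_len(i - exclude_k)], k_[seq_len(i - exclude_k)])
    hi <- .line_fit(c_[seq.int(i + 1L + exclude_k, n)],
                    k_[seq.int(i + 1L + exclude_k, n)])
    sse <- lo$sse + hi$sse
    if (is.null(best) || sse < best$sse)
      best <- list(lo = lo, hi = hi, i = i, sse = sse)
  }
  if (is.null(best))
    .stop_ampchem("no admissible split after exclusion",
                  "ampchem_invalid_series")
  b <- list(a1 = best$lo$a, m1 = best$lo$m,
            a2 = best$hi$a, m2 = best$hi$m,
            se1 = best$lo$se, se2 = best$hi$se,
            r2_lo = best$lo$r2, r2_hi = best$hi$r2,
            i = best$i)
  b$cmc <- (b$a2 - b$a1) / (b$m1 - b$m2)
  b
}

#' CMC from a conductivity scan
#'
#' Below the CMC every added molecule is a free ion pair; above it micelles
#' with bound counterions conduct less per monomer, so the conductivity vs
#' concentration plot consists of two straight lines intersecting at the
#' CMC. The breakpoint is found by minimizing the total SSE of two
#' independent least-squares lines over all admissible split indices (at
#' least 4 points per side); the reported CMC is the abscissa of the
#' intersection of the two lines. The degree of ionization `alpha` is the
#' slope ratio above/below, and the counterion binding is `beta = 1 - alpha`
#' exactly.
#'
#' @param series A conductivity [concentration_series()]. Replicates are
#'   pooled for the segment fits.
#' @param exclude_k Number of points to drop on each side of the candidate
#'   break (absorbs rounding of the transition); default 0.
#' @param n_boot Residual-bootstrap resamples for the CMC confidence
#'   half-width (0 disables; `cmc_ci` is then `NA`).
#' @param seed Seed for the bootstrap.
#' @return A `cmc_result` with `cmc` \[mM\], `cmc_ci` (95% half-width),
#'   slopes, `alpha`, `beta` and per-segment R-squared.
#' @export
cmc_from_conductivity <- function(series, exclude_k = 0L, n_boot = 500L,
                                  seed = 1L) {
  stopifnot(inherits(series, "concentration_series"))
  if (series$kind != "conductivity")
    .stop_ampchem("series kind must be conductivity",
                  "ampchem_invalid_series")
  ord <- order(series$concentration)
  c_ <- series$concentration[ord]
  k_ <- series$response[ord]
  b <- .conductivity_breakpoint(c_, k_, exclude_k)
  if (abs(b$m1 - b$m2) <= 2 * sqrt(b$se1^2 + b$se2^2))
    .stop_ampchem("slopes above and below are indistinguishable: no breakpoint",
                  "ampchem_no_breakpoint")
  if (b$cmc <= 0)
    .stop_ampchem("negative intersection: ill-posed breakpoint",
                  "ampchem_ill_posed")
  ci <- NA_real_
  if (n_boot > 0L) {
    fitted_piece <- ifelse(seq_along(c_) <= b$i,
                           b$a1 + b$m1 * c_, b$a2 + b$m2 * c_)
    resid <- k_ - fitted_piece
    boots <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(j) {
        kb <- fitted_piece + sample(resid, replace = TRUE)
        bb <- tryCatch(.conductivity_breakpoint(c_, kb, exclude_k),
                       error = function(e) NULL)
        if (is.null(bb)) NA_real_ else bb$cmc
      }, numeric(1))
    })
    ci <- qnorm(0.975) * sd(boots, na.rm = TRUE)
  }
  .cmc_result(unname(b$cmc), ci, "conductivity",
              slope_below = unname(b$m1), slope_above = unname(b$m2),
              fit_quality = c(r2_below = b$r2_lo, r2_above = b$r2_hi))
}

#' CMC from pyrene I1/I3 fluorescence
#'
#' The I1/I3 vibronic ratio of pyrene sits near 1.6 in water and drops as
#' the probe partitions into micelle cores. The series is fitted with a
#' Boltzmann sigmoid `y = A2 + (A1 - A2) / (1 + exp((x - x0) / dx))` with
#' `x = log10(concentration)` by default (the transition develops over
#' orders of magnitude in concentration); the CMC is the back-transformed
#' midpoint `10^x0`.
#'
#' @param series A fluorescence [concentration_series()].
#' @param log_axis Fit on `log10(c)` (default) or on linear concentration.
#' @return A `cmc_result` with `cmc` \[mM\], sigmoid parameters in
#'   `$sigmoid`, and the fit RMSE in `fit_quality`. Slopes/alpha/beta are
#'   `NA` for this method.
#' @export
cmc_from_fluorescence <- function(series, log_axis = TRUE) {
  stopifnot(inherits(series, "concentration_series"))
  if (series$kind != "fluorescence")
    .stop_ampchem("series kind must be fluorescence",
                  "ampchem_invalid_series")
  ord <- order(series$concentration)
  x <- if (log_axis) log10(series$concentration[ord])
       else series$concentration[ord]
  y <- series$response[ord]
  if (diff(range(y)) < 0.1)
    .stop_ampchem("response spans < 0.1: no transition to fit",
                  "ampchem_no_transition")
  n <- length(x)
  a1 <- mean(head(y, 3)); a2 <- mean(tail(y, 3))
  x0 <- x[which.min(abs(y - (a1 + a2) / 2))]
  dx <- diff(range(x)) / 10
  res_fn <- function(p) {
    y - (p[4] + (p[3] - p[4]) / (1 + exp((x - p[1]) / p[2])))
  }
  fit <- minpack.lm::nls.lm(par = c(x0 = x0, dx = dx, A1 = a1, A2 = a2),
                            fn = res_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500L))
  p <- fit$par
  # standard error of dx from the linearized covariance
  cov <- tryCatch(solve(fit$hessian) * fit$deviance / (n - 4L),
                  error = function(e) matrix(NA, 4, 4))
  se_dx <- sqrt(abs(cov[2, 2]))
  if (is.finite(se_dx) && abs(p[["dx"]]) < 2 * se_dx)
    .warn_ampchem("transition width consistent with 0: step-like change",
                  "ampchem_step_change")
  cov_x0 <- sqrt(abs(cov[1, 1]))
  cmc <- if (log_axis) 10^p[["x0"]] else p[["x0"]]
  ci <- if (log_axis && is.finite(cov_x0))
    cmc * log(10) * 1.96 * cov_x0 else 1.96 * cov_x0
  rmse <- sqrt(fit$deviance / n)
  .cmc_result(cmc, ci, "fluorescence", fit_quality = c(rmse = rmse),
              extra = list(sigmoid = as.list(p), log_axis = log_axis))
}
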