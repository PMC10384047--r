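# Family registry: full parameter set, which parameters are positive-only
# (fitted on the log scale so the Levenberg-Marquardt core stays
# unconstrained), the default free set, and the forward evaluator.
.fit_families <- list(
  cylinder = list(
    pars = c("Rc", "Rh", "Lc", "rho_c", "rho_h", "rho_solv", "phi", "bkg"),
    log  = c("Rc", "Rh", "Lc", "rho_c", "rho_h", "rho_solv", "phi"),
    free = c("Rc", "Rh", "Lc", "rho_h"),
    eval = function(p, q, ctx = NULL) .cyl_raw(p, q, n_nodes = ctx$n_nodes)
  ),
  sphere = list(
    pars = c("Rc", "Rh", "rho_c", "rho_h", "rho_solv", "phi", "bkg"),
    log  = c("Rc", "Rh", "rho_c", "rho_h", "rho_solv", "phi"),
    free = c("Rc", "Rh", "rho_h"),
    eval = function(p, q, ctx = NULL) .sph_raw(p, q)
  ),
  bilayer = list(
    pars = c("Zh", "sigma_h", "drho_h", "sigma_c", "drho_c", "scale", "bkg"),
    log  = c("Zh", "sigma_h", "drho_h", "sigma_c", "scale"),
    free = c("Zh", "sigma_h", "drho_h", "sigma_c", "scale"),
    eval = function(p, q, ctx = NULL) .bil_raw(p, q)
  )
)

#' Define a scattering-curve fitting problem
#'
#' Couples a scattering curve to a forward-model family, a full named start
#' vector, the set of free parameters and optional box bounds. Bounds are
#' enforced softly: positive-only parameters are fitted on the log scale, and
#' starts must lie inside any stated bounds.
#'
#' @param family `"cylinder"`, `"sphere"` or `"bilayer"`.
#' @param data A [scattering_curve()]. If it carries no `sigma`, unit weights
#'   are used and a warning is issued; the reduced chi-squared is then on an
#'   arbitrary scale.
#' @param start Named numeric vector covering every parameter of the family
#'   (see [core_shell_cylinder()], [core_shell_sphere()],
#'   [gaussian_bilayer()] for names and units).
#' @param free Character vector of parameter names to fit; the rest are held
#'   fixed at their start values. Defaults to the family's conventional free
#'   set (e.g. geometry plus headgroup density for micelles, with the
#'   hydrophobic density fixed from Tanford volumes).
#' @param lower,upper Optional named vectors of box bounds for a subset of
#'   parameters.
#' @return An object of class `fit_problem`.
#' @export
fit_problem <- function(family = c("cylinder", "sphere", "bilayer"),
                        data, start, free = NULL,
                        lower = NULL, upper = NULL) {
  family <- match.arg(family)
  fam <- .fit_families[[family]]
  stopifnot(inherits(data, "scattering_curve"))
  if (!all(fam$pars %in% names(start)))
    .stop_ampchem(sprintf("start must name all parameters: %s",
                          paste(fam$pars, collapse = ", ")),
                  "ampchem_invalid_parameter")
  start <- start[fam$pars]
  if (is.null(free)) free <- fam$free
  if (!all(free %in% fam$pars) || length(free) == 0L)
    .stop_ampchem("free must be a non-empty subset of the family parameters",
                  "ampchem_invalid_parameter")
  for (nm in names(lower))
    if (start[nm] < lower[nm])
      .stop_ampchem("start below lower bound", "ampchem_invalid_parameter")
  for (nm in names(upper))
    if (start[nm] > upper[nm])
      .stop_ampchem("start above upper bound", "ampchem_invalid_parameter")
  if (is.null(data$sigma))
    .warn_ampchem("data carry no sigma; using unit weights (chi2 unscaled)",
                  "ampchem_unit_weights")
  structure(list(family = family, data = data, start = start, free = free,
                 lower = lower, upper = upper),
            class = "fit_problem")
}

#' Weighted reduced chi-squared
#'
#' `sum(((I - m) / sigma)^2) / (N - n_free)`. With unit weights (no sigma)
#' the value is on an arbitrary scale.
#'
#' @param data A [scattering_curve()].
#' @param model_eval Model intensities on the data's q grid.
#' @param n_free Number of free parameters.
#' @return The reduced chi-squared.
#' @export
reduced_chi_squared <- function(data, model_eval, n_free) {
  stopifnot(inherits(data, "scattering_curve"))
  n <- length(data$q)
  if (n <= n_free)
    .stop_ampchem("need more points than free parameters",
                  "ampchem_degrees_of_freedom")
  w <- if (is.null(data$sigma)) rep(1, n) else data$sigma
  sum(((data$intensity - model_eval) / w)^2) / (n - n_free)
}

# Per-parameter transforms to the unconstrained LM scale:
#   both bounds        -> scaled logit
#   positive-only      -> log
#   otherwise          -> identity
# Built once per problem; each entry carries to/from/deriv (dp/dz for the
# delta-method back-transformation of standard errors).
.build_transforms <- function(parnames, lognames, lower, upper) {
  lapply(setNames(parnames, parnames), function(nm) {
    lo <- if (!is.null(lower) && nm %in% names(lower)) lower[[nm]] else NA
    hi <- if (!is.null(upper) && nm %in% names(upper)) upper[[nm]] else NA
    if (is.finite(lo) && is.finite(hi)) {
      list(to = function(p) stats::qlogis((p - lo) / (hi - lo)),
           from = function(z) lo + (hi - lo) * stats::plogis(z),
           deriv = function(z) (hi - lo) * stats::plogis(z) *
             (1 - stats::plogis(z)))
    } else if (nm %in% lognames) {
      lo2 <- if (is.finite(lo)) lo else 0
      list(to = function(p) log(p - lo2),
           from = function(z) lo2 + exp(z),
           deriv = function(z) exp(z))
    } else {
      list(to = identity, from = identity, deriv = function(z) 1)
    }
  })
}

.to_z <- function(p, tr) {
  vapply(names(p), function(nm) tr[[nm]]$to(p[[nm]]), numeric(1))
}
.from_z <- function(z, tr) {
  vapply(names(z), function(nm) tr[[nm]]$from(z[[nm]]), numeric(1))
}
.dp_dz <- function(z, tr) {
  vapply(names(z), function(nm) tr[[nm]]$deriv(z[[nm]]), numeric(1))
}

#' Fit a forward model to a scattering curve
#'
#' Weighted Levenberg-Marquardt least squares (via [minpack.lm::nls.lm()])
#' with positive-only parameters handled on the log scale. A seeded random
#' multi-start (default 8 starts, the first being the supplied one, the rest
#' perturbed by +/- `perturb` relative) guards against the cosine-induced
#' local minima of the bilayer model. 95% confidence half-widths come from
#' the covariance of the linearized problem at the optimum, scaled by the
#' reduced chi-squared (and mapped back from the log scale by the delta
#' method).
#'
#' @param problem A [fit_problem()].
#' @param n_starts Number of multi-starts (>= 1).
#' @param perturb Relative perturbation applied to free parameters for the
#'   extra starts.
#' @param max_iter Maximum LM iterations per start.
#' @param seed Integer seed for the start perturbations.
#' @param stop_at_chi2 Optional early-stop threshold: once a converged start
#'   reaches this reduced chi-squared, remaining starts are skipped. With
#'   correctly specified uncertainties a value around 2 accepts only fits of
#'   global-minimum quality; `NULL` (default) always runs all starts.
#' @return An object of class `fit_result`: list with `estimates` (full
#'   named parameter vector), `ci95` (half-widths, `NA` for fixed
#'   parameters), `chi2_red`, `n_iter`, `converged`, `family`, `free`,
#'   and `model` (the refitted forward model evaluated on the data grid).
#' @export
fit_curve <- function(problem, n_starts = 8L, perturb = 0.2,
                      max_iter = 200L, seed = 1L, stop_at_chi2 = NULL) {
  stopifnot(inherits(problem, "fit_problem"))
  fam <- .fit_families[[problem$family]]
  data <- problem$data
  w <- if (is.null(data$sigma)) rep(1, length(data$q)) else data$sigma
  free <- problem$free
  fixed <- problem$start[setdiff(fam$pars, free)]
  trans <- .build_transforms(free, fam$log, problem$lower, problem$upper)

  # the quadrature order is frozen from the start geometry (with headroom)
  # so a wandering optimizer cannot inflate the per-evaluation cost
  ctx <- NULL
  if (problem$family == "cylinder") {
    lt0 <- problem$start[["Lc"]] + 2 * problem$start[["Rh"]]
    n_nodes <- max(64L, ceiling(0.8 * max(data$q) * lt0) + 16L)
    ctx <- list(n_nodes = min(32L * ceiling(n_nodes / 32L), 1024L))
  }

  residual <- function(zfree) {
    p <- c(.from_z(zfree, trans), fixed)[fam$pars]
    m <- tryCatch(fam$eval(as.list(p), data$q, ctx), error = function(e) NULL)
    if (is.null(m) || any(!is.finite(m)))
      return(rep(1e10, length(data$q)))
    (data$intensity - m) / w
  }

  z0 <- .to_z(problem$start[free], trans)
  starts <- list(z0)
  if (n_starts > 1L) {
    extra <- withr::with_seed(seed, {
      lapply(seq_len(n_starts - 1L), function(i) {
        # perturbation magnitude ramps up across starts so later starts
        # explore beyond the basin of a stalled early one
        p_i <- perturb * (0.5 + i / (n_starts - 1L))
        u <- runif(length(z0), -p_i, p_i)
        p1 <- problem$start[free] * (1 + u)
        # perturb in parameter space, clamp inside any bounds, re-map
        for (nm in names(p1)) {
          if (nm %in% names(problem$lower)) {
            lo <- problem$lower[[nm]]
            p1[nm] <- max(p1[nm], lo + 0.01 * abs(lo))
          }
          if (nm %in% names(problem$upper)) {
            hi <- problem$upper[[nm]]
            p1[nm] <- min(p1[nm], hi - 0.01 * abs(hi))
          }
        }
        .to_z(p1, trans)
      })
    })
    starts <- c(starts, extra)
  }

  dof <- max(length(data$q) - length(free), 1L)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = residual,
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter, maxfev = 100000L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (!is.null(stop_at_chi2) && fit$info %in% 1:4 &&
        fit$deviance / dof <= stop_at_chi2) break
  }
  if (is.null(best))
    .stop_ampchem("all starts failed numerically", "ampchem_fit_failure")

  z_hat <- best$par
  p_free <- .from_z(z_hat, trans)
  estimates <- c(p_free, fixed)[fam$pars]
  n <- length(data$q)
  model_eval <- fam$eval(as.list(estimates), data$q, ctx)
  chi2 <- reduced_chi_squared(data, model_eval, length(free))

  hess <- best$hessian
  cov_z <- tryCatch(solve(hess), error = function(e) NULL)
  rank_def <- FALSE
  if (is.null(cov_z)) {
    rank_def <- TRUE
    sv <- svd(hess)
    pos <- sv$d > max(sv$d) * 1e-12
    dinv <- ifelse(pos, 1 / sv$d, 0)
    cov_z <- sv$v %*% (dinv * t(sv$u))
    .warn_ampchem("singular Jacobian; confidence intervals inflated",
                  "ampchem_rank_deficiency")
  }
  s2 <- max(chi2, .Machine$double.eps)
  sd_z <- sqrt(pmax(diag(cov_z), 0) * s2)
  sd_p <- sd_z * abs(.dp_dz(z_hat, trans))
  if (rank_def) sd_p[sd_p == 0] <- Inf
  ci95 <- setNames(rep(NA_real_, length(fam$pars)), fam$pars)
  ci95[free] <- 1.96 * sd_p

  structure(list(estimates = estimates, ci95 = ci95, chi2_red = chi2,
                 n_iter = best$niter,
                 converged = best$info %in% 1:4,
                 family = problem$family, free = free,
                 model = model_eval),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %s model, chi2_red = %.4g, %s after %d iterations>\n",
              x$family, x$chi2_red,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  est <- data.frame(estimate = x$estimates, ci95 = x$ci95)
  est$status <- ifelse(rownames(est) %in% x$free, "free", "fixed")
  print(est)
  invisible(x)
}

#' Choose between cylinder and sphere micelle geometry
#'
#' Fits both core-shell cylinder and core-shell sphere models to
#' absolute-scale data and rejects geometries whose implied headgroup region
#' is physically implausible: hydration above 100 waters per headgroup, or a
#' volumetric headgroup density more than 50 e/nm^3 away from the fitted
#' one. Ties (both plausible or both implausible) are broken by the lower
#' reduced chi-squared; if neither geometry is plausible a warning is
#' raised and the better-fitting family returned.
#'
#' @param data An absolute-scaled [scattering_curve()].
#' @param spec A [surfactant_spec()].
#' @param start_cylinder,start_sphere Optional named start vectors; sensible
#'   defaults are built from the spec (Tanford geometry, water solvent).
#' @param seed,n_starts Forwarded to [fit_curve()].
#' @return A list of class `geometry_selection` with elements `family`
#'   (chosen), `cylinder`, `sphere` (both `fit_result`s), `derived`
#'   (per-family `micelle_derived`) and `plausible` (named logical).
#' @export
select_geometry <- function(data, spec, start_cylinder = NULL,
                            start_sphere = NULL, seed = 1L, n_starts = 8L) {
  stopifnot(inherits(data, "scattering_curve"),
            inherits(spec, "surfactant_spec"))
  lmax <- tanford_max_length(spec$n_formula_carbons - 1L)
  phi <- volume_fraction(spec)
  if (is.null(start_cylinder))
    start_cylinder <- c(Rc = 0.75 * lmax, Rh = 0.8, Lc = 6, rho_c = 275,
                        rho_h = 370, rho_solv = .rho_water, phi = phi,
                        bkg = 1e-4)
  if (is.null(start_sphere))
    start_sphere <- c(Rc = 0.75 * lmax, Rh = 0.8, rho_c = 275,
                      rho_h = 370, rho_solv = .rho_water, phi = phi,
                      bkg = 1e-4)
  fits <- list(
    cylinder = fit_curve(fit_problem("cylinder", data, start_cylinder),
                         seed = seed, n_starts = n_starts),
    sphere = fit_curve(fit_problem("sphere", data, start_sphere),
                       seed = seed, n_starts = n_starts))
  derived <- list()
  plausible <- c(cylinder = FALSE, sphere = FALSE)
  for (famname in names(fits)) {
    est <- fits[[famname]]$estimates
    mdl <- if (famname == "cylinder")
      structure(as.list(est), class = c("core_shell_cylinder", "saxs_model"))
    else
      structure(as.list(est), class = c("core_shell_sphere", "saxs_model"))
    d <- withCallingHandlers(
      derive_micelle_params(mdl, spec),
      ampchem_negative_hydration = function(w) invokeRestart("muffleWarning"))
    derived[[famname]] <- d
    plausible[famname] <- d$N_H2O <= 100 &&
      abs(d$rho_h_volumetric - est[["rho_h"]]) <= 50
  }
  chi <- vapply(fits, function(f) f$chi2_red, numeric(1))
  if (sum(plausible) == 1L) {
    family <- names(plausible)[plausible]
  } else {
    family <- names(which.min(chi))
    if (sum(plausible) == 0L)
      .warn_ampchem("no plausible geometry; returning best chi2_red",
                    "ampchem_no_plausible_geometry")
  }
  structure(list(family = family, cylinder = fits$cylinder,
                 sphere = fits$sphere, derived = derived,
                 plausible = plausible),
            class = "geometry_selection")
}
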