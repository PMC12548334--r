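# Simultaneous weighted least-squares fit of the biphasic sphere model to
# the three decomposed scattering terms, chi-squared profile intervals, and
# derived quantities (ions per peptide, phase metal concentrations,
# two-edge element ratios).

#' Default box bounds for the biphasic fit
#'
#' @return Named list of `c(lower, upper)` pairs per parameter.
#' @export
default_bounds <- function() {
  list(norm = c(1e-6, 1e6),
       phase1_density = c(0.9, 2.5),
       phase1_volfrac = c(0, 1),
       phase1_rmoles = c(0, 30),
       phase2_density = c(0.9, 2.5),
       phase2_volfrac = c(0, 1),
       mean_radius = c(10, 5000),
       rsig = c(0, 1.5))
}

.params_to_vector <- function(params) {
  unlist(params[.param_names])
}

.vector_to_params <- function(v) {
  do.call(biphasic_params, as.list(v[.param_names]))
}

## weighted residual vector over the stacked (S, C, R) data
.term_residuals <- function(params, comps, terms, n_nodes = 401L) {
  mod <- model_terms(params, comps, terms$q_grid, n_nodes = n_nodes)
  c((terms$saxs_term - mod$saxs_term) / terms$sigma_saxs,
    (terms$cross_term - mod$cross_term) / terms$sigma_cross,
    (terms$resonant_term - mod$resonant_term) / terms$sigma_resonant)
}

#' Fit the biphasic sphere model to decomposed scattering terms
#'
#' Minimises the weighted sum of squared residuals over all three terms
#' simultaneously, `sum_{T in {S,C,R}} sum_Q ((T_data - T_model)/sigma_T)^2`,
#' by bounded trust-region Levenberg-Marquardt. Parameters listed in
#' `fixed` are held at their `initial` values. The fit is deterministic
#' given the initial point.
#'
#' @param terms A [scattering_terms()] with uncertainties (as produced by
#'   [decompose()]).
#' @param comps A [phase_compositions()].
#' @param initial A [biphasic_params()] starting point (within bounds).
#' @param fixed Character vector of parameter names held fixed. The default
#'   frees `norm`, `phase1_rmoles`, `mean_radius` and `rsig`, the set that
#'   is identifiable from the three terms' two independent amplitudes plus
#'   the Q-shape; freeing densities and volume fractions as well makes the
#'   model degenerate with `norm`.
#' @param bounds Named list of `c(lower, upper)` per parameter; defaults to
#'   [default_bounds()].
#' @param n_nodes Quadrature nodes for the polydispersity average.
#' @param n_starts Controls the deterministic staged start. When
#'   `mean_radius` is free and `n_starts > 1`, a log grid of
#'   `2 * n_starts - 3` radii spanning a factor of 3 around the initial
#'   radius is scanned with the other free parameters re-optimised at each
#'   (warm-started along the scan), and the full fit is launched from the
#'   best scan point; this steps over the shallow local minima produced by
#'   residual form-factor fringes. Set to 1 for a single LM run from
#'   `initial`.
#' @param control Passed to [minpack.lm::nls.lm.control()].
#' @return Object of class `biphasic_fit`: `best_params`, `chi2`, `dof`,
#'   `intervals` (per free parameter, quadratic +/- 1 SE approximation to
#'   the delta-chi2 = 1 interval; see [chi2_map()] for the profiled
#'   version), `covariance`, convergence record, and the inputs needed for
#'   profiling.
#' @export
fit_biphasic <- function(terms, comps, initial,
                         fixed = c("phase1_density", "phase1_volfrac",
                                   "phase2_density", "phase2_volfrac"),
                         bounds = default_bounds(), n_nodes = 401L,
                         n_starts = 8L,
                         control = minpack.lm::nls.lm.control(maxiter = 200)) {
  stopifnot(inherits(terms, "scattering_terms"),
            inherits(comps, "phase_compositions"),
            inherits(initial, "biphasic_params"))
  if (is.null(terms$sigma_saxs)) {
    stop("terms must carry uncertainties to be fit", call. = FALSE)
  }
  if (all(terms$saxs_term == 0) && all(terms$cross_term == 0) &&
      all(terms$resonant_term == 0)) {
    stop("all-zero scattering terms: non-informative data", call. = FALSE)
  }
  stopifnot(all(fixed %in% .param_names))
  free <- setdiff(.param_names, fixed)
  if (length(free) == 0L) stop("no free parameters", call. = FALSE)
  p0 <- .params_to_vector(initial)
  lower <- vapply(free, function(nm) bounds[[nm]][1], numeric(1))
  upper <- vapply(free, function(nm) bounds[[nm]][2], numeric(1))
  if (any(p0[free] < lower | p0[free] > upper)) {
    stop("initial point outside bounds", call. = FALSE)
  }
  fn_nodes <- function(pfree, nn) {
    p <- p0
    p[free] <- pfree
    ## volume fractions may transiently sum above 1 inside the optimiser
    ## box; push back with a large finite residual instead of erroring
    if (p[["phase1_volfrac"]] + p[["phase2_volfrac"]] > 1) {
      return(rep(1e8, 3 * length(terms$q_grid)))
    }
    r <- .term_residuals(.vector_to_params(p), comps, terms, nn)
    if (any(!is.finite(r))) {
      stop("non-finite residuals at parameters ",
           paste(sprintf("%s=%g", free, pfree), collapse = ", "),
           call. = FALSE)
    }
    r
  }
  fn <- function(pfree) fn_nodes(pfree, n_nodes)
  start <- p0[free]
  if ("mean_radius" %in% free && n_starts > 1L && length(free) > 1L) {
    ## Staged start: the joint chi2 surface carries fringe-phase local
    ## minima in the (radius, rsig) plane. Scan a log grid of radii (and
    ## of rsig values, when rsig is free) around the initial point,
    ## re-optimising the remaining free parameters in each cell
    ## (warm-started along the scan), and launch the full fit from the
    ## best cell. Letting rsig float freely during the scan instead would
    ## inflate the width into a power-law catch-all branch.
    n_scan <- max(2L * n_starts - 3L, 5L)
    r0 <- min(max(p0[["mean_radius"]], bounds$mean_radius[1]),
              bounds$mean_radius[2])
    radii <- exp(seq(log(max(r0 / 3, bounds$mean_radius[1])),
                     log(min(r0 * 3, bounds$mean_radius[2])),
                     length.out = n_scan))
    rsigs <- NA_real_   # NA: rsig not scanned, stays at its fixed value
    shape <- "mean_radius"
    if ("rsig" %in% free) {
      s0 <- max(p0[["rsig"]], 0.02)
      rsigs <- exp(seq(log(max(s0 / 3, 0.01)),
                       log(min(s0 * 3, bounds$rsig[2])),
                       length.out = 7L))
      shape <- c("mean_radius", "rsig")
    }
    others <- setdiff(free, shape)
    if (length(others) == 0L) {
      others <- setdiff(free, "mean_radius")
      shape <- "mean_radius"
      rsigs <- NA_real_
    }
    best_scan <- NULL
    scan_ctrl <- minpack.lm::nls.lm.control(maxiter = 40)
    ## the scan only has to locate the basin: a coarser quadrature is fine
    scan_nodes <- min(n_nodes, 101L)
    for (s in rsigs) {
      warm <- p0[others]
      for (r in radii) {
        fn_cell <- function(pother) {
          v <- p0[free]
          v[others] <- pother
          v[["mean_radius"]] <- r
          if (!is.na(s)) v[["rsig"]] <- s
          fn_nodes(v, scan_nodes)
        }
        inner <- minpack.lm::nls.lm(
          par = warm, lower = lower[others], upper = upper[others],
          fn = fn_cell, control = scan_ctrl)
        warm <- inner$par
        if (is.null(best_scan) || inner$deviance < best_scan$deviance) {
          v <- p0[free]
          v[others] <- inner$par
          v[["mean_radius"]] <- r
          if (!is.na(s)) v[["rsig"]] <- s
          best_scan <- list(deviance = inner$deviance, par = v)
        }
      }
    }
    start <- best_scan$par
  }
  lm <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                           fn = fn, control = control)
  pbest <- p0
  pbest[free] <- lm$par
  best <- .vector_to_params(pbest)
  dof <- 3L * length(terms$q_grid) - length(free)
  if (dof <= 0L) stop("non-positive degrees of freedom", call. = FALSE)
  ## covariance of the weighted LS problem: (J'J)^-1 (residuals are
  ## already in sigma units, so no chi2/dof rescaling)
  jtj <- lm$hessian
  cov <- tryCatch(solve(jtj), error = function(e) NULL)
  se <- if (!is.null(cov)) sqrt(pmax(diag(cov), 0)) else rep(NA_real_,
                                                             length(free))
  names(se) <- free
  if (!is.null(cov)) {
    kap <- kappa(jtj, exact = TRUE)
    if (is.finite(kap) && kap > 1e8) {
      warning(sprintf(paste0("ill-conditioned fit (Hessian condition ",
                             "number %.3g): norm/volume-fraction ",
                             "degeneracy likely"), kap), call. = FALSE)
    }
  }
  intervals <- lapply(free, function(nm) {
    c(lower = pbest[[nm]] - se[[nm]], upper = pbest[[nm]] + se[[nm]])
  })
  names(intervals) <- free
  structure(
    list(best_params = best, chi2 = lm$deviance, dof = dof,
         intervals = intervals, se = se, covariance = cov,
         free = free, fixed = fixed, bounds = bounds, comps = comps,
         n_nodes = n_nodes,
         convergence = list(iterations = lm$niter, status = lm$info,
                            message = lm$message,
                            converged = lm$info %in% 1:4)),
    class = "biphasic_fit"
  )
}

#' @export
print.biphasic_fit <- function(x, ...) {
  cat("<biphasic_fit> chi2 = ", format(x$chi2, digits = 6), " on ", x$dof,
      " dof (chi2/dof = ", format(x$chi2 / x$dof, digits = 4), ")\n",
      sep = "")
  cat("  status: ", x$convergence$message, "\n", sep = "")
  for (nm in x$free) {
    cat(sprintf("  %-15s %.6g +/- %.3g\n", nm, x$best_params[[nm]],
                x$se[[nm]]))
  }
  if (length(x$fixed)) {
    cat("  fixed: ", paste(x$fixed, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Chi-squared profile of one fitted parameter
#'
#' Maps the chi-squared space along one free parameter: at each grid value
#' the parameter is fixed and all remaining free parameters are
#' re-optimised. The delta-chi2 <= 1 region, interpolated from the profile,
#' gives the 1-sigma confidence interval.
#'
#' @param result A converged [fit_biphasic()] result.
#' @param terms The [scattering_terms()] that were fit.
#' @param param Name of a free parameter of the fit.
#' @param grid Optional explicit grid of parameter values; default is
#'   `n_grid` points spanning +/- `span` approximate standard errors around
#'   the best fit (clipped to the bounds).
#' @param n_grid,span Grid resolution and half-width in SE units.
#' @return List with `profile` (data.frame of `value`, `chi2`), `interval`
#'   (the delta-chi2 = 1 crossing points), `best` and `chi2_min`. A
#'   one-sided interval (with a warning) results if the grid does not
#'   bracket a crossing.
#' @export
chi2_map <- function(result, terms, param, grid = NULL, n_grid = 41L,
                     span = 4) {
  stopifnot(inherits(result, "biphasic_fit"),
            inherits(terms, "scattering_terms"))
  if (param %in% result$fixed) {
    stop("parameter '", param, "' was fixed during the fit; not profiled",
         call. = FALSE)
  }
  stopifnot(param %in% result$free)
  pbest <- .params_to_vector(result$best_params)
  if (is.null(grid)) {
    se <- result$se[[param]]
    if (!is.finite(se) || se <= 0) {
      stop("no usable standard error to build a default grid; supply one",
           call. = FALSE)
    }
    b <- result$bounds[[param]]
    grid <- seq(max(b[1], pbest[[param]] - span * se),
                min(b[2], pbest[[param]] + span * se), length.out = n_grid)
  }
  others <- setdiff(result$free, param)
  chi2 <- vapply(grid, function(v) {
    init <- .vector_to_params(`[<-`(pbest, param, v))
    if (length(others) == 0L) {
      sum(.term_residuals(init, result$comps, terms, result$n_nodes)^2)
    } else {
      refit <- fit_biphasic(terms, result$comps, init,
                            fixed = c(result$fixed, param),
                            bounds = result$bounds,
                            n_nodes = result$n_nodes, n_starts = 1L)
      refit$chi2
    }
  }, numeric(1))
  chi2_min <- min(c(chi2, result$chi2))
  target <- chi2_min + 1
  ## interpolate the delta-chi2 = 1 crossings on each side of the minimum
  cross <- function(idx) {
    for (k in seq_along(idx)[-1]) {
      i1 <- idx[k - 1]; i2 <- idx[k]
      if ((chi2[i1] - target) * (chi2[i2] - target) <= 0 &&
          chi2[i1] != chi2[i2]) {
        return(grid[i1] + (target - chi2[i1]) *
                 (grid[i2] - grid[i1]) / (chi2[i2] - chi2[i1]))
      }
    }
    NA_real_
  }
  imin <- which.min(chi2)
  lower <- if (imin > 1) cross(rev(seq_len(imin))) else NA_real_
  upper <- if (imin < length(grid)) cross(seq(imin, length(grid)))
           else NA_real_
  if (is.na(lower) || is.na(upper)) {
    warning("profile grid does not bracket the delta-chi2 = 1 crossing; ",
            "returning a one-sided interval", call. = FALSE)
  }
  list(profile = data.frame(value = grid, chi2 = chi2),
       interval = c(lower = lower, upper = upper),
       best = pbest[[param]], chi2_min = chi2_min)
}

#' Total lanthanide ions per peptide in the aggregate
#'
#' Combines the fitted in-phase-1 stoichiometry (`phase1_rmoles`) with the
#' resonant ions of the cation-rich phase 2, expressed per peptide of
#' phase 1, using the fitted densities and volume fractions:
#' `N = rmoles + (vf2 * n_res,2) / (vf1 * n_peptide,1)`.
#'
#' @param result A [fit_biphasic()] result (or a bare [biphasic_params()]
#'   for forward checks).
#' @param comps A [phase_compositions()]; defaults to the one stored in the
#'   fit.
#' @return Dimensionless ions-per-peptide number.
#' @export
ions_per_peptide <- function(result, comps = NULL) {
  params <- if (inherits(result, "biphasic_fit")) result$best_params
            else result
  stopifnot(inherits(params, "biphasic_params"))
  if (is.null(comps)) comps <- result$comps
  if (params$phase1_volfrac <= 0) {
    stop("zero peptide content (phase1_volfrac = 0)", call. = FALSE)
  }
  m1 <- .phase1_material(comps, params$phase1_rmoles,
                         params$phase1_density)
  n_pep <- params$phase1_volfrac * formula_unit_density(m1)
  extra <- 0
  if (params$phase2_volfrac > 0) {
    m2 <- .phase2_material(comps, params$phase2_density)
    extra <- params$phase2_volfrac * formula_unit_density(m2) / n_pep
  }
  params$phase1_rmoles + extra
}

#' Molar concentration of the resonant element in each phase
#'
#' From the fitted mass densities, phase formulas and volume fractions.
#'
#' @inheritParams ions_per_peptide
#' @return List with `phase1`, `phase2` (mol/L inside each phase) and
#'   `aggregate_average` (volume-fraction-weighted mol/L over the sphere).
#' @export
phase_metal_concentrations <- function(result, comps = NULL) {
  params <- if (inherits(result, "biphasic_fit")) result$best_params
            else result
  stopifnot(inherits(params, "biphasic_params"))
  if (is.null(comps)) comps <- result$comps
  ## formula units per A^3 -> mol/L: / N_A * 1e27
  to_molar <- function(n_per_a3) n_per_a3 / .N_A * 1e27
  m1 <- .phase1_material(comps, params$phase1_rmoles,
                         params$phase1_density)
  c1 <- to_molar(params$phase1_rmoles * formula_unit_density(m1))
  m2 <- .phase2_material(comps, params$phase2_density)
  c2 <- to_molar(formula_unit_density(m2))
  list(phase1 = c1, phase2 = c2,
       aggregate_average = params$phase1_volfrac * c1 +
         params$phase2_volfrac * c2)
}

#' Element ratio from two single-edge fits of the same sample
#'
#' For a two-element sample measured below two different absorption edges,
#' each edge's fit sees only its own resonant element; the ratio of the two
#' total ions-per-peptide numbers is the separation factor (e.g.
#' Tb3+/Lu3+). The two fits must share the sample geometry.
#'
#' @param result_a,result_b [fit_biphasic()] results for elements A and B.
#' @param comps_a,comps_b Matching [phase_compositions()]; default to the
#'   ones stored in the fits.
#' @return Dimensionless ratio N_A / N_B.
#' @export
element_ratio <- function(result_a, result_b, comps_a = NULL,
                          comps_b = NULL) {
  na <- ions_per_peptide(result_a, comps_a)
  nb <- ions_per_peptide(result_b, comps_b)
  if (nb == 0) stop("element B has zero ions per peptide", call. = FALSE)
  na / nb
}

#' Fit the biphasic model directly to raw multi-energy intensities
#'
#' Cross-validation mode: instead of fitting the three decomposed terms,
#' minimises the weighted residuals of the full `I(Q, E)` matrix against
#' the assembled model. Useful to confirm that decomposition plus term
#' fitting loses nothing on well-conditioned scans.
#'
#' @param dataset An [energy_scan()].
#' @param comps A [phase_compositions()].
#' @inheritParams fit_biphasic
#' @return A `biphasic_fit` (dof counts all Ne x Nq points).
#' @export
fit_biphasic_raw <- function(dataset, comps, initial,
                             fixed = c("phase1_density", "phase1_volfrac",
                                       "phase2_density", "phase2_volfrac"),
                             bounds = default_bounds(), n_nodes = 401L,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 200)) {
  stopifnot(inherits(dataset, "energy_scan"),
            inherits(comps, "phase_compositions"),
            inherits(initial, "biphasic_params"))
  free <- setdiff(.param_names, fixed)
  p0 <- .params_to_vector(initial)
  lower <- vapply(free, function(nm) bounds[[nm]][1], numeric(1))
  upper <- vapply(free, function(nm) bounds[[nm]][2], numeric(1))
  f <- dispersion_at(dataset$dispersion, dataset$energies)
  fn <- function(pfree) {
    p <- p0
    p[free] <- pfree
    if (p[["phase1_volfrac"]] + p[["phase2_volfrac"]] > 1) {
      return(rep(1e8, length(dataset$intensity)))
    }
    tm <- model_terms(.vector_to_params(p), comps, dataset$q_grid,
                      n_nodes = n_nodes)
    res <- vapply(seq_along(dataset$energies), function(i) {
      (dataset$intensity[i, ] -
         assemble_intensity(tm, f$f_prime[i], f$f_doubleprime[i])) /
        dataset$sigma[i, ]
    }, numeric(length(dataset$q_grid)))
    as.numeric(res)
  }
  lm <- minpack.lm::nls.lm(par = p0[free], lower = lower, upper = upper,
                           fn = fn, control = control)
  pbest <- p0
  pbest[free] <- lm$par
  dof <- length(dataset$intensity) - length(free)
  structure(
    list(best_params = .vector_to_params(pbest), chi2 = lm$deviance,
         dof = dof, intervals = NULL,
         se = rep(NA_real_, length(free)), covariance = NULL,
         free = free, fixed = fixed, bounds = bounds, comps = comps,
         n_nodes = n_nodes,
         convergence = list(iterations = lm$niter, status = lm$info,
                            message = lm$message,
                            converged = lm$info %in% 1:4)),
    class = "biphasic_fit"
  )
}
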