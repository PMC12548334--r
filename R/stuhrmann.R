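# Stuhrmann decomposition: separate multi-energy SAXS intensities into the
# energy-independent SAXS term, the cross term (linear in f') and the
# resonant term (scaling with f'^2 + f''^2), per Q, by weighted least
# squares.

#' Multi-energy ASAXS dataset
#'
#' Container for a set of scattering profiles measured at several photon
#' energies below one absorption edge, on a common Q grid.
#'
#' @param q_grid Ascending positive Q grid, 1/A (length Nq).
#' @param energies Photon energies in keV (length Ne), all below the
#'   dispersion table's edge energy.
#' @param intensity Ne x Nq intensity matrix, 1/cm absolute scale.
#' @param sigma Ne x Nq matrix of 1-sd uncertainties, all > 0.
#' @param resonant_element Element symbol.
#' @param dispersion A [dispersion_table()] for that element covering all
#'   `energies`.
#' @return Object of class `energy_scan`.
#' @export
energy_scan <- function(q_grid, energies, intensity, sigma,
                        resonant_element, dispersion) {
  stopifnot(is.numeric(q_grid), all(q_grid > 0), all(diff(q_grid) > 0),
            is.numeric(energies), is.matrix(intensity), is.matrix(sigma),
            inherits(dispersion, "dispersion_table"))
  ne <- length(energies); nq <- length(q_grid)
  if (!all(dim(intensity) == c(ne, nq)) || !all(dim(sigma) == c(ne, nq))) {
    stop("intensity/sigma must be Ne x Nq matrices", call. = FALSE)
  }
  if (any(sigma <= 0)) stop("all sigma must be > 0", call. = FALSE)
  if (resonant_element != dispersion$element) {
    stop("resonant element does not match dispersion table", call. = FALSE)
  }
  if (any(energies >= dispersion$edge_energy)) {
    stop("all energies must lie below the edge energy", call. = FALSE)
  }
  structure(
    list(q_grid = q_grid, energies = energies, intensity = intensity,
         sigma = sigma, resonant_element = resonant_element,
         dispersion = dispersion),
    class = "energy_scan"
  )
}

#' @export
print.energy_scan <- function(x, ...) {
  cat("<energy_scan> ", length(x$energies), " energies x ",
      length(x$q_grid), " Q points, ", x$resonant_element,
      " edge at ", x$dispersion$edge_energy, " keV\n", sep = "")
  cat("  E in [", min(x$energies), ", ", max(x$energies), "] keV; Q in [",
      format(min(x$q_grid)), ", ", format(max(x$q_grid)), "] 1/A\n",
      sep = "")
  invisible(x)
}

#' Per-Q scattering-term triple
#'
#' Holds the SAXS term S(Q), cross term C(Q) and resonant term R(Q), with
#' optional 1-sd uncertainties (filled in by [decompose()]).
#'
#' @param q_grid Q grid, 1/A.
#' @param saxs_term,cross_term,resonant_term Term vectors, 1/cm.
#' @param sigma_saxs,sigma_cross,sigma_resonant Optional uncertainty
#'   vectors.
#' @return Object of class `scattering_terms`.
#' @export
scattering_terms <- function(q_grid, saxs_term, cross_term, resonant_term,
                             sigma_saxs = NULL, sigma_cross = NULL,
                             sigma_resonant = NULL) {
  nq <- length(q_grid)
  stopifnot(length(saxs_term) == nq, length(cross_term) == nq,
            length(resonant_term) == nq)
  for (s in list(sigma_saxs, sigma_cross, sigma_resonant)) {
    if (!is.null(s)) stopifnot(length(s) == nq, all(s > 0))
  }
  structure(
    list(q_grid = q_grid, saxs_term = as.numeric(saxs_term),
         cross_term = as.numeric(cross_term),
         resonant_term = as.numeric(resonant_term),
         sigma_saxs = sigma_saxs, sigma_cross = sigma_cross,
         sigma_resonant = sigma_resonant),
    class = "scattering_terms"
  )
}

#' @export
print.scattering_terms <- function(x, ...) {
  cat("<scattering_terms> ", length(x$q_grid), " Q points",
      if (!is.null(x$sigma_saxs)) ", with uncertainties", "\n", sep = "")
  cat(sprintf("  S(Qmin) = %.4g, C(Qmin) = %.4g, R(Qmin) = %.4g [1/cm]\n",
              x$saxs_term[1], x$cross_term[1], x$resonant_term[1]))
  invisible(x)
}

## Stuhrmann design matrix over the dataset energies: columns
## [1, 2 f'(E), f'(E)^2 + f''(E)^2]
.stuhrmann_design <- function(dataset) {
  f <- dispersion_at(dataset$dispersion, dataset$energies)
  cbind(1, 2 * f$f_prime, f$f_prime^2 + f$f_doubleprime^2)
}

#' Stuhrmann decomposition of a multi-energy dataset
#'
#' Solves, independently at every Q, the weighted linear least-squares
#' system `I(Q,E) = S(Q) + 2 f'(E) C(Q) + (f'(E)^2 + f''(E)^2) R(Q)` with
#' weights 1/sigma^2, returning the three term vectors with uncertainties
#' propagated from the weighted least-squares covariance. Negative
#' resonant-term estimates arising from noise are kept (not clipped) unless
#' `nonnegative = TRUE`, which clips S and R at zero after solving.
#'
#' @param dataset An [energy_scan()] with at least 3 energies.
#' @param nonnegative If `TRUE`, clip negative S and R estimates to zero
#'   (biased but occasionally convenient); default `FALSE`.
#' @param condition_limit Condition-number threshold above which the design
#'   is declared degenerate.
#' @return A [scattering_terms()] with per-term uncertainties.
#' @export
decompose <- function(dataset, nonnegative = FALSE,
                      condition_limit = 1e8) {
  stopifnot(inherits(dataset, "energy_scan"))
  ne <- length(dataset$energies)
  if (ne < 3L) stop("need at least 3 energies to decompose", call. = FALSE)
  x <- .stuhrmann_design(dataset)
  kap <- kappa(x, exact = TRUE)
  if (!is.finite(kap) || kap > condition_limit) {
    stop(sprintf(paste0("degenerate design matrix (condition number %.3g):",
                        " energies do not spread f' enough"), kap),
         call. = FALSE)
  }
  nq <- length(dataset$q_grid)
  est <- matrix(NA_real_, 3L, nq)
  err <- matrix(NA_real_, 3L, nq)
  for (j in seq_len(nq)) {
    w <- 1 / dataset$sigma[, j]^2
    xtw <- t(x * w)
    a <- xtw %*% x
    b <- xtw %*% dataset$intensity[, j]
    cov <- solve(a)
    est[, j] <- cov %*% b
    err[, j] <- sqrt(diag(cov))
  }
  if (nonnegative) {
    est[1, ] <- pmax(est[1, ], 0)
    est[3, ] <- pmax(est[3, ], 0)
  }
  scattering_terms(dataset$q_grid, est[1, ], est[2, ], est[3, ],
                   sigma_saxs = err[1, ], sigma_cross = err[2, ],
                   sigma_resonant = err[3, ])
}

#' Reconstruct intensities from decomposed terms
#'
#' Inverse of [decompose()] for round-trip checks: assembles the Ne x Nq
#' intensity matrix from the terms and the dataset's dispersion values.
#'
#' @param terms A [scattering_terms()].
#' @param dataset The [energy_scan()] providing energies and dispersion.
#' @return Ne x Nq intensity matrix, 1/cm.
#' @export
reconstruct_intensity <- function(terms, dataset) {
  x <- .stuhrmann_design(dataset)
  x %*% rbind(terms$saxs_term, terms$cross_term, terms$resonant_term)
}

#' Check the Cauchy-Schwarz bound on decomposed terms
#'
#' The three Stuhrmann terms of any physical density pair must satisfy
#' `C(Q)^2 <= S(Q) * R(Q)`; for a model in which resonant and non-resonant
#' contrast share one spatial profile the bound holds with equality. Noisy
#' decompositions may violate it; this reports, per Q, where
#' `C^2 > (1 + tolerance) * S * R`.
#'
#' @param terms A [scattering_terms()].
#' @param tolerance Relative tolerance (e.g. 0.1 for 10%).
#' @param n_sigma For terms carrying uncertainties (i.e. estimated from
#'   noisy data), a point is only flagged when the excess
#'   `C^2 - (1 + tolerance) S R` also exceeds `n_sigma` times its
#'   propagated standard error; exact terms (no uncertainties) are checked
#'   deterministically.
#' @return List with logical vector `violated`, integer `n_violations`,
#'   `worst_ratio` (max of C^2/(S R); where S R <= 0 the ratio is infinite
#'   and the point is subject to the same significance test).
#' @export
validate_cauchy_schwarz <- function(terms, tolerance = 0, n_sigma = 2) {
  stopifnot(inherits(terms, "scattering_terms"), tolerance >= 0)
  s <- terms$saxs_term; r <- terms$resonant_term; cc <- terms$cross_term
  sr <- s * r
  c2 <- cc^2
  ratio <- ifelse(sr > 0, c2 / sr, Inf)
  ratio[c2 == 0 & sr <= 0] <- 1
  excess <- c2 - (1 + tolerance) * sr
  violated <- excess > 0
  if (!is.null(terms$sigma_saxs)) {
    ## noisy estimates: require the excess to be significant as well
    ## (delta-method error of C^2 - (1+tol) S R)
    se <- sqrt((2 * cc * terms$sigma_cross)^2 +
                 ((1 + tolerance) * r * terms$sigma_saxs)^2 +
                 ((1 + tolerance) * s * terms$sigma_resonant)^2)
    violated <- violated & excess > n_sigma * se
  }
  list(violated = violated, n_violations = sum(violated),
       worst_ratio = max(ratio), q_violated = terms$q_grid[violated])
}

#' Linearity diagnostic of intensity against f'(E) at fixed Q
#'
#' Regresses `I(Q_fixed, E)` on `f'(E)` and `f'(E)^2`. Over a narrow
#' below-edge range where f'' is nearly constant, the model predicts an
#' intercept `S + f''^2 R`, a slope `2 C` and a quadratic coefficient `R`,
#' so the curvature statistic (the quadratic contribution's share of the
#' fitted intensity variation across the measured f' span) quantifies the
#' relative size of the resonant term.
#'
#' @param dataset An [energy_scan()] with at least 3 energies.
#' @param q_index Index into the Q grid.
#' @return List with `slope`, `intercept`, `quadratic` (the raw regression
#'   coefficients) and `curvature` (dimensionless relative-size statistic).
#' @export
linearity_diagnostic <- function(dataset, q_index) {
  stopifnot(inherits(dataset, "energy_scan"),
            q_index >= 1, q_index <= length(dataset$q_grid))
  if (length(dataset$energies) < 3L) {
    stop("need at least 3 energies", call. = FALSE)
  }
  fp <- dispersion_at(dataset$dispersion, dataset$energies)$f_prime
  if (diff(range(fp)) == 0) {
    stop("f' is constant across the energies; no linearity to diagnose",
         call. = FALSE)
  }
  y <- dataset$intensity[, q_index]
  fit <- stats::lm(y ~ fp + I(fp^2))
  co <- stats::coef(fit)
  span <- diff(range(fp))
  lin_excursion <- abs(co[["fp"]]) * span
  quad_excursion <- abs(co[["I(fp^2)"]]) * diff(range(fp^2))
  total <- lin_excursion + quad_excursion
  curvature <- if (total > 0) quad_excursion / total else 0
  list(slope = unname(co[["fp"]]), intercept = unname(co[["(Intercept)"]]),
       quadratic = unname(co[["I(fp^2)"]]), curvature = curvature)
}
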