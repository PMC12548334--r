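test_that("noise-free fit recovers a x1.5-perturbed truth to 0.1%", {
  comps <- phase_compositions("Tb")
  truth <- small_truth()
  q <- exp(seq(log(0.003), log(0.3), length.out = 120))
  exact <- model_terms(truth, comps, q)
  terms <- terms_with_sigma(exact, rel = 0.01)  # exact data, finite sigma
  init <- truth
  for (nm in c("norm", "phase1_rmoles", "mean_radius", "rsig")) {
    init[[nm]] <- init[[nm]] * 1.5
  }
  class(init) <- "biphasic_params"
  fit <- suppressWarnings(fit_biphasic(terms, comps, init))
  for (nm in c("norm", "phase1_rmoles", "mean_radius", "rsig")) {
    expect_equal(fit$best_params[[nm]], truth[[nm]], tolerance = 1e-3)
  }
  expect_lt(fit$chi2 / fit$dof, 1e-6)
})

test_that("all-zero terms are rejected as non-informative", {
  comps <- phase_compositions("Tb")
  zero <- scattering_terms(1:5 / 10, rep(0, 5), rep(0, 5), rep(0, 5),
                           sigma_saxs = rep(1, 5),
                           sigma_cross = rep(1, 5),
                           sigma_resonant = rep(1, 5))
  expect_error(fit_biphasic(zero, comps, small_truth()),
               "non-informative")
})

test_that("fixed parameters are honored and cannot be profiled", {
  comps <- phase_compositions("Tb")
  truth <- small_truth()
  q <- exp(seq(log(0.005), log(0.2), length.out = 50))
  terms <- terms_with_sigma(model_terms(truth, comps, q))
  fit <- suppressWarnings(
    fit_biphasic(terms, comps, truth,
                 fixed = c("phase1_density", "phase1_volfrac",
                           "phase2_density", "phase2_volfrac", "rsig")))
  expect_identical(fit$best_params$rsig, truth$rsig)
  expect_error(chi2_map(fit, terms, "rsig"), "fixed")
})

test_that("fit is invariant to uniform rescaling of data and sigma", {
  comps <- phase_compositions("Tb")
  truth <- small_truth()
  cfg <- synthetic_config(truth = truth, n_q = 80, seed = 55)
  terms <- decompose(generate_asaxs(cfg))
  init <- truth; init$phase1_rmoles <- 2.8; init$mean_radius <- 460
  class(init) <- "biphasic_params"
  fit1 <- suppressWarnings(fit_biphasic(terms, comps, init, n_starts = 1))
  scaled <- scattering_terms(
    terms$q_grid, 10 * terms$saxs_term, 10 * terms$cross_term,
    10 * terms$resonant_term, sigma_saxs = 10 * terms$sigma_saxs,
    sigma_cross = 10 * terms$sigma_cross,
    sigma_resonant = 10 * terms$sigma_resonant)
  # rescaled data describe a 10x denser suspension: same shape, norm x10
  init10 <- init; init10$norm <- 10 * init$norm
  class(init10) <- "biphasic_params"
  fit2 <- suppressWarnings(fit_biphasic(scaled, comps, init10,
                                        n_starts = 1))
  expect_equal(fit2$best_params$norm, 10 * fit1$best_params$norm,
               tolerance = 1e-5)
  expect_equal(fit2$best_params$mean_radius, fit1$best_params$mean_radius,
               tolerance = 1e-6)
  expect_equal(fit2$chi2, fit1$chi2, tolerance = 1e-6)
})

test_that("chi2 profile reproduces the analytic interval on a linear model", {
  # exactly quadratic chi2 surface: the resonant-free amplitude problem is
  # linear in norm, so the delta-chi2 = 1 interval must match +/- 1 SE
  # from the analytic covariance
  comps <- phase_compositions("Tb")
  truth <- small_truth()
  q <- exp(seq(log(0.005), log(0.2), length.out = 60))
  terms <- terms_with_sigma(model_terms(truth, comps, q), rel = 0.05)
  fit <- suppressWarnings(
    fit_biphasic(terms, comps, truth,
                 fixed = setdiff(.param_names_for_test(), "norm")))
  prof <- chi2_map(fit, terms, "norm")
  se <- fit$se[["norm"]]
  expect_equal(prof$interval[["upper"]] - prof$interval[["lower"]],
               2 * se, tolerance = 0.02)
  expect_lt(abs(prof$best - truth$norm), 1e-6)
  # interval contains the best value
  expect_gt(prof$best, prof$interval[["lower"]])
  expect_lt(prof$best, prof$interval[["upper"]])
})

test_that("interval width shrinks with the data uncertainty", {
  comps <- phase_compositions("Tb")
  truth <- small_truth()
  q <- exp(seq(log(0.005), log(0.2), length.out = 40))
  widths <- vapply(c(0.05, 0.005), function(rel) {
    terms <- terms_with_sigma(model_terms(truth, comps, q), rel = rel)
    fit <- suppressWarnings(
      fit_biphasic(terms, comps, truth,
                   fixed = setdiff(.param_names_for_test(), "norm")))
    prof <- chi2_map(fit, terms, "norm")
    prof$interval[["upper"]] - prof$interval[["lower"]]
  }, numeric(1))
  expect_equal(widths[2] / widths[1], 0.1, tolerance = 0.05)
})

test_that("derived quantities follow the stoichiometry arithmetic", {
  comps <- phase_compositions("Tb")
  # phase2_volfrac = 0: ions per peptide is just rmoles
  p <- biphasic_params(1, 1.35, 0.25, 2.2, 1.1, 0, 400, 0.2)
  expect_equal(ions_per_peptide(p, comps), 2.2)
  # with a phase-2 share, the hand-built arithmetic applies
  p2 <- biphasic_params(1, 1.35, 0.25, 2.25, 1.1, 0.01, 400, 0.2)
  m1 <- molar_mass("C103H149N23O36") + 2.25 * atomic_mass("Tb")
  m2 <- molar_mass("TbCl3(H2O)6")
  n_pep <- 0.25 * 1.35 * 6.02214076e23 / m1 / 1e24
  n_tb2 <- 0.01 * 1.10 * 6.02214076e23 / m2 / 1e24
  expect_equal(ions_per_peptide(p2, comps), 2.25 + n_tb2 / n_pep,
               tolerance = 1e-9)
  # zero peptide content errors
  p3 <- biphasic_params(1, 1.35, 0, 0, 1.1, 0.2, 400, 0.2)
  expect_error(ions_per_peptide(p3, comps), "zero peptide")
  # phase metal concentrations: density / molar mass arithmetic
  conc <- phase_metal_concentrations(p2, comps)
  expect_equal(conc$phase2, 1.10 / m2 * 1000, tolerance = 1e-9)
  expect_equal(conc$phase1, 2.25 * 1.35 / m1 * 1000, tolerance = 1e-9)
  # aggregate average scales linearly with volume fraction
  p4 <- p2; p4$phase2_volfrac <- 0.02; class(p4) <- "biphasic_params"
  c4 <- phase_metal_concentrations(p4, comps)
  expect_equal(c4$aggregate_average - conc$aggregate_average,
               0.01 * conc$phase2, tolerance = 1e-9)
})

test_that("element ratio divides per-peptide contents and inverts on swap", {
  comps_tb <- phase_compositions("Tb")
  comps_lu <- phase_compositions("Lu")
  pa <- biphasic_params(1, 1.35, 0.25, 1.7, 1.1, 0, 400, 0.2)
  pb <- biphasic_params(1, 1.35, 0.25, 1.0, 1.1, 0, 400, 0.2)
  expect_equal(element_ratio(pa, pb, comps_tb, comps_lu), 1.7)
  expect_equal(element_ratio(pb, pa, comps_lu, comps_tb), 1 / 1.7)
  pz <- biphasic_params(1, 1.35, 0.25, 0, 1.1, 0, 400, 0.2)
  expect_error(element_ratio(pa, pz, comps_tb, comps_lu), "zero")
})

test_that("ions per peptide from a concentrated-regime fit stays in band", {
  # truth built inside the 2-2.5 ions-per-peptide band; a fit to 1%-noise
  # synthetic data from the concentrated (800 uM-scale) regime must land
  # back in the band
  comps <- phase_compositions("Tb")
  truth <- small_truth()
  expect_gt(ions_per_peptide(truth, comps), 2)
  expect_lt(ions_per_peptide(truth, comps), 2.5)
  cfg <- synthetic_config(truth = truth, n_q = 120, seed = 77)
  terms <- decompose(generate_asaxs(cfg))
  init <- truth; init$phase1_rmoles <- 3; init$mean_radius <- 480
  init$norm <- 30; init$rsig <- 0.3
  class(init) <- "biphasic_params"
  fit <- suppressWarnings(fit_biphasic(terms, comps, init))
  n <- ions_per_peptide(fit)
  expect_gt(n, 2)
  expect_lt(n, 2.5)
})

test_that("raw-intensity fit agrees with the term fit on synthetic data", {
  comps <- phase_compositions("Tb")
  truth <- small_truth()
  cfg <- synthetic_config(truth = truth, n_q = 80, seed = 91)
  ds <- generate_asaxs(cfg)
  init <- truth; init$phase1_rmoles <- 2.5; init$mean_radius <- 430
  class(init) <- "biphasic_params"
  fit_terms <- suppressWarnings(fit_biphasic(decompose(ds), comps, init))
  fit_raw <- suppressWarnings(fit_biphasic_raw(ds, comps, init))
  expect_equal(fit_raw$best_params$phase1_rmoles,
               fit_terms$best_params$phase1_rmoles, tolerance = 0.02)
  expect_equal(fit_raw$best_params$mean_radius,
               fit_terms$best_params$mean_radius, tolerance = 0.02)
  expect_lt(fit_raw$chi2 / fit_raw$dof, 2)
})
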