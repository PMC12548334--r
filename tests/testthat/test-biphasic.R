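test_that("sphere amplitude matches its closed form and bounds", {
  expect_identical(sphere_amplitude(0, 100), 1)
  # x = pi: Phi = 3/pi^2
  expect_equal(sphere_amplitude(pi / 100, 100), 3 / pi^2,
               tolerance = 1e-12)
  x <- seq(0, 60, length.out = 500)
  phi <- sphere_amplitude(x, 1)
  expect_true(all(abs(phi) <= 1))
  # series/trig crossover is seamless
  expect_equal(sphere_amplitude(9.9e-4, 1), sphere_amplitude(1.01e-3, 1),
               tolerance = 1e-6)
})

test_that("effective contrasts follow the volume-fraction stoichiometry", {
  comps <- phase_compositions("Tb")
  # solvent-only sphere: zero contrast
  p0 <- biphasic_params(1, 1.35, 0, 0, 1.1, 0, 100, 0)
  con0 <- effective_contrasts(p0, comps)
  expect_equal(con0$delta_rho0, 0)
  expect_equal(con0$rho_res, 0)
  # no resonant content anywhere
  p1 <- biphasic_params(1, 1.35, 0.3, 0, 1.1, 0, 100, 0)
  expect_equal(effective_contrasts(p1, comps)$rho_res, 0)
  # hand-computed stoichiometry oracle for phase 1 only
  p2 <- biphasic_params(1, 1.35, 0.25, 2.25, 1.1, 0, 100, 0)
  con2 <- effective_contrasts(p2, comps)
  m_pep <- molar_mass("C103H149N23O36") + 2.25 * atomic_mass("Tb")
  ne <- formula_electrons("C103H149N23O36") + 2.25 * atomic_number("Tb")
  rho1 <- ne * 1.35 * 6.02214076e23 / m_pep / 1e24
  rho_w <- 10 * 6.02214076e23 / 18.015 / 1e24
  expect_equal(con2$delta_rho0, 0.25 * (rho1 - rho_w), tolerance = 1e-9)
  expect_equal(con2$rho_res,
               0.25 * 2.25 * 1.35 * 6.02214076e23 / m_pep / 1e24,
               tolerance = 1e-9)
})

test_that("model terms obey linearity, proportionality and units limits", {
  comps <- phase_compositions("Tb")
  q <- exp(seq(log(0.003), log(0.3), length.out = 50))
  p <- small_truth()
  tm <- model_terms(p, comps, q)
  expect_true(all(tm$saxs_term > 0))
  expect_true(all(tm$resonant_term > 0))
  # C^2 = S R to 1e-10 relative (shared spatial profile)
  expect_lt(max(abs(tm$cross_term^2 / (tm$saxs_term * tm$resonant_term)
                    - 1)), 1e-10)
  # doubling norm doubles every term
  p2 <- p; p2$norm <- 2 * p$norm
  tm2 <- model_terms(p2, comps, q)
  expect_equal(tm2$saxs_term, 2 * tm$saxs_term)
  expect_equal(tm2$cross_term, 2 * tm$cross_term)
  expect_equal(tm2$resonant_term, 2 * tm$resonant_term)
  # no resonant content: C and R vanish identically
  p3 <- p; p3$phase1_rmoles <- 0; p3$phase2_volfrac <- 0
  tm3 <- model_terms(p3, comps, q)
  expect_true(all(tm3$cross_term == 0))
  expect_true(all(tm3$resonant_term == 0))
  expect_true(all(tm3$saxs_term > 0))
})

test_that("rsig -> 0 recovers the monodisperse closed form", {
  comps <- phase_compositions("Tb")
  q <- exp(seq(log(0.003), log(0.3), length.out = 60))
  base <- small_truth()
  base$rsig <- 0
  class(base) <- "biphasic_params"
  tm0 <- model_terms(base, comps, q)
  con <- effective_contrasts(base, comps)
  re_cm <- 2.8179403262e-13
  v <- 4 / 3 * pi * base$mean_radius^3
  closed <- base$norm * 1e12 * re_cm^2 * con$delta_rho0^2 *
    (v * sphere_amplitude(q, base$mean_radius))^2
  expect_equal(tm0$saxs_term, closed, tolerance = 1e-10)
  # small rsig approaches the monodisperse limit
  tiny <- base; tiny$rsig <- 1e-4; class(tiny) <- "biphasic_params"
  tmt <- model_terms(tiny, comps, q)
  expect_equal(tmt$saxs_term, tm0$saxs_term, tolerance = 1e-6)
})

test_that("forward intensity at Q -> 0 scales as R^6", {
  comps <- phase_compositions("Tb")
  p <- small_truth(); p$rsig <- 0; class(p) <- "biphasic_params"
  pa <- p; pa$mean_radius <- 200
  pb <- p; pb$mean_radius <- 400
  q0 <- 1e-7
  ia <- model_terms(pa, comps, c(q0, 2e-7))$saxs_term[1]
  ib <- model_terms(pb, comps, c(q0, 2e-7))$saxs_term[1]
  expect_equal(ib / ia, 64, tolerance = 1e-6)
})

test_that("intensity assembly follows the f' / f'' rule and stays positive", {
  comps <- phase_compositions("Tb")
  tab <- builtin_dispersion_table("Tb")
  q <- exp(seq(log(0.003), log(0.3), length.out = 40))
  p <- small_truth()
  tm <- model_terms(p, comps, q)
  # f' = f'' = 0 reduces to the SAXS term
  expect_equal(assemble_intensity(tm, 0, 0), tm$saxs_term)
  # direct substitution oracle at one energy
  e <- 7.45
  f <- dispersion_at(tab, e)
  manual <- tm$saxs_term + 2 * f$f_prime * tm$cross_term +
    (f$f_prime^2 + f$f_doubleprime^2) * tm$resonant_term
  expect_equal(model_intensity(p, comps, q, tab, e), manual)
  # with C > 0 here, the more negative f' near the edge lowers I
  i_far <- model_intensity(p, comps, q, tab, 7.42)
  i_near <- model_intensity(p, comps, q, tab, 7.50)
  expect_true(all(i_near < i_far))
  # positivity across the table range
  for (e in seq(min(tab$energy), max(tab$energy), length.out = 7)) {
    expect_true(all(model_intensity(p, comps, q, tab, e) > 0))
  }
})

test_that("Guinier radius has the sqrt(3/5) limit and grows with rsig", {
  p <- biphasic_params(1, 1.35, 0.25, 2, 1.1, 0, 100, 0)
  expect_equal(guinier_radius(p), sqrt(3 / 5) * 100, tolerance = 1e-12)
  expect_equal(guinier_radius(p), 77.46, tolerance = 1e-4)
  rgs <- vapply(c(0, 0.1, 0.2, 0.3), function(s) {
    p$rsig <- s
    class(p) <- "biphasic_params"
    guinier_radius(p)
  }, numeric(1))
  expect_true(all(diff(rgs) > 0))
  # closed-form moment ratio of the log-normal: Rg = sqrt(3/5) R e^(7 s^2)
  p$rsig <- 0.2; class(p) <- "biphasic_params"
  # closed form over infinite support; the quadrature truncates at
  # +/- 5 sigma, so agreement is to ~1e-4
  expect_equal(guinier_radius(p), sqrt(3 / 5) * 100 * exp(7 * 0.04),
               tolerance = 1e-3)
})

test_that("low-Q slope of ln S vs Q^2 matches -Rg^2/3 in the Guinier window", {
  comps <- phase_compositions("Tb")
  for (rs in c(0, 0.2)) {
    p <- biphasic_params(23, 1.35, 0.25, 2.25, 1.1, 0.01, 50, rs)
    rg <- guinier_radius(p)
    q <- exp(seq(log(0.0005), log(0.65 / rg), length.out = 120))
    tm <- model_terms(p, comps, q)
    slope <- stats::coef(stats::lm(log(tm$saxs_term) ~ I(q^2)))[[2]]
    expect_equal(slope, -rg^2 / 3, tolerance = 0.01)
  }
})

test_that("parameter validation rejects unphysical sets", {
  expect_error(biphasic_params(1, 1.35, 0.6, 2, 1.1, 0.5, 100, 0.1),
               "sum")
  expect_error(biphasic_params(1, -1, 0.2, 2, 1.1, 0.1, 100, 0.1), "> 0")
  expect_error(biphasic_params(1, 1.35, 0.2, 2, 1.1, 0.1, 100, -0.1),
               "rsig")
  expect_error(biphasic_params(1, 1.35, 0.2, -2, 1.1, 0.1, 100, 0.1),
               "rmoles")
})
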