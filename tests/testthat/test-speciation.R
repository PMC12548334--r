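test_that("1:1 binding matches the closed-form quadratic example", {
  # 100 uM peptide + 100 uM metal, Kd = 1 uM -> complex = (201-sqrt(401))/2
  st <- solve_binding_1to1(100, 100, 1)
  expect_equal(st$metals$complexed, (201 - sqrt(401)) / 2,
               tolerance = 1e-12)
  expect_equal(st$free_peptide, 100 - (201 - sqrt(401)) / 2,
               tolerance = 1e-12)
  # stoichiometric limit: K -> Inf with excess metal
  tight <- solve_binding_1to1(100, 150, 1e12)
  expect_equal(tight$metals$complexed, 100, tolerance = 1e-6)
  expect_lt(tight$free_peptide, 1e-6)
  # degenerate inputs
  expect_equal(solve_binding_1to1(100, 0, 1)$metals$complexed, 0)
  expect_equal(solve_binding_1to1(100, 0, 1)$free_peptide, 100)
  expect_error(solve_binding_1to1(-1, 1, 1), ">= 0")
  expect_error(solve_binding_1to1(1, 1, 0), "> 0")
})

test_that("quadratic solver agrees with bisection to 1e-10 on 1000 draws", {
  set.seed(101)
  for (i in 1:1000) {
    p0 <- 10^runif(1, -2, 3)
    m0 <- 10^runif(1, -2, 3)
    k <- 10^runif(1, -4, 3)
    st <- solve_binding_1to1(p0, m0, k)
    # independent oracle: bisection on the equilibrium residual in the
    # complex concentration x: K (P0-x)(M0-x) - x = 0
    f <- function(x) k * (p0 - x) * (m0 - x) - x
    lo <- 0; hi <- min(p0, m0)
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    x_oracle <- (lo + hi) / 2
    expect_equal(st$metals$complexed, x_oracle,
                 tolerance = 1e-10)
    # mass balance to 1e-12 relative
    expect_lt(abs(st$free_peptide + st$metals$complexed - p0),
              1e-12 * max(p0, 1))
    expect_lt(abs(st$metals$free + st$metals$complexed - m0),
              1e-12 * max(m0, 1))
  }
})

test_that("titration curve is monotone and labels the saturation regimes", {
  ratios <- seq(0, 3, by = 0.25)
  tc <- titration_curve(100, 1, ratios)
  expect_equal(tc$free_peptide[1], 100)
  expect_true(all(diff(tc$free_metal) >= -1e-12))
  expect_true(all(diff(tc$free_peptide) <= 1e-12))
  expect_equal(tc$regime, ifelse(ratios > 1, "oversaturated",
                                 "undersaturated"))
  # the label flips exactly at ratio 1
  expect_equal(tc$regime[ratios == 1], "undersaturated")
  expect_equal(tc$regime[ratios == 1.25], "oversaturated")
})

test_that("competitive solver reduces to 1:1 and respects symmetry", {
  sys1 <- binding_system(50, data.frame(label = "Tb", total = 120,
                                        K_assoc = 0.3))
  st1 <- solve_competitive(sys1)
  ref <- solve_binding_1to1(50, 120, 0.3)
  expect_equal(st1$free_peptide, ref$free_peptide, tolerance = 1e-10)
  expect_equal(st1$metals$complexed, ref$metals$complexed,
               tolerance = 1e-10)
  # symmetric two-metal system
  sys2 <- binding_system(50, data.frame(label = c("A", "B"),
                                        total = c(100, 100),
                                        K_assoc = c(0.2, 0.2)))
  st2 <- solve_competitive(sys2)
  expect_equal(st2$metals$complexed[1], st2$metals$complexed[2],
               tolerance = 1e-12)
  # mass balances
  expect_lt(abs(st2$free_peptide + sum(st2$metals$complexed) - 50),
            1e-12 * 50)
})

test_that("dilute-excess bound ratio approaches the K ratio", {
  # weak-binding conditions: complexes deplete neither metal appreciably,
  # so complexed_A/complexed_B -> K_A/K_B (here 1.6 and 35)
  for (kr in c(1.6, 35)) {
    kb <- 1e-4
    sys <- binding_system(1, data.frame(label = c("A", "B"),
                                        total = c(10, 10),
                                        K_assoc = c(kr * kb, kb)))
    st <- solve_competitive(sys)
    expect_equal(st$metals$complexed[1] / st$metals$complexed[2], kr,
                 tolerance = 0.01)
  }
})

test_that("competitive mass balance holds across random systems", {
  set.seed(202)
  for (i in 1:50) {
    n <- sample(1:4, 1)
    sys <- binding_system(10^runif(1, -1, 2),
                          data.frame(label = letters[seq_len(n)],
                                     total = 10^runif(n, -1, 3),
                                     K_assoc = 10^runif(n, -4, 2)))
    st <- solve_competitive(sys)
    expect_lt(abs(st$free_peptide + sum(st$metals$complexed) -
                    sys$peptide_total), 1e-12 * max(sys$peptide_total, 1))
    expect_true(all(st$metals$free >= 0))
    expect_true(all(st$metals$complexed >= 0))
    for (j in seq_len(n)) {
      expect_lt(abs(st$metals$free[j] + st$metals$complexed[j] -
                      sys$metals$total[j]),
                1e-12 * max(sys$metals$total[j], 1))
    }
  }
})

test_that("Stokes-Einstein conversion matches the closed form", {
  # monomer-scale diffusion gives ~0.92 nm
  d <- hydrodynamic_diameter(5.34e-10, 298.15, 8.9e-4)
  expect_equal(d, 1.380649e-23 * 298.15 /
                 (3 * pi * 8.9e-4 * 5.34e-10) * 1e9, tolerance = 1e-12)
  expect_equal(d, 0.92, tolerance = 0.005)
  # inverse proportionality in D
  expect_equal(hydrodynamic_diameter(2.67e-10, 298.15, 8.9e-4), 2 * d,
               tolerance = 1e-9)
  expect_error(hydrodynamic_diameter(1e-10, 0, 8.9e-4), "> 0")
})

test_that("Smoluchowski zeta conversion matches the closed form", {
  z <- zeta_from_mobility(1e-8, 8.9e-4, 6.95e-10)
  expect_equal(z, 1e-8 * 8.9e-4 / 6.95e-10 * 1e3, tolerance = 1e-12)
  expect_equal(z, 12.8, tolerance = 0.01)
  expect_identical(zeta_from_mobility(0), 0)
  expect_lt(zeta_from_mobility(-1e-8), 0)
  # general Henry factor
  expect_equal(zeta_from_mobility(1e-8, 8.9e-4, 6.95e-10,
                                  henry_factor = 1.0),
               1.5 * z, tolerance = 1e-12)
  expect_error(zeta_from_mobility(1e-8, -1, 6.95e-10), "> 0")
})

test_that("Beer-Lambert conversion matches the worked numbers", {
  c_m <- concentration_from_absorbance(0.065, 1, 8250)
  expect_equal(c_m, 0.065 / 8250, tolerance = 1e-15)
  expect_equal(c_m * 1e6, 7.879, tolerance = 1e-3)
  expect_identical(concentration_from_absorbance(0, 1, 8250), 0)
  # doubling the path halves the concentration
  expect_equal(concentration_from_absorbance(0.065, 2, 8250), c_m / 2)
  expect_error(concentration_from_absorbance(0.1, 0), "> 0")
})

test_that("default association constants encode the selectivity ordering", {
  k <- default_association_constants()
  ktb <- k$K_assoc[k$label == "Tb"]
  expect_equal(ktb / k$K_assoc[k$label == "Lu"], 1.6, tolerance = 1e-12)
  expect_equal(ktb / k$K_assoc[k$label == "La"], 35, tolerance = 1e-12)
  # usable directly in a binding system
  sys <- binding_system(1e-6, data.frame(label = k$label,
                                         total = rep(1e-5, 3),
                                         K_assoc = k$K_assoc))
  st <- solve_competitive(sys)
  expect_true(all(diff(st$metals$complexed) < 0))
})

test_that("titration tables round-trip through the text writer", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tc <- titration_curve(100, 1, c(0, 0.5, 1, 2))
  write_titration(path, tc)
  back <- utils::read.table(path, header = TRUE, comment.char = "#")
  expect_equal(back$free_peptide, tc$free_peptide, tolerance = 1e-12)
  expect_equal(back$regime, tc$regime)
})
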