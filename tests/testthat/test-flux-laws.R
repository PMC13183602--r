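# Analytic flux laws: closed-form examples, limiting cases, and the
# Nernst-equilibrium / continuity properties of the GHK flux.

k <- physical_constants()

test_that("physical constants are in range and RT/F is thermal voltage", {
  expect_true(all(unlist(k[c("F", "R", "T", "Vw")]) > 0))
  expect_gt(k$RT_F, 26.5)
  expect_lt(k$RT_F, 27.0)
})

test_that("Nernst potential matches the closed form and rejects bad input", {
  expect_equal(nernst_potential(1, 10, 10), 0)
  # evaluated independently from the shipped constants
  expect_equal(nernst_potential(1, 100, 10), -(k$R * k$T / k$F) * log(10),
               tolerance = 1e-12)
  # sign symmetry for the anion with mirrored concentrations
  expect_equal(nernst_potential(-1, 10, 100), nernst_potential(1, 100, 10),
               tolerance = 1e-14)
  expect_error(nernst_potential(0, 10, 10), "valence")
  expect_error(nernst_potential(1, -1, 10), "positive")
})

test_that("GHK flux has the Fick, equilibrium, and field-free limits", {
  expect_equal(ghk_flux(1e-5, 1, 0, 10, 10), 0)
  expect_equal(ghk_flux(2e-6, 0, -70, 10, 4), 2e-6 * 6)
  # zero flux at the Nernst potential, z = +/-1, log-uniform concentrations
  set.seed(41)
  for (i in 1:50) {
    z <- sample(c(-1L, 1L), 1)
    Ci <- exp(runif(1, log(0.1), log(300)))
    Ce <- exp(runif(1, log(0.1), log(300)))
    V <- nernst_potential(z, Ci, Ce)
    expect_lt(abs(ghk_flux(1e-5, z, V, Ci, Ce)), 1e-12 * 1e-5 * Ci)
  }
})

test_that("GHK flux agrees with an independent expm1-based evaluation", {
  # same closed form, different floating-point path
  ghk_oracle <- function(P, z, V, Ci, Ce) {
    xi <- z * V / (k$R * k$T / k$F)
    P * xi * (Ci - Ce * exp(-xi)) / (-expm1(-xi))
  }
  cases <- expand.grid(z = c(-1, 1), V = c(-60, -5, 3, 80),
                       Ci = c(5, 140), Ce = c(4, 100))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    expect_equal(ghk_flux(1e-5, cs$z, cs$V, cs$Ci, cs$Ce),
                 ghk_oracle(1e-5, cs$z, cs$V, cs$Ci, cs$Ce),
                 tolerance = 1e-12)
  }
})

test_that("GHK flux is continuous and C1 across V = 0", {
  # continuity on a +/-1e-4 mV grid spanning both evaluation branches:
  # adjacent values differ by no more than slope x spacing (plus fp noise)
  V <- seq(-1e-4, 1e-4, length.out = 41)
  J <- vapply(V, function(v) ghk_flux(1e-5, 1, v, 140, 5), numeric(1))
  expect_true(all(is.finite(J)))
  slope0 <- 1e-5 * (140 + 5) / 2 / k$RT_F
  expect_lt(max(abs(diff(J))), 1.01 * slope0 * diff(V)[1] + 1e-12)
  # the small-|xi| branch agrees with the exact form at the crossover
  xi_at <- 1.0001e-6 * k$RT_F  # just outside the series branch
  xi_in <- 0.9999e-6 * k$RT_F  # just inside
  expect_equal(ghk_flux(1e-5, 1, xi_at, 140, 5),
               ghk_flux(1e-5, 1, xi_in, 140, 5), tolerance = 1e-9)
  # derivative continuity: series-branch slope at 0 matches the exact
  # branch's central-difference slope just outside the crossover
  h <- 5e-4
  d_exact <- (ghk_flux(1e-5, 1, h, 140, 5) -
                ghk_flux(1e-5, 1, -h, 140, 5)) / (2 * h)
  expect_equal(d_exact, slope0, tolerance = 1e-4)
})

test_that("pump flux has Michaelis-Menten limits and 3:2 stoichiometry", {
  act <- list(pump_Jmax = 1e-3, pump_K_Na = 15, pump_K_K = 5)
  expect_equal(unlist(nak_pump_flux(act, 0, 5)[c("J_Na_out", "J_K_in")]),
               c(J_Na_out = 0, J_K_in = 0))
  sat <- nak_pump_flux(act, 1e9, 1e9)
  expect_equal(sat$J_Na_out, 3 * act$pump_Jmax, tolerance = 1e-6)
  expect_equal(sat$J_K_in, 2 * act$pump_Jmax, tolerance = 1e-6)
  expect_equal(sat$J_Na_out / sat$J_K_in, 1.5, tolerance = 1e-12)
  # half-saturating Na with saturating K: (1/2)^3 of the maximum
  half <- nak_pump_flux(act, 15, 1e9)
  expect_equal(half$J_Na_out, 3 * act$pump_Jmax / 8, tolerance = 1e-6)
})

test_that("NHE3 exchange has equilibrium, inhibition, and sign behavior", {
  expect_equal(nhe3_flux(1e-4, 140, 14, 1e-4, 1e-5), 0)  # equal ratios
  expect_equal(nhe3_flux(0, 140, 15, 1e-4, 6e-5), 0)
  expect_gt(nhe3_flux(1e-4, 140, 15, 6e-5, 6e-5), 0)     # Na gradient drives
  expect_error(nhe3_flux(1e-4, -1, 15, 1e-4, 1e-4), "positive")
})

test_that("cotransport flux is zero at equilibrium, linear in activity,
           and sign-correct for NKCC2", {
  ci <- c(Na = 10, K = 10, Cl = 10)
  expect_equal(cotransport_flux(1e-8, c(Na = 1, K = 1, Cl = 2), ci, ci), 0)
  lum <- c(Na = 140, K = 6, Cl = 146)
  cell <- c(Na = 15, K = 130, Cl = 30)
  # sign oracle: sum of stoichiometry-weighted log ratios
  drive <- log(140 / 15) + log(6 / 130) + 2 * log(146 / 30)
  expect_gt(drive, 0)
  J1 <- cotransport_flux(1e-8, c(Na = 1, K = 1, Cl = 2), lum, cell)
  expect_gt(J1, 0)
  expect_equal(cotransport_flux(2e-8, c(Na = 1, K = 1, Cl = 2), lum, cell),
               2 * J1, tolerance = 1e-12)
  expect_error(
    cotransport_flux(1e-8, c(Na = 1, glucose = 1), lum, cell),
    "missing")
})

test_that("water flux is osmotically driven and linear", {
  expect_equal(water_flux(0.05, 290, 290), 0)
  expect_equal(water_flux(0, 200, 300), 0)
  expect_equal(water_flux(0.05, 290, 300), 10 * 0.05 * k$Vw * 1e-3)
  expect_gt(water_flux(0.05, 280, 300), 0)  # toward higher osmolarity
})
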