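# Steady-state solver: residual structure, conservation laws at the
# solution, warm-start behavior, and failure reporting.

test_that("residual vector has the documented structure and vanishes at a
           converged state", {
  for (ct in c("PCT", "mTAL")) {
    v <- cached_variant(ct, "male")
    st <- cached_baseline(ct, "male")
    r <- residuals_steady_state(v, st)
    expected_names <- c(paste0("mass_", v$solutes),
                        if (ct == "PCT") "water",
                        "electroneutrality", "current")
    expect_named(r, expected_names)
    expect_lt(max(abs(r)), 1e-10)
  }
})

test_that("baseline solutions satisfy conservation laws and the
           physiological window", {
  for (ct in c("PCT", "mTAL")) {
    for (sx in c("male", "female")) {
      st <- cached_baseline(ct, sx)
      expect_true(st$converged)
      # plausibility window
      expect_gt(st$conc[["Na"]], 10); expect_lt(st$conc[["Na"]], 25)
      expect_gt(st$conc[["K"]], 100); expect_lt(st$conc[["K"]], 145)
      expect_gt(st$Va, -90); expect_lt(st$Va, -40)
      # per-solute mass conservation: apical + source = basolateral
      fl <- transcellular_fluxes(st)
      imbalance <- fl$apical + fl$sources - fl$basolateral
      expect_lt(max(abs(imbalance)), 1e-10)
      # open circuit: transcellular + paracellular current sums to zero
      v <- cached_variant(ct, sx)
      cur <- sum(v$z * fl$basolateral) + sum(v$z * fl$paracellular)
      expect_lt(abs(cur), 1e-10)
      # cell electroneutrality
      q <- sum(v$z * st$conc) + v$cytosol_H +
        v$geometry$impermeant_valence * v$geometry$impermeant_amount / st$volume
      expect_lt(abs(q), 1e-8)
      # PCT water balance
      if (ct == "PCT") {
        expect_lt(abs(fl$Jv_apical - fl$Jv_basolateral), 1e-12)
      }
      # derived potentials
      expect_equal(st$Va, st$V_cell - st$V_lumen)
      expect_equal(st$Vb, st$V_cell)
    }
  }
})

test_that("a converged solution is a fixed point of the solver", {
  st <- cached_baseline("PCT", "male")
  again <- solve_steady_state(cached_variant("PCT", "male"),
                              initial_guess = st)
  expect_true(again$converged)
  expect_lte(again$iterations, 2)
  expect_equal(again$conc, st$conc, tolerance = 1e-10)
})

test_that("perturbing cytosolic Na changes the Na mass balance in the
           direction set by the pump slope", {
  v <- cached_variant("PCT", "male")
  st <- cached_baseline("PCT", "male")
  r0 <- residuals_steady_state(v, st)
  sts <- st
  deltas <- c(0.5, 1, 2)
  vals <- vapply(deltas, function(d) {
    sts$conc[["Na"]] <- st$conc[["Na"]] + d
    residuals_steady_state(v, sts)[["mass_Na"]]
  }, numeric(1))
  # more cytosolic Na -> more pump export -> net efflux (negative balance),
  # monotone in the perturbation
  expect_true(all(vals < r0[["mass_Na"]]))
  expect_true(all(diff(vals) < 0))
})

test_that("reducing pump activity raises cytosolic Na and lowers K", {
  for (ct in c("PCT", "mTAL")) {
    v <- cached_variant(ct, "male")
    base <- cached_baseline(ct, "male")
    pm <- apply_parameters(v, stats::setNames(c(0.75, 1, 1, 1),
                                              c("pump", setdiff(v$varied, "pump"))))
    st <- solve_steady_state(v, pm$activities, pm$membranes,
                             initial_guess = base)
    expect_true(st$converged)
    expect_gt(st$conc[["Na"]], base$conc[["Na"]])
    expect_lt(st$conc[["K"]], base$conc[["K"]])
  }
})

test_that("non-convergence yields an explicit failure object, not a wrong
           answer", {
  v <- cached_variant("PCT", "male")
  st <- suppressWarnings(
    solve_steady_state(v, max_iter = 2L))
  expect_s3_class(st, "steady_state_failure")
  expect_false(st$converged)
  expect_true(is.finite(st$residual_norm))
  expect_identical(st$iterations, 2L)
  expect_error(transcellular_fluxes(st), "converged")
})

test_that("Newton agrees with the pseudo-transient relaxation oracle on
           random parameter sets", {
  set.seed(7)
  for (ct in c("PCT", "mTAL")) {
    v <- cached_variant(ct, "male")
    for (i in 1:3) {
      frac <- stats::setNames(exp(runif(4, log(0.5), log(2))), v$varied)
      pm <- apply_parameters(v, frac)
      st <- solve_steady_state(v, pm$activities, pm$membranes)
      rx <- relax_to_steady_state(v, pm$activities, pm$membranes)
      expect_true(st$converged && rx$converged)
      expect_equal(rx$conc, st$conc, tolerance = 1e-6)
      expect_equal(rx$volume, st$volume, tolerance = 1e-6)
      expect_equal(rx$V_cell, st$V_cell, tolerance = 1e-6)
    }
  }
})
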