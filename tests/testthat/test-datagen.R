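# Designs, continuation sweeps, and dataset I/O.

test_that("grid designs are full factorials with a snake path", {
  d <- build_design(parameter_ranges("PCT"), "grid", 8)
  expect_equal(nrow(d$points), 4096)          # 8^4 full factorial
  expect_identical(colnames(d$points), varied_parameters("PCT"))
  expect_true(all(d$points >= 0.5 - 1e-12 & d$points <= 2 + 1e-12))
  # consecutive points differ in exactly one parameter by one level
  lev <- exp(seq(log(0.5), log(2), length.out = 8))
  step <- diff(log(lev))[1]
  dl <- abs(diff(log(d$points)))
  changed <- dl > 1e-12
  expect_true(all(rowSums(changed) == 1))
  expect_true(all(abs(dl[changed] - step) < 1e-9))
})

test_that("random designs are log-uniform, seeded, and reproducible", {
  d1 <- build_design(parameter_ranges("mTAL"), "random", 250, seed = 5)
  d2 <- build_design(parameter_ranges("mTAL"), "random", 250, seed = 5)
  expect_identical(d1$points, d2$points)
  d3 <- build_design(parameter_ranges("mTAL"), "random", 250, seed = 6)
  expect_false(identical(d1$points, d3$points))
  # geometric midpoint of [0.5, 2] is 1: empirical median near 1
  big <- build_design(parameter_ranges("mTAL"), "random", 4000, seed = 7)
  med <- apply(big$points, 2, stats::median)
  expect_true(all(abs(log(med)) < 0.1))
})

test_that("inhibition designs shift the named parameter as specified", {
  # NHE3 mean reduced 40%: empirical mean ~0.6 x baseline (within 2% at 250)
  d <- build_design(parameter_ranges("PCT"), "inhibition", 250, seed = 3,
                    inhibition = list(parameter = "NHE3",
                                      mean_reduction_frac = 0.40,
                                      half_width_frac = 0.2))
  expect_lt(abs(mean(d$points[, "NHE3"]) - 0.60), 0.02)
  expect_true(all(d$points[, "NHE3"] >= 0.4 & d$points[, "NHE3"] <= 0.8))
  # NKCC2 reduced 70%: all samples below the 0.5 training lower bound
  d2 <- build_design(parameter_ranges("mTAL"), "inhibition", 250, seed = 3,
                     inhibition = list(parameter = "NKCC2",
                                       mean_reduction_frac = 0.70,
                                       half_width_frac = 0.2))
  expect_true(all(d2$points[, "NKCC2"] < 0.5))
  expect_error(
    build_design(parameter_ranges("mTAL"), "inhibition", 10,
                 inhibition = list(parameter = "NHE3",
                                   mean_reduction_frac = 0.4)),
    "not among")
})

test_that("nuisance jitter adds a seeded log-uniform multiplier column", {
  d <- build_design(parameter_ranges("PCT"), "random", 500, seed = 9,
                    nuisance = list(SGLT2 = 0.10))
  expect_identical(colnames(d$nuisance), "SGLT2")
  expect_true(all(d$nuisance >= 0.9 & d$nuisance <= 1.1))
  d2 <- build_design(parameter_ranges("PCT"), "random", 500, seed = 9,
                     nuisance = list(SGLT2 = 0.10))
  expect_identical(d$nuisance, d2$nuisance)
})

test_that("a one-point all-baseline design reproduces the direct solve", {
  v <- cached_variant("mTAL", "male")
  d <- build_design(parameter_ranges("mTAL"), "random", 1, seed = 1)
  d$points[1, ] <- 1
  ds <- generate_dataset(v, d)
  st <- cached_baseline("mTAL", "male")
  expect_equal(ds$table$Na_cell, st$conc[["Na"]], tolerance = 1e-9)
  expect_equal(ds$table$Va, st$Va, tolerance = 1e-9)
  expect_equal(ds$table$J_Na, st$fluxes$basolateral[["Na"]],
               tolerance = 1e-9)
  expect_equal(ds$table$x_pump, v$activities$pump_Jmax, tolerance = 1e-12)
})

test_that("dataset generation is deterministic and fully converged", {
  ds <- cached_small_dataset("PCT", "male")
  expect_equal(nrow(ds$table), 256)
  expect_true(all(ds$table$converged))
  expect_false(ds$meta$incomplete)
  ds2 <- generate_dataset(cached_variant("PCT", "male"),
                          build_design(parameter_ranges("PCT"), "grid", 4))
  expect_identical(ds$table, ds2$table)
})

test_that("continuation needs fewer Newton iterations than cold starts on
           the same grid", {
  v <- cached_variant("PCT", "male")
  d <- build_design(parameter_ranges("PCT"), "grid", 5)
  warm <- generate_dataset(v, d)
  cold_iters <- vapply(seq_len(64), function(i) {
    pm <- apply_parameters(v, d$points[i * 9 - 8, ])
    suppressWarnings(
      solve_steady_state(v, pm$activities, pm$membranes))$iterations
  }, numeric(1))
  expect_lt(mean(warm$table$iterations), mean(cold_iters))
})

test_that("dataset CSV + JSON round trip is lossless and validated", {
  ds <- cached_small_dataset("PCT", "male")
  stem <- file.path(tempdir(), "ds_roundtrip")
  write_dataset(ds, stem)
  back <- read_dataset(stem)
  for (cn in names(ds$table)) {
    expect_equal(back$table[[cn]], ds$table[[cn]], tolerance = 1e-15)
  }
  expect_identical(back$meta$cell_type, "PCT")
  expect_equal(back$meta$n, ds$meta$n)

  # tampered row count in the sidecar is caught
  meta <- jsonlite::read_json(paste0(stem, ".json"))
  meta$n_rows <- 7
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE)
  expect_error(read_dataset(stem), "rows")

  # missing required column is named
  write_dataset(ds, stem)
  tab <- utils::read.csv(paste0(stem, ".csv"), check.names = FALSE)
  tab$Va <- NULL
  utils::write.csv(tab, paste0(stem, ".csv"), row.names = FALSE, quote = FALSE)
  expect_error(read_dataset(stem), "Va")
})

test_that("incomplete datasets are refused by write_dataset", {
  ds <- cached_small_dataset("PCT", "male")
  ds$meta$incomplete <- TRUE
  ds$meta$n_unconverged <- 3L
  expect_error(write_dataset(ds, tempfile()), "incomplete")
})

test_that("merged datasets concatenate rows and record both sexes", {
  a <- cached_small_dataset("PCT", "male")
  b <- cached_small_dataset("PCT", "female")
  m <- merge_datasets(a, b)
  expect_equal(nrow(m$table), nrow(a$table) + nrow(b$table))
  expect_identical(m$meta$sex, "male+female")
})
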