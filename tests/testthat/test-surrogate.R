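# Surrogate network: forward pass semantics, training behavior,
# serialization.

test_that("an all-zero network predicts the output-scaler mean", {
  s <- cached_quick_surrogate("PCT", "male")
  s0 <- s
  s0$W <- lapply(s$W, function(w) w * 0)
  s0$b <- lapply(s$b, function(x) x * 0)
  p <- mlp_forward(s0, matrix(c(1, 1, 1, 1), 1))
  expect_equal(unname(drop(p)), unname(s$output_scaler$mean),
               tolerance = 1e-12)
})

test_that("inference is deterministic; dropout only acts in training mode", {
  s <- cached_quick_surrogate("PCT", "male")
  x <- matrix(runif(8, 0.5, 2), 2, 4)
  expect_identical(mlp_forward(s, x), mlp_forward(s, x))
  # dropout_rate 0 in training mode equals inference
  s0 <- s
  s0$spec$dropout_rate <- 0
  expect_equal(mlp_forward(s0, x, training_mode = TRUE),
               mlp_forward(s0, x), tolerance = 1e-14)
  # with dropout, training mode is stochastic but seed-reproducible
  a <- mlp_forward(s, x, training_mode = TRUE, dropout_seed = 11)
  b <- mlp_forward(s, x, training_mode = TRUE, dropout_seed = 11)
  d <- mlp_forward(s, x, training_mode = TRUE, dropout_seed = 12)
  expect_identical(a, b)
  expect_false(identical(a, d))
  expect_error(mlp_forward(s, matrix(1, 1, 3)), "dimension")
})

test_that("training is bit-reproducible under a fixed seed", {
  ds <- cached_small_dataset("PCT", "male")
  s1 <- train_surrogate(ds, "forward", quick_config(seed = 33))
  s2 <- train_surrogate(ds, "forward", quick_config(seed = 33))
  expect_identical(s1$W, s2$W)
  expect_identical(s1$b, s2$b)
  expect_identical(s1$loss_history, s2$loss_history)
  s3 <- train_surrogate(ds, "forward", quick_config(seed = 34))
  expect_false(identical(s1$W, s3$W))
})

test_that("training reduces the test loss and records the full history", {
  s <- cached_quick_surrogate("PCT", "male")
  h <- s$loss_history
  expect_identical(h$epoch[1], 0L)
  expect_lt(min(h$test), 0.1 * h$test[1])
  expect_true(all(is.finite(h$train)) && all(is.finite(h$test)))
})

test_that("training refuses degenerate datasets", {
  ds <- cached_small_dataset("PCT", "male")
  tiny <- ds
  tiny$table <- ds$table[1:20, ]
  expect_error(train_surrogate(tiny, "forward", quick_config()), "50 rows")
  noK <- ds
  noK$table$K_cell <- NULL
  expect_error(train_surrogate(noK, "forward", quick_config()), "K_cell")
})

test_that("predict is vectorized, column-checked, and warns on
           extrapolation only via the logger", {
  s <- cached_quick_surrogate("PCT", "male")
  ds <- cached_small_dataset("PCT", "male")
  batch <- predict(s, ds$table[1:6, ])
  single <- do.call(rbind, lapply(1:6, function(i) predict(s, ds$table[i, ])))
  expect_equal(as.matrix(batch), as.matrix(single), tolerance = 1e-12)
  expect_named(batch, c("Na_cell", "K_cell", "Va", "Vb"))
  expect_error(predict(s, ds$table[, c("f_NHE3", "f_pump")]), "f_NBCe1")
  # outside the training box: finite, plausible outputs (no error)
  out <- predict(s, data.frame(f_NHE3 = 0.3, f_pump = 1, f_NBCe1 = 1,
                               f_PK_bas = 1))
  expect_true(all(is.finite(unlist(out))))
  expect_gt(out$K_cell, 50); expect_lt(out$K_cell, 200)
})

test_that("predictions on training rows are close to their targets", {
  s <- cached_quick_surrogate("PCT", "male")
  ds <- cached_small_dataset("PCT", "male")
  p <- predict(s, ds$table)
  rmse_std <- sqrt(mean(((p$Na_cell - ds$table$Na_cell) /
                           s$output_scaler$sd[["Na_cell"]])^2))
  expect_lt(rmse_std, 3 * sqrt(min(s$loss_history$test)))
})

test_that("unit changes in the targets rescale out exactly", {
  ds <- cached_small_dataset("PCT", "male")
  scaled <- ds
  for (cn in c("Na_cell", "K_cell", "Va", "Vb")) {
    scaled$table[[cn]] <- 1000 * scaled$table[[cn]]
  }
  s1 <- train_surrogate(ds, "forward", quick_config(seed = 5))
  s2 <- train_surrogate(scaled, "forward", quick_config(seed = 5))
  p1 <- as.matrix(predict(s1, ds$table[1:10, ]))
  p2 <- as.matrix(predict(s2, ds$table[1:10, ])) / 1000
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("row shuffling before training leaves validation error
           statistically unchanged", {
  ds <- cached_small_dataset("PCT", "male")
  shuf <- ds
  set.seed(99)
  shuf$table <- ds$table[sample.int(nrow(ds$table)), ]
  rownames(shuf$table) <- NULL
  s1 <- train_surrogate(ds, "forward", quick_config(seed = 8))
  s2 <- train_surrogate(shuf, "forward", quick_config(seed = 8))
  v <- cached_variant("PCT", "male")
  truth <- generate_dataset(
    v, build_design(parameter_ranges("PCT"), "random", 100, seed = 123))
  f1 <- fractional_mse(truth$table$Na_cell,
                       predict(s1, truth$table)$Na_cell)
  f2 <- fractional_mse(truth$table$Na_cell,
                       predict(s2, truth$table)$Na_cell)
  expect_lt(max(f1, f2) / min(f1, f2), 2)
})

test_that("surrogate bundles round-trip through disk at full precision", {
  s <- cached_quick_surrogate("PCT", "male")
  path <- file.path(tempdir(), "sur_bundle")
  save_surrogate(s, path)
  back <- load_surrogate(path)
  set.seed(2)
  X <- matrix(runif(400, 0.5, 2), 100, 4,
              dimnames = list(NULL, s$features))
  expect_equal(mlp_forward(back, X), mlp_forward(s, X), tolerance = 1e-12)
  expect_equal(back$loss_history, s$loss_history, tolerance = 1e-15)
  expect_identical(back$targets, s$targets)

  # manifest edited to a wrong layer size fails with a shape diagnostic
  man <- jsonlite::read_json(file.path(path, "manifest.json"),
                             simplifyVector = TRUE)
  man$layer_sizes <- c(4, 8, 16, 4)
  jsonlite::write_json(man, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns")
  expect_error(load_surrogate(path), "shape mismatch")
})
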