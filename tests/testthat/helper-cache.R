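# Shared lazily-built artifacts.  Heavy objects (training grids, trained
# surrogates, experiment tables) are built once per test run and reused
# across test files; everything is fully seeded, so cached and fresh
# objects are identical.

.nn_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .nn_cache, inherits = FALSE)) {
    assign(key, builder(), envir = .nn_cache)
  }
  get(key, envir = .nn_cache)
}

cached_variant <- function(cell_type, sex) {
  cache_get(paste("variant", cell_type, sex), function() {
    load_variant(cell_type, sex)
  })
}

cached_baseline <- function(cell_type, sex) {
  cache_get(paste("baseline", cell_type, sex), function() {
    solve_steady_state(cached_variant(cell_type, sex))
  })
}

# Full study-condition training grid (8^4 = 4096 points).
cached_grid <- function(cell_type, sex, jitter = FALSE, seed = 1L) {
  key <- paste("grid", cell_type, sex, jitter, seed)
  cache_get(key, function() {
    nuis <- if (jitter) list(SGLT2 = 0.10) else NULL
    training_grid(cell_type, sex, levels = 8, nuisance = nuis, seed = seed)
  })
}

# A small grid for cheap structural tests.
cached_small_dataset <- function(cell_type = "PCT", sex = "male") {
  cache_get(paste("small", cell_type, sex), function() {
    generate_dataset(cached_variant(cell_type, sex),
                     build_design(parameter_ranges(cell_type), "grid", 4))
  })
}

quick_config <- function(seed = 1L) {
  train_config(max_epochs = 150, patience = 50, polish_epochs = 50,
               seed = seed)
}

cached_quick_surrogate <- function(cell_type = "PCT", sex = "male",
                                   direction = "forward") {
  cache_get(paste("quick", cell_type, sex, direction), function() {
    train_surrogate(cached_small_dataset(cell_type, sex), direction,
                    quick_config())
  })
}

# Study-condition experiment results, shared between acceptance criteria.
cached_forward_matrix <- function(cell_type, seed) {
  cache_get(paste("fm", cell_type, seed), function() {
    run_forward_matrix(cell_type, seed = seed,
                       datasets = list(male = cached_grid(cell_type, "male"),
                                       female = cached_grid(cell_type, "female")))
  })
}

cached_inhibition <- function(cell_type, seed = 1L) {
  cache_get(paste("inh", cell_type, seed), function() {
    run_inhibition(cell_type, seed = seed,
                   surrogates = cached_forward_matrix(cell_type, seed)$
                     surrogates[c("male", "female")])
  })
}

cached_inverse <- function(cell_type, sex, seed) {
  cache_get(paste("inv", cell_type, sex, seed), function() {
    ds <- if (cell_type == "mTAL") cached_grid(cell_type, sex) else NULL
    run_inverse(cell_type, sex, seed = seed, dataset = ds)
  })
}

random_fractions <- function(variant, n, seed) {
  set.seed(seed)
  m <- matrix(exp(stats::runif(4 * n, log(0.5), log(2))), n, 4)
  colnames(m) <- variant$varied
  m
}
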