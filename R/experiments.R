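# One-command replication of the study design: forward sex-transfer matrix,
# transporter-inhibition extrapolation, and the inverse identifiability
# experiment.  All randomness is derived deterministically from one base
# seed; rerunning with the same seed reproduces every table bit-for-bit.

.sub_seed <- function(seed, k) (as.integer(seed) * 101L + k) %% 2000000000L

.default_inhibition <- function(cell_type) {
  if (cell_type == "PCT") {
    list(parameter = "NHE3", mean_reduction_frac = 0.40, half_width_frac = 0.2)
  } else {
    list(parameter = "NKCC2", mean_reduction_frac = 0.70, half_width_frac = 0.2)
  }
}

# SGLT2 is a fixed-baseline apical Na+ pathway competing with NHE3; in the
# PCT inverse experiment it is jittered +/-10% (log-uniform) so that NHE3 is
# partially confounded in the observables, as it is in real epithelia.
.inverse_nuisance <- function(cell_type) {
  if (cell_type == "PCT") list(SGLT2 = 0.10) else NULL
}

#' Generate (or reuse) the training grid for one cell type and sex
#'
#' Full-factorial `levels`^4 grid over the 50%-200% box, snake-ordered and
#' solved with continuation.
#'
#' @param cell_type "PCT" or "mTAL"
#' @param sex "male" or "female"
#' @param levels grid levels per parameter (default 8: 4096 samples)
#' @param nuisance optional nuisance jitter (see [build_design()])
#' @param seed design seed (only used by the nuisance jitter)
#' @return `transport_dataset`
#' @export
training_grid <- function(cell_type, sex, levels = 8, nuisance = NULL,
                          seed = 1L) {
  variant <- load_variant(cell_type, sex)
  design <- build_design(parameter_ranges(cell_type), "grid", levels,
                         seed = seed, nuisance = nuisance)
  generate_dataset(variant, design)
}

#' Forward sex-transfer experiment matrix
#'
#' Trains three forward surrogates per cell type - male-only, female-only,
#' and sex-inclusive (merged male + female) - and validates each against
#' fresh male and fresh female ground-truth samples.
#'
#' @param cell_type "PCT" or "mTAL"
#' @param seed base seed (training and validation sub-seeds derive from it)
#' @param levels training grid levels per parameter (8 = 4096 samples)
#' @param n_val validation points per cell (default 250)
#' @param config training configuration (default [train_config()])
#' @param datasets optional named list `list(male = , female = )` of
#'   pre-generated training grids (they are deterministic, so reuse is safe)
#' @return list with `table` (six-row results data.frame), `surrogates`,
#'   `datasets`, and `provenance`
#' @export
run_forward_matrix <- function(cell_type, seed = 1L, levels = 8,
                               n_val = 250, config = NULL,
                               datasets = NULL) {
  if (is.null(datasets)) {
    datasets <- list(male = training_grid(cell_type, "male", levels),
                     female = training_grid(cell_type, "female", levels))
  }
  if (is.null(config)) config <- train_config()

  cfg_with <- function(k) {
    c2 <- config; c2$seed <- .sub_seed(seed, k); c2
  }
  surrogates <- list(
    male = train_surrogate(datasets$male, "forward", cfg_with(1L)),
    female = train_surrogate(datasets$female, "forward", cfg_with(2L)),
    inclusive = train_surrogate(merge_datasets(datasets$male, datasets$female),
                                "forward", cfg_with(3L))
  )

  variants <- list(male = load_variant(cell_type, "male"),
                   female = load_variant(cell_type, "female"))
  rows <- list()
  reports <- list()
  for (tr in names(surrogates)) {
    for (va in c("male", "female")) {
      res <- validate_surrogate(surrogates[[tr]], variants[[va]],
                                n = n_val, seed = .sub_seed(seed, 10L + match(va, c("male", "female"))))
      key <- paste(tr, va, sep = "_")
      reports[[key]] <- res$metrics
      rows[[key]] <- data.frame(
        cell_type = cell_type, trained_on = tr, validated_on = va,
        fmse_aggregate = res$metrics$aggregate,
        t(res$metrics$per_output), check.names = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, surrogates = surrogates, datasets = datasets,
       reports = reports,
       provenance = list(cell_type = cell_type, seed = seed,
                         levels = levels, n_val = n_val,
                         config = unclass(config)))
}

#' Transporter-inhibition extrapolation experiment
#'
#' Validates same-sex forward surrogates on an inhibition-shifted design
#' (PCT: NHE3 mean reduced 40%; mTAL: NKCC2 mean reduced 70%; half-width
#' 0.2 x baseline) alongside the matched baseline validation, reporting
#' per-variable fractional MSE for both scenarios and the combined scatter
#' table.
#'
#' @param cell_type "PCT" or "mTAL"
#' @param spec inhibition spec (default per cell type, see Details)
#' @param seed base seed
#' @param levels,n_val,config as in [run_forward_matrix()]
#' @param surrogates optional named list `list(male = , female = )` of
#'   trained same-sex forward surrogates to reuse
#' @return list with `table` (per-sex, per-scenario, per-variable fMSE),
#'   `scatter`, `surrogates`, `provenance`
#' @export
run_inhibition <- function(cell_type, spec = NULL, seed = 1L, levels = 8,
                           n_val = 250, config = NULL, surrogates = NULL) {
  if (is.null(spec)) spec <- .default_inhibition(cell_type)
  if (is.null(config)) config <- train_config()
  if (!spec$parameter %in% varied_parameters(cell_type)) {
    stop("inhibition parameter '", spec$parameter, "' not varied in ", cell_type)
  }
  if (is.null(surrogates)) {
    surrogates <- list()
    for (sx in c("male", "female")) {
      ds <- training_grid(cell_type, sx, levels)
      c2 <- config; c2$seed <- .sub_seed(seed, match(sx, c("male", "female")))
      surrogates[[sx]] <- train_surrogate(ds, "forward", c2)
    }
  }
  rows <- list()
  scatter <- list()
  for (sx in c("male", "female")) {
    variant <- load_variant(cell_type, sx)
    base <- validate_surrogate(surrogates[[sx]], variant, n = n_val,
                               seed = .sub_seed(seed, 20L + match(sx, c("male", "female"))),
                               scenario = "baseline")
    inh <- validate_surrogate(surrogates[[sx]], variant, n = n_val,
                              seed = .sub_seed(seed, 30L + match(sx, c("male", "female"))),
                              inhibition = spec, scenario = "inhibition")
    for (sc in c("baseline", "inhibition")) {
      m <- if (sc == "baseline") base$metrics else inh$metrics
      rows[[paste(sx, sc)]] <- data.frame(
        cell_type = cell_type, sex = sx, scenario = sc,
        fmse_aggregate = m$aggregate, t(m$per_output), check.names = FALSE)
    }
    scatter[[sx]] <- rbind(base$scatter, inh$scatter)
    scatter[[sx]]$sex <- sx
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, scatter = do.call(rbind, scatter),
       surrogates = surrogates,
       provenance = list(cell_type = cell_type, inhibition = spec,
                         seed = seed, levels = levels, n_val = n_val))
}

#' Inverse identifiability experiment
#'
#' Trains an inverse surrogate (features: cytosolic Na+ and K+
#' concentrations and transcellular Na+ and K+ fluxes; targets: the four
#' transport-parameter fractions) and validates it on fresh samples,
#' reporting per-parameter fractional MSE.  For the PCT, the SGLT2 nuisance
#' pathway is jittered +/-10% in both training and validation data so that
#' apical Na+ entry is partially confounded.
#'
#' @param cell_type "PCT" or "mTAL"
#' @param sex "male" or "female"
#' @param seed base seed
#' @param levels,n_val,config as in [run_forward_matrix()]
#' @param dataset optional pre-generated training dataset
#' @return list with `table` (one row: per-parameter fMSE), `surrogate`,
#'   `dataset`, `provenance`
#' @export
run_inverse <- function(cell_type, sex, seed = 1L, levels = 8, n_val = 250,
                        config = NULL, dataset = NULL) {
  nuis <- .inverse_nuisance(cell_type)
  if (is.null(config)) config <- train_config()
  if (is.null(dataset)) {
    dataset <- training_grid(cell_type, sex, levels, nuisance = nuis,
                             seed = .sub_seed(seed, 40L))
  }
  c2 <- config; c2$seed <- .sub_seed(seed, 41L)
  surrogate <- train_surrogate(dataset, "inverse", c2)
  variant <- load_variant(cell_type, sex)
  res <- validate_surrogate(surrogate, variant, n = n_val,
                            seed = .sub_seed(seed, 42L), nuisance = nuis,
                            scenario = sprintf("%s/%s inverse", cell_type, sex))
  per <- res$metrics$per_output
  names(per) <- sub("^f_", "", names(per))
  tab <- data.frame(cell_type = cell_type, sex = sex,
                    fmse_aggregate = res$metrics$aggregate,
                    t(per), check.names = FALSE)
  rownames(tab) <- NULL
  list(table = tab, surrogate = surrogate, dataset = dataset,
       scatter = res$scatter,
       provenance = list(cell_type = cell_type, sex = sex, seed = seed,
                         levels = levels, n_val = n_val,
                         nuisance = nuis))
}

#' Run the full replication suite and write a results directory
#'
#' Runs, for both cell types: the forward sex-transfer matrix, the
#' transporter-inhibition scenario, and (PCT male/female plus mTAL
#' male/female) the inverse experiment.  Writes `datasets/`, `surrogates/`,
#' `reports/` (CSV + JSON) and `provenance.json` under `out_dir`.
#'
#' @param seed base seed for the whole suite
#' @param out_dir results directory (created if needed)
#' @param levels,n_val,config scale and training controls (defaults are the
#'   study conditions: 8^4 = 4096 training samples, 250 validation points)
#' @return invisibly, a list of all result tables
#' @export
replicate_all <- function(seed = 1L, out_dir = "results", levels = 8,
                          n_val = 250, config = NULL) {
  dir.create(file.path(out_dir, "reports"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "datasets"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "surrogates"), showWarnings = FALSE)
  results <- list()
  for (ct in c("PCT", "mTAL")) {
    fm <- run_forward_matrix(ct, seed = seed, levels = levels, n_val = n_val,
                             config = config)
    inh <- run_inhibition(ct, seed = seed, levels = levels, n_val = n_val,
                          config = config,
                          surrogates = fm$surrogates[c("male", "female")])
    results[[paste0(ct, "_forward")]] <- fm$table
    results[[paste0(ct, "_inhibition")]] <- inh$table
    utils::write.csv(fm$table,
                     file.path(out_dir, "reports", paste0(tolower(ct), "_forward_matrix.csv")),
                     row.names = FALSE)
    utils::write.csv(inh$table,
                     file.path(out_dir, "reports", paste0(tolower(ct), "_inhibition.csv")),
                     row.names = FALSE)
    utils::write.csv(inh$scatter,
                     file.path(out_dir, "reports", paste0(tolower(ct), "_inhibition_scatter.csv")),
                     row.names = FALSE)
    for (sx in c("male", "female")) {
      write_dataset(fm$datasets[[sx]],
                    file.path(out_dir, "datasets", paste0(tolower(ct), "_", sx, "_grid")))
      save_surrogate(fm$surrogates[[sx]],
                     file.path(out_dir, "surrogates", paste0(tolower(ct), "_", sx, "_forward")))
      inv <- run_inverse(ct, sx, seed = seed, levels = levels, n_val = n_val,
                         config = config)
      results[[paste(ct, sx, "inverse", sep = "_")]] <- inv$table
      utils::write.csv(inv$table,
                       file.path(out_dir, "reports",
                                 paste0(tolower(ct), "_", sx, "_inverse.csv")),
                       row.names = FALSE)
      save_surrogate(inv$surrogate,
                     file.path(out_dir, "surrogates",
                               paste0(tolower(ct), "_", sx, "_inverse")))
    }
    save_surrogate(fm$surrogates$inclusive,
                   file.path(out_dir, "surrogates", paste0(tolower(ct), "_inclusive_forward")))
  }
  all_json <- lapply(results, function(t) t)
  jsonlite::write_json(all_json, file.path(out_dir, "reports", "all_tables.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(seed = seed, levels = levels, n_val = n_val,
                            version = as.character(utils::packageVersion("nephroNN")),
                            created = format(Sys.time(), tz = "UTC", usetz = TRUE)),
                       file.path(out_dir, "provenance.json"), auto_unbox = TRUE)
  invisible(results)
}
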