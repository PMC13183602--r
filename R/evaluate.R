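# The validation metric and ground-truth validation runs.

#' Fractional mean square error (percent)
#'
#' A scale-free squared-error metric:
#'   100 * sum((predicted - actual)^2) / sum(actual^2).
#' It is invariant under joint rescaling of both vectors (unit changes) and
#' robust to individual near-zero entries.
#'
#' @param actual,predicted numeric vectors of equal length (>= 1)
#' @return percent error (scalar >= 0)
#' @export
#' @examples
#' fractional_mse(c(1, 2, 3), c(1, 2, 3))        # 0
#' fractional_mse(c(1, 2, 3), 1.1 * c(1, 2, 3))  # 1
fractional_mse <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 1) {
    stop("fractional_mse: vectors must have equal length >= 1")
  }
  denom <- sum(actual^2)
  if (denom == 0) stop("fractional_mse: actual values are all zero")
  100 * sum((predicted - actual)^2) / denom
}

.metrics_report <- function(actual, predicted, direction, scenario, n) {
  per <- vapply(colnames(actual), function(cn) {
    fractional_mse(actual[, cn], predicted[, cn])
  }, numeric(1))
  structure(list(
    per_output = per,
    aggregate = mean(per),
    n_samples = n,
    direction = direction,
    scenario = scenario
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s / %s (n = %d)\n", x$direction,
              x$scenario, x$n_samples))
  cat("  per-output fMSE (%): ",
      paste(sprintf("%s=%.3g", names(x$per_output), x$per_output),
            collapse = ", "), "\n")
  cat(sprintf("  aggregate fMSE: %.3g%%\n", x$aggregate))
  invisible(x)
}

#' Validate a surrogate against fresh mechanistic ground truth
#'
#' Builds a fresh design (random by default, or an inhibition design),
#' solves it with the mechanistic model, predicts with the surrogate, and
#' reports per-variable and aggregate fractional MSE plus the paired
#' (actual, predicted) scatter table.  Ground-truth rows that fail to
#' converge are excluded and counted; more than 5% unconverged rows aborts
#' the validation (that indicates a solver regression, not a surrogate
#' property).
#'
#' @param surrogate a `trained_surrogate`
#' @param variant the `model_variant` providing ground truth
#' @param n validation points (default 250)
#' @param seed design seed
#' @param inhibition optional inhibition spec passed to [build_design()]
#' @param nuisance optional nuisance jitter passed to [build_design()]
#' @param scenario label recorded in the report
#' @return list with `metrics` (a `metrics_report`) and `scatter`
#'   (long data.frame: variable, actual, predicted, scenario)
#' @export
validate_surrogate <- function(surrogate, variant, n = 250, seed = 1L,
                               inhibition = NULL, nuisance = NULL,
                               scenario = NULL) {
  mode <- if (is.null(inhibition)) "random" else "inhibition"
  if (is.null(scenario)) {
    scenario <- sprintf("%s/%s %s", variant$cell_type, variant$sex, mode)
  }
  design <- build_design(parameter_ranges(variant$cell_type), mode, n,
                         seed = seed, inhibition = inhibition,
                         nuisance = nuisance)
  truth <- generate_dataset(variant, design)
  tab <- truth$table
  bad <- !tab$converged
  if (mean(bad) > 0.05) {
    stop(sprintf("validation aborted: %.1f%% of ground-truth rows unconverged",
                 100 * mean(bad)))
  }
  tab <- tab[!bad, , drop = FALSE]

  pred <- predict(surrogate, tab)
  actual <- as.matrix(tab[, surrogate$targets, drop = FALSE])
  predicted <- as.matrix(pred)

  metrics <- .metrics_report(actual, predicted, surrogate$direction,
                             scenario, nrow(tab))
  metrics$n_excluded <- sum(bad)
  scatter <- do.call(rbind, lapply(surrogate$targets, function(cn) {
    data.frame(variable = cn, actual = actual[, cn],
               predicted = predicted[, cn], scenario = scenario,
               row.names = NULL)
  }))
  list(metrics = metrics, scatter = scatter, truth = truth)
}
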