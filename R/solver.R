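#' Assemble the scaled steady-state residual vector
#'
#' Evaluates, in fixed order, (a) one mass-balance residual per solute
#' (apical influx + intracellular source - basolateral efflux), (b) the water
#' balance Jv_apical - Jv_basolateral (water-permeable variants only),
#' (c) cell electroneutrality, and (d) the open-circuit condition (total
#' transcellular plus paracellular current from lumen to interstitium).
#' Residuals are scaled: mass balances by the baseline pump turnover
#' (3 x Jmax), the water balance by the osmotic flux of a 1 mM gradient,
#' electroneutrality by 1 mM, and current by F times the reference flux, so
#' a single tolerance is meaningful across equations.
#'
#' @param variant a `model_variant`
#' @param state list with `conc` (named, mM), `volume` (cm^3/cm^2),
#'   `V_cell`, `V_lumen` (mV); e.g. a `steady_state` object
#' @param activities,membranes optional overrides of the variant baselines
#' @return named residual vector
#' @export
residuals_steady_state <- function(variant, state, activities = NULL,
                                   membranes = NULL) {
  fns <- .make_model_fns(variant, activities, membranes)
  u <- fns$pack(unname(state$conc[variant$solutes]), state$volume,
                state$V_cell, state$V_lumen)
  r <- fns$residual(u)
  names(r) <- c(paste0("mass_", variant$solutes),
                if (fns$water) "water",
                "electroneutrality", "current")
  r
}

#' Solve the steady state of an epithelial cell variant
#'
#' Damped Newton iteration on transformed unknowns (log concentrations, log
#' volume for water-permeable variants, raw potentials) with a forward
#' finite-difference Jacobian and backtracking line search, until the scaled
#' residual infinity-norm falls below `tol` or `max_iter` iterations.
#'
#' On success returns a `steady_state` object carrying the cytosolic
#' composition, cell volume, membrane potentials (Va = V_cell - V_lumen,
#' Vb = V_cell, both relative to the interstitium at 0 mV) and the attached
#' flux record.  On failure returns a `steady_state_failure` object carrying
#' the last iterate, residual norm and iteration count - never a silent
#' wrong answer.
#'
#' @param variant a `model_variant`
#' @param activities,membranes optional overrides (e.g. from
#'   [apply_parameters()]); defaults are the variant baselines
#' @param initial_guess optional list with `conc`, `volume`, `V_cell`,
#'   `V_lumen` (e.g. a previous `steady_state`); default is the shipped
#'   cold-start guess
#' @param tol scaled residual infinity-norm tolerance (default 1e-10)
#' @param max_iter maximum Newton iterations (default 50)
#' @return `steady_state` or `steady_state_failure`
#' @export
solve_steady_state <- function(variant, activities = NULL, membranes = NULL,
                               initial_guess = NULL, tol = 1e-10,
                               max_iter = 50L) {
  fns <- .make_model_fns(variant, activities, membranes)
  guess <- if (is.null(initial_guess)) .cold_start(variant) else initial_guess
  conc <- unname(guess$conc[variant$solutes])
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop("initial guess concentrations must be positive and finite")
  }
  u <- fns$pack(conc, guess$volume, guess$V_cell, guess$V_lumen)

  n <- fns$n_unknown
  r <- fns$residual(u)
  rnorm <- max(abs(r))
  rmerit <- sqrt(sum(r^2))   # line-search merit: l2 norm
  iter <- 0L
  ok <- rnorm < tol

  while (!ok && iter < max_iter) {
    iter <- iter + 1L
    # forward finite-difference Jacobian, relative step 1e-7
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      h <- 1e-7 * max(abs(u[j]), 1)
      uj <- u
      uj[j] <- uj[j] + h
      J[, j] <- (fns$residual(uj) - r) / h
    }
    du <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(du) || any(!is.finite(du))) {
      return(.solve_failure(variant, fns, u, rnorm, iter,
                            "singular Jacobian"))
    }
    # full step, then a second-order correction (the algebraic constraints
    # are tightly scaled, so a plain Newton step can violate them at second
    # order even very close to the solution), then backtracking: halve up
    # to 20 times on merit increase
    accepted <- FALSE
    r_full <- tryCatch(fns$residual(u + du), error = function(e) NULL)
    if (!is.null(r_full) && all(is.finite(r_full))) {
      if (sqrt(sum(r_full^2)) < rmerit) {
        u <- u + du; r <- r_full
        rnorm <- max(abs(r)); rmerit <- sqrt(sum(r^2))
        accepted <- TRUE
      } else {
        dc <- tryCatch(solve(J, -r_full), error = function(e) NULL)
        if (!is.null(dc) && all(is.finite(dc)) &&
            sqrt(sum(dc^2)) < sqrt(sum(du^2))) {
          r_soc <- tryCatch(fns$residual(u + du + dc), error = function(e) NULL)
          if (!is.null(r_soc) && all(is.finite(r_soc)) &&
              sqrt(sum(r_soc^2)) < rmerit) {
            u <- u + du + dc; r <- r_soc
            rnorm <- max(abs(r)); rmerit <- sqrt(sum(r^2))
            accepted <- TRUE
          }
        }
      }
    }
    if (!accepted) {
      lambda <- 0.5
      for (k in seq_len(20L)) {
        u_try <- u + lambda * du
        r_try <- tryCatch(fns$residual(u_try), error = function(e) NULL)
        if (!is.null(r_try) && all(is.finite(r_try)) &&
            sqrt(sum(r_try^2)) < rmerit) {
          u <- u_try; r <- r_try
          rnorm <- max(abs(r)); rmerit <- sqrt(sum(r^2))
          accepted <- TRUE
          break
        }
        lambda <- lambda / 2
      }
    }
    if (!accepted) {
      return(.solve_failure(variant, fns, u, rnorm, iter,
                            "line search stalled"))
    }
    ok <- rnorm < tol
  }

  if (!ok) {
    return(.solve_failure(variant, fns, u, rnorm, iter, "max iterations"))
  }

  s <- fns$unpack(u)
  .nn_log(sprintf("solve %s/%s: converged in %d iters, |r|=%.2e",
                  variant$cell_type, variant$sex, iter, rnorm))
  .make_steady_state(variant, fns, s, iter, rnorm)
}

.make_steady_state <- function(variant, fns, s, iter, rnorm) {
  conc <- stats::setNames(s$conc, variant$solutes)
  fl <- fns$fluxes(s$conc, s$vol, s$V_cell, s$V_lumen)
  flux_record <- list(
    apical = stats::setNames(fl$apical, variant$solutes),
    basolateral = stats::setNames(fl$basolateral, variant$solutes),
    paracellular = stats::setNames(fl$paracellular, variant$solutes),
    sources = stats::setNames(fl$sources, variant$solutes),
    Jv_apical = fl$Jv_apical,
    Jv_basolateral = fl$Jv_basolateral,
    pump_rate = fl$pump_rate
  )
  structure(list(
    conc = conc,
    volume = s$vol,
    V_cell = s$V_cell,
    V_lumen = s$V_lumen,
    Va = s$V_cell - s$V_lumen,
    Vb = s$V_cell,
    fluxes = flux_record,
    converged = TRUE,
    iterations = iter,
    residual_norm = rnorm,
    cell_type = variant$cell_type,
    sex = variant$sex
  ), class = "steady_state")
}

.solve_failure <- function(variant, fns, u, rnorm, iter, reason) {
  s <- fns$unpack(u)
  .nn_log(sprintf("solve %s/%s FAILED (%s) after %d iters, |r|=%.2e",
                  variant$cell_type, variant$sex, reason, iter, rnorm),
          warn = TRUE)
  structure(list(
    conc = stats::setNames(s$conc, variant$solutes),
    volume = s$vol, V_cell = s$V_cell, V_lumen = s$V_lumen,
    converged = FALSE, iterations = iter, residual_norm = rnorm,
    reason = reason,
    cell_type = variant$cell_type, sex = variant$sex
  ), class = c("steady_state_failure", "steady_state"))
}

#' @export
print.steady_state <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat(sprintf("<steady_state: NOT CONVERGED (%s), |r|=%.2e after %d iters>\n",
                x$reason, x$residual_norm, x$iterations))
    return(invisible(x))
  }
  cat(sprintf("<steady_state> %s/%s  (%d Newton iters, |r|=%.1e)\n",
              x$cell_type, x$sex, x$iterations, x$residual_norm))
  cat("  cytosol [mM]: ",
      paste(sprintf("%s=%.2f", names(x$conc), x$conc), collapse = ", "), "\n")
  cat(sprintf("  Va=%.2f mV, Vb=%.2f mV, V_lumen=%.3f mV, vol=%.4g cm\n",
              x$Va, x$Vb, x$V_lumen, x$volume))
  invisible(x)
}

#' Per-solute flux record of a converged steady state
#'
#' Reports apical (lumen to cell), basolateral (= transcellular, at steady
#' state; cell to interstitium) and paracellular (lumen to interstitium)
#' fluxes per solute, intracellular source rates, and water fluxes.
#'
#' @param state a converged `steady_state`
#' @return the flux record (list; see [solve_steady_state()])
#' @export
transcellular_fluxes <- function(state) {
  if (!inherits(state, "steady_state") || !isTRUE(state$converged)) {
    stop("transcellular_fluxes: state is not a converged steady_state")
  }
  state$fluxes
}

.nn_log <- function(msg, warn = FALSE) {
  if (warn) {
    warning(msg, call. = FALSE)
  } else if (isTRUE(getOption("nephroNN.verbose", FALSE))) {
    message("[nephroNN] ", msg)
  }
  invisible(NULL)
}
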