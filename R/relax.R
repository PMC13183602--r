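#' Pseudo-transient relaxation to steady state (test oracle)
#'
#' Integrates the cell's solute amounts (and, for water-permeable variants,
#' the cell volume) forward in time with explicit Euler steps, resolving the
#' two potentials algebraically at every step by an inner 2-variable Newton
#' iteration that enforces (i) zero net charge accumulation in the cell and
#' (ii) the open-circuit condition.  Because charge accumulation is zeroed
#' exactly at each step, cell electroneutrality is preserved along the
#' trajectory.  Integration stops when the scaled state change per unit time
#' falls below `rate_tol`.  On numerical instability the step is halved and
#' the integration restarted, up to 10 times.
#'
#' This routine shares no machinery with the Newton solver's iteration and
#' serves as its independent oracle in the test suite; it is not a
#' user-facing simulation feature.
#'
#' @param variant a `model_variant`
#' @param activities,membranes optional overrides of the variant baselines
#' @param dt Euler time step, s
#' @param t_end maximum integrated time, s
#' @param rate_tol scaled rate-of-change tolerance (default 1e-12)
#' @return a `steady_state`-like list (conc, volume, V_cell, V_lumen, Va, Vb,
#'   converged flag, time integrated)
#' @export
relax_to_steady_state <- function(variant, activities = NULL,
                                  membranes = NULL, dt = 2, t_end = 40000,
                                  rate_tol = 1e-12) {
  if (dt <= 0) stop("dt must be positive")
  fns <- .make_model_fns(variant, activities, membranes)
  ns <- fns$ns
  z <- fns$z
  H_C <- fns$H_C

  for (attempt in seq_len(10L)) {
    res <- .relax_run(variant, fns, ns, z, H_C, dt, t_end, rate_tol)
    if (!is.null(res)) return(res)
    dt <- dt / 2
  }
  stop("relax_to_steady_state: unstable even after 10 step halvings")
}

.relax_run <- function(variant, fns, ns, z, H_C, dt, t_end, rate_tol) {
  cs <- .cold_start(variant)
  conc <- unname(cs$conc[variant$solutes])
  vol <- cs$volume
  # project the start onto the electroneutral manifold by adjusting Cl-
  iCl <- match("Cl", variant$solutes)
  conc[iCl] <- conc[iCl] +
    sum(z * conc) + H_C + fns$z_imp * fns$N_imp / vol
  if (conc[iCl] <= 0) stop("cold start cannot be made electroneutral")
  N <- conc * vol
  V_cell <- cs$V_cell
  V_lumen <- cs$V_lumen

  t <- 0
  nstep <- 0L
  repeat {
    conc <- N / vol
    if (any(!is.finite(conc)) || any(conc <= 0)) return(NULL)

    pots <- .resolve_potentials(fns, conc, vol, V_cell, V_lumen, z, H_C)
    if (is.null(pots)) return(NULL)
    V_cell <- pots$V_cell
    V_lumen <- pots$V_lumen
    fl <- pots$fl

    dN <- fl$apical + fl$sources - fl$basolateral
    dvol <- if (fns$water) fl$Jv_apical - fl$Jv_basolateral else 0

    rate <- max(abs(dN) / fns$ref_flux,
                if (fns$water) abs(dvol) / (fns$vol0 * 1e-3) else 0)
    if (!is.finite(rate)) return(NULL)
    if (rate < rate_tol || t >= t_end) {
      s <- list(conc = conc, vol = vol, V_cell = V_cell, V_lumen = V_lumen)
      out <- .make_steady_state(variant, fns, s, nstep,
                                max(abs(fns$residual(
                                  fns$pack(conc, vol, V_cell, V_lumen)))))
      out$converged <- rate < rate_tol
      out$time <- t
      out$method <- "relaxation"
      return(out)
    }

    N <- N + dt * dN
    if (any(N <= 0)) return(NULL)
    vol <- vol + dt * dvol
    if (vol <= 0) return(NULL)
    t <- t + dt
    nstep <- nstep + 1L
  }
}

# Inner 2-variable Newton: find (V_cell, V_lumen) such that
#   g1 = sum_k z_k dN_k/dt + C_H * dvol/dt = 0   (no charge accumulation)
#   g2 = F (sum_k z_k J_bl,k + sum_k z_k J_pc,k) = 0  (open circuit)
.resolve_potentials <- function(fns, conc, vol, V_cell, V_lumen, z, H_C,
                                tol = 1e-12, max_iter = 30L) {
  g <- function(vc, vl) {
    fl <- fns$fluxes(conc, vol, vc, vl)
    dN <- fl$apical + fl$sources - fl$basolateral
    dvol <- if (fns$water) fl$Jv_apical - fl$Jv_basolateral else 0
    list(val = c(sum(z * dN) + H_C * dvol,
                 sum(z * fl$basolateral) + sum(z * fl$paracellular)) /
           fns$ref_flux,
         fl = fl)
  }
  cur <- g(V_cell, V_lumen)
  for (it in seq_len(max_iter)) {
    if (max(abs(cur$val)) < tol) {
      return(list(V_cell = V_cell, V_lumen = V_lumen, fl = cur$fl))
    }
    h <- 1e-6
    g1 <- g(V_cell + h, V_lumen)$val
    g2 <- g(V_cell, V_lumen + h)$val
    J <- cbind((g1 - cur$val) / h, (g2 - cur$val) / h)
    dv <- tryCatch(solve(J, -cur$val), error = function(e) NULL)
    if (is.null(dv) || any(!is.finite(dv))) return(NULL)
    # dampen huge potential jumps
    step <- max(abs(dv))
    if (step > 50) dv <- dv * (50 / step)
    V_cell <- V_cell + dv[1]
    V_lumen <- V_lumen + dv[2]
    cur <- g(V_cell, V_lumen)
  }
  if (max(abs(cur$val)) < 1e-8) {
    return(list(V_cell = V_cell, V_lumen = V_lumen, fl = cur$fl))
  }
  NULL
}
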