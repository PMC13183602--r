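# Core steady-state machinery: flux assembly, scaled residuals, state
# packing.  The solver works on transformed unknowns (log concentrations,
# log volume, raw potentials) so positivity is guaranteed.
#
# Sign conventions (documented in the vignette): all potentials are relative
# to the interstitium (= 0 mV); fluxes are positive in the reabsorptive
# direction, i.e. apical lumen->cell, basolateral cell->interstitium,
# paracellular lumen->interstitium.

# Vectorised GHK over a solute vector (V scalar, z/P/C vectors).
.ghk_vec <- function(P, z, V, Ci, Ce, RT_F) {
  out <- P * (Ci - Ce)          # z == 0 (pure diffusion) default
  ion <- z != 0
  if (any(ion)) {
    xi <- z[ion] * V / RT_F
    small <- abs(xi) < 1e-6
    gi <- numeric(sum(ion))
    if (any(!small)) {
      em <- exp(-xi[!small])
      gi[!small] <- P[ion][!small] * xi[!small] *
        (Ci[ion][!small] - Ce[ion][!small] * em) / (1 - em)
    }
    if (any(small)) {
      gi[small] <- P[ion][small] * (Ci[ion][small] - Ce[ion][small]) +
        P[ion][small] * xi[small] * (Ci[ion][small] + Ce[ion][small]) / 2
    }
    out[ion] <- gi
  }
  out
}

# Build fast closures for one (variant, activities, membranes) combination.
# Returns residual(u), fluxes(conc, vol, V_cell, V_lumen), and helpers for
# packing/unpacking the unknown vector.
.make_model_fns <- function(variant, activities = NULL, membranes = NULL,
                            constants = physical_constants()) {
  if (is.null(activities)) activities <- variant$activities
  if (is.null(membranes)) membranes <- variant$membranes

  solutes <- variant$solutes
  ns <- length(solutes)
  z <- unname(variant$z)
  RT_F <- constants$RT_F
  RT <- constants$RT
  Fd <- constants$F
  Vw3 <- constants$Vw * 1e-3

  CL <- unname(variant$lumen$conc)
  CI <- unname(variant$interstitium$conc)
  H_L <- variant$lumen$H
  H_I <- variant$interstitium$H
  H_C <- variant$cytosol_H
  osm_L <- .compartment_osm(variant$lumen)
  osm_I <- .compartment_osm(variant$interstitium)

  P_ap <- unname(membranes$apical$P)
  P_bl <- unname(membranes$basolateral$P)
  P_pc <- unname(membranes$paracellular$P)
  Pf_ap <- membranes$apical$Pf
  Pf_bl <- membranes$basolateral$Pf

  x_NHE3 <- activities$x_NHE3
  x_SGLT2 <- activities$x_SGLT2
  x_NBCe1 <- activities$x_NBCe1
  x_NKCC2 <- activities$x_NKCC2
  pump_Jmax <- activities$pump_Jmax
  pump_K_Na <- activities$pump_K_Na
  pump_K_K <- activities$pump_K_K

  N_imp <- variant$geometry$impermeant_amount
  z_imp <- variant$geometry$impermeant_valence
  vol0 <- variant$geometry$volume
  water <- variant$water_permeable

  iNa <- match("Na", solutes)
  iK <- match("K", solutes)
  iCl <- match("Cl", solutes)
  iHCO3 <- match("HCO3", solutes)
  iGlc <- match("glucose", solutes)
  is_pct <- variant$cell_type == "PCT"

  # residual scaling (see vignette): mass balances by the baseline pump
  # turnover 3*Jmax, electroneutrality by 1 mM, current by F*ref_flux,
  # water balance by the osmotic flux a 1 mM gradient would drive.
  ref_flux <- 3 * variant$activities$pump_Jmax
  ref_Jv <- max(Pf_ap + Pf_bl, 1e-12) * Vw3 * 1

  n_unknown <- ns + 2L + as.integer(water)

  fluxes <- function(conc, vol, V_cell, V_lumen) {
    Va <- V_lumen - V_cell        # lumen minus cell (side i = lumen)
    J_ap <- .ghk_vec(P_ap, z, Va, CL, conc, RT_F)
    J_bl <- .ghk_vec(P_bl, z, V_cell, conc, CI, RT_F)
    J_pc <- .ghk_vec(P_pc, z, V_lumen, CL, CI, RT_F)
    src <- numeric(ns)

    J_nhe3 <- 0
    if (is_pct) {
      if (x_NHE3 > 0) {
        J_nhe3 <- x_NHE3 * (CL[iNa] * H_C - conc[iNa] * H_L) /
          ((CL[iNa] + conc[iNa]) * (H_L + H_C))
        J_ap[iNa] <- J_ap[iNa] + J_nhe3
        src[iHCO3] <- src[iHCO3] + J_nhe3   # CO2 hydration, H+ exported
      }
      if (x_SGLT2 > 0) {
        dmu <- RT * (log(CL[iNa] / conc[iNa]) + log(CL[iGlc] / conc[iGlc])) +
          1 * Fd * Va
        Js <- x_SGLT2 * dmu
        J_ap[iNa] <- J_ap[iNa] + Js
        J_ap[iGlc] <- J_ap[iGlc] + Js
      }
      if (x_NBCe1 > 0) {
        dmu <- RT * (log(conc[iNa] / CI[iNa]) +
                     3 * log(conc[iHCO3] / CI[iHCO3])) +
          (-2) * Fd * V_cell
        Jb <- x_NBCe1 * dmu
        J_bl[iNa] <- J_bl[iNa] + Jb
        J_bl[iHCO3] <- J_bl[iHCO3] + 3 * Jb
      }
    } else if (x_NKCC2 > 0) {
      dmu <- RT * (log(CL[iNa] / conc[iNa]) + log(CL[iK] / conc[iK]) +
                   2 * log(CL[iCl] / conc[iCl]))
      Jn <- x_NKCC2 * dmu
      J_ap[iNa] <- J_ap[iNa] + Jn
      J_ap[iK] <- J_ap[iK] + Jn
      J_ap[iCl] <- J_ap[iCl] + 2 * Jn
    }

    fNa <- (conc[iNa] / (conc[iNa] + pump_K_Na))^3
    fK <- (CI[iK] / (CI[iK] + pump_K_K))^2
    r <- pump_Jmax * fNa * fK
    J_bl[iNa] <- J_bl[iNa] + 3 * r
    J_bl[iK] <- J_bl[iK] - 2 * r

    osm_C <- sum(conc) + H_C + N_imp / vol
    Jv_a <- if (water) Pf_ap * Vw3 * (osm_C - osm_L) else 0
    Jv_b <- if (water) Pf_bl * Vw3 * (osm_I - osm_C) else 0

    list(apical = J_ap, basolateral = J_bl, paracellular = J_pc,
         sources = src, Jv_apical = Jv_a, Jv_basolateral = Jv_b,
         pump_rate = r, J_NHE3 = J_nhe3, osm_cell = osm_C)
  }

  unpack <- function(u) {
    conc <- exp(u[seq_len(ns)])
    if (water) {
      vol <- exp(u[ns + 1L])
      V_cell <- u[ns + 2L]
      V_lumen <- u[ns + 3L]
    } else {
      vol <- vol0
      V_cell <- u[ns + 1L]
      V_lumen <- u[ns + 2L]
    }
    list(conc = conc, vol = vol, V_cell = V_cell, V_lumen = V_lumen)
  }

  pack <- function(conc, vol, V_cell, V_lumen) {
    if (water) c(log(conc), log(vol), V_cell, V_lumen)
    else c(log(conc), V_cell, V_lumen)
  }

  residual <- function(u) {
    s <- unpack(u)
    fl <- fluxes(s$conc, s$vol, s$V_cell, s$V_lumen)
    mass <- (fl$apical + fl$sources - fl$basolateral) / ref_flux
    electro <- (sum(z * s$conc) + H_C + z_imp * N_imp / s$vol) / 1
    current <- (sum(z * fl$basolateral) + sum(z * fl$paracellular)) * Fd /
      (Fd * ref_flux)
    if (water) {
      wat <- (fl$Jv_apical - fl$Jv_basolateral) / ref_Jv
      res <- c(mass, wat, electro, current)
    } else {
      res <- c(mass, electro, current)
    }
    if (any(!is.finite(res))) {
      stop("non-finite residual component at u = ",
           paste(signif(u, 4), collapse = ", "))
    }
    res
  }

  list(residual = residual, fluxes = fluxes, unpack = unpack, pack = pack,
       n_unknown = n_unknown, ns = ns, z = z, ref_flux = ref_flux,
       vol0 = vol0, water = water, solutes = solutes,
       H_C = H_C, N_imp = N_imp, z_imp = z_imp, Fd = Fd)
}

# Shipped cold-start guess: interstitial composition with Na/K swapped toward
# typical cytosolic values, Cl lowered, baseline volume, V_cell -70 mV,
# V_lumen -1 mV.
.cold_start <- function(variant) {
  conc <- variant$interstitium$conc
  conc[["Na"]] <- 15
  conc[["K"]] <- 130
  conc[["Cl"]] <- 30
  if ("HCO3" %in% names(conc)) conc[["HCO3"]] <- 12
  if ("glucose" %in% names(conc)) conc[["glucose"]] <- 1
  list(conc = conc, volume = variant$geometry$volume,
       V_cell = -70, V_lumen = -1)
}
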