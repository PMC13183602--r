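#' Nernst equilibrium potential
#'
#' Potential (side i relative to side e) at which the electrochemical driving
#' force on an ion vanishes: (RT/zF) ln(C_e / C_i), in mV.
#'
#' @param z ion valence (nonzero integer)
#' @param C_in,C_out concentrations on the inner (i) and outer (e) side, mM
#' @param constants result of [physical_constants()]
#' @return equilibrium potential in mV
#' @export
#' @examples
#' nernst_potential(1, 10, 10)            # 0
#' nernst_potential(1, 100, 10)           # about -61.5 mV at 310 K
nernst_potential <- function(z, C_in, C_out, constants = physical_constants()) {
  if (any(z == 0)) stop("nernst_potential: valence z must be nonzero")
  if (any(C_in <= 0) || any(C_out <= 0)) {
    stop("nernst_potential: concentrations must be positive")
  }
  constants$RT_F / z * log(C_out / C_in)
}

#' Goldman-Hodgkin-Katz electrodiffusive flux
#'
#' Constant-field flux of an ion across a membrane. Positive flux is from
#' side i to side e; V is the potential of side i minus side e (mV).
#' With xi = zFV/RT:
#'   J = P * xi * (C_i - C_e * exp(-xi)) / (1 - exp(-xi)).
#' Near xi = 0 the regular (Fick + linear field) expansion
#'   J = P * (C_i - C_e) + P * xi * (C_i + C_e) / 2
#' is used so the flux is finite and C1-continuous across V = 0.  A neutral
#' species (z = 0) reduces to pure diffusion P * (C_i - C_e).
#'
#' @param P permeability, cm/s (>= 0)
#' @param z valence (integer, may be 0)
#' @param V membrane potential, side i minus side e, mV
#' @param C_i,C_e concentrations (mM) on sides i and e
#' @param constants result of [physical_constants()]
#' @return flux in mM cm/s (positive i to e)
#' @export
ghk_flux <- function(P, z, V, C_i, C_e, constants = physical_constants()) {
  if (any(P < 0)) stop("ghk_flux: permeability must be nonnegative")
  if (any(C_i <= 0) || any(C_e <= 0)) {
    stop("ghk_flux: concentrations must be positive")
  }
  if (z == 0) return(P * (C_i - C_e))
  xi <- z * V / constants$RT_F
  small <- abs(xi) < 1e-6
  if (all(small)) {
    P * (C_i - C_e) + P * xi * (C_i + C_e) / 2
  } else if (!any(small)) {
    em <- exp(-xi)
    P * xi * (C_i - C_e * em) / (1 - em)
  } else {
    out <- numeric(length(xi))
    em <- exp(-xi[!small])
    out[!small] <- P * xi[!small] * (C_i - C_e * em) / (1 - em)
    out[small] <- P * (C_i - C_e) + P * xi[small] * (C_i + C_e) / 2
    out
  }
}

#' Na+/K+-ATPase pump flux
#'
#' Michaelis-Menten cycle kinetics with cubic intracellular Na and squared
#' extracellular K saturation; each cycle exports 3 Na+ and imports 2 K+.
#'
#' @param act transporter activity list with \code{pump_Jmax},
#'   \code{pump_K_Na}, \code{pump_K_K}
#' @param C_Na_cell cytosolic Na+ (mM)
#' @param C_K_ext extracellular (interstitial) K+ (mM)
#' @return list with \code{J_Na_out} (= 3r), \code{J_K_in} (= 2r) and the
#'   cycle rate \code{r}
#' @export
nak_pump_flux <- function(act, C_Na_cell, C_K_ext) {
  if (any(C_Na_cell < 0) || any(C_K_ext < 0)) {
    stop("nak_pump_flux: concentrations must be nonnegative")
  }
  fNa <- (C_Na_cell / (C_Na_cell + act$pump_K_Na))^3
  fK <- (C_K_ext / (C_K_ext + act$pump_K_K))^2
  r <- act$pump_Jmax * fNa * fK
  list(J_Na_out = 3 * r, J_K_in = 2 * r, r = r)
}

#' NHE3 Na+/H+ exchange flux
#'
#' Symmetric mass-action antiport: 1 Na+ inward for 1 H+ outward,
#' electroneutral.  Positive flux = Na+ from lumen to cell (and H+ from cell
#' to lumen).
#'
#' @param x activity coefficient (>= 0)
#' @param C_Na_L,C_Na_C luminal / cytosolic Na+ (mM)
#' @param C_H_L,C_H_C luminal / cytosolic H+ (mM)
#' @return exchange flux
#' @export
nhe3_flux <- function(x, C_Na_L, C_Na_C, C_H_L, C_H_C) {
  if (any(c(C_Na_L, C_Na_C, C_H_L, C_H_C) <= 0)) {
    stop("nhe3_flux: concentrations must be positive")
  }
  x * (C_Na_L * C_H_C - C_Na_C * C_H_L) /
    ((C_Na_L + C_Na_C) * (C_H_L + C_H_C))
}

#' Linear thermodynamic cotransporter flux
#'
#' Cycle flux proportional to the net electrochemical driving force
#'   dmu = sum_k s_k RT ln(C_k,i / C_k,e) + z_net F V   (mJ/mmol),
#' J = x * dmu, positive from side i to side e.  Per-solute fluxes are
#' s_k * J.  Used for NKCC2 (apical, {Na 1, K 1, Cl 2}, z_net 0), NBCe1
#' (basolateral, {Na 1, HCO3 3}, z_net -2) and SGLT2 (apical,
#' {Na 1, glucose 1}, z_net +1).
#'
#' @param x activity (flux per unit driving force)
#' @param stoich named integer vector, solute name -> stoichiometry
#' @param conc_i,conc_e named concentration vectors (mM) for sides i and e;
#'   must contain every name in \code{stoich}
#' @param z_net net charge translocated per cycle
#' @param V membrane potential, side i minus side e (mV)
#' @param constants result of [physical_constants()]
#' @return cycle flux (multiply by stoichiometry for per-solute fluxes)
#' @export
cotransport_flux <- function(x, stoich, conc_i, conc_e, z_net = 0, V = 0,
                             constants = physical_constants()) {
  nm <- names(stoich)
  if (is.null(nm) || !all(nm %in% names(conc_i)) || !all(nm %in% names(conc_e))) {
    stop("cotransport_flux: stoichiometric solute missing from a compartment: ",
         paste(setdiff(nm, intersect(names(conc_i), names(conc_e))), collapse = ", "))
  }
  ci <- conc_i[nm]; ce <- conc_e[nm]
  if (any(ci <= 0) || any(ce <= 0)) {
    stop("cotransport_flux: concentrations must be positive")
  }
  dmu <- sum(stoich * constants$RT * log(ci / ce)) + z_net * constants$F * V
  x * dmu
}

#' Osmotic water flux
#'
#' Jv = Pf * Vw * (osm_e - osm_i) * 1e-3, in cm/s, positive from side i to
#' side e (water moves toward the higher osmolarity).  The 1e-3 converts
#' mOsm (mM) to mmol/cm^3.
#'
#' @param Pf osmotic water permeability, cm/s (>= 0)
#' @param osm_i,osm_e osmolarities (mOsm = mM) on sides i and e
#' @param constants result of [physical_constants()]
#' @return volume flux in cm/s
#' @export
water_flux <- function(Pf, osm_i, osm_e, constants = physical_constants()) {
  if (any(Pf < 0)) stop("water_flux: Pf must be nonnegative")
  Pf * constants$Vw * 1e-3 * (osm_e - osm_i)
}
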