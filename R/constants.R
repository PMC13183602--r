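#' Physical constants for epithelial transport calculations
#'
#' Returns the constants used throughout the flux laws and the steady-state
#' solver, in units chosen so that membrane potentials are in mV,
#' concentrations in mM, and chemical potentials in mJ/mmol:
#' \itemize{
#'   \item \code{F}: Faraday constant, 96.485 C/mmol (so F x V(mV) is mJ/mmol)
#'   \item \code{R}: gas constant, 8.314 mJ/(mmol K)
#'   \item \code{T}: absolute temperature, K (default 310 K, body temperature)
#'   \item \code{Vw}: partial molar volume of water, 0.018 cm^3/mmol
#' }
#' At 310 K, RT/F is about 26.7 mV.
#'
#' Concentrations are carried in mM throughout the package and passive fluxes
#' are P x C products (permeability cm/s times mM); the constant factor
#' converting mM to mmol/cm^3 is absorbed into that convention, as is usual in
#' epithelial cell models.  Osmotic water fluxes therefore include an explicit
#' 1e-3 factor so that Jv = Pf * Vw * dOsm(mM) comes out in cm/s.
#'
#' @param temperature absolute temperature in K
#' @return list with elements \code{F}, \code{R}, \code{T}, \code{Vw},
#'   \code{RT} (= R*T, mJ/mmol) and \code{RT_F} (= RT/F, mV)
#' @export
#' @examples
#' k <- physical_constants()
#' k$RT_F  # ~26.7 mV at 310 K
physical_constants <- function(temperature = 310) {
  stopifnot(temperature > 0)
  F_ <- 96.485        # C/mmol
  R_ <- 8.314         # mJ/(mmol K)
  list(
    F = F_,
    R = R_,
    T = temperature,
    Vw = 0.018,       # cm^3/mmol
    RT = R_ * temperature,
    RT_F = R_ * temperature / F_
  )
}
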