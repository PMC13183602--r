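#!/usr/bin/env Rscript
# Calibration script: writes the shipped variant configurations
# (inst/config/*.yaml).  Baseline permeabilities and transporter activities
# were tuned once so that each variant's baseline steady state lands in the
# physiological plausibility window (cytosolic Na 10-25 mM, K 100-145 mM,
# Va -90 to -40 mV); the resulting values are frozen here.  Female variants
# are derived from the male baselines by the multiplicative sex factors.
#
# Run from the repository root:  Rscript scripts/make_configs.R

pH_conc <- function(pH) 10^(-pH) * 1e3   # mM

balance_compartment <- function(conc, pH, target_osm = NULL) {
  # impermeant anion (z = -1) closes the charge balance; a neutral osmolyte
  # optionally tops osmolarity up to target_osm
  z <- c(Na = 1, K = 1, Cl = -1, HCO3 = -1, glucose = 0)
  H <- pH_conc(pH)
  q <- sum(z[names(conc)] * conc) + H
  if (q < 0) stop("net negative charge; impermeant anion cannot close it")
  imp <- q
  osm <- sum(conc) + H + imp
  neutral <- 0
  if (!is.null(target_osm)) {
    if (target_osm < osm) stop("target osmolarity below ionic osmolarity")
    neutral <- target_osm - osm
  }
  list(concentrations = as.list(conc), H_concentration = H,
       impermeant_conc = imp, impermeant_valence = -1L,
       neutral_osm = neutral)
}

make_female <- function(cfg, factors) {
  f <- cfg
  for (nm in names(factors)) {
    fac <- factors[[nm]]
    switch(nm,
      NHE3 = { f$activities$x_NHE3 <- f$activities$x_NHE3 * fac },
      NKCC2 = { f$activities$x_NKCC2 <- f$activities$x_NKCC2 * fac },
      NBCe1 = { f$activities$x_NBCe1 <- f$activities$x_NBCe1 * fac },
      pump = { f$activities$pump_Jmax <- f$activities$pump_Jmax * fac },
      PK_api = { f$membranes$apical$permeabilities$K <-
                   f$membranes$apical$permeabilities$K * fac },
      PK_bas = { f$membranes$basolateral$permeabilities$K <-
                   f$membranes$basolateral$permeabilities$K * fac }
    )
  }
  f$sex_factors <- factors
  f
}

## ---- PCT -------------------------------------------------------------
pct_lumen <- c(Na = 140, K = 5, Cl = 113, HCO3 = 25, glucose = 5)
pct_inter <- c(Na = 140, K = 5, Cl = 113, HCO3 = 25, glucose = 5)
lum <- balance_compartment(pct_lumen, pH = 6.8)
osm_target <- sum(pct_lumen) + pH_conc(6.8) + lum$impermeant_conc

pct_male <- list(
  cell_type = "PCT", sex = "male",
  water_permeable = TRUE,
  cytosol_H = pH_conc(7.2),
  lumen = balance_compartment(pct_lumen, pH = 6.8),
  interstitium = balance_compartment(pct_inter, pH = 7.4,
                                     target_osm = osm_target),
  membranes = list(
    apical = list(
      permeabilities = list(Na = 2e-8, K = 2e-6, Cl = 1e-8,
                            HCO3 = 1e-8, glucose = 1e-8),
      Pf = 0.05),
    basolateral = list(
      permeabilities = list(Na = 2e-8, K = 4e-6, Cl = 1e-6,
                            HCO3 = 3e-6, glucose = 1e-5),
      Pf = 0.05),
    paracellular = list(
      permeabilities = list(Na = 1e-6, K = 1e-6, Cl = 1e-6,
                            HCO3 = 0, glucose = 0),
      Pf = 0)
  ),
  activities = list(
    x_NHE3 = 3e-4, x_SGLT2 = 1.5e-8, x_NBCe1 = 1e-8, x_NKCC2 = 0,
    pump_Jmax = 1.15e-3, pump_K_Na = 15, pump_K_K = 5
  ),
  geometry = list(volume = 1e-3, impermeant_amount = 0.103,
                  impermeant_valence = -1L)
)

pct_female_factors <- list(NHE3 = 0.70, pump = 0.85, NBCe1 = 0.85,
                           PK_bas = 1.0)

## ---- mTAL ------------------------------------------------------------
mtal_lumen <- c(Na = 140, K = 6, Cl = 146)
mtal_inter <- c(Na = 140, K = 5, Cl = 145)

mtal_male <- list(
  cell_type = "mTAL", sex = "male",
  water_permeable = FALSE,
  cytosol_H = pH_conc(7.2),
  lumen = balance_compartment(mtal_lumen, pH = 7.0),
  interstitium = balance_compartment(mtal_inter, pH = 7.4),
  membranes = list(
    apical = list(
      permeabilities = list(Na = 1e-8, K = 3e-6, Cl = 1e-8),
      Pf = 0),
    basolateral = list(
      permeabilities = list(Na = 2e-8, K = 5e-6, Cl = 4e-6),
      Pf = 0),
    paracellular = list(
      permeabilities = list(Na = 4e-7, K = 4e-7, Cl = 2e-7),
      Pf = 0)
  ),
  activities = list(
    x_NHE3 = 0, x_SGLT2 = 0, x_NBCe1 = 0, x_NKCC2 = 1.8e-8,
    pump_Jmax = 1.2e-3, pump_K_Na = 15, pump_K_K = 5
  ),
  geometry = list(volume = 5e-4, impermeant_amount = 0.0575,
                  impermeant_valence = -1L)
)

mtal_female_factors <- list(NKCC2 = 1.15, pump = 0.90, PK_api = 1.10,
                            PK_bas = 0.90)

## ---- write -----------------------------------------------------------
out_dir <- file.path("inst", "config")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
write_cfg <- function(cfg, name) {
  yaml::write_yaml(cfg, file.path(out_dir, name), precision = 17)
  cat("wrote", file.path(out_dir, name), "\n")
}

write_cfg(pct_male, "pct_male.yaml")
pm_f <- make_female(pct_male, pct_female_factors); pm_f$sex <- "female"
write_cfg(pm_f, "pct_female.yaml")
write_cfg(mtal_male, "mtal_male.yaml")
mt_f <- make_female(mtal_male, mtal_female_factors); mt_f$sex <- "female"
write_cfg(mt_f, "mtal_female.yaml")
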