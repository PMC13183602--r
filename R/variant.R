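#' @keywords internal
"_PACKAGE"

# Solute valences for the two reduced variants.
.solute_z <- c(Na = 1, K = 1, Cl = -1, HCO3 = -1, glucose = 0)

.pct_solutes <- c("Na", "K", "Cl", "HCO3", "glucose")
.mtal_solutes <- c("Na", "K", "Cl")

# Names of the four varied transport parameters per cell type, in dataset
# column order.
.varied_params <- list(
  PCT = c("NHE3", "pump", "NBCe1", "PK_bas"),
  mTAL = c("NKCC2", "pump", "PK_api", "PK_bas")
)

#' Varied transport parameters of a cell-type variant
#'
#' @param cell_type "PCT" or "mTAL"
#' @return character vector of the four varied parameter names
#' @export
varied_parameters <- function(cell_type) {
  .varied_params[[match.arg(cell_type, names(.varied_params))]]
}

.compartment_from_config <- function(cfg, solutes) {
  conc <- unlist(cfg$concentrations)
  missing <- setdiff(solutes, names(conc))
  if (length(missing) > 0) {
    stop("compartment is missing solute concentration(s): ",
         paste(missing, collapse = ", "))
  }
  comp <- list(
    conc = conc[solutes],
    H = cfg$H_concentration,
    potential = if (is.null(cfg$potential)) 0 else cfg$potential,
    impermeant_conc = if (is.null(cfg$impermeant_conc)) 0 else cfg$impermeant_conc,
    impermeant_valence = if (is.null(cfg$impermeant_valence)) -1L else cfg$impermeant_valence,
    neutral_osm = if (is.null(cfg$neutral_osm)) 0 else cfg$neutral_osm
  )
  if (any(comp$conc <= 0) || comp$H <= 0) {
    stop("compartment concentrations and H+ must be positive")
  }
  comp
}

.compartment_charge <- function(comp, z) {
  sum(z[names(comp$conc)] * comp$conc) + comp$H +
    comp$impermeant_valence * comp$impermeant_conc
}

.compartment_osm <- function(comp) {
  sum(comp$conc) + comp$H + comp$impermeant_conc + comp$neutral_osm
}

.membrane_from_config <- function(cfg, solutes) {
  P <- unlist(cfg$permeabilities)
  missing <- setdiff(solutes, names(P))
  if (length(missing) > 0) {
    stop("membrane is missing permeability for: ", paste(missing, collapse = ", "))
  }
  if (any(P < 0)) stop("permeabilities must be nonnegative")
  Pf <- if (is.null(cfg$Pf)) 0 else cfg$Pf
  if (Pf < 0) stop("Pf must be nonnegative")
  list(P = P[solutes], Pf = Pf)
}

#' Load a cell-type x sex model variant
#'
#' Reads one of the shipped YAML configurations (or a user-supplied file) and
#' returns a fully validated `model_variant` object: solute set, boundary
#' compositions, membrane permeabilities, transporter activities, and cell
#' geometry.  Both the lumen and the interstitium must be electroneutral
#' (including their fixed impermeant anions) to within 1e-9 mM-equivalents.
#'
#' @param cell_type "PCT" (5 solutes: Na, K, Cl, HCO3, glucose) or
#'   "mTAL" (3 solutes: Na, K, Cl)
#' @param sex "male" or "female"
#' @param path optional path to a YAML variant configuration; default is the
#'   configuration shipped with the package
#' @return object of class `model_variant`
#' @export
load_variant <- function(cell_type = c("PCT", "mTAL"),
                         sex = c("male", "female"),
                         path = NULL) {
  cell_type <- match.arg(cell_type)
  sex <- match.arg(sex)
  if (is.null(path)) {
    fname <- sprintf("%s_%s.yaml", tolower(cell_type), sex)
    path <- system.file("config", fname, package = "nephroNN")
    if (path == "") stop("shipped config not found: ", fname)
  }
  cfg <- yaml::read_yaml(path)
  solutes <- if (cell_type == "PCT") .pct_solutes else .mtal_solutes
  z <- .solute_z[solutes]

  lumen <- .compartment_from_config(cfg$lumen, solutes)
  interstitium <- .compartment_from_config(cfg$interstitium, solutes)
  for (nm in c("lumen", "interstitium")) {
    comp <- if (nm == "lumen") lumen else interstitium
    q <- .compartment_charge(comp, .solute_z)
    if (abs(q) > 1e-9) {
      stop(sprintf("%s composition not electroneutral (net charge %.3g mM)", nm, q))
    }
  }

  membranes <- list(
    apical = .membrane_from_config(cfg$membranes$apical, solutes),
    basolateral = .membrane_from_config(cfg$membranes$basolateral, solutes),
    paracellular = .membrane_from_config(cfg$membranes$paracellular, solutes)
  )
  if (membranes$paracellular$Pf != 0) {
    stop("paracellular water permeability must be 0")
  }

  act <- cfg$activities
  activities <- list(
    x_NHE3 = act$x_NHE3 %||% 0,
    x_SGLT2 = act$x_SGLT2 %||% 0,
    x_NBCe1 = act$x_NBCe1 %||% 0,
    x_NKCC2 = act$x_NKCC2 %||% 0,
    pump_Jmax = act$pump_Jmax,
    pump_K_Na = act$pump_K_Na,
    pump_K_K = act$pump_K_K
  )
  if (any(unlist(activities) < 0)) stop("transporter activities must be nonnegative")
  if (cell_type == "PCT" && activities$x_NKCC2 != 0) {
    stop("x_NKCC2 must be 0 in the PCT variant")
  }
  if (cell_type == "mTAL" &&
      (activities$x_NHE3 != 0 || activities$x_SGLT2 != 0 || activities$x_NBCe1 != 0)) {
    stop("NHE3/SGLT2/NBCe1 activities must be 0 in the mTAL variant")
  }

  geometry <- list(
    volume = cfg$geometry$volume,
    impermeant_amount = cfg$geometry$impermeant_amount,
    impermeant_valence = cfg$geometry$impermeant_valence %||% -1L
  )
  if (geometry$volume <= 0 || geometry$impermeant_amount <= 0) {
    stop("cell volume and impermeant amount must be positive")
  }
  if (geometry$impermeant_valence >= 0) {
    stop("intracellular impermeant valence must be negative")
  }

  v <- structure(list(
    cell_type = cell_type,
    sex = sex,
    solutes = solutes,
    z = z,
    lumen = lumen,
    interstitium = interstitium,
    membranes = membranes,
    activities = activities,
    geometry = geometry,
    cytosol_H = cfg$cytosol_H,
    water_permeable = isTRUE(cfg$water_permeable),
    varied = varied_parameters(cell_type),
    sex_factors = cfg$sex_factors %||% list()
  ), class = "model_variant")
  if (v$cytosol_H <= 0) stop("clamped cytosolic H+ must be positive")
  if (cell_type == "PCT" && !v$water_permeable) {
    stop("PCT variant must be water permeable")
  }
  if (cell_type == "mTAL" && v$water_permeable) {
    stop("mTAL variant is water impermeable")
  }
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.model_variant <- function(x, ...) {
  cat(sprintf("<model_variant> %s (%s): %d solutes [%s]\n",
              x$cell_type, x$sex, length(x$solutes),
              paste(x$solutes, collapse = ", ")))
  cat(sprintf("  varied parameters: %s\n", paste(x$varied, collapse = ", ")))
  invisible(x)
}

#' Apply multiplicative parameter fractions to a variant
#'
#' Scales the variant's four varied transport parameters (and optionally the
#' SGLT2 nuisance activity) by the given fractions of baseline, returning the
#' modified activities and membranes.
#'
#' @param variant a `model_variant`
#' @param frac named numeric vector; names must be among the variant's varied
#'   parameters (plus optionally "SGLT2" for the PCT)
#' @return list with elements `activities` and `membranes`
#' @export
apply_parameters <- function(variant, frac) {
  act <- variant$activities
  mem <- variant$membranes
  allowed <- c(variant$varied, if (variant$cell_type == "PCT") "SGLT2")
  bad <- setdiff(names(frac), allowed)
  if (length(bad) > 0) {
    stop("unknown parameter(s) for ", variant$cell_type, ": ",
         paste(bad, collapse = ", "))
  }
  if (any(frac <= 0)) stop("parameter fractions must be positive")
  for (nm in names(frac)) {
    f <- frac[[nm]]
    switch(nm,
      NHE3 = { act$x_NHE3 <- act$x_NHE3 * f },
      NKCC2 = { act$x_NKCC2 <- act$x_NKCC2 * f },
      NBCe1 = { act$x_NBCe1 <- act$x_NBCe1 * f },
      SGLT2 = { act$x_SGLT2 <- act$x_SGLT2 * f },
      pump = { act$pump_Jmax <- act$pump_Jmax * f },
      PK_api = { mem$apical$P[["K"]] <- mem$apical$P[["K"]] * f },
      PK_bas = { mem$basolateral$P[["K"]] <- mem$basolateral$P[["K"]] * f }
    )
  }
  list(activities = act, membranes = mem)
}

#' Absolute values of the varied parameters at given fractions
#'
#' @param variant a `model_variant`
#' @param frac named fractions (variant's varied parameters)
#' @return named numeric vector of absolute parameter values
#' @export
absolute_parameters <- function(variant, frac = NULL) {
  base <- c(
    NHE3 = variant$activities$x_NHE3,
    NKCC2 = variant$activities$x_NKCC2,
    NBCe1 = variant$activities$x_NBCe1,
    pump = variant$activities$pump_Jmax,
    PK_api = unname(variant$membranes$apical$P[["K"]]),
    PK_bas = unname(variant$membranes$basolateral$P[["K"]])
  )[variant$varied]
  if (is.null(frac)) base else base * unlist(frac)[variant$varied]
}
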