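---
title: "Neural-network surrogates for renal epithelial transport: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural-network surrogates for renal epithelial transport: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`nephroNN` couples a reduced mechanistic steady-state model of a renal
epithelial cell to small feed-forward neural networks that learn the map
from membrane transport parameters to the cellular steady state (the
*forward* surrogate) and the map from measurable observables back to
transport parameters (the *inverse* surrogate). Two cell types are shipped:
a proximal convoluted tubule (PCT) cell and a medullary thick ascending
limb (mTAL) cell, each in a male and a female variant. The package's
experiment drivers replicate a complete study design: sex-specific,
cross-sex and sex-inclusive training/validation, transporter-inhibition
extrapolation, and inverse parameter identifiability.

# The reduced cell model

## Compartments, solutes, and unknowns

The cell exchanges water and solutes with two bath compartments of known
composition, the tubular lumen and the interstitium, through three
pathways: the apical membrane, the basolateral membrane, and a paracellular
shunt. The lateral intercellular space is not represented; the paracellular
pathway connects lumen and interstitium directly. This is a deliberately
reduced model: its purpose is to provide a smooth, stiff, electroneutral
steady-state map with the physiologically named transporters, not to
reproduce any published parameterization.

The PCT variant carries five solutes (Na+, K+, Cl-, HCO3-, glucose), an
osmotically driven water flux (so cell volume is an unknown), and four
transporters: the apical Na+/H+ exchanger NHE3, the apical Na+-glucose
cotransporter SGLT2, the basolateral Na+-3HCO3- cotransporter NBCe1, and
the basolateral Na+/K+-ATPase. The mTAL variant carries three solutes
(Na+, K+, Cl-), is water-impermeable (fixed volume), and transports through
the apical Na+-K+-2Cl- cotransporter NKCC2 plus the pump. pH is clamped in
every compartment (acid-base chemistry is out of scope); protons enter only
through the NHE3 driving force, and NHE3's H+ secretion is balanced by an
equal intracellular HCO3- production (CO2 hydration with the proton
exported), which keeps the PCT bicarbonate budget well posed.

Unknowns are the cytosolic concentrations, the cell volume (PCT only), and
two potentials: the cell potential `V_cell` and the lumen potential
`V_lumen`, both relative to the interstitium at 0 mV. The reported membrane
potentials are `Va = V_cell - V_lumen` (apical) and `Vb = V_cell`
(basolateral); the sign convention for Va (cell minus lumen) is fixed and
documented here because conventions differ between papers. Fluxes are
positive in the reabsorptive direction (lumen to cell, cell to
interstitium, lumen to interstitium).

## Flux laws

* Passive ion fluxes follow the Goldman-Hodgkin-Katz constant-field
  equation; neutral solutes reduce to Fick diffusion. Near zero potential
  the regular series limit is used so the flux is finite and C1-continuous.
* The Na+/K+-ATPase follows Michaelis-Menten cycle kinetics with cubic
  intracellular-Na and squared extracellular-K saturation
  (3 Na+ out : 2 K+ in per cycle). Defaults: half-saturation 15 mM (Na),
  5 mM (K).
* NHE3 is a symmetric mass-action 1:1 antiporter (electroneutral).
* NKCC2, NBCe1 and SGLT2 use a linear nonequilibrium-thermodynamic form:
  cycle flux = activity x electrochemical driving force, with the net
  translocated charge (0, -2, +1 cycles respectively) feeling the relevant
  membrane potential. These forms are standard, smooth, and
  thermodynamically sign-correct; the exact kinetics of the published
  full models are out of scope.
* Water crosses water-permeable membranes at
  `Jv = Pf * Vw * (osm_e - osm_i)` toward higher osmolarity.

Concentrations are carried in mM throughout and passive fluxes are P x C
products (the constant mM-to-mmol/cm^3 factor is absorbed into this
convention, as is usual in epithelial models); all balance equations use
the same convention, so it cancels everywhere except the osmotic water
flux, where the factor appears explicitly.

## Governing system and solver

At steady state the model imposes, in fixed order: one mass balance per
solute (apical influx + intracellular source - basolateral efflux), the
water balance (PCT), cell electroneutrality including the fixed
intracellular impermeant anion, and the open-circuit condition (zero total
transcellular-plus-paracellular current). Residuals are scaled so that one
tolerance is meaningful across equations: mass balances by the baseline
pump turnover (3 x Jmax), the water balance by the osmotic flux a 1 mM
gradient would drive, electroneutrality by 1 mM, and current by F times the
reference flux.

The solver is a damped Newton iteration on transformed unknowns - log
concentrations and log volume (guaranteeing positivity) with raw
potentials - using a forward finite-difference Jacobian (relative step
1e-7), to a scaled residual infinity-norm below 1e-10 within 50 iterations.
The line search tries the full step first; if the merit (residual l2 norm)
increases, a second-order correction step is attempted before backtracking
by halving (up to 20 times). The correction step matters here: the
algebraic constraints are scaled much more tightly than the mass balances,
so a plain Newton step violates them at second order even very close to
the solution, and without the correction the damping loop would crawl.
With it, a warm-started solve takes 2-7 iterations. Non-convergence returns
an explicit failure object carrying the last iterate and residual norm,
never a silent wrong answer.

The cold-start guess is the interstitial composition with Na+/K+ swapped
toward typical cytosolic values (Na 15, K 130 mM), Cl- lowered, baseline
volume, `V_cell` -70 mV and `V_lumen` -1 mV. It converges for every
shipped variant and, empirically, for the entire 50%-200% parameter box.

## The relaxation oracle

`relax_to_steady_state()` integrates the solute amounts (and volume)
forward in time with explicit Euler steps; at every step the two potentials
are resolved algebraically by an inner two-variable Newton iteration that
enforces zero net charge accumulation and the open-circuit condition, which
preserves electroneutrality exactly along the trajectory. The step halves
and the integration restarts on instability (up to 10 times). This routine
shares no machinery with the Newton path and exists as its independent
test oracle; the two agree to better than 1e-6 relative (typically 1e-10)
across random parameter sets. It is not a user-facing transient simulator.

## Baseline parameterization and calibration

Boundary compositions are physiologically plausible defaults (PCT lumen and
interstitium: Na 140, K 5, Cl 113, HCO3 25, glucose 5 mM; mTAL lumen
Na 140, K 6, Cl 146; interstitium Na 140, K 5, Cl 145 mM), closed to exact
electroneutrality by a fixed impermeant anion and, where needed, topped up
by a neutral osmolyte; they are not taken from any published model. Luminal,
cytosolic and interstitial pH are clamped at 6.8, 7.2 and 7.4.

The membrane permeabilities and transporter activities shipped in
`inst/config/*.yaml` were calibrated once, by the included
`scripts/make_configs.R`, against two targets and then frozen: (i) each
variant's baseline solution lies in the physiological plausibility window
(cytosolic Na 10-25 mM, K 100-145 mM, Va between -90 and -40 mV), and
(ii) the reduced model expresses the qualitative identifiability structure
expected of the real epithelium - the pump dominates the Na+/K+ observables,
NHE3 is partially confounded by the competing SGLT2 pathway, and NBCe1 is
compensated through the bicarbonate budget. Two calibration choices deserve
comment. The basolateral HCO3- permeability is kept small relative to
NBCe1's carriage, which pins the NBCe1 flux to the NHE3-driven bicarbonate
production; this is exactly the compensation that makes NBCe1 activity
unrecoverable from Na+/K+ observables. The apical K+ permeability is
sizable, so the K+ budget inherits the (unobserved) SGLT2-driven potential
fluctuations, which limits how precisely the basolateral K+ permeability
can be inferred.

Sex differences are multiplicative factors on the baselines, configurable
per variant: female PCT {NHE3 x0.70, pump x0.85, NBCe1 x0.85, basolateral
P_K x1.0}; female mTAL {NKCC2 x1.15, pump x0.90, apical P_K x1.10,
basolateral P_K x0.90}. The magnitudes are placeholders sized to produce a
measurable cross-sex surrogate error; they are not literature estimates.

# Datasets and designs

Training data are full-factorial grids with 8 log-spaced levels per
parameter over 50%-200% of baseline (4096 samples), ordered along a snake
path so that consecutive solves differ in exactly one parameter by one
level. Each solve is warm-started from its neighbor (continuation); on
failure the generator falls back to the nearest already-solved point, the
cold start, and finally the relaxation oracle. In practice the full grids
converge at every point for every variant. Validation designs draw 250
points log-uniformly over the same box (log-uniform because the range is
multiplicative and symmetric in log space). Inhibition designs draw the
named parameter uniformly on [mean - 0.2, mean + 0.2] x baseline with the
mean reduced by the stated fraction (40% for PCT NHE3, 70% for mTAL NKCC2 -
the latter lies entirely below the training box), other parameters kept at
their training distributions. The distribution family is a design choice;
only the mean reductions are prescribed.

Datasets store both the parameter fractions and the absolute values, the
solved outputs (cytosolic Na+ and K+, Va, Vb, transcellular Na+ and K+
fluxes), convergence flags and solver iterations, plus a JSON metadata
sidecar; CSV round trips are lossless.

# The surrogate

The network is a 4-16-16-4 multilayer perceptron with rectifier hidden
units and dropout 0.1 on hidden activations during training (inverted
scaling; inference is deterministic). Inputs and outputs are standardized
with training-split statistics, and the loss is the mean squared error on
standardized targets, so mM and mV outputs contribute comparably. Training
uses an 80:20 train-test split, Adam (learning rate 1e-3, batch 64, up to
2000 epochs), early stopping with patience 100 restoring the
best-test-loss weights, a step learning-rate decay (x0.5 every 250
epochs), and a final 200-epoch polish phase in which dropout is annealed
off at the decayed rate. The polish phase is a deliberate addition: in this
reduced model the surrogate's errors are orders of magnitude smaller than
in a full-complexity model, and the weight jitter that dropout leaves on
the late-training plateau would otherwise dominate the per-target errors
and scramble fine comparisons between them; annealing settles the weights
while dropout still regularizes the main phase. Everything - split,
initialization, shuffling, dropout masks - derives from one seed, so
identical seeds give bit-identical weights.

Forward surrogates map the four parameter *fractions of the sex-specific
baseline* to (cytosolic Na+, K+, Va, Vb). Fractions, rather than absolute
values, are the features because the study design varies 50%-200% of each
sex's own baseline; with fraction features the male and female maps are
genuinely different functions, which is what makes cross-sex validation
informative. The price is that a sex-inclusive network sees conflicting
targets at identical inputs and learns a compromise: its error lands well
below cross-sex error (the pattern the experiments assert) but above the
(very small) same-sex error, more so than in the original full-model
setting. Inverse surrogates use the same architecture with features
(cytosolic Na+, K+, transcellular Na+ and K+ fluxes) and the four parameter
fractions as targets.

Surrogate bundles serialize to a `manifest.json` plus a flat full-precision
`weights.csv`; loading reproduces predictions to 1e-12.

# Experiments and the error metric

Prediction error is the fractional mean square error,
`100 * sum((pred - actual)^2) / sum(actual^2)`, per output variable;
aggregate values are the arithmetic mean over the four outputs. This
definition is scale-free and robust to near-zero individual entries; it is
one reasonable reading of a "fractional MSE (%)" and other normalizations
(e.g. by centered variance) would give different absolute numbers.
Ground-truth rows that fail to converge are excluded and counted; more than
5% of them aborts the validation as a solver regression.

`run_forward_matrix()` trains male, female, and sex-inclusive forward
surrogates per cell type and validates each against fresh male and female
samples (a six-row table). `run_inhibition()` validates the same-sex
surrogates under the inhibition designs alongside matched baselines and
emits the per-variable table plus scatter pairs. `run_inverse()` trains and
validates the inverse surrogate; in the PCT the SGLT2 activity is jittered
+/-10% (log-uniform, seeded) in both training and validation data, so that
apical Na+ entry is partially confounded, as it is in a real cell where
SGLT2 abundance is not known exactly. `replicate_all()` runs the whole
suite from one seed into a results directory (`datasets/`, `surrogates/`,
`reports/`, `provenance.json`).

Experiments run at the study conditions by default: 4096-sample training
grids and 250-point validations. At these sizes the full replication suite
completes in a few minutes on one CPU.

# What the synthetic data do and do not show

The mechanistic sweep data emulate a clean laboratory of the model itself:
noiseless steady states on a smooth manifold, every parameter combination
solvable. Real data differ in ways these experiments cannot probe:
measurement noise, unmodeled solutes and regulation (acid-base chemistry,
ammonia, phosphate, flow-dependent transport), and inter-animal
variability. Consequences worth keeping in mind:

* Surrogate errors here are far smaller than would be reported against a
  15-solute model or against experiments; only orderings and bounds are
  meaningful, not absolute error magnitudes.
* The apical membrane potential in this reduced PCT responds to NHE3 only
  through the cytosolic-Na/SGLT2-current chain, a few near-linear mV across
  the whole parameter box. The strong apical-potential sensitivity that a
  full model shows under NHE3 inhibition (where NHE3 couples into acid-base
  species and pH-dependent conductances) is therefore *not* reproduced:
  under NHE3 inhibition the dominant extrapolation error sits on cytosolic
  Na+, and the potential errors remain at the training noise floor. The
  mTAL inhibition scenario (NKCC2 reduced 70%, entirely below the training
  box) does show the expected across-the-board error inflation.
* NBCe1 unidentifiability is structural (bicarbonate-budget compensation)
  and robust; the precise ordering of the three *well*-identified inverse
  targets is a fine comparison that sits close to the training noise floor
  even after the polish phase, and can occasionally invert at unlucky
  seeds.

# Numerical choices and degenerate inputs

* Solver tolerance 1e-10 (scaled infinity-norm), maximum 50 iterations;
  Jacobian by forward differences, relative step 1e-7.
* GHK switches to its regular series for |zFV/RT| < 1e-6.
* Relaxation: default dt 2 s, horizon 40000 s, scaled rate tolerance
  1e-12, dt halving on instability (10 attempts).
* Non-positive concentrations, missing stoichiometric solutes, zero-valence
  Nernst queries, and non-electroneutral boundary compositions are rejected
  with informative errors; unconverged states cannot be written into
  released datasets.
* Ties in design ordering cannot occur (log-spaced levels are distinct);
  the snake path is the unique boustrophedon for the given level order.

# Known limitations

No transient dynamics as a user feature; no lateral intercellular space; no
acid-base buffering species, ammonia, phosphate, formate or urea; no
nephron-segment axial coupling; no flow- or torque-regulated transport; no
hyperparameter search or GPU path. The shipped baselines are calibrated
stand-ins - structurally faithful to the class of epithelial models but not
parameter-matched to any published cell.
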