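# nephroNN

Neural-network surrogates for mechanistic models of renal epithelial
transport.

Steady-state models of kidney epithelial cells — stiff nonlinear
differential-algebraic systems describing solute fluxes, membrane
potentials, and cell volume — are powerful but fragile: Newton-type
solvers need initial guesses close to the solution, and exploring altered
physiology (a transporter inhibited, a parameter doubled) routinely ends
in convergence failure. `nephroNN` addresses this with a learn-the-solver
workflow:

1. A **reduced mechanistic cell model** (proximal convoluted tubule, PCT,
   with Na⁺/K⁺/Cl⁻/HCO₃⁻/glucose; medullary thick ascending limb, mTAL,
   with Na⁺/K⁺/Cl⁻; male and female variants) is solved by a damped Newton
   method with Goldman–Hodgkin–Katz electrodiffusion,
   J = P·ξ·(Cᵢ − Cₑ·e^(−ξ))/(1 − e^(−ξ)) with ξ = zFV/RT,
   Michaelis–Menten Na⁺/K⁺-ATPase kinetics (3 Na⁺ : 2 K⁺ per cycle), and
   linear thermodynamic cotransporters (NHE3, SGLT2, NBCe1, NKCC2),
   under mass balance, electroneutrality, and open-circuit constraints.
2. **Parameter sweeps with continuation** (snake-ordered 8⁴ grids over
   50%–200% of baseline, each solve warm-started from its neighbor)
   generate training data with zero convergence failures.
3. A small **multilayer perceptron** (4–16–16–4, ReLU, dropout 0.1,
   Adam, 80:20 split) learns the forward map
   (transport parameters → cytosolic [Na⁺], [K⁺], apical and basolateral
   potentials Vₐ, V_b) or the inverse map
   (observables → transport parameters), and predicts unseen parameter
   sets in microseconds.
4. **Experiment drivers** replicate a full study design: sex-specific /
   cross-sex / sex-inclusive validation, transporter-inhibition
   extrapolation (NHE3 −40% in PCT, NKCC2 −70% in mTAL), and inverse
   parameter identifiability, all reported as fractional mean square
   errors, fMSE = 100·Σ(ŷ−y)²/Σy².

The mechanistic model is a declared reduced stand-in (no lateral
intercellular space, clamped pH, 5/3 solutes instead of 15): orderings and
bounds are meaningful, absolute error magnitudes are model-specific. See
`vignettes/surrogate-methods.Rmd` for the full model description, design
choices, and limitations.

## Worked example

```r
library(nephroNN)

v  <- load_variant("PCT", "male")          # shipped YAML configuration
st <- solve_steady_state(v)                # cold start
st
#> <steady_state> PCT/male  (10 Newton iters, |r|=8.0e-12)
#>   cytosol [mM]:  Na=21.04, K=118.54, Cl=10.99, HCO3=9.55, glucose=15.86
#>   Va=-55.28 mV, Vb=-62.32 mV, V_lumen=-7.043 mV, vol=0.0008653 cm

# reduce pump activity 25%: cytosolic Na rises, K falls
pm <- apply_parameters(v, c(NHE3 = 1, pump = 0.75, NBCe1 = 1, PK_bas = 1))
solve_steady_state(v, pm$activities, pm$membranes, initial_guess = st)
#> <steady_state> PCT/male  (9 Newton iters, |r|=2.6e-13)
#>   cytosol [mM]:  Na=25.31, K=114.53, Cl=10.93, HCO3=8.88, glucose=15.33
#>   Va=-55.64 mV, Vb=-62.46 mV, V_lumen=-6.817 mV, vol=0.0008581 cm

# sweep a 5^4 grid with continuation and train a forward surrogate
ds <- generate_dataset(v, build_design(parameter_ranges("PCT"), "grid", 5))
s  <- train_surrogate(ds, "forward",
                      train_config(seed = 1, max_epochs = 300,
                                   patience = 60, polish_epochs = 60))
s
#> <trained_surrogate> forward: [f_NHE3, f_pump, f_NBCe1, f_PK_bas] -> [Na_cell, K_cell, Va, Vb]
#>   layers 4-16-16-4, dropout 0.10; best epoch 360, test loss 0.00625 (from 1.73)

# validate against 100 fresh mechanistic solves
validate_surrogate(s, v, n = 100, seed = 2)$metrics
#> <metrics_report> forward / PCT/male random (n = 100)
#>   per-output fMSE (%):  Na_cell=0.0614, K_cell=0.00208, Va=0.00266, Vb=0.00355
#>   aggregate fMSE: 0.0174%
```

The cytosolic composition sits in the physiological window (Na⁺ ≈ 21 mM,
K⁺ ≈ 119 mM, Vₐ ≈ −55 mV); cutting pump activity by a quarter raises
cytosolic Na⁺ by ~4 mM and lowers K⁺, the expected pump-dependence. The
surrogate trained on only 625 samples already predicts fresh steady states
to hundredths of a percent fMSE.

The full replication suite (both cell types, all scenarios, study-size
datasets) is one call, or one shell command via the thin CLI:

```r
replicate_all(seed = 1, out_dir = "results")
```

```sh
Rscript inst/cli/nephroNN replicate-all --seed 1 --out results
```

## Layout

```
R/                 flux laws, variants, Newton solver, relaxation oracle,
                   designs/datasets, MLP surrogate, metrics, experiments
inst/config/       calibrated variant configurations (YAML, one per
                   cell type x sex); regenerate with scripts/make_configs.R
inst/cli/nephroNN  thin command-line front end
scripts/           acceptance script and the config calibration script
tests/testthat/    unit, property, and study-condition acceptance tests
vignettes/         methods vignette (model, training protocol, limitations)
```
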