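# fsbnr

Forward modelling and multi-contrast co-refinement of specular neutron
reflectometry (NR) from asymmetric **floating supported bilayers**
(FSBs) — in vitro mimics of the Gram-negative bacterial outer membrane,
with lipopolysaccharide (LPS) in the outer leaflet and
chain-deuterated phospholipid (d-DPPC) in the inner leaflet, floating
on a ~15 Å water layer above an ω-thiolipid SAM / gold / permalloy /
silicon substrate.

The package is for membrane biophysicists and reflectometry analysts
who need to (i) model such interfaces layer by layer, (ii) co-refine
one structure against several isotopic and spin contrasts with honest
confidence limits, and (iii) validate the whole estimation pipeline on
synthetic data with known ground truth.

## The model and the statistics

The interface is a slab stack: substrate block, water gap, inner
PC head-group layer, inner and outer lipid-tail regions, the LPS
core-oligosaccharide head region, and optionally an adsorbed protein
layer. Each layer has a thickness, a composition (volume fractions,
ideally mixed: ρ = Σ fᵢ ρᵢ), and an interfacial roughness; bilayer
surface coverage *c* adds (1 − *c*) solvent to every membrane layer.
Reflectivity is exact slab optics (Abelès transfer matrix ≡ Parratt
recursion, both implemented, held to 1e-10 mutual agreement) with
Névot–Croce roughness factors, Gaussian dQ/Q resolution smearing, a
scale factor and a flat background.

Co-refinement minimises the error-weighted least squares

> χ² = Σ_datasets Σ_points ((R_model − R_obs)/dR)²

with the structure shared across contrasts, per-dataset scale and
background profiled out analytically, a seeded differential-evolution
(or multistart) global stage, a restarted Nelder–Mead local stage and
a Levenberg–Marquardt polish. 95 % confidence limits come from a
residual-resampling bootstrap (linearized or full-refit), reported in
the field's `value (range low, high)` style; leaflet asymmetry is
reported in the `LPS:PC` percent convention (e.g. `79:11`).

## Worked example

Simulate a 4-contrast polarized measurement of the best-bilayer
structure (79:11 / 8:82 LPS:PC leaflets, 15 Å water gap, 30 Å core,
93 % coverage, 9.31 Å roughness) and co-refine it:

```r
library(fsbnr)

sc  <- scenario_catalog()$baseline_best
ds  <- generate_datasets(sc, seed = 1)     # D2O/H2O x spin-up/down, 3 % noise
fit <- fsb_fit(ds, model = sc$truth, seed = 1,
               control = fsb_control(multistart = 12, global = FALSE))
fit
```

```
Co-refined floating supported bilayer fit
  4 datasets, 480 points, objective chi^2 = 451.7 (chi^2/dof = 0.974)
  water_gap          15.11 (range 14.94,15.25)
  t_inner_tail       15.76 (range 15.19,16.47)
  t_outer_tail       14.29 (range 11.53,16.76)
  t_core             29.94 (range 28.01,32.1)
  outer_f_lps        0.7884 (range 0.7494,0.8283)
  inner_f_pc         0.8309 (range 0.815,0.8427)
  coverage           0.9279 (range 0.9232,0.9321)
  sigma_bilayer      9.355 (range 9.264,9.428)
  leaflets (LPS:PC)  outer 79:11   inner 7:83
  coverage 92.8 %   seed 1   2695 objective evaluations
```

χ²/dof ≈ 0.97 says the fit is statistically consistent with the
simulated noise; every generating parameter is recovered within its
95 % range (water gap 15 Å, core 30 Å, roughness 9.31 Å, outer LPS
fraction 0.79, coverage 0.93), and the leaflet ratio strings reproduce
the 79:11 asymmetry the data were built from. `summary()`, `plot()`,
`predict()`, `residuals()`, `confint()` and `simulate()` work as for
any fitted-model object.

Higher-level experiments:

```r
rec <- recovery_experiment(sc, n_replicates = 20, seed = 1)  # bias/RMSE/coverage
rec$summary
```

A command-line pipeline (`simulate | fit | recover | report`) is
installed at `system.file("cli", "fsbnr", package = "fsbnr")`; it
writes ORSO `.ort` data files, a manifest, and machine- plus
human-readable reports.

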