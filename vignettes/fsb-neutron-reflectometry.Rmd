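---
title: "Modelling polarized neutron reflectometry of floating supported bilayer outer-membrane mimics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling polarized neutron reflectometry of floating supported bilayer outer-membrane mimics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsbnr)
```

## The system and the measurement

The outer membrane (OM) of Gram-negative bacteria is a profoundly
asymmetric bilayer: lipopolysaccharide (LPS) in the outer leaflet,
phospholipid in the inner leaflet. In vitro mimics of this membrane can
be built as *floating supported bilayers* (FSBs): the bilayer rests on a
thin (~15 Å) water layer above an ω-thiolipid self-assembled monolayer
(SAM) chemisorbed on a gold film, itself deposited over a magnetic
permalloy layer on a silicon substrate.

Specular neutron reflectometry (NR) measures the reflectivity `R(Q)` of
such a stack as a function of momentum transfer `Q` perpendicular to the
surface. `R(Q)` is determined by the depth profile of the neutron
scattering length density (nSLD), `ρ(z) = Σ b_i / V`. Because hydrogen
and deuterium have very different scattering lengths, repeating the
measurement in H₂O- and D₂O-based buffers — and, over the magnetised
permalloy layer, with spin-up and spin-down neutrons — yields several
independent curves constrained by one shared structure. Co-refining
them resolves what a single curve cannot: with chain-deuterated DPPC
(d-DPPC) in the inner leaflet and hydrogenous LPS outside, the
asymmetry of the bilayer becomes directly visible as a bright
inner-tail band against H₂O and a dark outer-tail band against D₂O.

This package implements the full quantitative chain for such
experiments: SLD arithmetic, the structural model, the reflectivity
forward engine, multi-contrast co-refinement with confidence limits,
derived structural metrics, and a synthetic-data generator with
packaged scenarios so the whole pipeline can be exercised and validated
without access to beamtime.

## The structural model

`fsb_model()` parametrizes the interface stack from the silicon
fronting medium to bulk solvent:

* a fixed substrate block — native oxide, permalloy, gold, and the SAM
  split into an alkyl-chain and a PC-head sublayer — whose thicknesses
  and roughnesses are fitted once per physical sample and then held
  fixed across perturbation experiments;
* the solvent-filled water gap the bilayer floats on;
* a thin inner (PC) head-group layer, inner and outer lipid-tail
  regions, and the thick LPS core-oligosaccharide head-group region;
* optionally an adsorbed protein layer above the core.

Each leaflet carries a `LeafletComposition` of LPS, PC and solvent
volume fractions summing to one. Layer SLDs follow ideal
(volume-fraction linear) mixing: tail regions mix the corresponding
tail materials, and head-group regions mix the leaflet's LPS component
as core-oligosaccharide material and its PC component as PC head-group
material, with the balance as solvent. Surface coverage `c` enters
every membrane layer uniformly as an extra `(1 − c)` solvent fraction —
the simplest convention compatible with quoting a single coverage
number for the film. A single roughness `σ_bilayer` applies to all
membrane interfaces (conformal roughness), while substrate interfaces
keep their own values.

Two conventions are worth stating explicitly:

* z = 0 at the silicon surface, increasing toward the solution; layers
  are listed fronting → backing, matching the beam-through-substrate
  geometry.
* "asymmetry reduced by X %" is interpreted as a change of X
  *percentage points* in the dominant species of each leaflet
  (`asymmetry_change()`); the relative-change reading is available via
  `relative = TRUE`.

The material table shipped in `inst/extdata/materials.csv` (silicon,
oxide, permalloy, gold, thiolipid chains, PC heads, h-/d-DPPC tails,
lipid-A tails, core oligosaccharide, lactoferrin, lysozyme, H₂O, D₂O)
is computed from tabulated coherent scattering lengths and molecular
volumes. These are documented literature-style defaults — the
experiment-specific values behind any one published fit are generally
not printed — and every entry can be overridden by loading a user
table. Protein layers use a fixed whole-protein SLD: labile-hydrogen
exchange with the solvent is *not* modelled, which slightly
underestimates protein SLDs in D₂O; this is a known limitation.

## The optics engine

`reflectivity()` evaluates exact specular slab optics. The default
engine is an Abelès characteristic-matrix kernel in compiled code; a
pure-R Parratt recursion is kept as an independently implemented oracle
(`method = "parratt"`), and the test suite holds the two to 1e-10
relative agreement on random stacks. Interfacial roughness enters
through Névot–Croce damping of each interface amplitude, consistent
with the error-function broadening `sld_profile()` applies to the
continuous nSLD profile. SLDs are treated as real: absorption is
negligible for these isotopes at NR wavelengths.

Instrumental effects are modelled by `measured_curve()` as
`scale · smear(R) + background`. Resolution smearing uses a Gaussian
kernel of constant relative width (FWHM `dQ/Q`, default 0.04),
truncated at ±3σ. Because the kernel width is proportional to `Q`, the
convolution is carried out on a shared log-spaced oversampled grid
(default 4× the data density): the reflectivity is evaluated once on
that grid and every data point's kernel is a weighted sum over it. At
the default settings this quadrature sits within 1 % of a dense
brute-force convolution — far below the 3 % measurement noise — and,
because the synthetic-data generator and the fitting engine share the
same operator, the residual quadrature error cancels in recovery
studies. The default Q grid is 120 log-spaced points over
0.008–0.30 Å⁻¹ with a flat 1e-6 background, typical of time-of-flight
reflectometers; all of it is configurable through `nr_instrument()`.

## Co-refinement

`fsb_fit()` refines one structure against all contrast datasets
simultaneously, minimising the error-weighted least squares
`Σ ((R_model − R_obs)/dR)²`. Thicknesses, compositions, coverage and
roughness are shared; only solvent-dependent and spin-dependent SLDs
differ between datasets. Per-dataset scale and background are free
nuisance parameters but never enter the search vector: for any
structure they minimise a weighted linear least-squares problem that is
solved in closed form at every objective evaluation.

The default free parameters are the water gap, the two tail
thicknesses, the core thickness, the dominant fraction of each leaflet,
coverage and the bilayer roughness (plus protein thickness and fraction
when a protein layer is present); the thin inner head-group layer and
the substrate are held at their defaults, since freeing them adds
little information and destabilises paper-faithful fits.

The search has three stages, all driven by one integer seed and
bit-reproducible:

1. **Global:** bounded differential evolution (rand/1/bin, population
   15 × n parameters by default). For warm starts a cheaper alternative
   is available: a Levenberg–Marquardt *multistart screen* from
   jittered copies of the start (`fsb_control(multistart = …)`), whose
   best point and the original start are both carried forward. Ties on
   the objective are broken toward the lowest roughness (parsimony).
2. **Local:** restarted Nelder–Mead. A single simplex run routinely
   stalls in this 8–10 parameter objective; restarting with a fresh
   simplex until the improvement falls below a threshold is the
   standard cure.
3. **Polish:** a short Levenberg–Marquardt run on the weighted
   residuals. This pins the simplex result onto the least-squares
   minimum precisely; without it, residual optimizer noise (not
   statistics) dominated the scatter of recovered parameters.

For before/after perturbation experiments (protein addition, calcium
sequestration) the recommended paired analysis refines the
pre-perturbation state with the full free set and then refines the
post-perturbation state *starting from that fit with the hydrocarbon
tail thicknesses held fixed*: the perturbing agents act on the
head-group/core region while the lipids themselves are unchanged, and
pairing this way lets the correlated tail/core uncertainty cancel in
the reported thickness and composition differences.

The objective surface is genuinely multimodal: at high roughness
(σ ≈ 13 Å, comparable to the tail-layer thickness) a secondary optimum
exists in which a thinner outer-tail layer is traded against a thicker,
more LPS-rich core region. The global stage exists to avoid it; the
recovery experiments discussed below showed that a purely local search
falls into it from roughly a third of perturbed starts.

## Confidence limits

`fsb_confint()` reports 95 % intervals in the
`value (range low, high)` convention, by three routes.

The default for a stand-alone fit is a residual-resampling bootstrap:
standardized residuals are resampled within each dataset, synthetic
data are rebuilt around the fitted curves, and each resample is
re-estimated — either in the Gauss–Newton linearization around the
best fit (fast) or by a full nonlinear Levenberg–Marquardt refit
warm-started at the optimum (`refit = TRUE`). Derived metrics (leaflet
percentages, coverage, total head-region thickness) get intervals by
transforming each draw. A random-walk Metropolis posterior sampler
(`method = "posterior"`) is also available.

`method = "profile"` computes MINOS-style profile-likelihood
intervals: each parameter is stepped away from the optimum while all
others are re-minimized (warm-chained Levenberg–Marquardt), and the
interval is the hull of the region where the objective stays within
`qchisq(0.95, 1)` of the minimum. The walk deliberately continues past
the first threshold crossing: with a competing optimum inside the
threshold the likelihood-ratio set is disconnected, and the hull is
the honest summary.

Recovery experiments use the profile method. The choice is empirical:
in calibration runs, both bootstrap flavours and the posterior sampler
under-covered the core-region thickness (the curved outer-tail/core
trade-off lets the estimator wander further between replicates than
locally re-estimated resamples suggest — measured sampling sd ≈ 1.26 Å
against a bootstrap spread of ≈ 1.0 Å), while in the high-roughness
structure a first-crossing profile walk truncated the leaflet-fraction
interval whenever a noise realization made the secondary optimum
global. The hull-profile construction stays calibrated in both regimes
(per-parameter coverage 0.90–1.00 at nominal 0.95 in 20-replicate
checks of both scenarios).

## Synthetic data and the packaged scenarios

`generate_datasets()` emulates a 4-contrast polarized NR measurement of
a scenario's ground-truth structure: D₂O and H₂O buffers, each at both
spin states (a 2-contrast "paper-minimal" option exists, matching the
pair of curves a publication typically shows). Noise is Gaussian with
σ = `noise_level` × curve — a constant-relative stand-in for counting
statistics, with the dR column set to the exact σ used. The default
noise level of 3 % was chosen to visually match published FSB data;
point densities and true counting statistics of any specific instrument
are not emulated, and neither are polarization inefficiencies or
detector effects. Passing tests on these data therefore demonstrate
correctness of the estimator under a faithful noise model, not
robustness to every instrumental artefact of real beamlines.

`scenario_catalog()` packages six ground-truth parameter sets encoding
the reported structures: the best (79:11 / 8:82 LPS:PC) and worst
(69:28 / 23:75) baseline bilayers, the EDTA-treated state (both
dominant fractions down 20 points), the lactoferrin state (a 90 Å
protein layer, coverage down 12 points, outer LPS down 30 points), and
the lysozyme before/after pair (core +20 Å, roughness 9.31 → 12.88 Å,
no coverage loss). Values that are only bounded in print are fixed at a
documented choice (coverage 0.93 for the "> 90 %" bound); tail
thicknesses sit at 16/14 Å inside the quoted 14–18 Å band, the inner
head at 8 Å, leaflet solvent fractions at 10 %, the EDTA scenario
changes only the printed composition shifts, and the lactoferrin
protein layer is 30 % protein by volume.

`recovery_experiment()` is the estimator's acceptance surface: generate
→ perturb the start (±20 % uniformly) → co-refine → record estimates
and intervals, then summarise bias, RMSE and interval coverage per
parameter. Its defaults (20 replicates, multistart screen + restarted
simplex + LM polish, profile-likelihood intervals) keep a 20-replicate
experiment at roughly five minutes on one CPU; these problem sizes are
the package's chosen benchmark scale and can be raised freely.

## Numerical choices and degenerate inputs

* Fraction sums are validated to 1e-6; `mix_sld()` refuses implicit
  voids — callers fill to one with solvent.
* A roughness exceeding half the adjacent layer thickness warns (the
  Névot–Croce factor degrades there) but does not error, since fits
  legitimately traverse such regions; the lysozyme-after structure
  itself lives in this regime.
* Zero-thickness layers are exactly invisible to the optics and
  `add_protein_layer(…, 0, …)` is a strict no-op on every curve.
* At zero noise the generator still emits strictly positive dR (a
  1e-6 relative floor) so weighted objectives remain defined.
* Datasets are put into a canonical contrast order inside `fsb_fit()`,
  making fits and intervals exactly invariant to input order.
* Reflectivities are clamped to [0, 1] against rounding at total
  external reflection.

## Known limitations

* No labile-H exchange for proteins and sugars; no wavelength-dependent
  absorption or incoherent-background prediction.
* No lateral structure: coverage is a uniform solvent admixture, not
  patch statistics; smooth (O-antigen) LPS and embedded outer-membrane
  proteins are out of scope.
* The instrument model is a constant-dQ/Q Gaussian; real time-of-flight
  resolution functions have tails the smearing operator does not
  reproduce.
* Model selection between alternative layer schemes is not provided;
  the layer structure is fixed by construction.
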