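---
title: "Models and methods behind folatekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind folatekin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(folatekin)
```

folatekin packages the quantitative machinery needed to characterize a
folate–peptide conjugate as a targeted thymidylate synthase (TS)
inhibitor: enzyme kinetics, subcellular quantification, biostability,
receptor-binding thermodynamics and combination-synergy scoring. This
vignette explains each model, its assumptions and the design choices we
made where more than one defensible option existed.

## The coupled-equilibrium inhibition model

Human TS is an obligate homodimer that interconverts between an
inactive conformation (`II`) and the catalytically competent dimer–dUMP
complex (`AA`). A difunctional folate–peptide inhibitor `i` can act in
two ways: its peptidic end binds the monomer–monomer interface of the
inactive dimer (species `IiI`), and its folate end competes with the
folate cosubstrate `s` (mTHF) at either catalytic pocket of the
dUMP-bound enzyme (`AAi` at the dUMP-occupied monomer, `iAA` at the
other, and the non-productive ternary `iAAs`). With dissociation-style
constants K1–K6 in μM (larger = weaker binding):

| eq. | reaction         | constant | meaning                                   |
|-----|------------------|----------|-------------------------------------------|
| 1   | `II + d = AA`    | K1       | dUMP-linked inactive/active coupling       |
| 2   | `II + i = IiI`   | K2       | interface binding (peptide end)            |
| 3   | `AA + i = AAi`   | K3       | pocket of the dUMP-occupied monomer        |
| 4   | `AA + i = iAA`   | K4       | pocket of the other monomer                |
| 5   | `AA + s = AAs`   | K5       | productive substrate binding               |
| 6   | `iAA + s = iAAs` | K6       | substrate binding to the inhibited complex |

Under fast equilibration and tracer-level enzyme, expressing every
species relative to `AA` and taking `v ∝ [AAs]` gives the closed form
implemented in `ts_rate()`:

```
v = Vmax·(s/K5) / [ (1 + K1/d) + i·(1/K3 + 1/K4 + K1/(d·K2))
                    + (s/K5)·(1 + i·K5/(K4·K6)) ]
```

This *is* the linear mixed-inhibition law
`v = Vmax·s/(Km_app(1+i/Ki) + s(1+i/Ki′))` with

* `Km_app = K5·(1 + K1/d)`,
* `1/Ki  = (1/K3 + 1/K4 + K1/(d·K2)) / (1 + K1/d)`,
* `Ki′   = K4·K6/K5`.

At the assay condition `d = 140` μM with `d/K1 ≈ 15` the factor
`1 + K1/d ≈ 1.07`, and the slope constant reduces to the composite
relation used for inference, `1/Ki = 1/K3 + 1/K4 + K1/(d·K2)` (for a
pure interface binder, `Ki = d·K2/K1`). `infer_micro_constants()`
applies those reduced relations exactly, consistent with how the
apparent constants are read off secondary Lineweaver–Burk plots; the
≈7 % correction is far below the standard errors such assays deliver.
`apparent_constants()` reports the exact values; K5 and K6 are
identifiable from steady-state rates only through the ratio `K4·K6/K5`,
so `params_from_apparent()` fixes one representative microscopic
realization (`K3 = K4`, interface path off) when only apparent
constants are prescribed, and `K6 = Inf` encodes the purely competitive
limit in which `iAAs` never forms.

**Numerical oracle.** `species_balance()` solves the same six
equilibria as a general mass balance — enzyme, inhibitor and substrate
all conserved, dUMP treated as a buffered free concentration because
the assays use ~140 μM dUMP against nanomolar enzyme — with a damped
2-D Newton iteration in log-concentration space (relative residual
tolerance 1e-10, step clamp ±2 log units). It makes no tracer-enzyme
assumption, so agreement with `ts_rate()` as enzyme → 0 (tested to
0.1 % over hundreds of random parameter draws) validates the algebra of
the closed form, and it quantifies depletion effects when enzyme is
*not* negligible.

## Double-reciprocal fitting and mode classification

`fit_inhibition()` follows the classical workflow: per inhibitor level,
an ordinary least-squares line of `1/v` on `1/s` (≥3 substrate levels
required; non-positive rates are dropped with a warning); then
secondary OLS lines of the primary slopes and intercepts on `i`. For
the linear mixed law the primary slope is `Km_app(1+i/Ki)/Vmax` and the
intercept `(1+i/Ki′)/Vmax`, so `Ki_app` and `Ki′_app` are the
x-intercept magnitudes of the secondary lines, with delta-method
standard errors from the secondary-fit covariance. Unweighted primary
OLS is the default (matching how such plots are traditionally fitted);
a `v⁴`-weighted option corrects the variance distortion of the
reciprocal transform under constant-CV noise.

**Competitive vs mixed.** The decision statistic is the intercept-vs-`i`
slope. We test it with a variance-weighted slope estimate whose
standard error is propagated from the known primary-fit intercept SEs
(two-sided, normal reference), not with the OLS residual t-test: with
only 3–4 inhibitor levels the residual test has at most 1–2 degrees of
freedom (critical t of 12.7 at 1 df) and, in our simulations at 5 %
rate noise on the 3-level conjugate design, it missed even a doubling
of the intercepts in over 90 % of runs, while the weighted test had
power ≈1 at a false-positive rate matching the nominal α = 0.05. The
test additionally requires the implied intercept change across the
design to exceed numerical noise (relative 1e-6), which keeps
noise-free competitive data competitive. With exactly two inhibitor
levels no test is possible; a >5 % relative intercept change decides,
flagged `low_confidence`. A non-positive (or numerically negligible)
slope-vs-`i` dependence yields `"no inhibition detected"` rather than
an error.

## Microscopic-constant inference

Two inference paths mirror the two inhibitor families:

* **peptide** (interface-only): `K2 = Ki_app/(d/K1)`; with the default
  `d_over_K1 = 15` an apparent Ki of 90 μM gives `K2 = 6` μM.
* **conjugate** (difunctional): `1/K3 + 1/K4 = 1/Ki_app − 1/((d/K1)·K2_ref)`
  using a peptide-derived `K2_ref`; the harmonic mean `2/(1/K3+1/K4)`
  summarizes the two pocket affinities. Apparent Ki values of 38 and
  73 μM with corrections 1/90 and 1/95 μM⁻¹ give 0.015 and
  0.003 μM⁻¹, i.e. harmonic means of ≈130 and ≈630 μM. (The source
  kinetics report the first conjugate's Ki both as 40 ± 15 and as 38 μM;
  we use 38, the value consistent with the printed 0.015 μM⁻¹, and
  surface both here.)

If the correction exhausts `1/Ki_app` the result is reported as
"interface binding fully explains inhibition" instead of a negative
pocket term. `composite_Ki()` provides the forward relation for
roundtrip checks.

## Compartment quantification

`compartment_geometry()` defaults encode the fractionation experiments:
2×10⁻¹² L cells, cytosol 60 % and vesicles 2.5 % of cell volume; the
extracellular default of 3×10⁻³ L is *inferred* from the reported
extracellular mass and concentration (10,200 ng at 2.38 μM), not
directly stated — override it when your medium volume is known.
Masses are in ng, volumes in L, concentrations in μM throughout;
`C = (mass/M)/V`. The charge-state layer uses a monoisotopic proton
mass of 1.00728 Da (configurable for average-mass work) and enforces
that all charge states of one conjugate agree on the neutral mass
within 0.05 Da.

Two documented inconsistencies in the source data are deliberately left
unresolved: the fraction masses together with the printed
concentrations imply a molar mass ≈1356 Da, whereas the m/z-derived
neutral mass is 1432.6 Da (34.4 ng over 10⁻⁷ L computes to 240 μM
against a printed 254 μM). The vesicle/cytosol concentration *ratio*
(13.7 at 37 °C) is independent of molar mass and cell count — the
factors cancel — and is therefore the quantity we treat as reliable.
Similarly, the fluorometric calibration factor was never published;
`fluorometric_concentration()` requires it as input (kcounts per pmol
in the pooled cytosol), and the value ≈0.598 kcounts/pmol that
reproduces the reported 20.2 μM from an 87-kcount emission difference
is provided in the tests as a back-derived fixture, not as a constant
of nature.

## Decay kinetics

First-order degradation is fitted as `ln C = ln C0 − k·t` by OLS
(`fit_decay()`), because the assay-scale data — five timepoints between
20 and 240 min with roughly constant relative error — are exactly the
regime where the log-linear estimator is simple, unbiased in slope and
transparent; a direct `nls()` exponential fit is available via
`method = "nls"`. `t½ = ln 2/k` identically; `k = 3.5×10⁻³ min⁻¹`
corresponds to `t½ ≈ 198 min`. Whether replicates were pooled in the
original analysis is unstated; we pool by default and offer
`per_replicate = TRUE`. Non-positive concentrations are dropped with a
warning; a numerically flat series reports `k = 0`, `t½ = Inf`.
`simulate_decay()` uses mean-corrected log-normal noise so the expected
concentration equals the noise-free curve.

## Binding competition and ΔΔG

The displacement model is one receptor, one labelled tracer, one
unlabelled competitor, solved with full ligand depletion by a bracketed
`uniroot()` on the free-receptor concentration. The default inference
route is the tracer limit, where displacement odds are proportional to
competitor affinity, so paired displacements give the binding-constant
ratio `[fa/(1−fa)]/[fb/(1−fb)]`: 80 %/40 % yields 6.0. The source
analysis reports a ratio near 5 for the same figures — receptor depletion or
nonspecific binding plausibly lowers the apparent ratio, and the full
mass-balance inversion is exposed for exactly that case — but we do not
guess the original calculation. `ΔΔG° = RT·ln(ratio)` with
R = 8.314 J mol⁻¹ K⁻¹ at a default 298.15 K (the stated ~4 kJ/mol for
a ratio of 5 corresponds to room temperature, although the displacement
assays run at 4 °C; the temperature is an explicit argument).

## Synergism quotients

`SQ = combined/(single_a + single_b)` on percent growth inhibition;
the published thresholds classify >1.1 as synergism, <0.9 as
antagonism, the closed band [0.9, 1.1] as additivity. The clustering
transform subtracts 10 below 0.9 and adds 10 at or above 1.1 — note the
two published rules disagree at exactly SQ = 1.1 (classification band
is closed, transform bound is closed on the synergism side); we honor
each rule as printed and document the conflict rather than harmonize
it. Clustering runs on transformed values (Euclidean distance, complete
linkage via `hclust`), so interaction class dominates the tree — classes
are ≥8.9 units apart by construction; `transform = FALSE` clusters raw
SQ values. Dendrograms export to Newick through `ape`.

## The synthetic-data generator

`generate_scenario()` emulates the study's assay designs: inhibition
grids at dUMP = 140 μM with inhibitor levels 0/25/50/100 μM (peptide,
apparent Ki 90 μM) and 0/20/40 μM (conjugate, apparent Ki 38 μM,
Ki′ 44 μM); decay sampling at 20/40/60/120/240 min from
C0 = 18.5 μM, k = 3.5×10⁻³ min⁻¹; the reported fraction masses; the
80 %/40 % displacement pair; and single-dose combination records
spanning all three SQ classes. The substrate grid (5, 10, 20, 50,
100 μM) is our choice — the published plots do not tabulate it — picked
to bracket Km_app = 15 μM over a 20-fold range, as a practitioner
would design it. Noise defaults are bench-plausible and fixed in the
config: 5 % CV on rates, 10 % CV on decay concentrations, 5 percentage
points (truncated to [0, 100]) on inhibition percentages.

The generator draws exactly the noise the models assume — multiplicative
Gaussian/log-normal, independent across observations. Passing recovery
tests therefore demonstrates correctness of the estimators under the
stated error model, not robustness to what real assays add: correlated
plate effects, heteroscedastic low-signal rates, partial substrate
depletion during the "initial" rate window, metabolite interference in
decay series, or receptor-site heterogeneity in displacement data.

## Problem sizes and numerical choices

Tests and the acceptance script run desk-scale: 500 random draws for
the oracle/closed-form agreement, 200 replicate fits for Ki recovery,
500 for decay-rate recovery, 100 seeds for the end-to-end study —
sizes at which Monte-Carlo medians are stable to well inside the
asserted bounds. Solver tolerances: 1e-10 relative residual in the
species balance, `uniroot` at 1e-12 relative in binding. Degenerate
inputs fail fast with informative messages (empty designs, <3 substrate
levels, mixed dUMP levels, zero cytosolic mass, displacement of exactly
1), except where the field expects tolerance: non-positive rates and
concentrations are dropped with warnings, and negative fluorometric
differences clamp to zero.

## Known limitations

* No global nonlinear fit of all six microscopic constants — the
  fixed-dUMP design leaves them underdetermined; only the composite
  combinations are estimated.
* No progress-curve kinetics, dose–response (IC50) fitting, or
  Chou–Talalay/Bliss/Loewe combination modelling.
* The compartment model is a three-compartment, homogeneous-volume
  idealization; vesicular pH, protein binding and export are outside
  it.
* The decay model assumes a single first-order route; product
  identification and parallel pathways are out of scope.
* Raw-signal processing (chromatograms, spectra, scintillation counts)
  is upstream of this package, which consumes peak-derived tables.
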