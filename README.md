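# folatekin

Quantitative analysis of folate–peptide conjugate assay data, for
enzymologists and cell pharmacologists characterizing receptor-targeted
thymidylate synthase (TS) inhibitors. The package covers the full
desk-side workup of such a study:

* **Inhibition kinetics.** Human TS is a homodimer that equilibrates
  between an inactive conformation and an active enzyme–dUMP complex. A
  difunctional folate–peptide inhibitor can bind the monomer–monomer
  interface of the inactive dimer and, through its folate end, either
  catalytic pocket of the dUMP-bound enzyme. Solving the six coupled
  equilibria under fast equilibration gives the linear mixed-inhibition
  rate law

  ```
  v = Vmax·s / ( Km_app·(1 + i/Ki) + s·(1 + i/Ki′) )
  ```

  with composite constants `1/Ki = 1/K3 + 1/K4 + K1/([d]·K2)` and
  `Ki′ = K4·K6/K5` at fixed dUMP concentration `[d]`. `fit_inhibition()`
  performs the classical double-reciprocal (Lineweaver–Burk) analysis —
  per-level `1/v` vs `1/s` lines, secondary slope- and intercept-vs-`i`
  lines — classifies the inhibition as competitive or mixed, and
  extracts `Ki` and `Ki′` with standard errors.
  `infer_micro_constants()` then converts apparent constants into
  microscopic ones: the interface constant `K2 = Ki/(d/K1)` for a pure
  interface binder, or the catalytic-pocket term `1/K3 + 1/K4` (and the
  harmonic mean `2/(1/K3 + 1/K4)`) for a difunctional conjugate. A
  numerical species-balance solver (`species_balance()`) validates the
  closed form without the tracer-enzyme assumption.

* **Compartment quantification.** `fraction_concentration()` converts
  masses measured in extracellular, cytosolic and vesicular fractions
  into molar concentrations using a cell-geometry model (2 pL cells,
  cytosol 60 % and vesicles 2.5 % of cell volume);
  `vesicle_cytosol_ratio()` gives the mass-independent
  vesicle-to-cytosol concentration ratio. Charge-state arithmetic
  (`neutral_mass_from_mz()`, `predict_mz()`), fluorometric
  back-calculation and the single-cell dilution formula are included.

* **Biostability.** `fit_decay()` fits first-order degradation by
  log-linear least squares and reports the rate constant and half-life
  `t½ = ln 2 / k`.

* **Receptor competition.** `bound_tracer_fraction()` solves the
  two-ligand/one-receptor equilibrium with ligand depletion;
  `infer_K_ratio()` turns paired tracer-displacement fractions into a
  binding-constant ratio (tracer-limit odds ratio, or full mass-balance
  inversion), and `delta_G_from_ratio()` converts it to
  `ΔΔG° = RT·ln(ratio)`.

* **Drug-combination synergy.** `synergism_quotient()` computes
  `SQ = combined / (single_a + single_b)` growth inhibition,
  `classify_sq()` applies the >1.1 / 0.9–1.1 / <0.9 thresholds,
  `transform_sq()` applies the ±10 class-separating shift, and
  `cluster_sq()` clusters the SQ matrix (Euclidean distance, complete
  linkage) with Newick export.

* **Synthetic data.** `generate_scenario()` emulates every assay design
  with configurable noise, so the whole pipeline is testable without
  external data; `run_pipeline()` chains all stages into one JSON-able
  report.

## Worked example

```r
library(folatekin)

b <- generate_scenario(scenario_config(seed = 7))   # synthetic assays

fit_pep <- fit_inhibition(b$rates_peptide)          # free peptide
fit_pep
#> Double-reciprocal inhibition analysis
#>   dUMP = 140 muM, 4 inhibitor levels, 20 rates
#>   mode: competitive
#>   Ki_app  = 82.25 +/- 19 muM
mc <- infer_micro_constants(fit_pep$Ki_app, fit_pep$Ki_app_se)
mc
#> Microscopic-constant inference (peptide path)
#>   K2 = 5.48 muM (Ki_app / (d/K1), d/K1 = 15)

fit_con <- fit_inhibition(b$rates_conjugate)        # folate conjugate
fit_con
#> Double-reciprocal inhibition analysis
#>   dUMP = 140 muM, 3 inhibitor levels, 15 rates
#>   mode: mixed
#>   Ki_app  = 30.38 +/- 3.4 muM
#>   Ki'_app = 48.62 +/- 5.6 muM
infer_micro_constants(fit_con$Ki_app, fit_con$Ki_app_se, K2_ref = mc$K2_est)
#> Microscopic-constant inference (conjugate path)
#>   1/K3 + 1/K4 = 0.0208 muM^-1
#>   harmonic mean of K3, K4 = 96.37 muM

fit_decay(b$decay)
#> First-order decay fit (loglinear, n = 5)
#>   k      = 0.003283 +/- 0.00051 per min
#>   t_half = 211.1 min
#>   C0     = 17.85 muM,  R^2 = 0.9330

vesicle_cytosol_ratio(34.4, 60.2, compartment_geometry(2e6))
#> [1] 13.71429
delta_G_from_ratio(infer_K_ratio(0.80, 0.40)$ratio)
#> [1] 4.441448
```

The peptide shows pure competitive inhibition (common reciprocal
intercepts) with an interface dissociation constant near 6 μM; the
conjugate is mixed-type, its extra catalytic-pocket binding summarized
by the `1/K3 + 1/K4` term. The simulated decay recovers a half-life
around 200 min (truth `k = 3.5e-3 min⁻¹`), the fractionation masses
give a 13.7-fold vesicle-over-cytosol concentration excess, and an
80 %/40 % paired displacement corresponds to a ~6-fold
binding-constant ratio, i.e. a free-energy difference of ~4 kJ/mol.

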