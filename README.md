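# eemparafac

PARAFAC modeling of dissolved organic matter (DOM) fluorescence
excitation–emission matrices (EEMs), in R.

Water-quality and treatment studies characterize DOM by measuring, for each
sample, a fluorescence surface over excitation wavelengths 220–450 nm and
emission wavelengths 250–550 nm. A set of samples forms a three-way array
that parallel factor analysis (PARAFAC) decomposes into chemically
interpretable trilinear components:

```
x_ijk = Σ_f  a_if · b_jf · c_kf  +  e_ijk
```

with `a_if` proportional to the concentration of fluorophore class *f* in
sample *i*, `b_jf` its emission spectrum and `c_kf` its excitation spectrum.
This package implements the full chemometric workflow around that model, for
analysts who need it scriptable and testable end to end:

* **Synthetic data** — Gaussian-band fluorophore libraries (a built-in
  seven-component DOM set), log-normal concentration designs, Rayleigh/Raman
  scatter, inner-filter attenuation, inter-source peak shifts, and "cocktail"
  contamination mixtures, all seeded and returning exact ground truth.
* **Preprocessing** — inner-filter correction (`10^((A_ex+A_em)/2)`), Raman
  normalization by the blank's 350/381–426 nm band area, scatter excision to
  a missing-value mask, and per-sample total-signal normalization with exact
  score reversal.
* **Fitting** — multi-start non-negative alternating least squares with
  missing-data support, core consistency, split-half validation, leverage
  and residual outlier screening, and a 3–7 component model-selection
  driver.
* **Comparison** — Tucker congruence `r_c = Σxy / sqrt(Σx²·Σy²)` with the
  conventional similarity classes (≥ 0.95 "equal", 0.85–0.95 "fair"),
  optimal one-to-one component matching across models, and cross-model
  `F_max` regressions.
* **Peak monitoring** — per-wavelength regression of raw intensity on
  component `F_max` (R² and slope maps), peak reports, and clean-vs-cocktail
  contamination experiments quantifying when single-pixel "peak picking"
  stops tracking a component.

## Worked example

```r
library(eemparafac)

lib <- dom_library()                       # G1-G7 component presets
sim <- simulate_dataset(lib, c("G1", "G2", "G6"),
                        concentration_design(30, seed = 101),
                        grid = default_grid(),
                        noise = noise_model(relative = 0.01, seed = 102))

fit <- parafac_fit(sim$dataset, ncomp = 3, nstarts = 10, seed = 1)
fit
#> parafac_model: 3 components, SSE 7.317, expl. var 0.9999, 65 iter (converged)

core_consistency(fit, sim$dataset)
#> [1] 99.99998

match_components(fit, parafac_fit(sim$dataset, 3, nstarts = 2, seed = 99))
#>   comp_a comp_b rc_ex rc_em combined class
#> 1      1      1     1     1        1 equal
#> 2      2      2     1     1        1 equal
#> 3      3      3     1     1        1 equal

peak_location(fit, 1)
#> $ex
#> [1] 365
#> $em
#> [1] 472
#> $secondary_ex
#> [1] 265
```

The fitted model explains 99.99 % of the variance (the remaining 0.01 % is
the injected 1 % relative noise), core consistency near 100 % confirms three
components, an independently seeded refit matches component-for-component
with congruence 1, and the strongest component is recovered at the
terrestrial humic-like position (ex 365 nm with a secondary band at 265 nm,
em 472 nm).

A complete run — simulate → preprocess → screen F = 3–7 → fit → peak report,
with every artifact written to disk — is one call:

```r
run_pipeline(pipeline_config(out_dir = "artifacts", seed = 4))
```

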