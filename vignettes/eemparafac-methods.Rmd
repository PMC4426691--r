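---
title: "PARAFAC modeling of DOM fluorescence EEMs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PARAFAC modeling of DOM fluorescence EEMs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Dissolved organic matter (DOM) in natural and engineered waters fluoresces.
An excitation–emission matrix (EEM) records intensity over a grid of
excitation wavelengths (typically 220–450 nm in 5 nm steps) and emission
wavelengths (250–550 nm at 1 nm), producing one surface per sample. A set of
samples forms a three-way array `x[i, j, k]` (sample × emission ×
excitation). Parallel factor analysis (PARAFAC) decomposes it into trilinear
components,

    x_ijk = Σ_f a_if · b_jf · c_kf + e_ijk,

where `a_if` is proportional to the concentration of fluorophore class `f`
in sample `i`, `b_jf` is its emission spectrum, `c_kf` its excitation
spectrum and `e_ijk` residual noise. Under the unit-maximum loading
convention used throughout this package, the maximum fluorescence of a
component in a sample, `F_max(i, f) = a_if · max(b) · max(c)`, equals the
score itself.

`eemparafac` implements the complete workflow: EEM correction and
normalization, the non-negative trilinear fit with validation, component
matching across models via Tucker congruence, and a sensitivity analysis of
the popular "peak-picking" monitoring shortcut — together with a synthetic
EEM generator so every stage can be exercised against known ground truth.

## The synthetic generator: what it emulates, what it does not

Fluorophore classes are modeled as sums of Gaussian bands in wavelength, one
set per optical mode (`fluorophore()`). The built-in library
(`dom_library()`) provides seven components spanning the classes commonly
recovered from mixed-source DOM: humic-like components with broad red
emission (G1 230,305/414; G3 245,285,335/420; G6 265,365/472) and
protein-like components with narrow blue emission (G2 280/332; G4 225/332;
G5 245,290/364; G7 265/314). Only peak positions are standardized in the
field; band widths are this package's choices, made once: 12–25 nm for
excitation bands and protein-like emission, 40–50 nm for humic-like
emission, which reproduces the visual character of published component
spectra.

Concentrations are drawn i.i.d. log-normal (median 1, sdlog 0.6), giving the
positive, right-skewed gradients natural sample sets show; sample counts in
the bundled experiments mirror field campaigns (30–86 samples). Noise is
zero-mean Gaussian with additive and multiplicative parts; the acceptance
experiments use 1 % relative noise, a realistic signal-to-noise for a bench
fluorometer. Scatter is synthesized as Gaussian ridges along the first- and
second-order Rayleigh lines and the water Raman line, whose emission center
follows the fixed 3382 cm⁻¹ water Raman shift (≈397 nm at 350 nm
excitation). Inner-filter attenuation can be applied from simulated
CDOM-like exponential absorbance spectra (`simulate_absorbance()`), so the
correction round trip is testable.

The generator deliberately omits: radiative-transfer-accurate scatter
physics, instrument drift, wavelength-dependent detector response, and
pH/temperature effects on quantum yield. A green test therefore establishes
that the *algorithms* behave as specified on data obeying the trilinear
model with realistic spectral overlap — not that any particular instrument
or water matrix is calibrated.

Gaussian bands are parameterized in wavelength rather than wavenumber.
Real emission bands are more nearly Gaussian in energy, but at the 20–50 nm
widths involved the difference is far below the effects under study, and
wavelength parameterization keeps peak arithmetic (shifts, grid steps) exact.

## Preprocessing

The correction chain runs in the canonical order — inner-filter correction,
Raman normalization, scatter excision, total-signal normalization — and
`preprocess_dataset()` records that order. All steps are per-sample; only
the blank Raman area is shared.

* **Inner-filter correction** uses the absorbance-based formula
  `corrected = raw · 10^((A_ex + A_em)/2)` for a 1 cm cell. Cells with
  `A_ex + A_em > 3` are counted and flagged: at that optical density the
  correction is unreliable and dilution is the right remedy.
* **Raman normalization** divides by the trapezoidal area under the blank's
  emission scan at 350 nm excitation over 381–426 nm (endpoints included),
  yielding Raman Units.
* **Scatter excision** masks cells within a half-width of the lines
  `em = ex`, `em = 2·ex` and the water Raman line, plus the whole physically
  meaningless `em < ex` triangle. Defaults (±15, ±15, ±5 nm) are typical
  tutorial values and fully configurable; a zero half-width disables its
  band. Masked cells are never imputed here — missing-data handling belongs
  to the fitting step.
* **Total-signal normalization** divides each sample by its Frobenius norm
  over unmasked cells so concentration gradients do not dominate the fit.
  The literature phrase for the reversal ("multiplying the scores by the sum
  of the squared values") is ambiguous between the norm and the squared
  norm; this package stores the norm and multiplies scores by it, the unique
  convention under which normalize → fit → reverse reproduces the raw-scale
  scores exactly. The stored per-sample factor makes either convention
  auditable.

## The PARAFAC fit

`parafac_fit()` is alternating least squares with column-wise
non-negativity in all three modes — the physical constraint for
fluorescence — solved per row by an active-set non-negative least-squares on
the normal equations (Gram matrices are the Hadamard products of the factor
Grams, so each update is cheap even on the full instrument grid).

Numerical choices, all explicit and logged in the model's config snapshot:

* **Initialization**: uniform-random positive factors; `nstarts = 10` by
  default, best final SSE kept; every start's seed derives from the user
  seed, so fits are bit-reproducible.
* **Convergence**: relative SSE change below `1e-8`, or 2500 iterations;
  iteration also stops if SSE falls below `1e-16` of the data norm (exact
  fit). On noiseless data the relative-change rule runs the fit to machine
  precision because ALS converges geometrically until it hits the floor.
* **Missing data**: EM-style imputation. Masked cells start from linear
  interpolation along the emission axis and are overwritten with the model
  reconstruction after every sweep; the reported SSE covers observed cells
  only. This was chosen over weighted ALS for simplicity and testability;
  at the ≤25 % missing fractions scatter excision produces, recovery is
  indistinguishable (the suite verifies truth recovery at 20 % random
  masking).
* **Identifiability conventions**: loadings rescaled to unit maximum (scale
  into scores), components ordered by contribution, non-negativity removes
  sign flips. A warning is raised when two components' combined ex·em
  congruence exceeds 0.98 — the classic symptom of two-factor degeneracy.

**Validation.** `core_consistency()` computes the least-squares Tucker core
given the fitted loadings and returns `100·(1 − Σ(g − t)²/Σt²)` against the
superidentity; a one-component model returns 100 by construction.
`split_half()` shuffles samples once (seeded), assigns alternately, fits the
halves independently and requires every matched component to reach Tucker
congruence 0.95 in both modes. `select_components()` screens F = 3–7 and
recommends the largest F that passes split-half with core consistency above
a floor (default 60 %); the floor matters because a mildly over-factored
model can pass split-half while its core consistency collapses.

## Component comparison

`tucker_congruence()` is the plain cosine between loading vectors.
Classification follows the conventional reading: below 0.85 dissimilar,
0.85 to just under 0.95 "fair", 0.95 and above "equal". The literature
leaves [0.94, 0.95) unspecified; the boundary here is right-closed at 0.95
and applied consistently. `match_components()` pairs components by
maximizing the summed product of excitation and emission congruences over
one-to-one assignments — the product, not the mean, because both spectra
must agree; the optimum is found exactly (exhaustive assignment, components
per model ≤ 8, so at most 8! candidate pairings). A match's similarity class
uses the weaker of its two modes, again the stricter choice.

## Peak-monitoring sensitivity

For each component, `regression_map()` regresses the intensity at every
unmasked wavelength pair (across samples) on the component's F_max,
reporting R² and slope maps; the regression includes an intercept since
baseline and scatter leakage would otherwise bias the slope. Maps are meant
to be computed on EEMs in physical units (after inner-filter and Raman
correction, before total-signal normalization) with F_max after reversal,
so both axes share the intensity scale. `peak_monitor_report()` adds the
"high-R² area": the fraction of unmasked pixels within ±25 nm of the peak
with R² ≥ 0.9 — both window and threshold are reporting conventions, not
physics, and are configurable.

`contamination_experiment()` stages the monitoring failure mode: a clean
multi-sample dataset versus a cocktail in which a minority of samples
(default 10 of 86) also contain an intruder whose emission peak sits a set
offset from a resident component. The cocktail model is fitted with one
extra component: the point is that *even when* the model resolves the
intruder, its spectral overlap at the resident peak pixel decouples that
pixel's intensity from the resident component's F_max, and R² at the peak
drops — increasingly so as intruder amplitude grows. At zero offset the
extra component merges with its twin instead (the matched-component count
drops) and the peak R² is essentially unharmed, which is the complementary
diagnostic.

## The diversity experiment

The acceptance suite's central scenario: two sources share a humic-like
fluorophore whose bands are shifted 20 nm (both modes) between sources, and
each source has one unique component. Fitted individually, each source's
model recovers its truth nearly perfectly. Fitted jointly with one
component fewer than the true rank, the global model merges the two
variants into a compromise whose congruence to either individual model
lands in the "fair" band, while well-separated source-unique components
still come out "equal". With the package's band-width choices the expected
congruence of a balanced merge, `sqrt((1 + ρ)/2)` with
`ρ = exp(−Δ²/(4σ²))`, is ≈0.91 in excitation (σ = 15 nm, Δ = 20 nm) —
comfortably inside the fair band — and that is what the simulations
produce. Two further design choices keep the experiment controlled:

* The source-unique components sit at spectrally separated positions
  (tyrosine-like 265/314; red humic-like 390/495). When a unique component
  overlaps the shifted pair strongly, part of the merge error leaks into it
  and its recovery degrades too — a real phenomenon, but a different
  experiment.
* Both sources realize the *same* concentration series (paired draws), and
  the unique components are prominent constituents of their sources (median
  twice the shared component's concentration). The rank-3 fit of the
  rank-4 merged data faces a choice between merging the two shared variants
  and discarding the weakest component outright; if a unique component's
  integrated signal happens to be drawn small relative to the merge cost,
  the least-squares optimum discards it instead of merging — a degenerate
  outcome for this experiment. Balanced, prominent uniques make the merge
  the optimum across seeds, which is the regime the experiment is about.

## Known limitations

* Weighted ALS and Tucker3 alternatives are out of scope; the EM imputation
  loop can be slow to converge above ~30 % missing data.
* The split-half scheme is a seeded random half split; the S4C6T3 variant
  is pluggable but not built in.
* The exhaustive matcher is exact only up to 8 components per model.
* Synthetic absorbance uses a single exponential slope; real CDOM deviates
  in the UV, which slightly flattens inner-filter round trips there (still
  exact to numerical precision, since generation and correction share the
  formula).
* The `select_components()` recommendation rule is a heuristic; the
  diagnostics table, not the single number, is the scientific output.
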