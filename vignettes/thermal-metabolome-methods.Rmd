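---
title: "Methods: thermal reaction norms of the fly metabolome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal reaction norms of the fly metabolome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Ectotherms acclimate to the temperature they develop at, and the metabolome
is a sensitive readout of that acclimation. `thermometab` implements an
analysis of 1D ^1^H-NMR metabolite profiles of *Drosophila melanogaster*
reared across the species' full permissible developmental range (12 to
32 °C, ten temperatures, both sexes, five replicate pools of 40 flies per
sex-by-temperature cell), together with four functional phenotypes measured
in the same design: critical thermal minimum and maximum (CT~min~, CT~max~),
egg-to-adult viability from vials of exactly 40 eggs, and developmental
time.

The central question is the *shape* of each metabolite's reaction norm
across the thermal gradient. Three a-priori shapes are distinguished:

1. **no change** — the metabolite is unrelated to developmental temperature;
2. **linear change** — the metabolite is part of the graded physiological
   acclimation response;
3. **U-shaped (or bell-shaped) change** — the metabolite responds to the
   *deviation* from benign temperatures, i.e. to shared stress at both
   extremes (12/15.5 °C and 31/32 °C).

Because no raw spectra are publicly deposited for this design, the package
ships a first-class synthetic-data generator that plants each of these
shapes (plus sex-dimorphic and null metabolites) with known ground truth,
so the entire pipeline can be exercised and validated by recovery tests.

## Pipeline overview

The preprocessing order is fixed and logged on the data containers, and
each step refuses to run twice:

1. **TSP referencing** — each spectrum is shifted (whole grid points) so
   the maximum in a ±0.25 ppm window sits at the grid point nearest
   −0.017 ppm, the TSP reference position.
2. **Alignment** — interval-based correlation-optimized shifting: per
   segment (default: one whole-window segment) each spectrum takes the
   integer-bin shift, capped at `max_shift` (default 0.01 ppm), that
   maximizes cross-correlation with the set's point-wise median spectrum;
   two passes, with the median recomputed between them. The published
   segment scheme is not recoverable, so the segment list and cap are
   configuration, echoed into the processing log.
3. **Trimming** — the residual-water window (closed interval 4.67–4.85
   ppm) and the spectrum edges are removed. The stated analysis window is
   9.5–0.5 ppm, but the assignment table's highest signal (nicotinamide
   ribotide, integrated at 9.581–9.595 ppm) lies above 9.5, so the
   *pipeline's* default keep-window extends to 9.6 ppm; `trim_spectrum()`
   itself defaults to the stated 9.5.
4. **Total-intensity normalization** — every spectrum is divided by its
   own summed intensity (each row then sums to one), removing
   sample-amount (dilution) variation.
5. **Pareto scaling** — per column, optionally mean-centred, divided by
   the square root of the standard deviation; all multivariate models run
   on Pareto-scaled data. The sex-difference analysis scales *without*
   centring, so score magnitude measures differentiation.

## Multivariate models

**PCA and target rotation.** Per sex, a centred PCA of the Pareto-scaled
matrix is rotated in the PC1/PC2 plane so the first rotated component
correlates maximally with developmental temperature (the *linear
component*); its in-plane complement is the *U-shape component*. The
optimal angle has the closed form of the regression direction
$u \propto V^{-1}c$ (with $V$ the score covariance and $c$ the
score–target covariance), which the tests verify against a 0.01° grid
search. Components are oriented so the linear component rises with
temperature and the U-shape component rises with the extreme-temperature
encoding; signs in all outputs follow that convention.

**OPLS.** Predictions of temperature (linear prior), of the two-state
extreme/intermediate encoding (U-shape prior; extreme = {12, 15.5, 31,
32 °C}), of condition-mean developmental time (per sex) and of pooled
egg-to-adult viability use orthogonal projections to latent structures in
the orthogonal-filtering formulation: the predictive weight is
$X^\top y$-direction; each orthogonal component is the part of the current
X loading orthogonal to that weight, deflated before the predictive
component is fitted. With no orthogonal components the model reduces to
single-component PLS (verified against an independent NIPALS
implementation). Component counts are written `"1+n"` (one predictive, n
orthogonal) and default to 1+2 / 1+1 / 1+2 / 1+2 for the four targets —
the published layout for this design.

**Cross-validated predictability.** Q² uses leave-one-condition-out
folds: all samples of one sex-by-temperature condition are held out
together, centring/scaling is re-estimated inside each training fold
(stricter than the source describes, and recorded as such), and
$Q^2 = 1 - \mathrm{PRESS}/\sum(y - \bar y_{\text{train}})^2$ with the
held-out deviations taken from each fold's pooled training mean. Whether
the original software used a fold-wise or global denominator is not
recoverable; the fold-pooled-training-mean convention is used and
documented here. Q² ≥ 0.5 is read as a significant model.

**OPLS-DA and clustering.** A multi-response OPLS against the 20-class
sex-by-temperature indicator matrix yields per-sample predictive scores;
per-condition mean scores are clustered with Ward's minimum-variance
criterion (Lance–Williams update on squared Euclidean distances, leaves
ordered lexicographically for deterministic ties) and exported as Newick.
The number of class-orthogonal components defaults to the value (0–3)
with the best class-stratified cross-validated prediction accuracy; the
original component count for this step is unreported.

## Metabolite screening

Each of the 30 assigned metabolites is quantified as the summed intensity
over its closed integration range (the bundled assignment table), then
correlated (Pearson) with seven targets: the linear and U-shape components,
the linear- and U-shape-prior OPLS scores, developmental-time OPLS scores
(all per sex), viability OPLS scores (sexes pooled, since viability is not
sex-resolved) and the first component of the sex-difference PCA.
Significance uses the sequential Bonferroni (Holm) step-down with
denominators starting at an **assumed family size of 100 metabolites** —
the strictest threshold is 0.05/100 — applied separately per target and
sex. Each correlation is additionally *verified* at the metabolite's other
characteristic shifts (±0.005 ppm windows): whether the source demanded
significance or only sign-consistency there is ambiguous, so
sign-consistency is implemented and reported as a separate flag, never
mixed into the significance decision.

A metabolite is labelled `linear±` / `ushape±` per sex when it is
significant on the component *or* the prior target of that shape with a
consistent sign; conflicting significant signs within a shape family yield
no label. A negative U-shape label is the inverted-U (bell) norm:
depressed at both extremes.

**Sex differences.** For every temperature, each female spectrum minus the
median male spectrum (`F-medM`) and the median female minus each male
spectrum (`medF-M`) form an uncentred difference matrix (10 rows per
temperature under the default design). After uncentred Pareto scaling, an
uncentred PCA gives scores whose deviation from zero *is* the sex
difference; PC1 (oriented to a non-negative grand mean) is regressed on
temperature with linear + quadratic + cubic terms per row tagging, and the
root-sum-of-squares of per-component mean scores summarizes total
differentiation per temperature. Scaling the differences in the
study's global Pareto manner is an assumption (only "not centred" is
stated) and is flagged in the result metadata.

## Phenotype models

* **Thermal limits** — OLS of CT~min~/CT~max~ on sex, temperature and
  their interaction, reduced sequentially by F-tests at α = 0.05
  (interaction first; main effects are never dropped while part of a
  retained interaction). Degenerate noiseless fits resolve explicitly: a
  vanishing extra sum of squares is never significant.
* **Viability** — binomial-logit regression of per-vial emergence on
  standardized temperature and its square; overdispersion is the Pearson
  χ²/df, reported standard errors are model SEs × √dispersion
  (quasi-binomial correction; point estimates equal the binomial fit);
  influential vials are retained by design.
* **Developmental time** — Poisson log-link GLMM with standardized
  temperature (linear + quadratic), sex, their interaction and a vial
  random intercept, fitted by Laplace-approximated ML (`lme4::glmer`);
  fixed effects reduced by likelihood-ratio tests with the same
  halt-on-interaction rule.

Quadratic terms use standardized (mean 0, SD 1) temperature. The original
report's second-degree coefficients appear to use an unstated (likely
orthogonal-polynomial) coding, so numeric equality of quadratic
coefficients is not a meaningful check — sign and curve shape are, and the
generator's curvature truths are instead derived from the reported curve
shapes (viability ≈ 40–50% at the extremes vs 60–80% at intermediate
temperatures; development ≈ 49 d at 12 °C down to ≈ 7.5 d at 29.5 °C).

## The synthetic-data generator

`simulate_spectra()` emulates processed (phased, baseline-correct) 1D
spectra on a −0.1 to 9.6 ppm grid at 0.001 ppm (~9,700 points): each
metabolite contributes a Lorentzian line (FWHM 0.002 ppm; multiplets are
collapsed to singlets) at each characteristic shift of the bundled
assignment table, with integrated area = baseline × a class modifier:

* linear: $1 + e\,(T - \bar T)/(T_{max} - T_{min})$;
* U-shape: $1 + e\,\mathbf{1}[T \in \{12, 15.5, 31, 32\}]$ — the two-state
  structure the analysis actually tests, not a smooth parabola;
* sex-dimorphic: a ±δ/2 female/male split, optionally weighted by a
  Gaussian hump in temperature for dimorphism that peaks at benign
  temperatures.

The default truth set plants 10 linear (5 up, 5 down), 5 inverted-U, 5
sex-dimorphic and 10 null metabolites among the 30 assigned names. Class
assignment respects spectral adjacency — metabolites whose integration
windows receive Lorentzian tail leakage from a close neighbour (the
leucine/isoleucine/valine cluster; leucine's 1.73 ppm line inside the
arginine window; maltose beside glucose) share that neighbour's class or a
temperature-neutral one — so the planted labels are exact on the scale the
analysis observes. One bundled-table quirk is handled in the generator:
β-alanine's printed shift list does not cover its printed integration
range, so a line at the range midpoint is added for simulation.

Three generator choices matter for interpreting the recovery tests:

* **Compositional closure.** Total-intensity normalization means only
  relative composition is observable. The generator therefore carries an
  unassigned spectral background (a comb of ~60 Lorentzian teeth placed
  away from every integration range, verification window and the water
  region) whose total area absorbs the planted-class imbalance, keeping
  the pre-dilution total exactly conserved. Without this, planted "null"
  metabolites would inherit apparent reaction norms from the denominator —
  an artefact of closure, not of the analysis.
* **Grid-quantized jitter.** The per-sample global chemical-shift jitter
  (uniform, ±0.005 ppm) is quantized to whole grid steps: the generator
  models exactly the rigid misalignment that referencing and alignment
  invert. Sub-grid lineshape interpolation is out of scope, as are all
  FID-level effects (no phase, no J-coupling, no CPMG relaxation).
* **Noise floor.** Additive baseline noise (SD 2 intensity units; strong
  lines have point SNR ≈ 160) is set *above* the residual tail leakage
  between neighbouring assignment windows, so null labels are null
  relative to noise. Planted effects (fractional effect size 0.6) remain
  far above three times the integrated noise SD.

Dilution is log-normal (sdlog 0.15). One parent seed is split into one
sub-seed per sample, so identical inputs give bitwise-identical spectra
and partial regeneration is reproducible. Phenotype truths use the
reported thermal-limit coefficients verbatim (CT~min~ −4.578 + 0.412 T;
CT~max~ 37.601 + 0.123 T, male offset −0.692, interaction 0.019),
beta-binomial vial emergence with variance-inflation 2, and Poisson
emergence days with a 0.03 log-scale male offset and vial SD 0.05.

What the generator does **not** emulate — and hence what passing recovery
tests do not show about real spectra: J-coupled multiplet structure,
baseline and phase distortions, peak-width variation, metabolite
covariance beyond the planted classes, and biological totals that really
do change with treatment (closure is an idealisation; on real data,
normalization artefacts remain a caveat of the method itself).

## Numerical choices and degenerate inputs

* PCA is computed by thin SVD; component signs follow the
  largest-magnitude-loading-positive convention; rank violations error
  with the achievable rank.
* Zero-variance columns: Pareto centred → all-zero column; uncentred →
  left unscaled with a warning. Zero-variance metabolite intensities are
  excluded from testing with a warning, never silently assigned p-values.
* An all-zero sex-difference matrix returns zero scores with a warning
  rather than a degenerate PCA.
* Alignment tie-breaks prefer the smallest |lag|; Ward ties are broken by
  lexicographic label order; Holm is implemented by explicit prefix
  checking (cross-checked against brute force).
* The noiseless thermal-limit reduction resolves 0/0 F-statistics
  explicitly (zero extra sum of squares → p = 1; positive extra sum of
  squares over zero residual → p = 0).

## Problem sizes used by the test-suite and acceptance script

The default design (100 spectra × ~8,900 retained points) runs end-to-end
in well under a minute. The recovery study uses 20 independent seeds of
the full default design; phenotype parameter-recovery studies use 100–200
replicates at the assayed-fly scale of the original design with 6 counted
vials per temperature (the subset scale at which vials were scored);
permutation baselines use 50 label permutations. These sizes were chosen
so each study's Monte-Carlo error is small relative to the effect being
checked.

## Known limitations

* Overlapping assignment windows are inherited from the assignment table;
  leakage between neighbours is real in the simulation, as in real
  spectra, and is handled by class placement and the noise floor rather
  than deconvolution (out of scope).
* The O2PLS "data-side" orthogonal structure beyond class-orthogonal
  filtering is not modelled; no VIP scores; no SIMCA file compatibility.
* Baseline/phase correction and vendor-format ingestion are out of scope;
  the pipeline starts from processed real-valued spectra.
* Q² denominators, icoshift segmentation and the OPLS-DA component count
  are unrecoverable from the source and are explicit configuration with
  documented defaults.
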