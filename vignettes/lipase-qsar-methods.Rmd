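---
title: "Methods: QSAR models of lipase substrate specificity"
author: "lipaseQSAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QSAR models of lipase substrate specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipaseQSAR)
```

## The problem

Three alkaline lipases (labeled L-A1, L-A2 and L-A3, secreted by marine
*Burkholderia* and *Acinetobacter* isolates) hydrolyze a broad spectrum of
esters — triglycerides, methyl and ethyl esters — at rates that vary with
the substrate's structure. The package models that substrate specificity
quantitatively: a linear quantitative structure–activity relationship
(QSAR) links tabulated molecular descriptors of each ester to the log10 of
the measured hydrolysis activity (U/ml, one U = 1 µmol fatty acid released
per minute), and a mixture rule extends the single-ester predictions to
natural oils treated as blends of homotriglycerides.

The measured activity comes from an NaOH titration of released fatty
acids; `activity_from_titration()` implements the assay conversion
\(X = (B-A)\cdot(c/0.05)\cdot 50\cdot\tfrac{1}{60}\cdot n\), and all
modeling is done on \(\log_{10} X\). Zero or negative activities are
rejected at the transform, never clamped: a silent floor would leak into
the least-squares fit.

## Data model and the bundled study tables

A `descriptor_table` is a validated data frame: one ester per row, an
integer `substrate_id`, a `role` ("training"/"test"), fully populated
numeric descriptor columns, and optionally the observed log activity. The
three bundled tables (`load_fixture("L-A1")`, …) transcribe the original
study's data for 16 esters each — 12 training and 4 test substrates
(training ids 1, 3, 4, 5, 7, 8, 9, 10, 12, 13, 14, 15) — together with the
originally printed prediction and residual columns, which the validation
machinery treats as reference output, never as input.

Two transcription caveats are built into the data model:

* The three tables are **self-contained**. Although they share substrate
  numbering, identically numbered rows carry incompatible descriptor
  values across tables (e.g. `Shadow_XYfrac` for the same id differs
  between the L-A1 and L-A2 tables), so rows are never joined by id.
* The L-A2 equation names a descriptor `Jurs_PNSA_1` while the
  corresponding table column is headed `Jurs_FPSA_1`. Which symbol is the
  typo cannot be decided from the printed data; the column is stored under
  its printed header and the equation binds to it through an explicit
  alias map carried by the table and the model.

## Model family and validation statistics

A `qsar_model` is an intercept plus terms, each term a descriptor under a
basis transform: identity, or the truncated-linear splines
\(\langle x-k\rangle=\max(x-k,0)\) and \(\langle k-x\rangle=\max(k-x,0)\)
used by genetic function approximation. Fitting is ordinary least squares
through a QR decomposition; a rank-deficient design is an error naming the
collinear columns rather than a silent drop.

`fit_ols()` reports the full validation suite:

* \(R^2 = 1 - SSE/SST\), adjusted
  \(R^2_{adj} = 1 - (1-R^2)\frac{n-1}{n-p-1}\), and the overall
  \(F = \frac{R^2/p}{(1-R^2)/(n-p-1)}\);
* the Friedman lack-of-fit score
  \(LOF = \frac{SSE/n}{(1-(c+d\,p)/n)^2}\) with the counting convention
  `c` = number of non-intercept terms, `p` = all coefficients including
  the intercept, and smoothing factor `d = 0.5` (the study's setting).
  The originally reported LOF and F values follow some other, undocumented
  counting convention and are not recoverable from the printed residuals,
  so LOF and F are validated against their closed forms and monotonicity
  properties instead of against those printed numbers;
* leave-one-out \(q^2 = 1 - PRESS/SST\), computed through the exact
  hat-matrix identity \(e_{(i)} = e_i/(1-h_{ii})\) and cross-checked in the
  test suite against a literal n-refit loop.

Descriptor importance uses standardized coefficient magnitudes
\(|b_j|\,sd(x_j)/sd(y)\), with ties broken by term label so rankings are
deterministic. On the L-A1 training data this reproduces the originally
reported importance values (≈ 54.5, 39.4, 19.9, 6.05, 0.61) and ordering.

### Refit protocol and coefficient rounding

The published equations print coefficients to about four significant
digits. Descriptors span three orders of magnitude (molecular volumes near
800 next to shadow fractions near 0.5), so that rounding alone moves
direct predictions by up to ~0.06 log units on training rows. Canonical
reproduction therefore refits OLS on each table's 12 training rows using
the published *term set*, recovering full-precision coefficients
(`reproduce_prediction_columns()`); the printed coefficients are kept
verbatim in the registry (`published_model()`) for provenance and direct
evaluation.

### Data-consistency findings

Reproduction succeeds fully only for L-A1, and the package's validation
battery documents why:

* For L-A1 the OLS refit matches every printed training prediction to
  better than 0.01 log units, and the leave-one-out q² (0.890) matches the
  reported 0.889.
* For L-A2 and L-A3 the printed training-prediction columns correlate with
  the observations (R² ≈ 0.985) **better than the best possible linear
  fit** on the printed descriptor columns (OLS refit R² ≈ 0.92 for both).
  No linear model — OLS or PLS at any number of components — on those
  printed columns can therefore reproduce the printed predictions; the
  values must have been produced from inputs that differ from what was
  printed (for L-A2, plausibly the unprinted true `Jurs_PNSA_1` values).
  The per-row reproduction checks for these two lipases are retained at
  their stated tolerance and fail visibly rather than being loosened.
* The L-A2 printed coefficients are additionally inconsistent with the
  printed table (direct evaluation of the equation lands ~0.9 log units
  from the printed predictions), and the four test-set prediction values
  are identical across all three tables — a transcription artifact — so
  test rows are compared but never gated.
* The study's summary and body report conflicting adjusted-R² and
  cross-validation figures for L-A1/L-A2 (apparently swapped); the
  per-equation lines in the body are taken as canonical.

## The GFA engine

`run_gfa()` evolves a population of descriptor-subset models under LOF
fitness: score, rank (ascending LOF, ties by fewer terms then
lexicographic keys), copy the `elite` best unchanged, then refill via
tournament selection, a single-shared-cut-point splice crossover
(duplicate (descriptor, transform) pairs collapse; sizes clamped back into
bounds), and a one-edit mutation (swap/add/drop a term, or toggle a spline
basis at a knot drawn from the training-quantile candidates — knots must
lie inside the data range to be identifiable). The search stops when the
best term set has been unchanged for `convergence_window` generations,
the "descriptors became constant" rule.

Only the population size (1500) and d = 0.5 were fixed by the original
study; the remaining defaults (crossover 0.9, mutation 0.1, elitism 2,
tournament 3, max 5 terms matching the published models, window 50) follow
common genetic-algorithm practice and are all exposed in `gfa_config()`.
`gfa_desk_config()` (population 200, 100 generations, window 20) is the
profile used throughout the test suite; on the pools involved (≤ 120
descriptors) it reaches the same optima as the full-size profile, which
remains the default of `gfa_config()`. Every run takes a mandatory seed
and restores the caller's RNG state, so results are exactly reproducible.
Fitness evaluations are cached by term-set key; unfittable models score
`Inf` and are culled by selection.

G/PLS refinement is exposed as an optional post-processing step
(`fit_gpls()` on a selected term set, PLS via mixOmics) rather than
interleaved per generation, since the original interleaving is
unspecified; at full components it coincides with OLS, which is the
built-in cross-check.

## The mixture predictor

Natural oils are modeled as mixtures of homotriglycerides with mass
fractions above 1% (the study's inclusion rule). The mixture activity is
the mole-fraction-weighted arithmetic mean on the linear U/ml scale,

\[ X_{mix} = \sum_i w_i X_i, \qquad
   w_i = \frac{y_i/M_i}{\sum_j y_j/M_j}, \]

the only reading of the original mixture rule in which every legend symbol
participates coherently. Averaging is done on the linear scale because
titration activity is additive in released fatty acids. An unweighted
`simple_mean` mode implements the alternative "divide by the component
count" reading; the renormalized mole-fraction mode is the default.
Default triglyceride molar masses (tripalmitin 807.3, tristearin 891.5,
triolein 885.4, trilinolenin 873.3, trilinolein 879.4 g/mol) can be
overridden per composition; printed mass fractions may sum to slightly
over 100% due to rounding, so the validator allows up to 101%.

The originally reported predicted oil activities cannot be reproduced:
the descriptor values for tristearin, trilinolein and trilinolenin were
never published, so the inputs are unrecoverable. The mixture module is
therefore validated by its algebraic properties (convexity, reordering and
rescaling invariance, single-component identity, agreement with a
brute-force evaluation of the mixture rule to 1e-12), and the bundled
measured activities are carried for side-by-side reporting only.

## The synthetic generator

`generate_synthetic()` produces tables with known ground truth that mimic
the statistical shape of the study data: latent standardized descriptors
from an equicorrelated Gaussian (pairwise correlation ρ), presented on
per-column scales drawn log-uniformly over three orders of magnitude, a
sparse linear (optionally spline) true model on the latent scale, and
Gaussian noise on log activity. It emulates scale heterogeneity,
collinearity and small-n noise — the features that stress
standardization, rounding amplification and subset search — and makes no
attempt to mimic real descriptor physics or distributions, so passing
tests demonstrate statistical correctness of the machinery, not chemical
realism. Seeds are mandatory; generation is bitwise reproducible.

`paper_like_scenario()` is the study-shaped preset: 16 substrates split
12/4, 120 candidate descriptors, a 5-term truth with effects
(0.10, −0.08, 0.06, −0.05, 0.04) log units against the observed activity
spread (s.d. ≈ 0.16), ρ = 0.3, and noise s.d. 0.022 calibrated so the true
support fits with training R² ≈ 0.98, the quality of the published models.

### The recovery experiment

The ground-truth recovery battery runs 50 seeded repeats of a
well-separated scenario (n = 30, 20 descriptors, 3 active, effects
(1, −0.8, 0.6) versus noise s.d. 0.1) and requires the GFA best model to
equal the true support in at least 80% of runs, with the model size fixed
at the known sparsity (`min_terms = max_terms = 3`), mirroring the
fixed-size exhaustive-search comparison. The size is fixed deliberately:
with d = 0.5 and a free size, adding a fourth term enlarges the LOF
denominator by only ~12% at these dimensions, while the best of ~17
spurious candidates frequently reduces SSE by more than that, so the LOF
optimum itself — correctly found by the search — often carries one decoy
term. That is a property of the lack-of-fit criterion at this n/d, not of
the genetic search, and fixing the size isolates the latter.

## Numerical choices and problem sizes

* OLS via QR; explicit errors for rank deficiency (naming columns) and
  for n < p + 1; with n = p + 1 the fit interpolates and
  degrees-of-freedom statistics are `NA`, as is LOF whenever
  c + d·p ≥ n.
* Leave-one-out via the hat-matrix identity; refits with leverage-1 rows
  are an error, not an NaN.
* All stochastic components (GFA, generator) consume explicit integer
  seeds and restore the caller's RNG state.
* The test suite runs the GFA at desk scale (populations 40–200, pools of
  5–20 descriptors, 10–50 seeded repeats) and the oracle batteries at
  100 random instances; the whole suite completes in about a minute on a
  single core.

## Limitations

* Descriptor values are consumed as tabulated inputs; the package does not
  compute descriptors from structures, and substrate identities beyond
  their numbering are unknown.
* Equivalence with the original modeling software is claimed at the level
  of the selected descriptor families and reproduced statistics, not
  bit-level search behavior, whose operator set is proprietary.
* The L-A2 and L-A3 printed prediction columns are internally inconsistent
  with their printed descriptors (see above); the package reproduces what
  the printed data support and reports the rest as red, rather than
  widening tolerances.
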