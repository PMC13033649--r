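---
title: "Reconstructing missing periodontal records: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing missing periodontal records: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perioimpute)
```

## The problem

Periodontal charts are high-dimensional and routinely incomplete: four
measurements (probing depth, clinical attachment loss, furcation involvement,
bleeding on probing) at many tooth sites, with holes from inconsistent
charting and record loss. Because the true values behind real holes are
unknown, imputation methods are best compared on a *synthetic* cohort where
the complete table exists, a known fraction of cells is hidden, and every
method is scored against the hidden truth. This package implements that whole
loop: simulator, masking, a denoising-autoencoder imputer, three classical
baselines, and the evaluation layer.

## The synthetic cohort

`generate_cohort()` draws, for each of `n_patients` (default 200) virtual
patients:

* **Age** — integer uniform on [18, 80] years; **gender, smoking, diabetes**
  — Bernoulli indicators. Their marginals default to 0.5 each: the clinical
  literature gives no canonical values for a generic periodontal cohort, and
  0.5 is the least-informative choice; all three are `sim_config()` fields
  for users who want epidemiologically matched prevalences.
* **Probing depth** (mm, per site) — Normal(3.5, 1.0) clipped from below at
  1 mm, the minimum biologically plausible pocket depth. Clipping, not
  rejection sampling: the floor is a constraint on emitted values, and
  clipping is the minimal mechanism that enforces it (it moves the mean by
  under 0.001 mm at the defaults).
* **Attachment loss** (mm, per site) — Normal(2.0, 1.0), negatives clipped to
  0, then coupled to the same site's probing depth by
  `AL <- AL + 0.5 (PD − AL)`. The order is draw → clip → couple; the result
  is automatically nonnegative (at least half the floored probing depth), so
  no re-clip is needed. The coupling gives the clinically expected positive
  PD–AL correlation, analytically 1/√2 ≈ 0.707 for unit-variance parents.
* **Furcation grade** — categorical on grades 0–3 with probabilities
  0.60/0.25/0.10/0.05. Grades are simulated at *all eight* sites, incisors
  included, because the benchmark's feature layout carries a furcation column
  for every site; clinically furcation only exists for multi-rooted teeth, so
  users modelling realism can suppress it by configuring sites accordingly.
* **Bleeding on probing** — Bernoulli(0.6).

Eight sites × four measurements gives 32 tooth-site features, plus the four
demographics: 36 features per patient.

One master seed spawns a named RNG substream per site and one for the
demographic block (`substream_seed()`), so adding or removing sites never
perturbs the draws of the remaining columns — a property the test suite
checks directly.

What the generator deliberately does **not** model: demographic→clinical
dependencies (a smoker's probing depths have the same distribution as a
non-smoker's), spatial correlation between sites beyond the per-site PD–AL
coupling, and any missing-at-random or missing-not-at-random structure.
Passing benchmarks on this cohort therefore demonstrates correct mechanics
and calibrated error magnitudes under MCAR with known marginals — not
performance on real charts, where structured heterogeneity and informative
missingness can reverse method rankings.

## Masking

`apply_mcar()` hides each tooth-site cell with an independent Bernoulli(0.15)
trial; demographics are never masked (they are recorded in essentially every
clinical setting). The boolean mask is returned, stored and shipped as its
own artifact; downstream code never re-infers missingness from the data, so
"structurally absent" and "imputed then compared" can never be confused.
Externally a masked cell is an empty CSV field, and the mask CSV (0/1) is
authoritative; the reader checks the two agree.

## The denoising autoencoder

The imputer operates on the standardized 32-vector of tooth-site features.
Pipeline, in `train_dae()`:

1. **Corruption / mean-fill** — masked cells are set to their column's
   observed mean. This *is* the denoising corruption: the network sees
   mean-filled vectors.
2. **Standardisation** — per-column mean and *population* standard deviation
   (divide by n) computed on the filled matrix, reused unchanged at
   imputation time so deployment introduces no new statistics. Columns with
   sd below 1e-8 degenerate to pure centering (sd set to 1, with a warning).
3. **Network** — encoder `h = tanh(W₁x + b₁)` with 18 hidden units, linear
   decoder `x̂ = W₂h + b₂`. Weights start Glorot-uniform (the stable default
   for tanh layers; the initialisation scheme and seed are recorded in
   `train_config()` so a run is fully reproducible), biases at zero.
4. **Training** — 100 epochs, each one full-batch forward pass plus one
   gradient step of size 0.01 on
   `L = (1/n) Σᵢ ‖x̂⁽ⁱ⁾ − x⁽ⁱ⁾‖²` (per-row squared norm averaged over
   patients; the per-entry variant L/32 is logged alongside in the trace for
   comparability with implementations that average over entries). Gradients
   are exact backpropagation, verified against central finite differences in
   the tests.

**Training target.** The network is trained to reproduce the standardized
*mean-filled matrix itself*, not the uncorrupted truth. This is a deliberate
design decision: on real data the uncorrupted truth does not exist, so a
truth-targeted trainer could never be deployed, and targeting the truth in a
benchmark leaks the quantity being scored into the fit. With the filled
matrix as target, the bottleneck (18 < 32) forces the network to express each
feature through shared latent structure, so reconstructions at masked cells
borrow information from correlated observed features (notably the PD–AL
pairs) instead of merely echoing the column mean. `train_dae(target =
"truth")` exposes the alternative reading for controlled experiments.

**Imputation.** `impute_dae()` replays the training preprocessing, runs the
network, inverse-transforms, and substitutes reconstructions at masked cells
only — observed cells are preserved bit-identically, an invariant the tests
enforce for every imputer. Two output modes:

* `raw` (default) — continuous reconstructions everywhere. All MAE/RMSE
  metrics are computed in this mode: a bleeding probability of 0.55 against
  a true 1 contributes 0.45, which keeps errors comparable across mixed
  types and matches the reference error magnitudes.
* `clinical` — chart-ready values: bleeding thresholded at 0.5, furcation
  rounded and clipped into grades 0–3, probing depth floored at 1 mm,
  attachment loss at 0. Agreement statistics (quadratic weighted kappa) are
  computed on grades, i.e. on the discretised values.

A fully masked patient standardises to the zero vector, so its imputation is
the inverse-transformed network output at **0** — approximately the column
means plus whatever the decoder's bias has learned.

## Baselines

* **Mean** — observed column mean per masked cell.
* **KNN** (`k = 5`) — Euclidean distance on the standardized tooth-site
  block over the coordinates observed in *both* patients, rescaled by
  `32 / #shared` so sparse overlaps are not spuriously close (the standard
  missing-aware scaling). Donors must observe the target feature; continuous
  targets take the donor mean, categorical targets a majority vote. Distance
  ties break toward the lower patient index and vote ties toward the lower
  grade — arbitrary but documented and deterministic. A cell with no
  eligible donor falls back to the column mean with a warning.
* **Chained equations** — `m = 5` stochastic imputations × 10 cycles.
  Masked cells start as random draws from their feature's observed values;
  each cycle visits incomplete features in column order and redraws their
  masked cells from a conditional model fitted on the rows where the feature
  is observed (all other features, demographics included, as predictors,
  carrying their current imputations — the standard chained-equations
  scheme). Conditionals by type: predictive mean matching (donor pool 5,
  random pick among the nearest predicted values) for probing depth and
  attachment loss; logistic regression with a Bernoulli draw for bleeding;
  proportional-odds logistic regression (via `MASS::polr`) with a
  categorical draw for furcation. Draws are clipped to plausible ranges
  (PD ≥ 1 mm, AL ≥ 0, grades 0–3). Singular designs — unavoidable when the
  36 predictors approach the number of observed rows — fall back to a
  ridge-regularised solve (diagonal jitter 1e-6) with a warning, and a
  failed proportional-odds fit falls back to a marginal draw. The final
  metrics average the per-imputation metrics across the m completions.

## Evaluation

All metrics are computed at masked cells only. Per feature: MAE and RMSE of
imputed minus truth. Category and overall metrics pool features weighted by
their masked-cell counts; crucially, RMSE pools *squared* errors (root of
the weighted mean square), not a weighted mean of per-feature RMSEs — the
pooled form is exactly the RMSE of the concatenated residuals, which is what
"aggregating across all imputed entries" means, and the tests prove the
identity on random fixtures. Quadratic weighted kappa uses the standard
`1 − Σ wO / Σ wE` form with quadratic distance weights; a degenerate
denominator (all mass on one grade) returns `NA` with a warning rather than
a misleading number. Distribution summaries bin observed and imputed values
on shared equal-width edges (default 15 bins over the pooled range).

## Problem sizes and reproducibility

The default study is 200 patients × 32 maskable cells at rate 0.15 — about
960 masked cells per replicate — and the headline numbers average 20
replicate seeds, i.e. roughly 19,000 scored cells; one replicate trains in
well under a second, so the full benchmark is interactive. The test suite
uses cohorts of 100,000 patients where moment checks need tight standard
errors, and cohorts of 8–120 where exhaustive oracles (scalar-loop
recomputation, brute-force neighbour enumeration, finite-difference
gradients) are the point. Every stochastic stage takes an explicit seed, and
`run_workflow()` derives per-stage substream seeds from each replicate seed,
so per-seed outputs are independent of how many seeds run and in what order.

## Known limitations

* MCAR only; the benchmark says nothing about informative missingness.
* The continuous reconstruction loss treats grades and probabilities as
  numbers; ordinal- or binary-aware heads would be the first upgrade.
* No demographic→clinical structure means the autoencoder faces an easier
  joint distribution than real charts present; synthetic results are upper
  bounds on, not estimates of, real-data performance.
* No hyperparameter search: depth, width, learning-rate schedules and
  regularisation are fixed at the reference configuration by design.
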