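# perioimpute

Missing entries are endemic in periodontal charting data: probing depths,
attachment levels, furcation grades and bleeding indicators are recorded per
tooth site, and incomplete charting, practice variation and record loss leave
holes that bias retrospective analyses and cripple predictive models.
`perioimpute` is a self-contained R workbench for studying how well different
imputation strategies reconstruct such records under controlled conditions:
it simulates a fully observed synthetic cohort, hides a known fraction of the
clinical cells completely at random, reconstructs them, and scores every
method against the ground truth. It is aimed at biostatisticians and dental
researchers who want a reproducible benchmark harness — and a reference
implementation of a minimal neural imputer — before committing to a method on
real charts.

## The model

Each virtual patient carries 4 demographics (age, gender, smoking, diabetes)
and 4 measurements at 8 tooth sites (32 clinical features): probing depth
PD ~ max(1, N(3.5, 1)) mm, attachment loss built from AL0 ~ max(0, N(2, 1)) mm
via the coupling update

    AL = AL0 + 0.5 (PD − AL0),

furcation grade ~ Categorical(0.60, 0.25, 0.10, 0.05) on grades 0–3, and
bleeding on probing ~ Bernoulli(0.6). Each tooth-site cell is then masked
independently with probability 0.15 (MCAR); demographics stay observed.

The core imputer is a denoising autoencoder on the standardized 32-vector
**x** of tooth-site features, with masked entries corrupted to their column
means:

    h = tanh(W₁x + b₁),   x̂ = W₂h + b₂,   W₁ ∈ ℝ³²ˣ¹⁸, W₂ ∈ ℝ¹⁸ˣ³²

trained for 100 epochs of full-batch gradient descent (learning rate 0.01) on
the mean squared reconstruction loss L = (1/n) Σᵢ ‖x̂⁽ⁱ⁾ − x⁽ⁱ⁾‖². Masked
cells are replaced by the inverse-standardized reconstruction; observed cells
are never touched. Classical baselines — column-mean imputation, k-nearest
neighbours (k = 5, missing-aware Euclidean distance), and chained equations
(m = 5 imputations × 10 cycles with predictive mean matching / logistic /
proportional-odds conditionals and plausibility constraints) — run through the
same interface. Quality is scored at the masked cells only: per-feature MAE
and RMSE, missing-count-weighted category and overall metrics (the pooled
RMSE equals RMSE on all masked residuals jointly), quadratic weighted kappa
for ordinal agreement, and histogram comparisons of observed versus imputed
distributions.

## Worked example

```r
library(perioimpute)

cohort  <- generate_cohort(sim_config(n_patients = 200, seed = 42))
mc      <- apply_mcar(cohort, rate = 0.15, seed = 43)
fit     <- train_dae(mc$masked, train_config(seed = 44))
imputed <- impute_dae(fit, mc$masked, mc$mask)
evaluate_imputation(cohort, imputed, mc$mask)
#> Imputation evaluation over 958 masked cells
#>   overall MAE 0.6322  RMSE 0.7981
#>   ProbingDepth       MAE 0.8175  RMSE 1.0352  (n = 242)
#>   AttachmentLoss     MAE 0.5349  RMSE 0.6718  (n = 248)
#>   Furcation          MAE 0.7142  RMSE 0.8812  (n = 224)
#>   BleedingOnProbing  MAE 0.4721  RMSE 0.5160  (n = 244)
```

With 958 of the 6,400 tooth-site cells hidden, the autoencoder reconstructs
them with an average absolute error of 0.63 units (mm for the continuous
features, grades for furcation, probability for bleeding). Bleeding on
probing — binary, predicted as a probability — is the easiest category;
attachment loss benefits from its coupling to probing depth; furcation's
discrete grades are hardest for a continuous decoder. RMSE exceeding MAE
signals a tail of larger errors, as expected for partially reconstructed
ordinal grades.

`run_workflow()` chains all stages over several seeds and methods and writes
all artifacts (cohort/mask/imputed CSVs, training traces, JSON reports);
a thin command-line wrapper with `simulate`, `mask`, `impute`, `evaluate` and
`run` subcommands lives at
`system.file("cli", "perioimpute.R", package = "perioimpute")`.

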