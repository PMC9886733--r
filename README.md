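# frailtykit

Tools for building and evaluating **deficit-accumulation frailty indices
(FI)** from mixed-type cohort data, with a data-driven supplement to the
standard construction procedure. The intended users are biostatisticians
and epidemiologists working with ageing or memory-clinic cohorts who want
an FI whose item list is refined empirically rather than fixed a priori.

## What it computes

A frailty index is the ratio of deficits present to deficits assessed,

FI_i = Σ_{j ∈ J_i} d_ij / |J_i|,  d_ij ∈ [0, 1],

defined only for subjects with < 20% missing items. `frailtykit`
implements the full standard procedure (screening by prevalence and
missingness, binary/ordinal/continuous deficit coding against a
declarative codebook, FI scoring and summaries) plus an unsupervised
refinement pipeline:

1. **FAMD** — joint PCA (continuous) + MCA (categorical) decomposition of
   the screened variables, after k-nearest-neighbour imputation; the
   components explaining 80% cumulative variance are retained;
2. **HCPC** — Ward clustering on the component scores with k-means
   consolidation, cluster count chosen by the relative loss of
   within-cluster inertia (a two-cluster "fit"/"frail" split by default);
3. **ranking** — each deficit regressed on cluster membership (logistic /
   ordinal-logistic / linear), likelihood-ratio tested, and selected at
   Benjamini–Hochberg FDR < 0.05 to form the refined index FI_r.

Evaluation batteries mirror standard validation practice: single-feature
LDA classification of diagnosis pairs with repeated stratified 10-fold CV
(undersampling and external pseudo-fold variants, paired t comparisons),
and Kaplan–Meier quartile curves with log-rank tests, Cox PH models
(FI × 100), Schoenfeld diagnostics, IPCW time-dependent AUC(t), and
Prentice-weighted average hazard ratios. A synthetic-cohort generator
with known latent fit/frail structure makes the whole pipeline testable
without restricted clinical data.

## Worked example

```r
library(frailtykit)
sim <- simulate_cohort(sim_config(n_subjects = 600,
                                  effect_continuous = 1.5, seed = 11))
res <- run_pipeline(sim$cohort, sim$codebook,
                    run_config(cv = cv_scheme(repeats = 20),
                               auc_grid = c(365, 730, 1095)))
print(res)
#> <fi_pipeline> n = 600; kept 50/50 deficits; 45 components; q = 2
#>   (sizes 432/168); refined set: 16 items
```

The cohort splits into a 432-subject "fit" and a 168-subject "frail"
cluster (adjusted Rand index 0.88 against the generator's latent labels),
and 16 deficits pass FDR < 0.05 to form FI_r. The standard 50-item FI_s
has median 0.193 [IQR 0.153; 0.239], mean 0.198 (SD 0.062), 99th
percentile 0.347 — the familiar right-shifted FI distribution. Diagnostic
and prognostic performance:

```r
res$classify$HC_vs_AD$fi_r
#> <metric_set>
#>   auc          0.805 (0.000)
#>   sensitivity  0.674 (0.000)
#>   specificity  0.884 (0.000)
#>   ppv          0.830 (0.000)
#>   npv          0.763 (0.000)
#>   f1           0.744 (0.000)

res$survival$cox        # MCI subset, FI x 100 + age + sex
#> <cox_fit> (efron ties)
#>              HR     lower    upper          p
#> fi100 1.0113431 0.9999497 1.022866 0.05102158
#> age   0.9861361 0.9625005 1.010352 0.25934926
#> sexM  1.0298662 0.7913049 1.340348 0.82672717
```

So a 0.01 FI increment multiplies the conversion hazard by ~1.01 in this
simulated cohort (generated under HR 1.04 with substantial noise), and
the refined FI separates simulated HC from AD with AUC ≈ 0.80. The SDs
print as 0.000 because the rank-based AUC of a single monotone feature is
invariant to the fold partition (this identity is tested exactly), and
the confusion metrics barely move across repeats at this sample size.

The packaged 93-item deficit catalogue (membership flags for the 93-item
standard, 26-item refined, and 40-item published comparison lists) is
available via `fi_item_catalogue()` / `catalogue_codebook()`.

A command-line driver covering
`simulate | screen | famd | cluster | rank | build-fi | classify |
survive | run-all` ships at `inst/cli/frailtykit.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "frailtykit.R", package = "frailtykit"))')" \
  simulate --n 400 --seed 3 --out sim_out
```

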