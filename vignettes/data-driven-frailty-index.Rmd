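---
title: "Data-driven construction of a frailty index: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-driven construction of a frailty index: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailtykit)
```

## The model

A frailty index (FI) operationalizes frailty as the accumulated burden of
health deficits: for subject $i$ with deficit scores
$d_{ij} \in [0, 1]$ over an item list $J$,

$$\mathrm{FI}_i \;=\; \frac{\sum_{j \in J_i} d_{ij}}{|J_i|},$$

where $J_i \subseteq J$ are the items observed for subject $i$. The FI is
only defined when the fraction of missing items is strictly below 20%
(`compute_fi(..., max_missing = 0.20)`), the conventional rule for
deficit-accumulation indices. Candidate deficits are screened by standard
criteria: present in at least 1% of the sample but not more than 80%, and
missing in at most 5% of subjects; bounds are read inclusively (keep iff
$0.01 \le \text{prev} \le 0.80$, missingness $\le 0.05$). Binary deficits
score 0/1, instrumental-activity items (FAQ-style) score ordinally
(0, 0.25, 0.5, 1 across the four response levels), and continuous
measurements are dichotomized against reference ranges, optionally
stratified by sex and age band, scoring 1 outside the applicable range.
Ordinal items contribute weight 1 to the denominator regardless of their
fractional score — the FI remains a deficit count, not a severity sum.

The package's contribution is the *data-driven supplement* to that
standard procedure, which refines the item list in three unsupervised
steps:

1. **Factor analysis of mixed data (FAMD).** Continuous variables are
   standardized (population SD, divisor $n$) as in PCA; category $k$ of a
   categorical variable enters as $(\mathbb{1}_k - p_k)/\sqrt{p_k}$ as in
   multiple correspondence analysis. The combined matrix with uniform row
   weight $1/n$ is decomposed by SVD; eigenvalues sum to
   $n_{\text{cont}} + \sum_j (k_j - 1)$ (the total inertia), which the
   tests verify to $10^{-8}$. Missing cells are first filled by k-nearest-
   neighbour imputation ($k = 10$ by default) under a mixed distance:
   squared standardized differences on continuous coordinates plus simple
   matching on categorical ones, averaged over mutually observed
   coordinates.
2. **Hierarchical clustering on principal components (HCPC).** The
   components explaining 80% cumulative variance are clustered with Ward
   linkage; the cluster count $q$ maximizes the relative inertia loss
   $[W(q-1)-W(q)]/[W(q)-W(q+1)]$ over $q \in \{2..q_{\max}\}$, and the
   partition is consolidated by k-means (Lloyd) started from the
   hierarchical centroids, which can only decrease within-cluster inertia.
   The two-cluster solution splits the cohort into a larger "fit" and a
   smaller "frail" subgroup, named post hoc by their mean standard-FI.
3. **Per-deficit ranking with FDR control.** Each deficit is regressed on
   the binomial cluster indicator — logistic for binary, proportional-odds
   ordinal logistic for ordinal, linear for continuous — and the cluster
   term is tested by likelihood ratio. Benjamini–Hochberg adjusted
   $q < 0.05$ defines the refined item list (FI$_r$); the standard list
   (FI$_s$, all screened items) and an optional published comparison list
   (FI$_c$) are scored alongside.

Evaluation mirrors how such indices are validated: single-feature linear
discriminant classification of diagnosis pairs under repeated stratified
ten-fold cross-validation (with an undersampling sensitivity path and an
external pseudo-fold variant that scores a fixed development-sample model
on validation folds), and a prognostic battery of Kaplan–Meier quartile
curves with log-rank tests, Cox proportional-hazards models (FI entered
as FI×100 so hazard ratios refer to a 0.01 increment), Schoenfeld
scaled-residual diagnostics, IPCW time-dependent AUC($t$), and
Prentice-weighted average hazard ratios for use when proportionality
fails.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| screening prevalence bounds | 0.01–0.80 (inclusive) | literal reading of the standard criteria |
| screening missingness | ≤ 0.05 | standard criterion |
| FI missingness rule | defined iff < 0.20 missing | strict "less than 20%" |
| imputation `k` | 10 | common kNN default; configurable |
| variance target | 0.80 (rule: smallest $m$ with cumulative share ≥ target) | conventional retention level for FAMD-based clustering |
| `q` (clusters) | 2 (fixed); criterion's choice recorded as `q_selected` | the fit/frail design is a two-group contrast; the selection rule is still computed and reported |
| FDR `alpha` | 0.05 | selection threshold |
| CV scheme | 10 folds × 100 repeats, stratified | replication unit for paired comparisons |
| Cox ties | Efron (Breslow available) | default of the field's reference implementation |
| AUC(t) CIs | percentile bootstrap, B configurable | deliberate, asymptotically equivalent simplification of the iid-representation closed form |
| AHR weights | $w(t) = \hat S(t^-)/\hat G(t^-)$ | Prentice-type weight with censoring correction; pluggable via `weight_fn` because the exact convention of existing software varies |

## The synthetic cohort: what it emulates and what it does not

Real deficit-accumulation studies in memory-clinic cohorts are built on
access-restricted data, so the package ships a generator
(`sim_config()`/`simulate_cohort()`) whose defaults state a plausible
world: ~800 subjects; a latent frail class of 28%; 50 mixed deficits
(30 binary with base prevalences 0.05–0.40, 8 four-level ordinal items,
12 continuous); 30% of deficits informative with a log-odds shift of 1.5
(binary) and a standardized shift of 1.0 (continuous, 1.5 in the
"strong separation" scenarios the recovery tests exercise, matching the
separation under which cluster recovery is claimed); diagnosis drawn
multinomially from the latent class so the marginals land near 28/49/23
HC/MCI/AD with a frail subgroup depleted of controls; Weibull conversion
times (shape 1.2, scale 2000 days) with log-hazard `log(1.04)` per FI×100
unit; 40% independent censoring; 2% MCAR missingness. All randomness fans
out from one master seed through named component streams, so adding a
deficit type does not perturb the others.

The generator deliberately does **not** emulate: informative (non-MCAR)
missingness, competing mortality risk, correlated deficit blocks beyond
the single latent class, item catalogues tied to any real instrument, or
calibration drift between development and validation samples. A green
recovery test therefore establishes that the pipeline recovers structure
*of the stated kind*, not that it would recover the structure of any
particular clinical cohort.

## Numerical choices

* FAMD uses population-SD standardization; eigenvalues below
  $10^{-12} \lambda_{\max}$ are dropped; component signs are fixed by
  making the largest-magnitude loading positive.
* Ward heights are reported as inertia gains (half the Lance–Williams
  dissimilarity on squared Euclidean input), so two points merge at half
  their squared distance. Tie-breaking inside the agglomeration follows
  the underlying `hclust` implementation; the tests verify cut partitions
  against a brute-force greedy Ward oracle on small data.
* The cluster-count rule maximizes $\text{gain}(q)/\text{gain}(q+1)$ with
  ties toward smaller $q$; an all-identical configuration (zero total
  inertia) is an error.
* Empty k-means clusters are re-seeded with the point farthest from its
  assigned centroid and logged.
* Logistic/ordinal separation (detected by non-convergence or coefficient
  magnitude > 15) falls back to an exact conditional (Fisher) test,
  flagged per item.
* `bh_adjust` computes the step-up in the same floating-point order as
  the textbook definition so oracle equivalence is exact, not
  approximate.
* Cross-validated AUC is computed from pooled out-of-fold *oriented
  feature* scores rather than pooled posteriors: per-fold posteriors are
  distinct monotone maps whose pooling could permute cross-fold ranks,
  whereas the oriented feature makes the rank-statistic identity
  (CV AUC = Mann–Whitney AUC of the feature) exact for a single monotone
  feature. Confusion metrics still use the posterior-0.5 threshold.
* In the external pseudo-fold validation the model is fixed, so the mean
  of fold-level confusion metrics is invariant to the repeat count only
  in expectation (fold-size ratios vary); the tests assert near-equality.
* IPCW AUC($t$) uses left-continuous Kaplan–Meier censoring-survival
  weights; a required weight of zero is an error rather than silent
  truncation. The average-hazard-ratio solver truncates zero censoring
  weights at the smallest positive value with a warning, since dropping
  late event times entirely would bias the average.
* Quartile cuts use the type-7 (linear interpolation) convention with
  ties to the lower quartile.

## Design decisions that were genuinely open

* **Raw scale into FAMD.** The decomposition runs on the screened
  variables at their raw scale (continuous as continuous, binary/ordinal
  as categorical) rather than on dichotomized deficit scores, because
  dichotomizing first would discard exactly the variance the mixed-data
  decomposition is meant to capture. The coded-score route remains
  available (`run_config(famd_input = "scores")`).
* **$q$ fixed at 2 in the pipeline.** The selection criterion is
  computed and recorded (`q_selected` in the manifest), but the pipeline
  contrasts two clusters by default: the ranking stage is defined against
  a binomial indicator, and the fit/frail framing is a two-group design.
  With `q = NULL` the criterion's choice is used; for $q > 2$ the ranking
  contrasts the frailest cluster against the rest, with a warning.
* **Likelihood-ratio tests throughout** (not Wald): uniformly defined
  across the three families and stabler for ordinal fits.
* **Positive class** in diagnosis pairs is the more-impaired group (AD in
  HC-vs-AD and MCI-vs-AD, MCI in HC-vs-MCI), configurable; sensitivity
  and specificity are asymmetric, so a fixed convention is required.
* **Component retention uses ≥.** The retention rule returns the
  smallest $m$ whose cumulative share reaches the target, so shares
  (0.5, 0.2, 0.1, ...) retain 3 components at the 0.80 target.

## Known limitations

* The ordinal regression delegates to `MASS::polr`; extremely sparse
  level occupancy can force the exact-test fallback, which discards the
  effect estimate (the p-value and ranking remain defined).
* The AHR sandwich variance treats the estimated weights as fixed, the
  usual first-order approximation.
* The packaged 93-item catalogue records item names, kinds and FI
  membership flags; its coding parameters (reference ranges, cut-points)
  are illustrative placeholders, not any study's laboratory table, and
  users should supply population-appropriate ranges via the codebook.
* No competing-risk modelling; subjects dying before conversion are
  treated as censored, as in the standard analysis this package
  operationalizes.

## A compact run

```{r example, eval = FALSE}
sim <- simulate_cohort(sim_config(n_subjects = 600, effect_continuous = 1.5,
                                  seed = 11))
res <- run_pipeline(sim$cohort, sim$codebook,
                    run_config(cv = cv_scheme(repeats = 20),
                               auc_grid = c(365, 730, 1095)))
print(res)
res$selection          # refined FI_r item list
res$classify$HC_vs_AD  # per-variant metric sets
res$survival$cox       # FI x 100 hazard ratios in MCI
```
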