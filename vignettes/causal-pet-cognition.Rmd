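---
title: "Causal region selection and cognitive-score prediction from regional FDG-PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal region selection and cognitive-score prediction from regional FDG-PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In Alzheimer's disease (AD), regional brain glucose metabolism — measured
by FDG-PET and summarized as standardized uptake values (SUV) per atlas
region — degrades before structural change is visible. Two clinical
instruments track the consequences: the MMSE (global cognition, 0–30,
higher is better) and the FAQ (daily functioning, 0–30, lower is better).
Correlation screens cannot say which regional changes *drive* score
changes; `petcog` implements a two-stage program:

1. **Causal stage.** Treat each region's mean SUV as a treatment and each
   score as an outcome inside a structural causal model (SCM) whose DAG is
   Age/Gender → SUV, Age/Gender → score, SUV → score. Age and gender are
   verified as confounders by constraint-based discovery (PC algorithm
   with Fisher-Z tests) plus univariate regression, then each region's
   direct effect is estimated by backdoor adjustment — an OLS fit of
   `score ~ SUV_region + age + gender` — at whole-cohort and per-group
   (AD/MCI/NC) scope. Regions are ranked by |effect|, validated by placebo
   (within-region permutation) tests and counterfactual do-interventions,
   and the union of whole-cohort and group-wise top lists is selected.
2. **Prediction stage.** A feature-wise-attention transformer regressor is
   trained on the selected regions plus demographics to predict each score.

Because the motivating cohort data (ADNI) is access-controlled, the package
ships a synthetic-cohort generator with known causal ground truth as its
primary test substrate; every claim the test suite makes is a claim about
recovering that known truth.

## The synthetic world

`generate_cohort()` draws, per subject,

* age uniform within the group's range, gender Bernoulli at the group's
  male fraction (1 = male);
* SUV per region: `base_r + a_r * age_std + g_r * gender + noise`, with
  `base_r ~ N(5, 0.4)` across regions and subject noise SD 0.08;
* raw scores: group intercept + `sum_r beta_r * SUV_r` + age/gender terms
  + Gaussian residual, then rounded and clipped to the group's admissible
  score range.

Defaults are the stated world of the reference cohort: 96 subjects per
group; AD MMSE 22.4 ± 3.2 (range 9–25), FAQ 15.0 ± 6.7 (5–30); MCI
26.8 ± 3.6 (10–28) / 5.4 ± 6.9 (0–26); NC 28.9 ± 1.4 (25–30) /
0.3 ± 1.3 (0–5). Ten regions carry nonzero effects whose magnitudes mirror
reported whole-cohort causal scores (e.g. Angular_L 3.25 on MMSE and −8.26
on FAQ, Temporal_Inf_L 3.68 on MMSE); regions reported as influential but
without a printed value get field-plausible magnitudes of the reported
sign. Group intercepts are calibrated analytically so group means match in
expectation; with `noise_sd = "auto"` the residual SD is calibrated so the
total raw-score SD matches the configured group SD (floored at 0.5).

Three deliberate choices deserve emphasis:

* **Small SUV dispersion.** Direct effects of up to 8 score points per SUV
  unit are only compatible with score SDs of 1.3–6.9 if inter-subject SUV
  dispersion is small; the default subject-level SUV noise is therefore
  0.08 SUV units. With realistic 10–20% dispersion the configured effect
  sizes would explain more score variance than the scores possess.
* **Confounder loadings.** Age loads −0.03 SUV/SD-age on every region and
  −0.08 (MMSE) / +0.08 (FAQ) points per year directly; gender 0.015 SUV
  and +0.6/−0.8 points. These are one-time realism choices (cross-sectional
  elderly cohorts show age slopes of this order), not reported values.
* **Clipping after rounding.** Scores are bounded integers; clipping is
  the minimal mechanism. The ground-truth object keeps raw scores and
  pre-clipping coefficients so parameter-recovery tests are exact.

What the generator does **not** emulate: longitudinal visits, PET image
physics (scatter, attenuation, partial volume), realistic inter-region
correlation (an optional shared factor exists, default off), missing data,
or diagnostic-label noise. A green suite therefore establishes that the
*estimators and machinery* are correct, not that the pipeline would
reproduce any particular clinical finding.

One structural consequence worth knowing: with Table-consistent group
intercepts (NC older yet higher-scoring), the *marginal* age–score
correlation in the pooled cohort can cancel even though age is a genuine
within-group confounder — the diagnostic group acts as a latent variable
the discovery stage does not see. Identifiability-focused tests therefore
use homogeneous-group worlds.

## SUV extraction

SUV = tissue activity / (injected dose / body weight), with units
reconciled by the standard unit-density convention (1 g ≡ 1 mL): kBq/mL
activity, MBq dose, kg weight give `activity * weight / dose` (the two
factors of 1000 cancel), so 5 kBq/mL at 370 MBq and 74 kg is SUV 1.0.
Region means are arithmetic means over exactly the voxels of each atlas
label (background excluded, NaN voxels dropped with a message), averaged
unweighted across dynamic frames. Conversion is applied voxelwise before
averaging — equivalent to the reverse order by linearity. No decay
correction is applied across frames, and SUVR (reference-region
normalization) is deliberately out of scope: SUV is used as the direct,
assumption-free metric. Volumes and atlases are assumed co-registered;
a shape check is the only alignment guard. Since the pre-installed R stack
has no NIfTI reader, the package carries a minimal NIfTI-1 implementation
(little-endian `.nii`/`.nii.gz`, common datatypes) sufficient for its own
fixtures and cross-checked against an independent reader in the tests.

## Causal machinery and its numerics

* **Fisher-Z test**: partial correlation via inversion of the correlation
  submatrix, clamped to ±(1 − 1e−12) before `atanh`;
  `z = sqrt(n − |S| − 3) atanh(r)`, two-sided normal p-value. Requires
  `n > |S| + 3`; singular conditioning sets raise a rank-deficiency error.
* **PC skeleton**: classic PC with deterministic lexicographic ordering of
  variables and conditioning subsets, so runs are reproducible and
  invariant to row order. Default `max_cond_size = 3`; the full 120-region
  problem is feasible but slow, so the pipeline exposes a regions subset
  for the discovery stage (the analysis only needs age/gender certified as
  upstream, not the full brain graph).
* **Orientation**: tier knowledge (demographics → imaging → scores) is
  applied before the v-structure rule; finite-sample collider evidence
  cannot reverse a tier-oriented edge (set `strict = TRUE` to error
  instead). Meek rules 1–3 close the orientation; acyclicity of the
  directed part is asserted on every run.
* **Backdoor estimator**: plain OLS with the usual t-based standard
  errors. SUVs enter unstandardized so effects read as score points per
  SUV unit (a `standardize` flag re-expresses per SD). Group-wise scopes
  are separate regressions (refit intercepts), not interaction terms. No
  multiple-testing correction is applied to the ranked tables — ranking,
  not inference, is the goal — and the Frisch–Waugh identity is enforced
  as a test oracle to 1e−10.
* **Selection**: top-30 whole-cohort and top-20 per group by |effect|
  (ties broken by region name), merged by `union_selection()` with
  per-region provenance. The exact merge rule behind a fixed-size
  published selection is not derivable from a ranked list alone, so the
  knobs are exposed rather than asserted.
* **Placebo**: each region's SUV column is permuted independently across
  subjects (marginal distribution preserved exactly — asserted per
  permutation), the estimator re-run; default 100 permutations with a
  99th-percentile pass criterion, chosen for stable null quantiles at desk
  scale.
* **Counterfactuals**: default mechanism is the linear SCM do-operator
  (`baseline mean + effect * (g − baseline SUV mean)`), whose slope equals
  the estimate exactly; a trained-network mechanism is also available and
  labeled, since the source of published counterfactual curves is
  ambiguous. Default grid: scoped mean ± 2 SD, 21 points.

## The prediction network

Inputs are the selected regions plus age and gender. The feature-wise
attention block computes per-sample softmax weights over the features
through a two-layer bottleneck (`A = softmax(W2 relu(W1 x + b1) + b2)`,
`x' = x ⊙ A`), giving feature-level interpretability; the attended vector
is linearly embedded into a 512-dimensional latent token, passed through a
stack of transformer encoder layers (post-norm: self-attention sublayer,
feed-forward with ReLU, layer normalization, dropout 0.3 between layers)
and a fully connected regression head to a scalar score. MMSE and FAQ get
separate models.

Because the whole feature vector is embedded as a *single* token (shapes
are batch × features throughout), the query–key softmax of multi-head
self-attention is identically 1, and the sublayer reduces exactly to its
value and output projections; the implementation uses that reduction
(query/key weights would receive zero gradient). The encoder still
contributes depth, residual structure and normalization.

Training: AdamW (lr 5e−5, weight decay 1e−8), Huber/SmoothL1 loss, global
gradient-norm clipping at 1.0, dropout 0.3 — all stated model settings —
plus choices the source leaves open, documented as defaults: 2 encoder
layers, 4 heads, feed-forward width 2×512, attention bottleneck
`max(f/2, 8)`, head width 64, batch size 32, 100 epochs with a
best-training-loss checkpoint (the stack converges on cohort-sized data
well before 100 and single-CPU runtime grows linearly), 90:10 train/test
split stratified by diagnostic group. Weights initialize uniform
±1/sqrt(fan_in) — the dense-layer default of the major frameworks; larger
He-scaled initializations make the 512-d stack memorize small tabular
training sets instead of generalizing. Features **and the target** are z-scaled with
training-set statistics only (the target so the Huber transition at 1
operates on a unit scale; predictions are mapped back). Training is
implemented in base R matrix algebra with hand-derived backpropagation,
verified against numerical gradients; the per-batch clip+AdamW update is a
small compiled kernel. Runs are bit-reproducible from the seed on a fixed
BLAS; evaluation mode is deterministic (dropout off).

Metrics are R² (about the held-out target mean), MSE and MAE. Zero-variance
test targets leave R² undefined; the package returns `NA` with a warning
(the stated "error plus partial results" contract cannot be both).

## Degenerate inputs and edge cases

Non-positive dose/weight, negative activity, empty atlas labels, shape
mismatches, zero frames, collinear designs, too-small scoped samples,
non-increasing counterfactual grids and invalid configurations all raise
typed, named errors (tested). `split_data` apportions the test set across
groups by largest remainder with alphabetical tie-breaks, so 288 subjects
at 90:10 give exactly 259/29 (10/10/9 by group).

## Known limitations

* The default world's effect sizes are weakly identified at n = 288 with
  whole-cohort scope (group heterogeneity inflates residuals); per-group
  estimates and the low-noise test worlds are where rankings stabilize.
  This mirrors the data reality, not a bug.
* PC on all 120 regions with `max_cond_size = 3` can take minutes; the
  pipeline's discovery stage defaults to a correlation-screened subset.
* The NIfTI implementation covers the package's own needs (no extensions,
  qform/sform ignored).
* Counterfactual curves extrapolate linearly outside the observed SUV
  range under the linear mechanism; interpret ±2 SD grids accordingly.
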