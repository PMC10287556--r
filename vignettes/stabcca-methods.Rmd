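---
title: "Methods: stability-selected sparse CCA for exposome, brain and genetic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stability-selected sparse CCA for exposome, brain and genetic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabcca)
```

# The problem

Large population cohorts measure hundreds of correlated environmental
exposures (deprivation indices, pollution, green space, urban form), dozens
of psychiatric symptom items, regional brain volumes and genome-wide
genotypes on the same participants. `stabcca` implements a multi-stage
inference pipeline for asking, in one coherent framework:

1. which sparse combinations of environmental categories co-vary with which
   sparse groups of psychiatric symptoms (stability-selected sparse CCA with
   out-of-sample permutation inference),
2. whether regional brain volumes share that covariance (three-block sparse
   CCA),
3. which genetic variants associate with the symptom variates (additive
   dosage scan, LD clumping, weighted gene scores), and
4. whether gene scores moderate a brain-mediated pathway from environment to
   symptoms (moderated mediation with bias-corrected bootstrap intervals).

Because the motivating cohort data are access-restricted, the package ships
a first-class synthetic-data generator with known planted structure; every
stage of the pipeline is exercised and tested against that ground truth.

# Latent environmental categories (CFA)

Raw environment items arrive in conceptual categories; multi-item categories
are collapsed to one latent score by a one-factor confirmatory factor
analysis fitted by maximum likelihood: `Sigma(theta) = lambda lambda' +
diag(psi)`, discrepancy `F_ML = log|Sigma| + tr(S Sigma^-1) - log|S| - p`,
factor variance fixed at 1 so loadings are comparable across items.  Fit is
judged by CFI, TLI, RMSEA and SRMR against the excellent-fit criteria
(TLI > 0.95, CFI > 0.95, RMSEA < 0.06, SRMR < 0.08); while the criteria are
unmet the item with the smallest absolute loading is dropped, down to a
floor of three items (at exactly three items the model is just-identified,
the indices are undefined and the criteria are treated as unmet).
Participants are scored out of fold: the model is pruned and fitted on the
other folds and applied to the held-out fold with regression-method scores
`f = lambda' Sigma^-1 (x - mean_train)`, so no participant's latent value
ever uses their own data in estimation.

Numerical choices: optimization is L-BFGS-B over `(lambda, log psi)` with an
analytic gradient; uniquenesses are floored at 1e-6 and such Heywood cases
are flagged rather than fatal, keeping the pruning loop total.  The
independence baseline for CFI/TLI is `chi2_b = (n-1) (-log|R|)`.

# Sparse CCA core

The rank-one solver is a penalized matrix decomposition: alternating updates
`w_x <- normalize(soft_threshold(C w_y, lambda_x))` on the cross-covariance
`C = X'Y/(n-1)`, with the threshold chosen by bisection as the smallest
value bringing the L1 norm of the unit-L2 weight below `s sqrt(p)`.  The
sparsity parameter follows the L1-bound convention: `s = 1` is the
unconstrained leading singular pair; `s = 0.5` halves the maximal L1/L2
ratio.  One consequence worth knowing when planting or interpreting
supports: a unit-norm vector with `m` comparable non-zeros has L1 about
`sqrt(m)`, so a support of size `m` is representable only when
`sqrt(m) <= s sqrt(p)`.

The unpenalized refit computes the first canonical pair by SVD of
`(S_xx + eps I)^(-1/2) S_xy (S_yy + eps I)^(-1/2)` with a ridge of 1e-6,
because refit sets can contain correlated categories.  Weights are unit-L2
with sign fixed so the canonical correlation is non-negative.

# The stability and permutation protocol

On the training split (90% of participants) the pipeline draws 100
half-samples without replacement, runs the sparse solver on each, and
retains per view the features with non-zero weight in at least 90% of
resamples (85% in the three-block analysis).  An unpenalized CCA is refitted
on the stable sets.  Training-set significance re-runs the *entire*
selection-plus-refit procedure on row-permuted symptom data (1,000
permutations at study scale), so the null distribution reflects every
adaptive choice; permutations whose selection returns nothing score zero,
which is conservative.  Test-set significance applies the frozen weights to
the held-out 10% and permutes only the rows of one view.  One-sided p values
use the add-one convention `(1 + #{r_perm >= r_obs})/(1 + n_perm)`;
Benjamini-Hochberg FDR is applied across the modes' test p values.

## Deflation

After a significant mode, both views' training and test matrices are
deflated and the search repeats.  Plain column-space projection
`M(I - ww')` removes the weight direction but does *not* decorrelate
successive variates (`w1' S w2~` need not vanish), which both violates the
orthogonality this decomposition is meant to deliver and lets residual
variance of an imperfectly estimated mode resurface as a spurious extra
mode.  The pipeline therefore uses orthogonalized projection deflation:
rows are first residualized on the extracted variate, then the weight
direction is projected out of the columns.  The composed operator still
satisfies `M'w = 0` exactly and in addition makes the next mode's training
variates exactly uncorrelated with the current one's.  The same scheme is
applied per block in the three-block pipeline.

The stopping rule gates on the test-set permutation p value (pre-FDR) at
the configured alpha; FDR-adjusted p values are reported for all extracted
modes afterwards.

## Cross-loadings, EV and FEV

The cross-loading of category `j` on symptom variate `k` is their Pearson
correlation; its square times 100 is the explained variance (EV).  The
fraction of explained variance (FEV) of symptom group `k` attributed to
profile `m` normalizes the summed squared cross-loadings of profile `m`'s
stable set by the total over all profiles, so FEV sums to 100% per symptom
group by construction.

# Genetics

The association scan regresses a canonical symptom variate on each
variant's effect-allele dosage plus covariates (age, sex, center, batch,
ancestry PCs), implemented by Frisch-Waugh-Lovell residualization, which is
exactly the per-variant OLS.  Greedy LD clumping sorts by p value (ties by
position, then id) and assigns to each index all unassigned variants within
250 kb *and* with dosage r-squared above 0.5; `p1 = 1` admits every variant
as a potential index.  Gene scores are `sum(dosage x beta)` over a gene's
index variants — the standard weighted allele score, using dosages rather
than hard calls.  Moderation of an exposure-symptom correlation by a gene
score is tested by a median split and Fisher's z on the per-stratum
correlations.

# Moderated mediation

The structural model places the moderator `W` on the a-path, b-path and
direct path:

```
M = a0 + a1 X + a2 W + a3 XW + covariates + e_M
Y = b0 + c' X + c2 W + c3 XW + b1 M + b2 MW + covariates + e_Y
```

`X`, `W` and `M` are mean-centered before products.  Conditional indirect
effects `(a1 + a3 w)(b1 + b2 w)` are reported at the moderator's 16th, 50th
and 84th percentiles (computed on the complete-case analysis sample), with
bias-corrected (BC, not accelerated) bootstrap intervals over participant
resamples; an interval excluding zero flags a significant conditional
mediation.  The explained mediation effect (EME) is implemented as the
proportion mediated at the median moderator,
`100 x indirect/(indirect + direct)`, with an instability guard when the
total effect is within 1e-6 of zero; the formula is deliberately simple and
exposed, since no canonical definition exists.

# The synthetic-data generator

The generator emulates the data structure the pipeline assumes: 128 raw
environment items collapsing into 53 categories (19 multi-item, 34
single-item), 21 symptom items, 139 regional brain volumes, biallelic
dosages in LD blocks, and covariates (age, sex, center, batch, 10 ancestry
PCs, total intracranial volume).

**Planted canonical modes.** Each mode `k` has an environment-side latent
`u_k` and a symptom-side latent `v_k`; support items are noisy indicators
with heterogeneous variance shares (linearly spaced in 0.45-0.75 by
default — exact ties would make the L1-bounded support non-unique, a
degeneracy real item sets do not have).  The latent correlation is inflated
to `r_k / sqrt(rel_x rel_y)` where `rel = S/(1+S)`, `S = sum a_j/(1-a_j)`
is the reliability of the optimal within-view composite, so the *population
first canonical correlation between the observed views equals `r_k`*
exactly.  Default strengths 0.30 and 0.15 sit inside the range of canonical
correlations such cohort analyses report (roughly 0.03-0.22), erring
slightly high so that desk-scale runs have workable power.  Environment
supports default to 8 and 6 of 53 categories; symptom supports to 5 and 4
of 21 items, because a support of `m` items is recoverable under sparsity
`s = 0.5` only when `sqrt(m) <= 0.5 sqrt(q)` (about 5.2 for `q = 21`) —
symptom groups are small item clusters.

**Mediation and moderation.** Part of mode 1's shared variance is routed
through a mediator latent `M = a1 u + a3 u W + e` whose indicators are a
subset of brain regions, with `W` a standardized gene score over one LD
block; the symptom latent mixes `M` and `u` so that the planted canonical
correlation is preserved while the brain genuinely mediates and the gene
score moderates the a-path.

**Genotypes.** Haplotypes are latent Gaussian AR(1) processes within blocks
(autocorrelation `ld_rho`, default 0.8), thresholded at block-specific
allele frequencies; dosage is the sum of two independent haplotypes,
optionally jittered into continuous expected counts.  INFO is set to 1.

**Confounds** enter every view additively and linearly (scale 0.2 by
default), so least-squares residualization removes them exactly — which is
what makes the preprocessing stage testable against ground truth.

What the generator does *not* emulate: spatial autocorrelation of
exposures, non-linear confounding, item-level ordinality, population
stratification beyond PC covariates, and imputation uncertainty.  Passing
tests therefore validate the statistical machinery, not robustness to those
real-data features.

# Problem sizes and numerical choices

Tests and the acceptance script run at desk scale, chosen a priori as the
smallest sizes at which each property is statistically decidable: planted-
mode recovery at n = 5,000 with 100 resamples and 199 permutations; null
calibration over 200 datasets of n = 1,000 at 99 permutations with 25
resamples and 12 x 8 features; mediation coverage over 200 replicates of
n = 2,000 with 999 bootstrap draws; the end-to-end demonstration config
uses n = 2,500, 50 resamples, 99 training permutations.  Study-scale
settings (1,000-10,000 permutations, 100 resamples) are the documented
defaults of `pipeline_config()`.

Null calibration needs one nuance: with the 90% stability gate on, a global
null almost never yields a stable set, so the full protocol's type-I error
is far *below* nominal (a design feature of stability selection).  The
calibration test therefore checks the permutation machinery with the gate
open (threshold 0), where observed and permuted statistics are exchangeable
and the rejection rate must sit near 0.05, and separately asserts the full
protocol's conservatism.

Other numerical choices: whitening ridge 1e-6; PMD bisection to 2^-40;
inner solver tolerance 1e-6 (1e-5 inside resampling loops, where only the
non-zero pattern matters); Heywood floor 1e-6; clumping ties broken by
position then id; the MAD filter uses the raw (unscaled) median absolute
deviation and masks individual values, not participants.

# Known limitations

- Rank-one extraction per deflation round; no joint multi-mode optimization.
- The three-block design matrix is fully connected with equal weights
  (Horst scheme); alternative schemes are not implemented.
- The moderated mediation model is cross-sectional; no causal claims follow
  from a significant indirect effect.
- Gene mapping is taken from the supplied variant annotation; no positional
  annotation is performed.
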