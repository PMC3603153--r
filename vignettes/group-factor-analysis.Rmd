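---
title: "Group factor analysis with a shared error covariance"
author: "groupfa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group factor analysis with a shared error covariance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupfa)
```

## The model

Neuroimaging studies typically scan healthy controls and patients on one
scanner with one protocol, so the measurement-error structure is common to
everybody, while the latent anatomy driving the measurements may differ by
diagnosis. `groupfa` fits a factor analysis model built around exactly that
asymmetry. With `M` diagnostic groups, `D` continuous features and `K`
latent factors, a subject in group `j` is modelled as

    x = mu_j + L_j f + u,    f ~ N(0, I_K),    u ~ N(0, Psi),

where the loading matrix `L_j` (`D x K`) and mean `mu_j` are specific to
the group but the diagonal error covariance `Psi` is shared across all
groups. The marginal covariance of group `j` is therefore
`L_j L_j' + Psi`. Conventional factor analysis is the `M = 1` special
case; fitting groups entirely separately would instead estimate `M`
different error covariances from much smaller samples, confounding noise
with anatomy.

### Estimation

`group_fa()` maximizes the likelihood by EM. The E-step evaluates, for
each subject and group, the conditional factor moments

    E[f | w_j, x] = R_j^{-1} L_j' Psi^{-1} (x - mu_j),
    Cov(f | w_j, x) = R_j^{-1},        R_j = L_j' Psi^{-1} L_j + I,

which by the Woodbury identity equals the regression predictor
`L_j'(L_j L_j' + Psi)^{-1}(x - mu_j)`; the package computes through
`R_j` so only `K x K` systems are solved and densities stay stable in log
space. The M-step is a responsibility-weighted least-squares update of the
augmented matrix `[L_j mu_j]` followed by the shared `Psi` update
`diag(sum_ij h_ij (x_i - [L_j mu_j] E[f~_i]) x_i') / N`.

Two membership regimes are exposed:

* **supervised** (default): the responsibilities `h_ij` are fixed to the
  clinical diagnosis for the whole run — each subject contributes only to
  its diagnosed group, and the trace records the supervised log likelihood
  `sum_i log N(x_i; mu_{j(i)}, L_{j(i)} L_{j(i)}' + Psi)`.
* **soft**: `h_ij` is recomputed each E-step as the posterior probability
  under prior proportions fixed at the observed label frequencies, and the
  trace records the mixture log likelihood.

Supervised fitting is the default because the diagnosis is the information
the design wants to exploit; the posterior (soft) responsibilities remain
available after any fit through `posterior_responsibilities()` and power
the re-estimated proportions of `reestimate_proportions()`, which are no
longer binary when groups overlap. Which likelihood a reported headline
number refers to is ambiguous in parts of the surrounding literature, so
`gfa_loglik()` computes either on demand.

### Rotation and alignment

For any orthogonal `H`, replacing `L_j` by `L_j H` (and `f` by `H'f`)
leaves `L_j L_j' + Psi` — hence the likelihood — unchanged, so each
group's solution is identified only up to rotation, column permutation and
column sign. `align_model()` therefore post-processes a fit in two steps:

1. **varimax** per group (`varimax_rotate()`), maximizing
   `sum_k [mean(lambda_k^4) - mean(lambda_k^2)^2]` by the standard
   SVD-ascent algorithm, with Kaiser row normalization on by default so
   every feature counts equally;
2. **alignment** of columns across groups (`align_loadings()`): for each
   non-reference group the column matching that maximizes total absolute
   Pearson correlation with the reference group's columns is solved as a
   `K x K` assignment problem with an in-package Hungarian
   (shortest-augmenting-path) solver, and each matched column's sign is
   set so the correlation is non-negative.

An exhaustive reference path (`method = "exhaustive"`) scans the complete
`2^(K M) (K!)^M` space of per-group sign vectors and permutations — the
reference group's own options included — under the reference-anchored
objective. Because a bijective relabelling of the reference changes no
objective value, the enumeration optimum always equals the Hungarian
value; the property suite verifies this on random instances, and the path
is guarded to `K <= 4`, `M <= 3` where the space stays enumerable.

Design choices that were genuinely open: column similarity is *absolute*
correlation (scale-free, and a factor equals its negation); sign ties at
zero correlation resolve to `+1`; the reference group defaults to group 1
(the controls); varimax runs before alignment, per group. Alignment to the
reference is pairwise, which coincides with a joint optimum under the
anchored objective.

## Preprocessing

`volume_normalize()` converts absolute structure volumes to intracranial
volume ratios. `standardize_features()` then applies one pooled (not
per-group) pass of centering and unit-variance scaling — the model
compares groups, so their differences must survive preprocessing; scaling
uses the unbiased `N-1` standard deviation (immaterial at cohort sizes,
and an `mle_variance` switch exists for exact comparability with
correlation-matrix methods). Missing values are rejected rather than
imputed, and constant features are refused by name.

## Diagnostics

* `scree_eigen()`: covariance eigenvalues, cumulative variance percent and
  the Kaiser count (eigenvalues above 1) — the usual `K` selection basis.
* `ks_normality()`: one-sample Kolmogorov-Smirnov test of factor scores
  against the *fixed* standard normal, because the model asserts
  `f ~ N(0, I)`; this is deliberately not a Lilliefors-type test with
  estimated moments, and the choice is documented here because published
  tables of this kind rarely state their null construction.
* `anova_per_feature()`: classical one-way ANOVA per feature across
  groups, `(M-1, N-M)` degrees of freedom.
* `compare_loadings()`: pairwise Frobenius distances of aligned loading
  matrices, their mean as the aggregate, and Pearson correlations of the
  vectorized matrices. A "distance between loading matrices" has no
  canonical definition, so the package states its own and makes no claim
  of numerical comparability with other software's figures.
* `score_covariate_association()`: per-group OLS of a covariate (e.g. a
  cognitive score) on a factor score.

## The synthetic cohort generator

`simulate_cohort()` draws labels, factors and noise exactly from the
generative model, bit-reproducibly under a stored seed. The preset
`ad_like_spec()` emulates a dementia morphometry study: `D = 15`
intracranial-volume-normalized subcortical features (7 bilateral pairs
plus the brain stem), `M = 3` groups with proportions
75.96% / 16.83% / 7.21% (controls, very mild and moderate dementia), and
`K = 3` exact simple-structure factors — limbic, striatal, diencephalic —
with bilateral pairs sharing loadings, echoing the empirical regularity
that left and right structures load alike.

Magnitudes were fixed once on realism grounds: dominant loadings 0.65-0.85
and shared `Psi = 0.25`, giving communalities around 0.63-0.74, typical of
volumetric data; patient means shifted down by 0.3-0.9 pooled standard
deviations, concentrated on hippocampus, amygdala, thalamus and putamen,
so that groups overlap and posterior memberships stay non-binary. On such
cohorts the eigenvalue scree retains 3 factors with roughly 77% cumulative
variance in the top three.

What the generator does *not* emulate: segmentation error correlated
across neighbouring structures, non-Gaussian tails, age and sex structure,
site effects, or label noise in the diagnosis. Passing recovery tests on
these cohorts therefore demonstrates correctness of the estimator under
its own assumptions, not robustness to real-data violations of them.

## Numerical choices

* Convergence: relative change `|dLL| / (|LL| + 1) < 1e-6`, at most 1000
  iterations (neither is dictated by theory; both are adjustable).
* `Psi` floored elementwise at `1e-6` to prevent Heywood-case collapse;
  floor events are recorded on the fit object.
* Initialization: group sample means, loadings i.i.d. `N(0, 0.1^2)` from a
  caller-supplied seed (the only randomness in a fit), `Psi` from pooled
  within-group residual variances.
* Degenerate inputs: groups with fewer than 2 members, `K >= D`,
  non-finite entries and constant columns are rejected up front; a row
  whose density underflows in every group aborts with a pointer to
  standardization.
* The EM trace is monotone up to `1e-8`; the test suite asserts this over
  many seeded replicates in both membership modes.

## Validation approach and measured limits

The test suite checks every computational step against an independent
route: dense-matrix Gaussian densities, loop-based M-step summations, a
covariance-form (sufficient-statistics) EM for the single-group reduction,
`stats::varimax` and a planar grid search for rotation, brute-force
permutation scans and full enumeration for the assignment step.

Problem sizes used by the heavier checks — 50 cohorts of `N = 300` for EM
monotonicity, 10 cohorts of `N = 2000` for the generate-fit-align recovery
loop, `N = 800` for the single-group reduction — keep the default test run
fast while leaving the statistics meaningful.

One honest limitation deserves its own paragraph. In the recovery loop at
`N = 2000`, `D = 15`, `M = 3`, aligned loadings come back within about
0.13 of truth (mean over seeds of the worst entry), but the per-group
model covariance `L_j L_j' + Psi` differs from truth by about 0.55 in
Frobenius norm on average. That is not an estimator defect: the error of
the fitted structured covariance coincides with the error of the raw
per-group sample covariance, i.e. the EM estimator operates at the
information limit, and a `15 x 15` covariance on unit-variance features
simply cannot be pinned much more tightly from a few hundred subjects per
patient group (relative error ~11% of the matrix norm). The acceptance
suite keeps a much stricter 0.2 absolute bound on record, and that check
is expected to fail at these sample sizes; the number it measures is
reported by `scripts/acceptance.R` either way.
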