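# groupfa

Group factor analysis with a shared diagonal error covariance, for
continuous feature tables that mix diagnostic groups measured under one
acquisition protocol — the motivating case being subcortical volume ratios
from structural MRI of healthy controls and dementia patients.

## The model

Conventional factor analysis either pools all subjects (one loading
pattern for everybody) or fits each group separately (each small group
gets its own noisy error estimate). `groupfa` takes the middle road: with
`M` groups, `D` features and `K` latent factors, a subject in group `j`
follows

```
x = mu_j + L_j f + u,     f ~ N(0, I_K),     u ~ N(0, Psi)
```

so every group has its own `D x K` loading matrix `L_j` and mean `mu_j`,
while the diagonal measurement-error covariance `Psi` is **shared** across
groups — errors come from the scanner and protocol, not from the
diagnosis. The marginal covariance of group `j` is `L_j L_j' + Psi`, and
the `M = 1` case is classical maximum-likelihood factor analysis.

Estimation is by EM with group memberships either fixed to the clinical
diagnosis (supervised, the default) or iterated as posterior
responsibilities (soft). Because loadings are only identified up to
orthogonal rotation, column order and column sign, fits are post-processed
by per-group varimax rotation followed by cross-group column alignment
(Hungarian assignment on absolute column correlations), making the `M`
loading matrices directly comparable.

## Worked example

Simulate a dementia-like cohort (416 subjects, 15 ICV-normalized
subcortical volumes, groups NL / vAD / AD at 75.96% / 16.83% / 7.21%),
standardize, fit, rotate and align:

```r
library(groupfa)

spec   <- ad_like_spec(n_subjects = 416, seed = 20)
cohort <- simulate_cohort(spec)
z      <- standardize_features(cohort$x)
fit    <- group_fa(z$x, cohort$groups, n_factors = 3, seed = 1)
fit
#> Group factor analysis (supervised mode)
#>   416 subjects, 15 features, 3 groups, 3 factors
#>   log likelihood -6284.146 after 37 EM iterations (converged)
#>   group proportions: NL 73.08%, vAD 19.47%, AD 7.45%

fit <- align_model(fit)            # varimax + cross-group alignment
round(fit$loadings$NL[c("hippocampus_l", "putamen_l", "thalamus_l"), ], 2)
#>                 F1    F2   F3
#> hippocampus_l 0.02 -0.04 0.85
#> putamen_l     0.79  0.01 0.04
#> thalamus_l    0.00 -0.81 0.04
```

After alignment each factor has the same meaning in every group: here F3
is the limbic factor (hippocampus), F1 the striatal one (putamen), F2 the
diencephalic one (thalamus; its sign is arbitrary and fixed by the
reference group). The diagnostics report bundles factor retention,
normality of scores, and cross-group loading comparisons:

```r
report <- diagnose(fit)
report
#> Diagnostics for 416 subjects in 3 group(s)
#>   Kaiser criterion retains 3 factor(s); top-3 cumulative variance 77.8%
#>   Re-estimated proportions: 72.73%, 19.34%, 7.92%
#>   Aggregate loading distance: 0.7678
```

Three eigenvalues exceed 1 and carry ~78% of the variance, supporting
`K = 3`; the re-estimated (soft, posterior-averaged) proportions drift
away from the observed label frequencies because the groups overlap. The
pairwise correlations of the aligned loading matrices
(`report$loading_comparison$pairwise_corr`) show how similar the latent
structure remains across diagnoses.

A thin command-line wrapper covering the same pipeline (simulate / fit /
diagnose subcommands) ships at `inst/cli/groupfa.R`.

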