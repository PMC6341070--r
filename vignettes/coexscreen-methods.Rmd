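---
title: "Methods: seed-gene co-expression screening with coexscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-gene co-expression screening with coexscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexscreen)
```

## The model

`coexscreen` asks a deliberately simple question of each expression
cohort: does feature $y$ co-vary linearly with a designated seed gene
$x$? The per-cohort model is ordinary least squares with intercept,

$$ y_i = \alpha + \beta x_i + \varepsilon_i, \qquad
   t = \hat\beta / \mathrm{se}(\hat\beta) \sim t_{n-2}
   \text{ under } H_0\colon \beta = 0, $$

with two-sided $p$ from the $t$ distribution, $r^2$ equal to the squared
Pearson correlation, and the one-predictor adjusted coefficient of
determination $1 - (1 - r^2)(n-1)/(n-2)$. The seed is always the
predictor; because $p$, $t^2$ and $r^2$ are orientation-invariant in
simple regression, every screening decision would be identical with the
roles reversed — only the reported slope changes, and the documentation
of `fit_seed_association()` states the convention.

Assumptions worth keeping in mind: expression values are on a log scale
(so slopes are log-fold-change ratios), samples within a cohort are
independent, and the association of interest is monotone and roughly
linear on that scale. No covariates are modelled; heterogeneity across
cohorts is handled by *requiring replication*, not by pooling.

Missing cells are tolerated pairwise-complete: a feature missing in more
than 20% of a cohort's samples is dropped at read time
(`read_expression_matrix(max_missing_frac = 0.2)`), and remaining `NA`s
exclude only that sample from that feature's regression. Exact
collinearity reports $p = 0$, $r^2 = 1$ (detected at relative residual
tolerance $10^{-12}$); $p$-values are otherwise never floored, and a
Benjamini–Hochberg column is emitted for reference but never consulted by
the filters, which operate on raw per-cohort thresholds by design.

## The candidate funnel

Filters are bundles of per-cohort conditions (`filter_tier()`), applied
sequentially so each tier narrows the previous tier's survivors:

* **relaxed** — $p \le 0.05$ in *every* cohort, with the same slope sign
  everywhere. Requiring measurement in all cohorts is intentional: a
  feature absent from one platform cannot demonstrate cross-cohort
  consistency. A zero slope counts as a direction mismatch.
* **strict** — $p \le 2\times10^{-6}$ *and* adjusted $r^2 \ge 0.1$ in at
  least five cohorts (counting only cohorts where the feature is
  measured). Direction consistency is not re-checked here because the
  relaxed tier already enforced it on every survivor.
* **heatmap** — additionally adjusted $r^2 \ge 0.3$ in at least one
  cohort, selecting candidates strong enough to structure a clustering.

All $r^2$ thresholds act on the *adjusted* $r^2$, the per-cohort statistic
the screen reports; with cohort sizes in the hundreds the difference from
raw $r^2$ is small, but the choice is fixed and documented. Tier
evaluation is deterministic and invariant to cohort and feature order,
and `run_tiered_screen(sequential = FALSE)` evaluates tiers independently
when the nested interpretation is not wanted. Each `candidate_set` keeps
per-(feature, cohort) evidence flags so the funnel is auditable.

## Replication, subtypes and specificity

A discovery set is only as interesting as its behaviour out of sample.
`replication_report()` counts, in a validation group, the candidates
significant at $\alpha$ (default 0.05 everywhere, configurable) whose
slope sign matches the discovery direction; the *consistent rate* divides
by all candidates (unmeasured candidates stay in the denominator, flagged
in `n_unmeasured`), while the *opposite-direction rate* divides the
sign-flipped significant candidates by all significant ones. Rates are
rendered at two decimals (`format_percent()`), e.g. 212/214 → "99.07%".

`subtype_screen()` intersects, across molecular subtypes, the candidates
significant with a common direction; subtypes whose regressions used
fewer than 30 samples are excluded up front so small groups cannot veto
the intersection through power alone. `classify_specificity()` compares
tumor and matched-normal associations of one feature and returns exactly
one of five calls — consistent, tumor-specific, normal-specific,
opposite, neither — a partition of the $(p_t, p_n, \text{sign})$ space.
`paired_regulation_frequency()` reports the fraction of matched pairs
beyond a log-fold-change threshold (default 1, i.e. two-fold, an explicit
configurable assumption).

## Survival screening and the antimode

The survival stage dichotomizes each feature's expression and compares
the two groups by the standard log-rank test (via `survival::survdiff`),
with the Kaplan–Meier product-limit estimator backing the curves and
restricted-mean survival (area under the KM curve up to the last observed
time) deciding which group benefits. Cox models are deliberately absent:
the method is a dichotomized-group comparison, and ties between events
and censorings at one time follow the events-first convention.

The cut point is the central interpretive decision. "The low point of the
histogram" is operationalized as the *antimode* of a Gaussian KDE with
Silverman's rule-of-thumb bandwidth (`stats::density`, `bw = "nrd0"`):
the density minimum between the two dominant modes. Finite KDE grids
wiggle, so a local maximum only counts as a mode if its density reaches
`min_peak_frac` (default 0.2) of the primary mode, and the valley must
dip at least `min_dip_frac` (default 0.1) below the lower of the two
modes. These defaults were chosen by simulating the rule's operating
characteristics: clearly separated equal mixtures should essentially
always be recognised as bimodal, while unimodal Gaussian samples should
essentially always fall back to the median split
(`method = "median_fallback"`). The same fallback triggers when the
antimode would strand fewer than `min_group_frac` (default 0.1) of the
samples in one group. Everything sits behind `antimode_threshold()`'s
arguments, so a different bandwidth or stricter prominence is one call
away.

## The synthetic generator

`generate_cohorts()` draws from a linear-Gaussian model: the seed is
standard normal, a planted feature with target correlation $\rho$ is
$\rho x + \sqrt{1-\rho^2}\,\epsilon$ (so the expected slope and
correlation are both $\rho$ and the expected $r^2$ is $\rho^2$), and null
features are independent normals. Defaults emulate the discovery setting
the package targets: eight cohorts of 99–575 samples (the scale of public
pediatric B-ALL series) and $\rho \in (0.15, 0.65)$, which makes planted
per-cohort adjusted $r^2$ span roughly 0.02–0.42. Per-cohort scale
multipliers and subtype-specific multipliers emulate heterogeneity;
`generate_paired()` realises the five specificity classes by
including/flipping the seed correlation per tissue; and
`generate_survival()` draws exponential event times whose hazard is
multiplied by `hazard_ratio` above the expression threshold, with
independent uniform censoring whose upper bound is solved numerically so
the expected censored fraction matches `censoring_rate` (defaults:
baseline hazard $10^{-3}$/day, ratio 2, censoring 0.2).

What the generator does *not* emulate — and what passing tests therefore
cannot certify on real data: heavy-tailed or count-distributed
expression, probe- and batch-level artefacts, informative censoring, and
cohort-specific normalization differences. The generator certifies the
*logic* of the pipeline (calibration, recovery, determinism), not the
robustness of OLS to microarray pathologies.

## Numerical and design choices

* Regression engine: closed-form normal equations on pairwise-complete
  pairs, shared verbatim between the single-pair and genome-wide paths,
  so the two are bitwise identical; `stats::lm` serves as the independent
  oracle in the test suite, and a permutation $p$-value
  (`permutation_p()`) provides a distribution-free cross-check.
* Determinism: all stochastic operations take an explicit seed and
  restore the caller's RNG state; `run_pipeline()` manifests carry md5
  checksums, and identical configs reproduce identical manifests.
* Degenerate inputs are classed conditions (`coex_constant_feature`,
  `coex_insufficient_samples`, `coex_format_error`, ...), so callers can
  distinguish skip-worthy features from broken files; the genome-wide
  screen records skipped features with reasons instead of failing.
* Test problem sizes are chosen to make the statistical assertions sharp
  at desk scale: 20,000 pooled null fits for p-value calibration, 1,000
  features × 8 cohorts for the null-filter runs, 2,000 log-rank
  replicates at n = 300 (large enough for the $\chi^2_1$ reference to be
  accurate — the log-rank chi-square is measurably anticonservative at
  n ≈ 100), and 100-replicate mixture draws for the antimode.

## Known limitations

Simple regression inherits sensitivity to outliers and to nonlinear
monotone relations; the screen is blind to associations mediated at the
protein level; requiring significance in *all* cohorts makes the relaxed
tier conservative when platforms differ in coverage; and the antimode
rule, like any histogram-valley method, is undefined in principle for
genuinely unimodal expression — the median fallback keeps the survival
screen total rather than right.
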