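---
title: "Age-stratified nonparametric testing of differential methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-stratified nonparametric testing of differential methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmstrat)
```

## The model

A methylation array reports, per locus and sample, a beta-value in [0, 1].
Two features make the usual K-group comparisons unreliable: the beta-value
is bounded and typically far from normal (often strongly skewed toward 0 or
1, with variance tied to the mean), and methylation drifts with age in a
way that need not be linear. `dmstrat` treats age as a stratification
variable rather than a regression covariate: samples are binned into G age
strata, a K-sample omnibus test is applied within each stratum (where the
age effect is approximately constant), and the per-stratum p-values
$p_1, \dots, p_G$ — independent because strata contain disjoint samples —
are combined per locus.

Fisher's method uses $X = -2\sum_g \log p_g \sim \chi^2_{2G}$ under the
null. The weighted Z uses
$Z = \sum_g n_g \Phi^{-1}(1-p_g) / \sqrt{\sum_g n_g^2} \sim N(0,1)$,
one-sided, weighting each stratum by its sample size $n_g$. The Z
combination is one-sided by construction: the per-stratum tests are
omnibus, so a small $p_g$ always points the same way ("some difference"),
and direction is not a meaningful concept to preserve. In practice Fisher
is the more robust choice when only a few strata carry signal; the Z gains
when effect sizes are comparable across strata.

## The base tests

All four tests consume K groups of beta-values within one stratum and
refer their statistic to an asymptotic null distribution:

* **Kruskal–Wallis** (`kw`): rank-based H with the standard tie correction,
  $\chi^2_{K-1}$. Invariant under monotone transforms — the natural default
  for bounded, skewed data.
* **One-way ANOVA** (`anova`): the classical F on the raw beta scale,
  $F_{K-1,\,N-K}$. Included as the parametric reference point; optimal
  under normality and homoscedasticity, both questionable here.
* **Mood's median** (`median`): $A_k$ counts observations in group k
  strictly above the pooled median (the pooled median for even N is the
  midpoint of the two central order statistics);
  $M = 4\sum_k (A_k - n_k/2)^2 / n_k \sim \chi^2_{K-1}$. Ties at the pooled
  median count as "not above"; beta-values are effectively continuous, so
  such ties are rare in practice.
* **Welch** (`welch`): with $w_k = n_k/s_k^2$, $w = \sum w_k$,
  $\hat\mu = \sum w_k \bar x_k / w$ and
  $h_k = (1 - w_k/w)^2/(n_k - 1)$,
  $$W = \frac{\sum_k w_k(\bar x_k - \hat\mu)^2/(K-1)}
             {1 + \frac{2(K-2)}{K^2-1}\sum_k h_k}
    \;\sim\; F_{K-1,\,f},\qquad f = \frac{K^2-1}{3\sum_k h_k}.$$
  These are the forms of Welch (1951); some secondary presentations
  garble the constant to $2(K-2)/(K^2-2)$ and drop the square in $h_k$,
  which is inconsistent with the f given above (at K = 2 the correct forms
  collapse exactly to the squared two-sample Welch t with the
  Welch–Satterthwaite df, which the test suite verifies to 1e-10).

**Degenerate data.** A genome-scale run will meet invariant loci. A stratum
whose values are all identical yields p = 1 with a warning rather than an
error; ANOVA with zero within-group variance but unequal means yields p = 0
with a warning; a Welch group with zero variance (infinite weight) makes
the stratum untestable. A stratum is testable when at least two condition
groups remain after dropping missing values (for Welch: at least two groups
with $n_k \ge 2$ and positive variance); untestable strata produce a
missing p.

## Combining across strata

Missing per-stratum p-values are dropped and the combiner runs on the
effective G — a locus observed in only four of six strata is combined over
those four with $\chi^2_8$, not $\chi^2_{12}$. If no stratum is testable
the locus p is missing, never 1. Boundary p-values are clamped before the
transforms ($p = 0$ to the smallest positive double; $p = 1$ to
$1 - 2^{-53}$ for the Z), since $\log 0$ and $\Phi^{-1}(0)$ are undefined;
the clamp only matters for loci that are already unambiguous. The Z
combiner's weights are the per-locus retained stratum counts, not the
global stratum sizes: the weight should reflect the information actually
used once missing beta-values are dropped.

## Pipeline conventions

* **QC defaults**: drop samples with bisulfite-conversion intensity
  below 4000 (arbitrary fluorescence units), coverage rate below 0.95,
  or age above 80 years; all three comparisons are strict, so bs = 4000,
  coverage = 0.95 and age = 80 are retained. A sample lacking an optional
  QC column passes that criterion.
* **Age bins**: edges 50, 55, 60, 65, 70, 75 with labels such as `50_55`;
  intervals are left-closed/right-open, and the final bin is closed on the
  right at the QC age cap, so age 55 falls in `55_60` and age 80 in
  `75_over`. Overlapping textbook labels like "50–55, 55–60" force some
  convention; this is the standard one and keeps bins disjoint.
* **Missing beta-values** are dropped per locus per stratum, not imputed.
* **No multiplicity adjustment** is applied: the pipeline reports raw
  combined p-values and counts of loci below fixed cutoffs
  (10^-3 ... 10^-6). Which FDR procedure suits correlated methylation loci
  is an open question we deliberately do not answer here.

## The simulation harness

Scenarios draw K groups per replicate and apply every requested test to the
*same* draw (common random numbers — method comparisons share sampling
noise, halving the variance of their differences). Rejection is strict
(p < alpha). Tables derive per-scenario child seeds from a master seed via
`set.seed(seed); sample.int(2^31 - 2, n)`, so any row can be reproduced in
isolation.

Three generating families are available:

* `beta(a, b)` — the natural beta-value model;
* `truncnorm(mu, sigma2)` — the parent normal $N(\mu, \sigma^2)$ truncated
  to (0, 1) by inverse-CDF sampling; `sigma2` is the *parent* variance,
  the conventional TN parameterization;
* `censnorm(mu, sd)` — $N(\mu, sd^2)$ *clipped* to [0, 1] (censored, with
  point masses at the boundaries).

The built-in presets (`table1_scenarios()`, 12 null settings;
`table2_scenarios()`, 10 power settings) reproduce a published benchmark of
these four tests. Its normal-family rows are labelled TN(μ, σ²) with scale
values 0.1–0.3, but under the literal reading — parent variance, proper
truncation — the printed power entries are irreproducible (off by up to 35
percentage points: with sd ≈ 0.55 truncated to a unit interval, mean shifts
of 0.05 are undetectable at n = 30). Treating the printed scale value as
the parent **standard deviation** and **clipping** rather than truncating
reproduces all twenty normal-family cells to within Monte-Carlo error, so
the presets use `censnorm` with sd equal to the printed value. This is a
deliberate reverse-engineering of the benchmark's generator (almost
certainly `rnorm(n, mu, s)` followed by clamping into the valid beta
range); the clean `truncnorm` family remains available for new scenarios.
Two caveats survive even then: the benchmark's unbalanced unequal-variance
null row prints ANOVA at 0.047 where every pairing we tried gives ~0.033
(theory agrees ANOVA should be conservative when larger groups carry larger
variances), and its balanced-unequal-variance median cell prints 0.067
where the recovered generator gives ~0.055-0.058. The test suite checks
those rows at the reduced-run tolerance (±0.02 at R = 2000) rather than
pretending the discrepancy away.

## What the synthetic cohorts do and do not emulate

`generate_fixture()` builds a loci × samples matrix plus annotation with G
strata × K conditions, ages uniform within bins, null loci i.i.d. across
conditions, and differential loci given per-condition parameter offsets
constant across strata (optionally scaled per locus for graded effects).
Defaults: Beta(5, 20) null — a mostly-unmethylated locus with mean 0.2 —
with offsets on b of (0, 5, 10), mirroring the benchmark's power settings;
3 strata × 3 conditions × 10 samples.

The generator emulates the *structure* real cohorts have (stratum
occupancy, missing values, planted effects) but not several features of
real arrays: loci are independent (no co-methylation blocks), every null
locus shares one distribution (no probe-specific means/variances, no
bimodal mixture across the methylated/unmethylated poles), there are no
batch effects, and ages carry no true methylation trend within a stratum.
A green calibration test on fixtures therefore establishes that the
machinery holds its nominal level under an idealised null — not that the
error rate is controlled on a real cohort, where inter-locus correlation
inflates the variance of any genome-wide count.

## Numerical and design choices

* KW uses the tie correction unconditionally (no-op for continuous data).
* Exact enumerative versions of KW or the median test are test-suite
  oracles only, never production paths.
* The chi-square/F references are asymptotic. At very small strata they are
  crude: full enumeration at K = 3, n_k = 3 shows the $\chi^2_2$ survival
  function can deviate from the exact KW permutation distribution by up to
  ~0.1 (and ~0.03 even where p < 0.1); Mood's test at n_k = 30, K = 3 has
  true level ≈ 0.044 at nominal 0.05 because of the discreteness of the
  median split. Stratify no finer than the data can support.
* Rejection in the harness and cutoff counting in the pipeline are both
  strict inequalities, consistently.
* `alpha` may be set to 1 to force all replicates significant
  (continuous-data p-values are < 1 almost surely); the strict-inequality
  convention is documented rather than special-cased.

## Limitations

Beyond the synthetic-data caveats above: the package does not download or
preprocess raw array data (no IDAT/GEO handling, no normalisation, no
computation of beta from M/U signals); p-value combination assumes
independent strata, so samples must not appear in two strata; and no
multiple-testing correction is offered. The combiners are extension points
— minimum-p and other meta-analytic rules would slot in beside Fisher and
Z but are not implemented.
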