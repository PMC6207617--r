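---
title: "Partitioning the variance of a multi-instrument longitudinal phenotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning the variance of a multi-instrument longitudinal phenotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the model

Self-reported "sociability" is measured with many different instruments
(extraversion scales, reward-dependence subscales, temperament surveys),
and findings about it — in particular associations with oxytocin-pathway
genotypes — often fail to replicate. One structural explanation is that a
score from any single questionnaire mixes several sources of variance:
stable differences between people, systematic disagreement between
instruments about the same person, genuine within-person change over time,
and noise. `sociovar` separates these sources for a phenotype observed on
several individuals, with several indicators, at several assessment waves.

Each standardized observation is modelled as

$$
y_i \;=\; \mathbf{x}_i^\top\beta \;+\; \gamma_{k[i]} \;+\; \alpha_{j[i]}
\;+\; \delta_{t[i]} \;+\; \varepsilon_i ,
$$

with mutually uncorrelated, mean-zero Gaussian random intercepts:

* $\gamma_k$ — one per **individual**: the *trait* (between-individual)
  component, constant over instruments and time;
* $\alpha_j$ — one per **individual x indicator** cell: the *indicator*
  component, a person-specific offset of one questionnaire that persists
  over time;
* $\delta_t$ — one per **individual x wave** cell: the *state*
  (within-individual) component, a time-specific shift shared by all
  questionnaires;
* $\varepsilon_i$ — observation-level *residual*: measurement error plus
  indicator-specific occasion effects.

The fixed part $\mathbf{x}_i^\top\beta$ carries an intercept, age (years,
uncentered), gender (0 = women, 1 = men), assessment wave (years since the
earliest wave, so the first wave is 0), and optionally a genotype
covariate. Each estimated variance is also expressed as a *share* (Var%):
its percentage of the sum of all components in the fitted model.

A genotype can moderate a variance component. Writing
$\delta_{t[i]} = \delta^*_{t[i]} + \xi_{t[i]} x_i$ for a genotype covariate
$x_i$, the extra random effect $\xi$ inflates the state variance for
carriers ($x_i = 1$) relative to non-carriers ($x_i = 0$); analogous terms
exist at the trait and indicator levels. Because a time-constant genotype
that amplifies responses to a fast-varying environment must inflate
within-individual variance, a nonzero $\mathrm{Var}(\xi)$ on the state term
is an *indirect* gene-environment-interaction signal that needs no
measurement of the environment itself. With the cumulative 0-4 risk score
as $x_i$, the term enters as a scaled random-effect column (entries
$x_i$), so $\mathrm{Var}(\xi)$ is the variance of the per-unit-score
deviation; for a single 0/1 risk flag this reduces exactly to the
carrier formulation. Reported Var% columns use the raw $\mathrm{Var}(\xi)$
in the denominator sum, which matches the published table convention;
an average-contribution convention ($\bar{x^2}\,\mathrm{Var}(\xi)$) would
be equally defensible for the 0-4 score and is left to the caller.

## Scale scoring

Five indicator definitions are built in: NEO-FFI Extraversion (12 items,
fielded only at the last two waves), TCI Reward Dependence subscales
Sentimentality (10), Social Attachment (8) and Dependence (6), and EAS
Sociability. All use a 1-5 response metric. Scoring rules:

* a scale score is the mean over answered items, computed only when at
  least 75% of items were answered — the threshold is inclusive, so 9 of
  12 qualifies;
* the Dependence subscale is keyed entirely in reverse; we implement the
  conversion as per-item reversal $r \mapsto 6 - r$ before averaging, so a
  higher score means higher dependence on the same 1-5 metric as the other
  scales. (A post-hoc linear rescaling of the scale score would differ
  only by an affine map and would standardize identically.)
* the EAS Sociability item count is not fixed by the source instruments'
  public descriptions; we use the 5-item adult form, the most common
  published version. Only the 75%-rule threshold depends on this choice.
* the small wording change of the response anchors introduced at the
  third wave is treated as inert: same metric, no recalibration.

Scores are standardized per indicator to mean 0 and variance 1 (sample SD,
$n-1$ denominator) at a reference wave — by default 2007, the first wave at
which every indicator was administered — and the same affine map is applied
to that indicator at all waves. Variances at non-reference waves are
therefore free to differ from 1, which is what makes the wave-level
variance components interpretable.

## Genotypes

Four oxytocin-pathway SNPs are coded into 0/1 risk flags using the
genotype groups previously associated with social difficulties:
rs1042778 TT, rs2254298 GG, rs53576 AA/AG, rs3796863 CC. Genotypes are
unordered allele pairs ("GA" is "AG"); phase is ignored because only
genotype groups matter. The cumulative risk score is the sum of the four
flags (0-4); an individual missing any SNP has a missing score and drops
out of genetic models. The score is used raw (uncentered) both as a fixed
covariate and as the variance-moderating $x_i$. A VCF reader
(`extract_from_vcf()`, via the vcfR package) is a convenience; the
canonical interchange is a plain genotype CSV.

## Estimation

The engine is written in the package (it does not call an external
mixed-model fitter). With $V = \sum_t \sigma_t^2 Z_t Z_t^\top + \sigma^2 I$
and relative SDs $\theta_t = \sigma_t/\sigma$, the REML (or ML) criterion
is evaluated through the penalized least-squares representation: a sparse
Cholesky factorization of $\Lambda^\top Z^\top Z \Lambda + I$ with a
symbolic pattern computed once and refactored in place per evaluation,
yielding the profiled deviance with $\beta$ and $\sigma^2$ concentrated
out. Numerical choices:

* optimization is quasi-Newton (`L-BFGS-B`) over $\log\theta_t$, which
  keeps variances positive, from a deterministic start plus 3 seeded
  random restarts; relative variances below $e^{-24}$ are reported as
  exact zeros with a `boundary` flag;
* for small designs (under ~800 random-effect levels) the same algebra
  runs through plain dense base-R Cholesky factorizations, which avoids
  per-call S4 dispatch overhead in tight simulation loops; the two paths
  agree to near machine precision and both are checked in the tests
  against an independent dense $V$-matrix evaluation of the likelihood;
* fixed effects are generalized least squares at the optimum; their
  p-values use the large-sample normal reference, appropriate for the
  thousand-plus-individual designs this model targets (no
  Satterthwaite/Kenward-Roger correction);
* variance components are reported from REML fits; AIC is always ML-based
  (for a REML fit, a warm-started ML optimization supplies it), and AIC
  comparisons refuse fits on different observation sets;
* confidence intervals for variance components are profile-likelihood
  intervals: bounds where the re-profiled deviance rises by the
  $\chi^2_1$ quantile, searched on the SD scale with warm-started inner
  optimizations and truncated below at 0. A parametric-bootstrap
  percentile interval is available behind `method = "boot"`;
* missing data are handled by observation-level listwise deletion
  (available-case analysis), with dropped-row counts logged;
* report tables round half-away-from-zero at the printed precision;
  shares are reported unrounded in fit objects, because published
  roundings of the same quantity are not always mutually consistent, and
  presentation rounding belongs to the caller;
* the per-indicator genotype test uses a sum-to-zero coded group contrast
  (+1 risk group, -1 other) in a model with an individual random
  intercept and age/gender/wave covariates; the Wald statistic is an
  F with 1 numerator df and residual denominator df
  $n_{obs} - \mathrm{rank}(X)$, consistent with the per-indicator
  observation counts such tests are reported with.

Degenerate inputs are handled explicitly: a response perfectly explained
by the fixed effects returns an all-zero variance decomposition; an
all-zero genotype-variance column is unidentified and pinned at the
boundary; a degenerate genotype covariate (single value) skips the
variance-interaction terms with a warning; collinear fixed-effect columns
are dropped with a warning.

## The synthetic cohort generator

`simulate_cohort()` emulates the accelerated-longitudinal design the model
targets, so every stage is testable without restricted cohort data: six
birth cohorts at 3-year spacing (1962-1977, allocated evenly), four
assessment waves (1997, 2001, 2007, 2012), five indicators with NEO-FFI
Extraversion restricted to the last two waves — 18 potential observations
per person, ages 20-35 at the first wave through 35-50 at the last. The
generator's defaults are the study conditions: generating variance
components (0.212, 0.387, 0.048, 0.298) and fixed effects (intercept
0.438, age -0.007, gender -0.442, wave -0.001) equal to the published
base-model estimates, 59% women, and per-SNP risk-group frequencies
(0.154, 0.843, 0.664, 0.408) matching the published prevalences. SNPs are
drawn independently (no linkage disequilibrium) under Hardy-Weinberg
proportions chosen to hit the risk-group frequency; this reproduces the
published marginal genotype table and, to a good approximation, the
published 0-4 risk-score distribution. Dropout is
missing-completely-at-random at a configurable rate (default 0: the
analysed genotyped subsample is essentially complete at ~18 observations
per person); the real cohort's attrition mechanism is unknown and not
modelled. Optional raw-metric emulation maps standardized scores back to
each indicator's 1-5 scale using the third-wave means/SDs as anchors,
clamped to the response bounds.

What the generator does *not* emulate: item-level response processes
(items are only simulated in tests, independently per item, to exercise
the scoring rules); informative dropout; population stratification; and
per-pair indicator correlations — a single indicator-level variance
implies exchangeable correlations between indicators, whereas real
instruments correlate unevenly. Passing tests therefore show that the
estimator recovers the generating mechanism of this design, not that the
model is correct for any particular real cohort.

## Test and simulation scales

The test suite fixes its problem sizes as follows: parameter recovery uses
20 replicates of 800 individuals (14,400 observations) under the default
design, with replicate-mean estimates required within +/-0.02 of each
generating variance and +/-0.05 of the gender effect; profile-interval
coverage uses 300 replicates of a compact 35-individual, 3-indicator,
3-wave design (95% intervals, acceptance band 0.92-0.98); the null
calibration of the per-indicator genotype F-test uses 1000 replicates of
150 individuals at one indicator (acceptance band 0.03-0.07 at
$\alpha = 0.05$). Likelihood-oracle equivalence is checked on designs of
at most 60 observations against a brute-force dense implementation written
independently in the test helpers, and against lme4 as an external
cross-check — lme4 is used only as an oracle, never as the engine.

## Known limitations

* Random intercepts only: no random slopes (e.g. on age), no covariances
  between terms, Gaussian responses only, and only the three stated
  crossed grouping factors.
* Var% for genotype-scaled terms uses the raw $\mathrm{Var}(\xi)$
  convention (see above); with a 0-4 score the share is not invariant to
  rescaling $x$.
* Profile intervals assume the usual $\chi^2_1$ calibration, which is
  approximate near the boundary; boundary components report a one-sided
  interval.
* The normal reference for fixed-effect p-values is anticonservative in
  very small samples; at the design sizes above the calibration tests
  show it holds its level.
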