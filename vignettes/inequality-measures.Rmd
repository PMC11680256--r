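---
title: "Measuring health inequality from disaggregated data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring health inequality from disaggregated data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthineq)
```

## The problem and the data model

Equity monitoring of health indicators — immunization coverage being the
motivating case — works from *disaggregated data*: an indicator estimated
separately for the subgroups of a *dimension of inequality*. Dimensions
come in three structural kinds, and the kind determines which summary
measures are meaningful:

* **binary** — exactly two subgroups (urban/rural residence);
* **ordered** — subgroups with an inherent ranking from least to most
  advantaged (wealth quintiles; subnational regions ranked by an external
  index such as the human development index);
* **non-ordered** — more than two subgroups with no inherent ranking
  (subnational regions, ethnicity, occupation).

The unit of computation is a `disagg_series`: one setting × one indicator
× one dimension, holding per-subgroup estimates `y_j` (always on the
percent scale, 0–100), optional standard errors, populations (counts or
shares; normalized internally, raw values retained for cross-setting
weighting), and, for ordered dimensions, a unique contiguous advantage
rank with rank 1 = least advantaged. An indicator is flagged *favourable*
(coverage: higher is better) or *adverse* (zero-dose prevalence); the flag
never changes D or R for binary/ordered dimensions — orientation there is
fixed by subgroup identity — but it selects the reference subgroup for
the impact measures and the interpretation metadata.

The setting average μ is the population-weighted mean of the subgroup
estimates *unless* the data source supplies its own national average, in
which case the supplied value is used consistently in every relative and
deviation-from-mean measure. The override exists because published
national averages typically come from survey-weighted microdata and need
not equal the re-aggregation of rounded subgroup estimates; reproducing
source behaviour requires honouring them.

Ordered subgroups are placed on [0, 1] by the standard ridit/midpoint
construction, `X_j = Σ_{k<j} p_k + p_j / 2`. Two properties matter
downstream and are asserted in the tests: `Σ p_j X_j = 1/2` for *any*
share vector, and `X_j` is strictly increasing in rank.

## Measure conventions worth stating

* **Extreme-subgroup pairing.** Binary: group of interest − reference,
  with urban − rural built in for residence and any other orientation
  declared explicitly per series. Ordered: most − least advantaged.
  Non-ordered: max − min estimate regardless of favourability, so D ≥ 0
  and R ≥ 1; ties are broken by input order and the tied label sets are
  recorded. Pairing by estimate (not by favourability) is what lets an
  adverse indicator with a near-zero region produce ratios in the
  hundreds, which is exactly the outlier-sensitivity phenomenon the
  measure suite is meant to expose.
* **Zero denominators are results, not errors.** A ratio against a
  zero-valued subgroup returns a result with `defined = FALSE` and a
  reason; the same applies to all measures dividing by μ when μ = 0.
  Pipelines keep running and the flag propagates to output tables.
* **RCI scaling.** RCI is reported as `100 · ACI / μ`, matching the ×100
  scaling of IDISU/IDISW/COV; users wanting the conventional [−1, 1]
  concentration-index scale can divide by 100. The choice is recorded
  here because reference material for this suite does not state it
  unambiguously.
* **MDMU's deliberate asymmetry.** MDMU takes *unweighted* mean absolute
  deviations about the *weighted* mean μ. Both MDMU variants share μ with
  MDMW/BGV/BGSD/COV/TI so that all deviation measures answer against the
  same centre.
* **Theil limit convention.** `0 · ln 0 := 0`, so zero-valued subgroups
  contribute nothing and TI stays finite — zero-dose data really do
  contain regions at exactly 0%.
* **SII/RII fitting variants.** Different software fits the underlying
  regression differently and the estimates differ slightly. The package
  makes the variant explicit instead of hiding it: the default is
  share-weighted least squares of `y_j` on `X_j` on the percent scale
  (closed form, exact on two points and on collinear data); a logit-link
  quasi-binomial GLM on the proportion scale is available, and every
  result records which variant produced it. Under the linear variant a
  steep negative gradient can drive the prediction at `X = 0` to or below
  zero, making RII undefined; the logit variant keeps predictions in
  (0, 100) and remains defined — this divergence is a property of the
  models, not a bug, and both behaviours are tested.
* **PAR reference rule and truncation.** Ordered dimensions use the most
  advantaged subgroup as the reference *even when it is not the best
  performer* — the point of an ordered analysis is the advantage
  gradient, and discordance between advantage and performance is a
  finding, not an error. Non-ordered dimensions use the best performer.
  When the reference is worse than μ, PAR is truncated to 0 with a flag;
  the raw signed value is kept in metadata because correlation analyses
  may legitimately prefer it. Adverse-indicator PAR is signed negative (a
  reduction in prevalence), with `par_magnitude()` as the absolute
  accessor, and `aggregate_par()` combines signed PARs with applicable
  population weights into current vs potential cross-setting averages.

## Confidence intervals

Closed-form reference formulas for every measure's variance were not
available to this implementation, so the package commits to a two-route
strategy rather than guessing:

* **Analytic** where the form is standard and stable: Wald for D
  (`SE = √(se_a² + se_b²)`); delta method on the log scale for R; for the
  linear SII, propagation of the subgroup SEs through the closed-form WLS
  slope (`Var(SII) = Σ c_j² se_j²` with the known slope coefficients
  `c_j`); for the linear RII, the delta method on the log predicted
  ratio, falling back to the bootstrap when the prediction at `X = 0` is
  within two standard errors of zero.
* **Parametric bootstrap** for everything else (ACI, RCI, the whole
  non-ordered family, PAR/PAF, and the logit-variant SII/RII): resample
  `y_j* ~ Normal(y_j, se_j)` censored to [0, 100], recompute, take
  percentile quantiles. Censored-normal resampling is a simplicity/
  symmetry choice at indicator scale and is a documented dialect
  difference from logit-normal alternatives. Seeded runs are
  bit-reproducible and the global RNG state is restored.

Two deliberate behaviours: a CI is flagged undefined (with a reason) when
any subgroup SE is missing or when the measure itself is undefined in
more than half the replicates; and percentile intervals are clamped to
contain the point estimate. The clamp exists because for a biased,
sign-constrained statistic such as BGV near zero, the raw percentile
interval can exclude the observed value — an interval that excludes its
own point estimate is harder to defend than a slightly conservative one,
and the package's contract is that every reported interval contains its
estimate.

`method = "auto"` picks the analytic route where one exists. Requesting
`"analytic"` for a bootstrap-only measure is an error rather than a
silent substitution.

## The synthetic-data generator as a stated world

`synthetic_scenario()` emulates the structure of survey-derived
immunization tables: percent-scale estimates, binomial sampling noise at
a chosen effective subgroup sample size (default 1000, the order of
magnitude of DHS/MICS subgroup denominators), the implied binomial SE
attached to each estimate, and population shares that are equal (exact
for wealth quintiles, idealized for regions) or drawn from a symmetric
Dirichlet when unevenness matters. Binomial — not normal — noise is used
because the indicators are proportions, and it lets exact 0% estimates
arise naturally in low-prevalence adverse scenarios, exercising the
zero-denominator and Theil-limit paths with realistic inputs.

Effect shapes: `null` (no inequality), `linear` (a gradient that is
linear in the equal-share midpoint rank with slope `gradient_size`, so
the true linear SII equals `gradient_size` exactly — the anchoring
property the recovery tests rely on; the extreme true values then span
`gradient_size · (n−1)/n`), `outlier` (one offset subgroup with a small
population share, the configuration separating weighted from unweighted
measures), and `step`. Scenarios whose true values leave [0, 100] are
rejected at construction.

What the generator does **not** emulate: survey design effects (clusters,
strata, design-based SE inflation), spatial or serial correlation between
subgroups, reporting heaping, or missing-subgroup patterns. A green test
against this world therefore establishes correctness of the estimators
and their sampling behaviour under independent binomial noise — not
robustness to the full messiness of household-survey data.

One validation note: coverage of the bootstrap interval is assessed on a
scenario with a *non-zero* true between-group variance (a step pattern
with true BGV = 100). Under a null scenario the truth is 0 while BGV is
strictly positive in every noisy replicate, so a percentile interval's
lower bound is positive almost surely and coverage of the truth is
near 0% by construction; a null-coverage check would test the geometry of
non-negative statistics, not the bootstrap.

## Pipeline choices

* Eligibility: binary series need both subgroups; ordered series need all
  expected levels (default 5, quintiles); non-ordered series are dropped
  when *more than* 15% of the setting's expected regions are missing —
  exactly 15% is kept, and the boundary is tested. Expected region counts
  must be supplied; the rule is skipped with a warning otherwise, never
  guessed from the observed data.
* Cross-setting summaries use type-7 (linear-interpolation) quantiles for
  medians and IQRs — R's default and the most common convention.
* Spearman correlations use midrank ties with the t-approximation for
  n ≥ 10 and full permutation enumeration below that; strength classes
  follow the ≥0.9 / ≥0.7 / ≥0.4 thresholds on |ρ|. Correlations of
  signed estimates are the default; absolute-value correlation is an
  explicit option, since for adverse indicators the two answer different
  questions.
* Quantile grouping of many-region settings (a resolution-control
  technique) is available as an explicit pre-processing helper,
  `group_quantiles()`; no measure applies it implicitly.

## Known limitations

* Inputs are aggregated estimates; nothing here replaces design-based
  estimation from microdata, and no small-sample or bounded-outcome
  corrections (Erreygers/Wagstaff normalizations) are applied to the
  concentration indices.
* Analytic SEs treat subgroup estimates as independent; within-survey
  correlation between subgroups is ignored, as it is invisible at this
  level of aggregation.
* The bootstrap's censoring at the [0, 100] boundary slightly shrinks
  resampled spread for estimates near the boundary.
* Exact permutation p-values are enumerated for n < 10 and are
  increasingly expensive from n = 8; at n ≥ 10 the t-approximation takes
  over.
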