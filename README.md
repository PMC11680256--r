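# healthineq

Summary measures of health inequality from disaggregated data.

Health-equity monitoring asks a deceptively simple question: given an
indicator estimated separately for population subgroups — immunization
coverage by wealth quintile, zero-dose prevalence by subnational region,
coverage in urban versus rural areas — how unequal is the distribution,
in one number? Different summary measures answer differently: absolute vs
relative, simple (two extreme subgroups) vs complex (all subgroups,
optionally population-weighted), more or less sensitive to outlying
subgroups. `healthineq` computes the standard suite of sixteen measures
with confidence intervals, so the choice of measure, and its consequences,
can be made explicit. It is aimed at epidemiologists and health-equity
analysts working with survey-derived subgroup estimates (DHS/MICS-style
tables), not microdata.

## The measures

For a series with subgroup estimates `y_j` (percent), population shares
`p_j`, setting average `μ = Σ p_j y_j` (or a supplied national average),
and — for ordered dimensions — midpoint (ridit) ranks
`X_j = Σ_{k<j} p_k + p_j/2`:

| Code | Definition | Scale | Dimension |
|------|------------|-------|-----------|
| D | `y_a − y_b` for extreme subgroups | pp | all |
| R | `y_a / y_b` | ratio | all |
| ACI | `Σ p_j y_j (2X_j − 1)` | pp | ordered |
| RCI | `100 · ACI / μ` | ×100 | ordered |
| SII | prediction gap at `X=1` vs `X=0` of share-weighted regression | pp | ordered |
| RII | prediction ratio at `X=1` vs `X=0` | ratio | ordered |
| MDMU | `(1/n) Σ |y_j − μ|` | pp | non-ordered |
| MDMW | `Σ p_j |y_j − μ|` | pp | non-ordered |
| IDISU / IDISW | `100 · MDM / μ` | ×100 | non-ordered |
| BGV | `Σ p_j (y_j − μ)²` | pp² | non-ordered |
| BGSD | `√BGV` | pp | non-ordered |
| COV | `100 · BGSD / μ` | ×100 | non-ordered |
| TI | `1000 · Σ p_j (y_j/μ) ln(y_j/μ)` | ×1000 | non-ordered |
| PAR | `y_ref − μ`, truncated at 0 | pp | ordered, non-ordered |
| PAF | `100 · PAR / μ` | % | ordered, non-ordered |

Sign conventions: for ordered dimensions, positive D/ACI/SII (and
R/RII > 1) mean higher values among the most advantaged. For binary
dimensions, D = group of interest − reference (urban − rural). Non-ordered
D/R compare the best and worst subgroup (D ≥ 0, R ≥ 1). For adverse
indicators (zero-dose prevalence), PAR is reported as a signed negative
change — the achievable reduction.

## Worked example

DTP3 coverage across wealth quintiles in one setting (q1 = poorest):

```r
library(healthineq)
s <- disagg_series(
  estimate   = c(62.1, 70.4, 78.9, 84.2, 91.3),   # percent
  population = c(21000, 20400, 19900, 19300, 19400),
  se         = c(2.1, 1.9, 1.7, 1.5, 1.2),
  subgroup   = paste0("q", 1:5), order = 1:5,
  dimension_type = "ordered", dimension = "wealth",
  indicator = "dtp3", setting = "EX", favourable = TRUE)
res <- compute_all(s, ci = ci_config(seed = 42))
for (r in res) print(r)
```

```
D = 29.2  [95% CI 24.46, 33.94]  (q5 vs q1)
R = 1.47  [95% CI 1.369, 1.579]  (q5 vs q1)
ACI = 5.807  [95% CI 4.922, 6.653]
RCI = 7.535  [95% CI 6.362, 8.721]
SII = 36.3  [95% CI 30.92, 41.67]
RII = 1.616  [95% CI 1.495, 1.747]
PAR = 14.23  [95% CI 11.85, 16.68]
PAF = 18.47  [95% CI 15.3, 21.72]
```

Reading: coverage is 29.2 percentage points higher in the richest than the
poorest quintile (D), 36.3 points when the gradient across all five
quintiles is used (SII — larger than D here because the middle quintiles
reinforce the gradient). ACI > 0: coverage is concentrated among the
richer quintiles. If every quintile reached the richest quintile's level,
the setting average (77.1%) would rise by 14.2 points (PAR), an 18.5%
relative gain (PAF).

The same API covers binary and non-ordered series
(`measure_mdmw()`, `measure_bgv()`, `measure_theil()`, ...), eligibility
filtering (`eligibility_filter()`), cross-setting medians/IQR
(`summarize_measures()`) and Spearman correlation matrices with the usual
strength thresholds (`correlate_measures()`), and a synthetic-data
generator with binomial survey noise (`synthetic_scenario()`,
`generate_series()`, `recover_parameters()`).

## Command line

```sh
exec/healthineq simulate --output data.csv --settings 20 \
    --dimension-type nonordered --subgroups 8 --shape outlier --seed 7
exec/healthineq compute  --input data.csv --output results.csv --seed 7
exec/healthineq compare  --input results.csv --output-summary summary.csv \
    --output-correlation correlations.csv
exec/healthineq filter   --input data.csv --output kept.csv --log excluded.csv
```

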