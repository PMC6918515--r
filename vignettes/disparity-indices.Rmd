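---
title: "Methods: frame-of-reference disparity indices for state BMI surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frame-of-reference disparity indices for state BMI surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hwdisparity)
```

## The problem and the model

Health-disparity indices summarise how mean body mass index (BMI) differs
across income groups within a geographic unit. The package implements two
such indices for U.S. states and quantifies how much the state rankings
they induce agree.

Both indices are sums of signed deviations of income-group adjusted mean
BMIs from a reference:

* **HWDI** uses a *national* frame: fixed dollar income cut points
  (low < \$35,000; middle \$35,000 to < \$75,000; high ≥ \$75,000 per
  year) and the fixed healthy-weight ceiling 24.9 kg/m² as reference,
  `HWDI = (24.9 − high) + (mid − 24.9) + (low − 24.9)`.
* **RHWDI** uses a *state-specific* frame: income groups from the
  household income-to-poverty-guideline ratio (low at or below 185% of
  the federal poverty level — the eligibility cutoff for several
  assistance programs; high above the state's 75th percentile of the
  ratio) and the state's own adjusted mean BMI as reference,
  `RHWDI = (mean − high) + (mid − mean) + (low − mean)`.

Algebraically `index = low + mid − high − reference`, so the two satisfy
the exact *frame identity* `RHWDI − HWDI = 24.9 − state mean`, which the
test suite checks to machine precision. RHWDI is invariant to adding a
constant to all four inputs; HWDI shifts one-for-one. A negative value
means high-income respondents are heavier than low/middle-income ones;
since disparity *size* is the ranked quantity, states are ranked by
ascending |index| with the sign carried as a flag (the published table
assigns rank 1 and rank 48 to states flagged negative, which is impossible
under signed ordering — magnitude ranking is the only reading consistent
with it). Magnitude ties break by unrounded signed value, then
alphabetically; both choices are deterministic because no tie rule is
documented for the published table.

## Income classification

Ordinal income categories are mapped to the *highest* dollar value of
their range (\$9,999 for the lowest; the open-ended ≥ \$75,000 category to
\$75,000) — the most optimistic assignment, which shrinks rather than
inflates disparities. The poverty-guideline ratio is
`100 × income / (base + (household size − 1) × increment)`, with separate
HHS guideline rows (effective January 2016) for the 48 contiguous states +
DC, Alaska, and Hawaii. Household size is adults + children, the only
composition variables coded.

The state 75th percentile uses the Hazen definition (plotting position
`h = np + 1/2`, linear interpolation between order statistics; R's
`quantile` type 5). On `{100, 200, 300, 400}` it gives 350; it is also
what Stata's default percentile returns there, relevant because the
original analysis was run in Stata. The percentile is unweighted by
default for determinism and oracle-testability (whether the original was
survey-weighted is unstated); a weighted variant interpolates the weighted
ECDF at the same plotting positions (`weighted_p75 = TRUE`). The
percentile is computed per state on the post-exclusion population,
separately within each imputed dataset, since imputed income moves the
cut point. If a state's p75 falls at or below 185 the middle group is
empty: a warning is raised, the group mean becomes non-computable, and the
state drops out of the ranking — mirroring how states with data problems
were removed rather than patched.

## Cohort rules

Respondents are excluded if pregnant, older than 65, or underweight
(BMI < 18.5, strict). A record matching several criteria is tallied once
under the first reason in that order. Age is coded in five categories
spanning 18–64; any other code is treated as over-65 (so age exactly 65 is
excluded — the variable coding enforces the criterion). Records *missing*
a criterion field are never excluded by it: missingness is resolved by
imputation afterwards, and dropping here would confound the two stages.

A state is ineligible when any analysis variable is more than 50% missing,
or when the observed 8×6 income-by-race cross-tabulation has an empty cell
whose marginals are both non-zero. Both screens run on observed,
pre-imputation data.

## Multiple imputation

Missing data are filled per state by chained equations with m = 20
datasets. Per-variable methods: Bayesian linear regression (BMI, adults,
children — coefficient and residual-variance posterior draws, so the m
datasets differ), predictive mean matching (education, income; 5 donors,
nearest predicted mean, distance ties to the lowest record index, type-0
matching with OLS predictions on both sides), and logistic regression
(sex; coefficient draw, with an observed-frequency fallback under
separation). Race/ethnicity is never imputed; records missing it are
case-wise deleted. The survey weight enters every model as a *predictor*,
not as a case weight. Variables are visited in ascending-missingness order
over 10 cycles (the common burn-in; the procedure is insensitive to this
for the single-variable chains used in the coverage screen, which
therefore run 2 cycles purely for speed). Imputed household counts are
rounded to non-negative integers. Per-dataset seeds derive from the master
seed by fixed offsets, so stacks are bit-reproducible.

## Adjusted means and pooling

Within each completed dataset, BMI is regressed on indicator-coded age,
race/ethnicity, sex, education and the scheme's three-level income group,
by weighted least squares with the survey weight as case weight. "Post-hoc
adjusted means" is operationalised as marginal standardisation
(g-computation): set every respondent's income group to g, predict, and
take the survey-weighted mean — the reading that reproduces raw group
means exactly when covariates are balanced, which the null-generator tests
verify. (Whether the original model included income or predicted at
covariate means is unstated; a predict-at-covariate-means flag exists, and
for a linear model the two coincide.) The overall marginal mean equals the
weighted raw BMI mean, and serves as the RHWDI reference so reference and
group means share one adjustment scale. Estimates are pooled across the m
datasets by Rubin's rule for point estimates (arithmetic mean), with
between-imputation variance kept for diagnostics. The complex design is
honoured for point estimation only; design-based variances are out of
scope.

## Concordance

Spearman's ρ is the Pearson correlation of average-tie ranks; its p-value
uses the t approximation with n − 2 df (exact permutation available for
n ≤ 10, used by oracle tests), multiplied by a Bonferroni family size m
(default 1 — a single correlation is tested; the original invokes
Bonferroni without stating a family). Rankings are cut into terciles,
largest bin first (17/16/16 at n = 49; the split is undocumented, this
rule is deterministic and monotone), and compared by Cohen's κ with the
large-sample null-SE test; "df = n − 1" is reported as presentation
metadata to mirror the field's convention, not as a test parameter.
Rank-difference summaries count states at |Δ| of 0, 1, 2, ≥ 5 and list the
top-k movers.

Computed from the packaged published table, ρ = 0.012 and tercile
κ = −0.072 — the published Abstract and Results disagree with each other
(ρ printed as 0.11 and 0.01), so the acceptance check asserts only the
qualitative finding, |ρ| ≤ 0.2 and |κ| ≤ 0.2 ("very weak", "not
concordant"), which these satisfy.

## The synthetic world

The generator emulates the analysis sample of a large telephone health
survey: eight ordinal income categories with the published margins (34.2%
in the top category), five age bands, 50.8% female, six race/ethnicity
groups, four education levels; BMI is built additively as
`state base + income-group gradient + covariate effects + N(0, σ)` with
σ = 6 kg/m² (a realistic adult BMI spread) and a default base of
27.5 kg/m², giving an overall mean near 28.2 after the default +1.5/+0.5/0
gradient. Survey weights are log-normal, normalised to mean 1 per state —
positive, right-skewed, scale-free. Pregnancy (3% of females) exists only
to exercise the exclusion. The gradient is injected by the *fixed-dollar*
group so the truth is known without reference to the simulated poverty
ratio; the poverty-ratio classification then genuinely re-classifies.
Missingness is MCAR or MAR-on-weight (logistic in the standardised log
weight, intercept calibrated so the mean probability equals the target
rate — monotone in the weight by construction).

What a green test does *not* establish: the generator has no dual-frame
telephone sampling, raking, reporting bias in self-reported height/weight,
or real geographic income structure; recovery results validate the
pipeline's arithmetic and its imputation machinery, not the substantive
published index values, which depend on the external survey.

Two deliberate experiment-design choices in the acceptance runs: (1) the
parameter-recovery world uses uniform race margins because, at
2,000 respondents/state, the published 1.6% race categories leave an
income×race cell empty often enough that the eligibility screen — which
emulates a data-quality failure unrelated to the estimand — would
stochastically censor states; (2) its 20% MCAR is applied to BMI, the
variable whose group means are the estimand. The oracle for recovery is
the weighted low-vs-high BMI gap on the *complete* (pre-masking),
post-exclusion data, so the underweight exclusion's truncation of the
injected gap affects oracle and estimate identically.

## Numerical choices and degenerate inputs

Seeds are 32-bit; child seeds derive by fixed affine offsets modulo
2³¹ − 1. Rank-deficient regression designs drop aliased columns with a
warning; single-level factors are dropped from the model formula. A
cross-product ridge of 1e−10 guards the posterior-draw Cholesky. States
where an imputable variable has no (or fewer than `min_complete` = 10)
observed values raise a typed `hwd_unimputable` condition; the pipeline
reports the state as dropped and continues. Concordance requires at least
3 computable states, else it is skipped with an explanation. Index values
are kept at full precision; rounding to 2 decimals is presentation-only.

## Known limitations

No design-based (replicate-weight or linearised) variance estimation; no
inflation or regional-price adjustment of the dollar cut points; no
imputation convergence diagnostics beyond the fixed cycle count; native
fixed-width survey export formats are not parsed (delimited text only).
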