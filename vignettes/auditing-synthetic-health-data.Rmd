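---
title: "Auditing subgroup fairness in synthetic health data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing subgroup fairness in synthetic health data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synfair)
```

## The problem

A synthetic dataset is released as a privacy-preserving stand-in for a
real one. Good *overall* resemblance does not guarantee good *subgroup*
resemblance: the generator may capture the majority distribution while
thinning or deleting minority subgroups, and any analysis stratified by
those attributes inherits the bias. `synfair` treats the two tables as
independent samples bound to one schema of categorical protected
attributes (race, gender, binned age, outcome, ...) and asks, for every
subgroup definable as a conjunction of levels, two questions: is the
subgroup *present at the right rate*, and are its *temporal trends
captured as well* as everyone else's?

## Representation rates

Write g(x) = 1 when row x matches every level of the subgroup's
assignment, 0 otherwise; the complement is all remaining rows of the
same dataset — deliberately not the sibling level, so g is binary even
for multi-level attributes. With observed rates $p_S$ and $p_R$ in the
synthetic and real tables the log disparity is

$$\mathrm{LD} = \log\frac{p_S/(1-p_S)}{p_R/(1-p_R)}.$$

The synthetic odds sit in the numerator, so positive values mean
over-representation in the synthetic data; for a binary attribute the
two levels' values are exact negatives of each other. The odds-ratio
form is not arbitrary: modelling "appears in the real sample" and
"appears in the synthetic sample" as independent binary sampling
indicators, with real sampling independent of subgroup membership, the
classic disparate impact ratio
$P(y'{=}1 \mid g{=}1)/P(y'{=}1 \mid g{=}0)$ reduces exactly to this
odds ratio. The package keeps that reduction testable:
`independent_population()` builds finite populations satisfying the
assumptions *by construction* (product-form replication), and
`disparate_impact_oracle()` computes both sides by brute-force
frequency counting; they agree to floating-point precision.

### Categories

Values are binned into six levels with thresholds $t_1 = |\log 0.9|$
(the "90 percent rule") and $t_2 = |\log 0.8|$ (the "80 percent rule",
the classic disparate-impact cutoff): `adequate` below $t_1$;
`over`/`under` between $t_1$ and $t_2$; `highly_over`/`highly_under` at
or beyond $t_2$; and `missing` for a subgroup present in the real data
but entirely absent from the synthetic data — a qualitatively different
failure (mode collapse) that gets its own (red) level rather than
$-\infty$. Two boundary conventions are ours, since a convention is
needed: values exactly on a threshold take the *more severe* category
(an audit should err toward flagging), and a subgroup absent from the
*real* data is an error, not `missing` — there is no reference rate to
compare against, so the row is flagged `absent_in_real` and skipped.

### Significance

Sampling noise alone produces nonzero disparities, so each subgroup is
tested against the null $p_S = p_R$ with the pooled two-proportion
z-statistic

$$z = \frac{p_S - p_R}{\sqrt{p(1-p)/n_S + p(1-p)/n_R}},
\qquad p = \frac{c_S + c_R}{n_S + n_R},$$

two-sided, since over- and under-representation are both of interest.
When any expected cell count under the pooled proportion falls below 5
(the textbook rule; configurable via `min_expected`) the Fisher exact
test replaces it. Because the lattice multiplies comparisons — 269
subgroups for the ICU-extract schema — Benjamini–Hochberg is applied
once per run across all subgroups evaluated together, and `significant`
means adjusted p < 0.05. Non-significant subgroups are *annotated*
(starred in exports), never suppressed: their disparity and category
are still reported, as the alternative — gating the metric on the test —
would hide exactly the small subgroups an audit cares about.

## Temporal trends

For longitudinal schemas each subgroup's rows are collapsed into one
series per temporal feature with a statistic f per time point: `mean`
(average sleep minutes, prevalence fractions), `sum`, or `count` of
nonzero cells (binary diagnosis columns). Resemblance between the real
and synthetic series is either the mapped Pearson correlation
$(r+1)/2 \in [0,1]$ — mapped so it can enter a log ratio — or
directional symmetry, the percentage of consecutive steps moving in the
same direction, with ties ($\ge 0$ products) counting as agreement.
The time-series log disparity contrasts subgroup and complement:

$$\mathrm{TSLD} = \log\frac{\mathrm{res}(TS_r, TS_s \mid g{=}1)}
{\mathrm{res}(TS_r, TS_s \mid g{=}0)},$$

categorized on the same six-level scale. The two metrics are
complementary — correlation ignores location/scale shifts, directional
symmetry ignores magnitudes — and can legitimately disagree: a series
matching the macro-trend but jittering against the micro-steps is
adequate by correlation and under-represented by direction. Both are
reported.

Design choices worth recording:

* **Expectation over features.** With one temporal feature the
  expectation in the ratio degenerates to the single resemblance value.
  For multivariate panels the per-feature rows are the primary output
  (one per subgroup × feature), with a `"(mean)"` summary row realizing
  the expectation as the arithmetic mean of per-feature resemblances;
  `concatenated` mode instead joins the features in schema order into
  one series of length $m \cdot T$ first.
* **Zero-variance series** (a constant prevalence curve) have no
  defined correlation. We raise a named `undefined_resemblance`
  condition and flag the row rather than imputing $r = 1$ or $0$ —
  any imputation invents information. Runs never abort on degenerate
  subgroups; they emit flagged rows.
* **No significance testing** is attached to the temporal metric; a
  proper reference distribution for aggregated-series resemblance is an
  open problem, and reporting a bogus p-value would be worse than none.

## The simulators and what they do (not) show

`simulate_pair()` generates paired datasets in three shapes: an ICU
mortality extract (race 5 × gender 2 × age 4 × mortality 2, categorical
only), a sleep survey (gender 2 × age 7, one feature of 30 contiguous
hourly minutes-asleep columns), and a pediatric claims panel (gender ×
race, seven binary diagnosis series of 10 six-month periods). Default
margins are fixed plausible compositions; the survey's gender margin
reproduces its published totals (13,135 M / 17,391 F of 30,526). Curves
are smooth circadian/prevalence templates that differ across cells, so
aggregation, correlation and direction all have signal to work with.

Rate bias is injected on *sampling odds*, not probabilities: multiplying
a subgroup's odds by ω and renormalizing makes ω exactly the disparity
ratio the metric estimates, so parameter recovery is a sharp test
(ω = 0.8 at 50,000 rows per arm is recovered within ±0.02; ω = 0
produces the `missing` category). Temporal bias flips the direction of
each synthetic increment independently with probability φ for rows of a
target subgroup: at φ = 0.5 the subgroup's aggregated series loses all
directional information, driving its directional symmetry to chance
(≈ 50%) while the untouched complement stays high. A single global seed
drives all draws, so fixtures are byte-identical across runs.

What passing these tests shows: the metrics, tests and categories
recover known, parametrically injected bias from data with the right
shapes and sizes. What they do not show: performance on real generator
output, where bias is not product-form, attributes are correlated with
the temporal signal, and missingness is structured. The simulators
emulate dataset *shapes*, not generator *pathologies* beyond the two we
inject.

## Numerical and testing choices

* Thresholds are kept in exact form (`-log(0.9)`, `-log(0.8)`), never
  rounded constants.
* An optional Haldane–Anscombe correction (+0.5 per cell) is available
  for sparse tables, off by default — the plain estimator is the metric's
  definition; the correction is an analyst's tool.
* The recovery invariant across the multiplier grid
  ω ∈ {0.5, 0.8, 1, 1.25, 2} is checked on the log scale against 3× the
  analytic standard error of the log odds ratio at n = 200,000 per arm
  (≈ 0.02), the statistically meaningful band at that size.
* Null calibration draws both arms from one multinomial — 10,000
  replicates of 2,000 rows per arm over the ICU-extract cells, 13
  univariate subgroups each — and checks the raw z rejection rate lies
  in 0.05 ± 0.01 and the replicate-mean false-discovery proportion of
  the BH procedure stays at or below 0.05 plus a Monte-Carlo margin.
  Under the global null, every rejection is false, which is what makes
  the FDP directly observable.
* Test problem sizes (hundreds of rows for fixtures, 50k–200k for
  recovery, 200 replicates for distortion) were chosen as the smallest
  sizes at which the sampling bands above are informative.
* With zero noise and zero flips, resemblance is exactly perfect only
  for full-order (single-cell) subgroups; marginal subgroups mix cells
  with arm-specific multinomial weights, so their aggregated curves
  differ slightly even without noise. The tests reflect this.

## Limitations

Protected attributes must be categorical with declared levels; continuous
covariates are binned by the caller before loading. Missing values in
protected or temporal columns are hard errors — the metrics assume
complete categorical membership. The real and synthetic tables are
treated as independent samples; no row alignment is used or assumed.
Alternative fairness definitions (equalized odds on downstream models,
demographic parity), additional resemblance metrics (DTW, MAPE), and
privacy/utility fairness are out of scope.
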