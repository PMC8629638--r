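---
title: "Methods: case-mix grouping and payment control for inpatient claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-mix grouping and payment control for inpatient claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casemixr)
```

`casemixr` implements the analysis a healthcare payer runs to build and
evaluate a DRG (diagnosis-related group) case-mix classification for
cerebrovascular hospitalizations (principal diagnosis ICD-10 I60–I69), and to
compare payment designs with and without length of stay (LOS) as a grouping
variable. This vignette is the package's account of its methods: the models,
the tunable parameters and why their defaults are what they are, the
interpretations made where the design was genuinely open, and what the test
suite does and does not establish.

## The synthetic claims generator

Real inpatient claims are confidential, so the package ships a seeded
generator (`simulate_claims()`) that emulates the structure of a one-year
cerebrovascular claims extract from a mid-sized city with secondary and
tertiary comprehensive hospitals. It defines the study conditions under which
every downstream stage is exercised.

Each categorical field is sampled independently from fixed cohort
proportions: 42.76% male; age bands <45 / 45–60 / ≥60 at 4.37% / 20.00% /
75.62%; 66.36% urban insurance; hospital levels B-secondary / A-secondary /
B-tertiary / A-tertiary at 16.70% / 37.04% / 20.20% / 26.06%; LOS bands
≤8 d / 9–13 d / ≥14 d at 50.18% / 20.94% / 28.88%; surgery yes / no / unknown
at 6.2% / 81.2% / 12.7%; discharge outcomes dominated by recovery (82.26%)
with 0.57% in-hospital deaths; five comorbidity/complication (CC) classes led
by arterial undersupply (45.94%); 20.41% grade-III hypertension. Vectors that
print to slightly less than 1 (rounding in the source proportions) are
renormalized exactly. Principal diagnoses are uniform over I60–I69 — a
neutral choice, since no code-level frequencies were available.

Cost follows a multiplicative log-normal model:

$$\mathrm{cost} = \exp\Big(\mu_0 + \textstyle\sum_j \log f_j + \varepsilon\Big),
\qquad \varepsilon \sim N(0, \sigma^2),$$

with baseline $\mu_0 = \log 700$ (log-USD) and $\sigma = 0.45$ by default.
A log-normal, rather than an additive model, keeps costs positive and
right-skewed — the shape on which median-and-IQR reporting and IQR outlier
fences are meaningful. The per-level factors $f_j$ carry the directions
established in cerebrovascular cost regressions — female below male (0.92),
longer stays up (1.55, 2.30), higher hospital levels up (1.18, 1.45, 2.05),
no surgery down (0.78), in-hospital death up (1.70), rural insurance down
(0.95), the infarction/ischemia CC classes below the arterial-undersupply
reference (0.85–0.95), older ages up (1.08, 1.16) — with magnitudes chosen
once for realistic cost ratios (top hospital tier ≈ 2× the bottom; 14+ day
stays ≈ 2.3× short stays). Hemorrhagic principal diagnoses (I61, I62, I64,
I68) carry a factor of 1.22; hemorrhagic strokes are costlier than ischemic
ones, and the factor gives the diagnosis block a real signal for the
without-LOS grouping to find. The directions, not the magnitudes, are the
calibration contract.

Ages in the youngest band are drawn on 16–44, so a raw extract contains a
small share of minors for the age filter to remove; 95% of records come from
comprehensive hospitals and 97% are hospitalized in the study city, giving
the other cleaning filters something to do. Day counts within an LOS band
are uniform integers on 1–8, 9–13, 14–60.

What the generator does **not** emulate: the joint dependence between fields
(real LOS correlates with age, severity and hospital level; here fields are
independent given the cost model), code-level diagnosis mix, readmissions,
and any real dollar totals. Passing tests therefore demonstrate that the
methods recover known structure of this form — not that they reproduce any
particular real cohort.

With $\sigma = 0$, cost is an exact deterministic function of the sampled
categories; the test suite uses this as an oracle for group-mean and weight
recovery.

## Cleaning

`clean_claims()` applies four filters in a fixed, declared order, counting
removals per filter so the reduction from raw to analytic cohort is
auditable: (1) comprehensive hospitals only; (2) cost outliers — log-cost
outside $[P_{25} - k\,\mathrm{IQR},\ P_{75} + k\,\mathrm{IQR}]$ computed on
the post-filter-1 records with type-7 (linearly interpolated) quantiles,
$k = 3$ by default; (3) age under 18 removed (18 retained); (4) out-of-city
hospitalizations removed. The fence is computed on the log scale because the
cleaning question is multiplicative ("is this bill implausibly many times the
typical bill?"), and $k = 3$ is deliberately loose: the cleaning fence should
only catch data errors, while the later *per-group* $P_{75} + 1.5\,
\mathrm{IQR}$ limit does the analytic work. A zero cost has log-cost
$-\infty$ and is always fenced out. The filter order is part of the contract
(the fence sees only comprehensive-hospital records) and is pinned by a test.

## Factor screening

`kruskal_h()` implements the Kruskal–Wallis statistic with midranks and the
standard tie-correction divisor, with p-values from $\chi^2_{k-1}$. When
every value is identical the tie correction degenerates; the convention
$H = 0$, $p = 1$ is applied. The implementation is written out (rank sums on
aggregates), and `stats::kruskal.test()` serves as an independent oracle in
the tests (agreement to $10^{-10}$ on random tied instances). The screen runs
each candidate variable at $\alpha = 0.05$ with no multiplicity correction
across variables — screening, not inference.

## Stepwise multiple-factor model

`stepwise_fit()` is identity-link least squares with blockwise selection:
whole categorical variables enter or leave together, judged by partial-*F*
p-values (enter the best block if $p < \alpha_{in} = 0.05$; drop the worst if
$p > \alpha_{out} = 0.10$). Identity-link OLS is used because the quantities
reported downstream — t-statistics, $R^2$, a condition index — are OLS
artifacts; the family is an extension point, not a default. A dropped or
perfectly collinear block is excluded from re-entry, which guarantees
termination and makes the collinearity guard loud (a warning) instead of a
crash. The condition index $\kappa$ is
$\sqrt{\lambda_{\max}/\lambda_{\min}}$ of the correlation-scaled
cross-product of the final design matrix without the intercept; values near 1
indicate negligible multicollinearity.

## CHAID on a continuous response

Classical CHAID is defined for categorical responses; hospitalization cost is
continuous. This is the package's largest interpretation, handled with two
modes in `chaid_control()`:

* `continuous_F` (default): pairwise merge tests are two-sample ANOVA
  *F*-tests and the omnibus split test is one-way ANOVA — the standard
  scale-response CHAID variant.
* `binned_chi2`: cost is discretized (default: quintiles of the node's
  costs, or fixed edges via `bins`) and Pearson chi-squared tests are used
  throughout, for a strictly chi-squared reading.

The merge step follows the classical mechanics: repeatedly merge the pair of
(compound) categories with the largest pairwise p-value while it exceeds
`alpha_merge`; ordinal ("monotone") predictors may merge only adjacent
categories. The omnibus p-value of the merged partition is multiplied by the
number of ways the original $c$ categories could have been reduced to $r$
groups — the Stirling number of the second kind $S(c, r)$ for nominal
predictors, $\binom{c-1}{r-1}$ for ordinal ones — and capped at 1. The node
splits on the predictor with the smallest adjusted p-value if it is below
`alpha_split` and every child meets `min_child`; adjusted-p ties break by the
declared predictor order, making trees deterministic.

One property worth stating precisely: with `alpha_merge = 0.05`, two
categories with *identical* distributions fail to merge in about 5% of
samples (their pairwise p-value is uniform under the null). That is inherent
to significance-based merging, not a defect; the shifted category in the
corresponding test is isolated in every replicate, while the exact
two-block partition appears at the ~95% null-merge rate.

Hyperparameters are not dictated by any published source, so the defaults
are conventional CHAID practice sized to cohorts of $10^4$–$10^5$ records:
`alpha_merge = alpha_split = 0.05`, `min_parent = 400`, `min_child = 200`,
`max_depth = 4`. All are configurable. Ordinal predictors are the LOS band,
age band and hospital level (B-secondary < A-secondary < B-tertiary <
A-tertiary); everything else is nominal. Records with `surgery == "unknown"`
are excluded from grouping runs — the field cannot support a split it might
be chosen for — and the pipeline logs the exclusion count.

All merge/split tests run on per-category aggregates (n, sum, sum of squares,
or bin counts), so tree growth costs $O(\text{categories}^2)$ per node
regardless of the number of records.

`extract_rules()` turns each leaf into a conjunction of merged-category
memberships along its path; the resulting rule set partitions the training
domain (every record matches exactly one rule).

## The shipped rule sets

Two reference rule sets ship as YAML fixtures (`builtin_ruleset()`): a
7-group set using LOS and an 8-group set without it. They are frozen,
declarative encodings of published-style grouping rules, so grouping and
payment analyses are reproducible without refitting a tree. Three encoding
decisions matter:

1. **Precedence.** As printed, the with-LOS rules overlap (a tertiary,
   short-stay, cerebral-infarction patient satisfies both a hospital×LOS rule
   and a CC/diagnosis rule). The engine is first-match-wins and the
   hospital×LOS rules (DRG 1–4) are listed before the tertiary CC/diagnosis
   rules (DRG 5–7), so the CC split applies to tertiary stays of 14+ days —
   the only reading under which the four LOS-banded rules and the CC rules
   form a tree. The order is explicit in the YAML and overridable.
2. **The residual CC class.** The printed rules never mention the residual
   "other" CC category. It is carried with the non-infarction CC classes
   (with-LOS DRG 5; without-LOS DRG 1/3/4), which makes both rule sets total:
   an exhaustive grid over hospital level × LOS × CC × ICD assigns zero
   records to the fallback, and a test pins this.
3. **One garbled rule.** The without-LOS set's printed fifth rule repeats the
   non-infarction CC list (overlapping its third rule) while every
   neighbouring rule follows a symmetric pattern — tertiary B/A ×
   cerebral-infarction CC × one of the two diagnosis blocks
   {I60, I63, I65, I66, I67, I69} and {I61, I62, I64, I68}. The fixture
   encodes the symmetric pattern and treats the printed CC list as a
   typographical slip.

Assignment with an incomplete rule set is total anyway — non-matching records
get the fallback label — but noisy: a warning lists the unmatched field
combinations.

## Case-mix metrics

For each group: the case-mix weight is the group mean cost over the overall
mean cost of all grouped records, so the n-weighted mean of the weights is
exactly 1 (a conservation test). CV uses the sample (n−1) standard
deviation; a CV below 1 flags the group as homogeneous, and a size-1 group's
CV is reported as 0 with `cv_defined = FALSE`. The cost limit is
$P_{75} + 1.5\,\mathrm{IQR}$ of within-group cost with type-7 quantiles — the
convention is pinned because interpolation schemes move small-sample limits
by more than reporting precision, even though at cohort scale the difference
is under 1%. Excess statistics count records strictly above the limit and sum
their above-limit spend. Outlier profiles (mean age and LOS of outliers
versus non-outliers) support the standard diagnostic of *who* the outliers
are.

## Payment-control simulation

The fee-for-service baseline pays billed charges. Under the simulated DRG
design each group's mean cost is recorded as the payment standard, spending
above the group cost limit is treated as oversupply, and a control intensity
$c$ recovers the fraction $c$ of every record's above-limit spend. This
linear-recovery model — rather than probabilistically capping bills at the
limit — is the only one that makes the sweep columns exactly linear in $c$:
$\mathrm{society}(c) = T - cE$, $\Delta\mathrm{hospital}(c) = -cE$ with $E$
the total excess. Linearity, conservation
($\mathrm{society}(c) + cE = T$) and monotonicity are contract invariants
with tests; a sweep with $E = 0$ is flagged rather than silently flat.
`payer_split()` separates insurer and patient totals with per-record
validation ($0 \le \text{insurer paid} \le \text{cost}$).

## Numerical conventions and degenerate inputs

Quantiles are type 7 everywhere. Ranks use midranks; the Kruskal–Wallis tie
correction denominator of 0 (all values identical) yields $H = 0$, $p = 1$.
Two-sample *F*-tests with zero within-group variance return $p = 0$ when
means differ and $p = 1$ otherwise. Empty inputs: cleaning an empty table
returns an empty table with a zeroed report; `simulate_claims(0, ...)`
returns a correctly typed empty tibble; empty groups are errors in
`kruskal_h()` and `compute_cost_limit()`. All randomness flows through
explicit seeds with pinned RNG kinds, and seeded functions restore the
caller's RNG state.

## Problem sizes used by the tests

The suite exercises parameter recovery at the sizes where the relevant
asymptotics hold without waste: factor-screen type-I error over 200 null
replicates of $10^4$ records; stepwise sign recovery and weight recovery
(delta-method ±3 SE) at $2 \times 10^4$ records; tree split-variable
stability over 10 seeded replicates at $2 \times 10^4$ records with a strong
two-variable structure; merge/partition behaviour at 300–500 records per
category over 50–100 replicates. Worked-example cells from published
case-mix tables (weights, outlier percentages, payer totals) are recomputed
from their printed inputs exactly.

## Known limitations

* Independence between generated fields understates real confounding; the
  stepwise model and the tree face an easier selection problem here than on
  real claims.
* The continuous-response CHAID modes can disagree with each other (and with
  categorical-response implementations) on weak signals; conclusions should
  be checked under both `response_mode`s.
* Significance-based merging keeps distinct-but-similar categories apart in
  a null-rate fraction of samples, as quantified above.
* The rule engine evaluates conjunctions of set/range conditions only — no
  MDC hierarchy, severity subclasses, or surgical partitions.
* Dollar outputs are synthetic unless real claims are supplied via
  `read_claims()`; no currency conversion is attempted.
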