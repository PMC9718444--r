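---
title: "Estimating reciprocity-corrected contact matrices from diary surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating reciprocity-corrected contact matrices from diary surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactsurvey)
```

## The estimation problem

A single-day contact-diary survey asks each participant to list the people
they had conversational or physical contact with on one day, together with
each contact's (approximate) age. From such diaries we want the
age-structured contact matrix: the `G x G` array whose entry `c_ij` is the
mean number of persons in age group `j` that a participant in age group `i`
contacts per day. These matrices are the mixing input of age-structured
transmission models, so getting their structure right matters more than any
single cell.

The package estimates `c_ij` as a survey-weighted per-group mean,

    c_ij = sum_p w_p y_pj / sum_p w_p   over group-i participants p,

where `y_pj` counts participant `p`'s reported contacts with group-`j`
persons and `w_p` is the survey weight (1 by default). Age groups default
to fifteen 5-year bins (0-4, ..., 65-69, 70+) with the half-open convention
`[lo, hi)`; contacts reported as an age range resolve to the bin containing
the integer midpoint `floor((lo + hi)/2)`. Both conventions are
configurable, and both are conventions — diary studies rarely publish them,
so we fix deterministic defaults and document them rather than guess
differently per dataset.

## Reciprocity correction

At the population level contacts are symmetric: the total number of
contacts group `i` has with group `j` must equal the total group `j` has
with `i`, i.e. `c_ij N_i = c_ji N_j` where `N_i` are population sizes from
an age pyramid. Raw survey estimates violate this because reporting rates
differ by age. `symmetrize_reciprocity()` projects the raw matrix onto the
reciprocal subspace by averaging the two population-level totals:

    d_ij = (c_ij N_i + c_ji N_j) / (2 N_i).

This is the standard population-weighted symmetrization. It has three
properties the tests enforce rather than assume: the residual
`|d_ij N_i - d_ji N_j|` vanishes to machine precision; the total number of
population contacts `sum_ij c_ij N_i` is conserved; and the map is
idempotent. Groups with no observed participants are a hard error, not an
imputed zero — a silent zero row would bias every reciprocal cell downward.

Four stratum matrices are estimated from one survey: weekday diaries (W),
weekend diaries (H), and the two enrolment periods of a two-wave
cross-sectional design around a mass event ("during" O, "after" A). A
calendar-average matrix is the convex combination `5/7 W + 2/7 H`; the 5/7
weighting is our convention for pooling, since the strata are usually
reported separately. Diaries covering `T` days convert to daily rates by
`phi_ij = c_ij / T`; a one-day diary has `T = 1`, the default.

Uncertainty comes from a percentile bootstrap that resamples participants
(with their complete contact lists) within the stratum and recomputes the
symmetrized matrix per replicate; `B = 1000` by default. The percentile
method was chosen over BCa for seed-stable reproducibility and because the
target quantities are means of moderate samples where the two methods
hardly differ.

Two scalar summaries compare stratum matrices: the population share of
within-group contacts `sum_i d_ii N_i / sum_ij d_ij N_i` (diagonal
dominance, an assortativity measure) and the ratio of dominant eigenvalues
`rho(a)/rho(b)`, a proxy for relative transmission potential since the
next-generation matrix scales linearly with the contact matrix.

## The synthetic-data generator

No raw diary survey of this design is publicly deposited, so the package
validates every estimator against a generator with known ground truth. The
truth matrix starts from `m0[i,j] ∝ N_j (1 + boost · 1[i=j])`
(population-proportionate mixing with a diagonal assortativity boost), is
rescaled so a pyramid-weighted random participant expects `base_rate`
contacts per day, and is then symmetrized exactly as above, so the truth
satisfies reciprocity by construction.

Each synthetic participant receives a pyramid-proportional age (uniform
within bin, with the open-ended 70+ bin sampled on [70, 90]), a period
assigned by the design quotas, and a weekday indicator with probability
0.659. The daily contact count is negative-binomial with mean equal to the
participant's truth row sum (optionally scaled by weekend and mass-event
multipliers) and dispersion `k` (variance `mu + mu^2/k`); contact age
groups are then allocated multinomially along the truth row.

The default configuration mirrors the study design it emulates: 1953
participants "during", 1384 "after", 65.9% weekday diaries, and an
approximate 2015 Japanese census pyramid in 5-year bins. The count
distribution is calibrated to the reported marginal moments, mean 8.92 and
SD 25.45. Because the marginal variance decomposes as
`E[mu] + E[mu^2]/k + Var(mu)` across age groups, the dispersion solving
those moments under the default truth is `k = 0.1255`, frozen as a named
constant. Two consequences are worth stating plainly:

* A single negative-binomial family cannot match the reported mean, SD
  *and* median simultaneously: at `k = 0.1255` the simulated median is 0,
  not the reported 3. We prioritized the mean/SD pair because the
  estimators under test are means; the median is a realism gap of the
  generator, not of the estimators.
* The stratum multipliers default to 1 — the generated truth carries no
  weekend or mass-event effect, matching the study's finding that neither
  factor changed contact counts substantially. Recovery tests on the
  default generator therefore check that the four stratum estimates agree
  with one shared truth.

The generator also simplifies group contacts: a shared dinner produces
correlated contact ages in real diaries, but contact ages here are
allocated independently (multinomially). Passing recovery tests therefore
show estimator correctness under independent allocation, not robustness to
clustered reporting. No household structure, panel attrition or epidemic
process is simulated.

## Count summaries, regression, power

`describe_counts()` uses linear interpolation of order statistics
(`quantile` type 7) and the `n - 1` standard deviation, so printed medians
and IQRs are reproducible across software. Percentage cells in descriptive
tables round half-up to one decimal (`table_percentage()`), matching how
such tables are conventionally printed; banker's rounding would flip some
cells.

`fit_nb_glm()` fits the log-link negative-binomial regression by
iteratively reweighted least squares at fixed `k`, alternating with a
dispersion update: a method-of-moments start refined by univariate
likelihood maximization in `log k`, capped at `1e8` where the model is
numerically Poisson. Standard errors are Wald, from the final weighted
information matrix. The suite checks the fitter three independent ways:
against `glm(family = poisson)` in the `k -> inf` limit, against
`MASS::glm.nb` on overdispersed draws, and by empirical Wald coverage
(93-97% at nominal 95% over 500 simulated datasets of n = 2000).

Sample-size planning for two-group comparisons uses the exact noncentral-t
power of the two-sample t test: with `n` per group the statistic under the
alternative is noncentral t with `2n - 2` degrees of freedom and
noncentrality `d sqrt(n/2)`. The two-sided formulation includes both
rejection tails; a normal approximation would undercount the required `n`
by one at small effect sizes (526 instead of 527 at `d = 0.2`, power 0.9,
alpha 0.05), which is why the noncentral-t route is the default and the
only one implemented. `sample_size_two_sample_t()` inverts the power
function by integer bisection, so the returned `n` satisfies the bracketing
identity `power(n) >= target > power(n - 1)` exactly.

```{r}
sample_size_two_sample_t(power_spec(0.2, power = 0.9))
sample_size_two_sample_t(power_spec(0.8, power = 0.9))
```

## Numerical and design choices

* **Error taxonomy.** All failures are classed conditions
  (`cs_schema_error`, `cs_integrity_error`, `cs_domain_error`,
  `cs_empty_stratum_error`, `cs_numeric_error`, `cs_config_error`), so the
  pipeline can distinguish configuration, data and numeric failures and
  callers can test for them precisely.
* **Fail-fast validation.** Referential integrity (every contact row names
  an existing participant) is enforced when a `survey_table` is built;
  contact rows with missing ages are rejected with a counted warning
  rather than imputed.
* **Determinism.** Every stochastic routine (generator, bootstrap,
  pipeline) takes an explicit seed and restores the caller's RNG state;
  identical configuration gives byte-identical CSV output, which the tests
  assert by double-write comparison.
* **Problem sizes.** Validation experiments run at sizes where Monte-Carlo
  noise is small relative to the tolerances checked: parameter recovery
  compares n = 2000 against n = 40000 over 20 seeds; bootstrap coverage
  uses 200 surveys of n = 3000 with B = 400 replicates; Wald coverage uses
  500 fits of n = 2000; the generator calibration check uses n = 50000.
* **Empty strata.** A stratum filter selecting no participants, or a group
  with no participants inside a stratum, raises an error naming the
  stratum or groups. Downweighting or zero-filling would silently bias the
  reciprocity correction.

## Limitations

The reciprocity weights come from the pyramid, not from survey weights, so
post-stratified designs where the two disagree need externally harmonized
inputs. The weighted-average symmetrization assumes the pyramid describes
the same population the survey sampled. Bootstrap intervals are cellwise,
not simultaneous. The generator's independence simplifications mean that
real-diary features — group contacts, proxy reporting for children, digit
preference in reported ages — are outside what the validation suite can
certify.
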