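---
title: "Gender-stratified healthy-ageing analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gender-stratified healthy-ageing analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agewell)
```

## What the package computes

`agewell` implements the quantitative core of a gender-stratified
quality-of-life analysis of older adults. The question such analyses ask is
whether women's longer life expectancy is a gain in healthy years or mostly
added years lived with disability and chronic disease (the "failures of
success" hypothesis). The stages are:

1. **Abridged life tables** from age-grouped population and death counts.
2. **Sullivan health expectancies**: the prevalence-weighted partition of
   life-table person-years into years free of (and with) disability or
   morbidity.
3. **Psychometric scale scoring**: GDS-15 depression, the 6-item
   De Jong Gierveld loneliness scale, and the WHOQOL-BREF, with Cronbach
   alpha for internal consistency.
4. **Active Ageing Indices** on the EU scale (a doubly weighted indicator
   composite) and the WHO scale (HDI-normalised dimension sums).
5. **Comparison statistics** between the sexes: Welch or pooled t from
   summary statistics, a z test for life-expectancy differences, Pearson
   chi-square, and the prevalence sample-size formula.

Because the census and household-survey microdata that feed real analyses
of this kind are restricted, the package ships a **synthetic-cohort
generator** that reproduces their statistical structure; every stage is
tested end to end against it.

## The life table

From age-specific deaths and exposures the central death rate is
$m_x = D_x / N_x$ per person-year. The probability of dying inside an
interval of length $n$ is

$$q_x = \frac{n\,m_x}{1 + (n - a_x)\,m_x},$$

with separation factor $a_x$ — the mean time lived in the interval by those
who die in it — set to 0.3 at age 0, 0.7 at age 1 and 0.5 at all other
ages. Survivorship follows $l_{x+n} = l_x(1 - q_x)$ from a radix of
100,000, person-years are $L_x = n\,l_{x+n} + a_x d_x$, the open-ended
terminal group is closed with $L = l/m$, and $e_x = T_x / l_x$.

**The separation-factor units question.** With $a_x = 0.5$ and $n = 5$ the
formula above places deaths on average half a *year* into a five-year
interval. Standard abridged tables instead use half the *interval*
($a_x n = 2.5$ years). Both readings are implemented:
`ax_convention = "literal"` (the default) applies the formula exactly as
written with $a$ in years; `"fraction"` treats $a$ as a fraction of the
interval, recovering the standard mid-interval convention at $a = 0.5$.
The convention is recorded in the returned table, and single-year tables
are identical under the two modes.

Other closure choices, made once and documented here: the radix is the
conventional 100,000; $q$ is clamped to $[0,1]$ with a warning when an
extreme rate pushes the formula past 1; a terminal rate of zero is an
error rather than a silent infinite expectancy.

**Variance.** No closed-form variance accompanies a published life-table
comparison, so the package uses the Chiang convention: binomial variance
$\mathrm{var}(q_x) = q_x^2(1-q_x)/D_x$ per interval, propagated by the
delta method,
$\mathrm{var}(e_x) = \sum_{i \ge x} l_i^2\,[(n_i - a_i) + e_{i+1}]^2\,
\mathrm{var}(q_i) / l_x^2$. Intervals with zero observed deaths contribute
zero variance, and the terminal group's $q$ is fixed at 1. The test suite
checks the propagation against numeric differentiation of the recursion.

## Sullivan health expectancies

With $D_x$ the proportion of an age group free of the condition,

$$\mathrm{freeLE}_x = \frac{\sum_{i \ge x} L_i D_i}{l_x}.$$

The derived report rows are `years_with_condition = LE − freeLE` and
`proportion_free = 100·freeLE/LE`; both identities hold to machine
precision in the returned objects, and report rounding (half-up to one
decimal) is applied only at presentation. Disability follows the
Washington-Group rule — any of the six functional limitations (vision,
hearing, walking/climbing, remembering, self-care, communicating) counts
as disabled — and morbidity categories nest: any count ≥ 1 is morbidity,
≥ 2 comorbidity, > 2 multimorbidity. Prevalence in the open-ended age
group is taken as observed in that group. Reference ages are always
explicit; both 60 and 65 are in common use for "older age" and both are
supported. The method is prevalence-based by design; incidence-based
(multistate) health expectancy is out of scope.

## Scale scoring

**GDS-15**: yes/no items, five reverse-keyed (satisfaction with life, good
state of mind, joyful, beautiful to be alive, full of energy). Totals
above 5 are *suggestive* and 10 or more *indicative* of depression.
**Loneliness (6-item)**: the three negatively worded items score on "yes"
(emotional subscale), the three positively worded on "no" (social
subscale). The published presentation treats the items as binary, and the
package follows it, although the original instrument has a three-category
format. **WHOQOL-BREF**: 26 items, four domains (physical 7,
psychological 6, social 3, environmental 8); the instrument's three
negatively phrased items (pain, dependence on medication, negative
feelings) are recoded $6 - r$; domain scores are reported raw, on the
4–20 scale ($4\times$ item mean), or 0–100. A domain with more than 20%
of its items missing is invalid; fewer missing items are mean-substituted.
The same 20% rule, applied as proration, governs the two binary scales —
the source presentation is silent there, and mirroring the WHOQOL
convention keeps one policy throughout.

Cronbach's alpha is computed complete-case with Feldt's F-based 95%
interval. Published domain-profile figures for the WHOQOL in this
literature are not always consistent with any single scoring mode (e.g. a
three-item domain shown near the ceiling of a scale it cannot reach), so
figure-level values are treated as format illustrations, never as scoring
targets.

## Active Ageing Indices

**EU scale.** Twenty-two indicators, each on 0–100, in four domains
weighted 35 (employment), 35 (participation in society), 10 (independent,
healthy and secure living) and 20 (capacity and enabling environment);
indicator weights sum to 100 within each domain. The bundled YAML
configuration is validated against these "Total 100" constraints at load.
Two capacity indicators are computed rather than surveyed:
$\min(100, 100\,e_{55}/50)$ (remaining life expectancy of 50 years at age
55, per the UNECE definition) and $100\,\mathrm{DFLE}_{55}/e_{55}$ (share
of healthy life expectancy at 55); both can also be supplied as numbers.

**WHO scale.** Fifteen binary indicators — health (3 wellness + 3
physical activity), community participation (3), security (3 financial +
3 physical). The actual score of a dimension is its sum of positive
responses, normalised HDI-style against goalposts 0 and the indicator
count. The overall index is the *unweighted mean* of the three dimension
indices: the source material computes dimension indices and an overall
value without stating the aggregation, and equal weighting is the neutral
choice. Levels follow the UNDP thresholds — low below 0.5, medium from
0.5 to just under 0.8, high from 0.8 — applied to the raw, unrounded
value (so 0.795 is medium).

## Inference

The t test defaults to Welch with Satterthwaite degrees of freedom
(pooled available by flag): where a source names only "the t-test", the
unequal-variance form is the safer default. Life-expectancy differences
use $z = (e_A - e_B)/\sqrt{\mathrm{var}_A + \mathrm{var}_B}$ with the
Chiang variances above. Chi-square is the uncorrected Pearson statistic
(`stats::chisq.test`, `correct = FALSE`), with a note when an expected
cell drops below 5.

The prevalence sample-size formula $n = Z^2 p(1-p)/e^2 \times DEff$ needs
a non-response adjustment; multiplying by a *rate* as sometimes printed
would shrink the sample, clearly a typo. Both standard conventions are
offered: multiply by $(1+NR)$ or divide by $(1-NR)$. With
$Z=1.96,\ p=0.084,\ e=0.05,\ DEff=2,\ NR=0.02$ either convention gives
242 — a published figure of 260 for this design is not recoverable from
the formula with its stated inputs, and the package makes no attempt to
force it.

## The synthetic cohort generator

The generator defines the study conditions under which the package is
tested; its defaults were chosen once, for realism, and are not tuning
knobs.

- **Mortality**: Gompertz force of mortality $\alpha e^{\beta x}$,
  evaluated at interval midpoints (open group: start + 5 years). Defaults
  ($\alpha$ = 1.9e-4 men / 1.2e-4 women, $\beta$ = 0.085/year) put the
  modal age at death near 72 and 77, a plausible schedule for a
  lower-middle-income country with a three-to-five-year female advantage.
- **Disability and morbidity**: any-condition prevalence is logistic in
  age with an additive female logit shift. Defaults give roughly 55%/71%
  any-disability and 63%/66% any-morbidity (men/women) at age 70,
  matching the prevalence ranges typical of surveys of adults 60+ in this
  setting. The six Washington-Group flags are independent Bernoullis
  given the person's age/sex risk with per-flag probability
  $1-(1-p_{any})^{1/6}$, so the any-of-six union matches the logistic
  target exactly; no additional latent correlation is imposed beyond the
  shared risk index. Morbidity counts are Poisson with rate
  $-\log(1-p_{any})$ (capped at 10), which makes the count model and the
  prevalence schedule mutually consistent by construction.
- **Status fields**: Bernoulli at per-sex marginals; the defaults (68.5%
  of women and 8.9% of men living alone, 57.8%/3.0% employed, 59.8%/4.7%
  earning, 60.7%/52.9% ADL-able, 61.4%/38.6% healthcare use) reproduce
  the headline marginals reported for older Bangladeshi adults.
- **Items**: one-factor latent-trait models. For the binary instruments
  the common discrimination is calibrated by deterministic quadrature so
  the model-implied alpha equals the instrument target (0.89 GDS-15,
  0.83 loneliness); difficulties are spread over $[-1, 1]$. WHOQOL items
  discretise a congeneric normal response (default loading 0.60 — no
  published alpha exists for it in this context, so a typical value was
  fixed once) at the 10/35/65/90 percent quantiles.
- **Ages** are drawn from the cohort range (default 60–100) with weights
  declining at 0.07/year, the usual older-adult pyramid shape.
- **Determinism**: everything derives from the profile seed through fixed
  per-field offsets; the same profile always yields bit-identical output.

What the generator does **not** emulate: cluster/stratum survey designs
and weights, spatial correlation between regions, cause-specific
mortality, and the fact that real analyses pool prevalences from several
surveys with different denominators (the synthetic cohort is one coherent
population). Passing tests therefore demonstrate correctness of the
estimators under clean sampling, not robustness to complex-survey
artefacts.

## The pipeline and default mappings

`run_pipeline()` chains the stages per sex: life tables on the abridged
grid 0, 1, 5, …, 95+; model-based prevalence schedules; Sullivan results
at ages 0, 60 and 65; cohort status indicators with binomial CIs; scale
summaries and alphas; both indices; and the three headline tests (z for
life expectancy at birth, Welch t for GDS means, chi-square for living
alone by sex). Where the EU indicator set asks for fields the cohort does
not carry, the pipeline fills survey-style indicators from cohort
marginals (all four employment-rate indicators from the employed flag, 50
for fields with no cohort counterpart) and computes the two capacity
indicators from the life table — a demonstration mapping, overridable via
`eu_indicators`. The WHO-scale positives are likewise a documented
demonstration mapping from cohort fields (`who_positives` in the source),
since the cohort schema does not contain the instrument's 15 items.

Report bundles are written as JSON plus per-sex life-table CSVs and a run
log (seed, convention, versions); every rounded presentation value is
re-derivable from the unrounded values stored in the bundle.

## Verification strategy and problem sizes

The test suite works at three levels. *Hand oracles*: the m→q conversion,
the survivorship recursion, domain transforms, weighted means and the
test statistics are checked against values computed by hand or by
closed form (e.g. Spearman–Brown for two items at correlation 0.5).
*Brute force*: all 64 loneliness response patterns and 1000 random GDS
patterns are scored independently from a literal keying table. *Microsimulation*:
one million piecewise-constant-hazard lifetimes, with per-interval state
draws, reproduce single-year-table $e(0)$ and the Sullivan
disability-free expectancy within 0.1 year. Marginal-recovery checks use
cohorts of 10,000 per sex with a three-standard-error band; alpha
recovery uses n = 5000 (estimate within ±0.02 of target); test-size
calibration uses 1000 null replicates with acceptance band [0.03, 0.07]
at nominal 0.05. These sizes keep the full suite under half a minute on
one core while leaving Monte-Carlo error well inside each band.

## Known limitations

- Prevalence-based (not incidence-based) health expectancy only.
- No survey-design variance estimation; CIs are simple binomial.
- The literal separation-factor convention, kept as the default for
  fidelity to the source formula, is demographically unusual for 5-year
  groups; use `"fraction"` for standard abridged tables.
- Gompertz mortality has no infant/childhood component, so synthetic
  life expectancy at birth is not calibrated to any national value; the
  generator's purpose is structural realism at older ages.
- Report rounding is half-up and defined for non-negative quantities.
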