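---
title: "Rasch measurement analysis with raschkit: models, tests and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rasch measurement analysis with raschkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raschkit)
```

## The model

raschkit fits the polytomous Rasch model in its partial credit (PCM) and
rating scale (RSM) parameterisations. For an item with ordered categories
$0..m_i$ and thresholds $\tau_{i1} \dots \tau_{im_i}$, the probability that a
person at ability $\theta$ responds in category $k$ is

$$P(X_{ni}=k) \propto \exp\Big(k\theta_n - \sum_{j \le k}\tau_{ij}\Big),$$

with category 0 as the reference and the normalising sum over all
categories. Each threshold is the latent location where two adjacent
categories are equally probable; the item location $\delta_i$ is the mean
of its thresholds. The dichotomous model is the one-threshold special
case (the familiar log-odds form $\theta - \delta$), and the RSM is the
constraint that all items share one threshold-spacing pattern.
Probabilities are evaluated in log space (log-sum-exp), so extreme
abilities or thresholds cannot overflow.

The point of the exercise is not to find the model that best describes
the data, but to test whether the data satisfy the *requirements* of the
model — homogeneity, local independence, unidimensionality, monotonicity,
group invariance, adequate reliability and targeting — because only data
meeting those requirements support transforming ordinal raw scores into
interval-level measures.

## Estimation

**Items.** Thresholds are estimated by conditional maximum likelihood
(CML): the likelihood of each response pattern given the person's raw
score, which is a sufficient statistic for the person parameter, so the
person parameters vanish and no assumption about the trait distribution
is needed. The conditional normalising constants (polytomous analogues of
elementary symmetric functions) are built by dynamic programming over
items, in log space, with persons grouped by missing-data pattern. A
quadratic penalty pins the otherwise-flat direction of the likelihood and
the solution is re-centred exactly so the mean item location is 0 (unless
an anchor fixes the metric). Standard errors come from the observed
information (numerically differentiated analytic gradient). We chose full
CML over the pairwise-conditioning shortcut because the two estimators
differ at finite samples (we measured differences around 0.1 logits on
30-person datasets) and only full CML matches the brute-force conditional
likelihood that serves as this package's estimation oracle.

**Persons.** Abilities use Warm's weighted likelihood (WLE): the score
equation $r - \sum_i E_i(\theta) + I'(\theta)/2I(\theta) = 0$, which
reduces the first-order bias of ML and keeps estimates finite at extreme
(zero/maximum) raw scores; those persons are flagged `extreme` and
excluded from residual-based statistics. The SE is $1/\sqrt{I(\hat\theta)}$.
On complete data, equal raw scores give identical estimates — the
sufficiency property that makes a raw-score-to-measure transformation
table possible at all.

**RSM vs PCM.** `rsm_vs_pcm()` compares the two parameterisations with a
likelihood-ratio test on the *conditional* likelihoods,
$-2(\log L_{RSM} - \log L_{PCM})$ on $(I-1)(m-1)$ df, so the choice is
also free of the trait distribution.

## Fit statistics and their calibration

Residuals are standardized cellwise: $z_{ni} = (x_{ni} - E_{ni})/\sqrt{W_{ni}}$,
with $E$ and $W$ the model mean and variance at the person's estimated
ability. One numerical subtlety matters: residuals evaluated at the
*estimated* ability have variance below $W$ — roughly
$W_{ni}(1 - W_{ni}/I_n)$, where $I_n$ is the person's test information —
because the estimate absorbs part of each response. INFIT and OUTFIT mean
squares, the class-interval chi-square and the person fit statistic
therefore use this estimation-adjusted variance; without it, mean INFIT
sits near $1 - 1/I$ (0.91 for an 11-item scale) instead of 1.0. The
residual matrix itself keeps the conventional $z$ definition.

Per item we report OUTFIT (unweighted mean square), INFIT (information
weighted), a cube-root (Wilson–Hilferty) standardized fit residual, the
class-interval chi-square (df = G − 1) and a one-way ANOVA of residuals
across class intervals, with Bonferroni-adjusted flags. Class intervals
default to `G = min(10, max(2, floor(n/50)))` equal-count groups on the
ability estimate — giving the df = 2 convention seen in published tables
at n ≈ 188. Person fit applies the same standardization per person with
the conventional ±2.5 bound.

`smith_interval(n)` implements the sample-size-corrected 5% critical
interval for INFIT, $1 \pm 2/\sqrt{n}$: the fixed 0.7–1.3 convention
corresponds to n = 45, and n = 200 gives 0.86–1.14. A caveat our own
simulations make concrete: for five-category items the sampling SD of
INFIT is larger than the $1/\sqrt{n}$ this formula presumes (we measure
0.055–0.07 at n = 500 across threshold layouts, against 0.045 presumed),
so even the corrected interval over-flags conforming polytomous data
(about 9–12% instead of 5%). The interval is reported as the field uses
it; the calibration experiment in `scripts/acceptance.R` quantifies the
discrepancy rather than hiding it. Conditional (estimation-bias-free)
item-level fit statistics would remove the remaining distortion but are
deliberately out of scope.

## Local dependency, testlets, dimensionality

Local item dependency (LID) is flagged from pairwise correlations of
standardized residuals: a pair is dependent when its correlation exceeds
the *average* off-diagonal correlation by 0.2 — the average is the
reference because with few items it is systematically negative (around
−0.1 for 11 items, −0.2 for 5 testlets in our fixture), so small positive
values already signal dependency. `make_testlets()` absorbs dependency by
summing grouped items into larger polytomous super items; totals are
conserved exactly on complete data, and threshold ordering of testlets is
reported as "not interpretable" because a testlet score mixes member
response combinations.

The unidimensionality check contrasts the two item subsets that load
oppositely on the first principal component of the residual correlation
matrix: each person is estimated from both subsets on the common anchored
metric and tested with $t = (\hat\theta_A - \hat\theta_B)/\sqrt{SE_A^2+SE_B^2}$;
the scale passes when at most 5% of persons differ (or the Clopper–Pearson
lower bound of that percentage does).

The explained common variance (ECV) summarises a bi-factor-style
decomposition: below 0.7 suggests a multidimensional model, above 0.9 an
essentially unidimensional one. Commercial software does not publish its
algorithm, so raschkit computes its own estimator, labelled an
approximation in reports: persons are estimated per testlet from the
member items on the common calibration; the common variance is the
average between-testlet covariance of those estimates (errors of disjoint
testlets are independent, so the covariance is unattenuated), and each
testlet's specific variance is its error-corrected variance in excess of
the common part. We first tried the more obvious
"variance of (testlet estimate − general estimate)" decomposition and
rejected it: under strong violations the general-solution calibration
distorts, its model-based SEs stop being trustworthy, and that estimator
saturates at 1 exactly when it should detect multidimensionality. The
covariance form has the right limits (duplicated testlets → 1;
uncorrelated aligned dimensions → near 0; unidimensional data → near 1).

## DIF

Group invariance is screened by a two-way ANOVA of standardized residuals
on group and class interval (`z ~ interval + group + interval:group`):
the group main effect is uniform DIF, the interaction non-uniform DIF,
Bonferroni-adjusted over items × factors. A flagged item can be split
into group-specific columns (structural missing elsewhere), and the
substantive-DIF test compares person estimates from split and unsplit
solutions anchored through DIF-free items, with a paired t-test and an
effect size = |mean difference| / SD of unsplit estimates. The decision
rule: not significant → no action; significant with effect ≥ 0.1 →
substantive, use the split; significant below 0.1 → retain the unsplit
solution, with 0.015 reported as the bound above which bias is
non-negligible. Two empirical notes. First, because the unsplit item
calibration sits at the information-weighted average of the group
calibrations, the paired differences largely cancel at the mean: even
1.5–2.5-logit injected DIF yields effect sizes around 0.03–0.05 — the
same order as published worked examples (0.050 on real stroke data,
verdict non-substantive) — so the ≥ 0.1 branch fires only for gross
distortions. Second, factors declared causal (e.g. side of stroke,
aphasia) are reported but never auto-resolved, since DIF there carries
the construct's intended information.

## Reliability, targeting, transformation, equating

The person separation index is reliability on the logit metric,
$(\mathrm{Var}(\hat\theta) - \overline{SE^2})/\mathrm{Var}(\hat\theta)$
over non-extreme persons; Cronbach's alpha comes from raw scores on
complete cases. The two agree for roughly normal samples and PSI drops
below alpha under skew or off-targeting; separation and the strata count
$(4s+1)/3$ translate reliability into the number of distinguishable
ability levels, with 0.9 the individual-use bound. Targeting summarises
the person-item offset (warning beyond ±1 logit) and produces Wright-map
bin data (0.25-logit bins by default).

`transformation_table()` maps each total raw score to its WLE (finite at
the extremes — we use the weighted-likelihood value there rather than an
extrapolation constant, because it exists and preserves monotonicity) and
linearly rescales so the endpoints hit the target range exactly, 0–100 by
default. `equate_tests()` places several scales on one metric by fitting
their total scores as polytomous items; it refuses to equate when a
scale-item's thresholds are disordered, and cross-walks scores through
the per-scale transformation tables.

## The protocol

`run_protocol()` automates the reporting sequence: baseline fit (with the
LR-test model choice), person-fit review, a threshold-ordering report
(action deferred until dependency and dimensionality are settled), LID
rounds, the dimensionality tests, DIF screening with the
split/substantive/retain decision, then reliability and the
transformation table. The LID rounds use a two-tier policy derived from
how published analyses proceed: pairs with strong absolute correlation
(≥ 0.2) merge one at a time (a priori domain testlets are applied first
when a domain map is supplied); when only diffuse positive flags remain,
the connected components of the flag graph are taken as a component
structure and merged together; a round limit (5) guards against endless
merging, and a merge that would collapse the scale below two columns is
refused with the flags left on record. Every automated decision is logged
with the rule and values that triggered it, and the JSON report contains
every number the human-readable summary shows.

## The synthetic-data generator

`sim_design()`/`simulate_responses()` generate truth-tagged polytomous
data: abilities are (multivariate) normal with a chosen mean/SD and
between-dimension correlation; responses come from the PCM at the
person's ability on the item's dimension; uniform DIF adds a group
location shift, non-uniform DIF multiplies the group's ability; LID
copies the source item's response into the dependent item with
probability d (the simplest mechanism giving a tunable positive residual
correlation); missingness is MCAR. Fixed seeds give bit-identical output.

`whodas_like_data()` emulates the structure of a WHODAS-12 stroke
inpatient sample: n = 188, the 11 analysable five-category items (the
work item is omitted, as structural missingness leaves too few employed
respondents), six ICF domains with within-domain dependency (d = 0.3–0.45),
an extra link between household responsibilities and self-care, two
latent components (physical activities vs cognitive/social) correlated
0.65, trait SD 1.4 centred on the scale (well targeted), a mild
(0.35-logit) education effect on the cognitive/social items, and
covariates grouped age, gender, education (with an illiterate category)
and grouped duration. The component correlation was set so that the
component-level dependency is visible at n = 188, which reproduces the
canonical accommodation sequence — item-level LID → domain testlets → a
residual merge → two components — and the fall in alpha as dependency is
absorbed; published analyses of comparable real data suggest even more
closely related components (ECV ≈ 0.93–0.99), so this fixture is
conservative about unidimensionality. What the fixture does *not*
emulate: informative missingness, response styles, longitudinal
dependency, or real category-usage quirks — so passing tests on it show
the detectors work under controlled violations, not that any particular
real dataset fits.

Problem sizes in the test-suite simulations (n = 300–1000, 3–50
replicates per property) were chosen to give stable Monte-Carlo checks of
each calibration and power claim at desk scale; the acceptance script
uses 11 items × 5 categories at n = 500 with 50–100 replicates.

## Known limitations

* Unconditional fit statistics inflate Type I error as n grows (the
  protocol warns beyond n = 500); conditional item-level fit is not
  implemented.
* Smith's corrected INFIT interval under-covers for polytomous items (see
  above); its flags should be read alongside the chi-square and ANOVA
  tests.
* The pairwise information in very sparse designs (many missing patterns)
  makes CML slower; the implementation groups patterns but is pure R.
* The ECV estimator is an approximation with the documented banding
  semantics, not a reimplementation of any proprietary algorithm.
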