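---
title: "Methods: building adolescent GWG charts from pooled multi-site cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building adolescent GWG charts from pooled multi-site cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwgchart)
```

## The problem

Gestational weight gain (GWG) references for pregnant adolescents do not
exist, and no single country holds a dataset large enough to build them.
The practical route is to pool longitudinal antenatal records from many
countries, which raises four methodological problems that this package
addresses as a tested, reusable pipeline:

1. **Harmonization and quality control** — heterogeneous records must pass a
   common set of eligibility rules, and biologically impossible weight
   sequences must be found and removed, with a transparent accounting of
   every exclusion.
2. **Heterogeneity** — before pooling, one must check that sites are similar
   enough to combine, here via Standardized Site Differences (SSD).
3. **First-trimester missingness** — adolescents often enter prenatal care
   late, so first-trimester weights are missing *because* care started late:
   a missing-not-at-random (MNAR) mechanism that must be imputed carefully.
4. **Centile estimation** — reference curves are fitted with the LMS/BCCG
   distributional model over gestational age, per pre-pregnancy BMI
   category.

Because the pooled individual-level data this methodology was developed for
are not publicly deposited, the package ships a first-class synthetic cohort
generator that reproduces the *statistical structure* of such a dataset.
Every stage is tested against that generator's ground truth, against
closed-form oracles, or against brute-force re-computation.

## The synthetic cohort generator

`generate_cohort()` simulates a multi-site pooled cohort. Its defaults are
the package's reference study conditions and are deliberately fixed:

* nine sites of 750 subjects (so that, after the generator's built-in
  ineligibility — ~2% disease flags, ~3% stunting, ~1% out-of-range birth
  weights — the cleaned cohort lands near 6,400 subjects with ~32,000
  weight records, about 5 per subject);
* a pre-pregnancy BMI-for-age mix of 1.5% underweight, 71.8% normal,
  21.4% overweight, 5.3% obesity;
* per-category mean GWG curves that are monotone piecewise quadratics in
  gestational week: a near-flat first trimester followed by acceleration,
  so that most gain accrues in the *third* trimester — the adolescent
  pattern, unlike the second-trimester-dominated adult pattern. Defaults
  total roughly 13.1 / 11.4 / 9.4 / 7.4 kg at week 40 for the four
  categories;
* subject-level variation as a multiplicative random effect on the curve
  (SD 0.12), site-level shifts in height (SD 1.5 cm) and in GWG (SD 0.4 kg
  at term, scaled linearly with gestational age so GWG is 0 at conception),
  and 0.6 kg of visit-level measurement noise;
* visits starting at a latent week of entry into prenatal care and
  recurring every ~7 weeks until week 40. The entry-week distribution puts
  11% of its mass after week 13 (within the 10–13% range typical of such
  cohorts): those subjects simply have no first-trimester record. Because
  the deletion depends only on the *latent* entry week — not on any
  observed variable — the missingness is genuinely MNAR;
* implausible records injected as ±10 kg shifts at random interior visits
  (rate 1%), as ground truth for the QC stage.

What the generator does **not** emulate: real covariate structure beyond
what the pipeline consumes, seasonal or secular trends, within-subject
autocorrelated measurement error, digit-preference in recorded weights, and
site-specific visit-scheduling policies. Passing tests therefore demonstrate
correctness of the *algorithms* under the stated statistical structure, not
fitness of any particular real dataset.

## Eligibility filtering and trajectory QC

`apply_eligibility()` retains subjects who: are 10–19 completed years at
conception (conception dated by `conception_date()` from LMP + 14 days,
EDD − 266 days, or a known gestational age on a known date); have at least
one plausible weight in weeks 14–27 and one in weeks 28–42; gave birth at
term (37–42 weeks) with birth weight 2,500–4,000 g; carry none of five
disease flags; are not stunted (height-for-age z ≥ −2, strict `<` −2
defining stunting); have maximal cumulative GWG **below 30 kg (inclusive
cap at 30.0)**; and have no missing variable of interest. The trimester
windows, thresholds and the cap are all configurable
(`harmonization_options()`).

Two interpretations were genuinely open:

* *Maximal vs final GWG for the 30 kg rule.* The cap is evaluated on the
  **maximum** observed cumulative GWG: a subject who reaches 30 kg at any
  visit has an implausible total gain regardless of a possibly lower last
  measurement.
* *Trajectory cleaning.* Manual review of plotted weight sequences does not
  transfer to a pipeline, so the package codifies it: per subject, a robust
  straight line (Siegel repeated-median slope and intercept, resistant to
  nearly half the points being wrong) is fitted to weight vs gestational
  age; the visit with the largest absolute residual is flagged when the
  residual exceeds 4 kg or an adjacent inter-visit rate leaves
  [−1, +3] kg/week; the line is refitted and the rule repeated. The
  defaults have a physiological reading: sustained gain above 3 kg/week or
  loss beyond 1 kg/week is not biologically plausible, and 4 kg exceeds any
  credible measurement error. Flags remove measurements, never subjects.
  On the generator's truth (±10 kg errors, 0.6 kg noise) the rule attains
  ≥ 95% sensitivity with ≤ 2% false flags.

QC flags are computed first and the visit-dependent criteria (trimester
coverage, GWG cap) are evaluated on plausible visits only; the exclusion
ledger still reports its rows in the documented fixed order (age, coverage,
term, birth weight, diseases, stunting, GWG cap, implausible-visit removal,
completeness). This makes the filter idempotent: re-running it on its own
output removes nothing.

## Standardized Site Differences

Within each BMI-category × gestational-age-bin cell (bins 0–7, 8–14, 15–21,
22–28, 29–35, 36–42 completed weeks), each site's mean is standardized
against the pooled statistics:

$$\mathrm{SSD}_s = \frac{\bar{x}_s - \bar{x}_{\text{pooled}}}{SD_{\text{pooled}}}$$

Sites with |SSD| ≤ 0.5 are judged homogeneous (combinable). Three
conventions are not fixed by the SSD literature as used here and are
therefore explicit package choices:

* the **pooled SD is the sample SD of the individual observations** in the
  cell (n − 1 denominator), not the SD of site means — site means are
  standardized against the pooled distribution of measurements;
* Cohen-style magnitude bands are half-open: |SSD| < 0.2 small,
  0.2 ≤ |SSD| < 0.8 acceptable, ≥ 0.8 large;
* the small-cell sensitivity analysis drops sites with **n < 10** in a cell
  (strict less-than; the threshold is the `min_n` argument) and recomputes
  pooled statistics from the remaining observations.

Two identities are tested in every cell: \(\sum_s n_s \,\mathrm{SSD}_s = 0\)
and scale invariance. Under the exchangeable simulation, ≥ 95% of well-filled
cells are homogeneous; a single site shifted by δ pooled-SDs is recovered at
its exact expectation δ(1 − 1/K)/√(1 + δ²(1 − 1/K)/K), which accounts for the
shifted site's own contribution to the pooled mean and SD.

## First-trimester imputation

Subjects with no weight in weeks 5–13 (inclusive) receive one uniformly
random integer week in that window — drawn once per subject and shared by
all imputations — and `m = 5` imputed weights at that week under the
**normal linear model with bootstrap**: each imputation bootstraps the
complete cases, takes the least-squares coefficients and residual SD from
the resample (propagating parameter uncertainty), and simulates
`X beta* + N(0, sigma*^2)`. Estimates computed on the m completed datasets
are pooled by Rubin's rules
(`T = Ubar + (1 + 1/m) B`, df by the standard small-sample formula).
A predictive-mean-matching imputer (5 nearest donors) is provided as a
comparator behind the same interface; by default only the underweight and
overweight categories are imputed, the categories whose sparse first
trimester needs completion.

Design choices worth stating:

* **Predictors.** The response is the *weight* at the assigned week; GWG is
  derived afterwards, never imputed directly. The default predictor set is
  {assigned/observed window week, number of antenatal visits,
  **pre-pregnancy weight**}. The last is essential: without any
  subject-level weight information the imputed weights scatter with the
  between-subject SD (~8 kg), and the derived GWG falls far outside the
  observed first-trimester envelope. A subject identifier is not usable as
  a numeric covariate, so subject-level anthropometry is the interpretable
  carrier of that information; the predictor set is configurable.
* **Iterations.** An `iterations` knob (default 50) is recorded for API
  fidelity with chained-equations software, but for a univariate
  single-block imputation there is nothing to iterate over: it is a
  documented no-op.
* The assigned week is fixed per subject across the m imputations (one
  week, m weights).

Tested guarantees: observed rows are byte-identical across completed
datasets; imputations reproduce a noiseless linear truth exactly; on
`y = 45 + 0.3·week + N(0,1)` at n = 2,000 the imputed-value bias is below
0.15 kg; Rubin pooling matches hand-computed closed forms; imputed
first-trimester GWG stays inside the [min − 2 SD, max + 2 SD] envelope of
observed first-trimester GWG; and 95% Rubin intervals for mean GWG at week
9 achieve ≥ 90% empirical coverage over 100 replicates at n = 1,000 with
10% MNAR missingness (coverage can degrade under stronger MNAR; the test
asserts the 90% floor rather than exact nominal coverage).

## BCCG centile estimation

Centile curves are fitted with the Box-Cox Cole–Green (LMS) distribution:
`z = ((y/mu)^nu − 1)/(nu·sigma)` standard normal (log form at ν = 0), with
the usual positive-support truncation normalizer `Phi(1/(sigma|nu|))`.
`log mu(t)` and `log sigma(t)` are linear in B-spline bases of configurable
degrees of freedom; `nu` is constant (or linear, or fixed). Estimation
cycles backfitting-style through the three coefficient blocks, each updated
by BFGS with analytic gradients; a block update is accepted only if it does
not increase the deviance, so the deviance trace is non-increasing by
construction. Cycling stops when the relative deviance change drops below
1e-6 (or at 200 cycles, recorded in the convergence flag). Initialization is
ν = 1, `log mu` from least squares of `log y` on the μ basis, σ constant at
the sample CV — stated because likelihood surfaces of this family are
initialization-sensitive.

Numerical choices: η_σ is clamped to ±15 and ν·log(y/μ) to ±250 inside the
likelihood to avoid overflow during line searches; the truncation terms use
log-scale `pnorm`/Mills-ratio forms and switch to their ν → 0 limits below
|ν| < 1e−5; quantile residuals are clipped to (1e−12, 1 − 1e−12) before
`qnorm`.

GWG can legitimately be negative in early pregnancy while BCCG needs
positive support, so `fit_gwg_centiles()` applies a fixed, recorded shift
(default +10 kg) before fitting and removes it from every evaluated
centile. Degrees of freedom default to (μ = 3, σ = 2, ν = 1) and can be
selected by GAIC(k = 3) over a user grid; GAIC(2) is the AIC by definition.
Model adequacy is checked with normalized quantile residuals (Shapiro–Wilk
on an evenly spaced subsample of at most 5,000), per-centile empirical
coverage, and the correlation of |residual| with gestational age as a
homoscedasticity probe. For charting across the m completed datasets the
model is fitted per dataset and the centile curves are averaged pointwise;
per-dataset fits remain available.

The BCCG family itself is an assumption: the response distribution behind
published GWG charts is rarely reported, and BCCG/LMS is the standard
growth-chart family. Four-parameter extensions (BCT, BCPE) are out of scope.

## Problem sizes used by the test suite

The suite favours sizes that keep the full run near half a minute while
leaving the statistical assertions sharp: oracle and boundary checks run on
hand-built fixtures; calibration and recovery use 100–200 replicates of
9 × 200–500 observations; the BCCG self-consistency check uses one fit at
n = 5,000; the Rubin-coverage property uses 100 replicates of a 1,000
subject cohort; end-to-end determinism uses two full runs of a 180-subject
cohort. The acceptance script regenerates the full nine-site default cohort
(6,750 subjects before cleaning).

## Known limitations

* The trajectory QC rule is a codification of a manual review; its
  threshold and rate bounds are physiologically motivated defaults, not
  estimates.
* SSD homogeneity is descriptive: no meta-analytic heterogeneity statistic
  (I², Q) or mixed-model site effect is computed.
* The MNAR treatment assigns a random week and imputes under a model fitted
  to completers; it does not bound sensitivity via delta-adjustment.
* Height is treated as fixed over pregnancy; continued adolescent growth is
  not modelled.
* The imputation engine is univariate single-block by design; arbitrary
  missingness patterns need a full chained-equations engine, which this
  package does not provide.
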