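---
title: "Methods: three-estimator causal analysis of treatment effects in cerebral palsy gait cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-estimator causal analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

Orthopedic and neurological treatments in ambulatory children and young
adults with cerebral palsy are almost never evaluated in randomized
trials. Clinical gait laboratories instead accumulate observational
limb-level records: baseline covariates, a treatment decision, and
follow-up outcomes roughly a year later. Two features make naive
comparisons badly misleading:

* **Confounding by severity.** More severely involved limbs are treated
  more often and also have worse natural history, so a raw
  treated-minus-control contrast mixes the treatment effect with
  prognosis.
* **Targeted selection.** Clinicians treat the patients they expect to
  benefit. When treatment probability depends on expected outcomes,
  regularized outcome regressions inherit a systematic bias
  (regularization-induced confounding), which ordinary covariate
  adjustment does not remove.

`cpcausal` estimates the average treatment effect on the treated (ATT)
with three estimators of different character, at four outcome levels of
a causal chain — body structures, specific gait kinematics, overall
gait kinematics (a GDI-like index), and functional mobility (FAQt) —
and reports them side by side. Agreement across estimators is the
practical robustness check; effect sizes are expressed as Cohen's d and
categorized with the conventional thresholds (small ≥ 0.2, medium ≥
0.5, large ≥ 0.8, very large ≥ 1.2, boundaries inclusive).

## The three estimators

**Direct matching (DM).** One-to-one optimal-subset matching of treated
to control limbs on the Mahalanobis rank distance over
treatment-relevant covariates, with a soft propensity caliper (pairs
whose propensity gap exceeds 0.2 pooled-SD units are penalized, not
excluded), near-fine balance on prior and interval co-treatment
indicators, and optional moment balance on selected means. The ATT is
the mean difference in outcome change (follow-up minus baseline)
between matched treated and control limbs. The subset weight — the cost
of leaving a treated limb unmatched — defaults to the median of the
distance matrix.

The solver: small instances are solved exactly by depth-first branch
and bound whose admissible bound ignores the (non-negative) balance
penalties; larger instances start from the exact assignment optimum
(Hungarian algorithm on a cost matrix augmented with one
`subset_weight` dummy column per treated limb) and are polished by
deterministic best-improvement local search over replace, add, drop,
and swap moves. Balance requirements are per-unit penalties beyond a
slack (defaults: slack = ceiling of 3% of the matched count per
co-treatment; penalty = 5 × subset weight), which doubles as a graceful
relaxation when exact balance is infeasible. A result is labeled
`"optimal"` only when provably so: the branch and bound finished, or
the assignment optimum already carried zero balance penalty.

**Virtual twins (VT).** A Bayesian Additive Regression Trees (BART)
model of the follow-up outcome on all covariates and all treatment
flags — the baseline value of the outcome always included. Each treated
limb gets a *virtual twin*: the same covariate row with the index
treatment flag set to 0. The per-limb effect is the posterior-mean gap
between the actual and twin predictions; the ATT averages these over
the treated limbs of the requested sample.

**Bayesian Causal Forest (BCF).** The outcome is decomposed as

y = μ(x, π̂) + τ(x) · z + ε,

a prognostic forest μ and a treatment-moderating forest τ, with the
estimated propensity score π̂ supplied as a covariate. Regularizing μ
*around* the propensity score is what absorbs targeted selection; τ is
regularized separately and more strongly, encoding the belief that
effect heterogeneity is smoother than prognosis. Both forests receive
π̂ by default (`include_pihat_tau = TRUE`): both surfaces are treated
as functions of the covariates and the propensity score. Some
implementations feed π̂ to the prognostic forest only; that behavior
is available via the switch.

Because DM can only estimate an effect for treated limbs that found a
control, VT and BCF are each run twice — on the matched subset and on
all treated limbs. A gap between the two flags bias from omitted
observations. That yields five estimates per treatment × outcome:
DM-matched, VT-matched, VT-all, BCF-matched, BCF-all.

## The BART engine

The sum-of-trees sampler is implemented from scratch in C++ (it
underlies the propensity model, VT, and both BCF forests):

* Outcome rescaled to [−0.5, 0.5]; a constant outcome maps to 0 exactly
  (zero-variance guard).
* Tree structure prior p(split at depth d) = α(1+d)^−β with α = 0.95,
  β = 2; leaf means N(0, σ²_μ) with σ_μ = 0.5/(k√m), k = 2; m = 50
  trees; σ² ∼ νλ/χ²_ν with ν = 3 and λ calibrated so the prior puts
  probability 0.9 below the marginal outcome SD.
* Metropolis–Hastings proposals grow / prune / change with mix
  0.28/0.28/0.44, conjugate marginal likelihood (leaf means integrated
  out), conjugate leaf and σ² draws. `change` re-draws the rule of a
  node with two leaf children; because the same rows reach the node
  before and after, the proposal ratio reduces to the likelihoods.
* Numeric split candidates are the unique observed values in the node
  (excluding the minimum; `x < cut` goes left). Factors are one-hot
  encoded and split as binary indicators — the convention of the
  tooling this analysis models itself on — with "Miss" an ordinary
  level; a level unseen at training maps to all-zero indicators,
  deterministically.
* Binary outcomes (propensity models) use Albert–Chib latent-normal
  augmentation with σ fixed at 1 and leaf scale 3/(k√m); fitted values
  map to probabilities through the normal CDF.
* All randomness flows through R's RNG: a fixed `set.seed()` makes
  every fit bit-reproducible. The sampler is single-threaded.

BCF runs the same engine as two coupled forests updated by Bayesian
backfitting: the μ forest fits all rows against y − z·τ(x); the τ
forest fits the treated rows against y − μ(x). The τ forest uses the
stronger depth prior (base 0.95, power 3), 200 trees in each forest,
and leaf scale 0.674·SD(y)/√m_τ — the τ-forest tree count and base
raised from the conventional 50 and 0.25 because substantial outcome
heterogeneity is expected in this population. The reference MCMC budget
is 1000 burn-in + 1000 kept draws; the pipeline default is a reduced
250/500 budget for desk-scale work, with `paper_fidelity = TRUE`
restoring the full budget.

## Uncertainty

Confidence intervals come from a limb-level bootstrap (1000 replicates,
percentile 2.5/97.5). Limbs — not individuals — are the resampling
unit, which avoids assumptions about the correlation between limbs of
the same person. For DM the resampled unit is the matched pair. For VT
and BCF, resampling posterior-mean per-limb effects alone would ignore
estimation uncertainty and produce degenerately narrow intervals, so
each bootstrap replicate also samples one posterior draw of the
per-limb effect vector; the interval then reflects model uncertainty
and sampling variability together. Models are not refit inside the
bootstrap.

Cohen's d standardizes a raw ATT by the SD of the outcome change over
all analysis limbs (treated and control). The standardizer choice is
recorded in each estimate; control-only or baseline-SD standardizers
would be defensible alternatives and change only the scale, not the
sign, of reported effects.

## The synthetic cohort generator

No clinical gait database is publicly deposited, so the package ships a
generator that reproduces the *statistical structure* the estimators
must survive, together with the ground truth needed for
parameter-recovery testing:

* **Limbs nested in individuals.** Each subject carries a latent
  standard-normal severity factor; limb severity is
  √ρ·subject + √(1−ρ)·noise with ρ = 0.6.
* **Mixed covariates loading on severity**: continuous exam measures,
  ordinal spasticity (0–4) and strength (0–5) scores from thresholded
  latent Gaussians (preserving monotone association with severity),
  GMFCS I–IV, topography, motor control, age, sex, follow-up interval
  uniform on [0.9, 2.5] years.
* **Assignment from the chart.** The treatment logit depends on an
  *observed* severity index (a standardized combination of exam
  measures and GMFCS) and standardized age — not on the latent factor —
  so treatment is ignorable given the measured covariates, which is the
  identifying assumption of the whole framework. An earlier design that
  let assignment see the latent factor broke ignorability for every
  estimator and was discarded.
* **Targeted selection.** The logit adds λ × expected benefit
  (in change-SD units, judged from observables, not centered): a
  uniformly beneficial treatment is also used more often as λ grows.
  At λ = 0 assignment ignores benefit; the default λ = 1 is moderate;
  λ = 3 with a half-SD effect raises the treated fraction well above
  the λ = 0 base rate and stresses overlap.
* **Four-level outcomes.** Baseline values load negatively on severity;
  the untreated change is drift (worse for severe and for younger
  limbs — rapid progression during growth) plus level-specific noise.
  The index-treatment effect profile `delta` is expressed in units of
  the untreated change SD per level, default (0.4, 0.2, 0.1, 0) —
  attenuating along the causal chain — with optional severity-linear
  heterogeneity. Co-treatments (13 categories mirroring common
  surgeries) have homogeneous effects spread over 0.05–0.45 change-SD,
  attenuated with the same profile shape.
* **Functional mobility** is generated as a latent score emitted
  through 23 graded FAQ items; the follow-up FAQt must be reconstructed
  from the items by the preprocessing chain, as with real data.
* **Structured missingness**: GMFCS missing at 20%, neurological scores
  at low rates with a severity-dependent logit shift (informative
  missingness), one continuous exam measure missing (handled by
  listwise deletion), item-level FAQ non-response at 5% plus
  whole-questionnaire non-response at 8% (which leaves FAQt undefined
  when fewer than 18 of 23 items remain).

What the generator does **not** emulate: raw kinematic waveforms (the
outcome indices are generated directly), calibration of the derived
indices, informative loss to follow-up, and clinician-specific
treatment styles. Recovery of known effects here shows the estimators
work under the assumed structure — ignorable, overlap-limited,
severity-confounded assignment — not that the assumptions hold in any
particular clinical database.

## Preprocessing rules

Eligibility: age < 25 years, follow-up in [0.75, 2.5) years (at least
nine months, less than 30), knee varus-valgus range of motion ≤ 15°
(beyond which transverse-plane kinematics are unreliable). Missing
categorical entries become the literal level "Miss" (missingness in
clinical data is often informative, so it is modeled, not imputed).
The FAQt is the difficulty-weighted average of the 23 mobility items;
when 18–22 items are present the missing ones are filled by a
single-pass ridge regression of each missing item on the observed items
(coefficients from complete rows, ridge penalty 1) — a deliberately
simple imputer appropriate for near-complete rows — and rows under the
18-item floor keep a missing FAQt. The item difficulty weights are not
publicly tabulated; the generator fixes a weight vector
(`faq_weights_default()`, increasing from 0.5 to 2) and the
preprocessing consumes the same vector. Covariate balance uses the
absolute standardized mean difference, with the multivariate
(Yang–Dalton) form for factors and a Moore–Penrose pseudo-inverse when
the multinomial covariance is singular.

## Numerical and design choices

* Ties in ranks take the average rank; constant covariates are dropped
  from the distance with a warning; the pooled rank covariance falls
  back to a pseudo-inverse when singular.
* The caliper is a soft penalty (2 × subset weight per caliper-width of
  excess), matching a design that penalizes rather than excludes.
* Matching tie-breaks are deterministic: the branch and bound accepts a
  new incumbent only on strict improvement, and the local search is
  best-improvement with a fixed move order.
* Estimates whose CI straddles zero are still categorized by point
  estimate and flagged (`ci_covers_zero`) rather than suppressed.
* Propensities are clipped to [1e-4, 1 − 1e-4] before entering BCF.
* Degenerate inputs: zero-variance outcomes collapse to the mean;
  all-one or all-zero treatment vectors, fewer than 10 limbs per arm,
  or single-class held-out sets raise errors rather than silent
  nonsense.

## Problem sizes in the shipped studies

The calibration studies in the test suite use cohorts of 400 subjects
(800 limbs) with 20 replicates per scenario at the reduced MCMC budget,
and the full-pipeline demonstrations use 300–400 subjects with two to
thirteen treatments — sizes chosen to mirror the scale of a single-
center clinical cohort while keeping a complete run on one desktop CPU
in minutes. The flagship reproduction script
(`scripts/acceptance.R`) analyzes all 13 treatments at 800 limbs.

## Known limitations

* The bootstrap does not refit the models, so DM intervals can be
  slightly narrow when match quality varies across cohorts.
* The near-fine-balance penalties guarantee the 3%-scale co-treatment
  balance only when enough interchangeable controls exist; the status
  field reports when a solution is heuristic rather than provably
  optimal.
* The FAQt imputer conditions on FAQ items only, not on other
  covariates.
* Individual treatment effects and moderator discovery are out of
  scope; the package reports ATTs.
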