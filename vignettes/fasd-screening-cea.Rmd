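---
title: "Methods: modelling the cost-effectiveness of FASD screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling the cost-effectiveness of FASD screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fasdcea)
```

## The decision problem

A cohort of children *suspected* of fetal alcohol spectrum disorder (FASD)
can either all be referred for diagnostic testing (no screening), or be
screened first so that only screen-positives are referred. Screening saves
testing costs and, because most suspected children who test negative then
use cheaper services, also service costs; but an imperfect screen leaves
false negatives undiagnosed, and the effectiveness outcome here — years of
life lived with an accurate FASD diagnosis before age 18 — is lost for as
long as they remain undiagnosed. Two published comparisons are modelled:
meconium fatty acid ethyl ester testing of newborns (screen at birth,
diagnostic testing at age 5 in both arms) and the Neurobehavioral
Screening Tool for 5-year-olds (screen and test at age 5). Costs are 2017
Canadian dollars from the public-healthcare perspective.

## Model structure

`initial_distribution()` implements the decision tree: with prevalence
$\pi$, sensitivity $Se$ and specificity $Sp$,
$N\pi Se$ children await testing, $N\pi(1-Se)$ are undiagnosed,
$N(1-\pi)(1-Sp)$ await rule-out testing and $N(1-\pi)Sp$ are never
tested. The Markov engine (`advance_cycle()`, `run_strategy()`) then
advances one-year cycles to age 18 through the states *awaiting testing
(FASD / no FASD)*, *diagnosed*, *undiagnosed*, *no FASD* and *dead*,
applying in order: mortality, scheduled testing (cost \$3,870 per test,
perfectly accurate by default), future-diagnosis conversion of
undiagnosed children (probability 0.05 per cycle, incurring a re-screen
plus a test), annual state costs, and diagnosed-year accrual. Occupancy
is conserved to the cohort size at every cycle and the engine stops with
an internal error otherwise.

### Parameters

| Parameter | Default | Units / notes |
|---|---|---|
| cohort size | 100 | results are "per 100 screened" |
| prevalence | 0.663 | suspected children truly meeting criteria |
| meconium Se / Sp | 0.924 / 0.515 | pooled, see below |
| NST Se / Sp | 0.859 / 0.729 | pooled |
| screen cost | \$175 (meconium), \$20 (NST) | per screen |
| diagnostic testing | \$3,870 | one-off, never inflated |
| first year of life | \$15,976 pre-inflation (\$20,265) | all living children, from-birth model only |
| diagnosed / undiagnosed / no-FASD annual | \$3,426 / \$2,713 / \$3,101 pre-inflation | per person-year |
| inflation factor | 1.268465 | recovered from the three printed cost pairs |
| discount rate | 0.015 / year | mid-cycle discounting |
| future diagnosis rate | 0.05 / year | false negatives, after the testing age |
| SMR diagnosed / no-FASD | 3.15 / 3.15 | undiagnosed ×1.10 |
| horizon | age 18 | no terminal value beyond the horizon |

The undiagnosed annual cost is not a free parameter: it is derived from
the diagnosed cost and the psychiatric-care recommendation rates (55.6%
diagnosed vs 33.0% undiagnosed) by assuming undiagnosed children receive
the psychiatric-influenced share of services proportionally less
(`undiagnosed_annual_cost()`). That share (≈ 0.512) is calibrated once so
the base-case inputs reproduce the published \$2,713 (pre-inflation) and
\$3,441 (2017 CAD) anchors; the functional form is an assumption — the
original derivation is not public — and the calibration is verified by an
independent back-solve in the tests.

## Accuracy pooling

Study accuracies are pooled with DerSimonian–Laird random effects on the
raw proportion scale (`pool_random_effects()`), after capping 100%
proportions at 99% and imputing unreported SDs with
$\sqrt{p(1-p)/(n+1)}$. Raw-scale pooling is the default because it
reproduces the published pooled values from the published study rows; a
logit-scale option exists but is off by default. The pooled
between-study SD is reported as $\sqrt{\tau^2}$; the published pooled SDs
are of similar but not identical magnitude and their exact definition is
not stated, so no agreement is forced — the model's base case uses the
published means and SDs directly.

## Conventions the published analysis leaves open

Several mechanical conventions are not stated in the published analysis.
Each is exposed as a `model_options()` switch; the defaults are the
combination that best reproduces the published incremental results
(deltas within ~2%, ICERs within ~2%, all four alternative-discount-rate
ICERs within 2%), which the acceptance tests verify at their stated
tolerances:

* **Half-cycle correction** (`half_cycle`): the default accrues costs and
  effects on the *average* of start- and end-of-cycle occupancy
  (trapezoidal) with mid-cycle discounting; pure mid-cycle evaluation
  (end-of-cycle occupancy) is available. Under the trapezoid, the
  diagnosis cycle contributes half a diagnosed year, so the exact
  zero-mortality/zero-discount closed form for no-screen diagnosed years
  is $\pi N (T - 0.5)$ rather than the mid-cycle variant's $\pi N T$;
  both are tested exactly.
* **Cost basis** (`use_inflated_costs`, `inflate_no_fasd`): annual costs
  are normalized to 2017 CAD before modelling, including the no-FASD
  cost. Modelling on the pre-inflation basis is possible but understates
  the published cost deltas by roughly 10%. (Curiously, the published
  per-arm *totals* are closer to a pre-inflation run; since the deltas
  and ICERs are the decision quantities, the inflated basis is the
  default and per-arm totals print above the published ones.)
* **Conversion timing** (`conversion_start`): future-diagnosis
  conversions begin in the cycle containing the testing age; starting
  one cycle later overstates the effectiveness delta by 5–8%.
* **Conversion dynamics** (`future_diagnosis_model`): the default applies
  the 5% rate to the *remaining* undiagnosed pool (geometric hazard); a
  variant applying it to the original false-negative pool (uniform
  conversion time) is provided.
* **Costing children awaiting testing** (`pending_fasd_cost`): FASD
  children awaiting testing are costed as undiagnosed (default);
  no-FASD or diagnosed costing are available. False positives awaiting
  rule-out are always costed at the no-FASD rate.
* One-off costs (screening, testing, re-diagnosis) are discounted at the
  mid-cycle factor of the cycle in which they occur.

## Synthetic data and validation

`make_life_table()` generates the background mortality input: an infant
death probability of 0.005 at age 0 and a flat 0.0002 thereafter,
magnitudes chosen as plausible for a contemporary Canadian pediatric
population. This emulates only the *shape* of a national life table
(elevated infant mortality, low flat child mortality) — not year-to-year
structure, sex differences or cohort trends. Because all-cause child
mortality is small, model results are insensitive to it (the tornado
ranks mortality near the bottom), so passing tests with the synthetic
table say little about mortality realism and everything about the
engine's bookkeeping. A real life table can be supplied via
`read_life_table()`.

`make_accuracy_studies()` generates binomial study sets around a known
true proportion for parameter-recovery tests of the pooling estimator;
it does not emulate publication bias, spectrum effects or correlated
sensitivity/specificity, so those failure modes of real meta-analyses
are out of scope.

`microsimulate()` re-implements the model per individual with Bernoulli
draws for true status, screen result, death and conversion. Every cohort
transition is linear in occupancy, so the microsimulation's expectation
equals the cohort output; the tests require agreement within 3
Monte-Carlo standard errors at 200,000 individuals on randomized
parameter sets, and exact agreement in a degenerate configuration
(perfect screen, no mortality, stratified prevalence).

## Probabilistic and one-way analysis

The probabilistic analysis (`run_psa()`, 5,000 draws by default) samples
every parameter independently: betas moment-matched to mean/SD for
proportions; log-normals (SD 10% of mean) for the experimentally derived
annual costs, sampled pre-inflation and then inflated; normals bounded
to ±25% of the mean (SD 10%) for screening and testing costs, by
rejection rather than clipping; uniforms for the future-diagnosis rate
(3–7%) and the undiagnosed mortality multiplier (1.0–1.2); and SMR
normals truncated below at 1. Draws in which the sampled undiagnosed
psychiatric-recommendation rate exceeds the diagnosed rate would invert
the undiagnosed-cost relationship and are rejected and resampled (the
count is recorded on the result). A single `set.seed()` at the start of
the run makes the draw sequence reproducible.

Because screening sits in the south-west quadrant, the acceptability
curve (`ceac()`) is a *willingness-to-accept* curve: a draw is acceptable
at threshold $\lambda$ when its savings per diagnosed year forgone are at
least $\lambda$ (dominant draws always, dominated draws never). The
curve is therefore non-increasing in $\lambda$ — the mirror image of a
textbook willingness-to-pay CEAC — matching the direction of the
published curves. This is the one place the package deliberately departs
from textbook net-benefit acceptability, and it is the only rule
consistent with the published curve falling from high acceptability at
low thresholds to below 50% at \$3,000.

The one-way analysis (`one_way()`) reruns the deterministic model at
0.75× and 1.25× of each parameter, capping proportions at 1. At a capped
sensitivity of 1 the screen arm forgoes no diagnosed years while still
saving costs, so the ICER grows without bound; the endpoint is recorded
as a signed infinity and sensitivity tops both tornado rankings, with
tool cost, mortality and the future-diagnosis rate in the bottom half.

## Problem sizes

The shipped tests run the full 5,000-draw probabilistic analysis for the
meconium comparison, 10^5-draw distribution-support checks, and 200,000
individual microsimulations — the same sizes the analysis itself uses;
the whole suite completes in well under a minute on one core.

## Known limitations

* Sensitivity and specificity are sampled independently; real screening
  thresholds induce negative correlation, so the PSA likely overstates
  joint accuracy uncertainty.
* Diagnosed-year effectiveness is not a QALY; no health-related quality
  of life is modelled.
* No individual heterogeneity (sex, severity), no costs outside the
  public healthcare payer (education, justice), no adult extension
  beyond age 18, and no terminal value at the horizon.
* The undiagnosed-cost functional form and the future-diagnosis rate are
  assumptions inherited from the analysis being reproduced; both are
  exposed to one-way and probabilistic variation.
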