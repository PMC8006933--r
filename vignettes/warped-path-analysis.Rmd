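---
title: "Warped path analysis of body-weight drivers: models, scoring and elicitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Warped path analysis of body-weight drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obesipath)
```

## Overview

`obesipath` implements a complete analysis chain for survey studies of the
socioeconomic and intrapersonal drivers of body weight:

1. **Scoring** — BMI and weight-status categories, Stunkard figure-rating
   measures (body-image dissatisfaction, weight misperception), and the
   ATOP/BAOP Likert instruments.
2. **Elicitation** — prospect-theory risk aversion (σ), loss aversion (λ)
   and probability weighting (γ) inverted from switching points in a
   three-series multiple-price-list lottery menu.
3. **Estimation** — robust non-linear ("warped") path analysis over the
   scored variables, with bootstrap inference, Cohen effect sizes and ten
   global fit/quality indices.
4. **Simulation** — a seed-reproducible synthetic-cohort generator with
   exported ground truth, used throughout the test suite for parameter
   recovery.

This vignette records the modelling choices, the tunable parameters, the
numerical conventions, and what the synthetic cohorts do and do not
emulate.

## Scoring conventions

**BMI** is weight/height² (kg/m²) with categories cut at 18.5, 25 and 30.
The printed category ranges of survey codebooks ("18.5–24.9", "25–29.9")
leave values such as 24.95 unassigned; we use half-open lower-inclusive
intervals ([18.5, 25), [25, 30), [30, ∞)), the standard WHO reading, so
`classify_bmi(18.5)` is `normal`.

**Stunkard measures.** The nine silhouettes collapse to the four weight
categories as 1–2 / 3–4 / 5–7 / 8–9. Body-image dissatisfaction (BID) is
the signed difference current − preferred; its *degree* is the absolute
value, and both are kept (`bid`, `bid_degree`). The weight-perception
score compares the category rank implied by the chosen "current"
silhouette with the measured BMI category rank (underweight = 1 …
obese = 4); comparison happens at category level because the instrument
elicits a categorical self-assessment, not a continuous BMI guess.

**ATOP/BAOP.** Both instruments are scored by the canonical three steps:
negate the reversed items (ATOP: 2–6, 10–12, 14–16, 19, 20; BAOP: 1, 3–6,
8), sum, and add the offset (60 and 24). The item response range is not
part of the published scoring rules; we bundle the 6-point scale
{−3, −2, −1, +1, +2, +3} because it is the only symmetric integer scale
that reproduces the documented score ranges 0–120 and 0–48 exactly. A
neutral 0 can be admitted via `allow_zero = TRUE`; it only affects the
attainable score parity.

## Prospect-theory elicitation

Prospects are valued with a power value function, v(z) = z^σ for gains and
−λ(−z)^σ for losses, and Prelec weighting w(p) = exp(−(−ln p)^γ). For
prospects whose outcomes share a sign the weight applies to the stated
probability of the first outcome with 1 − w(p) on the other; for mixed
gain/loss prospects both outcomes are weighted separately,
w(p)·v(x) + w(1−p)·v(y). The mixed-prospect convention is load-bearing:
with 50/50 odds the common factor w(0.5) cancels from every series-3
comparison, so the loss-aversion inequalities are independent of γ. At
σ = λ = γ = 1 the value reduces exactly to expected value.

**Design.** The bundled menu follows the canonical three-series structure
used in field elicitations: two all-gain series of 14 rows each, with Plan
A fixed and Plan B's high payoff escalating down the rows (a unique switch
row exists for any parameter triple), and a 7-row mixed gain/loss series
at 50/50 odds. Payoffs are read in euros; under a power value function a
uniform payoff rescaling multiplies all utilities by a common factor, so
the currency unit never affects choices. Any design with the same
structural invariants can be supplied as a YAML/JSON file.

**Inversion.** For a fixed γ, the utility gap of an all-gain row is a
four-term exponential sum in σ whose coefficients sum to zero per plan;
σ = 0 is always a root, leaving at most one positive root, which
`uniroot` locates inside the box σ ∈ [0.05, 2]. The observed switch rows
therefore trace two indifference curves σ(γ), one per series; their
crossing (nested bisection over γ ∈ [0.05, 1]) is the point estimate, and
the region where the two per-series σ-intervals intersect gives interval
bounds. The γ feasibility boundaries are refined by bisection beyond the
0.01 scan grid and the σ envelope extremes are polished with local
optimization, so reported intervals are conservative: in noiseless
round-trip tests they contain the generating triple in 100% of interior
cells. λ is bracketed by the series-3 row thresholds
c_r(σ) = (x_B^σ − x_A^σ)/(|y_B|^σ − |y_A|^σ) (Plan A preferred exactly
when λ ≥ c_r) and reported as the bracket midpoint at the σ point, with
bounds taken over the whole σ interval.

**Censoring.** Never-switch and immediate-switch menus give one-sided
intervals clipped to σ ∈ [0.05, 2], γ ∈ [0.05, 1], λ ∈ [0, 12] (ranges
chosen to cover observed field estimates, σ up to 1.5 and λ up to ~11.8);
the point estimate is then the midpoint of the clipped feasible box, and
for λ the boundary threshold ± half the adjacent cell width. Point
estimates near but not exactly at 1 are categorized strictly (risk averse
σ < 1, neutral σ = 1, loving σ > 1; loss averse λ ≥ 1): under interval
inversion a point estimate never lands exactly on 1, so category
round-trip checks are interval-based.

Non-monotone choice vectors (multiple switches within a series) are
excluded with a logged warning, never repaired — mirroring the usual
survey practice of discarding incomplete or inconsistent records.

## Warped path analysis

All model variables are observed, single-indicator and standardized
(mean 0, SD 1, denominator n − 1). Estimation is per endogenous equation:

1. Each incoming edge's predictor is *warped* against the raw criterion —
   a least-squares polynomial fit of y on x of degree 1 (`linear`), 2
   (`quadratic`) or 3 (`s_curve`, the default), with x replaced by the
   fitted values, restandardized.
2. The warped block enters one OLS regression; coefficients on the
   standardized scale are the path coefficients.

Three conventions matter:

* **Orientation.** A fitted warp always correlates positively with the
  criterion, which would force every path coefficient positive; we
  therefore re-orient each warped predictor to correlate positively with
  its own *source* variable, so monotone-decreasing relationships keep
  negative coefficients. For sign-symmetric shapes (a pure U) the
  orientation of the fitted curve is kept.
* **Binary variables** (gender, income band, diet, correct perception)
  cannot support a polynomial warp; they are detected (≤ 2 distinct
  values) and forced to the linear mode with a log note.
* **Warping against the raw criterion**, not residualized on the other
  predictors — the simplest defensible choice; alternatives can be swapped
  behind `warp_edge()`.

With linear modes everywhere the estimator reproduces textbook OLS to
10⁻¹⁰ (tested against the normal equations), and s_curve fits converge to
the linear coefficients when the generating truth is linear.

**Inference.** Rows are resampled with replacement B times (default
B = 5000, giving the conventional t statistic with 4999 degrees of
freedom), the whole model — including the warps — refit on each resample,
and per-edge standard errors taken as bootstrap SDs; p-values are
two-tailed from t = β/se. Resamples that degenerate (zero variance in a
column) are redrawn, at most ten times. Type-I error for a null edge at
n = 172, B = 500 sits at ≈ 0.05 in 500-replication calibration runs.
Effect sizes are |β × r| with Cohen bands small/medium/large at
0.02/0.15/0.35.

**Fit indices.** APC (mean |β|), ARS / AARS (mean (adjusted) R²), AVIF
(mean VIF across warped predictor blocks with ≥ 2 predictors), AFVIF
(mean full-collinearity VIF over all model variables), GoF
(√(communality × ARS), which is exactly √ARS for single-indicator
models), SPR (share of edges whose β sign matches the warped bivariate
correlation), RSCR (positive share of β × r contributions), SSR (share of
edges with |β| ≤ |r|), and NLBCDR (share of edges whose warped bivariate
R² in the hypothesized direction weakly exceeds the reversed direction,
half credit on ties — linear edges are exact ties by construction). The
published literature on robust path analysis states acceptance thresholds
for these ratios rather than formulas; the definitions above are this
package's versioned, declared choices.

**Curve shapes.** `relationship_curve()` exports each edge's fitted
polynomial on the observed range and labels it linear / U / inverted-U /
S / inverted-S / J / exponential-like from derivative sign patterns. A
curve whose deviation from its best linear approximation (central 80% of
the range) stays below 30% of its spread is labelled linear — the
threshold separates cubic overfitting of linear truth (≤ ~22% at
n = 400–1000) from genuinely cubic truth (≥ ~45%) in simulation. For full
cubics with two interior stationary points the leading-coefficient sign
decides the S orientation (positive → S, negative → inverted-S).

**Model structure.** The default 15-edge model places BMI at the centre
with five endogenous equations (BMI, attitude, dissatisfaction degree,
diet, loss aversion). Read jointly, the BMI → BID → diet → BMI edges form
a feedback pattern; estimation is per-equation over the declared edge
list, so acyclicity is enforced only within each equation — bidirectional
feedback as such is out of scope, as is any latent measurement model.

## The synthetic cohort

`generate_cohort()` emulates the *record layout* and the *structural
relations* the analysis assumes — it makes no claim of distributional
fidelity beyond first and second moments. Defaults mirror an adult urban
survey population: 70% female, 69% married, 36% university, 32% low
income, 24% dieting, age ~ N(45.8, 11.22²) truncated to [20, 70], BMI
centred at 25.17 (SD 4.21), σ centred at 0.58 (SD 0.37), λ at 3.67
(SD 3.88), γ at 0.7 (SD 0.15).

Structure: belief → attitude through a convex (exponential) map; BMI from
a rise–fall–rise cubic in age, linear binary effects, attitude/belief
terms, an inverted-U in σ; dissatisfaction from BMI through a convex map;
silhouettes drawn category-consistent with measured BMI except with the
configurable misperception probability (default 0.1; at 0 every subject
perceives correctly by construction); item vectors quantized from the
latent scale levels with uniform jitter (the minimal item-level model
that makes scoring testable — no claim about real item response
processes); lottery choices simulated from each subject's true (σ, λ, γ)
with a small logistic temperature (default 0.005, which discards ≈ 5% of
subjects as non-monotone, the order of magnitude real surveys lose to
inconsistent answers).

Two relations are emulated only qualitatively: the diet → BMI and
perception → BMI edges sit inside the feedback pattern above, so the
generator draws a latent diet propensity before BMI and realizes the diet
flag after dissatisfaction; the resulting associations have the right
sign but are not exact structural coefficients. Recovery tests therefore
use acyclic custom edge configurations, for which fitting with the
matching warp mode recovers the generating coefficients to ±0.05 at
n = 1000 and labels the generating shape correctly in ≥ 95% of seeded
replicates.

What passing tests show — and do not show. Green recovery and calibration
suites demonstrate that the estimator is consistent and its inference
calibrated *under the generator's assumptions* (independent subjects, the
stated functional forms, additive Gaussian latent noise). They cannot
certify behaviour under real-survey features the generator omits:
measurement error in height/weight, item non-response, correlated
demographics, or preference heterogeneity beyond the configured normals.

## Problem sizes and numerical choices

The shipped simulations use cohorts of 172 subjects (the scale of the
survey setting the package addresses), n = 1000 for recovery runs, 40
seeded replicates for shape stability, 500 replications at B = 500 for
bootstrap calibration, and B = 5000 for reported inference. Tolerances:
OLS oracle agreement 10⁻¹⁰; standardization idempotence 10⁻¹²; NLBCDR tie
window 10⁻⁸ (protects exact ties from summation-order noise); SSR
comparison slack 10⁻¹⁰ (single-predictor equations have β = r exactly);
collinearity guard at condition number 10⁸ with perfect-collinearity
errors naming the offending variable. All randomness flows from explicit
integer seeds; equal config + seed reruns are byte-identical at every
pipeline stage.

## Known limitations

* Interval inversion, not maximum likelihood: with noisy choices the PT
  point estimates inherit the menu's cell resolution; the intervals are
  the honest summary.
* Per-equation estimation cannot separate feedback loops; the edge list
  declares direction, it does not test it (NLBCDR is a heuristic check).
* The polynomial warp family covers the S/U/J/exponential shapes reported
  in this literature but cannot represent plateaus or thresholds.
* Binary endogenous variables (diet) are fit as linear probability
  models.
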