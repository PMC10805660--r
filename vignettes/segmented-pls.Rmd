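---
title: "PLS path modelling with response-based and finite-mixture segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PLS path modelling with response-based and finite-mixture segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plsseg)
```

## The problem

Applied path models in epidemiology and the social sciences relate
unobservable constructs — here a community-practice factor, a food
(maternal nutrition supply) factor, a health-service factor and toddler
nutritional status — each measured by a handful of observed indicators.
Partial least squares (PLS) path modelling estimates such systems by
building a composite score for every latent variable from its indicator
block and regressing the scores on one another along the declared
structural paths.  PLS is attractive when samples are modest, indicators
are skewed and the analyst wants a distribution-free estimator.

A second, harder question is *unobserved heterogeneity*: the fitted
global model may average over sub-populations that obey different
structural regimes.  `plsseg` implements the two standard answers.
REBUS-PLS grows segments by iteratively reassigning units to whichever
segment-local PLS model fits them best, measured by a residual-based
closeness measure.  FIMIX-PLS fits a finite mixture of inner-model
regressions on the global latent scores by expectation–maximisation and
assigns units by posterior probability.

## The estimator

`pls_path()` runs the classic alternating algorithm.  Indicators are
standardized (sample, n−1 convention).  Outer weights start at one per
block, scaled for unit score variance — a deterministic initialisation,
so fits are exactly reproducible.  Each iteration forms inner proxies
from adjacent latents' scores under the chosen scheme (`centroid` by
default: the sign of the score correlation; `factor`: the correlation;
`path`: regression weights for predecessors, correlations for
successors), then updates the outer weights: Mode A (reflective) weights
are covariances of the indicators with the proxy, Mode B (formative)
weights are the multiple-regression coefficients of the proxy on the
block.  The textbook Mode A expression carries a denominator written as
the variance of the *squared* latent; it is computed here as the
variance of the latent itself, the standard Mode A estimator — after the
unit-variance rescaling the two differ only by a positive block
constant, which cancels.  Iteration stops when no outer weight moves by
more than `tol` (default 1e-6, `max_iter` 300); on the packaged
synthetic data convergence takes well under 20 iterations.

The sign of every composite is pinned by requiring the sum of
indicator–score correlations to be non-negative per block; flipping a
block's indicators flips its loadings and adjacent path coefficients but
leaves R², communalities and residual magnitudes untouched (tested).

Path coefficients are then per-equation OLS of each endogenous score on
its predecessors' scores — an identity the test suite checks against a
normal-equations oracle at 1e-10.  Loadings are indicator–score
correlations (equivalent to the Mode A normal equations on standardized
data), communalities their squares.  Location parameters translate the
fit back to the original measurement scale: a latent's mean is its
block's outer weights, normalised to sum to one, applied to the
indicator means (so a single-indicator latent inherits its indicator's
mean), and structural intercepts follow from evaluating each equation at
the means.

## Model evaluation

`evaluate()` assembles the standard quality report.  Cronbach's alpha is
computed from the block correlation matrix; a single-indicator block is
reported as 1 by convention and excluded from reliability flags.  AVE
and composite reliability use the standardized-loading error variances
1−λ².  VIF is the reciprocal unexplained variance of each predictor
regressed on the others.  Q² is the chained product 1−∏(1−R²ⱼ) — by
construction it is monotone in each R² and never below the largest one.
The GoF index is the geometric mean of average communality and average
R²; the `pooled` variant (all indicators weighted equally rather than
block-averaged) is the form used inside the REBUS machinery, and the two
coincide when blocks share a size.  f² is Cohen's inclusion/exclusion
effect size.  It is computed on the *fitted scores* (two inner
regressions, with and without the predictor) rather than by refitting
the whole PLS model without the edge: holding scores fixed makes the
zero-coefficient case exactly zero and the single-predictor case exactly
R²/(1−R²), and avoids the degenerate refit that removing a chain edge
would cause (the upstream latent would lose its only neighbour and its
inner proxy).  Conventional cut-offs (loading > 0.5, α > 0.7, CR > 0.6,
AVE > 0.5, VIF < 10, GoF > 0.36) are emitted as flags, never enforced.

## Bootstrap inference

`bootstrap_pls()` resamples units with replacement (default B = 500) and
refits.  Each replicate is sign-aligned to the original fit blockwise
before aggregation, because an unaligned sign flip would masquerade as
sampling variance.  The reported t statistic is the original estimate
over the bootstrap standard error, referred to a t distribution with
n−1 degrees of freedom — a deliberately conservative, conventional
choice, since the reference distribution for PLS bootstrap t statistics
is not settled; at n = 216 the critical value is within half a percent
of the normal 1.96.  Rejection requires |t| to *strictly* exceed the
critical value.  A calibration check in the acceptance suite plants a
true-zero structural path and verifies the empirical type-I rate at
α = 0.05 stays within [0.01, 0.12] over 200 small simulations.

## REBUS-PLS

The closeness measure CM(i, g) multiplies two normalised residual
ratios evaluated under segment g's local model: the unit's squared
measurement residuals, each divided by its indicator's communality,
relative to the segment average of the same quantity with an
(n_g − m_g − 1) degrees-of-freedom correction; and the analogous
structural-residual ratio normalised by the local R².  By default m_g
counts the local model's free parameters (paths plus loadings;
`mg = "latents"` switches to the latent count) and the denominator sums
over the units currently in the class (`scope = "all"` sums over all
units).  Local models are fitted on the globally standardized data
without re-centring, so residuals — and hence CM values — are comparable
across segments.

The iteration is Ward-initialised.  A subtlety matters here: raw
residuals of the global model have mean zero within *any* segment that
differs from the rest only in its path coefficients, so a Ward cut on
raw residuals is blind to slope-type heterogeneity (we verified ARI ≈ 0
against planted sign-flipped segments).  The initialisation therefore
clusters three standardized channels: the outer residuals, the inner
residuals, and one slope-signature column per structural edge — the
structural residual times the sign of the predecessor score, which is
the unit's (sign-stabilised) contribution to the equation's normal
equations and acquires a segment-specific mean exactly when slopes
differ.  Channels are weighted 1/√p with the slope channel doubled,
because its per-column signal is intrinsically weaker than the residual
channels' under level heterogeneity.

Reassignment sends each unit to its row-minimum CM, with ties kept at
the current segment to help the composition settle.  Iteration stops
when fewer than 0.05% of units move (at n = 216 effectively zero) or
after `max_iter` (default 50 — on well-separated data the rule is
typically met within a handful of passes, comfortably inside the ten to
fifteen a practitioner expects).  When a pass would push a
segment below the minimum estimable size (max(10, parameters + 2)), the
default keeps the segment's best-fitting core units rather than
aborting (`on_small = "fail"` restores the strict behaviour); without
this, a poor initial partition can collapse the iteration before the
reassignment step has a chance to recover.

The group quality index summarises a partition in the GoF pattern:
GQI_outer is the square root of the size-weighted mean pooled
communality of the local models, GQI_inner the square root of the
size-weighted mean R², and the overall GQI their product — with one
segment it collapses to the global pooled GoF.  `rebus_select()`
recommends the G with the largest overall GQI *among candidates whose
reassignment reached composition stability*: an oscillating partition is
not a valid segmentation, and over-segmented runs typically fail to
settle, while their local fits' GQI saturates upward mechanically.

### A note on the recovery ceiling

On the packaged separated fixture (sign-flipped slopes ±0.8), the CM
assignment rule plateaus around ARI 0.85 even when the local models are
fitted on the true segments, while FIMIX — the likelihood classifier on
the same composite scores — reaches ARI ≈ 0.92, about the model-based
ceiling given the composite measurement noise.  The gap is intrinsic to
the CM construction: residual ratios relative to class averages discard
the variance calibration a likelihood uses, and the outer ratio
contributes pure noise when segments share loadings.  Users should
treat REBUS assignments as a fit-based grouping, not a Bayes-optimal
classification.

## FIMIX-PLS

`fimix()` takes the global fit's latent scores as fixed and models the
endogenous equations as a K-component Gaussian mixture: within
component k each equation has its own coefficients and its own error
variance (Ψ diagonal — the inner model is a recursive chain estimated
equation by equation, and independent per-equation errors are the
matching assumption).  Regressions carry no intercepts, consistent with
centred scores; this is also why the synthetic generator never plants
segment-specific score means for mixture benchmarks — a mean-shifted
component would demand intercepts the model family does not contain.

EM alternates posterior updates with weighted least squares; the
log-likelihood trace is monitored and must be nondecreasing (tested to
1e-8 slack).  Mixing proportions are floored at 1e-4 to prevent silent
collapse, a component variance below 1e-8 aborts that restart, and the
best of `n_restarts` (default 10) random initialisations wins; an
optional hard partition (for instance the REBUS assignment) seeds one
extra start.  Components are reported in descending mixing proportion;
hard labels are posterior argmax with ties toward the larger component
(descriptions of mixture assignment occasionally say units join the
segment with the *smallest* membership probability, which is
inconsistent with the entropy logic; the argmax rule is the only
coherent reading and is the one implemented).

Model order is scored by AIC (−2lnL + 2N), BIC (−2lnL + ln(I)·N) and
CAIC (−2lnL + (ln(I)+1)·N), with N = (K−1) + KR and R the number of
inner-model predictors (coefficients only, the literal reading;
`count_variances = TRUE` also counts the K per-equation variances), and
by the normed entropy EN = 1 − Σ −P ln P / (I ln K), which is 1 for
crisp posteriors and 0 for uniform ones.  `fimix_select()` recommends
the K with maximal EN — the rule that favours the crispest separation —
and reports the likelihood criteria alongside, plus a K = 1 baseline
row.

## The synthetic generator

`simulate_pls_data()` draws each unit's segment, propagates
standard-normal exogenous scores through the segment's structural
equations with Gaussian inner noise, standardises scores to their
theoretical variance, emits indicators as λ·score plus N(0, 1−λ²)
measurement error, and finally rescales pooled columns.  One seed drives
label, score and error draws in a fixed order, so tables are
reproducible byte for byte.

Composite scores built from error-laden indicators have reliability
below one, so a PLS refit of latent-level coefficients is attenuated —
with the bundled loadings the middle chain coefficient would converge
near 0.76 rather than its stated 0.829.  Because the coefficient values
a PLS study reports are composite-level estimates, the generator's
default treats the declared coefficients as composite-level estimands
and backs out the latent generating system through the asymptotic block
reliabilities (weights ∝ loadings); a consistency test confirms the
fitted chain recovers the stated 0.390/0.829/0.287 within ±0.02 at
n = 20000.  `target = "latent"` takes coefficients at face value, and
is used automatically when a spec pins `inner_sd` or `r_squared`.

Bundled truths: `nutrition_global_spec()` (the homogeneous chain,
n = 216 by default), `nutrition_segments()` (two segments of proportions
75/216 and 141/216 with moderately different coefficients and loadings —
the *overlapping* regime), and `separated_segments()` (sign-flipped
slopes ±0.8, inner noise sd 0.02, loadings 0.995).  The separated
fixture is deliberately idealised: with per-segment standardized scores
a slope of ±0.8 pins the per-equation R² at 0.64, where even the
Bayes-optimal classifier only reaches ARI ≈ 0.6 — "well separated"
necessarily means near-noiseless structure and measurement.  Score-level
mixture benchmarks use `simulate_mixture_scores()`, which stays on the
raw regression scale so the planted slopes are exactly the
within-segment coefficients.

What the generator does *not* emulate: raw count scales (everything
lives on the standardized scale the estimator consumes), missing data,
non-Gaussian indicator error, and segment-specific score means (see the
FIMIX intercept note).  Passing recovery tests on these fixtures
therefore certifies the algorithms, not robustness to real-data
pathologies.

## Problem sizes and numerical choices

The test and acceptance suites run at the study's scale: n = 216 units,
10 indicators, 20-seed batteries for convergence and model-order
selection, 50 replicates at n = 400 for mixture recovery, 200
simulations with B = 199 resamples for the bootstrap calibration, and
n = 20000 for generator consistency.  Tolerances: weight convergence
1e-6; EM convergence 1e-6 on the log-likelihood with 500-iteration cap;
oracle identities at 1e-10; zero-residual assertions at 1e-10.
Degenerate inputs are rejected with named errors: zero-variance or
missing-valued columns, all-zero outer weights, singular inner
regressions, cyclic path declarations, and segments too small for the
CM degrees-of-freedom correction.

## Limitations

No higher-order constructs, nonmetric scaling, mediation decomposition,
HTMT, blindfolding Q², BCa intervals, or concomitant-variable mixtures.
The REBUS recovery ceiling discussed above applies to any
slope-differentiated segmentation.  GQI values of near-noiseless data
saturate toward 1 across G, which is why segment-count selection leans
on composition stability rather than on the index alone.
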