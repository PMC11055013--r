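---
title: "Methods: sequential polynomial classification of weight trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequential polynomial classification of weight trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weighttraj)
```

## The model and its assumptions

Each participant's weight series is treated as an independent curve-fitting
problem: weight `y` (kg) against the day index `t`, with `t = 1` at the
participant's first retained record. Three nested ordinary-least-squares
polynomials (degrees 1, 2, 3) are fitted per participant. The approach
assumes:

- additive, roughly homoscedastic measurement noise around a smooth
  participant-level mean curve;
- that a cubic is flexible enough to express the clinically interesting
  shapes (one plateau, one reversal, or both) over spans of 11 weeks to a
  year. Seasonal oscillation or multiple regains are out of model;
- no pooling across participants: irregular and unequal sampling is handled
  trivially because nothing requires a common grid, at the price of noisier
  per-participant estimates for sparse series (hence the 5-record minimum).

## Data screening and selection

Record-level screening drops, in order: records with no reported unit,
records with raw weight 0, and records outside 40–250 kg. The bounds are
applied **after** unit conversion (1 lb = 0.45359237 kg) because they are
stated in kg. Participant-level selection then collapses same-day duplicates
to their mean, re-anchors days so the first retained record is day 1,
truncates records beyond day 365, and requires a span `ttotal = tz - t1` of
at least 77 days, no gap above 30 days (a gap of exactly 30 is retained — the
exclusion is "more than 30 days apart"), and at least 5 records. Every
function attaches a consort-style accounting report
(`screening_report()`) whose tallies balance exactly; nothing is dropped
silently.

## Model selection by adjusted R²

The comparison statistic is the Ezekiel adjusted
`R²_adj = 1 - (1 - R²)(n - 1)/(n - p - 1)` with `p` the polynomial degree.
Selection is sequential: m2 vs m1, then m3 against the winner of that
comparison. The more complex model wins only when its **relative**
improvement `(adj_complex - adj_simple)/|adj_simple|` exceeds the threshold
(default 5%). Three deliberate choices:

- *Relative, not absolute change.* A "5% change" is read as a percentage
  change, which makes the rule scale-free near high R² values (an adjusted R²
  above `1/1.05 ≈ 0.952` can never be beaten — a useful parsimony property).
- *Absolute fallback.* When the simpler model's adjusted R² is ≤ 0 the
  relative change is ill-defined (or sign-flipped); the rule then degrades to
  an absolute difference `> threshold`, and the decision trail says so. This
  mainly affects flat, noise-dominated series, where parsimony is the right
  bias anyway.
- *m3 is compared against the m1/m2 winner,* not against m1 unconditionally:
  the sequential reading keeps the comparison chain consistent with
  parsimony. The `trail` column of `select_models()` records every comparison
  so the convention is auditable per participant.

Fitting internally centres and scales `t` (day³ reaches ~5×10⁷ on the raw
scale) and maps coefficients back to raw day units via the binomial
expansion, so reported `beta_k` are in kg/dayᵏ and predictions agree with a
raw-scale fit to well below 1e-8.

## Landmarks

All landmarks come from elementary calculus on the fitted polynomial:

- quadratic stationary point ("nadir") at `-b1/(2*b2)`; a true minimum only
  when `b2 > 0`, callers check the sign;
- cubic: the derivative `3*b3*t² + 2*b2*t + b1` has discriminant
  `D = 4*b2² - 12*b1*b3`; when `D > 0` the stationary points are
  `(-2*b2 ± sqrt(D))/(6*b3)`, reported **time-ordered** (`x1 < x2`) so that
  downstream criteria never depend on the sign of `b3`. `D ≤ 0` means the
  vertices are undefined — a state, not an error.

Both forms are verified in the test suite against dense-grid extremum
searches and finite-difference oracles rather than trusted as algebra.

## The decision tree

The classifier maps (selected model, landmarks) to patterns 1–7. Thresholds
are `K` (kg; default 1 — differences of at most `K` count as "no substantial
change"), `d2` (the quadratic stationary point is "early" when at most
`ttotal/d2`; default 2) and `d3` (cubic first-third / plateau-width divisor;
default 3).

- **m1**: decline of more than `K` → pattern 1; rise of more than `K` →
  pattern 7; otherwise flat (6).
- **m2**: if both `|y_start - y_nadir|` and `|y_end - y_nadir|` are ≤ `K` →
  flat (6). Convex (`b2 > 0`): nadir inside `(0, ttotal)` → 3; nadir ≤ 0
  (rising throughout) → 7; nadir at/after the end (declining throughout) → 1.
  Concave: maximum ≤ 0 → 1; an early maximum (≤ `ttotal/d2`) with net
  decline → 4; otherwise → 7.
- **m3**: no vertices or none inside `(0, ttotal)` → monotone: 1 if the curve
  declines net, else 7. With an interior vertex: flat if both the net change
  and the vertex-to-vertex swing are ≤ `K` (6); `b3 < 0` (min-then-max):
  pattern 2 when the curve declines again after the plateau
  (`y_x2 - y_end > 0`), else 3; `b3 > 0` (max-then-min): pattern 4 when the
  early maximum sits in the first `1/d3` of the span and the initial rise
  exceeds `K`, pattern 5 when the terminal rise returns to within `K` of the
  starting weight, else 3.

Design notes, where the design was genuinely open:

- *Magnitude checks.* The flatness criteria compare magnitudes in the
  direction of the fitted slope. A literal one-sided reading of
  `y_start - y_max ≤ K` would classify every concave fit as flat, because
  that difference is never positive at a maximum.
- *Tie-breaks.* Equality at a threshold (`difference = K`, stationary point
  exactly at `ttotal/d2`) always falls on the "no change" / simpler branch.
- *Windows.* "Interior" means the open interval `(0, ttotal)` in
  participant-relative days.
- *Configurability.* The tree topology is fixed, documented code; the
  thresholds (`K`, `d2`, `d3`) are parameters, and `evaluate_criteria()`
  exposes every criterion value so alternative reconstructions can be
  compared offline. A fully declarative rule-file interpreter was considered
  and rejected: the tree *is* the scientific object under test here, and an
  interpreter adds failure modes without adding testable science.
- Every assignment carries its `criteria_path`, so any label can be traced to
  the exact sequence of criteria that produced it.

## Early prediction

The 14-day predictors are `X1 = (first - last recorded weight within days
1–14)/14` in kg/day (**positive = loss**; with a single record in the window
`X1 = 0` and a sparse flag is set), `X2` = the record count in the window,
`X3 = ttotal`. Raw records are used, not fitted values: the predictor is the
observed early change. The sign convention makes "faster early loss" a larger
`X1`, so the odds ratio for the "no substantial decrease" category is
expected below 1. Note the unit: ORs are per 1 kg/day, an enormous increment
(typical `X1` values are ±0.1), so extreme-looking ORs are a unit artefact,
not instability.

The multinomial logit `log(p_j/p_ref) = x'b_j` is fitted by maximum
likelihood — BFGS on the negative log-likelihood with analytic gradient,
predictors standardized internally and estimates mapped back to the raw
scale (delta-method transform of the covariance). Standard errors are Wald
(inverse numerical Hessian); confidence intervals are `exp(b ± 1.96·SE)`.
Profile-likelihood intervals are deliberately not offered. Convergence and
(quasi-)separation diagnostics are attached to the fit and raised as
warnings, never swallowed: with separated data the Wald output is
meaningless and the `separation_suspected` flag says so. In the two-category
case the fit reduces exactly to binary logistic regression, which the test
suite exploits as an independent oracle (`glm` coefficients and standard
errors must match).

## Validation

Cross-validation is **within-participant**: each participant's records are
randomly partitioned into 10 folds (reduced to the record count, i.e.
leave-one-out, for very short series), the selected degree is refitted on
the training folds, and held-out RMSE/R² are aggregated per participant.
Held-out R² uses the fold's own mean as baseline; folds with fewer than two
test records report RMSE only, and training folds too small to identify the
model are skipped with a flag. Fold assignment is seeded and reproducible.

The sensitivity analysis re-classifies the cohort under perturbed thresholds
(`K` ∈ {0.5, 1.5, 2}; `d2` ∈ {1.5, 2.5}; `d3` ∈ {2.5, 3.5} — read as
divisors of `ttotal` around their defaults) and reports the percentage of
participants whose pattern changes. Model selection is *not* re-run: the
thresholds only enter the classification stage. The analysis is
deterministic, and the default thresholds are a fixed point (0% change) by
construction.

## The synthetic cohort generator

`simulate_cohort()` draws, per participant: a pattern from a default mixture
dominated by the three weight-loss shapes (30.6/15.4/47.2% for patterns
1–3, the remainder spread over 4–7); an initial weight from N(89.4, 22.5²) kg
truncated to [48, 243]; a span `ttotal` uniform on 77–364 days (day indices
are 1-based and capped at day 365, so a span of 365 is unreachable — the cap
keeps every generated series selection-compliant by construction); irregular
observation days with geometric-like gaps truncated at 29 days (mean ≈ 1.4
days, day 1 and the final day always present); and additive N(0, 0.5 kg)
noise. The 0.5 kg default reflects self-reported scale weights: diurnal
variation and clothing produce half-kilogram-scale fluctuation, and it places
cross-validated RMSE in a realistic regime.

Archetype mean curves are exact polynomials, so noise-free archetypes are
fixed points of the whole pipeline (a tested invariant). Amplitudes default
to 8–13% of initial weight (at least 6 kg), chosen once so that landmark
margins dominate the 1 kg threshold. Geometry worth recording:

- pattern 2 (decline–plateau–decline) is the cubic with derivative roots at
  0.35·T and 0.70·T and `b3 < 0`, scaled to the target net loss; the plateau
  hump is ~6% of the loss, comfortably above flat-detection but far from
  pattern-3 behaviour;
- pattern 4 places the early maximum at 0.20·T with the second root beyond
  the span, so the initial rise (~21% of the net loss) exceeds 1 kg;
- pattern 5 places the early vertex at `a·T` with `a = 0.05` and solves
  `1/3 - (a+b)/2 + ab = 0` for the late-minimum position `b·T`, which makes
  the net change over the span exactly zero: the curve dips and returns to
  its start, the defining geometry of "decline with terminal rise".

What the generator does **not** emulate: behavioural feedback (weigh-in
frequency responding to success), heteroscedastic or autocorrelated noise,
digit preference, demographic covariates and their missingness, or dropout
correlated with trajectory. A green archetype-recovery test therefore
establishes that the pipeline recovers curve *shapes* under irregular
sampling and measurement noise — not that it would reproduce any particular
program's empirical pattern shares.

`simulate_prediction_cohort()` draws the three early predictors from
realistic marginals and labels from a user-supplied multinomial logit, for
parameter-recovery testing of the early-prediction model.

## Numerical choices and degenerate inputs

- Quantiles in percentile charts are type 7 (linear interpolation between
  order statistics), R's default; percentile bands are cross-participant
  empirical percentiles of model-predicted weight, never model-based
  prediction intervals, and a participant contributes nothing beyond their
  own last observed day (no extrapolation).
- Fits require `n > degree + 1` and more distinct days than parameters;
  violations are errors, not NA-coefficient fits.
- A quadratic fit with `b2 = 0` exactly has no stationary point; the
  classifier falls back to the linear branch and records that in the
  criteria path.
- Exact-threshold ties in the classifier go to the "no change" branch;
  selection ties (improvement exactly 5%) keep the simpler model.
- All simulation is seed-deterministic; the cross-validation folds derive
  per-participant seeds from the user seed.

## Limitations

- The seven patterns are shape classes of a single cubic fit; trajectories
  with two regain episodes or strong seasonality will be projected onto the
  nearest cubic shape.
- Hard thresholds produce boundary sensitivity by design; the sensitivity
  analysis quantifies it rather than hiding it.
- The early-prediction model is associational. No causal reading is
  supported, and pattern labels derived from the full series are used as the
  outcome, so it is a *prediction of the eventual classification*, not of
  weight itself.
- With very sparse early windows (`X2 = 1`) the early loss rate is set to 0
  and flagged; those participants carry little signal for `X1`.
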