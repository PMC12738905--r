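---
title: "Designing and regulating light recipes for grafting-ready seedlings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and regulating light recipes for grafting-ready seedlings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`graftlight` chains five components: multi-criteria scoring of seedling
grafting suitability, combination weighting, a synthetic growth
simulator (the "plant twin"), forward prediction of morphology from
light recipes, and inverse design plus closed-loop regulation. This
vignette explains the science and the design decisions behind each, in
the package's own terms.

## Scoring and weighting

A grafting machine tolerates only a narrow window of seedling shapes.
The scoring module standardizes heterogeneous indicators onto [0, 1]
with 1 meaning "most suitable": larger-is-better indicators use min–max
scaling, smaller-is-better the reversed scaling, target-value
indicators decay linearly with distance from the target `a` scaled by
the worse of the two sides (`max(a − L_min, L_max − a)`, so the score
reaches exactly 0 at the most distant admissible value), and
target-range indicators hold a plateau of 1 between `s_min` and
`s_max` with linear ramps to the admissible limits. Out-of-range values
are a measurement error for the first three kinds (hard error naming
the indicator); for the target-range kind the outer branch of the
piecewise definition makes them score 0, so no error is raised. When a
target range touches its admissible limit the corresponding ramp is
empty and no division by zero can occur (moisture content ships
configured that way). The default registry encodes a clamp-and-cut
grafting machine — hypocotyl target 50 mm in an admissible 0–150 mm,
stem target range 2.7–3.3 mm in 0–5 mm — and lives in a plain CSV so a
different machine can redefine targets without touching code. One
published source also quotes an optimal stem range of 3–3.5 mm for a
related machine; the registry follows the 2.7–3.3 mm configuration and
leaves the alternative to the configuration file.

Weights come from three routes. AHP turns a Saaty 1–9 pairwise
judgment matrix into its principal right eigenvector (power iteration,
convergence 1e-13), with consistency index `CI = (λ_max − n)/(n − 1)`
and ratio `CR = CI/RI(n)` against the standard random-index table;
`CR ≥ 0.1` warns but does not abort, because re-eliciting judgments is
the caller's decision. Entropy weighting is purely data-driven: on
standardized values, `p_ij = x_ij / Σ_i x_ij`,
`e_j = −(1/ln n) Σ p_ij ln p_ij` (with `0·ln 0 = 0`), and
`w_j ∝ 1 − e_j`, so more dispersed — more discriminating — indicators
weigh more. Standardized rather than raw values feed the entropy chain
so units and directions are already unified. The game-theoretic
combination solves the Gram system `(c_i · c_k) α = (c_i · c_i)` and
normalizes `α`; this is the method's own first-order condition taken
from its published derivation. Note a subtlety: the quantity the
method's motivating objective (total squared deviation from every
input vector) would *exactly* minimize is the plain centroid of the
inputs; the Gram system is the method as defined, and the package
implements and tests the system itself (against a brute-force grid
solve and a hand-solved 2×2 case) rather than the centroid. Negative
combined weights can arise when inputs disagree strongly; because a
negative weight is uninterpretable, the package errors by default and
offers a non-negative constrained solve (`nonneg = TRUE`) rather than
silently clipping. The expert judgment matrices behind published
machine-specific weights are not public, so the package ships an
illustrative matrix encoding the one robustly stated priority:
hypocotyl length and stem diameter dominate everything else, because a
seedling outside the machine's tolerance on either cannot be grafted
at all.

## The plant twin

No public dataset accompanies the cultivation experiments this package
operationalizes, so the twin is a first-class, tested simulator whose
role is to make every downstream stage verifiable. It is a fixture
with the right qualitative physiology, not a biological model.

Both traits follow daily-step logistic growth. Hypocotyl elongation is
rate-driven and path-dependent: the rate rises with the red fraction,
falls with total intensity (Hill form with half-constant 180 µmol),
rises with photoperiod up to a 16 h/d saturation then declines, is
boosted 1.8× during the elongation window (days 5–9), and decays
exponentially after a maturation day (13, time constant 5 d) —
elongation is an early, largely irreversible process, which is exactly
why later recipe-transition timings leave strictly longer hypocotyls.
Stem thickening relaxes toward a light-determined plateau that rises
with the blue fraction (with a mild decline beyond 65 % blue —
combined light outperforms near-monochromatic), rises with intensity
up to a 260 µmol photoinhibition peak, and rises with photoperiod.
Monochromatic blue adds a small elongation boost (toggleable), echoing
the reported anomaly. Noise enters only at measurement
(zero-truncated Gaussian; defaults 0.5 mm hypocotyl, 0.03 mm stem,
the spread of replicate caliper readings), plus a per-plant vigour
factor (1 % CV on the daily rate, the uniformity plant-factory plug
trays are chosen for).

Two calibrations anchor the defaults, both fixed before any testing:
a blue-heavy recipe near (55 red, 151 blue, 14.4 h/d) reaches ≈50 mm
hypocotyl with the stem inside the 2.7–3.3 mm grafting window around
day 25 (the scenario the inverse designer should find plausible), and the design arms' trajectories
bracket the grafting-relevant morphology grid (hypocotyls 40–50 mm
with stems 2.95–3.5 mm) so validation targets are physically
reachable. The emulated design is the real experiment's: 5 light
qualities at 50 µmol, 5 intensities at R:B 50:50, 5 photoperiods at
200 µmol, and 5 recipe-transition timings (days 5–9), sampled on days
5–30 in 5-day steps — 20 treatments in all (three single-factor series
of five plus the five transitions). What the twin does *not* emulate:
temperature, humidity and CO₂ effects (held constant in the emulated
protocol), genotype differences beyond a scalar rootstock/scion rate
factor, and any mechanical-property dynamics. Passing tests therefore
demonstrate the pipeline's correctness and internal consistency, not
predictive validity on real seedlings.

## Forward growth models

Features are (red, blue, photoperiod, day) — light quality enters as
separate channel intensities, matching the decision variables of the
inverse design; ratio and total are derivable. The split is by
sampling occasion: the first `⌈0.8 K⌉` of the K distinct days train,
the remainder test, so evaluation is always a forward extrapolation in
time ("time points" means sampling occasions, and with six of them the
split is days 5–25 against day 30). Augmentation appends one jittered
copy of each training record — Gaussian target noise scaled as 0.01 of
each target's standard deviation (the published constant is
dimensionless; a fraction of the trait's spread is the unit-robust
reading) and multiplicative ±5 % feature jitter — and never touches
the test set.

Four families are built in: ordinary least squares; ridge with penalty
1.0 applied through the closed-form normal equations with an
unpenalized intercept (this matches the convention of the reference
implementation the penalty value comes from, which penalized
unstandardized coefficients — the popular R ridge entry points
rescale the penalty and would silently change it); random forest (100
trees); and gradient boosting (200 rounds, learning rate 0.1, depth 6,
subsample 0.8). Each output gets its own regressor; a comprehensive R²
averages the two output R² values, by default with equal weights —
the combined indicator weighting puts hypocotyl and stem nearly equal
on top, and the equal-weight average is also the only weighting
consistent with the published summary values. Recurrent
sequence models are deliberately out of scope (they underperformed in
the source experiments and would pull in a deep-learning stack); the
`model_spec()` interface documents where an external regressor would
attach.

Hyperparameter search is sequential model-based optimization: a Latin
hypercube seeds the design (always including the incumbent default, so
the result can never be worse on the objective), a Gaussian-process
surrogate with RBF kernel models objective vs hyperparameters, and
expected improvement picks each next candidate. The objective is
5-fold cross-validated MSE, summed over the outputs after dividing by
each target's variance — without that normalization the
millimetre-scale hypocotyl error would drown the stem error. Each
candidate trains with early stopping (50 stagnant rounds, cap 300).
Folds are ordinary shuffled folds under the fixed seed; time-ordered
folds would halve the usable data at these sizes and the final
evaluation is already a pure forward split.

## Inverse design

The designer searches (red, blue, photoperiod, days) within 50–300
µmol, 10–18 h and 3–40 d, minimizing the Euclidean distance in raw
millimetres between the model's prediction and the target morphology —
raw units, because both traits are millimetres here and the published
threshold (0.3) is stated unitless in that scale; a per-trait
normalized mode is available for targets of very different scales.
The evolutionary engine is `best1bin` with a population of 15 members
per dimension (the convention of the reference optimizer's population
multiplier), dither F ∈ [0.5, 1), crossover 0.7, at most 1000
generations, relative-spread convergence tolerance 0.01, bounded
quasi-Newton polish, seed 42. The whole population is evaluated in one
call per generation, so a boosted-tree objective costs one predict
call per generation. Stage 1 archives *every* evaluated candidate
below the error threshold; stage 2 filters that archive for the
fewest days (ties: smaller error, then lower total flux — energy).
Days are continuous during the search and feasibility is re-checked at
the rounded integer day actually cultivated. An optional red/blue
ratio box (default 1/3–3, off by default) is enforced by penalty. A
search that finds nothing feasible returns an explicit infeasibility
result carrying the best candidate — a deployment still needs a
recipe to start from.

A tree-model surrogate is only trustworthy near its training support;
elsewhere its piecewise-constant extrapolations are fantasy. For
desk-top design that does not matter (the reported error is the
model's own), but a design meant to drive a real cultivation should
pass `support` (the training features) to confine the search to the
surrogate's validity region: candidates beyond a normalized distance
threshold are penalized and excluded from the feasible set.

## Closed-loop regulation

The controller runs one cultivation tray: each day the twin cohort
(20 plants by default, each with its own vigour factor) grows a day
under the current recipe, the tray is imaged and the cohort mean
measured, and the measurement is compared with the model's prediction
at the current recipe and day. A violation needs both a >10 % relative
deviation (a grafting robot's stated operational tolerance) and an
absolute deviation beyond the measurement floor (2 mm hypocotyl,
0.2 mm stem) — a tenth of a millimetre on a day-2 stem is a 30 %
"deviation" no camera resolves — and control starts on day 5, the
first occasion the emulated protocol considers seedlings measurable.
Directions follow the rule table (hypocotyl short → red ratio up,
intensity down, photoperiod down; stem thin → the reverse ratio with
intensity and photoperiod up; measured long/thick invert the rules).
When both traits violate at once, the hypocotyl rule takes the
spectral and photoperiod levers and the stem rule the intensity lever:
a hypocotyl outside tolerance fails the graft outright, while
intensity is the stronger stem lever. Step sizes (0.1 of total flux
reallocated, 10 µmol, 0.5 h) are engineering defaults; ratio moves
conserve total flux, and every recipe is clipped to bounds.

The deployment cycle in `validate_target()` mirrors how such a system
is actually commissioned. The design data sample days only every five
days, so a tree model's day axis is a staircase between occasions —
its apparent error at an intermediate day is an artifact. The cycle
therefore alternates design and *calibration cultivations*: each
candidate recipe is piloted open-loop for the full horizon, its daily
records join the training set (resolving the day axis exactly where
the system operates — the published workflow's online accumulation),
the model refits and the design repeats; the deployed (recipe, days)
pair is the one whose pilot measured closest to the target, with the
harvest day read off the pilot log. Only history-free (constant-
recipe) treatments train this model: a memoryless (recipe, day)
feature map cannot distinguish transition treatments that share
features but differ in light history, and their per-feature averages
would bias the design. Evaluation then runs independently seeded
closed-loop cultivations and reports deviations both against the
target and against the model's final-day prediction; the latter is
the quantity a cultivation validation compares (a paired test of
actual versus predicted values), and with a feasible design the two
differ by at most the design error, under a percent of the target.

## Numerical choices and degenerate inputs

Singular Gram systems (collinear weight inputs) fall back to the
least-squares pseudo-solution with a warning. All-uniform entropy
input (no dispersion anywhere) returns equal weights, the formula's
limit. Constant training targets short-circuit the linear families to
a constant predictor. Zero-variance test targets make R² undefined;
it is reported as `NaN` with a warning rather than an arbitrary
number. The twin's Euler step uses a daily grid — the same cadence as
measurement and control — and clamps state at the asymptotes so
trajectories are non-decreasing by construction. Seeds: every
stochastic path (twin noise, augmentation, boosting subsampling, DE,
GP search, closed-loop replication) is reproducible from explicit seed
arguments; the boosting library draws from R's own generator, so seeds
are set immediately before each training call.

## Problem sizes

The shipped defaults are sized for a laptop: the standard twin dataset
is 20 treatments × 6 days × 6 plants = 720 records per organ role
(the scale of one real cultivation season), model fits take a second
or two, a full inverse design under a second, and the nine-target
closed-loop validation with twenty replicate cultivations per target a
few minutes. The test suite exercises reduced versions of everything.

## Known limitations

* The twin's parameter values are fixture calibrations, not estimates;
  only their signs and thresholds carry meaning. Conclusions about
  real seedlings require refitting the forward model on real records.
* The forward feature map is memoryless; recipe-transition treatments
  can be simulated and scored but not faithfully learned by the
  forward model (they are excluded from deployment training).
* The controller's fixed step sizes are not optimized; re-planning
  (re-running the inverse design mid-cultivation) is available as a
  flagged alternative in the deployment workflow but is not the
  default, to keep runs reproducible.
* Environmental factors other than light are out of scope, as in the
  emulated protocol.
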