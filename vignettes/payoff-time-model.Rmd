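---
title: "The payoff-time model of saccade reaction times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The payoff-time model of saccade reaction times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saccadepay)
library(dplyr)
```

## The problem

Saccadic reaction times (SRT) to stepping targets are not fixed
reflexes: they lengthen dramatically — by 100 ms and more — when the
target is large relative to its step size. When eccentricity `e` and
target diameter `D` are combined into the unitless ratio `e/D`, median
SRT collapses onto a single decreasing function of that ratio, falling
as a power law up to `ratio = 1` and plateauing beyond it ("proximal
procrastination": nearer or larger targets are foveated later). This
package implements a normative account of that phenomenon, a
generator for synthetic datasets with the same statistical structure,
and the decision-model machinery needed to test the account on choice
behaviour.

## The model

A saccade latency is split into two stages. Stage 1 is a fixed sensory
detection and selection window, `T_s = 80` ms for the suprathreshold
targets considered here; its exact value trades off against the scaling
constant below and is not separately identifiable. Stage 2 is a linear
rise-to-threshold accumulator (LATER-style) whose rate is drawn once
per trial from a normal distribution; reciprocal stage-2 latency
("promptness") is therefore normally distributed, which is the
recinormal law that makes reciprobit plots linear.

The contribution is what sets the accumulator's **mean** rate: a
cost/benefit heuristic. Foveating a target at eccentricity `e` buys a
resolution gain `b = 1 - r_e/r_0`, where `r_e` is the target's average
visual resolution viewed peripherally and `r_0` its average resolution
once foveated. The cost is the saccade's duration `T(A)` (vision is
suppressed during the movement). The **payoff-time**

```
PT = T(A) / (1 - r_e/r_0)
```

is the post-saccadic time at which the information gained by moving
overtakes what staying put would have delivered. The model posits that
motor preparation is prioritised inversely to this quantity: the
threshold-normalized mean rate is `mu = 1/(k * PT)`, so the stage-2
median is exactly `k * PT`, with a single free scaling constant `k`
per setup (and per direction where nasal/temporal asymmetries matter).

Predicted median SRT for a condition is then

```
SRT(e, D) = T_s + k * T(e) / (1 - r_e(e, D) / r_0(D))
```

with the saccade amplitude taken equal to the target-center
eccentricity.

### Ingredient curves

*Resolution.* Within the foveola (point targets stepping fractions of
a degree) resolution follows reciprocal cone spacing:
`151.7/sqrt(1 + 3.19 e)` on the temporal meridian and
`148.7/sqrt(1 + 3.27 e)` on the nasal. Beyond the foveola, where
several cones converge on each ganglion cell, the package uses the
standard direction-averaged peripheral estimate normalized to
`1/(1 + 0.365 e)`. Extended (ring) targets use the peripheral family.

*Movement cost.* Saccade duration follows the main sequence. Below 4
degrees it is a power law, `T_R = 10^1.21 A^0.25` (rightward/temporal)
and `T_L = 10^1.22 A^0.33` (leftward/nasal); above 4 degrees it is
quasi-linear, and the package either continues the power law or
switches to a linear extension (default slope 2.2 ms/deg, the classic
large-amplitude value, continuous at the break). The linear mode is
what produces the empirically familiar SRT rise beyond ~9-10 degrees
(the "bowl" shape), because duration cost keeps growing while the
foveation benefit saturates.

*Urgency (deadline).* Task instructions that emphasise reacting add a
deadline process. It is modelled as a linear growth of the
accumulation rate with time since target onset,
`rate(t) = mu (1 + u t)`, giving the closed-form stage-2 median
`(sqrt(1 + 2 u k PT) - 1)/u` (implemented in the cancellation-free
form `2 k PT / (sqrt(1 + 2 u k PT) + 1)`, exact as `u -> 0`). A
collapsing decision bound is an equivalent formulation; only the
rate-acceleration variant is implemented. Urgency is referenced to
target onset, not fixation onset; the alternative is not identifiable
from median-level fits.

### Averaging resolution over extended targets

How to average resolution over a ring target is genuinely open: the
locus of the thin ring itself, the enclosed disc, or the horizontal
chord are all defensible. All three are implemented. The package
default for model predictions is the **disc area**, for a numerical
reason discovered when implementing the alternatives: averaging the
peripheral resolution function over the ring *locus* makes the
off-center average *exceed* the centered average for large rings at
small steps (the function is convex, and the near arc dominates), so
the foveation benefit `1 - r_e/r_0` turns negative for `D >= 8` at
ratios below about 0.5 and the model is undefined exactly in the
regime the proximal-procrastination data occupy. Disc averaging is
strictly positive and monotone everywhere tested, and preserves the
qualitative structure (benefit decreasing in `D` at fixed `e`,
curves collapsing on `e/D`). `ring_average_resolution()` still
implements the ring locus exactly, and `foveation_benefit(mode =
"ring")` reproduces the degeneracy as an explicit error.

`r_0` for an extended target is the average resolution of the same
target centered at the fovea — the peak resolution for that target
size — so the benefit of a ring of diameter `D` never reaches 1 even
at infinite eccentricity.

Quadrature is a deterministic midpoint rule (256 angular nodes by
default, 64 radial nodes for the disc). At 256 nodes, doubling the
node count changes averages by less than 1e-6 except exactly at the
kink cases `e = D/2` (where the integrand's distance function touches
zero), which are still accurate to ~1e-5.

## Fitting

`fit_payoff_model()` minimises the squared error between observed and
predicted per-condition median SRTs with Nelder-Mead from the fixed
start `k = 4` (`u = 0.001` when free), on log-scale parameters so
positivity is structural. Medians, not means, are the fitting target
throughout: the median of a recinormal is `T_s + 1/mu` exactly, so
median-level fits are robust to the skew of the latency distribution.
One free parameter (`k`) suffices for the foveolar data; the second
(`u`) captures instruction-induced urgency for the ring experiments.

## The race model of free choice

Two simultaneous targets each drive their own accumulator with the
rate statistics inferred from that target's single-target trials. With
equal thresholds, the unit drawing the larger rate wins, so the choice
probability is the closed form `Phi((mu1' - mu2') / sqrt(sigma1^2 +
sigma2^2))`. Two-choice latencies are slower than single-target ones;
the package models this as **mutual inhibition**: both mean rates are
scaled by a factor `beta` in `(0, 1]`, leaving the rate SDs untouched.
This choice matters: scaling the mean alone is a parallel shift on
reciprobit axes (the observed signature of the two-choice effect),
whereas a threshold/start-level account would scale mean and SD
together and swivel the line about its infinite-time intercept, and a
pure delay would steepen it about a point between median and
intercept. `hick_mechanism_test()` fits all three three-parameter
accounts by maximum likelihood (with the reciprocal-transform Jacobian
included so the likelihoods are comparable on the latency scale) and
refuses to pick a winner within 2 log-units ("indeterminate"). In the
simulation studies the three generators are matched in effect size:
rate scaling 0.85, delay +37 ms, and threshold scaling chosen so the
median shift also equals 37 ms at the reference rates — comparable
effects, cleanly discriminated at 480 trials per condition.

Directional bias (some observers prefer rightward targets) enters as a
signed rate offset on whichever unit's target is on the right,
estimated by pooling rightward-choice counts across conditions (the
bias is treated as ratio-independent) and inverting the race formula.
Predictions average over the counterbalanced left/right placements, so
a side bias cancels to first order in the condition-level prediction.

The **priority index** locates an observed choice probability between
the salience-by-proximity benchmark (always choose the nearer target:
`cp = 0` when the competing target is nearer, `1` when the reference
target is) and the race-model prediction:
`(cp_obs - cp_salience) / (cp_model - cp_salience)`. The verbal
definition it implements — the proportion of choices explained by the
race given the measured rate variability — pins its anchors (1 at the
race prediction, 0 at salience, above 1 beyond the race preference)
and this is the simplest form with those properties; it is also
invariant under a common affine rescaling of all three probabilities.

## The synthetic-data generator

`generate_experiment()` builds complete trial tables with the
published designs: the 27-condition ring grid (3 diameters x 8 shared
eccentricities plus 3 fill-ins, 15 distinct ratios, 24 repetitions,
non-ageing foreperiods), the 30-condition foveolar grid (15
eccentricities x 2 directions, 52 repetitions for the 1560-trial
session total, uniform 800-1300 ms foreperiods), and the free-choice
design (11 single conditions x 44, 8 choice pairs x 120). Non-ageing
foreperiods are a truncated exponential on 620-1510 ms whose rate is
solved numerically for a 1000 ms mean (bounds and mean are published;
the rate is not).

Stage-2 latencies are drawn from a recinormal whose median equals the
payoff-time prediction for that condition, so "medians follow the
model" holds by construction and every downstream fit has a known
truth. Defaults chosen once for the unpublished knobs: rate
variability `sigma/mu = 1/6` (typical of latency data of this kind);
10% lognormal between-participant jitter on `k`; mutual inhibition
`beta = 0.85`; 7% planted invalid trials (the published aggregate
exclusion rate), planted in rotation across anticipatory, too-slow,
wrong-direction and blink and resampled so valid trials stay inside
the 80-600 ms window, keeping validity bookkeeping exact. The ring
templates default to `k = 4` with urgency `u = 0.1`, which keeps
predicted medians within the validity window across the whole ratio
grid (135-390 ms); the foveolar template uses the printed constants
(`k` 4 temporal / 3.6 nasal, `u = 0`). With disc averaging, the
model's predicted dynamic range across ratios is steeper than the
published empirical curves (the generator is a model world, not a
reproduction of the deposited data), so descriptive statistics
computed on synthetic data — power-law constants, the scale-effect
magnitude — characterise that model world.

Gaze traces are 500 Hz positions with a scaled-logistic saccade
profile rising from 0.5% to 99.5% of amplitude across the
main-sequence duration, plus Gaussian position noise. The logistic is
a detection fixture, not a kinematic theory: it gives realistic peak
velocities and sharply localised threshold crossings. What the
generator does *not* emulate: oculomotor drift and microsaccades
during fixation, pupil artefacts, vertical components, express
saccades, sequential dependencies, or any departure of real observers
from the payoff-time law itself — so green tests certify the
machinery, not the biology.

## Preprocessing conventions

Velocity is a central difference over `i ± separation` samples
(default 1, exposed because real trackers need wider stencils to beat
instrument noise: at 500 Hz the default stencil turns 0.05 deg of
position noise into ~18 deg/s of speed noise, which swamps the
thresholds; at 0.01 deg — typical of good video trackers — onsets of
saccades of 1 degree and larger are recovered to within 2 ms).
Saccades are marked when speed exceeds 15 deg/s for at least two
consecutive samples, with start/end where it falls below 10 deg/s;
the sub-threshold tails this clips cost a few percent of amplitude.
Offline validity filters: latencies below 80 ms (anticipatory) or
above 600 ms (too slow) — both bounds exclusive, so 80 and 600
themselves are valid — wrong initial direction (single-target trials
only; on choice trials either side is a legitimate choice), and any
blink between fixation start and first-saccade offset. When several
apply, blink takes precedence, then anticipatory, too-slow,
wrong-direction.

## Numerical choices and edge cases

* Truncated-normal rates (resampling at zero) keep latencies finite; a
  warning fires when `sigma/mu > 0.5` and truncation visibly distorts
  recinormality.
* Reciprobit plotting positions are Hazen, `(rank - 0.5)/n`, with
  midranks for ties; ties are never dropped.
* `fit_recinormal()` uses the maximum-likelihood (`n`-denominator) SD
  of promptness after subtracting the stage-1 window; `t0_ms = 0`
  recovers the classic no-subtraction convention.
* Binomial confidence intervals are exact Clopper-Pearson throughout
  (the published analyses state binomial limits without naming a
  method; exact is reproducible and correct at the 0/1 boundaries).
* The mutual-inhibition fit matches observed two-choice SRT deciles to
  analytic race quantiles (root-finding on the product-of-normals CDF
  of the max rate), Nelder-Mead from `beta = 0.9`; estimates at the
  `[0.5, 1]` search bounds raise a boundary warning.
* AUC separation is the midrank Mann-Whitney statistic, so
  `auc(A, B) + auc(B, A) = 1` holds exactly under ties.

## Problem sizes used in the shipped checks

The test suite and the acceptance script regenerate everything from
seeds at the published design sizes where those are what is being
checked (1560 foveolar trials per participant, 960 choice trials, 480
trials per condition for mechanism discrimination) and at smaller
sizes where only the machinery is being exercised. Replicate counts
for the simulation studies are 100 (parameter recovery, mechanism
classification) and 50 (end-to-end free-choice loop with one
simulated participant per replicate).

## Known limitations

* The disc-averaging default is a package decision where the original
  averaging rule is unstated; ring and chord modes are provided for
  sensitivity analysis, and ring mode is genuinely unusable for large
  rings at small ratios (documented error).
* Only the LATER (rate-variability) accumulator is implemented; no
  drift-diffusion variant.
* The urgency form is one of several observationally similar deadline
  mechanisms; fits of `u` should be read as effect sizes of urgency,
  not mechanism identification.
* Gap/overlap paradigms are treated only as additive SRT offsets;
  they are not generated or modelled.
* The race model is strictly two-alternative with symmetric
  inhibition.
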