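---
title: "Methods: foot placement control and local dynamic stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: foot placement control and local dynamic stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitstab)
```

This vignette is the package's own account of the science it implements:
the models, the constants, the design choices that were genuinely open, and
what the synthetic validation does and does not show about real recordings.

## The foot placement control model

During walking, lateral balance is maintained largely by choosing where to
place the swing foot relative to the body's center of mass (CoM). The
step-to-step component of that control is captured by a linear model fitted
over the steps of an analysis block:

$$FP = \beta_{pos}\,CoM_{pos} + \beta_{vel}\,CoM_{vel} + \varepsilon$$

where $FP$ is the demeaned mediolateral placement of the new stance heel
relative to the previous stance heel measured at midstance (i.e. the
demeaned step width), and $CoM_{pos}$, $CoM_{vel}$ are the demeaned
mediolateral CoM position and velocity relative to the stance foot at
terminal swing. Two outcome measures summarise each block:

* the **degree of foot placement control**: the relative explained variance
  $R^2$ of the model;
* the **magnitude of foot placement error**: the standard deviation of the
  residual $\varepsilon$ (in meters; reports usually format it in mm).

$R^2$ is relative — it can be inflated or deflated by the total placement
variance — so the residual sd complements it as an absolute measure of
placement precision.

Two conventions are deliberate choices rather than consequences of the
model, and both are configurable points in the code:

* **Intercept.** The regression includes an intercept even though all
  columns are demeaned. When demeaning is exact the intercept estimate is
  zero and changes nothing; when the demeaning grouping upstream differs
  from the fit grouping (e.g. fitting across several blocks at once) it
  keeps the residual mean exactly zero, so the variance decomposition
  $\mathrm{sd}(\varepsilon)^2 + \mathrm{explained} = \mathrm{total}$ holds
  as an invariant. Whether the original analyses included one is not
  documented anywhere we could check; with exact demeaning the two choices
  coincide.
* **Denominator.** The residual sd uses $n-1$, the ordinary sample
  convention. With block sizes of 60 steps the difference from $n$ is about
  1%.

## From markers to the stride table

The pipeline needs only three markers: both heels and a thorax marker that
serves as CoM proxy. The coordinate convention is fixed package-wide: `ml`
mediolateral (positive right), `ap` anteroposterior (positive in the
walking direction), `vert` vertical (positive up); meters and seconds
everywhere internally.

**Filtering.** All signals are low-pass filtered with a bidirectional
(zero-phase) Butterworth filter, 10 Hz cutoff by default, before
differentiation or event detection. Ten hertz comfortably preserves gait
content at 100 Hz sampling while suppressing marker noise; the cutoff is a
parameter of every entry point.

**Events.** A heelstrike is detected as a local maximum of the heel's
anteroposterior position relative to the thorax — the standard kinematic
treadmill method. Candidates closer than 0.4 s on the same side are
resolved in favour of the larger excursion, events within 0.5 s of the
record edges are dropped, and left/right alternation is enforced by
discarding the weaker of two consecutive same-side events.

**Sampling instants.** Two instants per step are not observable directly
and had to be defined:

* *Terminal swing* is taken as the instant of the swing foot's heelstrike
  (a configurable backward offset is available). Heelstrike is the only
  unambiguous instant available from kinematics, and the CoM state sampled
  there is the state the landing foot could last have responded to.
* *Midstance* is the temporal midpoint between a heelstrike and the next
  contralateral heelstrike. Other definitions (e.g. vertical-excursion
  based) can be substituted by editing the events table before
  `build_stride_table()`.

Both definitions are potential sources of small systematic differences
against analyses that used force-plate events or different instants.

**Side pooling.** Left and right steps are pooled into one regression per
block. To make that side-invariant, values are demeaned per block *and
side* (removing any left/right asymmetry) and left steps are then mirrored
(mediolateral sign flipped) so that "wider than usual" is positive for both
sides. A fully left-right mirrored recording therefore yields an identical
stride table, which the test suite asserts.

**Blocks.** One row of the stride table is one step; a stride is two
consecutive steps; an analysis block is 30 consecutive strides (60 steps)
within a condition, and incomplete trailing blocks are left unassigned.
A step belongs to a condition only when both of its defining heelstrikes
fall inside the condition window, so strides spanning window boundaries
(e.g. between concatenated training bouts) are dropped. Steps whose stride
time falls outside [0.4, 3] s are flagged and excluded from fits.

## The local divergence exponent

Local dynamic stability is quantified by the local divergence exponent
$\lambda$ of the mediolateral CoM velocity — the short-term, finite-time
analogue of the largest Lyapunov exponent. Lower $\lambda$ means nearby
trajectories in state space separate more slowly: more stable gait. The
estimator follows the standard nearest-neighbour divergence-tracking
scheme with the conventional gait parameterisation, all constants exposed
in `lde_params()`:

1. time-normalize the signal so that a stride is 100 samples long *on
   average* (one global resampling between the first and last left-leg
   heelstrike; no per-stride warping);
2. embed in a 6-dimensional state space with 25-sample delayed copies;
3. for each point with at least 1000 future samples, find its 5 nearest
   Euclidean neighbours among points at least half an average stride
   (50 samples) away in time;
4. track $\ln\|x_{i+s} - x_{j+s}\|$ for $s = 0\ldots999$ and average over
   all pairs;
5. the exponent is the least-squares slope of that curve over its first 50
   samples (half a stride).

Numerical choices:

* **Zero distances** occur for exactly periodic inputs (the synthetic
  noise-free walker); distances are floored at $10^{-12}$ before the log so
  the curve stays finite. The floor is configurable.
* **Admissibility.** The neighbour itself must also be trackable for the
  full horizon; a pair is tracked completely or not used at all, so every
  curve sample averages the same pair set.
* **Ties** in neighbour distance are broken toward the smaller index, which
  makes the search deterministic and lets the test suite require exact
  agreement with an $O(n^2)$ brute-force oracle.
* **Theiler window** is applied symmetrically ($|i-j| \ge w$); an
  asymmetric (forward-only) exclusion would only enlarge the candidate set
  with time-reversed twins of excluded pairs.
* The divergence average pools all reference–neighbour pairs rather than
  averaging per reference first; with a fixed neighbour count the two
  weightings coincide except for skipped references.
* Natural logarithms are used; the exponent is reported per normalized
  sample and, multiplied by 100, per stride.

Calibration, re-run in the test suite and the acceptance script: the $r=4$
logistic map (known Lyapunov exponent $\ln 2$ per iterate) is recovered
within 0.07 using a 2-dimensional, delay-1 embedding; an exactly periodic
synthetic walker yields $|\lambda| \le 0.005$; and per-cycle jitter
strictly raises $\lambda$ across seeds.

Within a session the exponent is computed once per condition by default.
Per 30-stride block it is feasible (3000 normalized samples against a
1000-sample horizon) but leaves few reference points, so the per-block
variant is offered behind `lde_scope = "block"` and averaged over blocks.
For conditions recorded as several bouts, each bout is time-normalized
separately and the normalized segments are concatenated; the handful of
pairs straddling a junction is diluted by all others, but users comparing
against bout-wise analyses should be aware of the choice.

## The synthetic walker

Every stage of the pipeline is validated against a generator whose ground
truth is known exactly. Its defaults are the study conditions the analysis
is designed for: stride time 1.1 ± 0.02 s, step width 0.10 m, foot
placement gains $\beta_{pos} = 1.5$, $\beta_{vel} = 0.30$ s, placement
noise $\sigma_\varepsilon = 5$ mm, CoM state variability 10 mm / 0.05 m/s,
100 Hz sampling. The gain and noise magnitudes are in the range reported
for healthy adults walking on a treadmill; the CoM variability values are
order-of-magnitude choices for a typical participant, not estimates of any
particular population, and are documented as such.

Design decisions, in the generator's own terms:

* **CoM states are drawn i.i.d. per step** (sign-flipped by side so sway
  alternates in the lab frame). The placement model only constrains the
  step-wise linear mapping, and i.i.d. draws make ordinary-least-squares
  recovery bounds analytic — the ±0.1 recovery bounds asserted in the tests
  are validated by a 1000-repetition Monte-Carlo in the suite itself. An
  AR(1) option (`com_phi`) provides temporally correlated sway for
  divergence-sensitivity experiments.
* **Step durations** are drawn as independent half-stride normals so that
  same-leg stride times are normal with the configured mean and sd while
  both legs' heelstrike times remain well defined.
* **The thorax trajectory is a cubic Hermite spline** through each step's
  CoM position with the drawn CoM velocity as knot slope. A monotone
  interpolant was considered to rule out overshoot, but it cannot honour
  prescribed knot derivatives, and without them the generator's CoM
  velocity ground truth would be unrecoverable downstream; overshoot
  between knots is harmless because nothing is sampled there.
* **The heel's lateral transition is confined to the second half of
  swing**, so at the moment the contralateral midstance is sampled the
  trailing heel still marks its previous placement and placement measured
  at midstance equals the generated placement. The anteroposterior profile
  is a symmetric triangle wave (linear belt-back in stance, linear return
  in swing) whose apex marks the contact instant under zero-phase
  filtering.
* **Terminal swing in the generator is the heelstrike instant**, mirroring
  the analysis-side definition, so generator and analyzer agree by
  construction.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: pendulum mechanics or ground reaction forces, soft
tissue and marker artefacts, drift in treadmill position, double-support
timing (each foot's lateral position is idealised as constant through
stance), and any physiological coupling between consecutive CoM states
beyond the optional AR(1). The generator validates the *estimators*, not
the biomechanics.

## Problem sizes

The suite and the acceptance script size their simulations to run on a
single CPU in a few minutes while keeping sampling error far from the
asserted bounds: 300-stride truth tables for parameter recovery (the
Monte-Carlo uses 1000 repetitions of the same size), 200 rendered strides
for event detection, 45-stride renderings for each divergence estimate, and
a 5000-sample logistic-map series. All randomness flows through explicit
seeds; the acceptance script derives every simulation from its `--seed`
argument.

## Known limitations

* Event detection is purely kinematic; against force-plate timing it can
  carry a systematic offset of a few milliseconds, which cancels in stride
  times but not in the terminal-swing instant.
* The midstance and terminal-swing definitions above are reasonable but not
  unique; analyses using other instants will differ slightly in $FP$ and
  CoM state values.
* Whether demeaning should be per 30-stride block or per condition is not
  settled; per block (and side) is implemented because outcomes are
  computed per block.
* The divergence exponent on 30-stride blocks is noisy; the per-condition
  default trades temporal resolution for stability of the estimate.
* C3D files are not read directly; trajectories must be exported to the
  package's CSV dialect.
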