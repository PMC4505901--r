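---
title: "Identifying the composition of wrist motor commands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying the composition of wrist motor commands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristdecon)
```

## The model

The wrist is treated as a linear viscoelastic joint with two degrees of
freedom (flexion/extension on the x axis, radial/ulnar deviation on y).
Joint torque can be written two ways — from the muscles, and from the
movement:

$$\tau(t) \;=\; \sum_{i=1}^{4} a_i\,T_i(t)
        \;=\; M\,\ddot\theta(t) + B\,\dot\theta(t) + K\,\theta(t)$$

where $T_i(t)$ are the normalized tensions of the four wrist prime movers
(ECR, ECU, FCU, FCR), $a_i$ convert tension into torque (their signs are
constrained by each muscle's pulling direction), and $M$ (kg·m²), $B$
(Nm·s/rad), $K$ (Nm/rad) weight the acceleration-, velocity- and
position-proportional torque components. $M$, $B$, $K$ are scalars shared
by both axes, while each axis gets its own four muscle weights — the
simplest structure that fits both axes with one set of joint dynamics.

Joint torque itself is never measured, so absolute values of $B$ and $K$
are unidentifiable: any common rescaling of $(M, B, K)$ can be absorbed by
the $a_i$. What *is* identifiable is their ratio. The central quantity is
therefore $B/K$, the relative weight of velocity- versus
position-proportional drive in the motor command: $B/K \ll 1$ means
position-dominated commands (typical of rapid step tracking toward a fixed
target), $B/K \gtrsim 1$ means velocity and position contribute comparably
(required for tracking a target that moves with known velocity). The
damping ratio $\zeta = B/(2\sqrt{KM})$ is reported alongside because it is
invariant to the common scale.

## Signal conditioning

Raw surface EMG is full-wave rectified and low-pass filtered
(second-order Butterworth, cutoff 3.0 Hz) to estimate muscle tension.
Three numerical choices matter here:

* **Zero-phase filtering.** The filter is applied forward and backward
  (`signal::filtfilt`), because any group delay between the tension
  envelopes and the kinematics would bias a correlation-based
  identification. The filter family is a package choice; only the order
  and cutoff are fixed by the processing convention.
* **Constant end padding.** Plain forward–backward filtering implicitly
  pads with zeros. A trial that ends on a held posture ends at a non-zero
  level, and zero padding then injects a large end transient whose
  *derivative* dominates uncentered cross-products. Every channel is
  therefore padded with its own endpoint value (2 s) before filtering and
  trimmed after. Padding by an endpoint value is linear in the signal, so
  any linear identity among channels (such as the model above) is
  preserved exactly by the filter.
* **A common filter for both sides.** Tensions and angles pass through the
  *same* linear zero-phase filter. Applied to both sides of a linear
  model, filtering preserves the model exactly; applied to one side only,
  it would manufacture spurious misfit.

Tensions are normalized so that the envelope amplitude during a reference
isometric contraction of 0.78 Nm maps to 1.0, and the mean normalized
tension during the central-position hold is subtracted, putting zero at
the resting posture. Baseline-subtracted tensions can therefore be
slightly negative; they are passed through unchanged. (Keeping activities
"positive or zero" and subtracting a central baseline are mutually
inconsistent demands; we resolve them in favour of a well-defined zero at
the central position, and treat the no-intercept convention of the CCA —
below — as the way the positivity of raw envelopes is respected.) Small
negative envelope excursions from filter ringing are clipped to zero
*before* normalization.

Angles arrive in degrees and are converted to radians at the processing
boundary; everything model-facing is SI. Velocity and acceleration come
from central differences (one-sided at the endpoints) of the filtered
angle. Signals band-limited at 3 Hz are vastly oversampled at a 2 kHz
acquisition clock, so processing decimates to a 100 Hz working rate (any
integer divisor of the acquisition rate works); this makes the CCA and the
grid search cheap without information loss.

## Identification by uncentered CCA

The two torque expressions are two linear combinations — of the tension
channels and of the kinematic channels. Canonical correlation analysis
finds the weight vectors maximizing the correlation between them. Two
conventions matter:

* **No centering.** Cross-products $X'X$, $X'Y$, $Y'Y$ are computed
  without mean subtraction, so the zero of the tension scale (the resting
  posture) is meaningful rather than being absorbed into means.
* **Stacked axes.** By default one CCA pools both axes: the kinematic
  design holds (acc, vel, angle) rows for axis x then axis y sharing one
  $(M, B, K)$, while the tension design is block-structured so each axis
  keeps its own four muscle weights. A per-axis mode (two independent
  CCAs, ratios averaged) is also provided, since pooling versus averaging
  is a genuinely open choice; on model-consistent data the two agree.

The solution whitens with Cholesky factors of the uncentered
cross-products and takes an SVD; singular values are the canonical
correlations of all pairs, and the first pair's squared share of their sum
is reported (`eigen_proportion_first`). Weights are sign-normalized so the
elastic coefficient is positive and scale-normalized so $K = 1$; the
reported quantities are the ratios $B/K$ and (when the acceleration column
is included) $M/K$. Rank-deficient designs are ridge-regularized with a
relative epsilon of 1e-8 and a warning. Sign constraints on the $a_i$ are
*not* imposed inside the CCA (mirroring an unconstrained no-intercept
canonical analysis); fits whose muscle-weight signs violate the muscle
table are flagged post hoc. Trials whose peak excursion stays at or below
1° are excluded as containing no movement.

## Identification by grid search

The search-based route asks a sharper question: does a *specific*
$(B, K)$ pair fit better than others with the same ratio? For every pair
on a physiological grid ($0 \le B \le 10$ Nm·s/rad, $0 \le K \le 10$
Nm/rad, step 0.2), the kinematic torque is formed with the subject's hand
inertia $M = 7mr^2/5$ (hand modeled as a uniform sphere of density
1.0 g/ml rotating about an axis on its surface), the muscle weights are
fitted by sign-constrained least squares per axis, and the arithmetic mean
of the two axes' uncentered correlations is recorded. The $B=K=0$ cell is
skipped (torque would be the near-zero inertial term alone).

The constrained solver enumerates all $2^4$ zero/free active sets exactly
— small, deterministic, and verifiable against an independent nonnegative
least-squares route — rather than iterating to a tolerance. Since the
muscle weights absorb any common rescaling of $(B, K)$ whenever the
inertial term is negligible, the correlation surface forms a ridge along
rays of constant $B/K$; the scientifically meaningful output is the ridge
ratio. Because a 0.2-step grid cannot express fitted values of order 0.1,
a refinement pass evaluates log-spaced ratios through the best cell and
reports the refined ratio; the coarse surface is kept for contour
rendering.

## Group statistics

Per-subject, per-task ratios are summarized (mean, SD with $n-1$, range)
and compared between groups with a Mann–Whitney U test and a Student
two-sample t-test. The U test computes exact two-sided p-values by dynamic
programming over the null distribution of U for untied samples with
$n_1 + n_2 \le 40$, and otherwise uses mid-ranks with the tie-corrected
normal approximation and continuity correction (the convention of common
statistics toolboxes). Within groups, the overlap of the two tasks' ratio
ranges is reported: disjoint ranges mark intact task-dependent switching
of the command composition; overlap marks its loss. A single value has
undefined SD (reported as `NA`). Per-direction tests in the agonist
analysis are not corrected for multiple comparisons, matching the
reporting convention of this literature.

## Direction tuning and agonists

Preferred directions are estimated by cosine fitting
$m(d) = b_0 + b_1\cos(d - \mathrm{pd})$ to the mean activity in each of
the eight step directions (classically a ±25 ms window around movement
onset); the fit is linear in $(b_0, b_1\cos\mathrm{pd},
b_1\sin\mathrm{pd})$ and pd is wrapped to $[0, 360)$. Tuning is flagged
unreliable when the cosine terms are not jointly significant. Movement
onset is the first time tangential speed exceeds 5% of its trial peak and
stays there for 50 ms.

Agonists for a direction are the muscles whose preferred direction lies
within 67.5° of it, keeping at most the two nearest (with the default
preferred directions one direction would otherwise collect three), with a
nearest-muscle fallback when the window is empty. The agonist-correlation
analysis then correlates each agonist's tension, from onset to the end of
the trial, with the displacement along the target direction and with the
tangential speed, averaging across agonists when there are two. Both the
assignment window and the correlation window are package choices; the
source analyses leave them unstated.

## The synthetic-data generator

No recordings ship with the package, so every identification and
statistics stage is validated by parameter recovery on model-consistent
virtual subjects:

* **Step task**: minimum-jerk point-to-point movements of 18° amplitude in
  the eight canonical directions (0.4 s movement, variable 1–2 s central
  hold, 1.5 s target hold), three repetitions per direction.
* **Pursuit task**: one lap of a smooth closed figure-eight (2:1 Lissajous
  $x = 10\sin 2\psi$, $y = -8\cos\psi$, spanning ±10° × ±8°) traversed at
  a constant tangential speed of 6.2°/s by arc-length parameterization,
  preceded by a central hold, a transit to the path's upper-left extreme,
  and a start hold; five repetitions. The real task's path shape is not
  recoverable from text, so any smooth closed path at the stated speed is
  acceptable; the start anchor is approximated by the path's upper-left
  extreme point.
* **Torque-to-tension inversion**: the joint model produces torque from
  the kinematics; the positive and negative torque on each axis is then
  carried by the antagonist muscle pair pulling that way, with the pair's
  shares solved so their off-axis components cancel exactly. A
  co-contraction term (default tension 0.05) lies along a nonnegative null
  vector of the weight matrix, adding activity with zero net torque. The
  reconstruction $\sum_i a_i T_i = \tau$ is exact to rounding before
  noise.
* **Noise**: multiplicative log-normal noise on the tension envelopes
  (signal-dependent, EMG-envelope-like; default SNR 20 dB) and additive
  white noise on the recorded angles (SD 0.02°).
* **Cohorts**: per-subject, per-task ratios are drawn from the group
  distributions (controls 0.17 ± 0.06 step and 1.30 ± 0.27 pursuit;
  patients 0.24 ± 0.10 and 0.54 ± 0.28; truncated at 0.02), with $B =$
  ratio × $K$ at task scales $K$ = 0.090 (step) and 0.085 (Nm/rad,
  pursuit), and hand inertia drawn from the spherical model at radius
  0.049 ± 0.002 m. The default design is 10 controls and 19 patients; the
  validation suite uses 100 virtual subjects (both tasks each), a size at
  which the whole recovery run takes well under a minute per 30 subjects
  on one CPU.

What the generator does *not* emulate, and hence what passing tests do not
show about real data: motor-unit physiology behind the EMG envelope
(envelopes are modeled directly), neural tuning of muscle *activity*
preferred directions away from the mechanical pulling directions (the
generator's muscles respond exactly along their pulling vectors at
45°/315°/225°/135°, whereas measured activity PDs — the packaged defaults
68°/125°/189°/265° — are rotated away from them; synthetic agonist
analyses therefore use the pulling-direction table), trajectory
irregularity of ataxic movement (patient subjects differ only in their
ratio distributions), electrode crosstalk, and any activation dependence
of $B$ and $K$ within a task.

Two measured properties of the synthetic conditions deserve note. First,
the inertial premise: dropping the acceleration term changes pursuit
ratios by at most a few percent (inertial torque share ≈ 0.035 of the
elastic share), but rapid 0.4 s steps transiently violate
$M\lVert\ddot\theta\rVert \ll K\lVert\theta\rVert$ (share ≈ 0.2), and
step ratios then shift by several percent more — the with/without
agreement is therefore asserted where its premise holds. Second, the
first canonical pair carries ≈ 0.99 of the eigenvalue sum on step data
but ≈ 0.91 on pursuit data; the second pair (cc ≈ 0.3) arises from the
rectified positive/negative tension parts themselves and persists at zero
noise. Both numbers are recomputed, not assumed, by the test suite and
the acceptance script.

## Reproducibility

Every stochastic stage takes an explicit seed; a cohort regenerated under
the same seed is bit-identical. Command-line outputs carry the package
version and seed. The bundled reference tables (per-subject ratios of 10
controls and 19 patients for both tasks, and example $(M, B, K)$ fits)
make the group statistics and damping-ratio computations runnable with no
synthesis at all.

```{r}
cmp <- compare_groups(reference_cohort())
print(cmp)
with(reference_fits(), damping_ratio(M, B, K))
```

## Known limitations

* Absolute $B$ and $K$ are not estimable by design; all downstream
  statistics operate on ratios.
* The uncentered CCA is unconstrained; pathological data can return
  muscle weights that violate pulling-direction signs (flagged, not
  repaired). The grid-search route enforces the signs.
* The exact Mann–Whitney distribution assumes no ties; tied data fall
  back to the corrected normal approximation even at small $n$.
* The generator's step trajectories are minimum-jerk; dysmetric or
  intermittent trajectories are out of scope for recovery validation.
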