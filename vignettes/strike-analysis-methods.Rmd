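---
title: "Methods: strike kinematics and kinetics with strikelab"
author: "strikelab authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strike kinematics and kinetics with strikelab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(strikelab)
```

## The measurement problem

A striking snake accelerates its head and anterior body toward a target in
tens of milliseconds. On a flat, rigid substrate the propulsive reaction
must come through friction: Coulomb's criterion predicts slip whenever the
ratio of horizontal to vertical ground force exceeds the substrate friction
coefficient, $|F_{FA}|/F_V > \mu$. The package analyses trials in which a
snake strikes from a force platform (six-axis force/torque record at
1 kHz) while an overhead high-speed camera (500 frames s$^{-1}$) records
head and tail positions in dorsal view, with the camera trigger recorded on
the force clock for synchronization. Two platform conditions are compared:
an *open* featureless plane, and a *walled* platform whose vertical
surfaces behind the snake can brace the body.

From each trial the pipeline computes thirteen strike variables plus
strike duration: maximum fore--aft, lateral, vertical and total force (in
body weights, BW $= F/(mg)$); maximum head velocity and acceleration;
fore--aft impulse over the strike; strike distance; maximum tail velocity,
acceleration and displacement along the strike axis; the maximum FA/V
force ratio; and the percentage of the strike spent above the slip
threshold. A momentum budget then formalises the *inertial appendage*
hypothesis: momentum gained by the head must be balanced by ground impulse
plus rearward counter-momentum of the tail and posterior body.

## Pipeline

`analyze_strike()` runs, per trial:

1. **Synchronization** (`synchronize_trial()`): the force time base is
   shifted so the camera-trigger sample sits at $t = 0$; video frame 1 is
   at $t = 0$ by construction. Only timestamps change.
2. **Strike direction**: the strike frame is defined by the overall
   direction of head travel over the 10 video frames following onset,
   $\theta = \operatorname{atan2}(\Delta y, \Delta x)$. Because onset
   itself is defined on the fore--aft velocity — which requires the frame —
   the implementation is two-pass: a provisional direction is taken from
   the (large, high-SNR) head displacement around peak speed, velocity is
   projected onto it, onset is detected on that signed projection, and the
   10-frame rule is then applied at the detected onset using the smoothed
   head path. Detecting onset directly on head *speed* is avoided: a
   magnitude has a positive noise floor and triggers early, which would
   shrink the direction window into the pre-strike segment.
3. **Rotation** (`rotate_to_strike_frame()`): the planar axis rotation
   $x' = x\cos\theta + y\sin\theta$, $y' = -x\sin\theta + y\cos\theta$
   maps the strike direction to $+x'$ (fore--aft); the vertical channel
   passes through. Forces rotate as free vectors, positions about the
   onset head position. The sensor and camera frames are assumed
   co-registered (a fixed extra rotation can be composed in if a rig
   requires it).
4. **Smoothing** (`fit_smoothing_spline()`): every channel is fitted with
   a cubic smoothing spline, smoothing parameter chosen by generalized
   cross-validation. Splines rather than recursive filters avoid end
   effects on non-cyclic records; velocity and acceleration are the
   spline's analytic derivatives, never finite differences of raw
   samples. Forces are splined on the 1 kHz grid, kinematics on the
   500 Hz grid; metrics evaluate all splines on the recorded 1 kHz
   sample grid (evaluating a near-interpolating spline *between* samples
   wiggles at sharp features such as the friction-capped force plateau).
5. **Strike window** (`detect_strike_events()`): onset is the first time
   the fore--aft head velocity exceeds $\max(5\%\ \mathrm{of\ peak},
   0.05\ \mathrm{m\,s^{-1}})$ and holds for $\ge 10$ ms, backtracked to
   the preceding zero crossing or local minimum; the end of forward
   progress is the first post-peak time with $v \le 0$ (last sample, with
   a warning, if it never returns). Both times are then refined by a
   local quadratic fit around the threshold crossings: a smooth strike
   starts and ends with near-zero acceleration, so velocity approaches
   zero *tangentially* and the raw first-crossing time is
   noise-dominated, while the quadratic root is exact for a tangential
   approach. The fit window adapts to the local slope and to the velocity
   noise estimated from the pre-strike quiet segment. All thresholds are
   arguments with the defaults above.
6. **Metrics** (`compute_metrics()`): "maximum" follows peak semantics —
   the largest interior local maximum of the smoothed channel inside the
   window, falling back to the window maximum with a flag. Impulse is the
   trapezoidal integral of fore--aft force over the window. The slip
   statistic is computed from the *raw* rotated samples: at the friction
   boundary the capped ratio equals $\mu$ exactly and smoothing jitter
   would flip boundary samples above threshold. Samples with vertical
   force below 0.05 BW are excluded from the ratio (unstable near zero
   load) and counted as excluded. Vertical force is reported untared
   (resting body weight included), matching vertical maxima of roughly
   1.5--1.7 BW in recorded strikes; a `tare` switch subtracts the 50 ms
   pre-onset baseline.

## Synthetic trials

Because raw animal trials are not redistributable, every stage is
exercised against a generator with analytic ground truth.

**Mechanistic mode** (`generate_two_mass_trial()`): the body is reduced to
two point masses. The head mass $m_h$ (default 30% of total mass — the
literature gives no tail-mass fraction, so this is an explicit, adjustable
modelling choice) follows a minimum-jerk path
$x(\tau) = D(10\tau^3 - 15\tau^4 + 6\tau^5)$, chosen because its extrema
are closed forms usable as oracles: peak speed $1.875\,D/T$, peak
acceleration $(10/\sqrt{3})\,D/T^2$. The horizontal ground force is
$F_{FA} = m_h a_h + m_t a_t$ and the vertical force is body weight plus a
smooth half-sine bump (default peak 0.5 BW, so vertical maxima reach
$\approx$1.5 BW). In the walled setup the tail is braced ($a_t = 0$). In
the open setup the tail point mass recoils exactly enough to hold
$|F_{FA}|/F_V$ at or below $(1 - 0.02)\,\mu$: a hard clamp exactly at
$\mu$ would leave half the boundary samples above threshold after any
symmetric sensor noise, so the cap carries a 2% margin, and the clamp is a
$C^1$ quadratic saturation (engaging from 60% of the cap) rather than a
corner — corner-free tail accelerations are both more physiological and
recoverable by spline differentiation. A scenario whose required recoil
exceeds a plausibility bound (default 500 m s$^{-2}$) is rejected with the
binding sample named. Velocities are accumulated by the trapezoidal rule
on the sample grid so that the impulse--momentum identity
$\int F_{FA}\,dt = m_h \Delta v_h + m_t \Delta v_t$ holds to machine
precision on the noiseless series. Gaussian noise (defaults: 0.02 N per
force sample; 1 px $=$ 1 mm per digitised coordinate) is added under the
scenario seed; identical seeds give bit-identical trials.

**Direct-profile mode** (`generate_direct_profile_trial()`): force
channels follow stated closed forms (half-sine, trapezoid, constant,
piecewise) so that calibration targets — peak forces, impulse
$2F_0T/\pi$ for a half-sine, exact slip fractions — are true by
construction rather than emergent.

**Cohort mode** (`generate_cohort()`): per-trial metric values from the
additive mixed model grand mean $+$ setup effect $+$ individual $+$
setup$\times$individual $+$ residual, for calibrating the statistics.

Default scenario values are the recorded study conditions: $D = 0.21$ m,
mass 0.5863 kg, $\mu = 0.30$, 1 kHz/500 Hz sampling, four individuals
with about six trials per setup. The published summary means are not
jointly consistent with one minimum-jerk trial (0.21 m in 57 ms implies a
*mean* speed of 3.68 m s$^{-1}$, above the reported *peak* of
3.32 m s$^{-1}$ — real strikes are not minimum-jerk), so the default
duration is $T = 0.12$ s, which makes the minimum-jerk peak speed
$1.875 \times 0.21/0.12 = 3.28$ m s$^{-1}$ match the reported mean peak
speed; calibration trials for duration use $T = 57$ ms with $D$ set from
the peak-speed relation instead.

What the generator does *not* emulate: a continuous, frictionally coupled
body (two point masses only — the momentum budget's residual reports the
cost of that abstraction); autocorrelated sensor noise; digitisation
dropouts beyond short gaps; out-of-plane motion; strike-direction
curvature. Passing recovery tests therefore shows the pipeline is correct
for strike-like signals, not that real digitisation error is white.

## Momentum budget

`compute_momentum_budget()` evaluates, over onset $\to$ peak fore--aft
head velocity (the interval in which the head *gains* its momentum; over
the full window the head's net velocity change is $\approx 0$ and a
relative residual would be meaningless):

$$m_h \Delta v_h + m_t \Delta v_t - \int F_{FA}\,dt = \text{residual}.$$

The peak time is located by direct maximisation of the velocity spline
(not grid argmax) and the impulse integrated on a 10-fold refined grid,
keeping the noiseless relative residual below $10^{-3}$. The residual is
always reported, never absorbed. `classify_strategy()` labels the strike
ground-dominated, mixed, or tail-dominated by the fraction of head
momentum balanced by tail counter-momentum (cut-offs 0.25/0.75,
adjustable).

## Statistics

Per variable, `mixed_anova()` fits the two-way mixed model with setup
fixed and individual and setup$\times$individual random. For balanced
tables the classical expected-mean-squares tests are used: setup and
individual against the interaction mean square, interaction against the
residual ($F$-ratios verified in the tests against hand-computed sums of
squares). For unbalanced tables the model is refitted by REML
(`lmerTest`) with a Satterthwaite denominator for the setup effect and
likelihood-ratio tests for the random terms; exact agreement between the
two routes is expected only for balanced data. `brown_forsythe()` is
Levene's test on absolute deviations from group medians (via `car`),
reported both pooled across individuals and within each individual, since
"greater variation in one setup" admits both readings. `holm_adjust()`
applies the step-down Bonferroni correction across the variables of one
test family. Under the null at the study design size (4 individuals, 6
trials per cell), Monte-Carlo rejection rates of both tests at
$\alpha = 0.05$ fall within [0.03, 0.07] (the Brown--Forsythe
calibration uses iid groups; individual random effects are a true
violation of variance homogeneity of the pooled groups, not a test
defect).

## Numerical choices and limitations

* Problem sizes used in the shipped tests: single trials of 0.42 s
  (421 force samples), Monte-Carlo suites of 150--1000 replicates —
  enough for the binomial error of a calibration rate to sit well inside
  the stated bands.
* Detector timing accuracy is physics-limited by the tangential zero
  approach: at sub-pixel digitisation noise (0.5 px) and the recorded
  mean strike duration, 95% of windows land within 5 frames of truth; at
  a full pixel of noise, or for slow gentle strikes, errors of 10--20 ms
  occur and the direction estimate degrades likewise ($\sigma_\theta$
  scales with noise over 10-frame displacement). Noiseless recovery is
  sub-millisecond.
* The sign of tail extremum metrics is unstable when the recoil profile
  is nearly symmetric; magnitudes are the robust quantity (displacement
  keeps its sign, rearward negative).
* Degenerate inputs: zero-motion trials raise "no strike detected"
  rather than returning zero metrics; all-excluded slip windows, empty
  impulse windows, sparse ANOVA cells, and infeasible open-setup recoil
  all raise named errors.
* Torques are parsed and carried but unused (no centre-of-pressure
  analysis); no 3D kinematics; no continuum body model.

## A worked example

```{r example}
sc <- strike_scenario(setup = "open", seed = 1)
trial <- generate_two_mass_trial(sc)
fit <- analyze_strike(trial)
fit
coef(fit)
budget <- compute_momentum_budget(fit, c(head = 0.3, tail = 0.7))
budget
classify_strategy(budget)
```

```{r plot, fig.height = 7}
plot(fit)
```

Cohort-level comparison on simulated metric tables:

```{r stats}
d <- generate_cohort(4, 6,
                     grand_mean = c(max_fa_force_bw = 0.64,
                                    pct_above_slip = 22),
                     setup_effect = c(max_fa_force_bw = 0,
                                      pct_above_slip = -30),
                     between_individual_sd = c(0.1, 5),
                     interaction_sd = c(0.1, 5),
                     residual_sd = c(0.2, 10), seed = 2)
strike_stats(d, variables = c("max_fa_force_bw", "pct_above_slip"))
```
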