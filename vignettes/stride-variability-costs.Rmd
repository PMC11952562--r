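---
title: "How stride-to-stride variability inflates walking cost estimates"
author: "stridecost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How stride-to-stride variability inflates walking cost estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stridecost)
```

## The question

Human walking is never perfectly periodic: every stride differs a little in
timing, amplitude and force profile. When metabolic cost is estimated from
motion and force data, it is common to collapse many strides into a single
*averaged gait pattern* — map each stride to 0–100% of the gait cycle,
average channel-by-channel at each cycle fraction, and remap the mean
waveforms to the mean stride period — and to evaluate the cost of that one
synthetic stride. Because the effort and metabolic cost functions in use are
(largely) convex in torques, forces and activations, Jensen's inequality
says the cost of the mean pattern is at most the mean of the per-stride
costs: averaging first systematically *underestimates* the cost, and the
gap is a model-based estimate of the metabolic price of stride-to-stride
variability. A single randomly chosen stride, by contrast, errs in either
direction by whatever the stride-to-stride dispersion happens to be.

`stridecost` implements that comparison end-to-end on synthetic data:

* **method 1** — cost of a single (randomly selected) stride;
* **method 2** — cost of the averaged gait pattern;
* **method 3** — mean of the per-stride costs, the gold-standard reference.

Two cost models are evaluated: a torque-squared effort,
$\dot E = \frac1T \int_0^T \sum_j a_j \tau_j(t)^2 \, dt$ (weights $a_j = 1$),
and a four-term muscle metabolic model (mechanical fiber work plus
activation, maintenance, and shortening/lengthening heat) driven by
static-optimization muscle states. A feedback-controlled inverted-pendulum
walker provides the same story in a minimal dynamical setting: sensory or
motor noise raises both the mean stride cost and its dispersion.

## The synthetic gait generator

Validating every stage against real treadmill recordings is out of reach
for a self-contained package, so the generator emulates the *structure* of a
multi-subject treadmill dataset: ~2-minute trials (60 strides by default),
100 Hz motion and force sampling, speeds around 0.8–1.2 m/s, several dozen
strides per trial, and vertical forces that drop below the 30 N detection
threshold during every swing phase. The nominal single-cycle template uses
closed-form curves with the canonical features of sagittal gait — a
double-humped vertical ground reaction force whose cycle mean over both
feet equals body weight, braking-then-propulsive fore-aft force, anterior
heel-to-toe centre-of-pressure progression under a foot that translates
with the belt, and joint-angle waveforms with the usual stance/swing
morphology. Cycle duration shortens and amplitudes grow mildly with speed.

Stride-to-stride variability is layered on top as:

* a per-stride period drawn around the nominal (default sd 0.02 s);
* one shared multiplicative amplitude factor per stride (default sd 0.035)
  applied to the kinematic deviations and to the fore-aft force, so
  kinematics and kinetics co-vary roughly coherently, plus a vertical-load
  redistribution between the two force humps that survives the per-stride
  body-weight renormalization;
* a per-stride phase offset (default sd 0.006 cycle);
* a low-order (3-harmonic) random Fourier series added to each angle
  channel (default sd 0.02 rad) — smooth within-stride waveform noise;
* optional white measurement noise (defaults 0.003 rad, 1.5 N).

Stride joins are blended with a 50 ms cosine crossfade, so the trial is
continuous; with every noise term zero the generator emits an exactly
stride-periodic signal, which anchors the null tests (all three methods
must then agree to well below 0.1%). The default magnitudes were fixed once
so that single-stride cost errors in the default experiment span the
several-percent to ~15% range reported for treadmill walking, with
stride-period variability at the few-percent level typical of steady gait.
What the generator does *not* emulate: dynamic consistency between
kinematics and kinetics (real data lacks it too, which is why
residual-reduction steps exist), 3D and medio-lateral mechanics,
marker-level noise structure, and drifts such as a participant slowly
migrating on the belt. Passing tests therefore demonstrate the averaging
phenomenology and the pipeline's correctness, not fidelity to any specific
subject.

## Data preparation

The preparation chain follows standard gait practice: a 4th-order
Butterworth low-pass at 6 Hz applied forward-backward (zero phase; channels
are de-meaned and mirror-padded so constants pass exactly), heel strikes
detected as upward 30 N crossings debounced at 0.4 s, a seeded uniformly
random window of $N_{stride}+1$ consecutive left heel strikes segmented
into $N_{stride} = 5$ strides, cubic resampling onto a 101-point gait-cycle
grid, and centre-of-pressure repair during swing (vertical force < 30 N) by
a monotone cubic interpolant through the stance samples. The CoP repair is
inconsequential for the kinetics because the associated forces are
essentially zero — the package tests that the torque effort is unchanged to
below 1e-6 between different swing interpolants. The grid size (101) and
the cubic interpolant are conventional choices; averaging on the grid is a
per-point arithmetic mean and the averaged pattern inherits the mean stride
period.

## Inverse dynamics and the effort cost

A seven-segment planar sagittal model (head-arms-trunk, bilateral thigh,
shank, foot) is scaled from body mass and stature with de Leva-style
proportion tables; masses sum exactly to body mass. Bottom-up Newton-Euler
recursion per leg (foot, shank, thigh) with ground reaction forces applied
at the centre of pressure yields the six sagittal moments (bilateral hip,
knee, ankle); accelerations come from central differences of the filtered
signals, one-sided at the ends. The pelvis residual closing the chain is
computed but excluded from the effort sum, which covers the six joints
only. A full 3D musculoskeletal model would change absolute numbers but not
the averaging structure that drives the comparisons — the effort statistic
needs only joint moments, and convexity of the squared-torque integrand is
what makes method 2 a systematic underestimate.

## Muscle states and the metabolic model

Muscle redundancy is resolved by per-sample static optimization: minimize
the sum of squared activations subject to the net-moment constraint at
every joint, activations in [0, 1]. With a rigid tendon and constant moment
arms the fiber kinematics are fixed by the joint angles, force is linear in
activation, and the per-joint problem has a closed-form KKT solution (with
iterative capping at full activation; torques beyond the available strength
leave an explicitly reported residual). This replaces forward-dynamic
tracking controllers used with full musculoskeletal models: it is the
standard torque-distribution counterpart, it preserves the convex
activation-to-cost mapping that drives the headline result, and it keeps
absolute costs model-specific rather than comparable to published absolute
values — directional and comparative results are the target. The default
muscle set has eight muscles per leg (hip: iliopsoas, glutei; knee: vasti,
rectus femoris, hamstrings; ankle: soleus, gastrocnemius, tibialis
anterior) with literature-scale strengths chosen so normal walking stays
within capacity; two-joint muscles are represented by their dominant
single-joint action.

The energetics model decomposes the rate per muscle into mechanical fiber
work ($F \cdot v$, shortening positive) plus activation, maintenance, and
shortening/lengthening heats, using the published coefficient family:
activation+maintenance heat $128 \cdot ft + 25$ W/kg at full activation
(40% booked as activation heat, 60% as maintenance, the latter following
the force-length curve above optimal length), $A^{0.6}$ activation scaling
for those terms, $A^{2}$ for shortening heat, shortening coefficients
$100/v_{max,ST}$ and $153/v_{max,FT}$ with $v_{max,ST} = v_{max,FT}/2.5$,
lengthening coefficient $4 \times 100/v_{max,ST}$ with $A^{1}$ scaling, and
an aerobic scale of 1.5. In the modified form used by default the
whole-muscle rate is clamped non-negative; the clamp adjustment is booked
into the shortening/lengthening term so the four terms always sum to the
total, and a `clamp_total = FALSE` switch exposes the unclamped variant.
The basal rate is excluded by default (the comparison statistics are
differences and ratios); `include_basal` adds a constant. One modelling
consequence worth knowing: because the activation/maintenance heat scales
as $A^{0.6}$, the total rate as a function of required force is convex only
in the loaded regime (roughly above a quarter of capacity at appreciable
shortening velocity) and mildly concave very near zero force. The package's
convexity probe therefore samples the loaded range; the observed
underestimation by the averaged pattern is nevertheless robust in the
default experiment because the cost-relevant muscles operate well inside
the convex regime.

## The experiment and its statistics

The default layout mirrors a multi-participant treadmill protocol: 8
synthetic participants (mass 72.66 ± 13.51 kg, height 1.759 ± 0.061 m,
truncated to plausible ranges) × 3 speeds (0.8, 1.0, 1.2 m/s) × 1 trial,
with per-participant and per-trial seeds split deterministically from one
master seed. Per trial, `compare_methods()` reports the three estimates and
percent errors relative to method 3 (the denominators the package uses
throughout). Aggregation covers per-speed and pooled paired t-tests of
method 2 against method 3 (reported as mean ± s.e. percent difference),
sign-agreement counts, the single-stride error range, and an ordinary
least-squares regression of errors on speed. Degenerate cases are resolved
by convention and flagged: all-tied pairs give t = 0, p = 1; a constant
non-zero difference is a certain case (p = 0); a perfectly constant
regression response gives slope 0 with p = 1.

## The inverted-pendulum walker

Stance is an inverted pendulum ($\ddot\theta = \sin\theta$ in
nondimensional units with mass, leg length and gravity equal to one),
traversed from $-\alpha$ to $+\alpha$ where the step length is
$s = 2\sin\alpha$. Because stance is conservative, the implementation
advances the state with the exact energy integral
$E = v^2/2 - \cos\theta$ and obtains the stance duration by fixed 48-node
Gauss-Legendre quadrature of $1/v(\theta)$ — stance-phase energy is
conserved to machine precision by construction, and the mid-stance speed
follows in closed form, $v_{mid}^2 = v_0^2 - 2(1 - \cos\alpha)$. The
step-to-step transition applies an impulsive push-off $P$ along the
trailing leg followed by an inelastic heel-strike,
$v^+ = v^-\cos\Phi + P\sin\Phi$ with $\Phi$ the inter-leg angle; push-off
work is $P^2/2$. Stride cost adds an empirical swing cost $c_1 f^4$ per
step ($f$ = step frequency).

The nominal gait minimizes cost per distance over step length at fixed
average speed, with the push-off pinned by the periodic-gait condition
$P = v_0 \tan\alpha$. Long steps are infeasible at a given speed — the
pendulum would have to graze the vertical — so the optimizer first locates
the feasible window on a coarse grid and refines inside it. The swing-cost
coefficient was set once to $c_1 = 0.001$, which puts the optimum at step
length 0.49 L with mid-stance speed 0.25 at the default speed 0.4
$\sqrt{gL}$: comfortably interior to the feasible window, so the noisy
walker does not ride the fall boundary. (Pushing the optimum to ~0.6 L at
this speed would place it essentially on the feasibility edge, where any
noise causes falls.)

Deviations from nominal are corrected by a linear mid-stance-speed feedback
law: step length gain +1.0 and push-off gain −0.6 per unit sensed speed
deviation — walk too fast and the walker lengthens the next step (larger
heel-strike loss) and pushes off less. These gains contract perturbations
by roughly half per step, stable under the largest default noise. Sensory
noise perturbs the sensed mid-stance speed; motor noise perturbs the
executed push-off and foot placement. The default sweep uses five levels
(0, 0.0025, 0.005, 0.01, 0.02 nondimensional) per noise type, chosen so
falls are negligible across 50 replicates of 500 strides; with zero noise
every stride cost equals the nominal optimal cost exactly, and because the
nominal gait is a strict local minimum (positive curvature, verified
numerically), any small-support noise raises the expected cost — which the
sweeps confirm with bootstrap confidence, together with the growth of the
stride-cost standard deviation. Trials that fall are flagged, truncated at
the fall, and counted separately.

## Numerical choices and degenerate inputs

* Filter transients: channels are de-meaned and mirror-padded (2 s) before
  the forward-backward pass; analysed stride windows additionally exclude
  1 s at each trial end.
* Interpolation: cubic splines for gait-cycle resampling; monotone cubic
  for CoP repair; both exact on the stance samples they pass through.
* Static optimization tie-breaks: antagonists are never activated at the
  optimum (they only raise the objective); infeasible demands saturate
  activation at 1 and report the torque residual rather than failing.
* Heel-strike debounce 0.4 s; crossings at series boundaries are excluded.
* Zero-variance paired differences and exactly collinear regressions are
  reported with explicit conventions (see above) instead of NaN.
* Walker degenerate states (balanced upright rest) are flagged as
  degenerate, distinct from falls (failure to pass vertical).

## Problem sizes

The shipped tests and the acceptance script run the analysis at the scale
the package documents as its defaults: 24-trial experiments (8 × 3 × 1)
with 60 generated strides per trial and 5 analysed strides; 1000
random trajectory sets for the convexity check; 50 replicates × 500
strides per noise level for the walker sweeps; 10,000 strides for the
energy-conservation audit. A full default experiment takes a few seconds
on one core.

## Known limitations

Absolute metabolic values are not calibrated to indirect calorimetry and
are not comparable to published whole-body costs; only directions,
dispersions and percent comparisons are meaningful. The reduced planar
model omits 3D joint mechanics, two-joint muscle coupling, tendon
elasticity and activation dynamics. The generator's variability is
stationary by construction — systematic drifts (fatigue, belt-position
migration) that can push the averaged pattern's cost in either direction
are absent, which is precisely why the synthetic sign-agreement statistic
is cleaner than what messy real data would give.
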