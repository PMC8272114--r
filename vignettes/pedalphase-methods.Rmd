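---
title: "Evaluating cyclic event detection: models, parameters and design choices"
author: "pedalphase authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating cyclic event detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedalphase)
```

## Scope

`pedalphase` evaluates how accurately and precisely an algorithm detects
recurring trigger events — 10, 40, 60 and 90% of the pedalling cycle —
from a single thigh-inclination angle channel, the signal an inertial
sensor on the thigh provides during FES-cycling. This vignette documents
the models, the tunable parameters and the choices made where the design
was genuinely open. It states no empirical result beyond what the package's
tests and acceptance script themselves compute.

## The baseline reference

The ground truth for evaluation is an a-posteriori linear phase. Cycles run
from one extension peak (signal maximum — by convention the fully extended
leg) to the next. Within a cycle:

* the **flexion half** runs from the extension peak (phase 0) to the
  flexion peak (phase 50); with peak values $A_e$ and $A_f$ the phase of a
  sample with angle $\theta$ is
  $50\,\arccos(u)/\pi$, $u = 2(\theta - A_f)/(A_e - A_f) - 1$;
* the **extension half** runs from the flexion peak to the next extension
  peak $A_e'$ (phase 100), with phase $100 - 50\,\arccos(u)/\pi$ under the
  same normalisation against $A_e'$.

The arc cosine linearises the phase because the underlying motion is
circular: for an exactly raised-cosine cycle the result is exactly linear
in time, which is also how the event-time oracle in the test suite is
built. $u$ is clipped to $[-1, 1]$ before the arc cosine: interpolated
samples can overshoot a peak's value by rounding, and clipping is the
minimal fix. A cycle in which a half has zero angle range cannot be
normalised; it is flagged and excluded rather than patched.

**Peak detection.** The segmentation uses an alternating-extremum scan: a
running extremum becomes a peak once the signal has reversed by a
prominence threshold. Defaults: prominence = 25% of the observed signal
range, minimum extension-peak separation 0.5 s (half the shortest
plausible cycle at the 60 RPM upper end of FES-cycling cadence). The scan
enforces ext/flex alternation by construction and picks up the boundary
extrema of a recording, so a recording of $n$ full cycles yields $n + 1$
extension peaks.

**Partial cycles** before the first and after the last extension peak are
marked out-of-cycle and produce no targets; how a study counts such
fragments is a reporting convention, and excluding them is the conservative
choice.

## Input conditioning

Recordings arrive irregularly sampled (the motivating system averages
63 Hz; at 60 RPM its 16 ms period spans 1.6% of a cycle). All analysis
runs on a uniform grid obtained by linear interpolation, 1000 Hz by
default, where the inter-sample spacing is 0.1% of such a cycle. No
extrapolation is performed beyond the recorded span — extrapolating would
fabricate data. Duplicate timestamps are rejected rather than averaged.

## The estimators

**BSgonio** (online, causal). Thresholds anchored to the latest extension
peak: $Th = L_{pk\_ext} - (ROM - (\cos(2\pi x) + 1)\,ROM/2)$ for detection
phase $x$. The range of motion is preset (default 40°) rather than
measured; with $x = 0.10$ this puts the threshold 3.82° below the peak. An
online peak is confirmed once the signal reverses by the hysteresis
(default 4°, 10% of the default ROM — the standard causal confirmation
rule; the threshold crossing that may fall between a peak and its
confirmation is recovered by interpolation over the already-seen samples).
Levels below 0.5 fire on downward crossings during the flexion descent,
levels at or above 0.5 on upward crossings during the extension ascent —
the geometry of the threshold equation, whose $x$ and $1-x$ thresholds
coincide in angle. Each level fires at most once per extension-to-extension
epoch. A preset ROM wider than the true one pushes near-peak events deeper
into the cycle (10% late, 90% early), which the test suite checks against
the closed-form inversion of the raised cosine.

**Hilbert** (offline). The instantaneous phase of the analytic signal of
the mean-removed angle, mapped to percent:
$\big(\arg(\mathrm{hilbert}(\theta))/\pi + 1\big)\times 50$. The analytic
signal is computed by the standard FFT half-spectrum construction (no
installed R package provides it). Mean removal matters: the formula assumes
a zero-mean oscillation and the thigh angle has a large DC offset. Note the
convention mismatch this mapping creates: the analytic argument is 0 at the
signal *maximum*, so a raw application puts the extension peak at phase 50
while the baseline puts it at 0. The pipeline therefore rotates the Hilbert
phase by −50 points (`rotate_phase()`) before extracting events; without
the rotation every Hilbert event would sit half a cycle from its target.
Being non-causal, Hilbert serves as a control method, not a real-time
candidate; its phase is also distorted within roughly half a cycle of the
record edges, which the tests exclude when checking tone linearity.

**GCI Observer** (online, causal). The equations of the original
gait-cycle-index observer are not public in a usable form, so the package
implements a transparent variant consistent with its published behaviour —
a sine reference model compared against the measured angle and angular
velocity, producing a linear phase in real time:

1. running midpoint and amplitude estimates (exponential averaging, time
   constant `amp_tau_s` = 3 s, warm-started as a running mean so the first
   cycles are usable) normalise the angle to $\theta_n$;
2. the finite-difference velocity is low-passed at `vel_lp_hz` = 5 Hz and
   normalised by the current frequency estimate to $\dot\theta_n$;
3. the measured phase for the reference model $\theta_{ref} = \cos\varphi$
   is $\varphi_m = \mathrm{atan2}(-\dot\theta_n, \theta_n)$;
4. the observer integrates
   $\hat\varphi \leftarrow \hat\varphi + (\hat\omega + k_{phase}\,e)\,\Delta t$
   and adapts $\hat\omega \leftarrow \hat\omega + k_{freq}\,e\,\Delta t$
   with the wrapped error $e = \mathrm{wrap}(\varphi_m - \hat\varphi)$.

Defaults $k_{phase} = 5\,\mathrm{s^{-1}}$, $k_{freq} = 2\,\mathrm{s^{-2}}$,
$\hat\omega_0 = 2\pi/2.62\,\mathrm{rad\,s^{-1}}$ (the typical passive
cadence) give lock within about three cycles on a steady tone and track a
20→30 RPM cadence step within five cycles — both checked in the tests. All
gains are config-exposed. Because this is a documented variant, any
quantitative result published for the original observer is not a
reproduction target for this package. When the running amplitude falls
below `amp_floor_deg` (0.5°) the signal is treated as flat and the phase
held, flagged rather than guessed. The observer accepts input up to
1000 Hz.

**Warm-up.** Events from an estimator's first epoch or lap (no confirmed
peak yet, observer not converged) are flagged `warmup` and included by
default — a detector answers for everything it emits — and can be excluded
with a flag.

## Pairing and delay normalisation

Each detection is matched greedily to the nearest same-level target within
one cycle duration of it. The window is a convention: it is wide enough
that genuine detections always match, narrow enough that a detection an
entire cycle adrift is excluded rather than charged to a distant target;
it is config-exposed. The closest detection per target is its primary
match; surplus same-level detections near a target are kept as false
positives and enter the delay statistics (the penalty philosophy). Targets
with no detection in the window are false negatives — with no detection
there is no delay to evaluate, so they appear only in the ledger, whose
conservation identity
`n_paired = n_targets − n_false_negative + n_false_positive` is tested on
randomised fixtures.

The delay is $100\,(t_{det} - t_{target})/T_{cycle}$ with $T_{cycle}$ the
duration of the target's own cycle. Normalising by cycle duration makes
the criterion invariant to cadence — the core rationale of the framework —
and the tests verify invariance under uniform time scaling exactly.

## Agreement layer

A Shapiro–Wilk gate (α = 0.05) decides between parametric and
non-parametric limits of agreement; cyclic-delay distributions are
typically heavy-tailed, so the non-parametric path — the 2.5th and 97.5th
percentiles — is the default. Percentiles interpolate order statistics at
rank position $(n-1)q + 1$ (the most common convention; conventions
differ, so it is stated here and checked against a brute-force
sort-and-interpolate oracle). The acceptance criterion passes when both
limits lie inside the accepted margin, ±10% of cycle duration by default —
100 ms at 60 RPM, strict relative to the delays inherent in neuromuscular
stimulation — which by the definition of the percentiles is equivalent to
at least 95% of delays falling inside the margin. The **absolute LoA**
column reported alongside is defined in this package as the 95th
percentile of $|delay|$; other reports use differing and sometimes
unstated definitions, so it should not be compared across tools.

Lin's concordance correlation coefficient is computed on (target level,
target level + delay) pairs, in percent-of-cycle units — target versus
detected phase, the four level clusters lying on the 45° identity line
under perfect agreement. With population (n-denominator) moments,
$\rho_c = 2 s_{xy}/(s_x^2 + s_y^2 + (\bar x - \bar y)^2)$, so on balanced
targets with level variance $V = 850$ and delay moments $(\mu_d, \sigma_d)$
uncorrelated with the level,
$\rho_c = 2V/(2V + \sigma_d^2 + \mu_d^2)$ — the closed-form identity used
by the acceptance checks, which `balanced_target_pairs()` instantiates
exactly. The 95% CI uses the Fisher z-transform with Lin's (1989)
asymptotic variance; the McBride interpretation classifies the *lower*
confidence limit (< 0.90 poor, 0.90–0.95 moderate, 0.95–0.99 substantial,
≥ 0.99 almost perfect). $\rho_c \le |r|$ always: concordance penalises
bias and scale on top of correlation.

## The synthetic-motion generator

`generate_motion()` emulates the recording conditions of passive
FES-cycling in adults with spinal cord injury: per-cycle durations drawn
from a normal with mean 2.62 s and SD 0.64 s (cadence 24.1 ± 4.9 RPM),
truncated below at half the mean so no non-physical near-zero cycle can
occur (rejection sampling — exact and seed-deterministic); a raised-cosine
angle within each cycle, range of motion 40° with the extension peak at
30°; sampling at a mean 63 Hz with ±20% uniform period jitter; optional
additive Gaussian noise. Asymmetry is a two-segment linear time warp
placing the flexion peak at cycle fraction $0.5 + a$ — the simplest warp
that moves the flexion peak off 50%. One signal (one thigh) is generated;
the evaluation is per-signal. Perturbations (`rom_shift`, `pause`,
`spike`) are parameterised primitives reproducing the qualitative failure
triggers seen in practice — range-of-motion changes, momentary holds, and
transients sharp enough to defeat an online peak detector's hysteresis.

What the generator does **not** model: harmonic content beyond the raised
cosine (real thigh traces are only approximately sinusoidal), sensor
physics (gyro drift, orientation-fusion error), stimulation-induced torque,
or bilateral coupling. Passing tests on synthetic motion therefore
demonstrate correctness of the framework's computations and the
estimators' behaviour under controlled conditions — not clinical
performance on real recordings.

## Numerical choices and problem sizes

* Upsampling: linear interpolation only; range-preserving, exact on
  piecewise-linear inputs, endpoints reproduced exactly.
* Crossing times (baseline targets, thresholds, phase levels) are linearly
  interpolated between bracketing samples; at 1000 Hz the discretisation
  error is well under 0.1% of a typical cycle.
* Ties and degenerate inputs: constant signals are errors for the Hilbert
  phase (no defined phase) and produce held-and-flagged output from the
  observer and no events from BSgonio; zero-range cycle halves are
  excluded, not patched.
* The test-suite and acceptance computations use 5–30 synthetic cycles and
  1000 random fixtures for the percentile oracle — sizes at which every
  check runs in seconds while the asymptotics they probe are already
  stable.

## Known limitations

* The GCI Observer is a documented reinterpretation; its gains were chosen
  for stable lock on cadences around 20–30 RPM and are not fitted to any
  clinical dataset.
* The pairing window (1.0 cycle) and the absolute-LoA definition are
  package conventions, config-exposed but not canonical.
* Warm-up handling (include by default) mildly penalises the online
  estimators relative to the offline Hilbert control; the flag allows the
  opposite convention.
* The CCC confidence interval is asymptotic; with the small balanced
  reconstructions (n = 8) it is indicative only, and the package reports
  the point estimate for those.
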