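# pedalphase

Quantifying the accuracy and precision of event-detection algorithms on
cyclic thigh-inclination signals, as used to time muscle stimulation in
FES-cycling (functional electrical stimulation cycling for people with
spinal cord injury).

## The problem

FES-cycling controllers trigger stimulation at fixed points of the pedalling
cycle. Adaptive controllers read those points from the thigh-inclination
angle measured by a single inertial sensor, so before such an algorithm
drives stimulation one must know how accurately and precisely it detects its
trigger events. `pedalphase` implements an evaluation framework for this
question:

- **Baseline phase reference.** Cycles are delimited from extension peak
  (signal maximum, fully extended leg) to extension peak. Each cycle is
  split at its flexion peak into a flexion half (0–50% of the cycle) and an
  extension half (50–100%); each half is normalised by its own peak-to-peak
  range and linearised with the arc cosine (the motion is circular, so
  `acos` of the normalised angle is linear in cycle progress). Target events
  are the baseline-phase crossings of 10, 40, 60 and 90% — ±10% of the cycle
  around each peak.
- **Three estimators** sharing the thigh angle as input:
  `run_bsgonio()`, an online adaptive-threshold peak detector whose
  thresholds follow `Th = Lpk_ext − (ROM − (cos(2πx) + 1)·ROM/2)` for
  detection phase `x` (with `ROM = 40°` and `x = 0.10` the threshold sits
  3.82° below the extension peak); `hilbert_phase()`, the offline
  instantaneous phase of the analytic signal,
  `phase = (arg(hilbert(θ))/π + 1)·50`; and `run_gci_observer()`, a causal
  oscillator-based phase observer inspired by central pattern generators.
- **Delay normalisation.** Each detection is paired with its nearest
  same-level target; the signed delay is expressed in percent of the
  target's own cycle duration, making the criterion invariant to cadence
  (10% of a 60 RPM cycle is 100 ms). Surplus detections are kept as false
  positives to penalise the detector.
- **Agreement statistics.** A Shapiro–Wilk gate; non-parametric Bland–Altman
  95% limits of agreement (2.5/97.5 percentiles) against a ±10% accepted
  margin; and Lin's concordance correlation coefficient
  `ρc = 2·s_xy / (s_x² + s_y² + (x̄ − ȳ)²)` on (target phase, detected
  phase) pairs, with a Fisher-z confidence interval and McBride
  strength-of-agreement class on the lower confidence limit.

Because clinical recordings of this kind are rarely shared, the package
includes a synthetic pedalling-motion generator (`generate_motion()`) with
known ground truth — raised-cosine cycles with truncated-normal durations
(default mean 2.62 s, SD 0.64 s), 40° range of motion, irregular ~63 Hz
sampling, optional noise, asymmetry and perturbations — so the whole
pipeline is testable end to end.

## Worked example

```r
library(pedalphase)

spec <- motion_spec(n_cycles = 30, noise_sd_deg = 0.3, seed = 42)
sim  <- generate_motion(spec)
sim$series
#> angle_series: 5283 samples over 83.921 s (mean rate 62.9 Hz)
#>   theta range: [-10.91, 30.81] deg

res <- evaluate_recording(sim$series)
res$ledger
#>    source n_paired n_false_positive n_false_negative n_excluded
#> 1 bsgonio      120                3                3          0
#> 2 hilbert      120                0                0          0
#> 3     gci      120                0                0          0

res$report[, c("source", "n", "mean_pct", "sd_pct", "lower_loa_pct",
               "upper_loa_pct", "criterion_pass", "ccc", "mcbride")]
#>    source   n mean_pct sd_pct lower_loa_pct upper_loa_pct criterion_pass   ccc        mcbride
#> 1 bsgonio 120   0.3560  3.825         -1.79          2.48           TRUE 0.992    substantial
#> 2     gci 120  -0.2465  3.440         -5.37          5.75           TRUE 0.993    substantial
#> 3 hilbert 120   0.0377  0.788         -1.66          1.36           TRUE 1.000 almost perfect
```

Reading the report: `mean_pct` is the bias and `sd_pct` the spread of the
detection delays, in percent of cycle duration (negative = early). The 95%
limits of agreement are the 2.5th/97.5th percentiles of the delays;
`criterion_pass` says both lie inside ±10% — equivalently, at least 95% of
detections land within ±10% of the cycle (about ±280 ms at this cadence).
The measurement noise provokes a few spurious and missed BSgonio peak
detections (3 false positives, 3 false negatives), which are kept and
penalise its spread. Delays convert to time via the cadence:

```r
delay_to_ms(res$report$mean_pct[res$report$source == "hilbert"],
            cadence_rpm = 60 / mean(sim$truth$cycle_durations))
#> [1] 1.053928   # about one millisecond of average delay
```

A thin command-line wrapper is installed at `exec/pedalphase`:

```sh
pedalphase simulate --out sim/ --n-cycles 30 --seed 42
pedalphase evaluate --input sim/angle.csv --out eval/
pedalphase report   --paired eval/paired_delays.csv --out rep/
```

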