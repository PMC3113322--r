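# gaitsock

Gait event detection from an instrumented-sock strain sensor.

A knitted piezo-resistive strain sensor worn at the ankle produces a voltage
whose waveform tracks sagittal-plane ankle motion: maxima around heel strike
(HS) and toe off (TO), minima around heel lift (HL) and mid-swing.  If those
three stance-phase events can be read from the sock alone, such a sensor can
trigger functional electrical stimulation for foot-drop gait assistance
without footswitches or shoes.  The raw signal, however, carries slow
baseline drift and hysteresis from the textile's viscoelasticity, and its
shape varies between individuals, so event detection needs both signal
conditioning and per-subject calibration.

`gaitsock` provides, for researchers working on wearable gait sensing:

* **Signal conditioning** — zero-phase brick-wall FFT high-/band-pass
  filtering (0.3 Hz removes baseline drift; 0.3–4 Hz is the detection band),
  a zero-lag 4th-order Butterworth low-pass (6 Hz, for the kinematic
  channel), linear upsampling (100 → 1500 Hz) and peak-to-peak scaling.
* **Similarity statistics** — per gait cycle, Pearson's *r* and the
  normalised mean absolute deviation
  `nMAD = (1/n) Σ |ṽᵢ − θ̃ᵢ|` between the sensor and ankle-angle signals,
  each scaled multiplicatively to unit peak-to-peak range.
* **The event detector** — a three-stage forward search with five
  parameters: find the first point *P₁* where the conditioned voltage is
  rising and exceeds a threshold *a₁*, predict HL at *P₁ + a₂*; find the
  first maximum after *P₁* (the TO peak), predict TO at peak *+ a₃*;
  advance by *a₄* and find the next maximum, predict HS at peak *+ a₅*.
  Offsets are fixed in seconds.  `calibrate()` fits all five parameters
  automatically from training trials, flagging subjects where no workable
  threshold exists (the documented spurious-peak failure mode).
* **Evaluation** — ground truth from 5 N force-plate crossings and the
  filtered ankle minimum before toe off; calibrate on trials 1–5, predict
  on trials 6–10; errors reported as mean absolute deviation and SD of the
  signed difference in % gait cycle.
* **A synthetic cohort generator** — subjects, walking trials (sensor,
  ankle, two GRF channels, with ground truth) and bench stretch-relax
  tests, emulating the sensor's documented behaviour: 0.2–0.4 V
  peak-to-peak, baseline drift, hysteresis-like asymmetry, trial-to-trial
  timing jitter, condition-dependent sensor-kinematics mismatch and the
  30 %-gait-cycle spurious peak.

## Worked example

```r
library(gaitsock)

profile <- make_profile("sock_only", seed = 1)
trials  <- lapply(1:10, function(j) simulate_trial(profile, j))

report <- evaluate_subject(trials)   # calibrates on 1-5, predicts on 6-10
print(report$params)
#> <detector params: a1=0.1379 V, a2=-0.1704 s, a3=0.0056 s, a4=0.2121 s, a5=0.0168 s>
round(report$mean_abs_pct_gc, 2)
#>   HL   TO   HS
#> 1.26 1.16 1.04
```

The fitted threshold (0.138 V on the band-passed voltage) sits midway
between this subject's early-cycle maxima and the toe-off peak; HL is
predicted 170 ms *behind* the threshold crossing (a₂ < 0 — the method is
retrospective).  On the five held-out trials the detector is accurate to
1.0–1.3 % of the gait cycle per event.

```r
subject_similarity(trials)           # sensor vs ankle angle, mean over cycles
#> r = 0.97, nMAD = 0.06

cohort <- simulate_cohort(3, 10, "sock_only", seed = 42)
writeLines(render_cohort_table(cohort_table(evaluate_cohort(cohort))))
#> Subject  Mean HL  Std HL  Mean TO  Std TO  Mean HS  Std HS
#> S01      0.6      0.8     0.6      0.9     0.7      0.8
#> S02      1        0.8     0.9      1.1     0.3      0.4
#> S03      1.1      0.4     0.8      0.2     0.5      0.5
#> Average  0.9      0.7     0.8      0.8     0.5      0.6
```

Subjects whose calibration is infeasible appear as dash rows and are
excluded from the `Average` row.

A command-line wrapper (`inst/exec/gaitsock.R`) exposes the same pipeline
as sub-commands (`simulate`, `bench`, `similarity`, `calibrate`, `detect`,
`evaluate`, `cohort`), each deterministic for a fixed `--seed` and stamping
its outputs with the resolved configuration hash.

## Acceptance script

`scripts/acceptance.R` re-runs the full benchmark from scratch with the
installed package: it simulates a 20-subject × 10-trial cohort per condition
(sock-only and shod), calibrates each subject's detector on trials 1–5,
predicts events on trials 6–10, and writes the cohort-average mean absolute
HL/TO/HS errors (% gait cycle) as JSON:

```sh
Rscript scripts/acceptance.R --seed 42 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/gait-event-detection.Rmd`) describes the
signal model, the calibration rules, the synthetic world's assumptions and
its limitations.
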