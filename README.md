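# fdbhrt

Heart-rate-gated threshold fall detection for wearable sensor streams.

Falls in the elderly are often preceded or caused by an arrhythmia: a heart
rate that drifts outside the normal 60–100 bpm range (bradycardia or
tachycardia) can lead to syncope and a fall. `fdbhrt` implements a hybrid
fall detector for body-worn heart-rate + tri-axial accelerometer devices
that exploits exactly this link: free-fall detection on the acceleration
signal is *gated* on a sustained abnormal heart rate, which suppresses the
false alarms that plague purely acceleration-threshold detectors.

The package is aimed at researchers evaluating wearable fall-detection
pipelines: it provides the streaming detector itself, seeded generators for
labelled evaluation traces (so experiments are reproducible without
volunteer data), the standard evaluation statistics, and the
emergency-dispatch arithmetic used to quantify a drone-based first-aid
response.

## The algorithm

Each sample carries a heart rate `HR` (bpm, 1 Hz) and a tri-axial
acceleration reading whose signal magnitude vector is

```
|a| = sqrt(Ax^2 + Ay^2 + Az^2)   [g]
```

(`|a| ≈ 1` g at rest, → 0 g in free fall, > 2 g on impact). The detector is
a finite state machine driven purely by sample timestamps:

1. **Online** — the device announces itself once, then monitors.
2. **HR gate** — if `HR < NHR_low` or `HR > NHR_high` (default 60/100 bpm)
   continuously for 5 s, fall checking is armed.
3. **Free fall** — a contiguous run of samples with `|a| < FAM_t`
   (default 0.5 g) lasting longer than `FT_t` (default 40 ms) emits a
   *fall alert* with the patient's GPS fix.
4. **Activity check** — 20 s after the fall, a 10 s window counts the
   activity counter `AC_m`: the number of distinct seconds containing a
   sample with `|a| > AAM_t` (default 2.5 g). `AC_m < AC_t` (default 10)
   means the patient is *inactive* → inactive alert, device awaits help.
5. **HR recheck** — an active patient is rechecked after 10 s; a still
   abnormal heart rate emits an *active, HR abnormal* alert; otherwise
   monitoring resumes.

Alerts are rendered as line-oriented text messages (patient ID, status,
map link with 6-decimal coordinates) that round-trip exactly through the
bundled parser.

## Worked example

```r
library(fdbhrt)

tr  <- gen_activity_trace("F1", seed = 1)   # forward fall, lying on ground
fit <- detect_falls(tr)
fit
#> FDB-HRT detection run: 4500 samples, 3 event(s)
#>   t=   12.31 s  FALL_ALERT               (HR abnormal, patient fall)
#>   t=   42.31 s  INACTIVE_ALERT           (patient inactive)
```

The tachycardic heart rate arms the detector, the free-fall dip at ~12.3 s
fires the fall alert, and after the 20 s post-fall delay plus the 10 s
activity window the motionless patient is declared inactive. A normal
activity trace crosses no threshold:

```r
detect_falls(gen_activity_trace("NA1", seed = 2))   # walking
#> FDB-HRT detection run: 3000 samples, 1 event(s)
#>   no alerts (online only)
```

The full evaluation battery (15 trials × 8 activity types through the
engine, treadmill scenarios, heart-rate and GPS agreement, dispatch
timing):

```r
run_battery_evaluation(seed = 42)
#> Activity battery evaluation
#>   F1  Forward fall, lying on ground                    15/15 detected
#>   F2  Fall to the right, lying on ground               15/15 detected
#>   F3  Backward fall from a seated position on a chair  14/15 detected
#>   F4  Forward fall, landing on knees                   15/15 detected
#>   NA1 Walking                                          0/15 flagged
#>   NA2 Ascending stairs                                 0/15 flagged
#>   NA3 Descending stairs                                0/15 flagged
#>   NA4 Sitting on chair                                 0/15 flagged
#> confusion counts: TP=59 FN=1 TN=60 FP=0 (n=120)
#> sensitivity 98.33%  specificity 100.00%  accuracy 99.2%
```

The single miss is the *arrested* backward chair fall — the person catches
the chair arm, so the magnitude never drops below the free-fall threshold;
the detector by design cannot see it. Dispatch arithmetic works on plain
mission tables:

```r
logistics_report(read_missions(system.file("extdata", "missions.csv",
                                           package = "fdbhrt")))
#>   average time savings = 105 s
#>   percentage of time saved = 31.81%
#>   low_power       880.5 h  (36 whole days)
#>   traditional      97.8 h  (4 whole days)
```

A thin command-line front end (`inst/cli/fdbhrt.R`) wires the same
functions into `simulate`, `detect`, `evaluate`, `logistics` and
`report-all` subcommands for shell pipelines.

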