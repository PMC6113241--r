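---
title: "Detecting the sleep period time window without a diary"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the sleep period time window without a diary}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepwin)
library(dplyr)
```

## The problem

Wrist-worn raw-data accelerometers are routinely worn around the clock in
large cohorts, but without a sleep diary there is no annotation of when the
night's sleep started and ended. The *sleep period time window* (SPT window)
— from sleep onset to the final awakening — is the basic unit that most
downstream sleep and physical-activity analyses need. `sleepwin` detects it
from the raw tri-axial signal alone.

The detector rests on one physiological observation: during sleep the
forearm barely changes orientation, while wakefulness — even quiet
wakefulness — involves frequent posture changes. Orientation is summarised
by the z-angle, the elevation of the axis perpendicular to the skin surface
(dorsal–ventral when the wrist is in the anatomical position) relative to
the horizontal:

$$\mathrm{angle}_z = \arctan\!\left(\frac{a_z}{\sqrt{a_x^2+a_y^2}}\right)\cdot 180/\pi,$$

where $a_x,a_y,a_z$ are per-axis rolling medians (5-second window) of the
raw acceleration in g. We use the square root of the summed squared
horizontal components in the denominator so the expression is a true
elevation angle of the gravity vector; some descriptions of this quantity
print the denominator without the root, which is dimensionally inconsistent,
and the rolling-median lineage of the method uses the rooted form. Angles
are averaged into 5-second epochs.

## The heuristic detector

Working per noon-to-noon day (so a night is never split), the pipeline is:

1. **Change statistic** (`rolling_var_statistic()`): absolute differences of
   successive epoch angles, smoothed by a 5-minute centered rolling median.
   Taking absolute *changes* makes the statistic invariant to how the device
   was oriented on the wrist — flipping the z-axis or swapping the
   horizontal axes changes nothing, a property the test suite asserts
   exactly.
2. **Adaptive threshold** (`derive_threshold()`): the 10th percentile of the
   day's statistic multiplied by 15. The percentile adapts the threshold to
   each person's angular-change distribution; quiet sleepers get a lower
   bar.
3. **Blocks** (`detect_blocks()`): maximal runs strictly below the
   threshold, kept when strictly longer than 30 minutes (shorter quiescence
   is treated as daytime stillness, not time in bed).
4. **Gap absorption** (`absorb_gaps()`): gaps between blocks strictly
   shorter than 60 minutes are counted towards the blocks — brief nocturnal
   awakenings should not split the night, while longer wakefulness
   legitimately separates sleep episodes (an evening nap stays separate).
5. **Selection** (`detect_spt()`): the longest merged block in the day is
   the SPT window.

### Numerical conventions

The boundary readings are deliberately literal: *below* the threshold is a
strict `<`, *longer than* 30 minutes a strict `>`, *less than* 60 minutes a
strict `<` (`hdcza_params(strict = FALSE)` flips all three). Percentiles use
linear interpolation between order statistics (`percentile_type = "nearest"`
selects the nearest-rank definition). Gap absorption runs left to right and
merges transitively, which is its own fixed point: chains of blocks
separated by short gaps collapse fully, and the result can only lengthen the
block that wins step 5, the conservative choice given that selection. Ties
between equal-length blocks go to the earliest. Epoch intervals are
half-open `[t, t + 5s)`; the change statistic is assigned to the left epoch
of each difference so every series lives on one grid; rolling-median windows
shrink at the edges of the recording; a trailing partial epoch of raw
samples is dropped. Days are labelled by local clock time, so
daylight-saving transitions produce 23- or 25-hour days instead of drifting
anchors.

Two conventions deserve a note because the method description leaves them
open. First, the threshold percentile is computed over whatever part of the
day is present; for a partially recorded day that is the available epochs,
and for in-bed-only recordings `detect_spt(var_stat, day = NULL, ...)` uses
the whole recording. Second, the per-axis rolling median advances one
*sample* at a time (not one 5-second block), which is the finer-grained
reading and the one the brute-force oracle in the tests pins down.

### Short recordings and the threshold clamp

An overnight-only recording (e.g. during polysomnography) contains almost no
wakefulness, so the 10th percentile reflects sleep itself and the derived
threshold is meaningless. Two measures fix this, both part of
`compare_psg()`: the recording is padded on both sides with 90 minutes of
simulated wakefulness — a sine wave of 40-degree amplitude and 15-minute
period plus Gaussian noise (sd 10°), which no sleep-like signal resembles —
and the threshold is clamped to `[0.13, 0.50]` degrees, the 2.5th–97.5th
percentile range of thresholds observed in daily-life recordings. Before
agreement is computed, 60 of the 90 simulated minutes are trimmed from each
side, so the compared span is the real recording plus 60 minutes. "24-hour"
accuracy and c-statistic expand the comparison to the full noon–noon day
under the assumption that all added daytime is correctly classified
wakefulness — both the in-window and expanded figures are reported because
that assumption flatters the expanded ones.

## The naive reference: L5 ± 6

`detect_spt_l5()` implements the reference detector the heuristic is judged
against: locate the least-active five hours of the day by ENMO
($\max(\lVert a\rVert - 1, 0)$, averaged per epoch), take the 12-hour window
centred on it, and span from the first to the last sustained inactivity bout
(SIB) inside that window. A SIB is a maximal period with no
consecutive-epoch angle change above 5 degrees lasting more than 5 minutes
(`detect_sib()`); the same bouts, clipped to the SPT window, are the sleep
episodes that `summarize_sleep()` turns into total sleep time, sleep
efficiency and WASO. The L5 window slides at epoch resolution with ties to
the earliest start; the method needs more than 12 hours of data and is
therefore not applicable to in-bed-only recordings. The
consecutive-difference reading of "absence of change" (rather than a
growing-range criterion) is the operationalisation we pin down with an
explicit anchor-scan oracle in the tests.

## What the synthetic generator emulates — and what it does not

`generate_recording()` produces multi-day raw recordings with known truth:
nights of near-constant orientation (default angular jitter 0.02°/epoch,
posture shifts roughly every 40 minutes), days of wandering orientation
(random-walk step 8°/epoch — wakeful arm movement routinely exceeds the
5-degree inactivity tolerance, which is what makes wake bouts and naps
visible to the bout detector), gravity-consistent unit-norm triples with
activity noise and daytime bursts so ENMO separates day from night, plus a
hypnogram and a diary with 10-minute reporting noise. The default night runs
23:45–07:30 (≈7.7 h, typical of an older cohort) with one 20-minute
awakening; these defaults put the unclamped adaptive threshold inside the
observed daily-life range of 0.13–0.50°. Angle dynamics are generated
directly in orientation space and then converted to acceleration triples:
the detectors consume only the z-angle and ENMO, so this is sufficient and
keeps the truth exact. `generate_psg_fixture()` produces in-bed-only
fixtures with a semi-Markov stage sequence whose angular variability is
ordered W > N1 > REM > N2 > N3.

What passing tests on this corpus shows is that the implementation detects
what the model says it should detect under the model's own assumptions:
distinct quiet-night/active-day regimes, wake bouts that involve arm
movement, naps distinguishable only by daytime context. What it cannot show
is performance on real wrists: real data contain non-wear, calibration
error, motionless wakefulness (reading, TV), restless sleep and sleep
scattered across the day — which is why the generator also exposes a
degenerate mode (equal day and night movement) whose detected windows are
flagged `low_contrast` rather than silently returned. Sensor
autocalibration and non-wear handling are out of scope; recordings are
assumed to be calibrated, worn, CSV-exported data.

## Problem sizes and reproducibility

The packaged property suite and `scripts/acceptance.R` run the whole stack
on generated corpora: 200 one-day daily-life recordings at 5 Hz for recovery
and diary concordance, 30 in-bed fixtures for the polysomnography protocol,
1000 short randomized series for the oracle-equivalence checks, and 100
seeds for the padding contract. One day at 5 Hz is sufficient because the
detector consumes 5-second epochs — the sampling rate only enters through
the per-axis rolling median, whose semantics the oracle tests pin down at
85.7 Hz as well. Every random draw sits behind an explicit integer seed
(`night_spec(seed = )`, `pad_with_wakefulness(seed = )`), and identical
seeds reproduce byte-identical artifacts, including written CSVs.

## A worked example

```{r example, eval = FALSE}
spec <- night_spec(seed = 42) # 23:45-07:30 night, one 03:00 awakening
rec <- generate_recording(spec, days = 1, sample_rate = 10)

z <- compute_z_angle(rec$raw)
vs <- rolling_var_statistic(z)
windows <- detect_spt_multiday(vs)
windows
plot_detection(vs, windows)

summarize_sleep(windows, detect_sib(z))
cmp <- compare_diary(mutate(windows, id = "p1"),
                     mutate(rec$diary, id = "p1"))
glance(cmp)
```

## Known limitations

* The SPT window lacks a crisp construct when sleep is split by hours of
  wakefulness; with a gap of 60 minutes or more the detector keeps only the
  longest fragment, and nights with much wakefulness show the largest
  duration differences (`stratify_by_wakefulness()` quantifies this).
* Sleep latency and time in bed are undetectable without a diary or lights
  marker; the sustained-inactivity episodes are orientation-based proxies,
  not EEG sleep, so motionless wakefulness inside the window inflates sleep
  time and efficiency.
* The c-statistic of the binary window classification is computed as
  balanced accuracy, $(\text{sensitivity}+\text{specificity})/2$ — the
  trapezoidal AUC of a single-operating-point classifier.
* The combined MAE pools onset and waking-time absolute errors (their joint
  mean), rather than averaging the two MAEs; with equal night counts the two
  definitions coincide.
* Per-night difference tables are exported for mixed-model analysis in
  standard tools; the package does not fit those models itself.
```
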