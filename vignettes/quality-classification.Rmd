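---
title: "Window-statistics quality classification for wearable ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-statistics quality classification for wearable ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgsqi)
```

## The problem and the model

Ambulatory single-lead ECG from textile or adhesive wearables is dominated
by two artifact mechanisms: electrode displacement or loss of adhesion,
which swings the differential input toward the ADC rails, and muscle
activity, which adds broadband variability. Both mechanisms share a
signature that simple order statistics can see. A readable trace, by
contrast, has a limited peak-to-peak range, limited standard deviation, and
a reasonably steady isoelectric line, whatever the beat morphology.

`ecgsqi` classifies readability, not rhythm: the question is only whether
P–QRS–T complexes could be identified, never what they mean. The classifier
compares each 2 s window's maximum, minimum and standard deviation
(`max_w`, `min_w`, `SD_w`) against two anchors:

* an **absolute** anchor — the device's ADC span — for the saturation rule,
  because rail-to-rail oscillation is an artifact regardless of patient; and
* a **relative** anchor — a per-recording *reference template*
  (`max_t`, `min_t`, `SD_t` of the first stable 10 s period) — for the
  low-amplitude floor and the SD rule, because normal amplitudes vary with
  electrode placement and body habitus.

The three rules fire in a fixed order (saturation → low amplitude → excess
SD) and the first to fire is reported as the window's rejection reason.
All inequalities are strict, so a window sitting exactly at a threshold is
acceptable; the same convention is used everywhere so batch, streaming and
any re-implementation agree at boundaries. Window verdicts are merged into
10 s sample labels by duration prevalence, which is also how interval
annotations from a human reader are mapped onto the same grid for
comparison (`intervals_to_sample_labels()`).

## Parameters

All thresholds live in `sqi_config()`; the zero-argument defaults are the
validated configuration.

| parameter | default | unit | role |
|---|---|---|---|
| `window_len_s` | 2 | s | analysis window; long enough for ≥ 1 beat at 30 bpm |
| `sample_len_s` | 10 | s | reporting granularity; must be a multiple of the window |
| `saturation_factor` | 0.95 | fraction of ADC span | rule 1 threshold |
| `floor_fraction` | 0.05 | fraction of template range | rule 2 threshold |
| `sd_multiplier` | 2 | × `SD_t` | rule 3 threshold |
| `template_min_duration_s` | 10 | s | minimum stable period |
| `template_variability_fraction` | 0.70 | fraction of ADC span | template amplitude cap |
| `baseline_drift_fraction` | 0.10 | fraction of span's own range | isoelectric-line stability |

Two of these encode genuinely open design points, resolved as follows.

**The span the saturation rule is anchored to.** The device's input range
is quoted as ±500 mV; a peak-to-peak quantity (`max_w − min_w`) is compared
against it, so the natural reading is the *full* span, 1000 mV, and that is
the default (`device_span()`). The same full-span reading is used for the
70% template amplitude cap. Both are configurable through
`device_profile()` and `sqi_config()` for devices quoted differently.

**What "constant isoelectric line" means.** Baseline stability is not
quantified by the underlying decision flow, so the template search
operationalises it: the spread of per-second sub-window means within a
candidate span must not exceed 10% of that span's own peak-to-peak
amplitude. Making the criterion relative to the candidate's range (rather
than to the ADC span) keeps it meaningful for both large- and
small-amplitude electrode placements. The search scans candidate spans in
1 s steps from t = 0 and returns the earliest hit; a finer scan changes
at most the template start by under a second and, on stable signal,
essentially nothing downstream. Constant spans are skipped — a template
with `SD_t = 0` would make rule 3 reject everything and rule 2 accept
anything. If no span qualifies, `find_reference_template()` raises a typed
error and the caller may pass a preset `ecg_template()` (the
device-characteristics fallback) or manually chosen bounds.

## Numerical choices

* **Population SD (denominator n).** At ≥ 500 samples per window the
  difference from n − 1 is far below any threshold's resolution; fixing one
  denominator makes results reproducible to the bit.
* **One statistics kernel.** Batch (`classify_signal()`) and streaming
  (`streaming_classifier()`) paths both buffer exactly one window and call
  the same sum-based kernel, so their verdicts are `identical()`, not just
  close. Running-moment accumulation (sum and sum of squares updated per
  sample) is how a device firmware would do it and is supported by the
  algorithm's design; it was not used here because one-pass variance can
  differ from the two-pass result in the last bits, which would make exact
  stream/batch equality platform-dependent.
* **Ties and partial units.** Duration-prevalence ties (possible only with
  an even window count per sample, or in interval annotations: exactly
  5 s / 5 s) resolve to *unacceptable* — the conservative choice for a
  quality gate. Trailing partial windows and partial sample groups are
  dropped and reported via typed messages; one-hour recordings divide
  evenly, so nothing is lost in the intended use.
* **Windows overlapping the template span are classified normally**; the
  window grid starts at t = 0 regardless of where the template was found.
* **Clipping at the rails** happens on read and on synthesis, with the
  clipped-sample count reported; re-reading a written clipped signal is a
  no-op (idempotence is tested).

## The synthetic generator

No public recordings exist for the device class this targets, so the
package ships a generator (`synth_recipe()`, `synth_ecg()`,
`generate_cohort()`) that stands in for them. Beats are sums of Gaussian
deflections (P, Q, R, S, T) at jittered RR intervals — the standard
closed-form simplification — with typical single-lead amplitudes
(R = 1.0, P = 0.15, T = 0.3, Q = S = −0.1 mV) at 60 bpm with 5% uniform RR
jitter, sampled at 250 Hz by default. The sampling rate is a free runtime
parameter everywhere because the algorithm is defined in seconds, not
samples.

Scheduled episodes reproduce the artifact morphologies the classifier is
meant to separate, with magnitudes chosen once as field-realistic defaults:

* *baseline wander*: 0.3 mV sinusoid at 0.33 Hz — readable by design, the
  classifier must tolerate it;
* *saturation*: 600 mV, 1 Hz oscillation clipped at the rails — every
  interior 2 s window exceeds the 95% span rule by construction;
* *muscle*: zero-mean noise high-passed above 20 Hz, SD 0.5 mV — about
  three times the clean trace's SD, clearly past the 2×SD rule;
* *flatline*: the trace scaled to 2% of its amplitude — below the 5% floor;
* *powerline*: 0.25 mV at 50 Hz — deliberately inside all three thresholds,
  to expose the known blind spot (see below).

Ground-truth labels derive from the schedule, never from the classifier: a
2 s window is truth-unacceptable when at least half of it is covered by a
saturation, flatline, or sufficiently strong muscle episode (SD at least
the clean trace's SD); wander and powerline are truth-acceptable. The
coverage fraction and muscle threshold are arguments of
`ground_truth_labels()`. Setting `strict_powerline = TRUE` switches to the
convention of a human reader who rejects 50 Hz contamination; under it the
classifier's sensitivity on powerline-only recordings collapses — the
acceptance script measures this rather than asserting it.

`generate_cohort()` emulates a validation study: each recording opens with
a 20 s clean lead-in (so a template is always found, at t = 0), after which
each 10 s block is independently corrupted with probability scaled so the
*expected* truth-unacceptable fraction equals the target (default 0.46);
a share of clean blocks receives benign wander or powerline so the
acceptable class is not trivially clean.

**What passing on this generator does and does not show.** Episodes are
block-aligned, unambiguous (magnitudes far from thresholds) and of a single
kind at a time, so near-perfect recovery on the synthetic cohort verifies
the machinery — windowing, template search, rules, aggregation, counting —
not clinical performance. Real artifacts grade smoothly into readable
signal, overlap, and disagree with human readers near boundaries; the
published validation on 7200 clinical samples reports ≈ 95% sensitivity and
specificity, which synthetic data can neither confirm nor contradict.

## Problem sizes used in the checks

The test-suite and acceptance script use recordings of 20–600 s for unit
properties, 100 random 24 s recipes for stream/batch equivalence, over a
thousand windows for brute-force oracle comparison, and a 20 × 1 h cohort
(7200 samples at 250 Hz) for end-to-end recovery — the same shape as the
reference validation study.

## Known limitations

* 50 Hz powerline interference passes all three rules at realistic
  amplitudes; a spectral check of the 50 Hz component against the reference
  window has been suggested as an extension but is not part of the
  validated rule set and is not implemented.
* The classifier grades readability only — visible waves do not imply
  measurable ST segments, and no QRS detection or rhythm analysis is
  attempted.
* A recording with no stable 10 s period anywhere cannot be auto-templated;
  the preset-template fallback trades per-recording adaptation for
  availability.
* Wald confidence intervals are reported because they reproduce the
  reference study's printed half-widths at one-decimal rounding; at
  proportions very near 0 or 1 a Wilson interval would behave better.
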