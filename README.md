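# ecgsqi

Real-time signal-quality classification for wearable single-lead ECG.

Wearable ECG monitors (textile Holter shirts, chest patches) spend a large
share of recording time producing traces too noisy to read: electrode
movement and loss of adhesion drive the signal toward the ADC rails, muscle
activity inflates its variability, and detached leads leave a flatline.
`ecgsqi` implements a deliberately simple classifier that grades readability
in real time from nothing but windowed order statistics, so it can run on
the device itself and prompt the wearer to fix an electrode before hours of
signal are lost. It is aimed at engineers and researchers validating quality
gates for ambulatory ECG pipelines.

## The algorithm

1. **Reference template.** Scan the recording from t = 0 in 1 s steps for
   the first stable 10 s period: peak-to-peak amplitude below 70% of the
   full ADC span and a steady isoelectric line. Its statistics
   (max_t, min_t, SD_t) define what "readable" looks like for this
   recording, electrode placement and patient.
2. **2 s windows.** From the start of the trace, compute max_w, min_w,
   SD_w (and the mean) over consecutive non-overlapping 2 s windows — long
   enough to contain at least one beat, cheap enough to update at every
   sample.
3. **Three rejection rules**, applied in order, all strict inequalities;
   the window is *unacceptable* if any fires:
   - **saturation:** `max_w − min_w > 0.95 × (ADC span)` — the trace
     oscillates near the rails;
   - **low amplitude:** `max_w − min_w < 0.05 × (max_t − min_t)` — ECG
     waves vanishingly small or absent;
   - **excess SD:** `SD_w > 2 × SD_t` — variability beyond a readable
     trace. Because only range and SD are compared, baseline drift alone
     does not reject a window.
4. **10 s samples.** Five consecutive window verdicts are merged into one
   acceptable/unacceptable sample label by duration prevalence (≥ 5 s).

With the default ±500 mV, 18-bit device profile the validated configuration
is exactly the zero-argument default of every function. A streaming variant
(`streaming_classifier()`) emits verdicts with one-window delay,
bit-identical to the batch path.

The package also ships a seeded synthetic generator (Gaussian-wave PQRST
beats plus scheduled baseline-wander, saturation, muscle, flatline and 50 Hz
powerline episodes with ground-truth labels) and an evaluation module for
the 2×2 agreement table and its diagnostic statistics (sensitivity,
specificity, PPV/NPV, likelihood ratios, efficiency, Wald CIs; positive
class = unacceptable).

## Worked example

```r
library(ecgsqi)

recipe <- synth_recipe(
  duration_s = 60, seed = 7,
  episodes = rbind(noise_episode("saturation", 24, 8),
                   noise_episode("muscle", 44, 8)))
rec <- synth_ecg(recipe)

verdicts <- classify_signal(rec$signal)
table(verdicts$reason)
#> excess_sd         ok saturation
#>         4         22          4

samples <- aggregate_windows_to_samples(verdicts)
samples$label
#> [1] "acceptable" "acceptable" "unacceptable" "acceptable" "unacceptable" "acceptable"

compute_metrics(confusion_from_labels(samples, rec$truth_samples))
#> <sqi_metrics> n = 6 (positive class: unacceptable)
#>   sensitivity  100.0% (+/-   0.0%)
#>   specificity  100.0% (+/-   0.0%)
#>   ...
```

The two corrupted stretches (electrode-loss saturation at 24–32 s, muscle
noise at 44–52 s) are flagged window by window — four windows each, by the
saturation and excess-SD rules respectively — and the 10 s samples covering
them majority-vote to *unacceptable*, matching the generator's ground
truth. On a printed agreement table the evaluation module works directly:

```r
compute_metrics(confusion_matrix(tp = 3150, fn = 175, fp = 177, tn = 3698))
#>   sensitivity   94.7% (+/-   0.8%)
#>   specificity   95.4% (+/-   0.7%)
#>   PPV           94.7%
#>   NPV           95.5%
#>   efficiency    95.1%
#>   prevalence    46.2%
#>   LR+          20.7
#>   LR-          0.055
```

A command-line interface with `synth`, `classify`, `evaluate` and
`metrics-from-table` subcommands is installed under
`system.file("cli", "ecgsqi.R", package = "ecgsqi")`.

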