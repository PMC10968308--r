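# Shared fixtures and small independent oracles.

# Population SD, written independently of the package kernel.
pop_sd <- function(x) {
  mu <- mean(x)
  sqrt(sum((x - mu)^2) / length(x))
}

# Drop the template attribute so batch and streaming verdict tibbles can be
# compared with identical().
strip_verdict_attrs <- function(v) {
  attr(v, "template") <- NULL
  class(v) <- class(tibble::tibble())
  v
}

# A clean synthetic recording (no artifact episodes).
clean_recipe <- function(duration_s = 30, seed = 1, fs = 250, jitter = 0.05) {
  synth_recipe(duration_s = duration_s, fs = fs, seed = seed,
               beat = beat_model(hr_jitter_fraction = jitter))
}

# Simple threshold-crossing R-peak counter (oracle for beat counts): counts
# upward crossings of half the R amplitude.
count_r_peaks <- function(values, threshold = 0.5) {
  above <- values > threshold
  sum(above[-1] & !above[-length(above)]) + as.integer(above[1])
}

# Brute-force re-statement of the three rejection rules, independent of
# classify_window().
brute_force_reason <- function(max_w, min_w, sd_w, template, span,
                               cfg = sqi_config()) {
  if ((max_w - min_w) > cfg$saturation_factor * span) return("saturation")
  if ((max_w - min_w) < cfg$floor_fraction * (template$max_t - template$min_t)) {
    return("low_amplitude")
  }
  if (sd_w > cfg$sd_multiplier * template$sd_t) return("excess_sd")
  "ok"
}

# One-row window-stats tibble built by hand.
stats_row <- function(max_w, min_w, sd_w, mean_w = (max_w + min_w) / 2,
                      index = 0L, start_s = 0) {
  tibble::tibble(index = index, start_s = start_s, mean_w = mean_w,
                 max_w = max_w, min_w = min_w, sd_w = sd_w)
}
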