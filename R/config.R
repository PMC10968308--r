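#' Classifier configuration
#'
#' All tunable thresholds of the quality classifier, with the validated
#' defaults: 2 s analysis windows aggregated into 10 s samples; a window is
#' rejected when its peak-to-peak range exceeds 95% of the full ADC span
#' (saturation), falls below 5% of the reference template's range (low
#' amplitude), or when its standard deviation exceeds twice the template SD.
#' The reference template is the first 10 s span whose peak-to-peak
#' amplitude is below 70% of the ADC span and whose isoelectric line is
#' stable (spread of per-second means at most `baseline_drift_fraction` of
#' the span's own peak-to-peak amplitude).
#'
#' @param window_len_s Analysis window length, seconds.
#' @param sample_len_s Aggregated sample length, seconds; must be a multiple
#'   of `window_len_s`.
#' @param saturation_factor Fraction of the full ADC span above which a
#'   window's range flags saturation.
#' @param floor_fraction Fraction of the template range below which a
#'   window's range flags a low-amplitude (absent ECG) signal.
#' @param sd_multiplier Multiplier of the template SD above which a window's
#'   SD flags excess variability.
#' @param template_min_duration_s Minimum stable-period length, seconds.
#' @param template_variability_fraction Maximum template peak-to-peak
#'   amplitude as a fraction of the full ADC span.
#' @param baseline_drift_fraction Maximum spread of per-second means within
#'   the template span, as a fraction of the span's peak-to-peak amplitude.
#'
#' @return An object of class `sqi_config`.
#' @examples
#' sqi_config()
#' @export
sqi_config <- function(window_len_s = 2,
                       sample_len_s = 10,
                       saturation_factor = 0.95,
                       floor_fraction = 0.05,
                       sd_multiplier = 2,
                       template_min_duration_s = 10,
                       template_variability_fraction = 0.70,
                       baseline_drift_fraction = 0.10) {
  fracs <- c(saturation_factor = saturation_factor,
             floor_fraction = floor_fraction,
             template_variability_fraction = template_variability_fraction,
             baseline_drift_fraction = baseline_drift_fraction)
  if (any(fracs <= 0 | fracs > 1)) {
    rlang::abort("All fraction parameters must lie in (0, 1].",
                 class = "ecgsqi_validation")
  }
  if (sd_multiplier <= 1) {
    rlang::abort("`sd_multiplier` must exceed 1.", class = "ecgsqi_validation")
  }
  if (window_len_s <= 0 || sample_len_s <= 0 ||
      abs(sample_len_s / window_len_s - round(sample_len_s / window_len_s)) > 1e-9) {
    rlang::abort("`window_len_s` must divide `sample_len_s`.",
                 class = "ecgsqi_validation")
  }
  structure(
    list(window_len_s = window_len_s,
         sample_len_s = sample_len_s,
         saturation_factor = saturation_factor,
         floor_fraction = floor_fraction,
         sd_multiplier = sd_multiplier,
         template_min_duration_s = template_min_duration_s,
         template_variability_fraction = template_variability_fraction,
         baseline_drift_fraction = baseline_drift_fraction),
    class = "sqi_config"
  )
}

#' @export
print.sqi_config <- function(x, ...) {
  cat("<sqi_config>\n")
  for (nm in names(x)) cat(sprintf("  %-30s %g\n", nm, x[[nm]]))
  invisible(x)
}
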