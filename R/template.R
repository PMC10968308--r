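#' Reference template of an acceptable signal
#'
#' The per-recording standard against which every 2 s window is compared:
#' maximum, minimum and standard deviation of the first stable period of the
#' recording (at least 10 s). `ecg_template()` builds one from explicit
#' values, e.g. a preset template derived from device characteristics, or
#' bounds picked manually on the trace.
#'
#' @param max_t,min_t Template maximum / minimum amplitude, mV.
#' @param sd_t Template standard deviation, mV (> 0).
#' @param start_s Start of the template span in the recording, seconds
#'   (`NA` for preset templates).
#' @param duration_s Span length, seconds (>= 10 for templates extracted
#'   from signal).
#'
#' @return An object of class `ecg_template`.
#' @examples
#' ecg_template(max_t = 1.1, min_t = -0.2, sd_t = 0.18)
#' @export
ecg_template <- function(max_t, min_t, sd_t, start_s = NA_real_,
                         duration_s = 10) {
  if (max_t <= min_t) {
    rlang::abort("`max_t` must exceed `min_t`.", class = "ecgsqi_validation")
  }
  if (sd_t <= 0) {
    rlang::abort("`sd_t` must be positive.", class = "ecgsqi_validation")
  }
  structure(
    list(max_t = max_t, min_t = min_t, sd_t = sd_t,
         start_s = start_s, duration_s = duration_s),
    class = "ecg_template"
  )
}

#' @export
print.ecg_template <- function(x, ...) {
  cat(sprintf(
    "<ecg_template> max_t=%.4g mV, min_t=%.4g mV, sd_t=%.4g mV (start %s s, %g s)\n",
    x$max_t, x$min_t, x$sd_t,
    if (is.na(x$start_s)) "NA" else format(x$start_s), x$duration_s))
  invisible(x)
}

#' Find the first stable reference period of a recording
#'
#' Scans candidate spans of `template_min_duration_s` seconds in 1 s steps
#' from the start of the recording and returns the statistics of the
#' earliest span that is both low-amplitude — peak-to-peak range strictly
#' below `template_variability_fraction` of the full ADC span — and
#' baseline-stable: the spread of its per-second sub-window means is at most
#' `baseline_drift_fraction` of the span's own peak-to-peak amplitude.
#' Constant (zero-variance) spans never qualify: the template SD must be
#' positive for the rejection rules to be meaningful.
#'
#' @param signal An [ecg_signal()].
#' @param cfg An [sqi_config()].
#'
#' @return An [ecg_template()] with `start_s` set to the span found.
#'
#' @section Errors: if no span qualifies anywhere in the recording, an error
#'   of class `ecgsqi_no_stable_reference` is raised; callers may fall back
#'   to a preset [ecg_template()].
#' @export
find_reference_template <- function(signal, cfg = sqi_config()) {
  stopifnot(inherits(signal, "ecg_signal"))
  fs <- signal_fs(signal)
  values <- signal$value_mv
  dur_n <- as.integer(round(cfg$template_min_duration_s * fs))
  step_n <- max(1L, as.integer(round(fs)))
  sub_n <- max(2L, as.integer(round(fs)))
  if (length(values) < dur_n) {
    rlang::abort(sprintf(
      "Recording (%.1f s) is shorter than the minimum template duration (%g s).",
      signal_duration(signal), cfg$template_min_duration_s),
      class = "ecgsqi_validation")
  }
  span <- device_span(signal_device(signal))
  offsets <- seq.int(0L, length(values) - dur_n, by = step_n)
  for (off in offsets) {
    v <- values[(off + 1L):(off + dur_n)]
    vmax <- max(v)
    vmin <- min(v)
    pp <- vmax - vmin
    if (pp <= 0 || pp >= cfg$template_variability_fraction * span) next
    n_sub <- dur_n %/% sub_n
    sub_means <- colSums(matrix(v[seq_len(n_sub * sub_n)], nrow = sub_n)) / sub_n
    if (max(sub_means) - min(sub_means) > cfg$baseline_drift_fraction * pp) next
    mu <- sum(v) / dur_n
    sd_t <- sqrt(sum((v - mu)^2) / dur_n)
    if (sd_t <= 0) next
    return(ecg_template(max_t = vmax, min_t = vmin, sd_t = sd_t,
                        start_s = off / fs,
                        duration_s = cfg$template_min_duration_s))
  }
  rlang::abort(
    "No stable reference period found; supply a preset `ecg_template()`.",
    class = "ecgsqi_no_stable_reference"
  )
}
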