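#' Per-window summary statistics
#'
#' Computes the four statistics the classifier uses — mean, maximum, minimum
#' and standard deviation — over one contiguous window of samples. The SD
#' uses the population denominator `n`; at the default 2 s windows (hundreds
#' of samples) the difference from `n - 1` is negligible, and fixing the
#' denominator keeps batch and streaming paths bit-identical. The mean is
#' reported for completeness but no rejection rule uses it.
#'
#' @param segment Numeric vector of amplitudes (mV), length >= 2.
#' @param start_s Window start time in seconds.
#' @param index 0-based window index.
#'
#' @return A one-row tibble with columns `index`, `start_s`, `mean_w`,
#'   `max_w`, `min_w`, `sd_w`.
#' @examples
#' compute_window_stats(c(-0.5, 0.5, -0.5, 0.5), start_s = 0, index = 0)
#' @export
compute_window_stats <- function(segment, start_s = 0, index = 0L) {
  if (length(segment) < 2L) {
    rlang::abort("Window segments must contain at least 2 samples.",
                 class = "ecgsqi_validation")
  }
  s <- window_stats_kernel(as.numeric(segment))
  tibble::tibble(index = as.integer(index), start_s = start_s,
                 mean_w = s[["mean"]], max_w = s[["max"]],
                 min_w = s[["min"]], sd_w = s[["sd"]])
}

# Shared statistics kernel. Deliberately sum-based (not mean()/sd()) so that
# every code path accumulates in the same order and batch == streaming holds
# exactly.
window_stats_kernel <- function(v) {
  n <- length(v)
  mu <- sum(v) / n
  c(mean = mu, max = max(v), min = min(v),
    sd = sqrt(sum((v - mu)^2) / n))
}

#' Classify one 2 s window against the reference template
#'
#' Applies the three rejection rules in the fixed order of the decision
#' flow, reporting the first that fires:
#' \describe{
#'   \item{saturation}{`max_w - min_w > saturation_factor * ADC span` — the
#'     trace oscillates near the rails (electrode movement / loss of
#'     adhesion).}
#'   \item{low_amplitude}{`max_w - min_w < floor_fraction * (max_t - min_t)`
#'     — the ECG waves are very low or absent.}
#'   \item{excess_sd}{`sd_w > sd_multiplier * sd_t` — statistical
#'     variability beyond that of a readable trace.}
#' }
#' All inequalities are strict; a window exactly at a threshold is
#' acceptable. Because only the range and SD are compared, a window whose
#' baseline has drifted away from the template's is still acceptable if its
#' morphology is preserved.
#'
#' @param stats A one-row tibble from [compute_window_stats()] (or any data
#'   frame with `max_w`, `min_w`, `sd_w` columns).
#' @param template An [ecg_template()].
#' @param device A [device_profile()].
#' @param cfg An [sqi_config()].
#'
#' @return The `stats` tibble with columns `label` (`acceptable` /
#'   `unacceptable`) and `reason` (`ok`, `saturation`, `low_amplitude`,
#'   `excess_sd`) appended.
#' @export
classify_window <- function(stats, template, device = device_profile(),
                            cfg = sqi_config()) {
  stopifnot(inherits(template, "ecg_template"))
  range_w <- stats$max_w - stats$min_w
  reason <- dplyr::case_when(
    range_w > cfg$saturation_factor * device_span(device) ~ "saturation",
    range_w < cfg$floor_fraction * (template$max_t - template$min_t) ~ "low_amplitude",
    stats$sd_w > cfg$sd_multiplier * template$sd_t ~ "excess_sd",
    .default = "ok"
  )
  dplyr::mutate(
    tibble::as_tibble(stats),
    label = ifelse(reason == "ok", "acceptable", "unacceptable"),
    reason = reason
  )
}

#' Classify a whole recording into 2 s window verdicts
#'
#' Splits the recording into consecutive non-overlapping windows of
#' `window_len_s` seconds starting at t = 0, computes each window's
#' statistics and classifies it against the reference template. If no
#' template is supplied, [find_reference_template()] is run first; windows
#' inside the template span are classified like any others. A trailing
#' partial window is discarded with a message.
#'
#' @param signal An [ecg_signal()].
#' @param cfg An [sqi_config()].
#' @param template An [ecg_template()], or `NULL` to extract one from the
#'   signal.
#'
#' @return A tibble of window verdicts (one row per window, columns as in
#'   [classify_window()]) with the template attached as attribute
#'   `template`.
#' @examples
#' rec <- synth_ecg(synth_recipe(duration_s = 30, seed = 7))
#' classify_signal(rec$signal)
#' @export
classify_signal <- function(signal, cfg = sqi_config(), template = NULL) {
  stopifnot(inherits(signal, "ecg_signal"))
  fs <- signal_fs(signal)
  wn <- as.integer(round(cfg$window_len_s * fs))
  values <- signal$value_mv
  if (length(values) < wn) {
    rlang::abort("Signal shorter than one analysis window.",
                 class = "ecgsqi_validation")
  }
  if (is.null(template)) {
    template <- find_reference_template(signal, cfg)
  }
  n_win <- length(values) %/% wn
  leftover <- length(values) - n_win * wn
  if (leftover > 0) {
    rlang::inform(sprintf("Discarding trailing partial window (%.3f s).",
                          leftover / fs), class = "ecgsqi_partial_window")
  }
  stat_mat <- vapply(seq_len(n_win), function(i) {
    window_stats_kernel(values[((i - 1L) * wn + 1L):(i * wn)])
  }, numeric(4))
  stats <- tibble::tibble(
    index = seq_len(n_win) - 1L,
    start_s = (seq_len(n_win) - 1L) * cfg$window_len_s,
    mean_w = stat_mat["mean", ],
    max_w = stat_mat["max", ],
    min_w = stat_mat["min", ],
    sd_w = stat_mat["sd", ]
  )
  out <- classify_window(stats, template, signal_device(signal), cfg)
  attr(out, "template") <- template
  out
}

#' Aggregate window verdicts into fixed-length sample labels
#'
#' Groups consecutive window verdicts into samples of `sample_len_s`
#' seconds and labels each sample with the quality class covering the
#' majority of its duration (with the default 2 s windows in 10 s samples,
#' k = 5 windows, so no tie can occur). An exact tie — possible only for an
#' even number of windows per sample — is labelled unacceptable, the
#' conservative choice for a quality gate. A trailing incomplete group is
#' dropped with a message.
#'
#' @param verdicts Window-verdict tibble from [classify_signal()].
#' @param cfg The [sqi_config()] used to produce the verdicts.
#'
#' @return A [label_series()] with `sample_len_s = cfg$sample_len_s`.
#' @export
aggregate_windows_to_samples <- function(verdicts, cfg = sqi_config()) {
  if (nrow(verdicts) == 0L) {
    rlang::abort("No window verdicts to aggregate.", class = "ecgsqi_validation")
  }
  k <- as.integer(round(cfg$sample_len_s / cfg$window_len_s))
  n_samp <- nrow(verdicts) %/% k
  if (n_samp == 0L) {
    rlang::abort("Fewer verdicts than one aggregation group.",
                 class = "ecgsqi_validation")
  }
  if (nrow(verdicts) %% k != 0L) {
    rlang::inform(sprintf("Dropping %d trailing window verdict(s) short of a full sample.",
                          nrow(verdicts) %% k), class = "ecgsqi_partial_sample")
  }
  unacc <- matrix(verdicts$label[seq_len(n_samp * k)] == "unacceptable",
                  nrow = k)
  unacc_dur <- colSums(unacc) * cfg$window_len_s
  labels <- ifelse(unacc_dur >= cfg$sample_len_s / 2, "unacceptable", "acceptable")
  label_series(labels, sample_len_s = cfg$sample_len_s)
}

#' Convert interval annotations to fixed-length sample labels
#'
#' Maps cardiologist-style interval annotations onto the same 10 s sample
#' grid the classifier reports on: each sample takes the label of the class
#' covering at least half of it. Time not covered by any interval is
#' counted as unacceptable (and reported); an exact tie is unacceptable. A
#' trailing remainder shorter than one sample is dropped with a warning.
#'
#' @param track Annotation tibble (`start_s`, `end_s`, `label`), as from
#'   [read_annotations()].
#' @param total_duration_s Recording duration in seconds.
#' @param sample_len_s Sample length in seconds (default 10).
#'
#' @return A [label_series()].
#' @export
intervals_to_sample_labels <- function(track, total_duration_s,
                                       sample_len_s = 10) {
  stopifnot(all(c("start_s", "end_s", "label") %in% names(track)))
  check_labels(track$label)
  n_samp <- floor(total_duration_s / sample_len_s)
  if (n_samp < 1) {
    rlang::abort("Recording shorter than one sample.", class = "ecgsqi_validation")
  }
  if (total_duration_s - n_samp * sample_len_s > 1e-9) {
    rlang::warn(sprintf("Dropping %.3f s trailing remainder short of a full sample.",
                        total_duration_s - n_samp * sample_len_s),
                class = "ecgsqi_partial_sample")
  }
  acc <- track[track$label == "acceptable", , drop = FALSE]
  t0 <- (seq_len(n_samp) - 1) * sample_len_s
  acc_dur <- vapply(t0, function(s) {
    sum(pmax(0, pmin(acc$end_s, s + sample_len_s) - pmax(acc$start_s, s)))
  }, numeric(1))
  covered <- vapply(t0, function(s) {
    sum(pmax(0, pmin(track$end_s, s + sample_len_s) - pmax(track$start_s, s)))
  }, numeric(1))
  if (any(covered < sample_len_s - 1e-6)) {
    rlang::inform("Uncovered time in the annotation track is counted as unacceptable.",
                  class = "ecgsqi_uncovered")
  }
  labels <- ifelse(acc_dur > sample_len_s / 2, "acceptable", "unacceptable")
  label_series(labels, sample_len_s = sample_len_s)
}
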