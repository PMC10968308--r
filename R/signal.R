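#' Construct an ECG signal tibble
#'
#' An `ecg_signal` is a tibble with columns `time_s` and `value_mv`, carrying
#' the sampling rate and the [device_profile()] as attributes. Time is
#' 0-based seconds from recording start; amplitudes are in mV and must lie
#' within the device rails (acquisition clips there).
#'
#' @param values Numeric vector of amplitudes in mV.
#' @param fs Sampling rate in Hz (> 0).
#' @param device A [device_profile()].
#' @param start_time_s Time of the first sample, seconds (default 0).
#'
#' @return A tibble of class `ecg_signal` with columns `time_s`, `value_mv`.
#' @examples
#' sig <- ecg_signal(sin(2 * pi * seq(0, 2, by = 1 / 250)), fs = 250)
#' signal_duration(sig)
#' @export
ecg_signal <- function(values, fs, device = device_profile(), start_time_s = 0) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    rlang::abort("`fs` must be a single positive sampling rate in Hz.",
                 class = "ecgsqi_validation")
  }
  if (length(values) < 1L) {
    rlang::abort("`values` must contain at least one sample.",
                 class = "ecgsqi_validation")
  }
  stopifnot(inherits(device, "device_profile"))
  values <- as.numeric(values)
  eps <- 1e-9
  if (any(values < device$adc_min_mv - eps | values > device$adc_max_mv + eps)) {
    rlang::abort(
      "Amplitudes outside the device rails; clip them first (see `clip_to_rails()`).",
      class = "ecgsqi_validation"
    )
  }
  out <- tibble::tibble(
    time_s = start_time_s + (seq_along(values) - 1) / fs,
    value_mv = values
  )
  attr(out, "fs") <- as.numeric(fs)
  attr(out, "device") <- device
  class(out) <- c("ecg_signal", class(out))
  out
}

#' @rdname ecg_signal
#' @param signal An `ecg_signal`.
#' @return `signal_fs()`: sampling rate in Hz; `signal_device()`: the
#'   [device_profile()]; `signal_duration()`: duration in seconds.
#' @export
signal_fs <- function(signal) attr(signal, "fs")

#' @rdname ecg_signal
#' @export
signal_device <- function(signal) attr(signal, "device")

#' @rdname ecg_signal
#' @export
signal_duration <- function(signal) nrow(signal) / attr(signal, "fs")

#' Clip amplitudes to the device rails
#'
#' @param values Numeric amplitudes in mV.
#' @param device A [device_profile()].
#' @return A list with `values` (clipped) and `n_clipped` (count of samples
#'   that hit a rail).
#' @keywords internal
clip_to_rails <- function(values, device) {
  lo <- device$adc_min_mv
  hi <- device$adc_max_mv
  n_clipped <- sum(values < lo | values > hi)
  list(values = pmin(pmax(values, lo), hi), n_clipped = n_clipped)
}
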