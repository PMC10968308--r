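#' Device acquisition profile
#'
#' Describes the analog front end of the recording device: the ADC input
#' range in millivolts and its nominal resolution. The defaults match a
#' wearable single-lead monitor with an input range of +/-500 mV and an
#' 18-bit converter. The full ADC span (`adc_max_mv - adc_min_mv`) anchors
#' the saturation rule of [classify_window()]; the resolution is metadata
#' only (amplitudes are kept in physical units, no quantisation is applied).
#'
#' @param adc_min_mv Lower ADC rail in mV.
#' @param adc_max_mv Upper ADC rail in mV.
#' @param resolution_bits Nominal ADC resolution in bits (>= 8).
#' @param name Free-text device label.
#'
#' @return An object of class `device_profile`.
#' @examples
#' device_profile()
#' device_span(device_profile())
#' @export
device_profile <- function(adc_min_mv = -500, adc_max_mv = 500,
                           resolution_bits = 18L, name = "wearable-adc") {
  if (!is.numeric(adc_min_mv) || !is.numeric(adc_max_mv) ||
      adc_max_mv <= adc_min_mv) {
    rlang::abort("`adc_max_mv` must be greater than `adc_min_mv`.",
                 class = "ecgsqi_validation")
  }
  if (resolution_bits < 8) {
    rlang::abort("`resolution_bits` must be at least 8.",
                 class = "ecgsqi_validation")
  }
  structure(
    list(
      adc_min_mv = as.numeric(adc_min_mv),
      adc_max_mv = as.numeric(adc_max_mv),
      resolution_bits = as.integer(resolution_bits),
      name = as.character(name)
    ),
    class = "device_profile"
  )
}

#' @rdname device_profile
#' @param device A `device_profile`.
#' @return `device_span()`: the full ADC span in mV.
#' @export
device_span <- function(device) {
  stopifnot(inherits(device, "device_profile"))
  device$adc_max_mv - device$adc_min_mv
}

#' @export
print.device_profile <- function(x, ...) {
  cat(sprintf("<device_profile> %s: [%g, %g] mV, %d bit\n",
              x$name, x$adc_min_mv, x$adc_max_mv, x$resolution_bits))
  invisible(x)
}
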