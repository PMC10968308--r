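#' Quality label series
#'
#' A `label_series` is a tibble of consecutive fixed-length sample labels
#' (columns `sample_index` 0-based, `start_s`, `end_s`, `label`), with the
#' sample length carried as an attribute. Labels are `"acceptable"` or
#' `"unacceptable"`; samples tile the recording from t = 0 with half-open
#' spans `[start_s, end_s)`.
#'
#' @param labels Character vector of `"acceptable"` / `"unacceptable"`.
#' @param sample_len_s Sample length in seconds (> 0).
#'
#' @return A tibble of class `label_series`.
#' @examples
#' label_series(c("acceptable", "unacceptable"), sample_len_s = 10)
#' @export
label_series <- function(labels, sample_len_s) {
  if (!is.numeric(sample_len_s) || length(sample_len_s) != 1L || sample_len_s <= 0) {
    rlang::abort("`sample_len_s` must be a single positive length in seconds.",
                 class = "ecgsqi_validation")
  }
  labels <- as.character(labels)
  check_labels(labels)
  idx <- seq_along(labels) - 1L
  out <- tibble::tibble(
    sample_index = idx,
    start_s = idx * sample_len_s,
    end_s = (idx + 1L) * sample_len_s,
    label = labels
  )
  attr(out, "sample_len_s") <- as.numeric(sample_len_s)
  class(out) <- c("label_series", class(out))
  out
}

#' @rdname label_series
#' @param series A `label_series`.
#' @return `sample_len_s()`: the sample length in seconds.
#' @export
sample_len_s <- function(series) attr(series, "sample_len_s")

quality_levels <- c("acceptable", "unacceptable")

check_labels <- function(labels) {
  bad <- setdiff(unique(labels), quality_levels)
  if (length(bad) > 0) {
    rlang::abort(
      sprintf("Unknown quality label(s): %s (expected %s).",
              paste(bad, collapse = ", "),
              paste(quality_levels, collapse = " or ")),
      class = "ecgsqi_validation"
    )
  }
  invisible(labels)
}
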