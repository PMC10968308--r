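#' Streaming (sample-by-sample) window classifier
#'
#' Real-time counterpart of [classify_signal()]: samples are pushed one at a
#' time as they are acquired, and exactly one window verdict is emitted when
#' `window_len_s * fs` samples have accumulated, after which the window
#' resets. The verdict is available with a delay of one window length. The
#' current window is buffered and evaluated with the same statistics kernel
#' as the batch path, so the emitted verdict sequence is bit-identical to
#' `classify_signal()` on the same series.
#'
#' @param template An [ecg_template()] — preset, or found beforehand with
#'   [find_reference_template()].
#' @param fs Sampling rate in Hz.
#' @param cfg An [sqi_config()].
#' @param device A [device_profile()].
#'
#' @return An object of class `streaming_classifier` with methods
#' \describe{
#'   \item{`$push(value)`}{Push one sample (mV). Returns a one-row verdict
#'     tibble when a window completes, otherwise `NULL` invisibly.}
#'   \item{`$push_all(values)`}{Push a vector of samples; returns the tibble
#'     of all verdicts emitted (zero rows if none).}
#'   \item{`$close()`}{Close the stream; any buffered partial window is
#'     discarded with a message. Pushing after close is an error.}
#' }
#' @examples
#' tpl <- ecg_template(max_t = 1, min_t = -0.2, sd_t = 0.2)
#' sc <- streaming_classifier(tpl, fs = 250)
#' v <- sc$push_all(rnorm(500, sd = 0.1))
#' nrow(v)
#' @export
streaming_classifier <- function(template, fs, cfg = sqi_config(),
                                 device = device_profile()) {
  stopifnot(inherits(template, "ecg_template"))
  wn <- as.integer(round(cfg$window_len_s * fs))
  buf <- numeric(wn)
  n <- 0L
  win_index <- 0L
  closed <- FALSE

  emit <- function() {
    stats <- compute_window_stats(buf, start_s = win_index * cfg$window_len_s,
                                  index = win_index)
    win_index <<- win_index + 1L
    n <<- 0L
    classify_window(stats, template, device, cfg)
  }

  push <- function(value) {
    if (closed) {
      rlang::abort("Stream is closed; no further samples accepted.",
                   class = "ecgsqi_stream_closed")
    }
    n <<- n + 1L
    buf[n] <<- value
    if (n == wn) emit() else invisible(NULL)
  }

  push_all <- function(values) {
    out <- vector("list", (n + length(values)) %/% wn)
    j <- 0L
    for (v in values) {
      res <- push(v)
      if (!is.null(res)) {
        j <- j + 1L
        out[[j]] <- res
      }
    }
    dplyr::bind_rows(out)
  }

  close <- function() {
    if (n > 0L) {
      rlang::inform(sprintf("Discarding %d buffered sample(s) of a partial window.", n),
                    class = "ecgsqi_partial_window")
    }
    closed <<- TRUE
    invisible(NULL)
  }

  structure(
    list(push = push, push_all = push_all, close = close,
         template = template, fs = fs, cfg = cfg, device = device),
    class = "streaming_classifier"
  )
}

#' @export
print.streaming_classifier <- function(x, ...) {
  cat(sprintf("<streaming_classifier> fs=%g Hz, window=%g s\n",
              x$fs, x$cfg$window_len_s))
  invisible(x)
}
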