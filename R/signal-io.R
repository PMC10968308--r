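#' Read a single-lead ECG signal from delimited text
#'
#' Accepts the two tabular layouts used throughout the package: two
#' comma-separated columns `time_s,value_mv`, or a single `value_mv` column
#' (in which case `fs` is required). A non-numeric first row is treated as a
#' header. Amplitudes are clipped to the device rails; the number of clipped
#' samples is reported with a warning and stored in the `n_clipped`
#' attribute of the result.
#'
#' @param path Path to the CSV file.
#' @param fs Sampling rate in Hz. Required for one-column files; for
#'   two-column files it defaults to the rate implied by the time column.
#' @param device A [device_profile()] giving the rails.
#'
#' @return An [ecg_signal()].
#' @seealso [write_ecg_signal()]
#' @export
read_ecg_signal <- function(path, fs = NULL, device = device_profile()) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    rlang::abort(sprintf("Empty signal file: %s", path), class = "ecgsqi_parse")
  }
  first <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  data_lines <- if (has_header) lines[-1] else lines
  if (length(data_lines) == 0L) {
    rlang::abort(sprintf("No data rows in signal file: %s", path),
                 class = "ecgsqi_parse")
  }
  parts <- strsplit(data_lines, ",", fixed = TRUE)
  ncol <- length(parts[[1]])
  if (!ncol %in% c(1L, 2L)) {
    rlang::abort(sprintf("Expected 1 or 2 columns, found %d in %s", ncol, path),
                 class = "ecgsqi_parse")
  }
  nfield <- lengths(parts)
  if (any(nfield != ncol)) {
    bad <- which(nfield != ncol)[1]
    rlang::abort(sprintf("Ragged row at line %d of %s",
                         bad + has_header, path), class = "ecgsqi_parse")
  }
  mat <- suppressWarnings(matrix(as.numeric(unlist(parts)),
                                 ncol = ncol, byrow = TRUE))
  if (anyNA(mat)) {
    bad <- which(apply(is.na(mat), 1, any))[1]
    rlang::abort(sprintf("Non-numeric value at line %d of %s",
                         bad + has_header, path), class = "ecgsqi_parse")
  }
  if (ncol == 1L) {
    if (is.null(fs)) {
      rlang::abort("`fs` is required for one-column signal files.",
                   class = "ecgsqi_validation")
    }
    values <- mat[, 1]
    start_time_s <- 0
  } else {
    time_s <- mat[, 1]
    values <- mat[, 2]
    if (length(time_s) > 1) {
      dt <- diff(time_s)
      fs_implied <- 1 / stats::median(dt)
      if (is.null(fs)) fs <- fs_implied
      if (any(dt <= 0) || any(dt > 1.5 / fs)) {
        rlang::abort(sprintf("Non-uniform time column in %s (gap > 1.5/fs).", path),
                     class = "ecgsqi_parse")
      }
    } else if (is.null(fs)) {
      rlang::abort("`fs` is required when the time column has a single row.",
                   class = "ecgsqi_validation")
    }
    start_time_s <- time_s[1]
  }
  clipped <- clip_to_rails(values, device)
  if (clipped$n_clipped > 0) {
    rlang::warn(sprintf("%d sample(s) outside the device rails were clipped.",
                        clipped$n_clipped), class = "ecgsqi_clipped")
  }
  out <- ecg_signal(clipped$values, fs = fs, device = device,
                    start_time_s = start_time_s)
  attr(out, "n_clipped") <- clipped$n_clipped
  out
}

#' Write an ECG signal as delimited text
#'
#' Writes `time_s,value_mv` rows with a header, amplitudes formatted to six
#' decimal places so that a write/read round trip reproduces values to that
#' precision. Output is byte-stable across runs.
#'
#' @param signal An [ecg_signal()].
#' @param path Output path.
#' @param include_time Write the time column (default) or a single
#'   `value_mv` column.
#' @return `path`, invisibly.
#' @export
write_ecg_signal <- function(signal, path, include_time = TRUE) {
  stopifnot(inherits(signal, "ecg_signal"))
  if (include_time) {
    lines <- c("time_s,value_mv",
               sprintf("%.6f,%.6f", signal$time_s, signal$value_mv))
  } else {
    lines <- c("value_mv", sprintf("%.6f", signal$value_mv))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write and read 10 s (or other fixed-length) label series
#'
#' `write_labels()` serialises a [label_series()] as CSV with columns
#' `sample_index,start_s,end_s,label`; `read_labels()` reads it back
#' exactly.
#'
#' @param series A non-empty [label_series()].
#' @param path File path.
#' @return `write_labels()`: `path` invisibly; `read_labels()`: a
#'   [label_series()].
#' @export
write_labels <- function(series, path) {
  stopifnot(inherits(series, "label_series"))
  if (nrow(series) == 0L) {
    rlang::abort("Refusing to write an empty label series.",
                 class = "ecgsqi_validation")
  }
  lines <- c("sample_index,start_s,end_s,label",
             sprintf("%d,%g,%g,%s", series$sample_index, series$start_s,
                     series$end_s, series$label))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_index", "start_s", "end_s", "label")
  if (!all(required %in% names(df))) {
    rlang::abort(sprintf("Label file %s must have columns %s.", path,
                         paste(required, collapse = ", ")),
                 class = "ecgsqi_parse")
  }
  if (nrow(df) == 0L) {
    rlang::abort(sprintf("Empty label file: %s", path), class = "ecgsqi_parse")
  }
  len <- df$end_s[1] - df$start_s[1]
  label_series(df$label, sample_len_s = len)
}

#' Read annotation intervals
#'
#' Reads cardiologist-style interval annotations from CSV with columns
#' `start_s,end_s,label` (header optional). Intervals are validated
#' (positive length, known labels, no overlap after sorting) and returned
#' sorted by start time.
#'
#' @param path File path.
#' @return A tibble with columns `start_s`, `end_s`, `label`.
#' @export
read_annotations <- function(path) {
  first <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(first[1])))
  df <- utils::read.csv(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) names(df) <- c("start_s", "end_s", "label")
  annotation_track(df$start_s, df$end_s, df$label)
}

#' Build a validated annotation track
#'
#' @param start_s,end_s Interval bounds in seconds (half-open).
#' @param label Quality label per interval.
#' @return A tibble sorted by `start_s`.
#' @export
annotation_track <- function(start_s, end_s, label) {
  start_s <- as.numeric(start_s)
  end_s <- as.numeric(end_s)
  label <- trimws(as.character(label))
  check_labels(label)
  if (any(end_s <= start_s)) {
    bad <- which(end_s <= start_s)[1]
    rlang::abort(sprintf("Interval %d has end_s <= start_s.", bad),
                 class = "ecgsqi_validation")
  }
  ord <- order(start_s)
  out <- tibble::tibble(start_s = start_s[ord], end_s = end_s[ord],
                        label = label[ord])
  if (nrow(out) > 1) {
    ov <- which(out$start_s[-1] < out$end_s[-nrow(out)] - 1e-9)
    if (length(ov) > 0) {
      rlang::abort(sprintf("Intervals %d and %d overlap.", ov[1], ov[1] + 1L),
                   class = "ecgsqi_validation")
    }
  }
  out
}
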