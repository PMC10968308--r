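#' 2x2 agreement table between predicted and reference labels
#'
#' The positive class is `unacceptable` throughout: `tp` counts samples both
#' classifier and reference call unacceptable, `tn` samples both call
#' acceptable, `fn` reference-unacceptable samples the classifier passed,
#' `fp` reference-acceptable samples it flagged.
#'
#' @param tp,fn,fp,tn Non-negative integer cell counts.
#' @return An object of class `sqi_confusion`.
#' @examples
#' confusion_matrix(tp = 3150, fn = 175, fp = 177, tn = 3698)
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    rlang::abort("Confusion cells must be non-negative integers.",
                 class = "ecgsqi_validation")
  }
  structure(as.list(cells), class = "sqi_confusion")
}

#' @export
print.sqi_confusion <- function(x, ...) {
  cat("<sqi_confusion>  (positive class: unacceptable)\n")
  cat(sprintf("                    reference unacc.  reference acc.\n"))
  cat(sprintf("  predicted unacc.  %16d  %14d\n", x$tp, x$fp))
  cat(sprintf("  predicted acc.    %16d  %14d\n", x$fn, x$tn))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.sqi_confusion <- function(x, ...) {
  tibble::tibble(
    cell = c("tp", "fn", "fp", "tn"),
    predicted = c("unacceptable", "acceptable", "unacceptable", "acceptable"),
    reference = c("unacceptable", "unacceptable", "acceptable", "acceptable"),
    n = c(x$tp, x$fn, x$fp, x$tn)
  )
}

#' Build the agreement table from two label series
#'
#' @param predicted,reference [label_series()] objects of equal length and
#'   sample length (classifier output and reference labels).
#' @return An `sqi_confusion`.
#' @export
confusion_from_labels <- function(predicted, reference) {
  stopifnot(inherits(predicted, "label_series"),
            inherits(reference, "label_series"))
  if (nrow(predicted) != nrow(reference)) {
    rlang::abort(sprintf("Series length mismatch: %d vs %d samples.",
                         nrow(predicted), nrow(reference)),
                 class = "ecgsqi_validation")
  }
  if (!isTRUE(all.equal(sample_len_s(predicted), sample_len_s(reference)))) {
    rlang::abort("Series have different sample lengths.",
                 class = "ecgsqi_validation")
  }
  p <- predicted$label == "unacceptable"
  r <- reference$label == "unacceptable"
  confusion_matrix(tp = sum(p & r), fn = sum(!p & r),
                   fp = sum(p & !r), tn = sum(!p & !r))
}

#' Diagnostic-test statistics from an agreement table
#'
#' Computes the full diagnostic report for the 2x2 table (positive class
#' unacceptable): sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`,
#' predictive values, likelihood ratios `LR+ = sens/(1-spec)` and
#' `LR- = (1-sens)/spec`, global efficiency `(tp+tn)/total`, prevalence
#' `(tp+fn)/total`, and Wald confidence-interval half-widths
#' `z * sqrt(p(1-p)/n)` for sensitivity and specificity on their respective
#' denominators. A ratio whose denominator is zero is returned as `NA` and
#' listed in the `undefined` field rather than reported as infinite.
#'
#' @param cm An `sqi_confusion` ([confusion_matrix()]).
#' @param ci_level Confidence level for the interval half-widths.
#' @return An object of class `sqi_metrics` (see [tidy.sqi_metrics()]).
#' @examples
#' m <- compute_metrics(confusion_matrix(tp = 3150, fn = 175, fp = 177, tn = 3698))
#' m
#' glance(m)
#' @export
compute_metrics <- function(cm, ci_level = 0.95) {
  stopifnot(inherits(cm, "sqi_confusion"))
  total <- cm$tp + cm$fn + cm$fp + cm$tn
  if (total == 0) {
    rlang::abort("Empty agreement table.", class = "ecgsqi_validation")
  }
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- safe_div(cm$tp, cm$tp + cm$fn)
  spec <- safe_div(cm$tn, cm$tn + cm$fp)
  ppv <- safe_div(cm$tp, cm$tp + cm$fp)
  npv <- safe_div(cm$tn, cm$tn + cm$fn)
  lr_pos <- if (!is.na(spec) && spec < 1 && !is.na(sens)) sens / (1 - spec) else NA_real_
  lr_neg <- if (!is.na(spec) && spec > 0 && !is.na(sens)) (1 - sens) / spec else NA_real_
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  wald <- function(p, n) if (!is.na(p) && n > 0) z * sqrt(p * (1 - p) / n) else NA_real_
  out <- list(
    sensitivity = sens,
    specificity = spec,
    ppv = ppv,
    npv = npv,
    lr_pos = lr_pos,
    lr_neg = lr_neg,
    efficiency = (cm$tp + cm$tn) / total,
    prevalence = (cm$tp + cm$fn) / total,
    ci_sensitivity_halfwidth = wald(sens, cm$tp + cm$fn),
    ci_specificity_halfwidth = wald(spec, cm$tn + cm$fp),
    n_total = total,
    ci_level = ci_level,
    cm = cm
  )
  out$undefined <- names(which(vapply(
    out[c("sensitivity", "specificity", "ppv", "npv", "lr_pos", "lr_neg")],
    is.na, logical(1))))
  structure(out, class = "sqi_metrics")
}

#' @export
print.sqi_metrics <- function(x, ...) {
  cat(sprintf("<sqi_metrics> n = %d (positive class: unacceptable)\n", x$n_total))
  pct <- function(v) if (is.na(v)) "   NA" else sprintf("%5.1f%%", 100 * v)
  cat(sprintf("  sensitivity  %s (+/- %s)\n", pct(x$sensitivity),
              pct(x$ci_sensitivity_halfwidth)))
  cat(sprintf("  specificity  %s (+/- %s)\n", pct(x$specificity),
              pct(x$ci_specificity_halfwidth)))
  cat(sprintf("  PPV          %s\n", pct(x$ppv)))
  cat(sprintf("  NPV          %s\n", pct(x$npv)))
  cat(sprintf("  efficiency   %s\n", pct(x$efficiency)))
  cat(sprintf("  prevalence   %s\n", pct(x$prevalence)))
  cat(sprintf("  LR+          %s\n",
              if (is.na(x$lr_pos)) "undefined" else sprintf("%.3g", x$lr_pos)))
  cat(sprintf("  LR-          %s\n",
              if (is.na(x$lr_neg)) "undefined" else sprintf("%.2g", x$lr_neg)))
  if (length(x$undefined)) {
    cat("  undefined (zero denominator):", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy and glance methods for metric reports
#'
#' `tidy()` returns one row per statistic; `glance()` a one-row tibble of
#' all statistics, convenient for binding across recordings.
#'
#' @param x An `sqi_metrics` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sqi_metrics <- function(x, ...) {
  nm <- c("sensitivity", "specificity", "ppv", "npv", "lr_pos", "lr_neg",
          "efficiency", "prevalence", "ci_sensitivity_halfwidth",
          "ci_specificity_halfwidth")
  tibble::tibble(metric = nm, value = vapply(x[nm], identity, numeric(1)))
}

#' @rdname tidy.sqi_metrics
#' @importFrom generics glance
#' @export
glance.sqi_metrics <- function(x, ...) {
  nm <- c("sensitivity", "specificity", "ppv", "npv", "lr_pos", "lr_neg",
          "efficiency", "prevalence", "ci_sensitivity_halfwidth",
          "ci_specificity_halfwidth", "n_total")
  tibble::as_tibble(x[nm])
}

#' Per-recording efficiency summary
#'
#' Summarises agreement across recordings: per-recording efficiency (the
#' fraction of correctly classified samples) with its order statistics.
#'
#' @param per_recording A data frame with columns `recording`, `tp`, `fn`,
#'   `fp`, `tn` (one row per recording), or a named list of
#'   [confusion_matrix()] objects.
#' @return An object of class `sqi_recording_summary`: `$per_recording`
#'   (tibble of recording, efficiency and cells) and `$summary` (one-row
#'   tibble: mean, median, min, max efficiency, n_recordings).
#' @export
summarize_by_recording <- function(per_recording) {
  if (is.list(per_recording) && !is.data.frame(per_recording) &&
      all(vapply(per_recording, inherits, logical(1), "sqi_confusion"))) {
    per_recording <- dplyr::bind_rows(lapply(per_recording, function(cm) {
      tibble::tibble(tp = cm$tp, fn = cm$fn, fp = cm$fp, tn = cm$tn)
    }), .id = "recording")
  }
  per_recording <- tibble::as_tibble(per_recording)
  stopifnot(all(c("tp", "fn", "fp", "tn") %in% names(per_recording)))
  if (nrow(per_recording) == 0L) {
    rlang::abort("No recordings to summarise.", class = "ecgsqi_validation")
  }
  if (!"recording" %in% names(per_recording)) {
    per_recording$recording <- sprintf("rec%02d", seq_len(nrow(per_recording)))
  }
  per <- dplyr::mutate(
    per_recording,
    efficiency = (.data$tp + .data$tn) /
      (.data$tp + .data$fn + .data$fp + .data$tn)
  )
  summary <- dplyr::summarise(
    per,
    mean_efficiency = mean(.data$efficiency),
    median_efficiency = stats::median(.data$efficiency),
    min_efficiency = min(.data$efficiency),
    max_efficiency = max(.data$efficiency),
    n_recordings = dplyr::n()
  )
  structure(list(per_recording = per, summary = summary),
            class = "sqi_recording_summary")
}

#' @export
print.sqi_recording_summary <- function(x, ...) {
  cat(sprintf("<sqi_recording_summary> %d recording(s)\n",
              x$summary$n_recordings))
  cat(sprintf("  efficiency: mean %.3f, median %.3f, range [%.3f, %.3f]\n",
              x$summary$mean_efficiency, x$summary$median_efficiency,
              x$summary$min_efficiency, x$summary$max_efficiency))
  invisible(x)
}

#' @export
tidy.sqi_recording_summary <- function(x, ...) x$per_recording

#' @export
glance.sqi_recording_summary <- function(x, ...) x$summary
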