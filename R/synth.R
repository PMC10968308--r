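#' Beat morphology model for synthetic ECG
#'
#' One cardiac cycle is modelled as a sum of Gaussian deflections, one per
#' wave (P, Q, R, S, T) — the usual simplification for seedable,
#' amplitude-controllable ECG synthesis. Wave centres are expressed as a
#' fraction of the RR interval relative to the R peak; widths are Gaussian
#' SDs in seconds. Defaults are typical single-lead amplitudes: R = 1.0 mV,
#' P = 0.15 mV, T = 0.3 mV, Q = S = -0.1 mV.
#'
#' @param heart_rate_bpm Mean heart rate, beats per minute (30-220).
#' @param hr_jitter_fraction Uniform RR jitter as a fraction of the mean RR
#'   interval (0 disables jitter).
#' @param waves Data frame with columns `wave`, `amp_mv`, `offset_frac`,
#'   `width_s`; the R row must have the largest absolute amplitude.
#'
#' @return An object of class `beat_model`.
#' @examples
#' beat_model(heart_rate_bpm = 72)
#' @export
beat_model <- function(heart_rate_bpm = 60, hr_jitter_fraction = 0.05,
                       waves = NULL) {
  if (is.null(waves)) {
    waves <- tibble::tibble(
      wave = c("P", "Q", "R", "S", "T"),
      amp_mv = c(0.15, -0.10, 1.00, -0.10, 0.30),
      offset_frac = c(-0.25, -0.045, 0, 0.045, 0.30),
      width_s = c(0.025, 0.010, 0.012, 0.010, 0.060)
    )
  }
  waves <- tibble::as_tibble(waves)
  stopifnot(all(c("wave", "amp_mv", "offset_frac", "width_s") %in% names(waves)))
  if (heart_rate_bpm < 30 || heart_rate_bpm > 220) {
    rlang::abort("`heart_rate_bpm` must lie in [30, 220].",
                 class = "ecgsqi_validation")
  }
  if (any(waves$width_s <= 0)) {
    rlang::abort("Wave widths must be positive.", class = "ecgsqi_validation")
  }
  r_amp <- waves$amp_mv[waves$wave == "R"]
  if (length(r_amp) != 1L || any(abs(waves$amp_mv[waves$wave != "R"]) >= r_amp)) {
    rlang::abort("The R wave must dominate all other wave amplitudes.",
                 class = "ecgsqi_validation")
  }
  structure(
    list(heart_rate_bpm = heart_rate_bpm,
         hr_jitter_fraction = hr_jitter_fraction,
         waves = waves),
    class = "beat_model"
  )
}

#' Scheduled artifact episode
#'
#' One noise episode of a given kind over `[start_s, start_s + duration_s)`.
#' Kinds and their parameters (defaults in parentheses):
#' \describe{
#'   \item{baseline_wander}{additive low-frequency sinusoid;
#'     `amplitude_mv` (0.3), `frequency_hz` (0.33, must be <= 0.5).
#'     Readable: the rules tolerate a drifting isoelectric line.}
#'   \item{saturation}{the trace is replaced by a large low-frequency
#'     oscillation clipped at the ADC rails, emulating electrode movement /
#'     loss of adhesion; `amplitude_mv` (600), `frequency_hz` (1).}
#'   \item{muscle}{additive zero-mean noise high-passed above 20 Hz with the
#'     given standard deviation; `sd_mv` (0.5).}
#'   \item{flatline}{the trace is scaled to `residual_fraction` (0.02) of
#'     its amplitude, emulating an absent ECG.}
#'   \item{powerline}{additive 50 Hz sinusoid; `amplitude_mv` (0.25). Small
#'     enough to leave the window statistics inside all thresholds — the
#'     classifier's documented blind spot.}
#' }
#'
#' @param kind Episode kind (see above).
#' @param start_s,duration_s Episode span in seconds.
#' @param amplitude_mv,frequency_hz,sd_mv,residual_fraction Kind-specific
#'   magnitudes; unused ones are ignored.
#'
#' @return A one-row tibble; bind rows to schedule several episodes.
#' @examples
#' noise_episode("saturation", start_s = 20, duration_s = 10)
#' @export
noise_episode <- function(kind, start_s, duration_s,
                          amplitude_mv = NULL, frequency_hz = NULL,
                          sd_mv = NULL, residual_fraction = NULL) {
  kinds <- c("baseline_wander", "saturation", "muscle", "flatline", "powerline")
  if (!kind %in% kinds) {
    rlang::abort(sprintf("Unknown episode kind '%s'.", kind),
                 class = "ecgsqi_validation")
  }
  if (duration_s <= 0) {
    rlang::abort("`duration_s` must be positive.", class = "ecgsqi_validation")
  }
  defaults <- switch(kind,
    baseline_wander = list(amplitude_mv = 0.3, frequency_hz = 0.33),
    saturation = list(amplitude_mv = 600, frequency_hz = 1),
    muscle = list(sd_mv = 0.5),
    flatline = list(residual_fraction = 0.02),
    powerline = list(amplitude_mv = 0.25, frequency_hz = 50)
  )
  take <- function(given, nm) {
    if (!is.null(given)) given else defaults[[nm]] %||% NA_real_
  }
  frequency_hz <- take(frequency_hz, "frequency_hz")
  if (kind == "baseline_wander" && !is.na(frequency_hz) && frequency_hz > 0.5) {
    rlang::abort("Baseline wander frequency must be <= 0.5 Hz.",
                 class = "ecgsqi_validation")
  }
  tibble::tibble(
    kind = kind,
    start_s = as.numeric(start_s),
    duration_s = as.numeric(duration_s),
    amplitude_mv = take(amplitude_mv, "amplitude_mv"),
    frequency_hz = frequency_hz,
    sd_mv = take(sd_mv, "sd_mv"),
    residual_fraction = take(residual_fraction, "residual_fraction")
  )
}

#' Synthetic recording recipe
#'
#' Everything needed to generate one synthetic recording deterministically:
#' duration, sampling rate, device, beat model, artifact schedule and seed.
#' All randomness (RR jitter, muscle noise, cohort schedules) is a pure
#' function of the seed.
#'
#' @param duration_s Recording length in seconds (>= 20, so a stable
#'   template period always fits).
#' @param fs Sampling rate in Hz (default 250, a typical wearable rate; the
#'   device's true rate is a runtime parameter throughout).
#' @param device A [device_profile()].
#' @param beat A [beat_model()].
#' @param episodes Episode tibble ([noise_episode()] rows), or `NULL`.
#' @param seed Integer seed fixing all randomness.
#'
#' @return An object of class `synth_recipe`.
#' @export
synth_recipe <- function(duration_s = 60, fs = 250, device = device_profile(),
                         beat = beat_model(), episodes = NULL, seed = 1L) {
  if (duration_s < 20) {
    rlang::abort("`duration_s` must be at least 20 s.", class = "ecgsqi_validation")
  }
  if (fs <= 0) {
    rlang::abort("`fs` must be positive.", class = "ecgsqi_validation")
  }
  stopifnot(inherits(device, "device_profile"), inherits(beat, "beat_model"))
  if (is.null(episodes)) {
    episodes <- noise_episode("powerline", 0, 1)[0, ]
  }
  episodes <- tibble::as_tibble(episodes)
  if (nrow(episodes) > 0) {
    if (any(episodes$start_s < 0 |
            episodes$start_s + episodes$duration_s > duration_s + 1e-9)) {
      rlang::abort("Episodes must lie within [0, duration_s).",
                   class = "ecgsqi_validation")
    }
    by_kind <- split(episodes, episodes$kind)
    for (e in by_kind) {
      if (nrow(e) > 1) {
        e <- e[order(e$start_s), ]
        if (any(e$start_s[-1] < (e$start_s + e$duration_s)[-nrow(e)] - 1e-9)) {
          rlang::abort(sprintf("Episodes of kind '%s' overlap.", e$kind[1]),
                       class = "ecgsqi_validation")
        }
      }
    }
  }
  structure(
    list(duration_s = duration_s, fs = fs, device = device, beat = beat,
         episodes = episodes, seed = as.integer(seed)),
    class = "synth_recipe"
  )
}

#' Generate the clean (artifact-free) ECG of a recipe
#'
#' Builds the Gaussian-wave beat train at jittered RR intervals. Only the
#' recipe's beat model, duration, sampling rate and seed are used; the
#' episode schedule is applied separately by [apply_episodes()]. The output
#' is deterministic given the seed.
#'
#' @param recipe A [synth_recipe()].
#' @return An [ecg_signal()].
#' @export
generate_clean_ecg <- function(recipe) {
  stopifnot(inherits(recipe, "synth_recipe"))
  fs <- recipe$fs
  n <- as.integer(round(recipe$duration_s * fs))
  beat <- recipe$beat
  rr_base <- 60 / beat$heart_rate_bpm
  values <- withr::with_seed(recipe$seed, {
    v <- numeric(n)
    t_end <- recipe$duration_s
    peak <- rr_base / 2
    waves <- beat$waves
    while (peak < t_end + rr_base) {
      rr <- rr_base * (1 + beat$hr_jitter_fraction * stats::runif(1, -1, 1))
      for (w in seq_len(nrow(waves))) {
        centre <- peak + waves$offset_frac[w] * rr
        sd_w <- waves$width_s[w]
        i0 <- max(1L, as.integer(floor((centre - 4 * sd_w) * fs)) + 1L)
        i1 <- min(n, as.integer(ceiling((centre + 4 * sd_w) * fs)) + 1L)
        if (i1 < i0) next
        tt <- (seq.int(i0, i1) - 1) / fs
        v[i0:i1] <- v[i0:i1] +
          waves$amp_mv[w] * exp(-0.5 * ((tt - centre) / sd_w)^2)
      }
      peak <- peak + rr
    }
    v
  })
  dev <- recipe$device
  if (any(values < dev$adc_min_mv | values > dev$adc_max_mv)) {
    rlang::abort("Beat model drives amplitudes beyond the device rails.",
                 class = "ecgsqi_validation")
  }
  ecg_signal(values, fs = fs, device = dev)
}

#' Apply the recipe's artifact episodes to a clean signal
#'
#' Applies each scheduled [noise_episode()] to the clean trace (additive for
#' wander, muscle and powerline; replacement for saturation; scaling for
#' flatline) and clips the result to the device rails. Muscle noise is the
#' only stochastic transform; it is seeded from the recipe so the result is
#' deterministic.
#'
#' @param clean An [ecg_signal()] from [generate_clean_ecg()].
#' @param recipe The [synth_recipe()] carrying the episode schedule.
#' @return An [ecg_signal()] with attribute `n_clipped`.
#' @export
apply_episodes <- function(clean, recipe) {
  stopifnot(inherits(clean, "ecg_signal"), inherits(recipe, "synth_recipe"))
  fs <- signal_fs(clean)
  n <- nrow(clean)
  values <- clean$value_mv
  eps <- recipe$episodes
  if (nrow(eps) > 0 &&
      any(eps$start_s < 0 | eps$start_s + eps$duration_s > n / fs + 1e-9)) {
    rlang::abort("Episode outside the recording.", class = "ecgsqi_validation")
  }
  values <- withr::with_seed(recipe$seed + 1L, {
    v <- values
    for (i in seq_len(nrow(eps))) {
      e <- eps[i, ]
      i0 <- as.integer(floor(e$start_s * fs)) + 1L
      i1 <- min(n, as.integer(round((e$start_s + e$duration_s) * fs)))
      idx <- i0:i1
      tau <- (idx - 1) / fs - e$start_s
      v[idx] <- switch(e$kind,
        baseline_wander = v[idx] +
          e$amplitude_mv * sin(2 * pi * e$frequency_hz * tau),
        powerline = v[idx] +
          e$amplitude_mv * sin(2 * pi * e$frequency_hz * tau),
        saturation = e$amplitude_mv * sin(2 * pi * e$frequency_hz * tau),
        flatline = v[idx] * e$residual_fraction,
        muscle = v[idx] + band_limited_noise(length(idx), fs, e$sd_mv)
      )
    }
    v
  })
  clipped <- clip_to_rails(values, signal_device(clean))
  out <- ecg_signal(clipped$values, fs = fs, device = signal_device(clean))
  attr(out, "n_clipped") <- clipped$n_clipped
  out
}

# Zero-mean white noise high-passed above 20 Hz (Butterworth, zero phase),
# rescaled to the requested population SD.
band_limited_noise <- function(len, fs, sd_mv) {
  white <- stats::rnorm(len)
  cutoff <- 20 / (fs / 2)
  if (len > 24 && cutoff < 1) {
    bf <- signal::butter(4, cutoff, type = "high")
    white <- signal::filtfilt(bf, white)
  }
  white <- white - sum(white) / len
  s <- sqrt(sum(white^2) / len)
  if (s == 0) return(numeric(len))
  white * (sd_mv / s)
}

#' Ground-truth quality labels implied by a recipe
#'
#' Derives the labels a perfect reader would assign, directly from the
#' episode schedule (never from the classifier): a 2 s window is truth-
#' unacceptable iff at least `coverage_fraction` (default half) of it is
#' covered by a corrupting episode — saturation, flatline, or muscle noise
#' whose SD is at least `muscle_sd_factor` times the clean signal's SD.
#' Baseline wander and powerline interference leave the trace readable and
#' are truth-acceptable; setting `strict_powerline = TRUE` applies the
#' stricter convention under which 50 Hz contamination is unacceptable,
#' which exposes the classifier's blind spot as a sensitivity deficit.
#' 10 s labels follow by the same duration-prevalence rule the classifier
#' uses.
#'
#' @param recipe A [synth_recipe()].
#' @param clean_sd Population SD of the recipe's clean signal; computed via
#'   [generate_clean_ecg()] when omitted.
#' @param strict_powerline Treat powerline episodes as corrupting.
#' @param coverage_fraction Minimum corrupted fraction of a window.
#' @param muscle_sd_factor Corruption threshold for muscle noise, as a
#'   multiple of the clean-signal SD.
#' @param cfg An [sqi_config()] (window/sample lengths).
#'
#' @return A list with [label_series()] elements `windows` (2 s) and
#'   `samples` (10 s).
#' @export
ground_truth_labels <- function(recipe, clean_sd = NULL,
                                strict_powerline = FALSE,
                                coverage_fraction = 0.5,
                                muscle_sd_factor = 1,
                                cfg = sqi_config()) {
  stopifnot(inherits(recipe, "synth_recipe"))
  if (is.null(clean_sd)) {
    v <- generate_clean_ecg(recipe)$value_mv
    mu <- sum(v) / length(v)
    clean_sd <- sqrt(sum((v - mu)^2) / length(v))
  }
  eps <- recipe$episodes
  corrupting <- eps[
    eps$kind %in% c("saturation", "flatline") |
      (eps$kind == "muscle" & eps$sd_mv >= muscle_sd_factor * clean_sd) |
      (strict_powerline & eps$kind == "powerline"), , drop = FALSE]
  wlen <- cfg$window_len_s
  n_w <- floor(recipe$duration_s / wlen)
  coverage <- numeric(n_w)
  if (nrow(corrupting) > 0) {
    iv <- merge_intervals(corrupting$start_s,
                          corrupting$start_s + corrupting$duration_s)
    for (i in seq_len(n_w)) {
      w0 <- (i - 1) * wlen
      coverage[i] <- sum(pmax(0, pmin(iv$end, w0 + wlen) - pmax(iv$start, w0)))
    }
  }
  win_labels <- ifelse(coverage >= coverage_fraction * wlen - 1e-9,
                       "unacceptable", "acceptable")
  windows <- label_series(win_labels, sample_len_s = wlen)
  k <- as.integer(round(cfg$sample_len_s / wlen))
  n_s <- n_w %/% k
  unacc <- matrix(win_labels[seq_len(n_s * k)] == "unacceptable", nrow = k)
  samp_labels <- ifelse(colSums(unacc) * wlen >= cfg$sample_len_s / 2,
                        "unacceptable", "acceptable")
  samples <- label_series(samp_labels, sample_len_s = cfg$sample_len_s)
  list(windows = windows, samples = samples)
}

# Merge possibly-overlapping intervals into a disjoint union.
merge_intervals <- function(start, end) {
  ord <- order(start)
  start <- start[ord]; end <- end[ord]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

#' Generate one synthetic recording with ground truth
#'
#' Runs [generate_clean_ecg()], [apply_episodes()] and
#' [ground_truth_labels()] for one recipe.
#'
#' @param recipe A [synth_recipe()].
#' @param strict_powerline Passed to [ground_truth_labels()].
#' @return An object of class `synth_result`: a list with `signal`
#'   ([ecg_signal()]), `truth_windows` and `truth_samples`
#'   ([label_series()]), `clean_sd` and the `recipe` echo.
#' @examples
#' res <- synth_ecg(synth_recipe(duration_s = 40, seed = 3))
#' res$truth_samples
#' @export
synth_ecg <- function(recipe, strict_powerline = FALSE) {
  clean <- generate_clean_ecg(recipe)
  v <- clean$value_mv
  mu <- sum(v) / length(v)
  clean_sd <- sqrt(sum((v - mu)^2) / length(v))
  sig <- apply_episodes(clean, recipe)
  truth <- ground_truth_labels(recipe, clean_sd = clean_sd,
                               strict_powerline = strict_powerline)
  structure(
    list(signal = sig, truth_windows = truth$windows,
         truth_samples = truth$samples, clean_sd = clean_sd,
         recipe = recipe),
    class = "synth_result"
  )
}

#' @export
print.synth_result <- function(x, ...) {
  cat(sprintf("<synth_result> %.0f s at %g Hz, %d episode(s), %d/%d truth-unacceptable 10 s samples\n",
              x$recipe$duration_s, x$recipe$fs, nrow(x$recipe$episodes),
              sum(x$truth_samples$label == "unacceptable"),
              nrow(x$truth_samples)))
  invisible(x)
}

#' Generate a cohort of synthetic recordings
#'
#' Emulates a validation study: `n_recordings` independent recordings, each
#' starting with a 20 s clean lead-in (so a reference template is always
#' findable), with the remaining 10 s blocks corrupted independently —
#' saturation, flatline or muscle noise covering the whole block — with a
#' probability scaled so the expected fraction of truth-unacceptable 10 s
#' samples over the whole recording equals `target_unacceptable_fraction`.
#' A share of the clean blocks receives benign baseline wander or powerline
#' interference so the acceptable class is not artificially easy.
#'
#' @param n_recordings Number of recordings.
#' @param duration_s Length of each recording in seconds (default 3600).
#' @param target_unacceptable_fraction Expected truth-unacceptable fraction
#'   of 10 s samples, in `[0, 1)`.
#' @param seed Integer seed; fixes schedules and per-recording seeds.
#' @param fs Sampling rate in Hz.
#' @param device A [device_profile()].
#' @param beat A [beat_model()].
#' @param wander_prob,powerline_prob Probability that an uncorrupted block
#'   receives a benign wander / powerline episode.
#'
#' @return A list of [synth_ecg()] results, named `rec01`, `rec02`, ...
#' @export
generate_cohort <- function(n_recordings, duration_s = 3600,
                            target_unacceptable_fraction = 0.46,
                            seed = 1L, fs = 250,
                            device = device_profile(), beat = beat_model(),
                            wander_prob = 0.15, powerline_prob = 0.03) {
  if (target_unacceptable_fraction < 0 || target_unacceptable_fraction >= 1) {
    rlang::abort("`target_unacceptable_fraction` must lie in [0, 1).",
                 class = "ecgsqi_validation")
  }
  block_s <- 10
  n_blocks <- as.integer(duration_s %/% block_s)
  lead_blocks <- 2L  # 20 s clean lead-in
  eligible <- n_blocks - lead_blocks
  if (eligible < 1) {
    rlang::abort("Recording too short for the clean lead-in.",
                 class = "ecgsqi_validation")
  }
  p <- target_unacceptable_fraction * n_blocks / eligible
  if (p > 1) {
    rlang::abort("Target fraction infeasible with the mandatory clean lead-in.",
                 class = "ecgsqi_validation")
  }
  withr::with_seed(seed, {
    lapply(stats::setNames(seq_len(n_recordings),
                           sprintf("rec%02d", seq_len(n_recordings))),
           function(r) {
      corrupt <- stats::runif(eligible) < p
      kind <- sample(c("saturation", "flatline", "muscle"), eligible,
                     replace = TRUE)
      rows <- list()
      for (j in seq_len(eligible)) {
        b0 <- (lead_blocks + j - 1L) * block_s
        if (corrupt[j]) {
          rows[[length(rows) + 1L]] <- noise_episode(kind[j], b0, block_s)
        } else {
          u <- stats::runif(1)
          if (u < wander_prob) {
            rows[[length(rows) + 1L]] <-
              noise_episode("baseline_wander", b0, block_s)
          } else if (u < wander_prob + powerline_prob) {
            rows[[length(rows) + 1L]] <- noise_episode("powerline", b0, block_s)
          }
        }
      }
      recipe <- synth_recipe(
        duration_s = duration_s, fs = fs, device = device, beat = beat,
        episodes = if (length(rows)) dplyr::bind_rows(rows) else NULL,
        seed = sample.int(.Machine$integer.max - 1L, 1)
      )
      synth_ecg(recipe)
    })
  })
}
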