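test_that("clean synthesis has the requested length and is deterministic", {
  recipe <- clean_recipe(duration_s = 20, seed = 5, fs = 250)
  sig <- generate_clean_ecg(recipe)
  expect_equal(nrow(sig), 20 * 250)
  sig2 <- generate_clean_ecg(clean_recipe(duration_s = 20, seed = 5, fs = 250))
  expect_identical(sig$value_mv, sig2$value_mv)
  sig3 <- generate_clean_ecg(clean_recipe(duration_s = 20, seed = 6, fs = 250))
  expect_false(identical(sig$value_mv, sig3$value_mv))
})

test_that("beat count matches the heart rate (threshold peak-finder oracle)", {
  sig <- generate_clean_ecg(clean_recipe(duration_s = 60, seed = 2, jitter = 0))
  n_peaks <- count_r_peaks(sig$value_mv, threshold = 0.5)
  expect_gte(n_peaks, 59)
  expect_lte(n_peaks, 61)
})

test_that("beat models driving amplitudes beyond the rails are rejected", {
  waves <- tibble::tibble(
    wave = c("P", "Q", "R", "S", "T"),
    amp_mv = c(0.15, -0.10, 600, -0.10, 0.30),
    offset_frac = c(-0.25, -0.045, 0, 0.045, 0.30),
    width_s = c(0.025, 0.010, 0.012, 0.010, 0.060)
  )
  recipe <- synth_recipe(duration_s = 20, seed = 1, beat = beat_model(waves = waves))
  expect_error(generate_clean_ecg(recipe), class = "ecgsqi_validation")
})

test_that("episode schedules are validated", {
  expect_error(
    synth_recipe(duration_s = 30, episodes = noise_episode("muscle", 25, 10)),
    class = "ecgsqi_validation"
  )
  expect_error(
    synth_recipe(duration_s = 60, episodes = rbind(
      noise_episode("muscle", 20, 10), noise_episode("muscle", 25, 10))),
    class = "ecgsqi_validation"
  )
  # distinct kinds may overlap
  expect_s3_class(
    synth_recipe(duration_s = 60, episodes = rbind(
      noise_episode("muscle", 20, 10), noise_episode("baseline_wander", 25, 10))),
    "synth_recipe"
  )
  expect_error(noise_episode("baseline_wander", 0, 5, frequency_hz = 2),
               class = "ecgsqi_validation")
})

test_that("saturation episodes exceed the saturation rule by construction", {
  res <- synth_ecg(synth_recipe(duration_s = 40, seed = 4,
                                episodes = noise_episode("saturation", 20, 12)))
  fs <- signal_fs(res$signal)
  span <- device_span(signal_device(res$signal))
  for (w0 in seq(20, 30, by = 2)) {
    seg <- res$signal$value_mv[(w0 * fs + 1):((w0 + 2) * fs)]
    expect_gt(max(seg) - min(seg), 0.95 * span)
  }
})

test_that("flatline episodes fall below the template floor by construction", {
  res <- synth_ecg(synth_recipe(duration_s = 40, seed = 4,
                                episodes = noise_episode("flatline", 20, 12)))
  sig <- res$signal
  tpl <- find_reference_template(sig)
  fs <- signal_fs(sig)
  for (w0 in seq(20, 30, by = 2)) {
    seg <- sig$value_mv[(w0 * fs + 1):((w0 + 2) * fs)]
    expect_lt(max(seg) - min(seg), 0.05 * (tpl$max_t - tpl$min_t))
  }
})

test_that("powerline interference changes window SD within the RMS bounds", {
  recipe <- clean_recipe(duration_s = 30, seed = 6)
  clean <- generate_clean_ecg(recipe)
  amp <- 0.25
  noisy <- apply_episodes(clean, synth_recipe(
    duration_s = 30, seed = 6, beat = recipe$beat,
    episodes = noise_episode("powerline", 10, 10, amplitude_mv = amp)))
  fs <- signal_fs(clean)
  for (w0 in seq(10, 18, by = 2)) {
    idx <- (w0 * fs + 1):((w0 + 2) * fs)
    sd0 <- pop_sd(clean$value_mv[idx])
    sd1 <- pop_sd(noisy$value_mv[idx])
    rms <- amp / sqrt(2)
    expect_lte(sd1, sd0 + rms + 1e-9)
    expect_gte(sd1, abs(sd0 - rms) - 1e-9)
    expect_lt(abs(sd1 - sqrt(sd0^2 + rms^2)), 0.05)
  }
})

test_that("ground-truth labels count corrupted coverage correctly", {
  res <- synth_ecg(synth_recipe(duration_s = 60, seed = 7,
                                episodes = noise_episode("saturation", 10, 30)))
  expect_equal(sum(res$truth_windows$label == "unacceptable"), 15L)
  expect_equal(nrow(res$truth_windows), 30L)

  clean <- synth_ecg(clean_recipe(duration_s = 60, seed = 7))
  expect_true(all(clean$truth_windows$label == "acceptable"))
  expect_true(all(clean$truth_samples$label == "acceptable"))
})

test_that("ground truth matches an independent interval-coverage oracle", {
  episodes <- rbind(
    noise_episode("saturation", 21, 5),
    noise_episode("muscle", 30, 3),                 # corrupting (default SD)
    noise_episode("muscle", 36, 3, sd_mv = 0.01),   # below the corruption threshold
    noise_episode("baseline_wander", 40, 10),       # readable
    noise_episode("powerline", 50, 6)               # readable unless strict
  )
  recipe <- synth_recipe(duration_s = 60, seed = 8, episodes = episodes)
  res <- synth_ecg(recipe)

  corrupting <- rbind(c(21, 26), c(30, 33))
  oracle <- vapply(0:29, function(i) {
    w0 <- i * 2
    cov <- sum(pmax(0, pmin(corrupting[, 2], w0 + 2) - pmax(corrupting[, 1], w0)))
    if (cov >= 1) "unacceptable" else "acceptable"
  }, character(1))
  expect_equal(res$truth_windows$label, oracle)

  strict <- ground_truth_labels(recipe, clean_sd = res$clean_sd,
                                strict_powerline = TRUE)
  expect_equal(sum(strict$windows$label == "unacceptable"),
               sum(oracle == "unacceptable") + 3L)
})

test_that("synthesis is a pure function of the recipe", {
  recipe <- synth_recipe(duration_s = 40, seed = 10,
                         episodes = noise_episode("muscle", 25, 10))
  r1 <- synth_ecg(recipe)
  r2 <- synth_ecg(recipe)
  expect_identical(r1$signal$value_mv, r2$signal$value_mv)
  expect_identical(r1$truth_samples$label, r2$truth_samples$label)
})

test_that("cohorts have the right shape, lead-in and determinism", {
  co <- generate_cohort(3, duration_s = 600, seed = 9)
  expect_named(co, c("rec01", "rec02", "rec03"))
  for (r in co) {
    expect_equal(nrow(r$truth_samples), 60L)
    expect_equal(signal_duration(r$signal), 600)
    # clean lead-in: template always findable, at the very start
    tpl <- find_reference_template(r$signal)
    expect_equal(tpl$start_s, 0)
    expect_true(all(r$recipe$episodes$start_s >= 20))
  }
  co2 <- generate_cohort(3, duration_s = 600, seed = 9)
  expect_identical(co$rec02$signal$value_mv, co2$rec02$signal$value_mv)
  expect_error(generate_cohort(2, duration_s = 30, seed = 1,
                               target_unacceptable_fraction = 0.99),
               class = "ecgsqi_validation")
})
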