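tpl_default <- ecg_template(max_t = 1.0, min_t = -0.2, sd_t = 0.15)
dev_default <- device_profile()

test_that("each rejection rule fires on a window constructed to violate it", {
  # saturation: range 960 > 0.95 * 1000
  v <- classify_window(stats_row(480, -480, sd_w = 300), tpl_default, dev_default)
  expect_equal(v$label, "unacceptable")
  expect_equal(v$reason, "saturation")

  # low amplitude: range 0.05 < 0.05 * 1.2
  tpl <- ecg_template(max_t = 1.0, min_t = -0.2, sd_t = 0.15)
  v <- classify_window(stats_row(0.05, 0, sd_w = 0.01), tpl, dev_default)
  expect_equal(v$reason, "low_amplitude")

  # excess SD: 0.31 > 2 * 0.15
  v <- classify_window(stats_row(0.8, -0.2, sd_w = 0.31), tpl_default, dev_default)
  expect_equal(v$reason, "excess_sd")

  # clean window passes all three
  v <- classify_window(stats_row(0.9, -0.15, sd_w = 0.16), tpl_default, dev_default)
  expect_equal(v$label, "acceptable")
  expect_equal(v$reason, "ok")
})

test_that("all inequalities are strict: windows exactly at a threshold pass", {
  # sd_w exactly at 2 * sd_t
  v <- classify_window(stats_row(0.8, -0.2, sd_w = 0.30), tpl_default, dev_default)
  expect_equal(v$label, "acceptable")
  # range exactly at 0.95 * span
  v <- classify_window(stats_row(475, -475, sd_w = 0.1), tpl_default, dev_default)
  expect_false(v$reason == "saturation")
  # range exactly at the 5% floor (template range 1.2 -> floor 0.06)
  v <- classify_window(stats_row(0.06, 0, sd_w = 0.01), tpl_default, dev_default)
  expect_false(v$reason == "low_amplitude")
})

test_that("rules short-circuit in the order saturation, low amplitude, excess SD", {
  # violates both saturation and excess SD: saturation is reported
  v <- classify_window(stats_row(490, -490, sd_w = 400), tpl_default, dev_default)
  expect_equal(v$reason, "saturation")
  # violates both the floor and excess SD: low amplitude is reported
  tpl <- ecg_template(max_t = 1.0, min_t = -0.2, sd_t = 0.001)
  v <- classify_window(stats_row(0.02, 0, sd_w = 0.01), tpl, dev_default)
  expect_equal(v$reason, "low_amplitude")
})

test_that("a T-second recording yields floor(T/2) verdicts, partials dropped", {
  sig10 <- generate_clean_ecg(clean_recipe(duration_s = 30, seed = 3))
  v <- classify_signal(sig10)
  expect_equal(nrow(v), 15L)
  expect_equal(v$start_s, seq(0, 28, by = 2))

  sig32 <- generate_clean_ecg(clean_recipe(duration_s = 32, seed = 3))
  sig11 <- ecg_signal(sig32$value_mv[1:(31 * 250)], fs = 250)
  expect_message(v11 <- classify_signal(sig11), class = "ecgsqi_partial_window")
  expect_equal(nrow(v11), 15L)
})

test_that("verdicts are shift-invariant under baseline offsets", {
  set.seed(11)
  tpl <- tpl_default
  for (i in 1:50) {
    lo <- stats::runif(1, -1, 0)
    hi <- stats::runif(1, 0.1, 2)
    sd_w <- stats::runif(1, 0.01, 0.5)
    offset <- stats::runif(1, -50, 50)
    v0 <- classify_window(stats_row(hi, lo, sd_w), tpl, dev_default)
    v1 <- classify_window(stats_row(hi + offset, lo + offset, sd_w), tpl, dev_default)
    expect_identical(v1$reason, v0$reason)
  }
})

test_that("low-amplitude and excess-SD rules are scale-covariant", {
  set.seed(12)
  for (i in 1:50) {
    gamma <- stats::runif(1, 0.2, 5)
    hi <- stats::runif(1, 0.001, 2)
    lo <- -stats::runif(1, 0, 1)
    sd_w <- stats::runif(1, 0.001, 0.6)
    tpl <- ecg_template(max_t = stats::runif(1, 0.5, 1.5),
                        min_t = -stats::runif(1, 0.05, 0.5),
                        sd_t = stats::runif(1, 0.05, 0.3))
    tpl_g <- ecg_template(max_t = gamma * tpl$max_t, min_t = gamma * tpl$min_t,
                          sd_t = gamma * tpl$sd_t)
    v0 <- classify_window(stats_row(hi, lo, sd_w), tpl, dev_default)
    v1 <- classify_window(stats_row(gamma * hi, gamma * lo, gamma * sd_w),
                          tpl_g, dev_default)
    # the saturation rule is anchored to the ADC span and exempt
    if (v0$reason != "saturation" && v1$reason != "saturation") {
      expect_identical(v1$reason, v0$reason)
    }
  }
})

test_that("growing zero-mean noise eventually and permanently rejects a window", {
  set.seed(13)
  fs <- 250
  base <- generate_clean_ecg(clean_recipe(duration_s = 30, seed = 3))
  tpl <- find_reference_template(base)
  win <- base$value_mv[1:(2 * fs)]
  noise <- stats::rnorm(length(win))
  labels <- vapply(seq(0, 3, by = 0.05), function(s) {
    classify_window(compute_window_stats(win + s * noise), tpl, dev_default)$label
  }, character(1))
  expect_equal(labels[1], "acceptable")
  first_bad <- match("unacceptable", labels)
  expect_false(is.na(first_bad))
  expect_true(all(labels[first_bad:length(labels)] == "unacceptable"))
})

test_that("classify_window agrees with a brute-force restatement of the rules", {
  set.seed(14)
  cfg <- sqi_config()
  span <- device_span(dev_default)
  for (i in 1:1000) {
    tpl <- ecg_template(max_t = stats::runif(1, 0.2, 2),
                        min_t = -stats::runif(1, 0.05, 1),
                        sd_t = stats::runif(1, 0.02, 0.5))
    hi <- stats::runif(1, -400, 500)
    lo <- hi - stats::rexp(1, rate = 1 / 100)
    lo <- max(lo, -500)
    sd_w <- stats::runif(1, 0, (hi - lo) / 2 + 1e-9)
    v <- classify_window(stats_row(hi, lo, sd_w), tpl, dev_default, cfg)
    expect_identical(v$reason, brute_force_reason(hi, lo, sd_w, tpl, span, cfg))
    expect_identical(v$label,
                     if (v$reason == "ok") "acceptable" else "unacceptable")
  }
})

test_that("whole-recording verdicts equal per-window recomputation", {
  res <- synth_ecg(synth_recipe(
    duration_s = 60, seed = 8,
    episodes = rbind(noise_episode("saturation", 30, 6),
                     noise_episode("flatline", 44, 6))
  ))
  v <- classify_signal(res$signal)
  tpl <- attr(v, "template")
  fs <- signal_fs(res$signal)
  for (i in seq_len(nrow(v))) {
    seg <- res$signal$value_mv[((i - 1) * 2 * fs + 1):(i * 2 * fs)]
    expect_identical(
      brute_force_reason(max(seg), min(seg), pop_sd(seg), tpl, 1000),
      v$reason[i]
    )
  }
})

test_that("windows inside the template span are still classified", {
  sig <- generate_clean_ecg(clean_recipe(duration_s = 20, seed = 4))
  v <- classify_signal(sig)
  tpl <- attr(v, "template")
  expect_equal(tpl$start_s, 0)
  expect_equal(nrow(v), 10L)
  expect_equal(v$start_s[1], 0)
})
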