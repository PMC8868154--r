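p10 <- score_params()

sine_segment <- function(freq_hz, amp = 1, fs = 10, dur = 30, noise = 0, seed = 1) {
  set.seed(seed)
  t <- seq(0, dur, by = 1 / fs)
  breathing_trace(t, amp * sin(2 * pi * freq_hz * t) + rnorm(length(t), sd = noise))
}

test_that("breathing spectra concentrate power where it belongs", {
  sp <- estimate_breathing_spectrum(sine_segment(0.1333), p10)
  expect_lt(abs(sp$freq[which.max(sp$power)] - 0.1333), 0.005)
  # total spectral area recovers the segment variance (taper-corrected)
  seg <- sine_segment(0.1333, noise = 0.2, seed = 4)
  sp2 <- estimate_breathing_spectrum(seg, p10)
  expect_lt(abs(sum(sp2$power) * sp2$df - var(seg$y)) / var(seg$y), 0.05)
  # constant segment: essentially no power after mean removal
  flat <- breathing_trace(seq(0, 30, 0.1), rep(3, 301))
  expect_lt(sum(estimate_breathing_spectrum(flat, p10)$power), 1e-20)
  expect_error(estimate_breathing_spectrum(sine_segment(0.1, dur = 10), p10),
               "shorter")
  bad <- sine_segment(0.1); bad$y[5] <- NaN
  expect_error(estimate_breathing_spectrum(bad, p10), "non-finite")
})

test_that("two-tone segments show band powers in the squared amplitude ratio", {
  # amplitudes a and 2a at well separated frequencies -> integrated
  # powers ~1:4 (sinusoid power a^2/2); checked against the DFT oracle
  t <- seq(0, 30, by = 0.1)
  y <- 1 * sin(2 * pi * 0.12 * t) + 2 * sin(2 * pi * 0.35 * t)
  sp <- estimate_breathing_spectrum(breathing_trace(t, y), p10)
  p_low <- sum(sp$power[sp$freq >= 0.08 & sp$freq <= 0.16]) * sp$df
  p_high <- sum(sp$power[sp$freq >= 0.31 & sp$freq <= 0.39]) * sp$df
  expect_lt(abs(p_high / p_low - 4), 0.2)
  score_impl <- biofeedback_value(sp, p10)
  expect_equal(score_impl, oracle_band_score(
    stats::approx(t, y, xout = seq(0, 30, 0.1))$y[1:300]), tolerance = 1e-6)
})

test_that("biofeedback value rewards in-band breathing and maps degenerate input to 0", {
  expect_gte(biofeedback_value(estimate_breathing_spectrum(
    sine_segment(8 / 60, noise = 0.02), p10), p10), 0.9)
  slow <- biofeedback_value(estimate_breathing_spectrum(
    sine_segment(20 / 60, noise = 0.02, seed = 2), p10), p10)
  expect_lte(slow, 0.1)
  flat <- breathing_trace(seq(0, 30, 0.1), rep(1, 301))
  expect_identical(biofeedback_value(estimate_breathing_spectrum(flat, p10), p10), 0)
})

test_that("score_stream emits one score per hop starting after one full window", {
  tr <- sine_segment(8 / 60, dur = 60)
  st <- score_stream(tr, p10)
  expect_equal(st$t, seq(30, 60, by = 2))
  expect_length(st$score, 16)
  expect_true(all(st$score >= 0 & st$score <= 1))
  # stationary trace -> nearly constant scores
  expect_lte(max(st$score) - min(st$score), 0.05)
  expect_warning(st0 <- score_stream(sine_segment(0.1, dur = 20), p10), "shorter")
  expect_length(st0$score, 0)
})

test_that("scores transition monotonically after a pace step and match the DFT oracle", {
  fs <- 10
  t <- seq(0, 90, by = 1 / fs)
  pace <- ifelse(t < 45, 20, 8)
  phi <- 2 * pi * cumsum(pace / 60) / fs
  tr <- breathing_trace(t, sin(phi))
  st <- score_stream(tr, p10)
  # oracle recomputation of every window
  rs <- stats::approx(tr$t, tr$y, xout = seq(0, 90, by = 1 / fs))$y
  ends <- seq(300, length(rs), by = 20)
  oracle <- vapply(ends, function(e) oracle_band_score(rs[(e - 299):e]), numeric(1))
  expect_lt(max(abs(st$score - oracle)), 1e-6)
  # scores before the step are low, after the window clears the step high,
  # and the transition is monotone non-decreasing within tolerance
  trans <- st$score[st$t >= 45 & st$t <= 77]
  expect_true(all(diff(trans) > -0.02))
  expect_lt(st$score[st$t == 44], 0.1)
  expect_gt(st$score[st$t == 80], 0.9)
})

test_that("scores are scale invariant and increase with depth against a fixed noise floor", {
  set.seed(9)
  t <- seq(0, 60, by = 0.1)
  base <- sin(2 * pi * 8 / 60 * t)
  noise <- rnorm(length(t), sd = 0.3)
  s1 <- score_stream(breathing_trace(t, base + noise), p10)$score
  s_scaled <- score_stream(breathing_trace(t, 5 * (base + noise)), p10)$score
  expect_equal(s1, s_scaled, tolerance = 1e-9)
  # deeper breathing against the same additive noise scores higher
  s_deep <- score_stream(breathing_trace(t, 3 * base + noise), p10)$score
  expect_true(all(s_deep > s1))
})

test_that("baseline summary uses the last 29-sample reference window", {
  st <- make_bfb(seq(0, 1, length.out = 40))
  bs <- baseline_summary(st)
  expect_equal(bs$n_used, 29)
  expect_equal(bs$mean, mean(st$score[12:40]))
  expect_equal(bs$span_s, 56)
  expect_false(bs$short)
  # exactly 29 samples: all used
  st29 <- make_bfb(runif(29))
  expect_equal(baseline_summary(st29)$mean, mean(st29$score))
  # constant stream
  expect_equal(baseline_summary(make_bfb(rep(0.42, 35)))$mean, 0.42)
  # shorter stream warns and flags
  expect_warning(short <- baseline_summary(make_bfb(rep(0.5, 10))), "reference")
  expect_true(short$short)
  expect_error(baseline_summary(bfb_stream(numeric(0), numeric(0))), "empty")
})
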