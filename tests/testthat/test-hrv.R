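test_that("artifact screening removes impossible intervals and flags unusable series", {
  rr <- make_rr_constant(800, 80)
  cl <- clean_rr(rr)
  expect_equal(length(cl$rr), length(rr$rr))
  expect_equal(attr(cl, "removed"), 0)
  expect_true(attr(cl, "usable"))
  # one spurious 5000 ms interval
  bad <- rr_series(c(0, cumsum(c(rep(0.8, 50), 5, rep(0.8, 49)))))
  cl2 <- clean_rr(bad)
  expect_equal(attr(cl2, "removed"), 1)
  expect_equal(length(cl2$rr), 99)
  # constructed series: 3 of 100 out of range -> 97 retained
  iv <- rep(0.8, 100); iv[c(10, 40, 70)] <- c(0.2, 2.5, 0.25)
  cl3 <- clean_rr(rr_series(c(0, cumsum(iv))))
  expect_equal(length(cl3$rr), 97)
  expect_equal(attr(cl3, "removed_fraction"), 0.03)
  # > 20% removed flags the series unusable
  iv2 <- rep(c(0.8, 0.2), 50)
  expect_warning(cl4 <- clean_rr(rr_series(c(0, cumsum(iv2)))), "unusable")
  expect_false(attr(cl4, "usable"))
})

test_that("tachogram interpolation preserves level and recovers smooth modulation", {
  cl <- make_rr_constant(800, 120)
  tg <- rr_to_tachogram(cl)
  expect_equal(tg$fs, 4)
  expect_true(all(abs(tg$rr_ms - 800) < 1e-6))
  # sinusoidally modulated intervals: tachogram tracks the closed form
  beat_t <- numeric(200); tcur <- 0
  for (i in 1:200) {
    rr_ms <- 800 + 50 * sin(2 * pi * 0.1 * tcur)
    tcur <- tcur + rr_ms / 1000
    beat_t[i] <- tcur
  }
  tg2 <- rr_to_tachogram(rr_series(c(0, beat_t)))
  inner <- tg2$t > 5 & tg2$t < max(tg2$t) - 5
  # an interval ending at t started ~rr earlier; its value reflects that onset
  expected <- 800 + 50 * sin(2 * pi * 0.1 * (tg2$t[inner] - 0.8))
  expect_lt(mean(abs(tg2$rr_ms[inner] - expected)), 2)
  expect_lt(abs(mean(tg2$rr_ms) - mean(diff(c(0, beat_t)) * 1000)) /
              mean(tg2$rr_ms), 0.01)
  expect_error(rr_to_tachogram(rr_series(c(0, 0.8, 1.6))), "at least 4")
})

test_that("band powers separate LF from HF modulation and match Parseval", {
  mk_tach <- function(freq, amp, dur = 300) {
    t <- seq(0, dur, by = 0.25)
    structure(list(t = t, rr_ms = 800 + amp * sin(2 * pi * freq * t), fs = 4),
              class = "tachogram")
  }
  lf_dom <- hrv_band_powers(mk_tach(0.10, 50))
  expect_gt(lf_dom$lf_power, lf_dom$hf_power)
  expect_gt(lf_dom$lf_hf_ratio, 10)
  hf_dom <- hrv_band_powers(mk_tach(0.25, 50))
  expect_gt(hf_dom$hf_power, hf_dom$lf_power)
  # amplitude A sinusoid integrates to ~A^2/2 in its band
  expect_lt(abs(lf_dom$lf_power - 50^2 / 2) / (50^2 / 2), 0.1)
  expect_equal(lf_dom$mean_hr, 60000 / 800, tolerance = 1e-3)
})

test_that("coherence is 1 for a signal with itself and near the estimator bias for noise", {
  t <- seq(0, 600, by = 0.25)
  set.seed(5)
  x <- 800 + 50 * sin(2 * pi * 0.1 * t) + rnorm(length(t), sd = 10)
  tach <- structure(list(t = t, rr_ms = x, fs = 4), class = "tachogram")
  self_breathing <- breathing_trace(t, x)
  expect_equal(breathing_lf_coherence(self_breathing, tach), 1, tolerance = 1e-9)
  # independent white noise: expected MSC ~ 1/L
  for (seed in 1:3) {
    set.seed(seed)
    b <- breathing_trace(t, rnorm(length(t)))
    tn <- structure(list(t = t, rr_ms = 800 + rnorm(length(t), sd = 20), fs = 4),
                    class = "tachogram")
    expect_lte(breathing_lf_coherence(b, tn), 0.35)
  }
  expect_error(breathing_lf_coherence(
    breathing_trace(t[t < 60], x[t < 60]), tach), "overlap")
})

test_that("coherence is symmetric and invariant to positive scaling", {
  t <- seq(0, 300, by = 0.25)
  set.seed(8)
  a <- sin(2 * pi * 0.1 * t) + rnorm(length(t), sd = 0.3)
  b <- 800 + 40 * sin(2 * pi * 0.1 * t + 0.4) + rnorm(length(t), sd = 15)
  tach_b <- structure(list(t = t, rr_ms = b, fs = 4), class = "tachogram")
  tach_a <- structure(list(t = t, rr_ms = a, fs = 4), class = "tachogram")
  c_ab <- breathing_lf_coherence(breathing_trace(t, a), tach_b)
  c_ba <- breathing_lf_coherence(breathing_trace(t, b), tach_a)
  expect_equal(c_ab, c_ba, tolerance = 1e-10)
  c_scaled <- breathing_lf_coherence(breathing_trace(t, 7 * a), tach_b)
  expect_equal(c_ab, c_scaled, tolerance = 1e-10)
})

test_that("heart-rate change subtracts the baseline mean", {
  s <- make_mini_session(baseline_rr_ms = 1000, ingame_rr_ms = 800)
  expect_equal(hr_change(s), 75 - 60, tolerance = 1e-6)
  s2 <- make_mini_session(baseline_rr_ms = 800, ingame_rr_ms = 800)
  expect_equal(hr_change(s2), 0, tolerance = 1e-6)
  s$flags$rr_missing <- TRUE
  expect_true(is.na(hr_change(s)))
})

test_that("session_hrv propagates missing and unusable R-R data", {
  s <- make_mini_session()
  out <- session_hrv(s)
  expect_true(is.finite(out$mean_hr))
  s$ingame$rr <- NULL; s$flags$rr_missing <- TRUE
  out2 <- session_hrv(s)
  expect_true(all(is.na(unlist(out2))))
})
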