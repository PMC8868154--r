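test_that("binning averages 15 s bins and discards the first two", {
  # 450 samples at 0.5 Hz spanning 900 s -> 60 bins -> 58 retained
  st <- bfb_stream(seq(2, 900, by = 2), rep(0.5, 450))
  b <- bin_biofeedback(st)
  expect_equal(nrow(b), 58)
  expect_true(all(b$value == 0.5))
  expect_equal(min(b$bin), 2)
  # bin means equal the mean of their member samples exactly
  set.seed(7)
  sc <- runif(45)
  st2 <- bfb_stream(seq(0, by = 2, length.out = 45), sc)
  b2 <- bin_biofeedback(st2, drop_first = 0L)
  rel <- floor(st2$t / 15)
  expect_equal(b2$value, as.numeric(tapply(sc, rel, mean)))
  expect_equal(b2$n, as.integer(tapply(sc, rel, length)))
  expect_error(bin_biofeedback(make_bfb(rep(0.2, 10))), "fewer than 3")
})

test_that("phase trends recover exact slopes and the moving average fixes constants", {
  v <- 0.01 * (1:40)
  tr <- phase_trend(v)
  expect_equal(tr$slope, 0.01, tolerance = 1e-12)
  expect_equal(phase_trend(rep(0.4, 20))$slope, 0, tolerance = 1e-12)
  expect_equal(phase_trend(rep(0.4, 20))$smooth, rep(0.4, 20))
})

test_that("cross-pair tau matches exhaustive enumeration and boundary cases", {
  # complete separation
  expect_equal(tau_contrast(c(1, 2, 3), c(4, 5, 6))$tau, 1)
  expect_equal(tau_contrast(c(4, 5, 6), c(1, 2, 3))$tau, -1)
  # worked example: C = 7, D = 1, one tie
  tc <- tau_contrast(c(1, 3, 2), c(2, 4, 5))
  expect_equal(tc$tau, 6 / 9, tolerance = 1e-12)
  # antisymmetry under swapping sessions
  set.seed(11)
  x <- rnorm(12); y <- rnorm(15, 0.3)
  expect_equal(tau_contrast(x, y)$tau, -tau_contrast(y, x)$tau, tolerance = 1e-12)
  # all values tied
  tied <- tau_contrast(rep(1, 5), rep(1, 6))
  expect_equal(tied$tau, 0)
  expect_equal(tied$p_value, 1)
  # random cases against the loop oracle, including ties
  for (i in 1:50) {
    set.seed(100 + i)
    nx <- sample(3:50, 1); ny <- sample(3:50, 1)
    x <- sample(0:6, nx, replace = TRUE) + round(rnorm(nx), 1)
    y <- sample(0:6, ny, replace = TRUE) + round(rnorm(ny), 1)
    expect_equal(tau_contrast(x, y)$tau, oracle_cross_tau(x, y),
                 tolerance = 1e-12)
  }
})

test_that("contrast p-values agree with the Mann-Whitney normal approximation", {
  for (i in 1:20) {
    set.seed(300 + i)
    x <- round(rnorm(sample(5:40, 1)), 1)
    y <- round(rnorm(sample(5:40, 1), mean = 0.4), 1)
    p_ref <- suppressWarnings(stats::wilcox.test(y, x, exact = FALSE,
                                                 correct = TRUE)$p.value)
    expect_equal(tau_contrast(x, y)$p_value, p_ref, tolerance = 1e-9)
  }
})

test_that("tau-b option stays below the cross-pair tau for separated sessions", {
  x <- c(1, 2, 3, 4); y <- c(5, 6, 7, 8)
  expect_equal(tau_contrast(x, y)$tau, 1)
  tb <- tau_contrast(x, y, method = "tau_b")$tau
  expect_lt(tb, 1)  # tie-corrected ceiling for a binary grouping variable
  expect_gt(tb, 0.5)
})

test_that("subject contrasts enumerate the design and report missing sessions", {
  set.seed(21)
  bins <- setNames(lapply(1:10, function(i) rnorm(10, 0.5, 0.1)), as.character(1:10))
  ct <- subject_contrasts(bins)
  expect_equal(nrow(ct), 8)
  expect_equal(sum(ct$direction == "addition"), 4)
  expect_false(any(ct$missing))
  # phases of each pair respect the design
  d <- phase_design()
  for (r in which(ct$direction == "addition"))
    expect_identical(unname(d$phase_of_session[as.character(c(ct$from[r], ct$to[r]))]),
                     c("A", "B"))
  # missing session 8 knocks out S7-S8 and S8-S9
  bins8 <- bins; bins8[["8"]] <- NULL
  ct8 <- subject_contrasts(bins8)
  expect_setequal(ct8$pair[ct8$missing], c("S7-S8", "S8-S9"))
  expect_equal(sum(!ct8$missing), 6)
})

test_that("meta combination is a pair-count-weighted tau with Stouffer p", {
  mk <- function(tau, p, n_i, n_j, dir = "addition")
    data.frame(pair = "x", from = 1, to = 2, direction = dir, tau = tau,
               p_value = p, n_i = n_i, n_j = n_j, significant = p < 0.05,
               missing = FALSE)
  # single contrast: identity
  one <- combine_contrasts(mk(0.42, 0.01, 10, 10))
  expect_equal(one$combined_tau, 0.42)
  expect_equal(one$combined_p, 0.01, tolerance = 1e-9)
  # identical taus with equal weights
  two <- combine_contrasts(rbind(mk(0.5, 0.2, 8, 8), mk(0.5, 0.2, 8, 8)))
  expect_equal(two$combined_tau, 0.5)
  # hand-weighted mean: taus {0.6, 0.2}, weights {100, 300} -> 0.3
  w <- combine_contrasts(rbind(mk(0.6, 0.04, 10, 10), mk(0.2, 0.3, 20, 15)))
  expect_equal(w$combined_tau, (100 * 0.6 + 300 * 0.2) / 400, tolerance = 1e-12)
  expect_error(combine_contrasts(mk(0.4, 0.2, 5, 5)[0, ]), "non-missing")
})

test_that("six-feature summary detects level shifts and stays silent on identical phases", {
  d <- phase_design()
  # constant phases: A sessions at 0.2, B sessions at 0.6
  bins <- setNames(lapply(1:10, function(i) {
    lv <- if (unname(d$phase_of_session[as.character(i)]) == "B") 0.6 else 0.2
    rep(lv, 10) + seq(-1e-4, 1e-4, length.out = 10)  # break exact ties
  }), as.character(1:10))
  ct <- subject_contrasts(bins)
  ft <- six_feature_summary(bins, ct)
  add_rows <- ft$features[ft$features$direction == "addition", ]
  expect_equal(add_rows$level_change, rep(0.4, 4), tolerance = 1e-3)
  expect_equal(add_rows$immediacy, rep(0.4, 4), tolerance = 1e-3)
  expect_equal(add_rows$trend_change, rep(0, 4), tolerance = 1e-4)
  expect_true(ft$intervention_effect)  # level, immediacy, overlap all >= 3
  expect_gte(ft$feature_counts[["level"]], 3)
  expect_gte(ft$feature_counts[["overlap"]], 3)
  # identical A and B data: nothing changes, decision false
  set.seed(31)
  flatv <- rnorm(10, 0.5, 0.05)
  flat <- setNames(lapply(1:10, function(i) flatv), as.character(1:10))
  ft0 <- six_feature_summary(flat, subject_contrasts(flat))
  expect_false(ft0$intervention_effect)
  expect_true(all(ft0$feature_counts == 0))
})

test_that("repeated-measures correlation strips subject offsets", {
  # y = x + subject offset -> r = 1
  subj <- rep(1:4, each = 5)
  x <- rnorm(20)
  y <- x + rep(c(10, -5, 3, 0), each = 5)
  r <- repeated_measures_correlation(x, y, subj)
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_equal(r$df, 20 - 4 - 1)
  # invariance to adding per-subject constants to either variable
  set.seed(41)
  x2 <- rnorm(20); y2 <- 0.5 * x2 + rnorm(20, sd = 0.5)
  base <- repeated_measures_correlation(x2, y2, subj)
  shifted <- repeated_measures_correlation(x2 + rep(rnorm(4, sd = 50), each = 5),
                                           y2 - rep(rnorm(4, sd = 50), each = 5),
                                           subj)
  expect_equal(base$r, shifted$r, tolerance = 1e-9)
  # subjects with < 2 complete sessions are dropped with a warning
  x3 <- c(x2, 1); y3 <- c(y2, 2); s3 <- c(subj, 99)
  expect_warning(r3 <- repeated_measures_correlation(x3, y3, s3), "fewer than 2")
  expect_equal(r3$n_subjects, 4)
})

test_that("repeated-measures correlation matches the ANCOVA oracle", {
  for (i in 1:5) {
    set.seed(500 + i)
    subj <- rep(1:3, each = 6)
    x <- rnorm(18)
    y <- 0.4 * x + rep(rnorm(3, sd = 2), each = 6) + rnorm(18, sd = 0.8)
    r <- repeated_measures_correlation(x, y, subj)
    orc <- oracle_rmcorr(x, y, subj)
    expect_equal(r$r, orc$r, tolerance = 1e-10)
    expect_equal(r$df, orc$df)
  }
})

test_that("contrast power increases monotonically with the phase shift", {
  set.seed(61)
  rejection <- sapply(c(0, 0.1, 0.2, 0.3), function(shift) {
    mean(replicate(250, {
      tau_contrast(rnorm(20, 0, 0.15), rnorm(20, shift, 0.15))$p_value < 0.05
    }))
  })
  expect_true(all(diff(rejection) > 0))
})
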