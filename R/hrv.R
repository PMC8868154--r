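#' Artifact-screen an R-R series
#'
#' Chest-strap R peak detection occasionally misfires, producing
#' physiologically impossible intervals. Intervals outside
#' `[min_ms, max_ms]` are removed; when more than `max_removed_frac` of
#' the series is lost the series is marked unusable (the session should
#' then be excluded from HRV analyses).
#'
#' @param rr An [rr_series].
#' @param min_ms,max_ms Acceptance range (ms); defaults 300 and 2000.
#' @param max_removed_frac Usability threshold; default 0.2.
#' @return The cleaned [rr_series] with attributes `removed` (count),
#'   `removed_fraction` and `usable` (logical).
#' @export
clean_rr <- function(rr, min_ms = 300, max_ms = 2000, max_removed_frac = 0.2) {
  if (!inherits(rr, "rr_series")) stop("rr must be an rr_series")
  keep <- rr$rr >= min_ms & rr$rr <= max_ms
  out <- structure(list(beat_t = rr$beat_t[keep], rr = rr$rr[keep]),
                   class = "rr_series")
  frac <- mean(!keep)
  attr(out, "removed") <- sum(!keep)
  attr(out, "removed_fraction") <- frac
  attr(out, "usable") <- frac <= max_removed_frac
  if (!attr(out, "usable"))
    warning(sprintf("%.0f%% of intervals removed; series flagged unusable",
                    100 * frac))
  out
}

#' Uniform tachogram from an R-R series
#'
#' Cubic interpolation of interval duration against beat time, sampled
#' at `fs` (4 Hz by standard HRV practice), enabling Fourier analysis of
#' heart-period fluctuations.
#'
#' @param rr An [rr_series] with at least 4 beats.
#' @param fs Sampling rate (Hz).
#' @return List of class `tachogram`: `t` (s), `rr_ms`, `fs`.
#' @export
rr_to_tachogram <- function(rr, fs = 4) {
  if (!inherits(rr, "rr_series")) stop("rr must be an rr_series")
  if (length(rr$beat_t) < 4L) stop("need at least 4 beats for interpolation")
  grid <- seq(rr$beat_t[1L], rr$beat_t[length(rr$beat_t)], by = 1 / fs)
  y <- stats::spline(rr$beat_t, rr$rr, xout = grid, method = "fmm")$y
  structure(list(t = grid, rr_ms = y, fs = fs), class = "tachogram")
}

#' Spectral HRV metrics of a tachogram
#'
#' Welch band powers of heart-period fluctuations: low frequency
#' (0.04-0.15 Hz) and high frequency (0.15-0.4 Hz) power in ms^2, their
#' ratio, and mean heart rate. Welch settings: 60 s Hann segments, 50%
#' overlap (shortened when the record is brief, keeping at least four
#' segments).
#'
#' @param tach A `tachogram` from [rr_to_tachogram].
#' @param lf,hf Band edges (Hz).
#' @return List of class `hrv_metrics`: `lf_power`, `hf_power`,
#'   `lf_hf_ratio`, `mean_hr` (beats/min), plus `low_resolution` flag
#'   (`TRUE` for records shorter than 120 s).
#' @export
hrv_band_powers <- function(tach, lf = c(0.04, 0.15), hf = c(0.15, 0.4)) {
  if (!inherits(tach, "tachogram")) stop("tach must be a tachogram")
  n <- length(tach$rr_ms)
  dur <- tach$t[n] - tach$t[1L]
  low_res <- dur < 120
  if (low_res) warning("tachogram shorter than 120 s; band powers are low-resolution")
  nperseg <- welch_nperseg(n, pref = as.integer(60 * tach$fs))
  w <- welch_cross(tach$rr_ms, fs = tach$fs, nperseg = nperseg)
  lf_power <- band_integral(w$freq, w$sxx, lf[1], lf[2], w$df)
  hf_power <- band_integral(w$freq, w$sxx, hf[1], hf[2], w$df)
  structure(list(
    lf_power = lf_power, hf_power = hf_power,
    lf_hf_ratio = if (hf_power > 0) lf_power / hf_power else NA_real_,
    mean_hr = 60000 / mean(tach$rr_ms),
    low_resolution = low_res
  ), class = "hrv_metrics")
}

#' Breathing / low-frequency HRV coherence
#'
#' Magnitude-squared coherence between the breathing signal and the
#' heart-period tachogram, Welch-averaged and summarized as the mean
#' over the low-frequency band (0.04-0.15 Hz) - the range where paced
#' slow breathing drives heart-period fluctuations (respiratory sinus
#' arrhythmia). Bounded in \[0, 1\]; frequency-specific similarity of
#' the two series.
#'
#' @param breathing A [breathing_trace] overlapping the tachogram for at
#'   least `min_overlap` seconds.
#' @param tach A `tachogram`.
#' @param band LF band edges (Hz).
#' @param min_overlap Minimum common time support (s); default 120.
#' @return Mean magnitude-squared coherence over the band, in \[0, 1\].
#' @export
breathing_lf_coherence <- function(breathing, tach, band = c(0.04, 0.15),
                                   min_overlap = 120) {
  if (!inherits(breathing, "breathing_trace")) stop("breathing must be a breathing_trace")
  if (!inherits(tach, "tachogram")) stop("tach must be a tachogram")
  lo <- max(breathing$t[1L], tach$t[1L])
  hi <- min(breathing$t[length(breathing$t)], tach$t[length(tach$t)])
  if (hi - lo < min_overlap)
    stop("breathing and tachogram overlap less than ", min_overlap, " s")
  grid <- seq(lo, hi, by = 1 / tach$fs)
  b <- stats::approx(breathing$t, breathing$y, xout = grid, rule = 2)$y
  r <- stats::approx(tach$t, tach$rr_ms, xout = grid, rule = 2)$y
  nperseg <- welch_nperseg(length(grid), pref = as.integer(60 * tach$fs))
  w <- welch_cross(b, r, fs = tach$fs, nperseg = nperseg)
  msc <- Mod(w$sxy)^2 / (w$sxx * w$syy)
  msc[!is.finite(msc)] <- 0
  sel <- w$freq >= band[1] & w$freq <= band[2]
  mean(pmin(1, pmax(0, msc[sel])))
}

.mean_hr_of <- function(rr) {
  # duration-weighted time-domain mean heart rate: total beats over total time
  60000 / mean(rr$rr)
}

#' In-game heart-rate change from baseline
#'
#' Mean in-game heart rate minus mean baseline heart rate (beats/min),
#' both as duration-weighted time-domain means of the respective R-R
#' segments. Arousal induction in the task typically raises this by
#' around +10 beats/min.
#'
#' @param session A [session_record] with baseline and in-game R-R
#'   streams present.
#' @return Heart-rate change in beats/min, or `NA` when either R-R
#'   stream is flagged missing.
#' @export
hr_change <- function(session) {
  if (!inherits(session, "session_record")) stop("session must be a session_record")
  if (session$flags$rr_missing || session$flags$baseline_rr_missing) return(NA_real_)
  .mean_hr_of(session$ingame$rr) - .mean_hr_of(session$baseline$rr)
}

#' Per-session HRV metric set
#'
#' Composes the spectral HRV stage for one session: artifact screening,
#' tachogram interpolation, band powers, breathing-LF coherence (when a
#' breathing trace is present) and heart-rate change from baseline.
#' Sessions whose cleaned R-R series is unusable yield all-`NA` metrics.
#'
#' @param session A [session_record].
#' @return One-row data frame: `lf_power`, `hf_power`, `lf_hf_ratio`,
#'   `lf_breathing_coherence`, `mean_hr`, `hr_change`, `rr_usable`.
#' @export
session_hrv <- function(session) {
  empty <- data.frame(lf_power = NA_real_, hf_power = NA_real_,
                      lf_hf_ratio = NA_real_, lf_breathing_coherence = NA_real_,
                      mean_hr = NA_real_, hr_change = NA_real_,
                      rr_usable = NA)
  if (session$flags$rr_missing) return(empty)
  cleaned <- suppressWarnings(clean_rr(session$ingame$rr))
  if (!attr(cleaned, "usable")) { empty$rr_usable <- FALSE; return(empty) }
  tach <- rr_to_tachogram(cleaned)
  hb <- suppressWarnings(hrv_band_powers(tach))
  coh <- if (!session$flags$breathing_missing)
    breathing_lf_coherence(session$ingame$breathing, tach) else NA_real_
  data.frame(lf_power = hb$lf_power, hf_power = hb$hf_power,
             lf_hf_ratio = hb$lf_hf_ratio, lf_breathing_coherence = coh,
             mean_hr = hb$mean_hr, hr_change = hr_change(session),
             rr_usable = TRUE)
}
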