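#' Biofeedback scoring parameters
#'
#' Parameters of the sliding-window breathing score. The training
#' rewarded slow diaphragmatic breathing around 8 breaths/min by scoring
#' the spectral power of the last 30 s of belt signal inside the 6-10
#' breaths/min band (0.1-0.1667 Hz) relative to total power, updated
#' every 2 s (0.5 Hz).
#'
#' @param window Analysis window length (s). Default 30.
#' @param hop Update interval (s). Default 2.
#' @param band_lo,band_hi Target band edges (Hz). Defaults 0.1 and 1/6,
#'   i.e. 6 and 10 breaths/min.
#' @param fs Uniform resampling rate for belt traces (Hz). Default 10,
#'   far above twice the band's upper edge.
#' @param nfft Zero-padded FFT length; default 4096 gives a grid of
#'   about 0.0024 Hz, fine enough to integrate a 0.067 Hz wide band
#'   stably (a raw 30 s window resolves only 0.033 Hz).
#' @param power_floor Total-power floor below which the score is defined
#'   as 0 (flat-signal degenerate case).
#' @param target_bpm Rewarded pace, breaths/min (documentation only).
#' @return A list of class `score_params`.
#' @export
score_params <- function(window = 30, hop = 2, band_lo = 0.1, band_hi = 1 / 6,
                         fs = 10, nfft = 4096L, power_floor = 1e-10,
                         target_bpm = 8) {
  if (!(band_lo > 0 && band_lo < band_hi && band_hi < fs / 2))
    stop("need 0 < band_lo < band_hi < fs/2")
  if (hop > window) stop("hop must not exceed window")
  structure(list(window = window, hop = hop, band_lo = band_lo,
                 band_hi = band_hi, fs = fs, nfft = as.integer(nfft),
                 power_floor = power_floor, target_bpm = target_bpm),
            class = "score_params")
}

# Tapered, zero-padded one-sided power spectrum of one window's samples
# (already uniform at params$fs). Returns density on the padded grid,
# DC excluded; integrating it over frequency recovers the (taper-weighted)
# segment variance.
.window_spectrum <- function(x, params) {
  n <- length(x)
  w <- hann_window(n)
  xt <- (x - mean(x)) * w
  X <- stats::fft(c(xt, numeric(params$nfft - n)))
  nf <- params$nfft %/% 2L
  scale <- 2 / (params$fs * sum(w^2))
  list(freq = (1:nf) * params$fs / params$nfft,
       power = scale * Mod(X[2:(nf + 1L)])^2,
       df = params$fs / params$nfft)
}

#' Spectral density estimate of one breathing window
#'
#' Mean-removed, Hann-tapered, zero-padded power spectrum of a single
#' window-length breathing segment. The segment is linearly resampled to
#' `params$fs` first if its native rate differs.
#'
#' @param segment A [breathing_trace] covering one analysis window
#'   (duration equal to `params$window` within one sample).
#' @param params [score_params].
#' @return An object of class `spectral_estimate`: list with `freq` (Hz,
#'   increasing, DC excluded), `power` (non-negative density) and `df`
#'   (grid spacing, Hz).
#' @export
estimate_breathing_spectrum <- function(segment, params = score_params()) {
  if (!inherits(segment, "breathing_trace")) stop("segment must be a breathing_trace")
  if (any(!is.finite(segment$y))) stop("non-finite samples in breathing segment")
  dur <- segment$t[length(segment$t)] - segment$t[1L]
  if (dur < params$window - 1 / params$fs - 1e-9)
    stop("segment shorter than the analysis window")
  if (dur > params$window + 1 / params$fs + 1e-9)
    stop("segment longer than the analysis window")
  rs <- resample_uniform(segment$t, segment$y, params$fs)
  n <- min(length(rs$y), as.integer(round(params$window * params$fs)))
  sp <- .window_spectrum(rs$y[seq_len(n)], params)
  structure(sp, class = "spectral_estimate")
}

#' Biofeedback value of one spectrum
#'
#' The unit-interval score: area under the spectral density inside the
#' target breathing band divided by the total area. This is the bounded
#' monotone transform r/(1+r) of the in-band/out-of-band power ratio r,
#' so it preserves the ordering of the raw ratio while staying in
#' \[0, 1\]. Degenerate (near-zero-power) spectra score 0.
#'
#' @param spectrum A `spectral_estimate` from
#'   [estimate_breathing_spectrum].
#' @param params [score_params].
#' @return A single score in \[0, 1\].
#' @export
biofeedback_value <- function(spectrum, params = score_params()) {
  total <- sum(spectrum$power) * spectrum$df
  if (!is.finite(total) || total < params$power_floor) return(0)
  inband <- band_integral(spectrum$freq, spectrum$power,
                          params$band_lo, params$band_hi, spectrum$df)
  min(1, max(0, inband / total))
}

#' Score a whole breathing trace
#'
#' Recomputes the 0.5 Hz biofeedback stream offline: every `hop` seconds
#' the last `window` seconds of belt signal are analyzed, the first score
#' falling at t = window after trace onset (no scores during warm-up).
#'
#' @param trace A [breathing_trace] of duration at least `params$window`.
#' @param params [score_params].
#' @return A [bfb_stream]; empty (with a warning) when the trace is
#'   shorter than one window.
#' @export
score_stream <- function(trace, params = score_params()) {
  if (!inherits(trace, "breathing_trace")) stop("trace must be a breathing_trace")
  if (any(!is.finite(trace$y))) stop("non-finite samples in breathing trace")
  rs <- resample_uniform(trace$t, trace$y, params$fs)
  n_win <- as.integer(round(params$window * params$fs))
  hop_n <- as.integer(round(params$hop * params$fs))
  N <- length(rs$y)
  if (N < n_win) {
    warning("trace shorter than one analysis window; empty stream")
    return(bfb_stream(numeric(0), numeric(0), spacing = params$hop))
  }
  ends <- seq(n_win, N, by = hop_n)
  # window matrix: one column per score
  idx <- outer((-n_win + 1L):0L, ends, "+")
  xm <- matrix(rs$y[idx], nrow = n_win)
  xm <- sweep(xm, 2L, colMeans(xm))
  w <- hann_window(n_win)
  xm <- xm * w
  pad <- matrix(0, params$nfft - n_win, ncol(xm))
  X <- stats::mvfft(rbind(xm, pad))
  nf <- params$nfft %/% 2L
  P <- Mod(X[2:(nf + 1L), , drop = FALSE])^2
  freq <- (1:nf) * params$fs / params$nfft
  scale_df <- 2 / (params$fs * sum(w^2)) * params$fs / params$nfft
  total <- colSums(P) * scale_df
  inband <- colSums(P[freq >= params$band_lo & freq <= params$band_hi, ,
                      drop = FALSE]) * scale_df
  score <- ifelse(total < params$power_floor, 0,
                  pmin(1, pmax(0, inband / total)))
  bfb_stream(trace$t[1L] + ends / params$fs, score, spacing = params$hop)
}

#' Baseline biofeedback summary
#'
#' Baseline recordings are inconsistent in length across sessions, so the
#' shortest recording observed in practice (29 samples of the 0.5 Hz
#' stream, spanning 56 s) is the length reference: only the last
#' `min(n_ref, n)` samples enter the mean.
#'
#' @param stream A non-empty [bfb_stream] from the baseline segment.
#' @param n_ref Reference sample count; default 29.
#' @return List with `mean` (baseline score), `n_used`, `span_s` (time
#'   spanned by the samples used, interval-counting convention) and
#'   `short` (`TRUE` when the stream had fewer than `n_ref` samples).
#' @export
baseline_summary <- function(stream, n_ref = 29L) {
  if (!inherits(stream, "bfb_stream")) stop("stream must be a bfb_stream")
  n <- length(stream$score)
  if (n == 0L) stop("empty biofeedback stream")
  n_used <- min(n_ref, n)
  if (n_used < n_ref) warning("baseline stream shorter than the ", n_ref,
                              "-sample reference")
  keep <- (n - n_used + 1L):n
  spacing <- if (n >= 2L) stats::median(diff(stream$t)) else 0
  list(mean = mean(stream$score[keep]),
       n_used = n_used,
       span_s = (n_used - 1L) * spacing,
       short = n_used < n_ref)
}
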