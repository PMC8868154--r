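# Shared spectral machinery: Hann taper, uniform resampling, Welch
# cross-spectral estimation. Kept internal; module functions expose the
# domain-facing surface.

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
}

# Linear resampling of an irregular series onto a uniform grid.
resample_uniform <- function(t, y, fs) {
  grid <- seq(t[1L], t[length(t)], by = 1 / fs)
  list(t = grid, y = stats::approx(t, y, xout = grid, rule = 2)$y)
}

# Welch-averaged auto/cross spectra. Returns one-sided densities on the
# positive-frequency grid (DC excluded). `sxy` is complex; sxx/syy real.
# Scaling: integrating sxx over frequency recovers the signal variance
# (Hann power normalization 1/(fs * sum(w^2)), factor 2 one-sided).
welch_cross <- function(x, y = x, fs, nperseg = NULL, overlap = 0.5,
                        detrend = TRUE) {
  n <- length(x)
  if (length(y) != n) stop("series must have equal length")
  if (is.null(nperseg)) nperseg <- min(n, 240L)
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- hann_window(nperseg)
  scale <- 1 / (fs * sum(w^2))
  nf <- nperseg %/% 2L
  acc_xx <- acc_yy <- numeric(nf)
  acc_xy <- complex(nf)
  for (s in starts) {
    xs <- x[s:(s + nperseg - 1L)]
    ys <- y[s:(s + nperseg - 1L)]
    if (detrend) { xs <- xs - mean(xs); ys <- ys - mean(ys) }
    X <- stats::fft(xs * w)[2:(nf + 1L)]
    Y <- stats::fft(ys * w)[2:(nf + 1L)]
    acc_xx <- acc_xx + Mod(X)^2
    acc_yy <- acc_yy + Mod(Y)^2
    acc_xy <- acc_xy + Conj(X) * Y
  }
  k <- length(starts)
  list(freq = (1:nf) * fs / nperseg,
       sxx = 2 * scale * acc_xx / k,
       syy = 2 * scale * acc_yy / k,
       sxy = 2 * scale * acc_xy / k,
       n_segments = k,
       df = fs / nperseg)
}

# Rectangular band integration of a density on a uniform grid.
band_integral <- function(freq, power, lo, hi, df) {
  sum(power[freq >= lo & freq <= hi]) * df
}

# Segment length giving >= min_segments Welch segments at 50% overlap,
# capped at `pref` samples.
welch_nperseg <- function(n, pref = 240L, min_segments = 4L) {
  cap <- max(8L, 2L * floor(n / (min_segments + 1L)))
  min(pref, cap, n)
}
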