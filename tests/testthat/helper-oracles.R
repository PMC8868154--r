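# Independent oracles used to cross-check the package implementations.
# Each one deliberately takes a different computational route than the
# code it validates.

# Brute-force band-ratio score of one uniform 30 s segment: direct DFT
# by complex matrix product (no fft), same taper/pad settings as the
# implementation, band vs total power ratio. Scale factors cancel in
# the ratio.
oracle_band_score <- function(y, fs = 10, nfft = 4096L,
                              band = c(0.1, 1 / 6), floor_ = 1e-10) {
  n <- length(y)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  xt <- (y - mean(y)) * w
  k <- 1:(nfft %/% 2L)
  E <- exp(-2i * pi * outer(k, 0:(n - 1)) / nfft)
  P <- Mod(as.vector(E %*% xt))^2
  freq <- k * fs / nfft
  scale_df <- 2 / (fs * sum(w^2)) * fs / nfft
  total <- sum(P) * scale_df
  if (total < floor_) return(0)
  min(1, max(0, sum(P[freq >= band[1] & freq <= band[2]]) / sum(P)))
}

# Exhaustive cross-pair enumeration of the non-overlap tau by explicit
# double loop.
oracle_cross_tau <- function(x, y) {
  C <- 0L; D <- 0L
  for (xi in x) for (yj in y) {
    if (yj > xi) C <- C + 1L else if (yj < xi) D <- D + 1L
  }
  (C - D) / (length(x) * length(y))
}

# Standard-normal quantile by root finding on the CDF (independent of
# qnorm).
oracle_z <- function(p) {
  stats::uniroot(function(z) stats::pnorm(z) - p, c(-12, 12),
                 tol = .Machine$double.eps^0.8)$root
}

oracle_sdt <- function(hits, misses, fa, cr) {
  h <- (hits + 0.5) / (hits + misses + 1)
  f <- (fa + 0.5) / (fa + cr + 1)
  zh <- oracle_z(h); zf <- oracle_z(f)
  list(d_prime = zh - zf, criterion = -(zh + zf) / 2)
}

# Repeated-measures correlation through the ANCOVA route: fit
# y ~ subject + x, convert the slope's partial sum of squares to a
# signed correlation; df is the residual df.
oracle_rmcorr <- function(x, y, subject) {
  d <- data.frame(x = x, y = y, subject = factor(subject))
  d <- d[stats::complete.cases(d), ]
  fit <- stats::lm(y ~ subject + x, data = d)
  a <- stats::anova(fit)
  ss_x <- a["x", "Sum Sq"]; ss_e <- a["Residuals", "Sum Sq"]
  r <- sign(stats::coef(fit)[["x"]]) * sqrt(ss_x / (ss_x + ss_e))
  list(r = r, df = a["Residuals", "Df"])
}
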