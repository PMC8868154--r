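#' Bin a biofeedback stream for SCED analysis
#'
#' The withdrawal-design statistics need multiple data points per
#' session: the 0.5 Hz score stream is averaged within consecutive 15 s
#' bins. The first two bins of each session are discarded because the
#' 30 s scoring window still reaches back into the pre-game baseline
#' there.
#'
#' @param stream The in-game [bfb_stream] of one session.
#' @param bin_width Bin width (s); default 15.
#' @param drop_first Number of leading bins to discard; default 2.
#' @return Data frame of class `bin_series`: `bin` (0-based index before
#'   dropping), `bin_t` (bin start, s, relative to stream onset),
#'   `value` (mean score), `n` (samples in bin).
#' @export
bin_biofeedback <- function(stream, bin_width = 15, drop_first = 2L) {
  if (!inherits(stream, "bfb_stream")) stop("stream must be a bfb_stream")
  if (length(stream$score) == 0L) stop("empty biofeedback stream")
  rel <- stream$t - stream$t[1L]
  bin <- floor(rel / bin_width)
  agg <- tapply(stream$score, bin, mean)
  cnt <- tapply(stream$score, bin, length)
  ids <- as.integer(names(agg))
  out <- data.frame(bin = ids, bin_t = ids * bin_width,
                    value = as.numeric(agg), n = as.integer(cnt))
  out <- out[out$bin >= drop_first, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) < 3L) stop("fewer than 3 bins survive; session too short to analyze")
  class(out) <- c("bin_series", "data.frame")
  out
}

#' Within-phase trend of binned scores
#'
#' Degree-1 least-squares trend over the concatenated bin sequence of
#' one phase's sessions, plus a centered moving-average display curve.
#'
#' @param values Numeric vector of bin values (concatenated in session
#'   and bin order).
#' @param ma_window Moving-average window (bins); default 5.
#' @return List: `slope` (score units per bin), `intercept`, `smooth`
#'   (same length as `values`; edges fall back to the raw values).
#' @export
phase_trend <- function(values, ma_window = 5L) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 bins to fit a trend")
  x <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, x), values)
  sm <- stats::filter(values, rep(1 / ma_window, ma_window), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- values[is.na(sm)]
  list(slope = unname(fit$coefficients[2L]),
       intercept = unname(fit$coefficients[1L]),
       smooth = sm)
}

#' Kendall cross-pair tau non-overlap contrast
#'
#' Non-overlap effect size between the binned biofeedback values of two
#' consecutive sessions: over all `n_i * n_j` between-session bin pairs,
#' tau = (C - D) / (n_i * n_j), where C counts pairs with the
#' later-session bin higher and D the reverse; ties count in neither.
#' Complete separation gives exactly +1/-1. The two-sided p-value uses
#' the Mann-Whitney normal approximation with tie correction and
#' continuity correction. No baseline trend correction is applied:
#' within-session trends in this design are typically negative, so
#' Theil-Sen style detrending would manufacture false positives.
#'
#' @param bins_i Bin values of the earlier session (numeric vector or
#'   `bin_series`).
#' @param bins_j Bin values of the later session.
#' @param direction `"addition"` (A-to-B) or `"removal"` (B-to-A).
#' @param alpha Two-sided significance level; default 0.05.
#' @param method `"cross"` (the cross-pair tau above, default) or
#'   `"tau_b"` (tie-corrected Kendall tau-b of value against session
#'   membership, whose ceiling for balanced sessions is about 0.71).
#' @return List of class `tau_contrast`: `pair` (when known),
#'   `direction`, `tau`, `p_value`, `n_i`, `n_j`, `significant`.
#' @export
tau_contrast <- function(bins_i, bins_j, direction = c("addition", "removal"),
                         alpha = 0.05, method = c("cross", "tau_b")) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  x <- if (is.data.frame(bins_i)) bins_i$value else as.numeric(bins_i)
  y <- if (is.data.frame(bins_j)) bins_j$value else as.numeric(bins_j)
  nx <- length(x); ny <- length(y)
  if (nx < 3L || ny < 3L) stop("each session needs at least 3 bins")
  d <- sign(outer(y, x, "-"))
  S <- sum(d)                       # C - D
  tau <- if (method == "cross") S / (nx * ny) else {
    suppressWarnings(stats::cor(c(rep(0, nx), rep(1, ny)), c(x, y),
                                method = "kendall"))
  }
  if (is.na(tau)) tau <- 0          # tau_b with zero-variance values
  # Mann-Whitney normal approximation on S = 2U - nx*ny, tie-corrected
  N <- nx + ny
  ties <- table(c(x, y))
  var_s <- nx * ny / 3 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (var_s <= 0) {
    p <- 1
  } else {
    z <- (abs(S) - 1) / sqrt(var_s)   # continuity correction (1 on the S scale)
    p <- 2 * stats::pnorm(-max(z, 0))
    p <- min(1, p)
  }
  structure(list(pair = c(NA_integer_, NA_integer_), direction = direction,
                 tau = tau, p_value = p, n_i = nx, n_j = ny,
                 significant = p < alpha),
            class = "tau_contrast")
}

#' All withdrawal contrasts of one subject
#'
#' Computes the four addition (A-to-B) and four removal (B-to-A)
#' consecutive-session contrasts of the ABBABABABA design. Contrasts
#' touching a missing session are reported as missing rows, never
#' silently dropped.
#'
#' @param session_bins Named list mapping session index ("1".."10") to a
#'   `bin_series` (or numeric vector of bin values); `NULL` entries mark
#'   missing sessions.
#' @param design A [phase_design].
#' @param alpha Significance level passed to [tau_contrast].
#' @param method Tau variant passed to [tau_contrast].
#' @return Data frame with one row per contrast: `pair` ("S1-S2", ...),
#'   `from`, `to`, `direction`, `tau`, `p_value`, `n_i`, `n_j`,
#'   `significant`, `missing`.
#' @export
subject_contrasts <- function(session_bins, design = phase_design(),
                              alpha = 0.05, method = "cross") {
  rows <- list()
  for (dir in c("addition", "removal")) {
    pairs <- design[[dir]]
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      bi <- session_bins[[as.character(i)]]
      bj <- session_bins[[as.character(j)]]
      lab <- sprintf("S%d-S%d", i, j)
      if (is.null(bi) || is.null(bj) ||
          (is.data.frame(bi) && nrow(bi) < 3L) || (!is.data.frame(bi) && length(bi) < 3L) ||
          (is.data.frame(bj) && nrow(bj) < 3L) || (!is.data.frame(bj) && length(bj) < 3L)) {
        rows[[lab]] <- data.frame(pair = lab, from = i, to = j, direction = dir,
                                  tau = NA_real_, p_value = NA_real_,
                                  n_i = NA_integer_, n_j = NA_integer_,
                                  significant = NA, missing = TRUE)
      } else {
        ct <- tau_contrast(bi, bj, direction = dir, alpha = alpha, method = method)
        rows[[lab]] <- data.frame(pair = lab, from = i, to = j, direction = dir,
                                  tau = ct$tau, p_value = ct$p_value,
                                  n_i = ct$n_i, n_j = ct$n_j,
                                  significant = ct$significant, missing = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Combine one direction's contrasts into a meta effect
#'
#' Aggregates a subject's addition (or removal) contrasts into a single
#' non-overlap score: the pair-count-weighted mean of the taus (weights
#' `n_i * n_j`, the number of bin pairs each contrast summarizes) with a
#' combined p-value by Stouffer's weighted method on signed contrast
#' z-scores.
#'
#' @param contrasts Data frame of contrasts (rows of
#'   [subject_contrasts]) of a single direction; missing rows are
#'   ignored.
#' @param alpha Significance level for the combined effect.
#' @return List of class `meta_effect`: `direction`, `combined_tau`,
#'   `combined_p`, `k` (contrasts combined), `significant`.
#' @export
combine_contrasts <- function(contrasts, alpha = 0.05) {
  cc <- contrasts[!contrasts$missing, , drop = FALSE]
  if (nrow(cc) == 0L) stop("no non-missing contrasts to combine")
  if (length(unique(cc$direction)) > 1L)
    stop("combine contrasts of a single direction")
  w <- cc$n_i * cc$n_j
  combined_tau <- sum(w * cc$tau) / sum(w)
  z <- sign(cc$tau) * stats::qnorm(1 - cc$p_value / 2)
  z[!is.finite(z)] <- 0
  z_comb <- sum(w * z) / sqrt(sum(w^2))
  combined_p <- min(1, 2 * stats::pnorm(-abs(z_comb)))
  structure(list(direction = cc$direction[1L], combined_tau = combined_tau,
                 combined_p = combined_p, k = nrow(cc),
                 significant = combined_p < alpha),
            class = "meta_effect")
}

.phase_of <- function(idx, design) unname(design$phase_of_session[as.character(idx)])

#' Six-feature SCED visual-analysis summary
#'
#' Operationalizes the six features of single-case visual analysis -
#' level, trend, variability, immediacy of effect, consistency across
#' similar phases, and data overlap - for every phase change of one
#' subject, and applies the intervention decision rule: an intervention
#' effect is declared when at least three of the six features show a
#' change at a minimum of three phase transitions (in the direction the
#' intervention predicts: higher scores when biofeedback is added,
#' lower when removed).
#'
#' Per transition the features are: `level_change` = later minus earlier
#' phase mean; `trend_change` = later minus earlier within-session
#' slope; `variability_ratio` = later/earlier bin SD; `immediacy` =
#' mean of the first 3 bins of the new phase minus mean of the last 3
#' bins of the prior phase; `consistency` = whether the level change
#' exceeds the spread (SD) of session means within the same phases
#' (i.e. the jump stands out against phase-internal consistency);
#' `overlap` = the tau contrast and its significance.
#'
#' @param session_bins Named list of per-session bin series (as in
#'   [subject_contrasts]).
#' @param contrasts Output of [subject_contrasts] for the same subject.
#' @param design A [phase_design].
#' @param level_threshold Minimal expected-direction mean/immediacy
#'   change to count (score units); default 0.05.
#' @param trend_threshold Minimal expected-direction slope change
#'   (score units per bin); default 0.002.
#' @param var_ratio_threshold Variability change counts when the SD
#'   ratio leaves `[1/x, x]`; default 1.5.
#' @return List of class `sced_features`: `features` (one row per
#'   transition with values and per-feature change booleans),
#'   `feature_counts` (named vector over the six features),
#'   `intervention_effect` (logical decision).
#' @export
six_feature_summary <- function(session_bins, contrasts,
                                design = phase_design(),
                                level_threshold = 0.05,
                                trend_threshold = 0.002,
                                var_ratio_threshold = 1.5) {
  vals <- function(i) {
    b <- session_bins[[as.character(i)]]
    if (is.null(b)) return(NULL)
    if (is.data.frame(b)) b$value else as.numeric(b)
  }
  session_means <- vapply(1:10, function(i) {
    v <- vals(i); if (is.null(v)) NA_real_ else mean(v)
  }, numeric(1))
  phases <- vapply(1:10, .phase_of, character(1), design = design)
  rows <- list()
  for (r in seq_len(nrow(contrasts))) {
    ct <- contrasts[r, ]
    xi <- vals(ct$from); xj <- vals(ct$to)
    if (ct$missing || is.null(xi) || is.null(xj)) {
      rows[[ct$pair]] <- data.frame(
        pair = ct$pair, direction = ct$direction,
        level_change = NA_real_, trend_change = NA_real_,
        variability_ratio = NA_real_, immediacy = NA_real_,
        consistency_sd = NA_real_, overlap_tau = NA_real_,
        level = NA, trend = NA, variability = NA, immediacy_chg = NA,
        consistency = NA, overlap = NA)
      next
    }
    sgn <- if (ct$direction == "addition") 1 else -1
    level_change <- mean(xj) - mean(xi)
    trend_change <- phase_trend(xj)$slope - phase_trend(xi)$slope
    variability_ratio <- stats::sd(xj) / stats::sd(xi)
    k <- min(3L, length(xi), length(xj))
    immediacy <- mean(utils::head(xj, k)) - mean(utils::tail(xi, k))
    # spread of session means within the two phases involved
    ph_sd <- function(p) {
      m <- session_means[phases == p & !is.na(session_means)]
      if (length(m) >= 2L) stats::sd(m) else NA_real_
    }
    consistency_sd <- sqrt(mean(c(ph_sd(phases[ct$from])^2,
                                  ph_sd(phases[ct$to])^2), na.rm = TRUE))
    rows[[ct$pair]] <- data.frame(
      pair = ct$pair, direction = ct$direction,
      level_change = level_change, trend_change = trend_change,
      variability_ratio = variability_ratio, immediacy = immediacy,
      consistency_sd = consistency_sd, overlap_tau = ct$tau,
      level = sgn * level_change >= level_threshold,
      trend = sgn * trend_change >= trend_threshold,
      variability = is.finite(variability_ratio) &&
        (variability_ratio > var_ratio_threshold ||
           variability_ratio < 1 / var_ratio_threshold),
      immediacy_chg = sgn * immediacy >= level_threshold,
      consistency = is.finite(consistency_sd) && consistency_sd > 0 &&
        abs(level_change) > consistency_sd,
      overlap = isTRUE(ct$significant) && sgn * ct$tau > 0)
  }
  features <- do.call(rbind, rows)
  rownames(features) <- NULL
  cnt <- function(col) sum(features[[col]], na.rm = TRUE)
  feature_counts <- c(level = cnt("level"), trend = cnt("trend"),
                      variability = cnt("variability"),
                      immediacy = cnt("immediacy_chg"),
                      consistency = cnt("consistency"),
                      overlap = cnt("overlap"))
  structure(list(features = features, feature_counts = feature_counts,
                 intervention_effect = sum(feature_counts >= 3L) >= 3L),
            class = "sced_features")
}

#' Repeated-measures correlation
#'
#' The common within-subject association between two per-session
#' measurements, estimated by removing each subject's means from both
#' variables and correlating the pooled residuals (equivalent to the
#' ANCOVA formulation with subject as a factor). Degrees of freedom are
#' `n_obs - n_subjects - 1`; the p-value comes from the t-distribution.
#' Incomplete (x, y) pairs are dropped listwise; subjects left with
#' fewer than 2 complete sessions are dropped with a warning.
#'
#' @param x,y Numeric vectors of per-session values.
#' @param subject Subject identifier vector, same length.
#' @return List of class `rmcorr_result`: `r`, `df`, `p_value`,
#'   `n_obs`, `n_subjects`.
#' @export
repeated_measures_correlation <- function(x, y, subject) {
  if (length(x) != length(y) || length(x) != length(subject))
    stop("x, y and subject must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]; subject <- as.character(subject[ok])
  tab <- table(subject)
  small <- names(tab)[tab < 2L]
  if (length(small)) {
    warning("dropping subjects with fewer than 2 complete sessions: ",
            paste(small, collapse = ", "))
    keep <- !(subject %in% small)
    x <- x[keep]; y <- y[keep]; subject <- subject[keep]
  }
  k <- length(unique(subject))
  n <- length(x)
  if (k < 2L) stop("need at least 2 subjects with 2 complete sessions each")
  xc <- x - stats::ave(x, subject)
  yc <- y - stats::ave(y, subject)
  r <- stats::cor(xc, yc)
  df <- n - k - 1L
  tval <- r * sqrt(df / (1 - r^2))
  structure(list(r = r, df = df,
                 p_value = 2 * stats::pt(-abs(tval), df),
                 n_obs = n, n_subjects = k),
            class = "rmcorr_result")
}

#' @export
print.rmcorr_result <- function(x, ...) {
  cat(sprintf("Repeated-measures correlation: r(%d) = %.3f, p = %.4g (n = %d, subjects = %d)\n",
              x$df, x$r, x$p_value, x$n_obs, x$n_subjects))
  invisible(x)
}
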