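#' Per-session metric row
#'
#' Runs every analysis stage on one session and returns a single tidy
#' row: biofeedback summaries (session mean, baseline mean,
#' control-of-self, awareness), HRV metrics (band powers, ratio,
#' breathing-LF coherence, mean heart rate, heart-rate change), and
#' behavioral metrics (outcome counts, d', criterion, priming
#' false-alarm difference). Fields whose source stream is flagged
#' missing stay `NA` - they are never zero-filled. Deterministic given
#' its inputs.
#'
#' @param session A [session_record].
#' @param params [score_params]; used only when `recompute_scores`.
#' @param recompute_scores When `TRUE`, the in-game score stream is
#'   recomputed from the breathing trace instead of using the logged
#'   stream.
#' @return One-row data frame (`subject_id`, `session_index`, `phase`,
#'   metric columns, missing-data flags).
#' @export
session_metrics <- function(session, params = score_params(),
                            recompute_scores = FALSE) {
  if (!inherits(session, "session_record")) stop("session must be a session_record")
  ig_bfb <- session$ingame$biofeedback
  if (recompute_scores && !session$flags$breathing_missing)
    ig_bfb <- score_stream(session$ingame$breathing, params)
  mean_bfb <- cos_score <- awareness <- baseline_bfb <- NA_real_
  if (!is.null(ig_bfb) && length(ig_bfb$score)) {
    mean_bfb <- mean(ig_bfb$score)
    cos_score <- control_of_self(ig_bfb)
    if (!session$flags$self_rating_missing)
      awareness <- awareness_score(cos_score, session$self_rating_control_of_self)
  }
  if (!session$flags$baseline_bfb_missing)
    baseline_bfb <- suppressWarnings(baseline_summary(session$baseline$biofeedback)$mean)
  hrv <- session_hrv(session)
  beh <- data.frame(hits = NA_integer_, misses = NA_integer_,
                    false_alarms = NA_integer_, correct_rejections = NA_integer_,
                    d_prime = NA_real_, criterion = NA_real_,
                    priming_fa_diff = NA_real_)
  if (!session$flags$events_missing && nrow(session$ingame$events) > 0L) {
    counts <- tally_events(session$ingame$events)
    sdt <- sdt_metrics(counts)
    beh <- data.frame(hits = counts$hits, misses = counts$misses,
                      false_alarms = counts$false_alarms,
                      correct_rejections = counts$correct_rejections,
                      d_prime = sdt$d_prime, criterion = sdt$criterion,
                      priming_fa_diff = suppressWarnings(priming_fa_difference(counts)))
  }
  cbind(
    data.frame(subject_id = session$subject_id,
               session_index = session$session_index,
               phase = session$phase,
               mean_biofeedback = mean_bfb,
               baseline_biofeedback = baseline_bfb,
               control_of_self = cos_score,
               awareness = awareness),
    hrv, beh,
    data.frame(rr_missing = session$flags$rr_missing,
               breathing_missing = session$flags$breathing_missing,
               bfb_missing = session$flags$bfb_missing,
               events_missing = session$flags$events_missing)
  )
}

#' Cohort metrics table
#'
#' @param sessions List of [session_record]s.
#' @param ... Passed to [session_metrics].
#' @return Data frame with one row per subject-session.
#' @export
cohort_metrics <- function(sessions, ...) {
  out <- do.call(rbind, lapply(sessions, session_metrics, ...))
  rownames(out) <- NULL
  out
}

.round_df <- function(df, digits = 4L) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

.subject_session_bins <- function(sessions, subject) {
  bins <- stats::setNames(vector("list", 10L), as.character(1:10))
  for (rec in sessions) {
    if (rec$subject_id != subject) next
    if (rec$flags$bfb_missing || is.null(rec$ingame$biofeedback)) next
    b <- try(bin_biofeedback(rec$ingame$biofeedback), silent = TRUE)
    if (!inherits(b, "try-error"))
      bins[[as.character(rec$session_index)]] <- b
  }
  bins
}

#' Cohort-level withdrawal report
#'
#' Runs the full analysis over a cohort of session records and writes a
#' report bundle to `out_dir`:
#' \itemize{
#'   \item `metrics.csv` - one row per subject-session, full precision.
#'   \item `contrasts.csv` - long table of all tau contrasts (subject,
#'     pair, direction, tau, p, significance; missing contrasts kept as
#'     empty cells).
#'   \item `contrasts_wide.csv` - one row per subject: the eight
#'     transition taus (columns `S1-S2` .. `S9-S10`) plus addition and
#'     removal meta tau/p; significance rendered in separate star
#'     columns, never merged into numeric cells.
#'   \item `rmcorr.csv` - repeated-measures correlations of the session
#'     mean biofeedback score with LF coherence, LF power and HF power.
#'   \item `features.csv` / `decisions.csv` - six-feature summaries and
#'     per-subject intervention decisions.
#' }
#' Report floats are rounded to 4 decimals except `metrics.csv`.
#' Session records are never mutated.
#'
#' @param sessions List of [session_record]s (at least one complete
#'   subject).
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing and just returns the tables.
#' @param alpha Per-contrast significance level.
#' @param ... Passed to [session_metrics].
#' @return Invisibly, a list with elements `metrics`, `contrasts`,
#'   `contrasts_wide`, `rmcorr`, `features`, `decisions`.
#' @export
cohort_report <- function(sessions, out_dir = NULL, alpha = 0.05, ...) {
  if (length(sessions) == 0L) stop("empty cohort")
  metrics <- cohort_metrics(sessions, ...)
  subjects <- unique(metrics$subject_id)
  design <- phase_design()
  contrast_rows <- list(); wide_rows <- list()
  feature_rows <- list(); decision_rows <- list()
  for (s in subjects) {
    bins <- .subject_session_bins(sessions, s)
    ct <- subject_contrasts(bins, design, alpha = alpha)
    ct_out <- cbind(subject_id = s, ct)
    contrast_rows[[s]] <- ct_out
    meta <- list(addition = NULL, removal = NULL)
    for (dir in c("addition", "removal")) {
      sub <- ct[ct$direction == dir, , drop = FALSE]
      meta[[dir]] <- if (any(!sub$missing)) combine_contrasts(sub, alpha = alpha)
                     else list(combined_tau = NA_real_, combined_p = NA_real_,
                               significant = NA)
    }
    taus <- stats::setNames(ct$tau, ct$pair)
    stars <- stats::setNames(ifelse(is.na(ct$significant), "",
                                    ifelse(ct$significant, "*", "")), ct$pair)
    wide_rows[[s]] <- data.frame(
      subject_id = s, as.list(taus), check.names = FALSE,
      addition_meta_tau = meta$addition$combined_tau,
      addition_meta_p = meta$addition$combined_p,
      addition_meta_sig = ifelse(isTRUE(meta$addition$significant), "*", ""),
      removal_meta_tau = meta$removal$combined_tau,
      removal_meta_p = meta$removal$combined_p,
      removal_meta_sig = ifelse(isTRUE(meta$removal$significant), "*", ""),
      stars = paste(stars, collapse = "")
    )
    ft <- six_feature_summary(bins, ct, design)
    feature_rows[[s]] <- cbind(subject_id = s, ft$features)
    decision_rows[[s]] <- data.frame(
      subject_id = s, t(ft$feature_counts),
      intervention_effect = ft$intervention_effect)
  }
  rm_tab <- do.call(rbind, lapply(
    c(lf_breathing_coherence = "lf_breathing_coherence",
      lf_power = "lf_power", hf_power = "hf_power"),
    function(v) {
      res <- tryCatch(suppressWarnings(repeated_measures_correlation(
        metrics$mean_biofeedback, metrics[[v]], metrics$subject_id)),
        error = function(e) NULL)
      if (is.null(res)) return(data.frame(variable = v, r = NA_real_,
                                          df = NA_integer_, p_value = NA_real_,
                                          n_obs = NA_integer_,
                                          n_subjects = NA_integer_))
      data.frame(variable = v, r = res$r, df = res$df, p_value = res$p_value,
                 n_obs = res$n_obs, n_subjects = res$n_subjects)
    }))
  rownames(rm_tab) <- NULL
  out <- list(metrics = metrics,
              contrasts = do.call(rbind, contrast_rows),
              contrasts_wide = do.call(rbind, wide_rows),
              rmcorr = rm_tab,
              features = do.call(rbind, feature_rows),
              decisions = do.call(rbind, decision_rows))
  for (nm in names(out)) rownames(out[[nm]]) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(.round_df(out$contrasts), file.path(out_dir, "contrasts.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(.round_df(out$contrasts_wide),
                     file.path(out_dir, "contrasts_wide.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(.round_df(out$rmcorr), file.path(out_dir, "rmcorr.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(.round_df(out$features), file.path(out_dir, "features.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(.round_df(out$decisions), file.path(out_dir, "decisions.csv"),
                     row.names = FALSE, na = "")
  }
  invisible(out)
}

#' Write a cohort manifest
#'
#' Saves each session record as a JSON log under `dir` and writes
#' `manifest.csv` (`subject_id`, `session_index`, `phase`, `path`).
#'
#' @param sessions List of [session_record]s.
#' @param dir Output directory.
#' @return Path of the manifest, invisibly.
#' @export
write_cohort <- function(sessions, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(sessions, function(rec) {
    fn <- sprintf("subject%s_session%02d.json", rec$subject_id, rec$session_index)
    save_session(rec, file.path(dir, fn))
    data.frame(subject_id = rec$subject_id, session_index = rec$session_index,
               phase = rec$phase, path = fn)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}

#' Load a cohort from a manifest
#'
#' @param manifest_path Path to a `manifest.csv` written by
#'   [write_cohort].
#' @return List of [session_record]s.
#' @export
read_cohort <- function(manifest_path) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  lapply(manifest$path, function(p) load_session(file.path(base, p)))
}
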