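#' Synthetic cohort configuration
#'
#' Generative parameters of the synthetic training cohort that stands in
#' for the restricted dataset. Defaults emulate the study conditions:
#' nine subjects, ten 15-minute sessions under the ABBABABABA
#' withdrawal design, a 90 s pre-game rest baseline (so the 0.5 Hz
#' baseline score stream spans at least the 29-sample / 56 s reference
#' after the 30 s warm-up), an in-game heart-rate rise of about
#' +10 beats/min over baseline, fourteen enemy waves with dispatch
#' body-type reliability declining from 100% to 50%, and per-subject
#' learning dynamics in which breathing-pace adherence grows across
#' sessions, receives a boost while biofeedback is displayed (B phases),
#' and partially transfers to later feedback-free (A) sessions.
#'
#' @param n_subjects Number of subjects; default 9.
#' @param base_adherence Session-1 pace adherence in \[0, 1\]; default 0.35.
#' @param learning_rate Adherence gain per session; default 0.04.
#' @param bfb_boost Extra adherence while biofeedback is displayed;
#'   default 0.25.
#' @param transfer_retention Fraction of accumulated learning retained
#'   in feedback-free sessions; default 0.6.
#' @param subject_sd Between-subject SD on `base_adherence` and
#'   `bfb_boost`; default 0.04.
#' @param target_bpm Rewarded breathing pace; default 8.
#' @param rest_bpm Spontaneous (non-adherent) pace; default 14.
#' @param depth Breathing amplitude (belt units); default 1.
#' @param pace_jitter_sd Fast breath-to-breath pace jitter SD (bpm);
#'   default 0.8.
#' @param pace_wander_sd Slow spontaneous pace wander SD (bpm); default 2.5.
#' @param pace_wander_tau Wander correlation time (s); default 60.
#' @param noise_sd Additive fixed-amplitude belt noise SD; default 0.1.
#' @param fs Belt sampling rate (Hz); default 10.
#' @param baseline_hr Resting heart rate (beats/min); default 75.
#' @param hr_rise In-game heart-rate increase (beats/min); default 10.
#' @param rsa_gain_ms Respiratory sinus arrhythmia gain: peak heart-period
#'   swing per unit normalized breathing (ms); default 40.
#' @param mayer_amp_ms Amplitude of the 0.1 Hz Mayer-wave heart-period
#'   oscillation (ms); default 10.
#' @param rr_noise_sd_ms White beat-to-beat interval noise SD (ms);
#'   default 5.
#' @param d_prime_true Agent sensitivity; default 1.5.
#' @param criterion_true Agent response bias; default 0.
#' @param priming_bias Criterion shift toward shooting primed targets;
#'   default 0.3.
#' @param n_waves Enemy waves per session; default 14.
#' @param targets_per_wave Targets per wave; default 8.
#' @param p_hostile Hostile fraction; default 0.5.
#' @param reliability_start,reliability_end Dispatch body-type
#'   reliability in the first and last wave; defaults 1.0 and 0.5.
#' @param ingame_s In-game duration (s); default 900.
#' @param baseline_s Baseline duration (s); default 90.
#' @param seed Master seed fixing the whole cohort.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 9L,
                          base_adherence = 0.35, learning_rate = 0.04,
                          bfb_boost = 0.25, transfer_retention = 0.6,
                          subject_sd = 0.04,
                          target_bpm = 8, rest_bpm = 14, depth = 1,
                          pace_jitter_sd = 0.8, pace_wander_sd = 2.5,
                          pace_wander_tau = 60, noise_sd = 0.1, fs = 10,
                          baseline_hr = 75, hr_rise = 10, rsa_gain_ms = 40,
                          mayer_amp_ms = 10, rr_noise_sd_ms = 5,
                          d_prime_true = 1.5, criterion_true = 0,
                          priming_bias = 0.3,
                          n_waves = 14L, targets_per_wave = 8L,
                          p_hostile = 0.5,
                          reliability_start = 1.0, reliability_end = 0.5,
                          ingame_s = 900, baseline_s = 90, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_subjects >= 1, cfg$d_prime_true >= 0,
            cfg$reliability_start >= cfg$reliability_end,
            cfg$pace_jitter_sd >= 0, cfg$pace_wander_sd >= 0,
            cfg$noise_sd >= 0, cfg$rr_noise_sd_ms >= 0)
  structure(cfg, class = "cohort_config")
}

#' Read / write a cohort configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_cohort_config`, a `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(cohort_config, vals[names(vals) %in% names(formals(cohort_config))])
}

#' @rdname read_cohort_config
#' @param config A `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Deterministic sub-seed derivation (kept below 2^31).
.sub_seed <- function(seed, ...) {
  k <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (v in k) s <- (s * 69069 + as.double(v) * 9973 + 1) %% 2147483647
  as.integer(s)
}

.ou_process <- function(n, dt, sd, tau, seed = NULL) {
  if (!is.null(seed)) set.seed(.sub_seed(seed, 11L))
  if (sd == 0) return(numeric(n))
  a <- exp(-dt / tau)
  e <- stats::rnorm(n, sd = sd * sqrt(1 - a^2))
  as.numeric(stats::filter(e, a, method = "recursive")) # stationary-ish OU
}

#' Generate a synthetic breathing trace
#'
#' A phase-continuous chirp: the belt signal is `depth * sin(phi(t))`
#' with instantaneous frequency `pace(t)/60` Hz integrated over time
#' (so pace changes introduce no spectral discontinuities), plus
#' optional smooth pace jitter and additive fixed-amplitude measurement
#' noise. Identical seeds give bit-identical traces.
#'
#' @param duration Trace duration (s).
#' @param pace_bpm Breathing pace: scalar, per-sample vector, or
#'   `function(t)`; values must lie in \[2, 40\] breaths/min.
#' @param depth Amplitude (belt units).
#' @param pace_jitter_sd Pace jitter SD (bpm), applied as a smooth
#'   (10 s correlation) perturbation of the pace.
#' @param noise_sd Additive white noise SD (belt units).
#' @param fs Sampling rate (Hz); default 10.
#' @param seed Optional seed.
#' @return A [breathing_trace].
#' @export
gen_breathing <- function(duration, pace_bpm = 8, depth = 1,
                          pace_jitter_sd = 0, noise_sd = 0, fs = 10,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, by = 1 / fs)
  n <- length(t)
  pace <- if (is.function(pace_bpm)) pace_bpm(t)
          else if (length(pace_bpm) == 1L) rep(pace_bpm, n)
          else stats::approx(seq(0, duration, length.out = length(pace_bpm)),
                             pace_bpm, xout = t, rule = 2)$y
  if (any(pace < 2 | pace > 40)) stop("pace must stay within [2, 40] breaths/min")
  if (pace_jitter_sd > 0)
    pace <- pmin(40, pmax(2, pace + .ou_process(n, 1 / fs, pace_jitter_sd, 10)))
  phi <- 2 * pi * cumsum(pace / 60) / fs
  y <- depth * sin(phi)
  if (noise_sd > 0) y <- y + stats::rnorm(n, sd = noise_sd)
  breathing_trace(t, y, rate = fs)
}

#' Generate an R-R series driven by a breathing trace
#'
#' The instantaneous heart period is
#' `h(t) = 60000/hr(t) + rsa_gain_ms * b(t) + mayer_amp_ms * sin(2*pi*0.1*t)`
#' where `b(t)` is the breathing trace normalized to unit peak amplitude
#' (the respiratory sinus arrhythmia pathway). Beats are emitted by
#' integrate-and-fire over `1/h(t)` (IPFM), then white interval noise is
#' added. The realized mean heart rate stays within 2% of the target.
#'
#' @param breathing A [breathing_trace] (drives RSA and supplies the
#'   time grid).
#' @param mean_hr Target heart rate: scalar or per-sample vector
#'   (beats/min, each in \[40, 200\]).
#' @param rsa_gain_ms RSA heart-period gain (ms per unit breathing).
#' @param mayer_amp_ms Mayer-wave amplitude (ms).
#' @param rr_noise_sd_ms White interval noise SD (ms).
#' @param seed Optional seed.
#' @return An [rr_series].
#' @export
gen_rr <- function(breathing, mean_hr = 75, rsa_gain_ms = 40,
                   mayer_amp_ms = 10, rr_noise_sd_ms = 5, seed = NULL) {
  if (!inherits(breathing, "breathing_trace")) stop("breathing must be a breathing_trace")
  if (!is.null(seed)) set.seed(seed)
  t <- breathing$t
  n <- length(t)
  hr <- if (length(mean_hr) == 1L) rep(mean_hr, n) else mean_hr
  if (any(hr < 40 | hr > 200)) stop("mean_hr must lie in [40, 200]")
  b <- breathing$y - mean(breathing$y)
  pk <- max(abs(b))
  if (pk > 0) b <- b / pk
  h_ms <- 60000 / hr + rsa_gain_ms * b + mayer_amp_ms * sin(2 * pi * 0.1 * t)
  if (any(h_ms < 300))
    stop("parameters yield instantaneous heart periods below 300 ms")
  dt <- c(diff(t)[1L], diff(t))
  cum <- cumsum(1000 / h_ms * dt)   # beats elapsed
  n_beats <- floor(cum[n])
  if (n_beats < 2L) stop("trace too short to emit beats")
  beat_t <- stats::approx(cum, t, xout = seq_len(n_beats))$y
  rr <- diff(beat_t) * 1000
  if (rr_noise_sd_ms > 0) rr <- rr + stats::rnorm(length(rr), sd = rr_noise_sd_ms)
  if (any(rr < 300))
    stop("parameters yield R-R intervals below 300 ms")
  rr_series(c(beat_t[1L], beat_t[1L] + cumsum(rr) / 1000),
            rr = NULL)
}

#' Generate a session's game events
#'
#' Targets arrive in `n_waves` waves. Each wave announces a hostile body
#' type and eye color over dispatch; hostile targets always carry the
#' announced eye color (the reliable small identifier) but match the
#' announced body type only with probability given by the declining
#' reliability schedule; friendly targets carry other eye colors and
#' random body types. A target is `primed` when its body type matches
#' the announcement. The agent is an equal-variance Gaussian observer
#' with sensitivity `d_prime`, bias `criterion`, and a criterion shift
#' of `-priming_bias` for primed targets (more willing to shoot).
#'
#' @param duration Session duration (s); event times are spread across it.
#' @param n_waves Number of waves.
#' @param targets_per_wave Targets per wave.
#' @param p_hostile Probability a target is hostile.
#' @param reliability Vector of per-wave body-type reliability
#'   (recycled/interpolated to `n_waves`), non-increasing from 1 toward
#'   0.5 by default.
#' @param d_prime,criterion,priming_bias Agent parameters.
#' @param t_offset Added to all event times (s).
#' @param seed Optional seed.
#' @return A validated game event data frame.
#' @export
gen_game_events <- function(duration = 900, n_waves = 14L,
                            targets_per_wave = 8L, p_hostile = 0.5,
                            reliability = seq(1, 0.5, length.out = n_waves),
                            d_prime = 1.5, criterion = 0, priming_bias = 0,
                            t_offset = 0, seed = NULL) {
  if (n_waves < 1L) stop("need at least one wave")
  if (!is.null(seed)) set.seed(seed)
  if (length(reliability) != n_waves)
    reliability <- stats::approx(seq_along(reliability), reliability,
                                 xout = seq(1, length(reliability),
                                            length.out = n_waves))$y
  rows <- vector("list", n_waves)
  wave_len <- duration / n_waves
  for (wv in seq_len(n_waves)) {
    m <- targets_per_wave
    announced_body <- sample(.body_types, 1L)
    announced_eye <- sample(.eye_colors, 1L)
    hostile <- stats::runif(m) < p_hostile
    body <- character(m); eye <- character(m)
    for (i in seq_len(m)) {
      if (hostile[i]) {
        eye[i] <- announced_eye
        body[i] <- if (stats::runif(1) < reliability[wv]) announced_body
                   else sample(setdiff(.body_types, announced_body), 1L)
      } else {
        eye[i] <- sample(setdiff(.eye_colors, announced_eye), 1L)
        body[i] <- sample(.body_types, 1L)
      }
    }
    primed <- body == announced_body
    evidence <- stats::rnorm(m, mean = ifelse(hostile, d_prime, 0), sd = 1)
    cutoff <- d_prime / 2 + criterion - priming_bias * primed
    shoot <- evidence > cutoff
    kind <- ifelse(hostile,
                   ifelse(shoot, "shot_hit", "miss_reached"),
                   ifelse(shoot, "shot_false_alarm", "correct_rejection"))
    tt <- sort(stats::runif(m, (wv - 1) * wave_len, wv * wave_len))
    rows[[wv]] <- data.frame(t = t_offset + tt, kind = kind, body_type = body,
                             primed = primed, eye_color = eye,
                             hostile = hostile,
                             distance = stats::runif(m, 5, 50), wave = wv)
  }
  validate_events(do.call(rbind, rows))
}

# Per-session effective pace adherence under the learning model:
# skill grows linearly with session index; B sessions add the
# biofeedback boost; A sessions retain a fraction of accumulated skill.
.adherence <- function(session_index, phase, base, rate, boost, retention) {
  skill <- base + rate * (session_index - 1L)
  adh <- if (phase == "B") skill + boost else base + retention * (skill - base)
  min(1, max(0, adh))
}

#' Generate one synthetic subject-session
#'
#' Builds the full session: a continuous breathing trace covering the
#' rest baseline (spontaneous pace) and the game (pace pulled toward
#' the 8 breaths/min target in proportion to the session's adherence),
#' the biofeedback stream recomputed from that trace with the standard
#' scoring parameters and split at game start, an R-R series whose rate
#' steps up by `hr_rise` during the game, the game event log, and a
#' noisy self-rating of control-of-self (players overestimate early in
#' training).
#'
#' @param subject_id Subject identifier.
#' @param session_index Session 1..10.
#' @param adherence Effective pace adherence in \[0, 1\].
#' @param config A [cohort_config].
#' @param seed Seed for this session.
#' @param components Character subset of `c("rr", "events")`: streams to
#'   generate besides breathing/biofeedback (skipping unused streams
#'   speeds up large simulation studies).
#' @param params [score_params] used to recompute the score stream.
#' @return A [session_record].
#' @export
gen_session <- function(subject_id, session_index, adherence,
                        config = cohort_config(), seed = 1L,
                        components = c("rr", "events"),
                        params = score_params(fs = config$fs)) {
  phase <- unname(phase_design()$phase_of_session[as.character(session_index)])
  total_s <- config$baseline_s + config$ingame_s
  fs <- config$fs
  set.seed(.sub_seed(seed, 1L))
  t <- seq(0, total_s, by = 1 / fs)
  ingame <- t > config$baseline_s
  wander <- config$rest_bpm +
    .ou_process(length(t), 1 / fs, config$pace_wander_sd, config$pace_wander_tau)
  wander <- pmin(24, pmax(6, wander))
  pace <- ifelse(ingame,
                 adherence * config$target_bpm + (1 - adherence) * wander,
                 wander)
  breathing <- gen_breathing(total_s, pace_bpm = function(tt) pace,
                             depth = config$depth * (0.6 + 0.4 * adherence),
                             pace_jitter_sd = config$pace_jitter_sd,
                             noise_sd = config$noise_sd, fs = fs,
                             seed = .sub_seed(seed, 2L))
  scores <- score_stream(breathing, params)
  bl_sel <- scores$t <= config$baseline_s
  bl_bfb <- bfb_stream(scores$t[bl_sel], scores$score[bl_sel])
  ig_bfb <- bfb_stream(scores$t[!bl_sel], scores$score[!bl_sel])
  ig_breathing <- breathing_trace(breathing$t[ingame], breathing$y[ingame],
                                  rate = fs)
  bl_rr <- ig_rr <- NULL
  if ("rr" %in% components) {
    hr <- ifelse(ingame, config$baseline_hr + config$hr_rise, config$baseline_hr)
    rr_all <- gen_rr(breathing, mean_hr = hr,
                     rsa_gain_ms = config$rsa_gain_ms,
                     mayer_amp_ms = config$mayer_amp_ms,
                     rr_noise_sd_ms = config$rr_noise_sd_ms,
                     seed = .sub_seed(seed, 3L))
    bsel <- rr_all$beat_t <= config$baseline_s
    if (sum(bsel) >= 4L)
      bl_rr <- structure(list(beat_t = rr_all$beat_t[bsel], rr = rr_all$rr[bsel]),
                         class = "rr_series")
    isel <- !bsel
    ig_rr <- structure(list(beat_t = rr_all$beat_t[isel], rr = rr_all$rr[isel]),
                       class = "rr_series")
  }
  events <- NULL
  if ("events" %in% components)
    events <- gen_game_events(
      duration = config$ingame_s, n_waves = config$n_waves,
      targets_per_wave = config$targets_per_wave, p_hostile = config$p_hostile,
      reliability = seq(config$reliability_start, config$reliability_end,
                        length.out = config$n_waves),
      d_prime = config$d_prime_true, criterion = config$criterion_true,
      priming_bias = config$priming_bias, t_offset = config$baseline_s,
      seed = .sub_seed(seed, 4L))
  set.seed(.sub_seed(seed, 5L))
  actual <- control_of_self(ig_bfb)
  overestimate <- max(0, 30 - 3 * (session_index - 1L))
  reported <- min(100, max(0, actual + overestimate + stats::rnorm(1, sd = 10)))
  session_record(subject_id, session_index, phase,
                 game_start_s = config$baseline_s,
                 baseline = list(biofeedback = bl_bfb, rr = bl_rr),
                 ingame = list(breathing = ig_breathing, rr = ig_rr,
                               biofeedback = ig_bfb, events = events),
                 self_rating_control_of_self = reported)
}

#' Generate a full synthetic cohort
#'
#' `n_subjects` subjects, ten sessions each under the ABBABABABA design,
#' with per-subject learning parameters drawn around the configured
#' means. One master seed fixes the whole cohort.
#'
#' @param config A [cohort_config].
#' @param components Streams to generate per session (see
#'   [gen_session]).
#' @return List of [session_record]s (subject-major order) with
#'   attribute `ground_truth`: per-subject data frame of the drawn
#'   learning parameters and per-session adherence.
#' @export
gen_cohort <- function(config = cohort_config(),
                       components = c("rr", "events")) {
  design <- phase_design()
  set.seed(.sub_seed(config$seed, 99L))
  subj_base <- pmin(0.9, pmax(0.05,
    config$base_adherence + stats::rnorm(config$n_subjects, sd = config$subject_sd)))
  subj_boost <- pmax(0, config$bfb_boost +
                       stats::rnorm(config$n_subjects, sd = config$subject_sd))
  sessions <- vector("list", config$n_subjects * 10L)
  gt <- list()
  k <- 0L
  for (s in seq_len(config$n_subjects)) {
    adh <- vapply(1:10, function(i)
      .adherence(i, unname(design$phase_of_session[as.character(i)]),
                 subj_base[s], config$learning_rate, subj_boost[s],
                 config$transfer_retention), numeric(1))
    gt[[s]] <- data.frame(subject_id = as.character(s),
                          base_adherence = subj_base[s],
                          bfb_boost = subj_boost[s],
                          session_index = 1:10, adherence = adh)
    for (i in 1:10) {
      k <- k + 1L
      sessions[[k]] <- gen_session(
        subject_id = as.character(s), session_index = i, adherence = adh[i],
        config = config, seed = .sub_seed(config$seed, s, i),
        components = components)
    }
  }
  attr(sessions, "ground_truth") <- do.call(rbind, gt)
  sessions
}

#' Bin-level synthetic sessions (reduced-fidelity mode)
#'
#' A reduced model of the cohort that skips signal synthesis entirely
#' and draws the 15 s bin values directly: each session's bins are
#' i.i.d. normal around the session's expected score (an affine map of
#' its adherence), truncated to \[0, 1\]. Useful for large simulation
#' studies of the contrast statistics, where only the bin distribution
#' matters; by construction bins are independent, unlike the
#' full-fidelity streams whose overlapping score windows correlate
#' neighboring bins.
#'
#' @param config A [cohort_config].
#' @param n_bins Bins per session; default 58.
#' @param bin_sd Bin SD; default 0.1.
#' @return List (per subject) of named lists (per session "1".."10") of
#'   bin-value vectors, with attribute `ground_truth` as in
#'   [gen_cohort].
#' @export
gen_bin_sessions <- function(config = cohort_config(), n_bins = 58L,
                             bin_sd = 0.1) {
  design <- phase_design()
  set.seed(.sub_seed(config$seed, 98L))
  subj_base <- pmin(0.9, pmax(0.05,
    config$base_adherence + stats::rnorm(config$n_subjects, sd = config$subject_sd)))
  subj_boost <- pmax(0, config$bfb_boost +
                       stats::rnorm(config$n_subjects, sd = config$subject_sd))
  out <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    sess <- stats::setNames(vector("list", 10L), as.character(1:10))
    for (i in 1:10) {
      adh <- .adherence(i, unname(design$phase_of_session[as.character(i)]),
                        subj_base[s], config$learning_rate, subj_boost[s],
                        config$transfer_retention)
      mu <- min(0.95, max(0.05, 0.1 + 0.8 * adh))
      sess[[as.character(i)]] <- pmin(1, pmax(0, stats::rnorm(n_bins, mu, bin_sd)))
    }
    out[[s]] <- sess
  }
  out
}
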