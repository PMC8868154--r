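# Small fixtures built in code.

make_bfb <- function(scores, t0 = 0) {
  bfb_stream(t0 + seq(0, by = 2, length.out = length(scores)), scores)
}

make_rr_constant <- function(rr_ms, duration_s, t0 = 0) {
  beats <- seq(t0, t0 + duration_s, by = rr_ms / 1000)
  rr_series(beats)
}

# Minimal valid session: constant-rate heart, flat scores, no events.
make_mini_session <- function(subject = "1", session_index = 1,
                              baseline_rr_ms = 1000, ingame_rr_ms = 800,
                              game_start = 60, ingame_s = 150) {
  phase <- unname(phase_design()$phase_of_session[as.character(session_index)])
  bl_scores <- make_bfb(rep(0.3, 16), t0 = 30)
  ig_t <- seq(game_start + 2, game_start + ingame_s, by = 2)
  ig_scores <- bfb_stream(ig_t, rep(0.6, length(ig_t)))
  tr_t <- seq(game_start, game_start + ingame_s, by = 0.1)
  breathing <- breathing_trace(tr_t, sin(2 * pi * 0.1333 * tr_t))
  session_record(subject, session_index, phase, game_start_s = game_start,
                 baseline = list(biofeedback = bl_scores,
                                 rr = make_rr_constant(baseline_rr_ms, game_start)),
                 ingame = list(breathing = breathing,
                               rr = make_rr_constant(ingame_rr_ms, ingame_s,
                                                     t0 = game_start),
                               biofeedback = ig_scores,
                               events = make_events()),
                 self_rating_control_of_self = 50)
}

make_events <- function(hits = 3, misses = 2, fas = 1, crs = 4,
                        primed_fas = NULL, primed_crs = NULL, t0 = 60) {
  kind <- rep(c("shot_hit", "miss_reached", "shot_false_alarm", "correct_rejection"),
              c(hits, misses, fas, crs))
  n <- length(kind)
  hostile <- kind %in% c("shot_hit", "miss_reached")
  primed <- rep(FALSE, n)
  if (!is.null(primed_fas)) {
    idx <- which(kind == "shot_false_alarm")
    primed[utils::head(idx, primed_fas)] <- TRUE
  }
  if (!is.null(primed_crs)) {
    idx <- which(kind == "correct_rejection")
    primed[utils::head(idx, primed_crs)] <- TRUE
  }
  data.frame(t = t0 + seq_len(n), kind = kind,
             body_type = rep("tall_male", n), primed = primed,
             eye_color = ifelse(hostile, "red", "blue"),
             hostile = hostile, distance = rep(10, n),
             wave = pmin(14L, seq_len(n)))
}
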