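#' @title Domain types for biofeedback training sessions
#' @name session-types
#' @description Light S3 containers for the per-session data streams:
#'   belt breathing traces, R-R interval series, the 0.5 Hz biofeedback
#'   score stream, and the in-game event log. Constructors validate the
#'   invariants each downstream computation relies on.
NULL

#' Construct a breathing trace
#'
#' A respiration-belt amplitude signal. Timestamps are seconds from the
#' start of the session segment they belong to; amplitude is in arbitrary
#' belt units. The sampling rate is carried with the trace because belt
#' hardware varies; analyses resample to a uniform grid themselves.
#'
#' @param t Numeric vector of timestamps (s), strictly increasing.
#' @param y Numeric vector of belt amplitudes, same length as `t`.
#' @param rate Nominal samples/second. Defaults to the inverse median
#'   timestamp spacing.
#' @return An object of class `breathing_trace` with fields `t`, `y`, `rate`.
#' @examples
#' tr <- breathing_trace(seq(0, 60, by = 0.1), sin(2 * pi * 8 / 60 * seq(0, 60, by = 0.1)))
#' tr$rate
#' @export
breathing_trace <- function(t, y, rate = NULL) {
  t <- as.numeric(t); y <- as.numeric(y)
  if (length(t) != length(y)) stop("t and y must have equal length")
  if (length(t) < 2L) stop("breathing trace needs at least 2 samples")
  if (any(!is.finite(t))) stop("non-finite timestamps in breathing trace")
  if (any(diff(t) <= 0)) stop("breathing trace timestamps must be strictly increasing")
  if (is.null(rate)) rate <- 1 / stats::median(diff(t))
  if (!is.finite(rate) || rate <= 0) stop("rate must be > 0")
  structure(list(t = t, y = y, rate = rate), class = "breathing_trace")
}

#' Construct an R-R interval series
#'
#' Inter-beat intervals in milliseconds, aligned to the time of the beat
#' that closes each interval. Either supply beat times only (intervals are
#' derived, the first beat anchoring the series) or both vectors, which
#' must be mutually consistent.
#'
#' @param beat_t Seconds of each R peak, strictly increasing. When `rr` is
#'   `NULL`, all beats including the anchor; intervals are the successive
#'   differences and the returned `beat_t` drops the anchor beat.
#' @param rr Optional intervals (ms) aligned to `beat_t` (interval ending
#'   at that beat).
#' @param tol_ms Consistency tolerance between `rr` and `diff(beat_t)`.
#' @return An object of class `rr_series` with fields `beat_t`, `rr`
#'   (equal length).
#' @export
rr_series <- function(beat_t, rr = NULL, tol_ms = 0.5) {
  beat_t <- as.numeric(beat_t)
  if (any(diff(beat_t) <= 0)) stop("beat times must be strictly increasing")
  if (is.null(rr)) {
    if (length(beat_t) < 2L) stop("need at least 2 beats")
    rr <- diff(beat_t) * 1000
    beat_t <- beat_t[-1L]
  } else {
    rr <- as.numeric(rr)
    if (length(rr) != length(beat_t)) stop("rr must align to beat_t")
    if (length(beat_t) > 1L) {
      err <- abs(diff(beat_t) * 1000 - rr[-1L])
      if (any(err > tol_ms))
        stop("rr inconsistent with beat time differences (max deviation ",
             format(max(err)), " ms)")
    }
  }
  if (any(rr <= 0)) stop("rr intervals must be positive")
  structure(list(beat_t = beat_t, rr = rr), class = "rr_series")
}

#' Construct a biofeedback score stream
#'
#' The 0.5 Hz score series produced during training: one value every 2 s,
#' each in the unit interval.
#'
#' @param t Timestamps (s), 2 s spacing.
#' @param score Scores in \[0, 1\].
#' @param spacing Expected spacing (s); default 2.
#' @return An object of class `bfb_stream` with fields `t`, `score`.
#' @export
bfb_stream <- function(t, score, spacing = 2) {
  t <- as.numeric(t); score <- as.numeric(score)
  if (length(t) != length(score)) stop("t and score must have equal length")
  if (length(t) > 1L && any(abs(diff(t) - spacing) > 1e-6))
    stop("biofeedback stream must be sampled every ", spacing, " s")
  if (length(score) && (any(!is.finite(score)) || any(score < 0 | score > 1)))
    stop("scores must lie in [0, 1]")
  structure(list(t = t, score = score), class = "bfb_stream")
}

.event_kinds <- c("shot_hit", "miss_reached", "shot_false_alarm", "correct_rejection")
.body_types <- c("tall_male", "small_male", "tall_female", "small_female")
.eye_colors <- c("red", "blue", "yellow")

#' Validate a game event table
#'
#' Events are rows of a data frame with columns `t`, `kind`, `body_type`,
#' `primed`, `eye_color`, `hostile`, `distance` (optional, metres) and
#' `wave`. Outcome kinds must be consistent with the hostile flag: hits
#' and misses belong to hostile targets, false alarms and correct
#' rejections to friendly ones.
#'
#' @param events Data frame of events (may have zero rows).
#' @return The validated data frame, invisibly coerced to canonical
#'   column order.
#' @export
validate_events <- function(events) {
  req <- c("t", "kind", "body_type", "primed", "eye_color", "hostile", "wave")
  if (!is.data.frame(events)) stop("events must be a data frame")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols)) stop("events missing columns: ", paste(missing_cols, collapse = ", "))
  if (!"distance" %in% names(events)) events$distance <- NA_real_
  events <- events[, c(req[1:6], "distance", "wave")]
  if (nrow(events) == 0L) return(events)
  if (!all(events$kind %in% .event_kinds))
    stop("unknown event kind: ", paste(setdiff(events$kind, .event_kinds), collapse = ", "))
  if (!all(events$body_type %in% .body_types)) stop("unknown body_type")
  if (!all(events$eye_color %in% .eye_colors)) stop("unknown eye_color")
  if (!all(events$wave >= 1 & events$wave <= 14)) stop("wave must be in 1..14")
  hostile_kind <- events$kind %in% c("shot_hit", "miss_reached")
  if (!all(hostile_kind == events$hostile))
    stop("event kind inconsistent with hostile flag")
  events
}

#' The ABBABABABA withdrawal design
#'
#' The fixed 10-session design: biofeedback absent (phase A) in sessions
#' 1, 4, 6, 8 and 10, present (phase B) in sessions 2, 3, 5, 7 and 9.
#' Addition contrasts are the consecutive A-to-B session pairs, removal
#' contrasts the B-to-A pairs; together they cover every phase boundary
#' between consecutive sessions.
#'
#' @return An object of class `phase_design`: list with
#'   `phase_of_session` (named character vector over sessions 1..10),
#'   `addition` and `removal` (two-column integer matrices of session
#'   pairs, one contrast per row).
#' @examples
#' d <- phase_design()
#' d$phase_of_session[["2"]]  # "B"
#' nrow(d$addition)           # 4
#' @export
phase_design <- function() {
  phase <- c("A", "B", "B", "A", "B", "A", "B", "A", "B", "A")
  names(phase) <- as.character(1:10)
  addition <- cbind(from = c(1L, 4L, 6L, 8L), to = c(2L, 5L, 7L, 9L))
  removal  <- cbind(from = c(3L, 5L, 7L, 9L), to = c(4L, 6L, 8L, 10L))
  structure(list(phase_of_session = phase, addition = addition, removal = removal),
            class = "phase_design")
}

#' Assemble a session record
#'
#' One subject-session of the training: baseline segment (biofeedback
#' stream and R-R series recorded at rest before the game), in-game
#' segment (breathing trace, R-R series, biofeedback stream, event log),
#' the post-session self-rating of breathing control, and explicit
#' missing-data flags. Time origin is the start of the baseline
#' recording; `game_start_s` marks the in-game segment onset on the same
#' clock, and baseline streams must precede it.
#'
#' @param subject_id Subject identifier (character or integer).
#' @param session_index Session number 1..10.
#' @param phase "A" or "B"; must match the withdrawal design.
#' @param game_start_s In-game onset (s) on the session clock.
#' @param baseline List with elements `biofeedback` ([bfb_stream]) and
#'   `rr` ([rr_series]); either may be `NULL` when missing.
#' @param ingame List with elements `breathing` ([breathing_trace]),
#'   `rr`, `biofeedback`, `events`; any stream may be `NULL` when missing.
#' @param self_rating_control_of_self Self-estimated control-of-self
#'   percentage 0..100, or `NA` when not collected.
#' @return An object of class `session_record`. Missing streams are
#'   recorded in `$flags` (logical: `baseline_bfb_missing`,
#'   `baseline_rr_missing`, `breathing_missing`, `rr_missing`,
#'   `bfb_missing`, `events_missing`, `self_rating_missing`).
#' @export
session_record <- function(subject_id, session_index, phase, game_start_s,
                           baseline = list(), ingame = list(),
                           self_rating_control_of_self = NA_real_) {
  session_index <- as.integer(session_index)
  if (is.na(session_index) || session_index < 1L || session_index > 10L)
    stop("session_index must be in 1..10")
  design <- phase_design()
  expected <- unname(design$phase_of_session[as.character(session_index)])
  if (!identical(phase, expected))
    stop("phase ", phase, " inconsistent with session ", session_index,
         " (design says ", expected, ")")
  if (!is.na(self_rating_control_of_self) &&
      (self_rating_control_of_self < 0 || self_rating_control_of_self > 100))
    stop("self rating must be in [0, 100]")
  bl_bfb <- baseline$biofeedback; bl_rr <- baseline$rr
  for (s in list(bl_bfb, ingame$biofeedback))
    if (!is.null(s) && !inherits(s, "bfb_stream")) stop("biofeedback streams must be bfb_stream")
  for (s in list(bl_rr, ingame$rr))
    if (!is.null(s) && !inherits(s, "rr_series")) stop("rr streams must be rr_series")
  if (!is.null(ingame$breathing) && !inherits(ingame$breathing, "breathing_trace"))
    stop("ingame breathing must be breathing_trace")
  events <- ingame$events
  if (!is.null(events)) events <- validate_events(events)
  # baseline must precede the game on the shared clock
  for (tt in list(bl_bfb$t, bl_rr$beat_t))
    if (length(tt) && max(tt) > game_start_s + 1e-9)
      stop("baseline streams must end before game_start_s")
  flags <- list(
    baseline_bfb_missing = is.null(bl_bfb),
    baseline_rr_missing = is.null(bl_rr),
    breathing_missing = is.null(ingame$breathing),
    rr_missing = is.null(ingame$rr),
    bfb_missing = is.null(ingame$biofeedback),
    events_missing = is.null(events),
    self_rating_missing = is.na(self_rating_control_of_self)
  )
  structure(list(
    subject_id = as.character(subject_id),
    session_index = session_index,
    phase = phase,
    game_start_s = as.numeric(game_start_s),
    baseline = list(biofeedback = bl_bfb, rr = bl_rr),
    ingame = list(breathing = ingame$breathing, rr = ingame$rr,
                  biofeedback = ingame$biofeedback, events = events),
    self_rating_control_of_self = as.numeric(self_rating_control_of_self),
    flags = flags
  ), class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat("<session_record> subject", x$subject_id, "session", x$session_index,
      "phase", x$phase, "\n")
  miss <- names(Filter(isTRUE, x$flags))
  if (length(miss)) cat("  missing:", paste(miss, collapse = ", "), "\n")
  invisible(x)
}

.stream_to_json <- function(t, value, names_ = c("t", "value")) {
  out <- list(as.numeric(t), as.numeric(value))
  names(out) <- names_
  out
}

#' Save a session record to a canonical JSON log
#'
#' Serialization is canonical: fixed key order and shortest round-trip
#' float formatting, so saving the same record twice yields
#' byte-identical files and load/save round-trips are the identity.
#'
#' @param record A [session_record].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_session <- function(record, path) {
  if (!inherits(record, "session_record")) stop("record must be a session_record")
  enc <- list(
    meta = list(
      subject_id = record$subject_id,
      session_index = record$session_index,
      phase = record$phase,
      game_start_s = record$game_start_s,
      self_rating_control_of_self =
        if (is.na(record$self_rating_control_of_self)) NULL
        else record$self_rating_control_of_self
    ),
    baseline = list(
      biofeedback = if (!is.null(record$baseline$biofeedback))
        .stream_to_json(record$baseline$biofeedback$t,
                        record$baseline$biofeedback$score, c("t", "score")),
      rr = if (!is.null(record$baseline$rr))
        .stream_to_json(record$baseline$rr$beat_t,
                        record$baseline$rr$rr, c("beat_t", "rr_ms"))
    ),
    ingame = list(
      breathing = if (!is.null(record$ingame$breathing))
        c(.stream_to_json(record$ingame$breathing$t, record$ingame$breathing$y,
                          c("t", "y")),
          list(rate = record$ingame$breathing$rate)),
      rr = if (!is.null(record$ingame$rr))
        .stream_to_json(record$ingame$rr$beat_t, record$ingame$rr$rr,
                        c("beat_t", "rr_ms")),
      biofeedback = if (!is.null(record$ingame$biofeedback))
        .stream_to_json(record$ingame$biofeedback$t,
                        record$ingame$biofeedback$score, c("t", "score")),
      events = if (!is.null(record$ingame$events)) record$ingame$events
               else data.frame()
    )
  )
  txt <- jsonlite::toJSON(enc, pretty = 2, auto_unbox = TRUE, null = "null",
                          na = "null", digits = NA)
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

.parse_stream <- function(x, names_) {
  if (is.null(x)) return(NULL)
  for (nm in names_)
    if (is.null(x[[nm]])) stop("session log stream missing field '", nm, "'")
  lapply(x[names_], as.numeric)
}

#' Load a session record from a JSON log
#'
#' Missing streams (JSON `null`) are recorded in the record's flags,
#' never imputed. Schema violations raise an error naming the offending
#' field; non-monotone timestamps fail stream validation.
#'
#' @param path Path to a session log written by [save_session] (or any
#'   file conforming to the same schema).
#' @return A [session_record].
#' @export
load_session <- function(path) {
  if (!file.exists(path)) stop("no such session log: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  meta <- raw$meta
  for (f in c("subject_id", "session_index", "phase", "game_start_s"))
    if (is.null(meta[[f]])) stop("session log missing meta field '", f, "'")
  bl_bfb <- .parse_stream(raw$baseline$biofeedback, c("t", "score"))
  bl_rr <- .parse_stream(raw$baseline$rr, c("beat_t", "rr_ms"))
  ig_br <- .parse_stream(raw$ingame$breathing, c("t", "y"))
  ig_rr <- .parse_stream(raw$ingame$rr, c("beat_t", "rr_ms"))
  ig_bfb <- .parse_stream(raw$ingame$biofeedback, c("t", "score"))
  events <- raw$ingame$events
  if (is.null(events) || length(events) == 0L) {
    events <- data.frame(t = numeric(), kind = character(),
                         body_type = character(), primed = logical(),
                         eye_color = character(), hostile = logical(),
                         distance = numeric(), wave = integer())
  }
  session_record(
    subject_id = meta$subject_id,
    session_index = meta$session_index,
    phase = meta$phase,
    game_start_s = as.numeric(meta$game_start_s),
    baseline = list(
      biofeedback = if (!is.null(bl_bfb)) bfb_stream(bl_bfb$t, bl_bfb$score),
      rr = if (!is.null(bl_rr)) rr_series(bl_rr$beat_t, bl_rr$rr_ms)
    ),
    ingame = list(
      breathing = if (!is.null(ig_br))
        breathing_trace(ig_br$t, ig_br$y,
                        rate = if (!is.null(raw$ingame$breathing$rate))
                          as.numeric(raw$ingame$breathing$rate)),
      rr = if (!is.null(ig_rr)) rr_series(ig_rr$beat_t, ig_rr$rr_ms),
      biofeedback = if (!is.null(ig_bfb)) bfb_stream(ig_bfb$t, ig_bfb$score),
      events = validate_events(events)
    ),
    self_rating_control_of_self =
      if (is.null(meta$self_rating_control_of_self)) NA_real_
      else as.numeric(meta$self_rating_control_of_self)
  )
}

#' Tidy table view of a session stream
#'
#' @param record A [session_record].
#' @param stream One of "baseline_biofeedback", "baseline_rr",
#'   "breathing", "rr", "biofeedback", "events".
#' @return A tidy data frame (empty when the stream is missing).
#' @export
stream_table <- function(record, stream = c("biofeedback", "rr", "breathing",
                                            "baseline_biofeedback",
                                            "baseline_rr", "events")) {
  stream <- match.arg(stream)
  obj <- switch(stream,
    baseline_biofeedback = record$baseline$biofeedback,
    baseline_rr = record$baseline$rr,
    breathing = record$ingame$breathing,
    rr = record$ingame$rr,
    biofeedback = record$ingame$biofeedback,
    events = record$ingame$events)
  if (is.null(obj)) return(data.frame())
  if (is.data.frame(obj)) return(obj)
  if (inherits(obj, "breathing_trace")) return(data.frame(t = obj$t, y = obj$y))
  if (inherits(obj, "rr_series")) return(data.frame(beat_t = obj$beat_t, rr_ms = obj$rr))
  data.frame(t = obj$t, score = obj$score)
}
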