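#' Tally shoot/don't-shoot outcomes
#'
#' Exhaustive, mutually exclusive tally of a session's game events:
#' hits (shot an incoming hostile), misses (hostile reached the player),
#' false alarms (shot a friendly) and correct rejections (withheld on a
#' friendly), each also stratified by whether the target's body type had
#' been primed as hostile by radio dispatch.
#'
#' @param events Game event data frame (see [validate_events]).
#' @return List of class `outcome_counts`: totals `hits`, `misses`,
#'   `false_alarms`, `correct_rejections`, plus `primed` and `unprimed`
#'   sublists with the same four counts.
#' @export
tally_events <- function(events) {
  events <- validate_events(events)
  count <- function(df) {
    k <- table(factor(df$kind, levels = .event_kinds))
    list(hits = unname(k[["shot_hit"]]),
         misses = unname(k[["miss_reached"]]),
         false_alarms = unname(k[["shot_false_alarm"]]),
         correct_rejections = unname(k[["correct_rejection"]]))
  }
  out <- count(events)
  out$primed <- count(events[events$primed, , drop = FALSE])
  out$unprimed <- count(events[!events$primed, , drop = FALSE])
  structure(out, class = "outcome_counts")
}

#' Signal-detection metrics with loglinear correction
#'
#' Sensitivity and response bias under the equal-variance Gaussian
#' observer model. Because some sessions contain no false alarms at all,
#' the loglinear (Hautus) correction - add 0.5 to each count and 1 to
#' each denominator - is applied to every session, keeping the
#' normal-quantile transform finite:
#' d' = z(hit rate) - z(false-alarm rate),
#' c = -\[z(hit rate) + z(false-alarm rate)\] / 2.
#'
#' @param counts An `outcome_counts` from [tally_events] with at least
#'   one hostile and one friendly target resolved.
#' @return List of class `sdt_metrics`: `hit_rate`, `fa_rate`
#'   (corrected proportions strictly inside (0,1)), `d_prime`,
#'   `criterion`.
#' @export
sdt_metrics <- function(counts) {
  if (!inherits(counts, "outcome_counts")) stop("counts must be outcome_counts")
  hostile <- counts$hits + counts$misses
  friendly <- counts$false_alarms + counts$correct_rejections
  if (hostile < 1L || friendly < 1L)
    stop("need at least one hostile and one friendly target")
  hit_rate <- (counts$hits + 0.5) / (hostile + 1)
  fa_rate <- (counts$false_alarms + 0.5) / (friendly + 1)
  zh <- stats::qnorm(hit_rate); zf <- stats::qnorm(fa_rate)
  structure(list(hit_rate = hit_rate, fa_rate = fa_rate,
                 d_prime = zh - zf, criterion = -(zh + zf) / 2),
            class = "sdt_metrics")
}

#' Priming effect on false alarms
#'
#' Difference in raw (uncorrected) false-alarm rate between friendly
#' targets whose body type matched the dispatch-primed description and
#' those whose did not. Positive values mean priming pushed shoot
#' decisions toward matching targets.
#'
#' @param counts An `outcome_counts` from [tally_events].
#' @return `fa_rate(primed) - fa_rate(unprimed)`, or `NA` (with a
#'   warning) when either stratum contains no friendly targets.
#' @export
priming_fa_difference <- function(counts) {
  if (!inherits(counts, "outcome_counts")) stop("counts must be outcome_counts")
  fp <- counts$primed$false_alarms + counts$primed$correct_rejections
  fu <- counts$unprimed$false_alarms + counts$unprimed$correct_rejections
  if (fp < 1L || fu < 1L) {
    warning("empty priming stratum; priming difference is missing")
    return(NA_real_)
  }
  counts$primed$false_alarms / fp - counts$unprimed$false_alarms / fu
}

#' Control-of-self score
#'
#' The percentage of the session spent with a biofeedback score of at
#' least `threshold` (0.8 by convention): the physiological-control
#' summary presented to the player after each session.
#'
#' @param stream A non-empty [bfb_stream] (post warm-up).
#' @param threshold Score threshold; default 0.8.
#' @return Percentage in \[0, 100\].
#' @export
control_of_self <- function(stream, threshold = 0.8) {
  if (!inherits(stream, "bfb_stream")) stop("stream must be a bfb_stream")
  if (length(stream$score) == 0L) stop("empty biofeedback stream")
  100 * mean(stream$score >= threshold)
}

#' Physiological awareness score
#'
#' Actual control-of-self score minus the player's own post-session
#' estimate, both percentages. Negative values indicate overestimation
#' of one's breathing control.
#'
#' @param actual_percent Achieved control-of-self, 0..100.
#' @param reported_percent Self-rated control-of-self, 0..100.
#' @return Signed difference in \[-100, 100\].
#' @export
awareness_score <- function(actual_percent, reported_percent) {
  if (any(c(actual_percent, reported_percent) < 0) ||
      any(c(actual_percent, reported_percent) > 100))
    stop("percentages must lie in [0, 100]")
  actual_percent - reported_percent
}
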