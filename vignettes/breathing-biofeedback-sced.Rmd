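---
title: "Breathing biofeedback scoring and single-case withdrawal analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breathing biofeedback scoring and single-case withdrawal analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and data model

`breathloop` analyzes biofeedback training delivered inside an arousing
shoot/don't-shoot decision task. The unit of analysis is one
subject-session (`session_record`): a rest baseline followed by a
~15-minute game segment, each carrying a respiration-belt trace, an R-R
interval series, the 0.5 Hz biofeedback score stream, the game event
log, and a post-session self-rating. Ten sessions per subject follow an
ABBABABABA withdrawal design - biofeedback visible in sessions 2, 3, 5,
7, 9 (phase B) and hidden in sessions 1, 4, 6, 8, 10 (phase A) - so
that the intervention is repeatedly added (A→B) and removed (B→A),
four contrasts in each direction per subject.

The time origin of every session is the start of the baseline
recording; the game onset is stored explicitly, since several
computations (baseline subtraction, bin trimming) need both segments on
one clock. Missing streams are carried as explicit flags and propagate
as `NA` through the pipeline; they are never imputed or zero-filled,
and downstream statistics drop flagged sessions listwise.

## The biofeedback score

Every 2 s, the last 30 s of belt signal are analyzed: the segment is
linearly resampled to 10 Hz, mean-removed, Hann-tapered, zero-padded to
4096 points, and turned into a one-sided power spectrum. The score is

$$s = \frac{\int_{0.1}^{1/6} P(f)\,df}{\int_{0^+}^{f_N} P(f)\,df} \in [0,1],$$

the spectral area inside the 6-10 breaths/min band over the total
area. The raw in-band/out-of-band power ratio $r$ is unbounded; $s =
r/(1+r)$ is its monotone bounded equivalent, which matches the score's
documented unit range while preserving the ordering. The score
therefore rewards both pace (energy concentrated in-band) and depth
(in-band amplitude relative to a fixed additive noise floor): it is
invariant to rescaling the whole signal, but grows with breathing depth
whenever measurement noise of fixed amplitude is present.

Numerical choices: zero-padding to a ≤ 0.01 Hz grid is needed because
a raw 30 s window resolves only 0.033 Hz - about half the target band's
width; the Hann taper bounds leakage from out-of-band components; total
power below `1e-10` (after mean removal) maps to score 0, covering flat
or disconnected-belt segments. No scores are produced before one full
window has elapsed (warm-up); the SCED binning discards the first two
15 s bins of each game segment for the complementary reason - those
windows still contain baseline breathing.

Baseline summaries use the shortest-baseline convention: only the last
29 samples of the 0.5 Hz baseline stream (spanning 56 s) enter the
baseline mean, so sessions with generous baselines are not advantaged.

The original real-time implementation's exact estimator settings are
published separately; the choices here are documented as this
package's own and validated against an independent direct-DFT oracle
(agreement below 1e-6) rather than claimed identical. The instructed
pace (5 s in / 5 s out, i.e. 6 breaths/min) and the rewarded 8
breaths/min both lie inside the band; the package takes no position on
that discrepancy.

## HRV spectral metrics

R-R intervals are screened to [300, 2000] ms (series losing more than
20% of beats are flagged unusable and excluded, mirroring how grossly
unreliable R-peak detection is handled), cubic-interpolated to a 4 Hz
tachogram, and analyzed with Welch's method (60 s Hann segments, 50%
overlap; segments shrink to keep at least four averages on short
records). LF (0.04-0.15 Hz) and HF (0.15-0.4 Hz) powers are band
integrals in ms²; mean heart rate is `60000/mean(rr)`; heart-rate
change is the duration-weighted in-game mean minus the baseline mean
(the averaging domain for "HR change" is a design choice here -
beat-domain averaging would weight short intervals up).

Breathing-LF coupling uses magnitude-squared coherence on a common
4 Hz grid, summarized as the *mean* MSC over the LF band (not the
maximum - the band mean is stabler and makes the estimator's bias
explicit: with $L$ Welch segments, independent signals still show
MSC ≈ 1/L). Coherence of a signal with itself is 1 at every frequency;
the estimator is symmetric and scale-invariant.

## Behavioral metrics

Session tallies (hits, misses, false alarms, correct rejections) feed
the equal-variance signal-detection indices with the loglinear (Hautus)
correction applied always - add 0.5 to each count and 1 to each
denominator - because whole sessions without false alarms would
otherwise produce infinite quantiles:

$$d' = z(H) - z(F), \qquad c = -\tfrac{1}{2}\,[z(H) + z(F)].$$

The sum form for $c$ is the standard definition; a difference form
would collapse to $-d'/2$ and could not vary independently of
sensitivity, which contradicts how criterion behaves as a separate
index. The priming effect is the raw (uncorrected) false-alarm-rate
difference between dispatch-primed and unprimed friendly targets;
corrected rates would leak information across strata of unequal size.
Control-of-self is the percentage of scores at or above 0.8; awareness
is actual minus self-reported control (negative = overestimation).

## SCED withdrawal statistics

Scores are averaged in 15 s bins (first two bins dropped) giving ~58
bins per 900 s session. Each consecutive-session phase contrast is a
cross-pair Kendall tau:

$$\tau = \frac{C - D}{n_i\,n_j},$$

over all between-session bin pairs. This variant was chosen over
tie-corrected tau-b deliberately: its range is exactly [-1, 1] with
complete separation = 1, whereas tau-b computed against a balanced
binary phase indicator has a ceiling near 0.71 and cannot express the
large non-overlap effects this design produces (tau-b remains available
via `method = "tau_b"`). The two-sided p-value uses the Mann-Whitney
normal approximation with tie and continuity corrections. No Theil-Sen
baseline detrending is applied: within-session trends in this paradigm
are usually *negative* (fatigue), so detrending would manufacture false
positives. Significance is α = 0.05 two-sided.

Per direction, contrasts aggregate into a meta effect as the
pair-count-weighted mean tau (weights $n_i n_j$, the number of pairs
each contrast summarizes) with a Stouffer weighted-z combined p. The
combination rule is configurable in principle and logged as a design
choice; the weighting makes contrasts with more data count more without
letting any single contrast dominate.

The six visual-analysis features (level, trend, variability, immediacy,
consistency, overlap) are operationalized per transition as: phase-mean
difference; slope difference; bin-SD ratio outside [1/1.5, 1.5]; first-3
vs last-3 bin means; whether the level jump exceeds the SD of session
means within the same phases; and a significant tau in the expected
direction. Thresholds (0.05 score units for level/immediacy, 0.002 per
bin for trend) are conventional operationalizations - the decision rule
declares an intervention effect when at least three features change at
three or more transitions. These cutoffs are deliberately conservative
on the 0-1 score scale; sensitivity to them can be explored via the
exported arguments.

Repeated-measures correlation removes each subject's means from both
variables and correlates the pooled residuals - algebraically the
ANCOVA formulation with subject as factor - with
df = n_obs − n_subjects − 1. With 8 subjects × 10 sessions and three
recording failures this yields df = 68 (77 complete pairs).

## The synthetic cohort generator

The restricted source data cannot be redistributed, so every pipeline
stage is validated against a generator with known ground truth.

* **Breathing** is a phase-continuous chirp: instantaneous frequency
  pace(t)/60 integrated over time (concatenating sinusoids would
  scatter spectral artifacts at every pace change), with smooth
  (10 s correlation) pace jitter and additive fixed-amplitude noise at
  10 Hz.
* **Cardiac activity** uses integrate-and-fire (IPFM) beat emission
  over an instantaneous heart period
  `60000/hr(t) + rsa_gain·b(t) + mayer_amp·sin(2π·0.1t)` plus white
  interval noise, so the tachogram-interpolation stage is genuinely
  exercised rather than fed pre-made uniform data. Baseline heart rate
  is 75 beats/min, stepping up by 10 during the game - the arousal
  rise the task is designed to elicit.
* **Game events** arrive in 14 waves; hostile targets always carry the
  announced eye color while their body type matches the announcement
  with probability declining linearly from 1.0 to 0.5 across waves. The
  agent is an equal-variance Gaussian observer (default d′ = 1.5,
  c = 0) whose criterion shifts by −0.3 for primed targets.
* **Learning dynamics**: per-subject adherence starts near 0.35, grows
  by 0.04 per session, gains +0.25 while biofeedback is displayed, and
  A-sessions retain 60% of accumulated learning (transfer). Adherence
  pulls the pace toward 8 breaths/min away from a spontaneous ~14
  breaths/min wander and deepens breathing. Sessions are 900 s with a
  90 s rest baseline - the baseline breathing must exceed 86 s for the
  0.5 Hz score stream to span the 29-sample / 56 s reference after the
  30 s warm-up, which is why the baseline is longer than the reference
  itself.

One master seed fixes the entire cohort byte-for-byte.

**What the generator does not emulate**: motion artifacts, ectopic-beat
morphology, postural effects on HRV, strategic behavior changes, or
fatigue. Passing recovery tests therefore demonstrates the *pipeline's*
correctness on data obeying the generative assumptions, not robustness
to every failure mode of field recordings.

**A known property of the full-fidelity mode**: because scoring windows
are 30 s with a 2 s hop, neighboring 15 s bins share underlying signal
and are positively correlated. The Mann-Whitney p-value assumes
independent bins, so on full-fidelity *null* streams the contrast test
is anticonservative - a limitation inherited from the design being
modeled, worth remembering when interpreting per-contrast significance
on real recordings. Calibration studies of the test itself therefore
use the generator's documented bin-level mode (`gen_bin_sessions`),
which draws bins i.i.d. around the adherence-mapped session mean; under
that independence the empirical type-I error sits at the nominal 5%.

## Problem sizes used in the shipped studies

The test-suite and `scripts/acceptance.R` run: oracle equivalence on
500 random 30 s segments (DFT), 120 random contrast pairs up to 50×50
(enumeration), 60 SDT configurations (quantile root-finding), and 20
rmcorr datasets (ANCOVA); null calibration on 2,000 i.i.d. 58-bin
session pairs plus 500 bin-mode null subjects (4,000 contrasts);
parameter recovery over 100 simulated sessions (d′), 420 s coherence
scenarios isolating the RSA pathway (Mayer wave disabled there so only
the breathing-driven route remains), and one full-fidelity 9-subject
cohort. These sizes keep every study deterministic and reproducible
from a single seed.
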