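---
title: "Significant-change spotting: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Significant-change spotting: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigspot)
```

## The problem

Continuous wrist-worn accelerometry of everyday periodic tasks -- wiping a
table, sweeping a floor -- has no natural record boundaries. Activity
monitors that count gestures or measure their duration first need to segment
the stream. `sigspot` implements an event-defined segmentation: instead of
classifying fixed windows, it spots *significant series* -- the short
intervals where the wearer applies force to reverse motion direction, i.e.,
the trough-to-peak transition of each stroke on the axis that carries the
motion. Each spotted series marks one gesture repetition.

The pipeline has two stages:

1. a deterministic **hierarchical candidate search** that over-generates
   plausible intervals, and
2. a **machine-learning spotting** step that accepts or rejects each
   candidate.

## Stage 1: hierarchical candidate search

**Preprocessing.** Each axis is band-pass filtered with a third-order
Butterworth filter, 0.1--12 Hz at the nominal 40 Hz sampling rate. The
high-pass corner removes gravity/orientation drift, the low-pass corner
sensor noise above the band occupied by voluntary motion. Filtering is
zero-phase by default (forward--backward application with odd-reflection
padding and steady-state initial conditions), because the method's output is
*sample indices* of motion extrema: a causal filter would shift every
boundary by its group delay. A causal mode (`causal = TRUE`) exists for
streaming parity. The forward--backward passes are implemented in the
package in direct form II transposed so that initial conditions can be set
to the step steady state; without them, a 0.1 Hz corner leaves transients
comparable to the signal on recording-length scales.

**Sliding frames.** The stream is cut into 4 s windows with 50% overlap
(`make_frames()`). Four seconds covers at least one complete motion, since a
single periodic gesture takes at most two seconds; the half-window stride
guarantees that every interval no longer than 2 s lies *entirely* inside at
least one frame, so boundary clipping in one frame is always compensated by
its neighbour.

**Dominant axis.** Per frame, the axis with the largest spread
`Avgmax - Avgmin` wins, where the two terms average the largest and smallest
ten percent of samples (`identify_dominant_axis()`). Tail averages rather
than plain min/max make the choice robust to single spikes. Ties break
deterministically X > Y > Z. All further search happens on the dominant axis
only.

**Mean-crossing events.** The event threshold is the frame mean of the
dominant axis. An event is an adjacent sample pair strictly straddling the
threshold in ascending order (`detect_events()`). Strict inequalities mean
samples exactly at the threshold never fire -- constant frames produce no
events at all. Descending crossings are ignored: a significant series is
defined by its rising limb.

**Boundary extension.** An event localises a crossing, not the whole
transition. `extend_end()` grows the upper event sample to the series end: a
step inspects the window from the current index to `alpha_upper` samples to
its right and jumps to the window argmax; the search stops when the current
index already attains the maximum (a fixed point). `extend_start()` mirrors
this leftward with `alpha_lower` and the minimum. Because the index strictly
advances, termination within the window length is guaranteed; a defensive
iteration cap in the implementation turns any violation into an error, and a
fuzz suite plus an independent brute-force oracle pin the semantics.
Two tie-break details matter in practice:

* the argmax/argmin tie goes to the index *closest to the current point*,
  which makes constant runs immediate fixed points rather than infinite
  plateau walks;
* windows clip at frame boundaries, so candidates never leave their frame.

The boundary sizes `(alpha_upper, alpha_lower)` (in samples) are the
method's key hyperparameters. Small windows stall on local extrema created
by muscle vibration, producing fragments of the true series; large windows
step over the ripple. The default pair (9, 12) is the best overall
combination in the reference evaluation grid.

**Merging.** Overlapping frames re-detect the same series. Two candidates
are duplicates when their global intervals overlap by more than half the
shorter one; among duplicates `merge_candidates()` keeps the *longest*
interval (ties: earliest frame). Keeping the longest rather than the
earliest-frame instance is deliberate: the earliest frame may contain only a
boundary-clipped fragment, while the 50% overlap guarantees some frame holds
the complete series; discarding the complete detection in favour of a
fragment would cap achievable recall below 1 even on noise-free data.

## Stage 2: features and spotting

Each candidate is summarised by nine descriptors of its dominant-axis
samples (`extract_features()`): maximum, minimum, mean, population standard
deviation, RMS, range, movement time (length / sample rate, s), peak number,
and a jerk metric. Peak number counts strict `+` to `-` sign changes of the
first difference with zero-runs compressed (a plateau counts once, at
entry). The jerk metric is defined here as the RMS of the first difference
times the sample rate, normalised by the candidate's range -- an
amplitude-invariant smoothness measure, 0 for constant series. This
definition is an interpretation: the source assessment literature for
"jerk" admits several normalisations, and the normalised RMS-jerk variant
is the one that is well-defined on arbitrarily short candidates.

Spectral features are deliberately absent: candidates are typically shorter
than half a second, too short for reliable spectral estimates.

**Feature selection.** Per dominant axis, `sequential_forward_selection()`
greedily adds the feature that maximises a stratified 5-fold inner-CV F1 of
the chosen classifier, stopping when no feature strictly improves the score.
The inner folds are seeded, so selection is deterministic. The greedy trace
is non-decreasing by construction.

**Classifiers.** Three standard kinds (`train_spotter()`):

* **NB** -- Gaussian class-conditional naive Bayes (e1071 fit), raw
  features;
* **kNN** -- k = 5, Euclidean distance on z-scored features; distance and
  vote ties resolve to the nearest neighbour's label, making prediction
  fully deterministic;
* **SVM** -- RBF kernel (e1071), C = 1, kernel width 1/(d · var) on
  z-scored features.

Standardisation parameters are fitted on training rows only; distance and
kernel methods get z-scored inputs, NB does not need them. One model is
fitted per dominant axis, because the reference feature-selection results
differ per axis; an axis whose training partition lacks at least 5 rows of
each class (5 = the kNN vote size -- fewer members than the vote can never
win it, and so few rows support no meaningful class model) falls back to a
pooled model fitted on all rows. A fully single-class training set yields a
constant majority classifier with a warning recorded in the model metadata
-- the only fit a one-class sample supports.

Labels for training come from `label_candidates()`: a candidate is positive
when its Jaccard overlap with some ground-truth interval is at least 0.5.
Jaccard (rather than one-sided coverage) is symmetric: a candidate ten times
longer than the truth interval it covers is not a good detection.

## Evaluation protocol

`match_events()` matches spotted against truth intervals one-to-one,
greedily by descending Jaccard, discarding pairs under 0.5. Greedy matching
is deterministic and, on instances up to five intervals, provably equal to
exhaustive optimal matching in our oracle tests. Counts conserve exactly:
`tp + fp` = spotted, `tp + fn` = truth. Precision, recall and F1 follow the
usual closed forms with 0/0 defined as 0 (`compute_metrics()`).

`loocv()` leaves one *session* (recording day) out at a time -- never a
random row split, since candidates within a session are strongly dependent.
Feature selection and training happen inside each fold on the training
sessions only; counts are pooled over folds before computing summary
metrics. Training rows are canonically sorted so results are invariant to
session order.

`boundary_sweep()` evaluates the LOOCV on a grid of
`(alpha_upper, alpha_lower)` pairs, default 1..15 x 1..15, and aggregates
5 x 5 blocks into nine areas A1..A9 in row-major order (upper-boundary
blocks as rows). A1 is therefore the narrowest-boundary corner and A9 the
widest. The 15 x 15 layout is forced by the nine-areas-of-25-cells
aggregation itself.

## The synthetic generator

No public corpus of annotated wrist-worn cleaning recordings exists, so the
package ships a generator (`generator_config()`, `generate_dataset()`) that
emulates the statistical structure the algorithm consumes -- not limb
biomechanics.

Each session is a sequence of motion bouts separated by idle gaps. A bout
repeats strokes on one scheduled dominant axis. A stroke is piecewise
raised-cosine: a dip 0 to -A (20% of the period), a fast rise -A to +A
(30%), and a slow fall +A back to 0 (50%); junction slopes are zero, so the
noise-free signal is piecewise smooth with a closed-form curvature bound
that the tests assert. The asymmetric, non-sinusoidal shape exercises the
search on the kind of direction-asymmetric strokes real wiping produces.
The ground-truth significant series is the rising limb, trough to peak --
exactly the interval the candidate search should return.

Defaults describe one plausible subject at 40 Hz: 1.2 s mean period (single
motions stay under 2 s), ±15% period and ±20% amplitude jitter per
repetition, 1 g amplitude, two bouts of five repetitions per 40 s session,
4 s idle gaps (one full analysis window, so bouts on different axes never
share a frame), five sessions with ±5% day-to-day drift of period and
amplitude means. Noise has three components with distinct roles:

* **muscle vibration** (default sd 0.12 g): band-limited to 8--12 Hz, the
  physiological tremor band, and present only while the arm moves. This is
  the component that superimposes local extrema on the strokes themselves,
  which is precisely what makes small extension boundaries stop short of
  the true stroke extrema -- the phenomenon the boundary-parameter sweep
  studies. Stationary wide-band noise at realistic amplitudes does not
  produce this signal character, which is why the generator models the
  vibration as motion-locked.
* **sensor floor** (sd 0.02 g): white, always on; creates occasional
  spurious idle-time candidates, i.e., a realistic negative class.
* **incidental sway** (sd 0.04 g): slow AR(1) wrist drift on all axes.

Spikes (default 0.2 per second, 0.5 g scale, random axis and sign) model
knocks and contact transients. Everything is clipped at the ±6 g sensor
range. Generation is deterministic given `(seed, session index)`; sessions
draw independent sub-seeds.

What the generator does **not** emulate: gravity orientation changes,
multi-axis coupling of real 3-D strokes, subject-to-subject variation, and
truly ambiguous gestures. Passing the synthetic benchmarks therefore
demonstrates correctness of the algorithmic chain and qualitative behaviour
of its parameters, not field performance on real recordings.

## Numerical and degenerate-input choices

* Sample indices are 0-based and intervals half-open in every file format
  and in global (recording) coordinates; `start`/`end` of a candidate are
  the inclusive indices of its boundary samples, so `global_end = end + 1`.
* Candidates with `start == end` (one-sample "series") are discarded before
  feature extraction; `extract_features()` refuses series shorter than 2.
* Duplicate overlap uses a strict `>` at exactly half the shorter interval,
  so a pair overlapping by exactly 50% is kept as two candidates.
* Metric 0/0 cases are defined as 0, and the all-empty count triple is
  additionally flagged (`empty`).
* Event detection at the threshold is strict on both sides.
* NB class-conditional standard deviations are floored at
  `1e-3 * feature sd` so a feature constant within one class cannot
  produce degenerate densities.

## Problem sizes used in the shipped benchmarks

The packaged tests and the acceptance script run the generator's default
scale: 5 sessions x 10 repetitions (50 true events per condition), the
clean and noisy conditions at boundary pair (9, 12), and two 5 x 5 corner
blocks (A1, A9) of the boundary grid with all three classifiers. The full
15 x 15 sweep is the same call with the default grids
(`boundary_sweep(sessions)`), left to the user because it is 4.5 times the
work of the two-corner comparison.

## Known limitations

* One classifier per axis presumes the axis schedule seen in training
  covers deployment; unseen axes silently use the pooled model.
* Greedy event matching can differ from optimal assignment on adversarial
  overlap patterns larger than our oracle-verified sizes.
* The candidate search never proposes intervals longer than one frame; a
  motion slower than the window would need a larger `window_seconds`.
* The boundary parameters are in samples; at sampling rates other than
  40 Hz the grid should be rescaled accordingly.
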