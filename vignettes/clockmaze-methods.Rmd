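---
title: "clockmaze: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clockmaze: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clockmaze)
```

## The task and the analysis problem

The paddling-pool task places a mouse at the center of an 85 cm circular
pool in 2 cm of cool water. Twelve 4 cm holes pierce the perimeter wall at
equal spacing, like the hours of a clock face; eleven are plugged
("decoys"), one opens into a dry escape pipe. The animal paddles — shallow
water prevents swimming — and must use distal cues to find the true exit
within 60 s. Video tracking yields a 3-point time series (nose, body
center, tail base) at 30 Hz; everything in this package consumes those
coordinates, never the video.

The scientific quantities of interest are per-trial: how fast the animal
escaped, how many decoys it inspected, and what search strategy that
implies; and per-cohort: how strategy use and latency evolve with training.

## Geometry and conventions

The coordinate frame has its origin at the arena center, +x toward
3 o'clock, +y toward 12 o'clock, units cm, angles in degrees
counterclockwise-positive. Hole *k* sits at angle 90° − 30°·*k*, exactly on
the wall circle (the hardware drawing gives no inward offset, so none is
applied). All zones are **closed** sets — a point on the boundary belongs to
the zone — which makes tie-breaking deterministic.

Zones built by `build_arena()`:

* one circular *hole zone* per hole (radius 2 cm, the published error-zone
  geometry);
* the *periphery* annulus (default width 8 cm), the thigmotaxis measure;
* four quadrant sectors. Default boundaries sit at 45° + k·90° so that each
  quadrant holds exactly three holes and a target hole is central in its
  quadrant; the published description never defines the "target quadrant",
  so this is a package convention, switchable to axis-aligned via
  `quadrant_offset_deg = 0`. The classifier itself never uses quadrants.
* probe-test zones: 6 cm circles at every hole (target zone at the former
  exit, non-target at the 11 decoys). The published probe analysis does not
  state the TZ geometry; 6 cm is this package's default, configurable, and
  deliberately larger than the 2 cm error zone because the probe measures
  search bias, not physical inspection.

A watermaze variant (160 cm pool, no holes, 16 cm hidden-platform zone,
default at the center of the southeast quadrant) supports cross-task
comparisons; quadrants there default to axis-aligned only if requested.

## Error events

An "error" is a frontal or side inspection of a decoy. The published
operational definition ("half a body length including the nose inside a
2 cm zone") is not literally attainable for an 8 cm mouse against a flat
wall, so the detector implements the intent: an event opens when the
**nose** stays inside a hole zone continuously for ≥ 0.1 s (debounce, 3
frames at 30 Hz), and the zone re-arms only after the nose leaves the zone
dilated by 1.5×. The debounce discards single-frame grazes; the dilated
re-arm prevents boundary jitter from splitting one inspection into many.
Both constants are exposed (`debounce_s`, `rearm_factor`). Repeat visits to
the same decoy count separately, matching "number of visits to decoys".
Tracks without nose coordinates are accepted for center-based metrics but
error detection refuses to run rather than silently substituting the center.

## Escape, censoring, termination

A track that ends before the cutoff must end with the nose inside the
true-exit zone — the animal left through the pipe — and its latency is the
final timestamp. Tracks reaching the cutoff are censored at exactly 60 s,
so `escaped == FALSE` if and only if `latency == cutoff`; any post-cutoff
samples (experimenter-guided escapes) are truncated before analysis. A
sub-cutoff track ending elsewhere is rejected as malformed rather than
guessed about. Probe trials (all exits blocked) are censored by definition
and carry no error count: their outputs are zone dwell and occupancy.

## Metric definitions and numerical choices

* **Path length** uses a dead-band rule: distance accrues only when the
  center moves ≥ `jitter_cm` (default 0.05) from the last counted position.
  This makes a stationary animal with sub-threshold tracking jitter cover
  exactly 0 cm. For noisy tracks the dead-band should be matched to the
  noise: at a per-axis jitter SD of 0.1 cm, a 1 cm dead-band keeps the
  length bias under ~2%, whereas raw step summing at 30 Hz inflates it by
  ~17%.
* **Mean speed** is `distance / latency`, not the mean of instantaneous
  speeds, so the latency–distance–speed correlation structure is internally
  consistent.
* **Rotations** unwrap the body-axis (nose − tail) heading and count each
  completed 360° excursion in either direction, resetting the reference
  after each count; CW and CCW excursions both count, so a full turn one
  way followed by a full turn back counts 2.
* **Meander** counts direction changes: per-step turning angles on the
  smoothed center path (5-sample moving average), steps slower than
  2 cm/s ignored, and a change is a sign reversal between consecutive
  *significant* turns (> 20°). Significance filtering matters because
  smoothing spreads one sharp corner over several small steps. The
  proprietary tracking software's exact smoothing is unknown; these
  defaults are declared, not inferred, and all exposed.
* **Heading to exit** averages, over moving steps, the absolute angle
  between the movement vector and the bearing to the exit; 0° is a
  dead-straight run, 180° directly away.
* **Zone dwell / occupancy** deposit each sample's forward inter-sample
  interval at the sample's position (nose for hole-like zones, center
  otherwise), so grid totals equal trial duration to within one sample
  interval.

## The strategy classifier

Censoring is evaluated first: a trial at the cutoff is **futile** whatever
its error count (a guided trial with one error is still a failure to
escape). Otherwise ≤ 3 errors is **spatial**, > 3 is **chain**. Trials with
an absent error count are flagged unclassifiable rather than defaulted.
Both thresholds are arguments (`cutoff_s`, `error_threshold`).

The CART validation layer is built from scratch: greedy binary splits
minimizing Gini impurity, candidate thresholds at midpoints of sorted
unique values, ties broken by lowest feature name then lowest threshold,
majority leaves, no pruning (`max_depth`, `min_leaf` are the only
regularizers). Misclassification is resubstitution by default — the
published "null misclassification" for the full model is only guaranteed
under resubstitution — with optional seeded k-fold reported alongside. When
latency is excluded, the inability to predict futile trials is reported as
a boolean (`predicts_futile`), never asserted on synthetic data, where
correlates such as distance ≈ speed × 60 can rescue the prediction.

## The simulator: a stated world

The generator exists so that every other module can be tested against known
ground truth. Its defaults are the task's stated conditions where the
protocol states them (60 s cutoff, 30 Hz, 12 trials over 3 days or 36 over
8, exit sequences 4-10-2 and 7-11-4-9-3-5-1-6, ~2 °C temperature drop per
full paddling trial, ~5 °C in the watermaze) and declared assumptions
elsewhere (speed ~ N(10, 2) cm/s truncated at 3 — paddling mice cover a few
body lengths per second; body length ~ N(8, 0.5) cm; tracking jitter SD
0.1 cm, a realistic sub-pixel scale for an overhead camera over an 85 cm
arena).

Trajectories are assembled from parameterized segments — straight legs with
lateral Ornstein–Uhlenbeck-style wiggle (innovation SD tied to
`heading_noise_kappa`), wall-following arcs at 4–4.5 cm inside the wall,
and hole dwells with the nose poked to the wall — sampled at 1/30 s. This
is a deliberate substitute for per-frame stepping: the same stated world,
but vectorized, so a 3,480-trial study simulates in seconds of CPU.

* **spatial** steers to the exit, first inspecting up to 3 neighbor decoys,
  each with probability 0.15 — so spatial trials almost always have ≤ 3
  errors without the classifier being wired into the generator;
* **chain** hits the wall at a uniformly random inter-hole bearing and
  wall-follows in one direction, dwelling 0.5–1.5 s at every decoy until
  the exit; the number of decoys passed is uniform on 0..11, so most (but
  not all) chain trials exceed 3 errors — boundary confusion with spatial
  is intentional and mirrors real data;
* **futile** wall-follows with random reversals, inspects decoys, and by
  construction never satisfies the exit-entry rule; the track is truncated
  at exactly 60 s.

The per-trial policy is drawn from the logistic learning curve
`P(spatial | t) = plogis(-1.5 + 0.35 t)`; the remaining mass splits between
chain and futile with the futile share decaying as `0.5 × 0.7^(t-1)`. The
0.5 base is a package choice (the decay constant alone does not fix the
trial-1 level); it makes futile common early and negligible by trial 12,
the qualitative published pattern. On *novel* trials — the first trial of a
day with a relocated exit — a drawn spatial policy is executed as chain,
because an agent cannot steer to a location it has never experienced; this
is what makes exit switches cost time, as observed.

Reproducibility: every trial runs in an RNG substream hashed from
`(seed, subject_id, trial_index)`, so cohorts are identical across runs and
insertion orders.

**What a green test establishes — and what it does not.** The simulator
reproduces the statistical skeleton the analysis relies on (censoring,
error-count clusters, learning trends, temperature–latency coupling,
thigmotaxis), not mouse biomechanics: no acceleration profiles, grooming,
freezing, or inter-trial carry-over beyond the learning curve, and its
speed scale is a declared assumption, not a calibrated fit. Tests against
it validate the *pipeline's* correctness and the classifier's structural
properties; they do not re-derive any published cohort statistic (those
depend on animal data this package does not ship). The published CART
misclassification percentages are plausibility context only.

## Other open choices made here

* **Learning score**: "inversed latencies" is implemented as the mean of
  per-trial reciprocals (failed trials at 1/60 s⁻¹), which preserves
  unit-free ordering; a linear alternative `(cutoff − latency)/cutoff` sits
  behind `method = "linear"` to document the ambiguity.
* **Percentiles** in ensemble bands interpolate linearly between the
  closest order statistics (the published figures do not state a method).
* **Pseudo-random exit schedules** draw uniformly without replacement per
  block of ≤ 12 days, seeded; the published protocol says only
  "pseudo-random scheme", and one sequence applies per cohort.
* **Spearman correlation** is the Pearson correlation of mid-ranks,
  implemented directly so tie handling is explicit and testable.

## Known limitations

Degraded (center-only) tracks lose errors, rotations and strategy labels by
design. The dead-band path length can undercount by up to one threshold on
pathological two-sample tracks. Chain trials that draw a very slow speed
can run past the cutoff and are then honestly censored (labeled futile),
a deliberate boundary effect. The watermaze simulator implements only
goal-directed and thigmotactic modes; it is a comparison scaffold, not a
swim-behavior model.
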