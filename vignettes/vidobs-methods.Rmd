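---
title: "Methods: from direct-observation annotations to evaluated frame classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from direct-observation annotations to evaluated frame classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vidobs)
```

`vidobs` operationalizes a measurement chain used in physical-behavior
research: a human observer annotates a video of one participant with
interval codes; those intervals become per-second labels; the labels become
a per-frame machine-learning dataset split into leakage-free folds; a
classifier is trained and evaluated with class-imbalance-aware statistics.
This vignette explains each model and the choices behind it.

## Rasterization: the majority rule on a second grid

Annotation tools export *events*: `(video, channel, code, start, end)`
intervals in decimal seconds. We place these on a 0-based half-open grid of
seconds `[i, i+1)` — half-open so that touching events never double-count a
boundary instant. For each second and channel, the code covering the
strictly largest fraction of the second is the primary label. A second
intersected by more than one code (on the posture or the intensity channel)
is flagged `is_transition`: these are the seconds where a per-second label
is necessarily an approximation.

Two edge policies are deliberate:

* **Exact 50/50 ties.** A ">50 % wins" rule is silent about exact ties,
  which occur whenever annotators cut at half-second marks. We award the
  tie to the earlier-starting event — deterministic, order-stable, and
  independent of code names. The second remains a transition.
* **Uncovered seconds.** Real logs have trims at session edges. Uncovered
  seconds get the sentinel `"unlabeled"`, are excluded from class
  distributions and training, and `strict = TRUE` turns them into errors
  for pipelines that require full coverage. A second with partial coverage
  takes its largest-covering code even when that coverage is below half —
  the alternative (an unlabeled sentinel amid annotated behavior) discards
  information an analyst clearly intended to provide.

Transition seconds are counted under their primary label everywhere
downstream; excluding them would shrink exactly the classes (short bouts)
that are already rarest.

## Taxonomies

Three consolidations of the raw coding vocabulary are built in, each a
*total* map (every raw code maps to exactly one class, unknown codes are
errors, not guesses):

* **T1** sedentary (sitting/reclining, lying down) vs active — posture
  channel.
* **T2** activity type: sedentary as T1; walking (`walk`, `walk with
  load`); running; mixed movement for every other posture or whole-body
  movement — posture channel.
* **T3** intensity: the annotated MET-based codes map 1:1 (sedentary;
  light < 3 METs; moderate 3–5.99; vigorous ≥ 6) — intensity channel. The
  MET cutoffs govern the human annotation, not a computation here, which is
  why T3 reads its own channel rather than deriving from posture.

Maps are serializable as YAML so site-specific schemes can be swapped in.

## Fold assignment as constrained optimization

Frames one second apart in the same video are visually near-identical, so a
frame-level random split lets a model memorize its evaluation data. Folds
are therefore sets of whole videos. Videos vary in length and class mix, so
the assignment is an optimization problem: minimize

$$\mathrm{score} = \sum_f w_f \, D(\mathrm{fold}_f, \mathrm{pooled}), \qquad
D(p,q) = \tfrac12 \sum_i \frac{(p_i - q_i)^2}{p_i + q_i},$$

over proportions, subject to (a) frame shares within ±5 points of 80/10/10
and (b) each class present in every fold *possible* — a class filmed in
fewer videos than there are folds is exempt, since no assignment can cover
all folds with it.

Choices here, where the problem statement was open:

* **χ² form.** The symmetric histogram χ² distance (the ½Σ(p−q)²/(p+q)
  form) matches the "sampled group vs population" goodness-of-fit usage and
  is zero iff proportions agree; the asymmetric Pearson form is available
  via `method = "pearson"`.
* **Fold weights** default to the target fractions (0.8/0.1/0.1): an
  imbalance in the large training fold harms downstream learning more than
  the same imbalance in a small fold. Uniform weights are one argument away.
* **Search.** `exhaustive` enumerates all `3^N` assignments in
  lexicographic order (ties therefore resolve to the lexicographically
  smallest mapping — reproducible by construction) and is capped at `3^10`
  candidates; beyond that, seeded random search draws assignments with
  per-video fold probabilities equal to the target fractions. Random search
  can never beat the exhaustive optimum, a dominance the tests assert.
* Folds are scored on **frame counts** (one frame per labeled second),
  because frames are what the classifier consumes.

## Frame preparation

One representative frame per labeled second, at the second's **midpoint** —
the instant maximally distant from the boundaries where transitions live.
Letterboxing scales the longest edge to the target (224 or 384), rounds the
short edge to the nearest integer (≥1), centers the content and pads with
black; nearest-neighbour resampling keeps the geometry contract exact
(`scale = target / max(H, W)`, verified analytically in tests). Training
augmentations — horizontal flip, a ±10 % multiplicative jitter on the HSL
lightness channel (HSL so that hue and saturation are untouched), and an
80–100 %-area aspect-preserving crop resized back — each fire with
configurable probability from R's seeded RNG; with all probabilities zero
the frame passes through bit-identical.

## Classification

The reference backend is gradient-boosted trees over pose-keypoint features:
17 body landmarks as `(x, y, confidence)` triples normalized to the unit
square, 51 features per frame. Frames with no detected person keep an
all-zero vector and a flag — the model may legitimately learn "no person".
Training uses only training-fold frames; after every boosting round the
testing-fold selection metric (averaged one-vs-rest AUC by default,
accuracy optionally) is recorded, training stops after 10 rounds without
improvement, and the model reverts to the best round. Backend
hyperparameters are the library defaults plus a fixed seed and a single
thread, all exposed in `classifier_config()`.

An explicit **leakage audit** (`audit_leakage()`) re-derives the set of
videos that contributed training rows and intersects it with the evaluation
fold; the pipeline records it on every run. Deep image backends are adapter
stubs behind the same interface: their value is pre-trained weights plus
GPU fine-tuning, neither of which belongs in a desk-scale package.

## Evaluation

Per-class precision, recall and F1 come from the confusion matrix (rows =
truth); a never-predicted class has precision 0 and is flagged rather than
dropped. Weighted aggregates are support-weighted, under which weighted
recall equals accuracy identically — one published summary table we checked
reports a weighted recall that differs from its own accuracy, which is
impossible under this definition, so the package implements the standard
definition and notes the discrepancy here rather than emulating it.

ROC curves are threshold sweeps over the unique scores (positive iff
`score ≥ t`), carrying TP/FP/TN/FN at every threshold; AUC is trapezoidal
and provably equal to the all-pairs Mann–Whitney statistic (asserted on
random instances against a brute-force pair count). Multiclass AUC is
one-vs-rest: per-class AUCs averaged with nonnegative class weights.
Because each class's sub-problem is independent, a class may be
**substituted** — its AUC computed from another fold's scores when it has no
evaluation-fold instances (the rare-class case) — and **suppressed** — its
weight scaled down when a substitute fold over-represents it. Both are
flagged in the report with their source fold. The optimal decision point
minimizes FP+FN; ties break toward the higher threshold (the stricter
decision rule at equal cost).

Reports print at the conventional precision (ratios to 2 decimals, percent
to 1) while JSON output keeps full precision.

## The synthetic generator

`generate_session()` emulates what the pipeline assumes about real data,
not what real video looks like:

* behavior is a **semi-Markov chain** over posture codes — exponential
  (memoryless) dwell times, rounded to whole seconds with a 1 s floor, and
  a transition matrix with no self-loops built from stationary tendencies;
  defaults make sessions sitting-dominated with bouts of standing, walking
  and rare vigorous movement, and per-video gamma-weighted mixtures make
  class distributions video-specific and imbalanced;
* the **intensity channel derives from posture** through a lookup with a
  small random level shift (5 % of bouts), so activity-type and intensity
  labels correlate as they do in real behavior;
* **pose features are class-conditional Gaussians** whose means come from
  per-class figure geometry (seated figures compact, locomotion elongated);
  with the default spread (`pose_sd = 0.02`) the class means sit well over
  4σ apart (`pose_separation()` reports the exact figure), so a working
  pipeline should classify held-out frames almost perfectly — making
  end-to-end accuracy a sharp smoke test;
* `render_frame()` draws seeded stick figures with class-dependent limb
  geometry to exercise frame preparation and the pose-extractor interface.

What this deliberately does **not** model: camera motion, occlusion,
lighting, multiple people, annotator disagreement, and pose-estimator
failure modes beyond missing detections. Green tests therefore certify the
pipeline's statistical machinery, not real-video accuracy.

The frozen benchmark (`make_benchmark_fixture()`) has six videos of
700/650/600/450/300/300 s (3,000 labeled seconds, small enough that the
whole suite runs in about a minute on one CPU, yet admitting an exact
80/10/10 frame split), one rare class present in exactly two videos to
exercise the fold-constraint exemption, and fully covering integer-aligned
events so rasterization can be cross-checked against stored ground truth.
Statistical tests on the simulator use longer single-video runs (up to
3×10⁴ s) so that stationary-share and dwell-mean checks have standard
errors comfortably inside their tolerances.

The chance-level check trains on shuffled labels and measures held-out
one-vs-rest AUC **against those shuffled labels** on the pooled testing and
evaluation folds. Against the true labels the statistic would not
concentrate at 0.5 here: features are nearly constant within a class, so
the effective sample size is the number of clusters, not the number of
frames. Against the shuffled labels the within-cluster positives and
negatives are exchangeable and the AUC concentrates at chance, which is the
property the check is meant to certify (no signal can be learned from
shuffled labels).

## Known limitations

* The fold optimizer is exact only up to `3^10` candidates; larger video
  sets rely on random search, which carries no optimality guarantee beyond
  seeded reproducibility and dominance-by-construction.
* Single-person assumption throughout; the pose interface carries one
  keypoint set per frame.
* Subject-level grouping (several videos of one person) is not modeled;
  folds split by video, so a participant could appear on both sides of a
  split if they contributed multiple videos.
* The built-in `bbox` pose backend is a geometric stand-in for a real
  skeletal extractor and is only meaningful on the synthetic renderer's
  output.
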