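---
title: "Group visual attention models from eye tracking: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group visual attention models from eye tracking: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`gazevam` implements a two-phase, region-of-interest-free analysis of gaze
over two-panel video stimuli that contrast biological and geometric motion.

**Phase 1 — learning one visual attention model (VAM) per group.**  A VAM
is a per-pixel binary classifier: given the feature vector of a pixel, it
predicts whether a viewer from its group will fixate that pixel.  The
training data come from the video itself and from the pooled gaze of the
group's subjects:

* frames are border-cropped, area-resized to 200 × 350 (70000 pixels) and
  stripped of 10 transition frames on each side of every segment cut;
* consecutive frames are aggregated greedily while the mean motion between
  the running mean frame and the next frame stays below 0.33 (mean over
  pixels of the per-pixel motion value, in [0, 1]);
* per frame set and group, gaze positions are accumulated into a fixation
  map and smoothed with a normalised 5 × 5 Gaussian;
* the 350 highest cells give class-1 training pixels, 350 uniformly drawn
  zero-valued cells give class-0, i.e. 700 balanced coordinates per map;
* each coordinate becomes a 28-feature vector (channels below), averaged
  over the set's member frames;
* a genetic-algorithm wrapper selects 15 channels per group;
* a neural network with one hidden layer of 10 sigmoid units and a linear
  output unit is trained with per-sample stochastic gradient descent on
  binary cross-entropy (learning rate 0.01, at most 1000 cycles, early stop
  when the mean epoch loss falls below 1e-7).

**Phase 2 — diagnosis.**  F^d = 50 frames, drawn uniformly across segments
and held out from learning, act as an independent diagnosis video.  Both
VAMs score every pixel of each diagnosis frame; probabilities ≥ 0.5 give a
binary saliency map per group.  The individual's binary fixation map for a
frame (1 where at least one valid gaze sample landed) is compared with both
saliency maps by the **match count** — the number of positions with equal
values.  The group with the larger count wins the frame's vote; ties go to
the control group.  A subject is classified as case when their case-vote
count reaches a threshold chosen by the Youden index (J = sensitivity +
specificity − 1, ties to the smallest threshold) on the ROC traced over all
integer thresholds.  Evaluation is subject-wise k-fold cross-validation:
VAMs are trained on 80% of subjects and the learning frames only, and the
held-out subjects are classified on the diagnosis frames.

## Feature channels

The frozen 28-channel registry (`vam_channels()`):

| family | channels | notes |
|---|---|---|
| steerable pyramid | 12 band-pass + low-pass residual | frequency-domain construction: log-raised-cosine radial windows at 4 scales × cos² angular windows at 3 orientations; absolute responses at frame resolution, min-max scaled per frame |
| conspicuity | colour, intensity, orientation, skin | centre-surround differences across a Gaussian pyramid (intensity; red-green and blue-yellow opponency), Gabor-energy pooling over 4 orientations, and a YCbCr skin-locus likelihood |
| colour | red, green, blue | raw channels |
| semantic | horizon, face, people | oracle masks when available (synthetic stimuli); otherwise pluggable detectors — the defaults are a horizontal-edge row scorer and smoothed skin-likelihood maps, deliberately simple deterministic baselines |
| geometry | distance to frame centre, distance to scene-half centre, biological flag, geometric flag | distances normalised by the largest attainable distance (centre pixel scores 0, corners 1); flags are complementary binary masks of the two halves |
| motion | 1 | same estimator as frame aggregation; the first frame is all-zero by convention |

The motion estimator defaults to the normalised absolute temporal intensity
difference on the luma channel (which is what the aggregation rule
describes); a dense normal-flow magnitude estimator (|It| / |∇I|, clipped
at a configurable maximum displacement) is available behind the same
interface since the original procedure cites optical flow.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| working resolution | 200 × 350 | px | the published preprocessing grid; all maps share it |
| black-border threshold | 0.02 | intensity | robust to compression noise near zero |
| transition trim | 10 + 10 | frames | stated trimming at every interior segment cut |
| aggregation threshold | 0.33 | mean motion | calibrated on the original stimulus; must be reviewed for other videos, hence exposed |
| smoothing kernel | 5 × 5, σ = 1 px | px | kernel size is prescribed, σ is not; σ = 1 is the customary choice for a 5-tap Gaussian and the kernel is renormalised to unit mass |
| coordinates per map | 350 + 350 | px | balanced classes by construction |
| GA | pop 40, 50 generations, one-point crossover 0.8, bit-flip 1/28, tournament 3, elitism 1 | — | conventional wrapper-GA settings; the search is deterministic given the seed and memoises repeated chromosomes |
| GA subset size | 15 | features | the reported subset size; enforced after the search by ranked gene frequency in the final population (set `subset_size_target = NULL` to leave cardinality free) |
| network | 10 hidden, lr 0.01, ≤ 1000 epochs, tol 1e-7 | — | the published training regime |
| vote threshold | Youden per fold | votes | chosen on the test fold's ROC as published (optimistic); `threshold_mode = "train"` gives the honest nested variant |
| learner | the SGD network | — | `vam_crossval(learner = ...)` accepts any `(x, y, subset, group, control, seed)` fitter whose `predict` returns fixation probabilities, so the classifier × selector comparison grid can be re-run with e.g. an SVM wrapper |

Numerical choices worth noting:

* **Linear output with binary cross-entropy** is read as logits-with-BCE: a
  logistic link is applied inside the loss and at prediction.  This is the
  only numerically coherent reading — BCE requires outputs in (0, 1).
* "Error less than 1e-7" is interpreted as the **mean epoch loss**
  (config-exposed); per-sample BCE rarely reaches that scale.
* Per-feature min-max normalisation is fitted on the training vectors and
  reapplied at prediction; structure channels are min-max scaled per frame,
  flags/distances/RGB have fixed analytic ranges.
* Coordinate selection breaks value ties deterministically by
  (value desc, row asc, col asc); the class-0 draw is seed-controlled.
  Zero-valued cells are *exact* zeros: FFT round-off from the Gaussian
  smoothing is squashed below 1e-9 so the class-0 pool keeps its intended
  meaning.
* Saliency thresholding maps probability exactly 0.5 to 1 (decided rule);
  tie votes go to the control group (conservative with respect to
  diagnosis).
* The degenerate inputs all fail fast: all-black frames (crop), segments
  shorter than 21 frames (trimming), single-class training labels, maps
  with fewer than 350 positive or zero cells (the error names the deficit).

## The synthetic data generator

The clinical recordings behind the original study are not public, so the
generator is a first-class, tested module that emulates the *study
conditions*, not the footage:

* **Stimulus**: two-panel frames with a black border; the biological half
  holds a cluster of textured moving ellipses, each carrying a
  high-contrast skin-toned face disc (with exact face/person oracle
  masks); the geometric half holds a rotating fractal-like interference
  pattern.  The biological side alternates between segments.  Consecutive
  segments use strongly contrasting palettes so that segment cuts produce
  mean motion above the 0.33 aggregation threshold, as real scene cuts do,
  while within-segment motion stays well below it.  Frames are 8-bit
  quantised so PNG fixtures round-trip losslessly.
* **Gaze**: a subject draws fixation targets at ~3 Hz from a mixture —
  geometric half with probability `p_geometric`, and within the biological
  half the face centroid with probability `face_attraction`, otherwise the
  half centre (`center_bias_sigma`); a small uniform component
  (`noise_weight`) stays within the chosen half.  Between draws the gaze
  dwells on the target with per-tick tracker jitter; scene cuts force a
  fresh fixation.  Dropout removes ticks entirely.  The dwell structure
  matters: independent per-tick draws disperse gaze so widely that pooled
  group maps leave almost no zero-fixation cells, violating the method's
  own precondition for class-0 sampling.
* Default tracker rate is 120 Hz, a decimated stand-in for the 300 Hz
  device class; the native rate after vendor filtering is not knowable, so
  the rate is a free parameter.

What the generator does *not* emulate: photorealistic content, saccade
dynamics, calibration drift, vendor fixation filtering, and
group-conditional dropout.  Passing end-to-end tests on synthetic cohorts
therefore demonstrates that the pipeline's machinery is correct and that
the stated group contrast is recoverable *to the extent the method allows*
— not that clinical performance figures transfer.

## Problem sizes used in the test-suite studies

The end-to-end cross-validation study in the test suite uses 9 segments of
30 frames at 5 fps (270 native frames at 270 × 480, 110 working frames
after transition trimming), 20 subjects per group at 120 Hz, 50 diagnosis
frames, and 5 folds; unit tests use 2-segment stimuli at 135 × 240.  These
sizes keep a full study in the minutes range on one CPU while preserving
every structural constant of the method (200 × 350 grid, 350 + 350
coordinates, 28 channels, 15-feature subsets, 50 diagnosis frames).

## Known limitations

* **The match-count vote is insensitive to sparse individual maps.**  For
  a diagnosis frame, sim(fix, sal) = 70000 − |sal| − k + 2·overlap, where
  k is the number of pixels the subject fixated in that frame (order 10).
  The vote therefore compares (|S_ctrl| − |S_case|) + 2(overlap_case −
  overlap_ctrl): the subject contributes at most ±2k matches, while the
  area difference between the two groups' saliency maps fluctuates by
  thousands of pixels from frame to frame when the group phenotypes differ
  strongly.  Votes are then almost entirely determined by the stimulus and
  the models, and only frames where the two areas nearly tie respond to
  the individual.  On synthetic cohorts with a large side-preference gap
  (0.8 vs 0.2) the cross-validated vote AUC lands around 0.5–0.75 per fold
  rather than near 1, even though the learned saliency maps separate the
  group preferences essentially perfectly (the case model predicts the
  geometric half, the control model the biological half).  Mitigations
  that would help — overlap-restricted similarity, area-calibrated
  thresholds, dilated individual maps — all modify the published
  comparison rule, so they are not the default; the individual-map
  dilation radius is exposed as a config should users want to explore it.
* The per-fold Youden threshold is chosen on the test fold, as published;
  this is optimistic and the nested variant is one flag away.
* Default semantic detectors for real (non-synthetic) video are simple
  heuristics; for serious use, register proper face/person detectors via
  the detector interface.
* Whether "raw data" means raw gaze samples or vendor-detected fixations
  is ambiguous in the source description; the package uses raw valid
  samples.
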