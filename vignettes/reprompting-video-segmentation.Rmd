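---
title: "Overseer-guided re-prompting for temporally consistent video segmentation"
author: "VideoReprompt authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overseer-guided re-prompting for temporally consistent video segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VideoReprompt)
```

## The model

Promptable memory-based video segmentation engines propagate a prompted set
of entities through a video: the prompt frame's mask is encoded into a
memory, and each subsequent frame is segmented conditional on that memory.
This design has a structural blind spot — the output class set can never
grow beyond the prompt. An object that enters the scene after the prompt
frame is invisible to the tracker, and an object that leaves may persist as
a ghost.

`VideoReprompt` couples the tracker `F(v)` with a frame-wise detection
overseer `M(v_t)` that predicts, for every frame independently, the classes
present together with boxes, scores and instance masks. The orchestration
(`runReprompt()`) works on class *sets*:

* the reference set `r` is the set of classes prompted into the tracker at
  the last prompt;
* every frame's overseer class set `c_t` (detections with score at or above
  `scoreThreshold`) is appended to a buffer;
* a **trigger** fires at the first frame `t'` such that `c_t != r` on every
  frame of the window `[t' - n_t, t']`, i.e. after `n_t + 1` consecutive
  discrepant frames;
* on a trigger, the tracker memory is reset to `t' - n_t - 1` and a fresh
  prompt is built from the overseer at `t' - n_t` — the first frame of the
  change — re-segmenting frames `t' - n_t .. t'` and overwriting the
  previous outputs. The reference set becomes the newly prompted set, the
  buffer run is cleared, and monitoring continues.

The persistence requirement makes the loop robust: a detector blip of up to
`n_t` frames can never cause a re-prompt, while a genuine entry or exit is
caught with a fixed latency of `n_t` frames that the back-tracking then
erases from the output.

Assumptions worth stating explicitly: the overseer is frame-wise and
independent across frames (its errors are uncorrelated in time, which is
what the persistence filter exploits); change detection is at the level of
class *presence*, not instance counts — a second instance of an
already-tracked class does not trigger (a recorded limitation); and a
re-prompt replaces the full entity set rather than incrementally adding
entities, because the overseer's mask at the back-track frame describes the
complete constellation.

## Tunable parameters

* `nT` (frames, default 4): the persistence threshold. Smaller values react
  faster but re-prompt on noise; larger values stretch the correction
  latency. The default follows the value commonly used for this mechanism
  on surgical video.
* `scoreThreshold` (probability, default 0.5): minimum detection confidence
  for a class to count as present. The reference detectors in this field do
  not publish a canonical cutoff; 0.5 is the neutral choice.
* `anchorsPerComponent` (count, default 1): anchor points sampled per
  8-connected component of each prompted class. The first anchor is the
  most interior pixel (distance-transform argmax, row-major tie-break);
  additional anchors are further local maxima in decreasing depth. One deep
  interior point per component is what a human prompter would click.
* `NoiseConfig`: per-detection miss probability, per-class per-frame
  spurious-blip start probability with a duration range, morphological
  jitter radius range, and score noise. These model an imperfect overseer;
  all draws are reproducible from the config seed, and the realisation log
  makes the injected events inspectable.

## What the synthetic generator emulates — and what it does not

`generateScene()` produces textured background "anatomy" regions and moving
"instrument" shapes (disks, rectangles, capsules) that enter and leave at
scripted frames, painted in list order (later objects on top). It returns,
alongside the rendered frames, the exact ground-truth label maps, the exact
displacement field of every frame pair (objects carry their configured
velocity, everything else is zero), per-frame ground-truth detections and
an entry/exit event log.

Design choices and their rationale:

* **Integer velocities by default.** With integer motion, nearest-neighbour
  warping along the ground-truth flow reproduces the next mask *bit
  exactly* on non-overlapping configurations, which turns the temporal
  consistency metrics into sharp oracles (expected value exactly 1.0).
  Sub-pixel velocities are permitted but exactness is then waived.
* **Value-noise textures.** Backgrounds and objects get smooth seeded
  textures (Gaussian-filtered white noise), and an object's texture
  translates rigidly with it, so dense flow estimators have gradients that
  follow the true motion; flat renderings would make flow estimation
  degenerate.
* **Occlusion caveat.** When a moving object occludes another labelled
  region, the uncovered pixels cannot be reconstructed from the previous
  mask by any warp; the exact-flow property is therefore only asserted for
  non-overlapping trajectories.

The generator does *not* attempt photorealism: no camera motion, specular
highlights, smoke, deformation, or class-dependent appearance models.
Consequently, passing tests demonstrate the correctness of the
orchestration mechanics, the metrics and the contracts — not that any
particular real detector or tracker will perform well on surgical footage.
Real backends are adapter points behind the same generics.

## Numerical choices

* **Warping.** Label maps are warped by forward splatting with flow rounded
  to the nearest integer, *half away from zero*; colliding splats resolve
  by class id (higher id on top) and target pixels without a source become
  background. A fixed collision order keeps results deterministic; with
  exact integer flow and non-overlapping objects no collisions occur.
* **Macro averaging.** Overlap scores average over the classes present in
  either mask, background included, classes absent from both excluded —
  absent classes would otherwise inflate scores with free 1.0 terms. An
  `all`-classes mode (absence agreement scores 1) is available.
* **Contour distance.** Boundary pixels are class pixels 4-adjacent to a
  different label or the frame edge. A class present in only one of the two
  masks contributes the frame diagonal `sqrt(H^2 + W^2)` as a flicker
  penalty — the metric is deliberately an outlier-sensitive flicker
  detector; a flag disables the penalty. Two all-background masks have no
  contours and are excluded from sequence means.
* **Matching.** Detection matching is greedy over same-class candidate
  pairs at box IoU ≥ 0.5, ordered by descending score, then descending
  IoU, then indices — the standard deterministic evaluation practice.
* **Losses.** Probabilities are clipped to `[1e-7, 1 - 1e-7]` before
  logarithms so saturated predictions stay finite; smooth-L1 uses the
  canonical transition point 1 on normalised box coordinates, summing the
  four coordinate terms per object and averaging over objects.
* **Degenerate inputs.** An overseer that reports nothing at frame 0 defers
  the initial prompt to the first frame with detections (logged); a class
  whose rendered prompt mask is empty (erased by jitter) is dropped from
  the prompt with a warning; a detection report with no predictions and no
  ground truths anywhere is vacuously perfect and warns.

## Open design points, as resolved here

* "Changed for more than `n_t` time steps" versus back-tracking to
  `t' - n_t` leaves an off-by-one open; this implementation requires
  `n_t + 1` consecutive discrepant frames and back-tracks to the first of
  them, which keeps both statements consistent (a 4-frame blip is
  suppressed at `n_t = 4`, a 5-frame change triggers with its first frame
  recovered).
* Discrepant sets need not be *identical* across the window — a drifting
  spurious label still counts as one persistent run.
* After a trigger, the buffer run is cleared, so a still-ongoing change
  relative to the new reference cannot re-trigger earlier than `n_t + 1`
  frames later (no trigger storms).
* Re-prompts pass both the mask and the anchor points to the tracker; the
  reference tracker consumes the mask, real backends may use either.
* Tracker state is value-semantic (every operation returns the updated
  tracker), which makes the Markov-after-reset property — reset + re-prompt
  is observationally equivalent to a fresh tracker — directly testable by
  exact mask equality.
* Mask storage uses single-channel 8-bit PNGs whose gray level *is* the
  class id, with names and palette colours in a plain-text sidecar: labels
  round-trip bit-exactly for any schema with up to 255 classes and no
  colour-table ambiguity can corrupt them.

## Problem sizes and limitations

The shipped test and acceptance protocol runs on 48×48 to 64×64 scenes of
20–60 frames with up to three classes — small enough that brute-force
per-pixel oracles (independent flood fills, pairwise boundary distances,
exhaustive matching) can verify every metric to 1e-12 on hundreds of seeded
random instances, and large enough that entry, exit, blip-suppression and
back-tracking scenarios all occur at realistic geometry.

Known limitations: instance-count changes within a class do not trigger;
the reference tracker has no appearance model, so its failure modes are
purely geometric; the Horn–Schunck flow estimator is a classical baseline
suitable for the consistency metrics' zero-motion sanity checks, not a
state-of-the-art flow method; and real-time or streaming operation is out
of scope — the orchestrator assumes random access to frames for
back-tracking.
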