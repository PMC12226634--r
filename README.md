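# VideoReprompt

Overseer-guided re-prompting for temporally consistent semantic video
segmentation.

## The problem

Memory-based promptable video segmentation engines (SAM2-style trackers)
propagate a prompted set of entities beautifully — until the scene
constellation changes. An instrument that enters the frame after the prompt
was never encoded into the tracker's memory and is silently predicted as
background; an instrument that leaves keeps ghosting through the
propagation. In surgical videos (cholecystectomy, cataract surgery) such
entry/exit events happen constantly, and manual re-prompting by a clinician
does not scale to hour-long recordings.

`VideoReprompt` implements the automated correction loop: a frame-wise
detection **overseer** `M(v_t)` runs in parallel to the **tracker** `F(v)`
and monitors the set of classes `c_t` present in every frame, stored in a
buffer `B`. Let `r` be the class set active at the last prompt. When
`c_t != r` holds for `n_t + 1` consecutive frames (trigger frame `t'`,
persistence threshold `n_t = 4` by default so short detector blips are
ignored), the orchestrator

1. back-tracks to `t' - n_t`, the first frame of the change,
2. resets the tracker's memory to `t' - n_t - 1`,
3. renders the overseer's semantic mask `m_{t'-n_t}`, samples one anchor
   point per 8-connected component of each class (the most interior pixel,
   i.e. the argmax of the distance transform), and
4. re-prompts the tracker with mask and anchors, re-segmenting frames
   `t' - n_t .. t'` (overwriting the earlier, wrong outputs) before
   continuing to the end of the video.

The package is a complete, self-contained laboratory for this mechanism. It
ships reference implementations of both contracts — an oracle overseer
(ground-truth detections plus a configurable noise model: misses, spurious
blips, boundary jitter, score noise) and a flow-propagation tracker that
reproduces the enter/leave failure mode by construction — plus a synthetic
scene generator with exact ground-truth optical flow, so every moving part
can be tested bit-exactly. Adapters for real detector and tracker backends
plug in by implementing the same `detect` / `promptTracker` /
`propagateTracker` / `resetTracker` generics.

Also included are the evaluation tools of this literature:

* **Temporal consistency**: `Dice_OF` / `IoU_OF` — macro Dice/IoU between
  the previous mask warped along the optical flow, `m'_{t+1} = W(m_t,
  OF(v_t, v_{t+1}))`, and the next mask; `CD_T` / `IoU_T` — contour
  distance and IoU of consecutive masks, ignoring image content.
* **Per-frame detection**: class F1 at 50% box IoU, mean box IoU over true
  positives, instance-mask Dice at 50% IoU, and macro-average semantic Dice.
* **The detection multi-task loss** `L = 1/N_cls Σ L_cls + 1/N_bb Σ L_box +
  1/N_mask Σ L_mask` (class cross-entropy, smooth-L1 box regression,
  per-pixel mask cross-entropy) as pure, testable operations.

## Worked example

A 64×64, 60-frame scene: textured anatomy background, a static disk
("grasper", class 2) present throughout, and a rectangle ("hook", class 3)
that enters at frame 20 and translates one column per frame.

```r
library(VideoReprompt)

schema <- LabelSchema(c("tissue", "grasper", "hook"))
cfg <- SceneConfig(64, 64, 60, schema,
  objects = list(
    ObjectSpec(2, "disk", center = c(20, 16), entryFrame = 0,
               exitFrame = 60, radius = 6),
    ObjectSpec(3, "rectangle", center = c(44, 12), velocity = c(0, 1),
               entryFrame = 20, exitFrame = 60, height = 9, width = 7)),
  backgroundRegions = list(
    ObjectSpec(1, "rectangle", center = c(58, 32), height = 12, width = 64,
               exitFrame = 60)))
bundle <- generateScene(cfg)
bundle
#> SceneBundle: 60 frames of 64 x 64, 2 objects, 1 background regions

overseer <- OracleOverseer(bundle)
tracker <- FlowPropagationTracker(frameDims(bundle), bundle@flow)
run <- runReprompt(bundle@frames, overseer, tracker, schema,
                   RepromptConfig(nT = 4))
run
#> RepromptRun: 60 frames, initial prompt at 0, 1 re-prompt(s)
#>   trigger 24 -> re-prompt 20 ({1,2} -> {1,2,3})
```

The overseer first reports the hook at frame 20; after four more discrepant
frames the change is accepted as persistent (trigger at `t' = 24`), the
tracker is rewound and re-prompted at frame 20, and the corrected output
contains the hook from its true entry frame onward. Without the re-prompt,
the flow tracker would score Dice 0 on class 3 for all 40 frames.

```r
temporalConsistencyReport(bundle@frames, run@masks, "ground_truth",
                          bundle@flow)
#> ConsistencyReport over 59 pairs: Dice_OF 0.996, IoU_OF 0.996, CD_T 0.637, IoU_T 0.953
macroOverlap(getMask(run@masks, 59), getMask(bundle@masks, 59))$dice
#> [1] 1
```

`Dice_OF` is exactly 1 on every frame pair except the one spanning the
entry event; the residual `CD_T` comes from the moving object's one-pixel
shift between consecutive masks.

The same pipeline is scriptable from a shell via
`inst/scripts/videoreprompt` with subcommands `generate`, `run` and `eval`
(numbered-PNG frame directories in, indexed-PNG masks and key-value/JSON
reports out); identical configurations and seeds produce bit-identical
artifacts.

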