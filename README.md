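# larvaInject

Hardware-free R implementation of the decision-making stack of an
automated microinjection robot for 2-dpf zebrafish larvae — the software
that turns camera images into injection decisions: where each larva is,
how it is oriented, where its injectable sites are (duct of Cuvier,
perivitelline space, hindbrain ventricle), when the descending needle is
in focus, touching the skin, and through it, how large the expelled
droplet is, and how a whole plate of ~20 larvae is worked through as a
macro-driven injection session.

Because the real instrument's inputs are live optics, everything here
runs against a built-in synthetic fixture generator with exact ground
truth: stylized bright-field plates, particle-flow vessel videos,
unimodal-sharpness focal stacks, drift-then-jump needle-approach
sequences and droplet-in-oil snapshots. That makes every stage of the
pipeline testable end to end, deterministically, on a laptop.

## What is implemented

* **Segmentation machinery** (the network itself is pluggable behind a
  `Segmenter` function contract):
  * annotation post-processing: overlapping polygon classes resolved
    per pixel by specificity (a pixel marked both *body* and *eye*
    becomes *eye*);
  * per-pixel class decision `argmax_k s(x, y, k)` over a W×H×N score
    array;
  * tiled inference with 304-px tiles overlapped by 50 px, stitched by
    nearest-tile-center assignment (segmentation networks err near
    their input edges, so each pixel trusts the tile it is most central
    in);
  * six-transform consensus: segment under the identity, rotations by
    90°/180°/270° and the two axis reflections, map back, majority-vote
    per pixel with specificity tie-breaks.
* **Targeting**: landmark centroids (eyes, yolk, swim bladder), the
  skewed coordinate frame `x = o + a·u + b·v` built from them (origin at
  the eyes, u toward the yolk, v toward the swim bladder), its exact
  inverse, orientation-aware needle angles, and site-specific poses:
  middle-of-DoC or user-chosen DoC point, PVS upper border at 30–60°,
  hindbrain start/direction points.
* **Blood-flow mapping**: activity = normalize(Σ_t |f_{t+1} − f_t|)
  over a short (default 10-frame) video, with the red overlay used for
  DoC recognition.
* **Autofocus & touchdown**: variance-of-Laplacian sharpness, causal
  peak detection with hysteresis for the coarse descent, rolling-median
  jump detection for surface touchdown, organised as a
  COARSE → FINE → TOUCHED state machine.
* **Puncture detection**: anchor points seeded at textured locations
  near the needle tip, tracked frame-to-frame by normalized
  cross-correlation with sub-pixel refinement; puncture fires when the
  collective (median) displacement jumps by a factor k (default 4, 2 px
  floor) over its history. A triplet-image classifier interface (with a
  toy trainable model) is provided as the alternative detector.
* **Droplet calibration**: equivalent-area diameter of the dark blob in
  mineral oil with sub-pixel (coverage-weighted) area, moment-based
  circularity gating, sphere volume V = (π/6)·d³, and a proportional
  pressure recommendation.
* **Sessions**: YAML injection macros (`await_touchdown`,
  `await_puncture`, `retract`, `pulse`, `repeat`, operator checkpoints
  …), plate scanning in top-to-bottom order, a simulated clock with a
  7-minute batch budget, per-larva outcome records, summary statistics
  (success rate, larvae/hour, placeholder survival) and the one-tailed
  Welch comparison used for mode-vs-mode tables.

## Worked example

```r
library(larvaInject)

plate <- generatePlate(nLarvae = 20, imageSize = c(1024, 1024), seed = 7)
plate
#> SyntheticPlate: 1024 x 1024 pixels, 20 larvae (seed 7)

lar1  <- scanPlate(plateImage(plate))[[1]]       # first larva in scan order
lm    <- landmarkCentroids(lar1$labels)
frame <- buildSkewedFrame(lm)
frame
#> SkewedFrame: origin (15.53, 16.21), u (18.97, 15.22), v (29.41, 32.84)

docTarget(lar1$labels, frame)
#> NeedlePose[doc_mid]: tip (28.00, 38.00), angle 48.2 deg

record <- runSession(plate, defaultMacro("doc"), seed = 11)
record
#> SessionRecord: 20 larvae (skipped=4, success=16)
summarizeSession(record)
#> SessionSummary: 16 injected, success 100.0%, 135.8 larvae/h, survival 93.8%
```

Reading this: the frame origin is the eyes centroid of the first
detected larva (in its local crop), `u`/`v` point to the yolk and
swim-bladder centroids, the needle pose sits on the duct-of-Cuvier band
at the angle implied by the larva's orientation, and the session
injected 16 of 20 larvae before the simulated 7-minute batch budget ran
out (the remaining 4 are logged as skipped, not failed). Success and
survival percentages come from the simulator's oracle-backed detectors
and placeholder survival model — they are software bookkeeping, not
biological outcomes.

A command-line wrapper with `simulate-plate`, `segment`, `bloodflow`,
`run-session` and `calibrate-droplet` subcommands is installed at
`system.file("scripts", "larvainject.R", package = "larvaInject")`.

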