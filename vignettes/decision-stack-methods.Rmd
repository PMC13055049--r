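---
title: "Methods: the decision stack of an automated larva microinjection robot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the decision stack of an automated larva microinjection robot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvaInject)
```

# Scope and assumptions

larvaInject implements, in software only, the image-analysis and
decision layer of a robot that microinjects 2-dpf zebrafish larvae at
three sites: the duct of Cuvier (DoC, intravenous), the perivitelline
space (PVS, subcutaneous-like) and the hindbrain ventricle (orthotopic
brain implantation). The hardware layer — stage motors, liquid lens,
pressure controller — is out of scope; wherever the real instrument
would consume an optical stream, this package consumes an image, an
image sequence or a score trace with identical semantics.

The package assumes throughout:

* grayscale images as numeric matrices in [0, 1], 0-based pixel
  coordinates, x rightward, y downward, angles in degrees turning from
  +x toward +y;
* larvae lie flat on an agarose plate and do not touch (plates are
  prepared that way);
* one segmentation class per pixel, with "more specific beats less
  specific" as the universal conflict rule (priority order: eye >
  swim bladder > yolk > DoC > PVS > hindbrain > body > background).

# The synthetic study conditions

No imagery ships with the package; a generator module produces every
input with exact ground truth. Its defaults are the package's study
conditions and are deliberately fixed:

* **Plates**: 20 larvae per 1024×1024 plate, matching the practical
  batch size (anesthetized larvae dry out, so a batch is injected
  within about 7 simulated minutes). Larvae are a stylized template —
  body ellipse (92×32 px), two eye disks, yolk disk, swim-bladder
  ellipse, a perivitelline crescent and a thin DoC arc on the yolk
  margin, a hindbrain disk — rotated to a random heading. The template
  is schematic on purpose: the pipeline's correctness claims concern
  geometry, contrast and bookkeeping, not photorealism.
* **Paint levels**: each class is rendered at its own gray level
  (`paintLevels()`), separated by at least 0.07 intensity. Additive
  Gaussian sensor noise (sd 0.005, clipped) leaves a pixel-wise
  nearest-level classifier (`templateSegmenter()`) essentially exact.
  This classifier is the package's reference `Segmenter`: being
  strictly pixel-wise it is translation-consistent by construction,
  which is precisely the property needed to validate tiling/stitching
  (a correct stitcher must reproduce its whole-image output exactly).
* **Vessel videos**: 10 frames, dark particles advancing 2 px/frame
  along the vessel centerline at 0.08 particles per centerline pixel,
  on a static speckled background — enough traffic that the summed
  frame differences mark the vessel clearly, as in real coaxial
  illumination recordings of blood flow.
* **Focal stacks**: one random texture blurred with
  sigma = 0.4 + 0.7·|i − peak|, so every reasonable focus measure is
  exactly unimodal at zero noise.
* **Needle-approach sequences**: a textured patch translating by
  `driftPx` (default cases use 0.5 px/frame) that snaps back by
  `jumpPx` (6 px) at the annotated puncture frame — the skin
  "retracting more rapidly" once punctured.
* **Droplets**: anti-aliased dark disks on a bright oil background at a
  known µm/px scale.

What the generator does **not** emulate: pigmentation variants,
developmental stages other than an idealized 2-dpf geometry,
illumination gradients, occlusions, needle shadows, or real tissue
deformation fields. Tests passing here therefore certify the decision
algorithms and their contracts, not robustness to real-world optical
variability — that robustness lives in the pluggable trained network,
which is out of scope.

# Segmentation inference

The network contract is a function from an image to a W×H×N score
array. Around it:

* **Tiling**: 304-px square tiles at stride 254 (50-px overlap), the
  last tile per axis clamped flush to the image edge; images smaller
  than a tile are reflect-padded and cropped back after stitching.
* **Stitching**: each output pixel takes the scores of the covering
  tile whose center is nearest. Networks of this family are least
  reliable near their input borders; nearest-center assignment encodes
  that edge distrust directly. Averaging scores across overlaps was
  the obvious alternative; hard assignment was chosen because it
  preserves the exact-equality property against a translation-
  consistent segmenter, making the machinery testable to the pixel.
* **Consensus**: of the eight square symmetries, the six used are the
  identity, rotations by 90°/180°/270°, and the horizontal and
  vertical reflections. Votes are per-pixel majorities over the six
  back-transformed label maps; ties go to the most specific class,
  then the lowest class index. With an equivariant segmenter the
  consensus provably equals the plain segmentation, which the tests
  exploit.

# Targeting

The three landmark centroids define a skewed (non-orthogonal) affine
frame: origin at the eyes centroid (the union of both eyes), u to the
yolk, v to the swim bladder. User coordinates (a, b) map to plate
pixels as o + a·u + b·v; the inverse is the exact 2×2 solve. Frames
with |u × v|/(|u||v|) < 1e-3 are rejected as degenerate. The
assignment of origin and axes is a package convention — any fixed
assignment works, since only the round trip and equivariance matter.

Site rules:

* **DoC**: the largest connected DoC component; the default ("middle")
  target is that component's centroid snapped to the nearest component
  pixel. A medial-axis midpoint was considered; the centroid was
  chosen because it is simpler, robust, and for the shallow DoC arc
  differs from the arc midpoint by about a pixel. A user-chosen point
  (in frame coordinates) is mapped to the plate and snapped the same
  way. Snapping quantizes the pose to the pixel grid; the continuous
  frame mapping underneath is what carries the sub-pixel equivariance
  guarantee.
* **PVS**: boundary pixels of the PVS component on the positive-v side
  of the larva's own frame ("upper border", orientation-invariant by
  construction), entry angle validated to [30°, 60°].
* **Hindbrain**: consumes a start point and a direction point (their
  prediction is a learned regressor on the real instrument and stays
  pluggable here); the pose is the start point with the angle of the
  connecting line.

# Descent, touchdown, puncture

Sharpness is the variance of the 4-neighbour Laplacian — the canonical
"classical algorithm" for focus tracking; it sits behind a plain
numeric score interface and is swappable. The descent is an explicit
COARSE → FINE → TOUCHED state machine:

* **Coarse**: causal peak detection. The running maximum is confirmed
  as the focus peak once the trace drops below max·(1 − h) with
  hysteresis h = 0.05 (defaults are config arguments, not constants in
  the logic). A trace that never rose, or never falls, yields no
  event; emitted events are never revised.
* **Fine**: touchdown fires at the first score ≥ 3× the rolling median
  (window 5) of the preceding scores. The detector arms only after 3
  baseline samples: a median over fewer samples is too easily dragged
  down by a single noise dip, which would fire spuriously. With noise
  up to 10% of the jump size this stays ≥ 95% accurate within ±1 step.

Puncture detection tracks ≥ 4 anchor points (default 6–8) seeded at
high-corner-response pixels near the needle tip, by normalized
cross-correlation of 9×9 patches over a ±6 px search window with
quadratic sub-pixel refinement (skipped at an exact correlation-1 match
so identical frames report exactly zero displacement). Points whose
best correlation falls below 0.5 are flagged lost and excluded. The
collective statistic is the median displacement of surviving points —
robust to individual losses; the event fires when it reaches k = 4
times the median of prior per-frame medians, with a 2 px absolute
floor. The floor is what keeps pure slow drift (0.5 px/frame) silent:
4 × 0.5 = 2 px is only reached by the genuine jump. The
triplet-image classifier path (three chronological frames as channels)
is provided behind a model-function interface with a toy logistic
model; the anchor method is the reference detector.

# Droplet calibration

The darkest blob is segmented at the midpoint between the image's
extreme quantiles; a second blob above half the largest blob's area is
an ambiguity error, not a guess. Circularity is moment-based:
area / (2π·Rg²) with Rg the radius of gyration — exactly 1 for a disk,
2ab/(a²+b²) for an ellipse — and blobs below 0.8 are rejected as
debris (droplets in oil are near-spherical). The diameter is the
equivalent-area diameter computed from the *coverage-weighted* area
(anti-aliased edge pixels contribute fractionally), which keeps the
volume error well under 0.5%. Volume is (π/6)·d³, 1 µm³ = 1e−6 nL.
The pressure recommendation is the first-order proportional update
new = current·(target/measured), clamped to a safe range; the real
pulse physics (and cell sedimentation, which makes droplet size
unrepresentative for cell suspensions) is out of scope — sessions
handle that with multi-pulse macros and operator checkpoints instead.

# Sessions and bookkeeping

Macros are declarative YAML step lists with a validity interlock: no
pressure pulse may precede puncture confirmation. The simulated clock
charges fixed per-action costs (`actionCosts()`); throughput numbers
are explicitly modelling bookkeeping, never real-hardware time. The
7-minute batch budget marks remaining larvae as skipped. Survival is a
seeded Bernoulli placeholder (default 0.9) per successful injection —
survival is a biological outcome software cannot compute, and the
summary labels it accordingly. Success in the simulator means "macro
completed with puncture confirmed and all pulses delivered"; the
in-vivo criteria (visible dye entering circulation etc.) are not
operationalizable here. Mode comparisons use the one-tailed Welch
(unequal-variance) t test with Welch–Satterthwaite degrees of freedom;
two zero-variance samples with equal means return p = 0.5 by
convention.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run at the sizes the
package's guarantees are stated for: 12–20 plates between 320² and
1024² for stitching exactness, 100 random 32×32 rasters (40 in the
script) for consensus voting, 1000 random frames for the round trip,
200 + 100 sequences of 48²–64² frames for puncture detection, 200
noisy traces for touchdown, 20 ten-frame vessel videos, and a
20-larva 1024² plate for the session checks. Degenerate inputs error
loudly and early: empty vessel masks, stacks of fewer than 3 steps,
collinear landmarks, polygons with fewer than 3 vertices, blocked
needles (measured volume 0).

# Known limitations

* The reference segmenter is an intensity lookup tied to the synthetic
  renderer; real imagery requires plugging a trained model into the
  `Segmenter` contract.
* Anchor tracking assumes locally translational motion; strong
  non-rigid deformation or occlusion by the needle shaft would degrade
  it (lost-point flagging mitigates, does not solve).
* Site poses are snapped to the pixel grid; applications needing
  sub-pixel needle placement should consume the frame mapping
  directly.
* All throughput and survival figures produced by the session module
  are simulation bookkeeping and must not be quoted as instrument
  performance.
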