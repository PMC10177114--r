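---
title: "Detecting and normalizing rotated animal faces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and normalizing rotated animal faces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotface)
```

## The problem

Face identification pipelines for livestock need three stages: find the
face, normalize it (rotate and crop it to a canonical upright pose), and
only then identify the animal. Animals do not cooperate with cameras —
overhead barn footage contains faces at every in-plane orientation — and
keypoint detectors trained for upright faces fail once the rotation is
large. `rotface` implements a one-stage, anchor-based convolutional detector
that predicts, for every face, an axis-aligned bounding box *and* the
in-plane rotation angle, so that normalization reduces to a closed-form
rotate–crop–scale.

## Angle representation

Angles are kept in half-turns: $\theta \in (-1, 1]$, with $\theta \times
180$ the rotation in degrees, positive counterclockwise. The angle of a
face is the direction of the vector from its left eye keypoint to its right
eye keypoint; an upright face has $\theta = 0$. Given keypoints $(x_l,
y_l)$ and $(x_r, y_r)$ in image coordinates (origin top-left, $y$ down),

$$\theta = \frac{1}{\pi}\,\mathrm{atan2}(y_l - y_r,\; x_r - x_l),$$

which realizes all six case branches of the slope-based definition (the
sign of $x_r - x_l$, the vertical cases, and the left–right reversal) while
keeping the vertical case exact and never forming an infinite slope.

A detector that regresses $\theta$ directly struggles near the $\pm 180°$
boundary: $\theta = 0.99$ and $\theta = -0.99$ are nearly the same physical
pose but numerically far apart. The model therefore predicts the *absolute*
angle value $|\theta| \in [0, 1]$ (a sigmoid output) and the rotation
*direction* (a two-way softmax) separately; both are continuous across the
boundary. At assembly time $\theta = +|\theta|$ if the counterclockwise
probability exceeds 0.5, else $-|\theta|$.

### Augmentation angle maps and one correction

Quarter-turn rotation and the two flips act on $\theta$ in closed form:
rot90ccw is $\theta + 0.5$ (wrapped), a horizontal flip is $-\theta$, and a
vertical flip is $1 - \theta$ (wrapped). Two conventions make these
consistent, and both are enforced by tests:

* Mirroring swaps the left/right roles of the keypoints — in the mirrored
  face, the keypoint that should be on the left of the upright face is the
  mirror image of the original *right* keypoint. Without the swap the
  horizontal-flip map would not be $-\theta$.
* For $\theta < 0$ the vertical-flip map must be $-1 - \theta$ (the wrapped
  form of $1 - \theta$), not $\theta - 1$. We validated this against a
  geometric oracle — transform the keypoints, recompute the angle — over
  $10^4$ random cases, and against the group identity
  $\mathrm{vflip} \circ \mathrm{hflip} = \mathrm{rot180}$. The package
  implements the geometrically consistent form; the sign-flipped variant
  fails both checks.

The wraparound metric $D(\theta^*, \theta) = |\Delta|$ if $|\Delta| < 1$,
else $2 - |\Delta|$, underlies the average angle difference (AAD) reported
in degrees.

## Anchors, encodings, and the network

Four pyramid levels with strides 8, 16, 32 and 64 carry prior boxes
("anchors"). Each level's grid is $\lceil W/s \rceil \times \lceil H/s
\rceil$ cells; each cell holds six templates (two scales $\{1, 2\}$ ×
three aspect ratios $\{1, 2, 0.5\}$ at constant area), centered on the cell
center, with per-level base sizes 32/64/128/256 px. At a 400 × 400 input
this yields grids of 50, 25, 13 and 7 cells a side and $6 \times (2500 +
625 + 169 + 49) = 20{,}058$ anchors. The stride assignment and the ceiling
grids are the unique combination that reproduces that count.

Boxes are regressed relative to their anchor in the usual dimensionless
form $t_x = 10(x - x_a)/w_a$, $t_y = 10(y - y_a)/h_a$, $t_w = 5\log(w/w_a)$,
$t_h = 5\log(h/h_a)$, inverted exactly at decode time.

The backbone is 14 convolution–batchnorm–ReLU (CBA) units in five blocks:
block 1 is two CBA (the first with a 7 × 7 kernel), blocks 2–5 are three
CBA each; the first convolution of every block has stride 2, and the third
CBA of blocks 2–5 is 4× as wide as its block's first two. The last three
block outputs (strides 8/16/32) feed a top-down neck: 1 × 1 lateral
projections to a common width, nearest-neighbor 2× upsampling with
element-wise addition (cropping one row/column when ceiling division makes
sizes differ, e.g. 26 vs 25), plus a fourth stride-64 map obtained by a
stride-2 convolution from the deepest merged map. One shared 3 × 3
convolution maps each of the four maps to $6 \times 9 = 54$ channels — per
anchor: two objectness logits, four box encodings, two direction logits,
one angle-value logit. Flattening follows the anchor order exactly
(level-major, cells row-major, template fastest), an alignment asserted by
a marker test.

Channel widths are configuration, not architecture: the sources for this
design state the ratios (doubling per block, 4× third CBA) but not the
absolute widths, so `net_config(base_width=, neck_width=)` exposes them.
The default `base_width = 16`, `neck_width = 64` gives a model in the
few-million-parameter class; the scaled-down experiment uses 8/32.

Two initialization choices matter in practice and are deliberate: the
shared head's weights start at `sd = 0.01` (He-normal elsewhere) so initial
logits sit at their biases, and the objectness-foreground bias starts at
−2, making the initial object probability ≈ 0.12. Without these the focal
objectness and Huber localization terms start far into their saturated
regimes and the first steps are spent undoing random head noise.

## Loss

The training loss is the weighted sum
$\lambda_{loc} L_{loc} + \lambda_{obj} L_{obj} + \lambda_{av} L_{av} +
\lambda_{ad} L_{ad}$ with defaults $(1, 5, 1, 10)$:

* $L_{loc}$: Huber ($\delta = 1$) on the four encoding residuals, averaged
  over sampled positive anchors.
* $L_{obj}$: focal loss ($\gamma = 2$) with $p_t = 1 - |p - p^*|$, averaged
  over a balanced sample of anchors (budget 256, target positive fraction
  0.25) drawn to counter the negative majority.
* $L_{av}$: squared error on the absolute angle value. Positives from the
  angle-labeled dataset (ds1) are weighted $\lambda_{ds1} = 10$; positives
  from the box-only dataset (ds2) are pulled toward zero with weight
  $\lambda_{ds2} = 0$ — i.e. masked out entirely by default. This is the
  dual-dataset mechanism: box-only images still train localization and
  objectness but contribute nothing to the angle terms.
* $L_{ad}$: focal loss on the direction probability, averaged over the
  gated set of positives whose true absolute angle exceeds
  $\varepsilon = 0.025$ — a face within ±4.5° of upright has an
  ill-defined direction. Box-only positives have no angle and are excluded
  from the gate.

Empty normalization sets ($N_{loc} = 0$, empty gate) return 0 rather than
NaN; probabilities are floored at $10^{-7}$ inside logarithms. Gradients
with respect to all nine head values are analytic and verified against
finite differences.

## Training procedure

Each step draws a dual-dataset batch: `t1` images from the angle-labeled
stream and `t2` from the box-only stream (streams reshuffle per epoch).
Per image, each affine augmentation fires independently with its configured
probability; tiling (2 × 2 or 3 × 3) then merges freshly drawn,
already-augmented partners, following the pipeline order affine-then-merge.
Images pass through the network one at a time (batch-norm statistics are
per image, with running averages kept for inference); gradients are
averaged over the batch. The optimizer is momentum SGD (0.9) under a
cosine-decayed learning rate with linear warm-up, plus a global
gradient-norm ceiling of 10 — a standard guard; without it an occasional
hard batch (a forced positive with a large encoding target) can destabilize
the small-batch runs. The optimizer family, learning rate and batch-level
averaging are not prescribed by the method's sources; they are package
choices, logged in the run configuration.

## Synthetic scenes as ground truth

`generate_synthetic_scene()` renders an ellipse "face" (semi-axes $a$ and
$1.35a$) with two dark eye dots placed symmetrically toward the forehead,
rotated by $\theta \sim U(-1, 1]$, on a noisy background. The recorded
ground truth is exact by construction: the box is the analytic axis-aligned
hull of the rotated ellipse and the keypoints are the rotated eye centers,
so recomputing the angle from the keypoints reproduces $\theta$ to machine
precision. That makes the generator an oracle for the angle codec, for all
three augmentations (transform the scene, recompute from keypoints, compare
with the closed form) and for the normalizer (a normalized glyph's eye line
must come out horizontal).

What the glyphs emulate: arbitrary orientation, variable scale (hull boxes
roughly 34–94 px on the 128 px canvas, matching the anchor sizes), a
direction cue analogous to eyes-toward-forehead, and single-channel
(infrared-like) or RGB rendering. What they do not emulate: texture,
occlusion, lighting, background clutter, multiple heterogeneous object
classes. Passing the scaled-down experiment therefore demonstrates that the
architecture, losses, augmentation bookkeeping and metrics are implemented
coherently — not that the model reaches photographic-data accuracy.

## The scaled-down experiment

`scaled_experiment()` is the package's end-to-end study, sized for one CPU
core: 300 training scenes, 100 held-out scenes, the small network (128 px
input, base width 8, neck width 32, ~1.4 M parameters), batches of 2
angle-labeled + 1 box-only image, 1,200 steps at peak learning rate 0.008.
The box-only stream reuses the training pool under the ds2 tag, so the
masking path runs in every step. Augmentation uses quarter-turns and flips
at probability 0.5 and 2 × 2 tiling at 0.25; tiling is kept light because
its purpose — diversity for small photographic datasets — is already
provided by the generator, while a high tiling rate would skew the training
scale distribution far below the evaluation scenes. Evaluation thresholds
are the package defaults (score 0.5, NMS IoU 0.5, matching IoU 0.5).
Typical results are average precision above 0.9 with an average angle
difference around 10° or better; exact numbers for given seeds are
produced by `scripts/acceptance.R`, and the test suite requires AP ≥ 0.8
and AAD ≤ 15° averaged over three seeds.

## Numerical choices and degenerate inputs

* Wrapping: every angle operation canonicalizes into $(-1, 1]$; exactly
  $-1$ maps to $+1$. $\theta = 0$ splits to direction "clockwise" by
  convention (assembly is unaffected).
* Matching: positive at IoU ≥ 0.5 or as a ground truth's argmax anchor
  (ties to the lowest anchor index); negative below 0.5; the thresholds are
  configurable because the method's sources leave them unstated.
* Convolution padding is "same with ceiling output" at stride 2 — required
  to reproduce the 13- and 7-cell grids; upsampled maps are cropped, never
  padded, when merging.
* NMS is greedy by descending score with stable tie-breaking by anchor
  index; AP uses all-points integration of the precision envelope.
* AAD is computed over true-positive matches only — they are the only
  detections with a ground-truth angle to compare against.
* Images with no ground truth make every anchor negative; batches with no
  positives contribute only objectness loss.
* Bilinear resampling everywhere (tiling, letterboxing, normalization);
  out-of-frame samples are zero. Quarter-turn rotations through the
  resampler are exact, which the equivariance test exploits.

## Known limitations

Training runs on one CPU core through compiled im2col/GEMM kernels; the
default 400 px, 50,000-step configuration from the full-scale method is
expressible but is a multi-day CPU run — the package's own experiments use
the scaled configuration above. Batch-norm statistics are per image rather
than per batch, a deliberate simplification that behaves well here but is
not identical to large-batch training. Rotated (oriented) boxes are out of
scope by design: the method predicts axis-aligned boxes plus a separate
angle, which is what makes single-stage detection and closed-form
normalization possible.
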