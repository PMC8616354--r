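---
title: "platemorph: models, phantoms and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{platemorph: models, phantoms and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(platemorph)
```

# Scope and pipeline

`platemorph` quantifies platelet shape and motion from phase-contrast
time-lapse microscopy. The pipeline is: fluorescence-derived ground-truth
binarization → trainable encoder–decoder segmentation of the phase-contrast
channel → per-platelet morphometry → spreading dynamics / migration
statistics → validation statistics. Because platelet microscopy data are
rarely deposited, the package ships a phantom module that generates
platelet-shaped masks, microscopy-like renders and time-lapse sequences
with *designed* ground truth; every downstream stage is validated against
these designed values in the test suite.

# Ground truth from fluorescence

Membrane-stain fluorescence is turned into a binary reference in three
steps: rolling-ball background subtraction, thresholding, hole filling.

- **Rolling ball.** The background is the grayscale opening of the image
  with a hemispherical structuring element of radius *R* (default 50 px at
  high magnification, configurable). Heights are `sqrt(R² − d²)` in
  intensity units without rescaling; with intensities in [0, 1] and *R* of
  tens of pixels the element acts nearly as a flat disk, which is the
  behaviour we want: structures narrower than the ball footprint survive
  subtraction, smooth background does not. Out-of-image ball positions are
  ignored, which makes a constant image map exactly to zero and the whole
  operation invariant to adding a constant.
- **Threshold.** Default is Otsu on the background-subtracted image; the
  original procedure does not publish a value, so this default is a design
  choice, not a reconstruction. Pixels strictly above the threshold are
  foreground.
- **Hole filling.** Background regions not 4-connected to the image border
  are filled. Foreground uses 8-connectivity, background 4-connectivity,
  the standard consistent digital topology.
- **Manual correction.** The original workflow included correction by eye;
  the automated path instead accepts an external override mask per frame.

# The segmenter

The segmenter is a standard contracting/expanding encoder–decoder with skip
connections: per level two 3×3 convolutions + ReLU, 2×2 max-pooling down,
nearest-neighbour upsampling and channel concatenation up, a 1×1 output
convolution and a sigmoid. It is implemented from first principles in
RcppArmadillo (im2col convolutions with exact backpropagation, verified by
numeric gradient checks in the test suite) because this R stack has no
deep-learning runtime. The training contract:

- min–max normalization `I' = (I − I_min)/(I_max − I_min)` of each input;
- reflection padding to a square network input (the instrument-scale
  geometry is 1608×1608 → 2048×2048; the pad/crop round trip is bit-exact);
- joint augmentation of image and mask: 90° rotation multiples, flips, and
  optional bounded rescaling (nearest-neighbour for the mask so it stays
  boolean);
- pixel-wise binary cross-entropy, Adam (10⁻³), one image per update,
  seeded 80/20 train/validation split by image;
- the returned model is the snapshot with **minimum validation loss**, not
  the final epoch;
- binarization of the output probability at 0.5.

Loss, optimizer, learning rate and split are config-exposed decisions; the
original publication states none of them. Training is reproducible for a
fixed seed under single-threaded deterministic kernels.

**Desk scale.** The default configuration (64–128 px inputs, 2–3 levels,
8–16 base filters) trains in minutes on one CPU. The full-resolution
instrument variant is the same architecture with a larger input and depth;
it is a compute concern, deliberately out of desk scope.

# Morphometry

Platelets are 8-connected components; components below a minimum area or
touching the image border are excluded (partial shapes bias every
parameter). Coordinates are 0-based pixel centres; areas are pixel counts
times `pixel_size²`.

- **Outline.** Moore-neighbour boundary tracing with the
  (pixel, backtrack) stopping rule, oriented counter-clockwise so convex
  curvature is positive.
- **Perimeter and the half-pixel outset.** The perimeter is the arc length
  of the Gaussian-smoothed boundary polygon **plus π**: boundary pixel
  centres sit ~0.5 px inside the true object boundary, and outsetting a
  simple closed curve by 0.5 px adds exactly 2π·0.5 to its length (total
  turning of a simple closed curve is 2π). Smoothing uses σ = 1 contour
  point by default. A heavier σ = 2 was considered and rejected for the
  perimeter: Gaussian smoothing shortens real corners by ≈ 0.6σ per 90°
  of turning, which biases the circularity of a 100-px square to 0.81
  (analytic π/4 ≈ 0.785), while σ = 1 yields 0.800 for the square, 0.799
  for a 45°-rotated diamond and 0.991 for an r = 50 px disk — all within
  ±0.02 of their analytic values. Circularity can exceed 1 by at most ~0.01
  (discretization); values are not clamped.
- **Ellipse fit.** Normalized second central moments of the filled
  component, +1/12 per axis for the pixel's own second moment; aspect ratio
  is the square-rooted eigenvalue ratio. Note the fit describes the whole
  component — protrusions pull the apparent elongation of a
  filopodia-bearing body toward 1 relative to the bare ellipse.
- **Curvature.** Central differences of the smoothed contour,
  κ = (x′y″ − y′x″)/(x′² + y′²)^{3/2}. Curvature and filopodia detection
  use σ = 2 smoothing (derivative estimation needs more regularization
  than length measurement); a digitized r = 50 px circle yields mean κ
  within 1 % of 1/r.
- **Filopodia.** Candidate tips are maximal arcs with κ ≥
  `min_tip_curvature` (default 2 µm⁻¹); from each arc's apex the contour is
  walked both ways to the first *genuinely concave* point, κ <
  −`min_tip_curvature`/4. A plain κ < 0 criterion fails: the straight
  flanks of a thin protrusion carry ±0.01–0.3 px⁻¹ discretization wiggle
  that terminates the walk early. The protrusion length is the distance
  from the apex to the farther of the two necks (robust when one walk still
  stops early), kept if ≥ `min_filopodium_length` (default 0.5 µm);
  candidates sharing both necks are merged. With these rules the designed
  count of 0–8 phantom filopodia is recovered exactly in 100 % of the
  seeded test suite (the stated requirement is ≥ 95 %). The thresholds are
  deliberately config-exposed: the upstream algorithm they descend from
  does not publish its parameterization.

# Spreading dynamics

Adhesion is the first frame at which the platelet exists as a tracked
component; all times are measured from it. **Idle time** is the time to the
first frame with area ≥ 1.15 × the adhesion-frame area — the baseline frame
and the inclusive crossing are conventions chosen here, flagged as such.
**Initial spreading rate** is the least-squares slope of A(t) over the
closed 2-minute window after idle time ends (a fit, not an endpoint
difference: robust to single-frame segmentation noise; the alternative
reading is noted as an open question in the upstream description). Windows
truncated by the end of the recording are flagged `truncated`; traces that
never cross 15 % are `censored` and excluded from rate statistics, never
silently dropped. The default frame interval is 10 s for spreading and 30 s
for migration, the standard acquisition rates for these experiments.

# Migration

Per-frame positions are **area centroids** of the filled components (an
outline-vertex mean is biased by contour point density). Linking is mutual
nearest-neighbour between consecutive frames within a gating distance
(default 20 px/frame, config-exposed; no linking rule is published), with
deterministic tie-breaks toward the smaller platelet id. Tracks that do not
span the full sequence are kept but flagged incomplete and excluded from
summaries — the published exclusion rule. Velocity uses accumulated
distance over time; straightness is Euclidean over accumulated distance;
⟨cos θ⟩ compares the single-frame displacement directions at the start and
end of each available interval and averages over intervals. Whether θ
compares single-step or net sub-interval directions is ambiguous in the
source description; both are implemented (`mode = "step"` default,
`"net"`), and both give 1 on straight tracks and ~0 on isotropic walks.
Alignment for path plots rotates each track rigidly about its start so the
first displacement points along +y, preserving all metrics bit-for-bit.

# Validation statistics

- **Pixel confusion**: TP/FP/FN fractions (true negatives excluded by
  construction, so the three fractions sum to 1) and IoU = TP/(TP+FP+FN).
- **Bland–Altman**: mean difference ± 1.96 × sample SD (n − 1).
- **Pearson r** on paired shape parameters.
- **Dunn's test**: joint mid-ranks, tie-corrected variance
  `(N(N+1)/12 − Σ(t³−t)/(12(N−1)))`, pairwise z and two-sided normal
  p-values. Whether the original analysis corrected for multiplicity is
  unstated; raw and Holm-corrected p are both reported. The stringent
  α = 0.001 used in the source suggests raw p.

# The phantom world

Phantoms are ellipse bodies (semi-axes a ≥ b) with filopodia drawn as
capsules (rectangle + rounded tip) along the local outward normal, angular
positions equally spaced with bounded seeded jitter so protrusions stay
separable (an invariant, enforced). Renders emulate the two channels:

- *phase contrast*: background 0.7, body 0.3, plus a bright halo (blurred
  outer boundary ring, peak 0.3) — the characteristic rim without
  transfer-function physics;
- *fluorescence*: body 1.0 on background 0.05;
- both: Gaussian optical blur (σ = 0.8 px in the default training world),
  optional linear background ramp, additive Gaussian noise (σ = 0.05),
  clipped at 0. Deterministic per seed.

The default segmentation training world (`make_segmentation_set`) draws
bodies of 8–15 px semi-major axis, 0–4 filopodia, random orientation and
position on a 64-px canvas — platelet-like scales at high magnification.
Every 10th image is a **platelet-free field**: real training corpora
contain empty fields, and they matter here because min–max normalization
amplifies noise on empty images into full-range texture; a network never
shown such fields hallucinates foreground on them, while with them the
empty-field negative control predicts < 0.1 % foreground.

Spreading phantoms are digitized disks following a piecewise-linear
two-phase area trajectory (idle, fast, slow) — the canonical spreading time
course. Migration phantoms move a body along straight, isotropic-random or
persistent-random paths; persistence p ∈ [0, 1] maps to wrapped-normal
heading increments with σ = π(1 − p) (p = 1 straight, p = 0 near
isotropic), a mapping chosen here and stated once.

**What a green phantom test does not establish.** Phantoms have sharp
in-silico boundaries, a single platelet per image, no debris, no focus
drift, no halo asymmetry and no intensity flicker. The ~99 % held-out IoU
on phantoms demonstrates that the training/inference machinery is correct
at desk scale — it does not certify instrument-scale accuracy, for which
the published full-scale figure is the reference. Similarly, thin
filopodia lose fluorescence intensity under blur: with σ = 1 px optics the
fluorescence-derived ground truth recovers filopodia-bearing masks at IoU
≈ 0.94 (the protrusions thin out), which is the same failure mode that
motivates manual correction in real ground-truth workflows.

# Numerical and I/O choices

- Images are numeric matrices (rows = y); 0-based pixel-centre
  coordinates; physical units µm, µm², µm/min throughout the tables.
- TIFF I/O is a minimal built-in baseline codec (uncompressed grayscale,
  8/16-bit unsigned or 32-bit float, multi-page, either byte order on
  read; pixel size in the resolution tags as pixels/cm). Float pages
  round-trip at single precision (~10⁻⁷ relative); integer and mask pages
  round-trip exactly. This is built in because the environment provides no
  R TIFF reader; it is deliberately not a general TIFF implementation.
- The CLI (`exec/platemorph`) is a thin dispatcher over the package API;
  the `run` subcommand executes a JSON-configured pipeline whose outputs
  embed the config hash and seed, and reruns reproduce deterministic
  outputs byte-for-byte.
- Model checkpoints are RDS files written at run time by the `train`
  subcommand.

# Known limitations

- Circularity of small compact polygons (≲ 60 px side) still carries a
  +0.01–0.03 corner-smoothing bias; at the 100-px scale used for
  validation it is within ±0.02.
- The two-level desk-scale network has a limited receptive field; phantoms
  larger than ~40 px across would need depth 3.
- Linking is frame-to-frame mutual nearest neighbour without gap closing;
  a platelet that vanishes for one frame starts a new track (it is then
  incomplete and excluded, matching the published exclusion rule).
- Dunn's p-values use the normal approximation; at n ≲ 5 per group an
  exact permutation test is preferable (the test suite verifies ≥ 99 %
  rejection agreement with a 10⁴-permutation oracle at n = 6–10).
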