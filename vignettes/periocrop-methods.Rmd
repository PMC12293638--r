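---
title: "Methods behind periocrop: rotated-box geometry, losses, and the cropping pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind periocrop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periocrop)
```

## The task and its conventions

Ocular-alignment photographs are taken with the patient's head in whatever
pose it happens to be in; the eye region is therefore best described by a
*rotated* rectangle: center $(c_x, c_y)$, side lengths $(w, h)$ with $w$
along the box's own x-axis, and an angle $\theta$ in radians measured from
the image x-axis. Coordinates follow the image convention ($x$ rightward,
$y$ downward); pixel $(i, j)$ occupies $[j-1, j] \times [i-1, i]$ so an
image of width $W$ spans $x \in [0, W]$.

Two conventions deserve to be explicit because everything else depends on
them:

* **Angle normalization.** A rotated rectangle is invariant under
  $\theta \mapsto \theta + \pi$, so angles are stored in $[-\pi/2, \pi/2)$;
  normalization never swaps $w$ and $h$. The representation
  $(w, h, \theta)$ and $(h, w, \theta + \pi/2)$ describe the same rectangle;
  `canonical_box()` resolves this by putting the long side first, which is
  also how the *ocular alignment angle* is defined: the signed angle of the
  box's long axis (the inter-eye axis) against the horizontal. The signed,
  symmetric range suits head tilts, which occur in both directions.
* **Units.** Tilt angles are specified in degrees at the user surface of the
  scene generator (clinically reported tilt ranges of roughly $-12.6$ to
  $+5.7$ only make sense in degrees — as radians they would exceed a full
  turn) and converted to radians in every `rotated_box`.

## Exact skew IOU by triangulation

For two convex polygons, the vertices of their intersection are exactly (a)
the pairwise edge–edge intersection points and (b) the vertices of one
polygon contained in the other. `skew_iou()` collects those points
(inclusive containment, so tangent configurations are kept), merges
near-duplicates, sorts the set counterclockwise by angle about its centroid,
and fan-triangulates from the first sorted vertex; the intersection area $I$
is the sum of the triangle areas and

$$\mathrm{IoU} = \frac{I}{\;\mathrm{area}(p) + \mathrm{area}(q) - I\;}.$$

Numerical choices:

* **Point-merge tolerance** $10^{-9}$ (input units). Coincident points arise
  whenever a vertex of one rectangle lies on an edge of the other; without a
  tolerance the convex sort would see spurious zero-area slivers. The value
  is far below any pixel-scale quantity the package handles and far above
  double-precision noise at those scales.
* **Fan anchor.** Any anchor vertex gives the same area for a convex
  polygon; the first sorted vertex is used so results are reproducible.
* **Degenerate input.** Fewer than three distinct intersection points means
  a zero-area intersection, reported as IOU 0 (never an error).

`raster_iou()` is a deliberately independent cross-check: it counts lattice
cell centers of an $n \times n$ grid laid over the joint bounding box, with
membership tested in each rectangle's own frame. Its error shrinks like
$1/n$; the test suite compares both routes at $n = 2000$ over 1,000 random
pairs (centers in the unit square, sides in $[0.05, 0.5]$, angles in
$[0, \pi)$) and the observed disagreement stays below $10^{-2}$.

## Gaussian surrogates and the ProbIoU loss

Exact polygon IOU has a gradient that is zero for disjoint boxes and
ill-behaved near degeneracies; Gaussian surrogates fix this. A box maps to
the 2-D Gaussian with the box center as mean and covariance
$R(\theta)\,\mathrm{diag}(w^2/12,\, h^2/12)\,R(\theta)^\top$ — the covariance
of the uniform distribution over the rectangle, the established surrogate
choice (`box_to_gaussian()`).

Writing the two Gaussians as $(x_i, y_i, a_i, b_i, c_i)$ with covariance
entries $a$ (xx), $b$ (yy), $c$ (xy), the Bhattacharyya distance splits into
a center term and a shape term:

$$B_1 = \frac{1}{4}\,
\frac{(a_1+a_2)(y_1-y_2)^2 + (b_1+b_2)(x_1-x_2)^2 + 2(c_1+c_2)(x_2-x_1)(y_1-y_2)}
     {(a_1+a_2)(b_1+b_2) - (c_1+c_2)^2},$$

$$B_2 = \frac{1}{2}\,
\ln\!\frac{(a_1+a_2)(b_1+b_2) - (c_1+c_2)^2}
          {4\sqrt{(a_1 b_1 - c_1^2)(a_2 b_2 - c_2^2)}}.$$

Both terms are nonnegative and vanish together iff the Gaussians coincide.
The $(b_1 + b_2)$ coefficient on $(x_1-x_2)^2$ is forced: a difference
$(b_1 - b_2)$ would make the "squared distance" sign-indefinite and
asymmetric in its arguments, so the sum is the only reading consistent with
$B_1$'s role as a Mahalanobis-type center term. The test suite verifies the
closed forms against an independent numeric Bhattacharyya integrator
(tensorized Gauss–Legendre quadrature of $\int \sqrt{p\,q}$) to $10^{-3}$
over 100 random Gaussian pairs.

From $B_D = B_1 + B_2$ the similarity is composed through the Bhattacharyya
coefficient $e^{-B_D}$ and the Hellinger distance
$H = \sqrt{1 - e^{-B_D}}$:

$$\mathrm{ProbIoU} = 1 - H, \qquad L_{Prob} = 1 - \mathrm{ProbIoU} \in [0, 1].$$

This is the one standard composition whose loss is provably bounded in
$[0,1]$, which the suite confirms empirically over 10,000 random box pairs.
ProbIoU ranks overlapping pairs almost identically to the exact skew IOU
(Spearman correlation above 0.8 in the tests) while still discriminating
disjoint pairs, where the polygon IOU ties everything at zero.

## Distribution focal loss

Rather than a single point estimate, each box offset is modelled as a
discrete distribution $S$ over `reg_max + 1` integer bins (default
`reg_max = 16`, so 17 bins). A continuous target $y$ in bin units is split
into its bracketing bins $y_i = \lfloor y \rfloor$, $y_{i+1} = y_i + 1$ and
the loss is the interpolation-weighted cross-entropy

$$L_{DFL} = -\big((y_{i+1} - y)\log S_i + (y - y_i)\log S_{i+1}\big).$$

This tolerates slightly-too-large boxes — appropriate since the eye-socket
boundary is itself fuzzy — while concentrating probability mass at the
label. Choices:

* Targets are expressed in *bin units* (pixels divided by a caller-chosen
  bin width); scaling is the detector's business, and a target outside
  $[0, \mathrm{reg\_max}]$ is an error (it indicates mis-scaling, not a hard
  example).
* At $y = \mathrm{reg\_max}$ the bracketing pair clamps to
  $(\mathrm{reg\_max}-1, \mathrm{reg\_max})$ with weights $(0, 1)$.
* Zero-probability bins are clamped at $\varepsilon = 10^{-12}$ before the
  logarithm, keeping the loss finite without visibly distorting any
  realistic value.
* The minimizer over distributions is the two-hot linear-weight distribution
  (`dfl_ideal_distribution()`), whose expectation decoding
  $\sum_i i\,S_i$ recovers $y$ exactly; the tests verify minimality by
  random search.

The combined regression loss is $L_{total} = 0.8\,L_{Prob} + 0.2\,L_{DFL}$
(`total_loss()`); detection is single-class, so there is no classification
term.

## Evaluation protocol

The metrics name a matching rule without fully specifying it; the package
implements the de-facto standard:

* **Matching** (`match_detections()`): detections in descending confidence;
  each claims the unclaimed truth of highest IOU, if that IOU reaches the
  threshold; ties break to the lowest truth index.
* **AP** (`average_precision()`): detections pooled across images and ranked
  by confidence globally; precision gets the monotone right-to-left envelope
  and is integrated over recall (continuous interpolation, not 11-point
  sampling — the two differ on sparse curves, and the envelope form is what
  the mAP50/mAP95 protocol uses).
* **mAP95** is the mean of AP over thresholds $0.50, 0.55, \ldots, 0.95$;
  with one class, mAP coincides with AP.
* **Conventions**: AP with zero ground-truth boxes is undefined and returned
  as `NA` (distinct from 0); with no detections and no truths,
  precision = recall = 1. Reported precision/recall depend on a confidence
  cutoff, exposed as a parameter (default 0.5) rather than fixed.

The implementation is checked exactly against a brute-force oracle that
re-derives the PR curve from scratch at every confidence cutoff.

## Letterbox, mosaic and photometric augmentation

`letterbox()` scales by the single factor $s = \mathrm{side}/\max(W, H)$
(aspect ratio exactly preserved), centers the content, and pads with
114/255 grey — a neutral fill that avoids biasing image statistics toward
either black or white. Boxes transform by the same scale and offset; the
inverse mapping round-trips within 0.5 px (rounding of the content size is
the only loss).

`mosaic_augment()` composes four annotated sources: a junction point is
drawn uniformly in the central 50% of a $2\times$-side canvas; each source
is scaled *to cover* its junction quadrant (anchored at the junction, so all
four images meet there, overflow clipped at the quadrant boundary); the
canvas is then resized back to the target side. Ground-truth boxes follow
each source's affine map; a box whose center leaves its quadrant is dropped
(and logged), and survivors are clipped in extent by projecting the
box-polygon∩quadrant intersection onto the box's own axes — the angle is
never altered by clipping. The cover-and-clip geometry is what makes the
drop/clip paths reachable; with four identical square sources and a centered
junction the result degenerates to the obvious symmetric composite.

`random_photometric()` applies an anisotropic stretch, a Gaussian blur
(EBImage's `gblur`), and a contrast scaling about mid-grey, each drawn
uniformly from configured ranges under an explicit seed (defaults: stretch
factors in $[0.9, 1.1]$, blur $\sigma \in [0, 1.5]$ px, contrast in
$[0.85, 1.15]$ — mild, realistic camera variation). An anisotropic stretch
does not map a rotated rectangle to a rectangle, so boxes are re-fit as the
minimum-area rotated box (rotating calipers) of their stretched corners.
Degenerate ranges reproduce the input exactly, and all augmentations are
pure functions of (input, seed).

## Deskewing crop

`deskew_crop()` rotates the content by minus the box's alignment angle
about the *box center* (not the image center), so the crop window is
axis-aligned after rotation, and resamples bilinearly into an output of size
$(1 + 2m)\,(w, h)$ where $m$ is the margin factor — the margin is a fraction
of the box size added per side, so $m = 0.1$ grows each axis by 20% in
total. When the stored representation has $h > w$ the axes are swapped
first, so "horizontal alignment" always refers to the inter-eye axis.
Samples beyond the source frame are filled with the letterbox grey and the
result is flagged. On synthetic scenes, cropping with the ground-truth box
leaves a residual eye-line angle below half a degree, limited only by
resampling.

## QA gate

The upload gate mirrors a clinical dual-layer check: at least 5 megapixels
(pre-model); detected eye-region area between 2.5% and 25% of the frame,
proxying the 33 cm–1 m shooting-distance window ("too far" / "too close"
otherwise); detection confidence at least 50%, else the image is flagged
unreliable — as it also is when the detector returns nothing. The rules are
phrased as strict inequalities ("less than", "more than", "falls below"), so
boundary values *pass*; the tests pin this behavior at and around all three
boundaries. The gate classifies rather than errors: its purpose is to tell
the user what to fix.

## The synthetic scene generator

`generate_scene()` stands in for clinical photographs. It renders a
skin-toned face oval on a darker backdrop, two eyes (bright sclera ellipse
with a dark iris disc), brows and a mouth, rotated by the requested tilt;
optional occluders (a bright swab-like bar or a dark finger-like blob near
one eye, placement adjustable) emulate the obstructions that occur during
eyelid retraction; seeded Gaussian noise is added last. Geometry is
parameterized by the eye height $h_e$: the inter-eye span is $3.2\,h_e$, the
sclera $1.6\,h_e \times h_e$, the iris radius $0.32\,h_e$, and the
ground-truth box pads the two-eye hull by 25% of the span horizontally and
40% of the eye height vertically — giving box sides $6.4\,h_e \times
1.8\,h_e$, so a target area fraction fixes $h_e$ exactly. Defaults emulate
the observed clinical distributions: tilt uniform in $[-15°, 15°]$, area
fraction in $[0.022, 0.305]$, frame 960×720 (a 4:3 photograph at reduced
resolution; rendering at native 24 MP camera resolution would add nothing to
the geometry being tested). Because the synthetic frames are deliberately
smaller than real uploads, the end-to-end pipeline test scales the QA
resolution threshold to the synthetic frame (0.5 MP) while keeping the
distance and reliability rules at their printed values; the 5 MP rule itself
is exercised separately at clinical sizes.

What the generator does *not* emulate: photographic texture, specular
reflections, skin-tone and iris-color diversity, eyelid shapes, glasses,
makeup, motion blur, or any correlation between tilt and gaze position.
Passing the pipeline tests therefore demonstrates that the geometry, QA
logic and crop are correct and self-consistent — not that the bundled
baseline detector would survive clinical images.

`detect_eyes_baseline()` is exactly that — a classical fixture, not a
learned model: adaptive dark-blob segmentation (threshold between the dark
tail and the median grey), connected components (EBImage's `bwlabel`),
area/eccentricity filtering, and pairing by size symmetry and
separation-to-radius plausibility (iris radius and inter-eye span have a
fixed ratio in the generator, and approximately in faces). Its confidence
heuristic — symmetry, roundness, contrast, separation — degrades
monotonically under occlusion, which is what lets the QA "unreliable" path
be exercised honestly.

## Problem sizes and runtime choices

The test suite runs the oracle comparisons at the sizes stated above (1,000
pairs × 2000² grid for the IOU oracle, 10,000 pairs for the loss bound, 100
pairs for the Bhattacharyya integrator, 200 scenes for the tilt-recovery
pipeline); these sizes were chosen so the full suite completes in a few
minutes on one CPU while keeping the statistical checks meaningful.
`scripts/acceptance.R` recomputes the package's headline constants in about
a second.

## Known limitations

* The skew-IOU path assumes convex (rectangular) inputs; non-convex
  polygons are out of scope.
* No gradients are provided: the losses are reference implementations of
  the objective values, not a training framework.
* On-disk image support is PNG (grey); in-memory functions accept any
  numeric matrix, so other decoders can be used upstream.
* The baseline detector is tuned to the generator's geometry; it is a test
  fixture and will not generalize to photographs.
* `dedup` and containment tolerances are absolute (units of the input
  coordinates); callers working at scales far from pixels/unit boxes should
  keep that in mind.
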