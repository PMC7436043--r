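---
title: "Measuring detrusor wall thickness from B-mode ultrasound: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring detrusor wall thickness from B-mode ultrasound: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(detrusor)
```

## The measurement problem

Bladder wall thickness (BWT), and in particular the thickness of the
detrusor muscle, is a noninvasive biomarker for bladder outlet obstruction,
detrusor overactivity and related voiding dysfunction, and it is a required
input for elastography of the bladder wall. On a transabdominal B-mode
sonogram the bladder appears as an anechoic (dark) sac bounded by an
echogenic (bright) wall; the anterior wall — the one nearest the transducer
— is where thickness is conventionally read. `detrusor` automates that
reading in two stages:

1. **Sac segmentation.** The inner boundary of the bladder is the single
   closed contour that encircles the rough bladder centre. After polar
   resampling around that centre, boundary detection becomes a minimal-cost
   left-to-right path problem, solved exactly by dynamic programming (DP).
2. **Wall tracking.** Inside a small search box centred on the mid-top of
   the sac contour, the outer and inner anterior wall boundaries are two
   nearly parallel lines. A multidimensional DP (MDP) over the joint state
   (outer row, inner row) tracks both at once, and the mean separation is
   the reported thickness in mm.

A convolutional segmenter (a compact U-Net) is provided as a faster
alternative for stage 1, and a synthetic phantom generator supplies images
with exact ground truth so every stage is testable end to end.

## Stage 1: polar dynamic programming

**Rough centre.** A 15-column band (about 3 mm) around the probe axis is
averaged into one axial intensity profile, and a 4th-degree polynomial is
fitted to it. The two interior maxima of the fit are taken as the anterior
and posterior wall depths; their midpoint is the rough centre `cP`. A
quartic has at most two interior maxima, so when the profile carries the
expected bright–dark–bright structure the two peaks are unambiguous; on
profiles without that structure (e.g. a blank or monotone image) the fit
has fewer than two interior maxima and a `center_detection_error` is
raised.

One numerical subtlety: a least-squares quartic can only take the
two-interior-maxima shape when its argument range ends reasonably close to
the posterior bright region — a long, almost-black far-field tail forces
the fitted curve into a single-hump shape regardless of the anatomy (we
verified this directly by fitting quartics to parametric profiles). Since
that tail is pure attenuation noise and carries no wall information,
`detect_center()` fits the polynomial over the *echogenic depth range*
only: leading and trailing rows below 15% of the profile maximum are
excluded (`tail_floor`). This makes the detector applicable across the
whole phantom geometry range while leaving well-behaved profiles
untouched.

**Maximum ray length.** The largest radius the sac can have, seen from
`cP`, is bounded by the sector geometry: `rB = wP/2 + |cP| tan(fov/2)`
with probe width `wP = 30` mm and field of view `fov = 60` degrees by
default. The half-angle is used in radians; a variant that applies
`arctan` to the half-angle instead is retained behind
`max_ray_length(..., variant = "arctan")` for fidelity to the formula as
sometimes printed, but the geometric tangent form is the default since it
is the actual sector half-width.

**Cost field.** The image is Gaussian-smoothed (default sigma 1 px) and
differentiated along the *outward* direction from the centre. On every ray
the lumen-to-wall transition is then a positive ridge regardless of angle
(a plain depth-axis derivative would flip sign between the anterior and
posterior walls, splitting the ridge). The gradient is resampled along 360
rays at 1-degree increments, one sample per pixel spacing out to `rB`, and
inverted (`max − value`) so that the strongest rising edge becomes the
cheapest path. Samples outside the image or the sector are assigned the
maximum cost so the path avoids them.

**The DP itself.** With columns indexed by angle and rows by radial
sample, the cumulative cost is

    C^(w, h) = min_delta [ C^(w−1, h−delta) + C(w, h) · (1 + |delta|/gamma) ]

with `|delta| <= 3` and `gamma = 20`, i.e. a 5% node-cost surcharge per
pixel of radial step — a soft continuity penalty. The first column carries
no step penalty. Closure over the 0/359-degree seam is enforced exactly:
the open problem is re-solved with the start row fixed to each candidate
row (and the final column restricted to the seam window), keeping the
feasible minimum. Because node costs are nonnegative the per-column minima
of the cumulative cost are monotone, so restarts are abandoned as soon as
they can no longer beat the incumbent; visiting start rows by ascending
first-column cost makes this pruning effective without affecting
exactness. Ties prefer smaller steps, then smaller rows, so results are
deterministic. The optimal radial path is projected back to image
coordinates and filled into a lumen mask by angular interpolation (the
contour is star-shaped about the centre by construction).

## Stage 2: dual parallel-line tracking

The anterior wall is searched in a box spanning 8 mm above to 6 mm below
the mean depth of the *anterior* contour points near the horizontal
midpoint of the sac, and 6 mm laterally (70 × 30 px at 0.2 mm/px). Within
the cropped intensity field, the smoothed depth-direction gradient `g`
scores the inner (wall-to-lumen, falling) boundary and its inversion
`g_inv = max(g) − g` scores the outer (tissue-to-wall, rising) boundary;
both are shifted to be nonnegative.

The MDP state per column is the pair (outer row `y1`, inner row `y2`) with
the separation `d = y2 − y1` restricted strictly between 1 mm and 7 mm —
the adult BWT range — converted to pixels with strict inequalities
(6…34 px at 0.2 mm/px). The node cost is `g_inv(x, y1) + g(x, y2)` and a
transition multiplies it by

    (1 + alpha1)^|delta1| · (1 + alpha2)^|delta2| · (1 + alpha3 · |dd|)

where `delta1, delta2` are the per-line steps (at most 1 px each),
`dd` is the change of separation, and `alpha1 = alpha2 = alpha3 = 0.2`:
each factor is a 20% surcharge, soft enough not to override the image
evidence but strong enough to keep the two lines smooth and parallel. The
optimum over the restricted state space is exact; ties prefer the smaller
outer row, then the smaller separation. Per-column separations times the
pixel spacing give the thickness profile, and their mean is the reported
BWT.

Because the per-column node cost reads single pixels at `(x, y1)` and
`(x, y2)` (rather than summing whole columns), the tracker localises each
boundary at the extremum of the gradient profile, which under symmetric
smoothing sits at the centre of the intensity transition — so the expected
bias of the separation is below one pixel. The noise-free recovery tests
assert exactly that.

## The U-Net alternative

The package includes a compact encoder–decoder segmenter in the classic
U-Net shape: five resolution levels with two 3×3 convolutions + ReLU per
level (ten encoder convolutions), four max-poolings, nearest-neighbour
upsampling followed by a 3×3 up-convolution and skip concatenation per
decoder level, and a final 1×1 convolution with softmax over two classes
(nine decoder convolutions). Weights are Glorot-uniform initialised,
dropout (rate 0.5) acts in the two deepest encoder levels during training,
and optimisation is Adam on a weighted categorical cross-entropy

    L = (1/n) sum_i sum_j −y_ij log(yhat_ij) w_j ,   w_j = max(n_0…n_m)/n_j ,

whose class weights counter the background/bladder pixel imbalance.
Training data can be multiplied by random elastic deformation (a smooth
displacement field drawn on a coarse control grid, applied bilinearly to
the image and nearest-neighbour to the mask; default magnitude 3 px keeps
the deformed mask at Dice ≥ 0.8 with its source and preserves the mask's
single-component topology). Cross-validation folds are formed at the
*subject* level so no subject contributes to both training and validation.

The network, its forward/backward passes and Adam are implemented directly
in R on BLAS matrix products (im2col convolutions); backpropagated
gradients are verified against finite differences in the test suite. Two
profiles are distinguished:

* the full-scale profile mirrors the published architecture at
  880 × 1068 input (padded to a multiple of 16) with 64 base feature maps
  and learning rate 1e-5 — supported, but not exercised by any test;
* the **desk-scale profile** used throughout the tests trains on
  64 × 80-px phantoms (2 mm/px) with 8 base feature maps and learning rate
  1e-3. The smaller, shallower problem needs proportionally larger steps;
  with the published 1e-5 the loss decreases but far too slowly for a
  30-epoch budget. The desk run trains a single subject-level fold in
  roughly two minutes on one CPU and reaches a held-out Dice above 0.9.

## The phantom generator: what it emulates, and what it does not

Volunteer images behind the original study are not publicly deposited, so
the package validates against synthetic sector phantoms with exact ground
truth. A phantom is an 880 × 1068 px, 0.2 mm/px curved-array sector (apex
at the top, 60-degree aperture, pixels outside the sector zeroed)
containing:

* an elliptical anechoic lumen (intensity ~10) with depth/lateral
  semi-axes `a`, `b`;
* a bright wall (intensity ~210) of exactly constant thickness `t` — the
  set of pixels within distance `t` of the lumen, built from an exact
  Euclidean distance transform; `t` is the ground truth the wall tracker
  is scored against;
* moderate surrounding tissue (~90) with an echogenic prevesical
  fat/fascia band (1.5× tissue, 5 mm) directly above the anterior wall;
* depth-dependent brightness: a near-field haze ramp (floor 0.35 over the
  first 20 mm, the unfocused zone of a curved array) and far-field
  attenuation driven by the *tissue-only* propagation path (full
  brightness up to 35 mm of tissue, linear roll-off to 0.12 over 30 mm).
  Driving attenuation by tissue path rather than raw depth automatically
  produces the posterior acoustic enhancement that real bladders show,
  because the fluid adds no attenuation;
* multiplicative Rayleigh speckle (`speckle_scale` 0.6 blends a unit-mean
  Rayleigh field toward 1) followed by a 1.5-px Gaussian blur;
* optional dropout arcs (angular ranges where the wall brightness is
  removed) and bright Gaussian clutter blobs, the knobs for "missing
  boundaries and clutter" difficulty.

The study-condition distribution used by the validation runs draws wall
thickness uniformly in 1.5–5 mm, both lumen semi-axes uniformly in
25–45 mm, and the anterior wall depth uniformly in 15–30 mm (a realistic
abdominal-wall range); the lumen centre depth follows from the anterior
depth plus whatever additional depth the sector cone needs to contain the
lumen laterally. All randomness is seeded; a fixed seed reproduces a
phantom bit for bit.

What the phantom does **not** emulate: physical wave propagation (no
point-spread function, no RF speckle statistics, no reverberation),
irregular non-elliptical bladder shapes, neighbouring organs, or the
degradation of wall brightness at small bladder volumes. Passing the
synthetic accuracy checks therefore demonstrates that the algorithms
recover known geometry under speckle, shading and blur — not clinical
performance on patient images.

## Numerical choices and degenerate inputs

* Gaussian smoothing uses an explicit separable kernel with replicate
  boundaries (no FFT wrap-around between the top and bottom of a depth
  image); sigma 0 is the identity.
* Polar resampling uses bilinear interpolation; out-of-field samples are
  flagged and costed maximally rather than dropped, so ray lengths stay
  uniform.
* The separation bounds are applied strictly (`dmin < d < dmax`) with
  integer pixel bounds `floor(dmin/s)+1` to the largest integer strictly
  below `dmax/s`.
* Tie-breaking is deterministic everywhere (smaller step, then smaller
  row; smaller outer row, then smaller separation) so repeated runs agree
  exactly.
* Degenerate inputs fail loudly: empty cost matrices, crops shorter than
  the minimum separation, contours outside the image, fewer subjects than
  folds, zero-count classes.
* The box clipped at an image border proceeds with a warning;
  centre-detection failure is a typed condition
  (`center_detection_error`) so callers can distinguish "no bladder
  found" from other errors.

## Problem sizes in the checks

The bundled checks run at sizes chosen for a laptop-class machine: the DP
and MDP are verified against exhaustive enumeration on at least 100 random
instances each (up to 6 columns and 6 or 12 rows — small enough that
enumeration is the oracle, large enough to exercise every transition
pattern); segmentation and thickness accuracy are measured on 50
full-resolution speckled phantoms; the network check trains one fold of 20
reduced-resolution phantoms for 30 epochs. The same package functions run
unchanged at larger sizes.

## Known limitations

* The centre detector presumes a bladder-like axial profile; severely
  off-axis bladders (outside the 15-column band) or multiple fluid
  collections can mislead it.
* The sac DP assumes the inner boundary is star-shaped about the centre
  (one crossing per ray); strongly folded bladder outlines violate this.
* Thickness is read only at the anterior wall, per clinical convention;
  posterior/lateral walls and the three-layer wall substructure are out of
  scope.
* The full-resolution U-Net profile is computationally untested here; the
  desk-scale profile demonstrates the training machinery, not the
  published model's capacity.
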