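---
title: "Measuring and classifying lentil seeds from uncalibrated photographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and classifying lentil seeds from uncalibrated photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lentileye)
```

## The problem

Genebank curators and in-situ custodians of lentil diversity describe an
accession by, among other descriptors, its grain size and its testa (seed
coat) pattern: absent, dotted, spotted, marbled, or complex. `lentileye`
computes both from a single photograph taken under loose conditions: seeds
scattered on a dark surface, quasi-top view, any camera, with a strip of
ordinary 1 mm graph paper somewhere in the frame. The package's assumptions
are exactly those of that acquisition style:

* seeds are approximately circular in projection and **brighter than the
  surface** they lie on;
* the graph-paper grid is visible well enough that a quorum of its squares
  can be found (this is also how focus problems are detected);
* perspective distortion is negligible (quasi-top view), so one scale factor
  per image suffices.

## Seed segmentation

Circles are found by randomized sampling: three edge pixels determine a
circumcircle (`circumcircle()`), and a candidate is accepted when the edge
set supports enough of its circumference. Edges come from a Canny detector
with the adaptive rule `low/high = 0.66/1.33 × median(gray)` — on a
seeds-on-dark-surface frame the median is the surface, so the thresholds
scale with exposure.

Several details of the randomized search are deliberate choices where the
method description leaves room, and they matter in practice:

* **Support is arc coverage, not an inlier count.** `support_fraction` is
  the fraction of ~3 px circumference sectors containing at least one inlier.
  A simple inlier count is inflated by dense point clusters (seed texture)
  and by chords; arc occupancy is a literal reading of "fraction of the
  circumference covered by edge pixels". The default acceptance threshold
  0.6 tolerates a missing quarter-arc (an occluded or defocused rim scores
  ~0.75) while random alignments stay far below.
* **Inliers must point at the centre.** Because seeds are bright on dark,
  the intensity gradient on a true rim points toward the circle centre.
  Inliers must satisfy this within 45°. This is the single most effective
  guard against false circles threaded through dot-patterned coats, where
  tangent alignments otherwise mimic support.
* **Neighbourhood sampling.** The second and third sample points are drawn
  from the 500 nearest neighbours of the first; uniform triples almost never
  land on one rim once several seeds share the frame.
* **Minimum evidence.** An acceptance needs at least `min_edge_pixels`
  (default 50) inliers — the same knob the method's authors describe using
  to avoid false circles, at the price of missing small or badly defocused
  seeds.
* **Refinement and suppression.** Accepted candidates are refined by up to
  three rounds of least-squares (Kasa) fitting on their inliers, which is
  what delivers sub-pixel accuracy; supporting *and interior* points are
  then removed (interior texture edges belong to the found seed); a new
  acceptance within half a radius of an old one merges (higher support
  wins), and an earlier small acceptance whose centre falls inside a later,
  larger one is dropped as a texture artefact.

Two plausibility filters follow, in the pipeline order *radius check, then
radiometric check*. The radius check discards radii outside mean ± 2 sd
within the image. Note a small-sample caveat asserted in the tests: with
very few circles a gross outlier inflates the standard deviation enough to
pass its own band (e.g. radii {50, 51, 49, 200} keep the 200); at realistic
per-image seed counts the same outlier is caught. A single circle is always
retained — no spread can be estimated from one sample.

The radiometric check discards circles whose interior holds more than 10%
background pixels. "Background" is decided by a **two-stage Otsu
threshold**: the first split separates bright content (seeds, graph paper)
from the dark class; the second split, within the dark class, separates the
true surface from dark testa patterns. A single global Otsu would label the
dark patterns of dotted/complex/marbled coats as background and discard
exactly the seeds the classifier most needs; when the dark class is too
uniform to split, the first threshold is used as-is.

`run_image()` additionally masks the located graph-paper strip out of the
edge map before detection: the grid supplies thousands of edge pixels that
buy nothing but false-candidate budget, and small circles found inside the
*bright* strip would not be removed by the (dark-) background check.

## Scale calibration

Grid cells are binarized with Otsu's threshold, labelled 4-connected, and
their outer contours followed and simplified (Ramer–Douglas–Peucker) to
polygons; only 4-vertex polygons with near-equal sides (max/min ≤ 1.3) and
near-right corners (|cos| < 0.3) survive. Each polygon side is compensated
by +2 px — half the separating grid line at both ends — so the measurement
is the line-centre-to-line-centre pitch. All 4n sides are histogrammed in
1 px bins and EDV is the mean of the sides in the modal bin ± 1 bin, which
shrugs off merged or broken contours. A quorum of 10 squares is required;
failing it raises a calibration-unavailable condition that `run_image()`
converts into an "unfocused" warning with sizes omitted.

One deliberate interpretation: the reported seed size is the **diameter**
`2 · r̄ · S`. The method's worked arithmetic only closes under this reading
(146 px mean radius at 56.64 px/mm → 5.16 mm), although its notation calls
the quantity a radius. Rounding happens only at presentation; `S` itself is
kept at full precision (1/56.64 = 0.0176554; the commonly printed 0.01765
is a truncation).

## Texture features and classification

Each retained circle yields a square patch of side one diameter with a
circular mask. The descriptor is 18 + 180 = 198 numbers:

* the rotation-invariant uniform LBP histogram with P = 16 neighbours at
  radius R = 2 (P + 2 = 18 bins — this is the standard variant whose
  histogram has length 18), computed on the BT.601 grayscale patch with
  bilinear sampling; pixels whose neighbourhood crosses the mask are
  skipped; an epsilon of 10⁻⁶ in the ≥ comparison absorbs floating-point
  noise in bilinear weights so flat regions land entirely in the 16-ones
  bin;
* three 60-bin colour histograms over [0, 255], masked pixels only, each
  block L1-normalized (normalization is our choice; the source is silent —
  it makes blocks comparable across patch sizes).

The three-group classifier (*rare / sparse / dense*) is a gradient-boosted
tree ensemble with a softmax objective, implemented in the package (depth 4,
200 rounds, learning rate 0.1, L2 penalty 1). Training is deterministic —
no row or column subsampling — so reproducibility needs no seed gymnastics;
ties in prediction break toward the earlier class in the fixed order
rare < sparse < dense. Class imbalance is left unweighted by default,
mirroring how such collections actually look (the dense class is rare);
`weights` enables the alternative. Evaluation offers true leave-one-out,
k-fold (the fast default), and leave-one-group-out (e.g. one image out);
the protocol used is recorded on the returned confusion matrix.

## Morphological subclassing

The second step runs the fixed sequence: Canny edges inside an eroded mask
(the rim erosion, 4% of the patch side and at least 3 px, keeps the seed's
own outline out of the statistics), closing with a rectangular structuring
element (3 × 5 at a 300 px reference side, scaled proportionally), hole
filling, connected components, contour following, area computation.
A region is *significant* at ≥ 0.5% of the masked area; coverage is the
significant area over the masked area. Decision rules: rare with no
significant region → absent, otherwise spotted (`spotted_min_regions = 1`:
any significant blob on an otherwise plain coat is a spot); sparse with
coverage strictly above 0.5 → complex, else dotted; dense → marbled,
unconditionally and with no recovery path.

The edge thresholds here are **not** the scene rule: inside a patch the
median *is* the bright coat, so 0.66/1.33 × median would sit above every
pattern edge. We use 0.2/0.4 × masked median, which clears sensor noise by
an order of magnitude while keeping pattern boundaries.

## The synthetic world

`generate_scene()` renders what the acquisition style describes: a dark
surface (gray 20), a graph-paper strip (ground 230, dark 1 px grid lines at
the stated pitch) across the top, and anti-aliased textured discs with
Gaussian pixel noise (sd 4) everywhere so nothing is degenerate. The five
texture generators are parameterized to satisfy the verbal class
definitions measurably: spotted draws 1–4 localized interior blobs; dotted
many small dots totalling ~10–15% of the coat (far below the 50% line);
complex accumulates large interior blobs until coverage strictly exceeds
0.62 by construction; marbled modulates the whole coat with a
low-frequency stain field. Every disc's interior exceeds the surface by at
least 60 gray levels, so the radiometric check always has contrast to work
with.

What a green test therefore establishes: geometry recovery (centres, radii,
pitch) at realistic noise, the correctness of every formula and decision
rule, and that the feature/classifier stack separates patterns *of this
synthetic kind*. What it does not establish: performance on real seed coats
(whose texture statistics, gloss, shadows and defocus are richer), on
perspective-distorted or unevenly lit frames, or with real annotation
noise. The bundled reference confusion matrices cover the published
real-data benchmark numbers; reproducing those tables' metrics is an exact
arithmetic check, not a re-run of the study.

## Numerical choices and degenerate inputs

* Coordinates are 0-based, x = column, y = row; centres and radii are
  floats.
* Collinear sample triples (twice the triangle area below 10⁻⁹ of the
  squared coordinate scale) raise a degenerate-geometry error and are
  simply skipped by the sampler.
* An empty edge map, an empty scene, or an empty manifest are valid inputs
  with empty outputs; a fully uniform image has no edges by construction
  (thresholds are floored above zero).
* Otsu's criterion is flat across an empty histogram gap; the threshold is
  the middle of the maximizing plateau, not its left edge, which keeps a
  symmetric margin between well-separated modes.
* F1 with a zero denominator is defined as 0; balanced accuracy refuses
  zero-support classes by name. `round_half_up()` exists because printed
  benchmark numbers use conventional half-up rounding and R's `round()`
  does not; the `round_recalls_first` flag on `balanced_accuracy()` exists
  solely to reproduce how such benchmarks are commonly printed.
* Model serialization uses R's native format plus a JSON metadata sidecar;
  predictions are bit-identical across a round trip.

## Limitations

* The +2 px square-side compensation assumes thin (~1 px) grid lines; very
  thick lines at low resolution would bias EDV slightly low.
* The gradient-direction check assumes bright seeds on a dark surface; the
  detector degrades gracefully (but noticeably) on inverted-contrast
  material.
* The subclass step is rule-based by design; a marbled seed misrouted to
  rare/sparse in step 1 cannot be recovered in step 2.
* True leave-one-out with hundreds of patches retrains hundreds of
  ensembles; it is provided for fidelity, but k-fold is the practical
  default and the one used in continuous testing.
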