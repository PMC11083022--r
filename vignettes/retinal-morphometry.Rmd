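---
title: "Retinal vascular morphometry with retvasc: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retinal vascular morphometry with retvasc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retvasc)
```

`retvasc` quantifies retinal microvascular geometry from a fundus
photograph plus two segmentation masks (artery/vein labels and the optic
disc), and turns the measurements into a reference-range risk flag that
can be AND-combined with an external classifier verdict. This vignette
is the package's own account of the science: what each stage assumes,
which knobs matter, what the synthetic phantoms do and do not emulate,
and where the genuinely open design choices were resolved.

## Pipeline and assumptions

The pipeline runs in a fixed order: enhancement chain, optic-disc
geometry and zones, per-class vessel graph extraction, morphometry,
risk. Everything is deterministic — there is no unseeded randomness
anywhere, and identical inputs serialize to byte-identical reports.

The central assumption is that segmentation is solved upstream: the
artery/vein mask is trusted as given (labels 0/1/2), widths are geometric
properties of the mask, and image intensities are used only for
enhancement and for the intensity term of vessel ranking. Consequences:
segmentation errors propagate directly into widths, and no measurement
is sub-pixel with respect to the mask boundary.

## Enhancement chain

Border masking thresholds the per-pixel channel maximum (default 10/255;
the threshold is a free parameter because 8-bit fundus borders are not
perfectly black), keeps the largest connected bright region and fills
its holes. Contrast-limited adaptive histogram equalization is applied
to the green channel only — the channel with the strongest
vessel/background contrast in fundus photography — with clip limit 1.0
and a 25×25 tile grid, then the equalized channel is multiplied by 0.8.
That factor darkens; it is applied as stated in the protocol this
package follows rather than "corrected". Blue and red channels pass
through untouched, and the final step is a 256-entry gamma lookup
`v -> round(255 (v/255)^(1/gamma))` with gamma defaulting to 1.2
(mildly brightening mid-tones; the source protocol leaves its value
unstated, so it is exposed in `preprocess_config()`).

A practical note: the equalizer requires image dimensions divisible by
the tile grid, so the green channel is padded by edge replication and
cropped back. A zero-dynamic-range channel is passed through unchanged
(a clipped flat histogram equalizes to the identity), which also defines
the fixture used in the tests: a uniform field of 128 must come back as
`round(0.8 * 128) = 102` inside the field of view.

## Optic-disc zones

The disc margin is modelled as the equivalent-area circle of the OD mask
(centroid centre, radius $\sqrt{A/\pi}$) — the mask is a free-form blob
and the margin definition is otherwise under-determined. Measurement
annuli in optic-disc diameters (ODD) beyond the margin: zone A covers
0–0.5 ODD, zone B 0.5–1 ODD, zone C 0.5–2 ODD. Zones B and C deliberately
overlap (both start at 0.5 ODD) — that is how the zone convention is
stated, and it is implemented as printed. Radial intervals are half-open
`[inner, outer)` so that A and B partition their union; boundary pixels
belong to the outer zone. Caliber summaries (CRAE/CRVE) default to zone
B, the convention of the Knudtson framework; this is a documented
convention, not a fact of the source protocol, and is configurable
(`run_config(caliber_zone = ...)`).

All coordinates are 0-based (row, col) conceptually, 1-based in R's
indexing; distances are Euclidean pixel distances. Widths can be scaled
to microns by `microns_per_pixel` at reporting time; no other micron
calibration exists.

## Vessel graphs

Each class's pixels are thinned to a one-pixel centerline with Guo–Hall
thinning. The choice is deliberate: two-subiteration schemes of the
Zhang–Suen family leave deletion-invariant two-pixel staircases on some
diagonal bands, which fragment the graph; Guo–Hall thins those cleanly,
and a sequential simple-point pass removes any residual thick spots.
Skeleton pixels with a neighbor count other than two become nodes
(adjacent node pixels are clustered), maximal chains between nodes
become edges, terminal spurs shorter than 5 px are pruned iteratively,
and pass-through nodes with exactly two incident chains (staircase
corners) are contracted away. Eight-connectivity throughout.

Arc length of a pixel chain systematically overestimates the underlying
curve (staircase effect), so path length is measured on a lightly
smoothed copy of the chain — a five-point moving average whose endpoints
stay fixed. Fixed endpoints guarantee `path >= chord`, keep straight
chains exactly straight, and the smoothing window is far below the
curvature scale of retinal vessels, so arc-length bias drops well below
one percent. One consequence, verified in the tests: the medial axis of
an $L \times h$ rectangle has an axial segment of length $L - h$, not
$L$ — thinning erodes half the width at each end, and measured lengths
reflect that.

Cross-sectional width at a centerline sample follows the minimum
opposite-edge-distance rule: rays march from the sample at every
`angle_step` degrees (default 1°) in both directions, in 0.5-px steps up
to `max_r` = 50 px, and the width is the minimum over angles of the
distance between the two opposite edge points. Two numerical choices
matter. First, an edge is declared at the first of *two consecutive*
background samples: a lone background cell clipped diagonally by a ray
is a rasterization notch in the band boundary, not the outside, and
accepting it biases the minimum low by more than a pixel at unlucky
orientations. Second, widths are sampled every 3 centerline px and
samples within 2 px of a junction node are discarded (junction blobs
inflate cross-sections). With these choices, rendered bands of width
5–12 px are recovered within ±1 px at all orientations tested.

At degree-3/4 nodes, each incident segment's local width is the median
of its samples within 12 centerline px of the node (the 2-px exclusion
zone plus 10 px of usable profile). The widest incident segment is the
parent — the protocol never says how to identify the parent, so the
alternative rule (the segment whose far end is nearest the optic disc)
ships behind `run_config(parent_rule = "od_proximal")`. Degree-5+ nodes
are outside the analyzed arity and skipped.

Vessel ranking scores each segment by
`0.4 norm(length) + 0.2 norm(contrast) + 0.3 norm(width) + 0.1 norm(connectivity)`
and keeps the top six per class. The weights are configuration, not
measurements; ties break by longer path, then top-left coordinate, so
ranking is reproducible. Contrast is the green-channel deficit of the
centerline against the in-field median; connectivity is constant for
uninterrupted chains (all chains produced by the tracer are
uninterrupted, the term exists for masks with breaks).

## Morphometry

Junction metrics (branching coefficient, junction exponent, optimality
ratio, diameter reduction) and their formulas are given in the README.
Two deserve comment:

* The junction "exponent" is implemented exactly as the printed cubic
  difference $r_0^3 - \sum r_i^3$, in px³ — despite the name it is a
  deviation-from-Murray's-law measure, not an exponent. The classical
  exponent $x$ with $r_0^x = \sum r_i^x$ is additionally reported
  (`junction_exponent_classical()`, root-bracketed on [0.5, 10]) so the
  two interpretations can be compared; the printed form is primary.
* Diameter reduction is only verbally specified in the source; the
  formula fixed here is $1 - \mathrm{mean}(r_i)/r_0$ — dimensionless,
  zero for no change, positive for narrowing, negative (reported, not
  clamped) for widening.

Tree path statistics treat each connected component as a rooted tree.
Cycles (segmentation artifacts) are broken by a maximum-weight spanning
forest, which removes the shortest edge of each cycle and flags the
report. The root is the node nearest the optic disc, or an endpoint of
the component's longest segment when no disc is supplied.

The Knudtson pairing sorts the (at most six) widths, combines largest
with smallest as $f\sqrt{w_1^2+w_2^2}$, carries the median of an odd
round unpaired, and iterates to a single value; $f$ is 0.88 for arteries
and 0.95 for veins. For six equal widths $w$ the closed form is
$f^2 w\sqrt{4f^2+2}$, the oracle frozen in the tests (17.48434 and
21.37607 at $w=10$; their ratio 0.81794 is the AVR of identical artery
and vein trees). A single available vessel is returned as-is with an
"insufficient vessels" flag. Caliber widths are the per-segment mean of
width samples inside the caliber zone, falling back (flagged) to the
whole-segment mean for ranked segments that never enter the zone.

Box counting uses grids of side $s$ in powers of two from
$\lfloor \min(h,w)/4 \rfloor$ down to 2, anchored at the image origin
(no multi-offset averaging — the counts are then exactly
translation-invariant for shifts that are multiples of every box size,
which the tests exploit), and $D$ is the least-squares slope of
$\log N(s)$ on $\log(1/s)$. The dimension is computed on the filled
vessel mask of both classes combined — self-similarity of the
vasculature, not of its skeleton — with `fd_on = "skeleton"` available.

## Risk flagging and scoring

The differentiator parameters are CRAE, AVR and mean artery width — the
measurements that separate cardio from healthy cohorts. A parameter
verdict is `cardio_suspect` when any of them falls inside its risk
interval; an `all` rule is available because the boolean combination
over the three parameters is not fixed by the source. Reference
intervals are deliberately not defaulted: population bands depend on
camera, resolution and cohort, and the published band figures are not
numeric. Users load clinically sourced intervals from JSON.

The combined verdict is a strict AND: cardio suspect only when both the
parameter branch and the external classifier branch agree, which
minimizes false positives at the cost of sensitivity. Without a
classifier verdict the parameter flag stands alone and is flagged
"single-branch". Subject-level aggregation over two eyes is an OR
(either eye suspect makes the subject suspect) — a documented choice,
the source being silent.

Confusion-matrix metrics are defined operationally: sensitivity
$100\,tp/(tp+fn)$, specificity $100\,tn/(tn+fp)$, accuracy, precision,
F1 from unrounded precision and recall, reported at two decimals. On the
published validation cells (28, 5 / 4, 29) these give 87.5, 85.29,
86.36, 86.15 — note that the narrative labels of those four numbers
disagree with their table (87.5 is the sensitivity by its own cells, not
the accuracy); the operational definitions here follow the cells.

## Synthetic phantoms

`random_phantom_spec()` draws the study layout: a 512×512 canvas,
optic-disc radius 40 px at the centre, six arteries and six veins
radiating at roughly 30° spacing (±8° jitter), widths uniform on 5–12 px,
sinusoidal centerlines with amplitudes 0–20 px and periods 150–300 px,
extending 2.5 ODD from the margin; optional bifurcations (daughters 7
and 5 px at 25–40° from the tangent) on two vessels per class. These
sizes emulate the geometry of an optic-disc-centric fundus photograph at
the native resolution of the measurement code; they were fixed once as
the package's study conditions. Vessels carrying junctions use odd
integer widths, because a rasterized band of even width has no single
well-defined integer width at all phases and ±1 px junction ground truth
would otherwise be ill-posed.

Ground-truth validity requires that distinct vessels never touch:
specs are therefore rejection-sampled (seeded, hence deterministic) —
a candidate vessel is redrawn until its centerline keeps a gap of the
two half-widths plus 2 px from every placed vessel over its whole
course, with a straight radial fallback. Truth tortuosity and path
length come from quadrature on the generating curve, not from any
rasterization.

The image renders vessels darker than a radially shaded background
(fundus vessels absorb light), brightens the disc, and adds seeded
Gaussian noise to the image only — masks are noise-free by construction.
What phantoms do **not** emulate: segmentation error (masks are exact),
pathology (hemorrhages, exudates), central reflex, crossing artery/vein
geometry, or photorealistic texture. Passing the recovery suite
therefore demonstrates that the measurement engine is correct on clean
segmentations; it says nothing about robustness to segmentation noise,
which is upstream of this package by design.

Recovery tolerances used in validation: widths within 10% for generating
widths ≥ 5 px; tortuosity within 0.02 of quadrature truth (tortuosity is
a percent-excess-length measure, so this is "within two points" — a
strictly relative bound on a value of order 0.1 would demand sub-0.1%
arc length accuracy from a pixel chain, beyond any pixel-resolution
method); junction widths within ±1 px. Measured margins on the default
suite of twenty phantoms are several-fold inside all three bounds.

## Problem sizes and limitations

The test and acceptance suites run twenty 512×512 phantoms (about 5 s
each single-threaded) plus closed-form fixtures; these sizes were chosen
to exercise every code path at the package's native scale. Known
limitations, beyond the phantom realism above:

* Widths are mask-geometric; no sub-pixel edge localization from image
  intensities, so all width statements carry ±1 px discretization.
* Even generating widths rasterize to bands whose apparent width
  alternates between the two adjacent integers with phase.
* Zone-resolved junction metrics can be noisy when few junctions fall
  inside a zone; the report carries junction counts so users can judge.
* The fractal dimension of a finite, few-decade box-count curve is a
  regression slope, not an asymptotic dimension; values for thin
  structures on small canvases sit slightly below their similarity
  dimension (the 243-px Sierpinski fixture measures ≈ 1.56 against
  log 3 / log 2 ≈ 1.585).
* The external classifier branch is an input flag; no image
  classification happens in this package.
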