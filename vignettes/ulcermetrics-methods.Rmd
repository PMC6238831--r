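---
title: "Methods: wound measurement from flash-lit foot photographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wound measurement from flash-lit foot photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ulcermetrics)
```

## The measurement problem

Diabetic foot ulcers heal over weeks to months, too slowly for change to
be visible to the naked eye between dressing changes. The clinically
useful signal is the *area trajectory*: if the wound area has shrunk by
more than 50 % within the first 4 weeks of care, healing is on track;
if not, the care plan deserves review. `ulcermetrics` turns a phone
photograph of the sole of the foot into that trajectory.

The imaging protocol the package assumes is deliberately constrained,
because the constraints are what make a phone photograph measurable:

* the **flash illuminates the foot while the background stays dark**,
  which guarantees a bimodal luminance histogram and makes global
  thresholding reliable;
* a **solid green circular sticker of 1 cm diameter** is on the skin,
  providing the only metric reference in the scene;
* the camera looks at the sole roughly head-on (top-down capture), so a
  single isotropic pixels-per-cm factor is adequate and no perspective
  correction is attempted.

## Pipeline

### Scale from the fiducial sticker

Green pixels are classified by a pure per-pixel rule,
`G > 1.3R` and `G > 1.3B` and `G >= 60` on 8-bit values. The ratio
constants reject skin tones (which are red-dominant) and the dark
background (which fails the absolute floor); they are exposed in
`pipeline_config()`. Candidate components (8-connectivity) must have at
least 50 px — a 1-cm sticker smaller than that would put the whole
measurement below a usable resolution anyway — and circularity
`4 * pi * A / P^2 >= 0.7`.

The perimeter `P` deserves a note. We count the unit edge segments
between component and non-component pixels, which is deterministic and
orientation-free, but for a digitized disc this axis-aligned count
approaches `8r` rather than the Euclidean `2 * pi * r`; plugging `8r`
into the circularity formula caps a perfect disc at
`pi^2/16 ≈ 0.62`, which would reject every clean sticker. We therefore
apply the Cauchy–Crofton factor `pi/4`, the standard correction from
axis-aligned boundary length to Euclidean perimeter of a convex
digitized shape, after which a clean disc scores ≈ 1 and the 0.7
threshold tolerates moderate raggedness. The stored circularity is
clamped to `[0, 1]`.

The sticker diameter is the equivalent-circle diameter
`2 * sqrt(A / pi)` of the surviving component, not a fitted circle: the
area statistic is robust to the ragged single-pixel edges rasterization
produces, and it is the single diameter definition used everywhere.
Since the physical diameter is 1 cm, `pixels_per_cm` equals that
diameter. Two surviving components with areas within 20 % of each other
are reported as ambiguous rather than silently picking one.

### Foot silhouette

Luminance is the Rec. 601 weighting, computed as
`(299R + 587G + 114B) / 1000`. The integer-weighted form matters: it is
exact for gray pixels, so two pixels with equal channel values have
*exactly* equal luminance and relief, and the watershed's deterministic
tie-breaking (below) is not scrambled by floating-point dust.

The threshold is Otsu's method on the 256-bin histogram (smallest
argmax on ties), chosen over a fixed cut because the capture protocol
only guarantees relative contrast, not absolute levels. A single 3×3
morphological opening suppresses salt noise before the largest
component is kept; enclosed holes are then filled, which is not
cosmetic: the ulcer is typically darker than skin and would otherwise
fall out of the silhouette, leaving the ulcer/foot area ratio with an
inconsistent denominator. A largest component under 2 % of the frame is
treated as "no foot".

### Scribble-seeded watershed

Fully automatic ulcer detection is a non-goal; instead the user draws
two rough strokes, one around the ulcer on intact skin and one inside
it. Stroke points are joined by Bresenham lines into a marker grid
(skin = 1, ulcer = 2); overlapping strokes are an error rather than a
guess.

The relief is the luminance-gradient magnitude
`g(p) = max over 4-neighbors q of |L(p) - L(q)|` — the minimal faithful
choice for a morphological watershed when nothing more specific is
known about the imaging chain. Segmentation is a marker-seeded priority
flood: initialize a queue with the unlabeled 4-neighbors of all marker
pixels (raster scan; neighbor order up, down, left, right), then
repeatedly pop the lowest-relief pixel — **FIFO among equal relief, by
insertion order** — assign it the label of the pixel that enqueued it,
and enqueue its unlabeled neighbors. Watershed output is otherwise
ill-defined on plateaus; the FIFO rule makes it bit-reproducible, which
is why the compiled implementation can be tested for *identity* against
a literal brute-force oracle (a list scanned for its minimum at every
pop) on random grids. Ridge pixels are not kept as a separate label:
the app needs a filled area, so every pixel joins the region that
reaches it first. Pixels outside the foot mask are pre-assigned the
skin label, so the ulcer cannot leak into the background, and marker
pixels always keep their seeded label.

The boundary shown to the user is a Moore-neighbor trace of the ulcer
mask, clockwise from the topmost-then-leftmost pixel, closed, painted
as pure green `(0, 255, 0)` on a copy of the photo.

### Metrics, trajectory, assessment

A measurement records the date, ulcer and foot pixel areas, the scale,
`ulcer_area_cm2 = A_px / ppc^2` and `area_ratio = A_ulcer / A_foot`.
The ratio needs no scale estimate at all and is invariant to uniform
rescaling of the scene — a useful cross-check on the cm² number.

The assessment takes the **earliest** measurement as baseline (the
clinical marker is anchored to the start of care, not to the best
value), looks for the measurement nearest to baseline + 28 days within
±3 days (nearest wins, earlier wins ties — a weekly photo habit lands
on day 28 exactly, and the window absorbs a missed day or two), and
declares `on_track` iff the percent reduction strictly exceeds 50.
Window and threshold are configurable; the strict inequality at exactly
50.0 % is deliberate and tested.

Reminder scheduling is the smallest `k >= 1` with
`anchor + k * interval > now`: querying exactly at a due time returns
the *next* one, so a notification is never re-issued for a moment that
has already passed.

### Capture guidance

The phone lies on the floor, camera up; the patient hovers the foot
above it. A silhouette that fills too much of the frame means the foot
is too *close* — the instruction is HIGHER. This mapping is the one
genuinely open design choice in the module (the sensor geometry fixes
it once stated) and is covered by tests. The decision order is: no foot
→ NO_FOOT; fraction above the band → HIGHER; below → LOWER; centroid
off-center beyond tolerance → CENTER; otherwise HOLD until
`stability_frames` consecutive compliant frames trigger CAPTURED, at
most once per session, any non-compliant frame resetting the counter.

Defaults: fraction band 0.25–0.45 (large enough for resolution, small
enough that toes are never clipped at the frame edge), center tolerance
10 % of the smaller image dimension, 3 stability frames (~a second of
steadiness at typical preview rates). These are engineering defaults,
not clinically derived values.

## The synthetic fixture generator

The generator renders what the segmentation stages *assume*: an
elliptical bright foot (luminance 200 by default) on a dark background
(15; the generator enforces a contrast of at least 80), a polygonal
ulcer of darker red, a green sticker disc on intact skin at least 10 px
from the ulcer, optional per-pixel Gaussian noise and a linear
illumination ramp. Masks are captured before noise and ramp, so ground
truth is exact. Rasterization is the pixel-center even-odd rule with a
half-open boundary convention, making axis-aligned shapes exact (a
40 × 40 px square is exactly 1600 px) and keeping analytic vs.
rasterized polygon area within 3 % for shapes of ≥ 400 px. All
randomness flows from one integer seed per scene; generation is
bit-deterministic.

Healing series scale the ulcer polygon about its centroid so the
analytic area follows `A0 * (1 - f)^w` at weeks `w = 0 … n`; capture
sweeps project the foot through a pinhole model (`size_px =
focal_px * size_cm / height_cm`), so silhouette area falls strictly
with height.

At the default scale (40 px/cm) the rendered "foot" is only ~5 × 7 cm —
a desk-scale miniature, chosen so sticker, ulcer and foot coexist in a
240 × 320 frame that keeps the full test suite fast. Since every
quantity the pipeline reports is relative to the sticker scale, the
miniature does not change what is being validated.

What the generator does **not** emulate — and what passing tests on it
therefore cannot show — are skin texture, specular flash highlights,
shadows, motion blur, oblique views, dressings or partially occluded
stickers, and wound beds whose color blends into surrounding skin. On
real photographs the watershed quality depends on a luminance edge at
the wound margin; the fixtures guarantee one. The package's accuracy
numbers are statements about the algorithmic contracts, not about
clinical photographs.

## Numerical choices

* Coordinates are `(row, col)`, 1-based, origin top-left, everywhere —
  scribbles, contours, centers. One convention, no off-by-one
  ambiguity, and it is the native indexing of R matrices.
* Otsu ties resolve to the smallest threshold; component labels are
  assigned in raster-scan order; the watershed tie rule is FIFO by
  insertion order — every tie in the pipeline has a stated winner.
* Degenerate inputs have defined behavior: an empty ulcer mask measures
  0 cm² (healed) with an empty contour; a zero-area baseline is an
  error for the percent curve; a contrast-free image is "no foot"; a
  session may end without capture.
* The sticker's green mask is unaffected by noise up to σ ≈ 10 because
  the dominance margins of the fixture colors are many standard
  deviations wide; scale-recovery robustness at that noise level is a
  property of the classifier's margins, not of any smoothing.

## Problem sizes

The shipped tests and the acceptance script use 240 × 320 px scenes: 50
scenes per segmentation property (sticker radii swept over 10–60 px),
101 watershed-oracle grids (8 × 8), 50 end-to-end fixtures, 5-point
weekly healing series, 30-frame guidance sweeps. These sizes give the
property estimates comfortable margins while keeping a full run in the
tens of seconds on a single CPU; all of them scale up by changing one
constant if finer estimates are wanted.

## Known limitations

* No perspective or tilt correction; an oblique capture biases both the
  scale (elliptical sticker) and the area.
* One connected ulcer per analysis; satellite lesions need separate
  scribbles and are not merged.
* The foot "size" in the ratio is silhouette *area*; if a clinic
  prefers foot length as the normalizer, the ratio is not comparable.
* Guidance thresholds are symbolic-engineering defaults; they have not
  been validated against human ergonomics.
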