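---
title: "Methods: tilt-calibrated single-plant maize phenotyping"
author: "phenomaize"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tilt-calibrated single-plant maize phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomaize)
```

phenomaize measures a single maize plant from one hand-held RGB photograph
taken against a dark backdrop. This vignette explains the models and
numerical choices behind each stage, what the built-in synthetic validation
does and does not show, and the limitations a user should know about.

## Tilt calibration from device angles

A hand-held shot is neither level nor orthographic. Two accelerometer
angles describe the pose: the depression angle $\alpha$ (between the screen
normal and the horizontal plane) and the rotation angle $\gamma$ (between
the screen y-axis and the zenith). The raster is first rotated by
$-\gamma$; the remaining vertical foreshortening is removed with a
marker-free perspective correction.

For a pinhole camera with half vertical field of view $\beta_{max}$ and
half vertical resolution $h_{max}$, a pixel $h'$ above the center row is
seen under the view angle $\beta = \arctan(h' \tan\beta_{max} / h_{max})$.
Projecting the image plane onto the vertical object plane through the
plant divides out two tilt factors: vertically
$y = y'\cos\beta / \cos(\alpha - \beta)$ and horizontally
$x = x'\cos\alpha \cos\beta / \cos(\alpha - \beta)$, with $\beta$ signed so
the lower image half picks up $\cos(\alpha + |\beta|)$. Substituting
$\tan\beta = y'/D$ with $D = h_{max}/\tan\beta_{max}$ shows the map is
*exactly projective*:
$(x, y, 1) \propto (\cos\alpha\, x',\; y',\; \cos\alpha + \sin\alpha\, y'/D)$.
`build_depression_map()` therefore synthesizes the four image-corner
correspondences and fits a 4-point homography, which reproduces the
analytic map to machine precision everywhere — no root finding, no
markers. At $\alpha = 0$ the map is the identity and the center row is
fixed for every $\alpha$.

Choices worth stating:

* **Sign convention.** Published treatments leave the sign of $\alpha$
  ambiguous; here the forward renderer (`render_tilted()`) and the
  calibration use the same convention, and correctness is established by
  round trip: rendering a flat plant at $\alpha \in \{10°, 15°, 20°\}$ and
  calibrating back recovers the mask with IoU $\ge 0.98$ and bounding-box
  height error $\le 0.5\%$ (the acceptance script recomputes this).
* **$\beta_{max}$** comes from the sidecar metadata; the default of 33° is
  typical for a phone main camera.
* **Resampling** is inverse-mapped bilinear with black fill, matching the
  dark-backdrop assumption downstream. Degeneracy
  ($\cos(\alpha-\beta) \le 10^{-6}$) raises an error.
* Rotation is applied before the depression correction; the small coupling
  between the two angles at hand-held magnitudes (a few degrees of roll)
  is ignored.

## Segmentation

The default segmenter is classical: excess green $ExG = 2G - R - B$,
Otsu's threshold, morphological opening (3×3) then closing (5×5), largest
8-connected component (plus components at least 5% of its size, to
tolerate occlusion-severed leaves), and hole filling below 200 px. A mask
produced elsewhere — e.g. by a semantic segmentation network — can replace
this stage via `load_external_mask()`, which takes the file verbatim; the
provenance tag travels into the trait CSV.

Colour enhancement (`enhance_color()`) runs before thresholding: a
gray-world white balance followed by a 1–99 percentile contrast stretch
computed **jointly** over the three channels. The joint stretch is
deliberate: a per-channel stretch on a dark-backdrop scene places each
channel's upper percentile at the plant's own level, saturating all three
and erasing the very colour difference ExG needs (measured on the
synthetic fixtures, it costs ~0.27 IoU under moderate sensor noise).

The evaluation harness (`evaluate_mask()`, `segmentation_report()`)
computes precision, recall, F1 and IoU, with 0/0 reported as undefined
rather than 0, so users with annotated data can replicate the standard
protocol. Note the 3×3 opening erodes structures thinner than the kernel;
on leafy synthetic plants this costs a few percent recall at the leaf
tips, which is why the package's own robustness tests assert IoU ≥ 0.90
under noise rather than a higher bound.

## Two-step distance-transform skeletonization

The medial axis drives all length traits. The algorithm ranks every
foreground pixel by how many of its 8 neighbours have a strictly smaller
exact Euclidean distance-transform value (the image border counts as
background). Pixels beating ≥ 3 neighbours form the seed set $S_3$; pixels
beating ≥ 2 form the looser routing pool $S_2 \supseteq S_3$. Seed
fragments are then connected through the pool by lowest-cost paths, where
stepping onto pixel $q$ costs $1/(1 + DT(q))$ (scaled by step length,
$\sqrt 2$ on diagonals), so connectors follow the ridge. When several
fragments exist, a minimum spanning tree over their pairwise ridge
distances decides which paths to add; if the pool cannot connect fragments
that share a foreground component, routing falls back to the full
foreground with a warning.

Numerical points:

* With float-valued exact Euclidean distances, ties are rare and $S_3$
  covers most of the interior of wide organs, with scattered non-member
  pixels inside. Those pinholes would survive topology-preserving thinning
  as spurious loops, so holes of the seed/connector union lying wholly
  inside the mask are filled first. Genuine mask holes are left open:
  an annular mask still yields a skeleton cycle (tested).
* The union is reduced to a curve by conditional thinning: vectorized
  two-subiteration passes (which preserve 8-connectivity and never remove
  endpoints) followed by a sequential simple-point polish, ordered by
  ascending distance value, that deletes redundant staircase corners. The
  result is a minimal 8-connected curve: degree ≥ 3 occurs only at true
  junctions, which the organ decomposition relies on.
* Spur pruning removes endpoint branches shorter than
  $\max(\text{min\_len}, 1.5 \times DT(\text{junction}))$ — twigs caused by
  boundary bumps are on the order of the local half-width. The floor
  (default 10 px at a 2000-px reference height) scales with image height.
  After each pass the skeleton is re-thinned, because deleting both
  branches of a forked tip can leave a junction cluster with no degree-1
  pixel.
* `compare_skeletons()` tabulates pixel count, endpoint count, a
  centredness score (mean DT on the skeleton minus the foreground mean)
  and runtime against two baselines: classical two-subiteration thinning
  of the full mask, and the raw distance-transform ridge.

## Stem and leaf decomposition

The lowest skeleton endpoint is the root. Shortest routes from the root to
every other endpoint are overlaid; pixels traversed by ≥ 2 routes form the
stem (the shared trunk of the bundle), and each route's remainder is a
leaf mid-axis, its apex at the endpoint. This "overlay" reading — rather
than intersecting all routes — matters when the topmost leaf diverges
early.

Two systematic raster effects are corrected:

* **Stem smoothing.** Where a blade merges into the stem, the medial axis
  of the union bulges sideways; the stem axis is lowess-smoothed (both
  coordinates against arc index) to recover the underlying near-straight
  stem line, and truncated at the topmost leaf insertion (the shared route
  otherwise overshoots into the apex blob where the top leaves merge).
* **Insertion refinement.** The skeleton branch point sits roughly one
  local half-width up the stem from the geometric insertion, and the first
  stretch of the skeletal leaf axis cuts across the merge wedge — left
  uncorrected this biases leaf lengths ~10% low. The blade midline outside
  the wedge is clean, so both its coordinates are fitted as quadratics in
  arc length over the first clear stretch (clear = the blade tube no
  longer overlaps the stem tube) and extrapolated backward until the curve
  meets the stem axis; the buried arc is credited to the leaf. A straight
  tangent intersection is the fallback when the extrapolation does not
  approach the stem. Similarly, the skeleton endpoint stops one
  half-width short of the blade tip, so $DT(\text{apex})$ is credited at
  the tip.

Pixel-level organ labels: the stem band stamps a disc of the local
half-width (capped at the stem's median half-width, so merge wedges do not
swallow blade pixels) along the axis; every remaining foreground pixel is
assigned to the geodesically nearest leaf axis *within the mask*
(multi-source shortest paths with a virtual terminal per leaf), so an
overhanging leaf cannot capture pixels of the leaf below it across
background. The labels partition the foreground exactly, which makes the
area identity TPA = TLPA + SPA hold to the last pixel.

Leaves are split into lower/upper halves at the stem's midpoint height,
using the refined insertion heights.

## Traits

45 traits are emitted per plant — 15 plant, 25 leaf, 5 stem — in physical
units via the mm-per-px scale (from the sidecar, or marker length when
given). Definitions that involved a choice:

* **MPH vs VPH**: MPH is the vertical extent from the soil line (lowest
  foreground row) to the topmost foreground pixel; VPH to the top of the
  stem axis.
* **Perimeter** (PP, PCH) is the 8-connected contour polyline length
  ($\sqrt2$ diagonals); compactness PC $= 4\pi\,TPA/PP^2$ then comes out
  ~2% above the ideal closed form on a rasterized square.
* **Leaf curvature** LC $= 1 - \text{chord}/\text{arc}$: scale-invariant,
  0 for a straight leaf, $1 - 2/\pi \approx 0.363$ for a semicircle
  (tested against the closed form).
* **Angles**: LTA between the local stem direction (oriented up) and the
  leaf tangent fitted over the first 15 axis pixels past the merge wedge;
  LSA uses the insertion-to-apex chord. Both in degrees, $[0°, 180°]$.
* **Fractal dimension**: box counting over dyadic sizes from 2 px to a
  quarter of the smaller image side, least-squares slope of $\log N$ vs
  $\log(1/s)$. At these sizes a straight line measures ~0.98 and a
  5-iteration Sierpinski triangle 1.585 (= $\log 3/\log 2$); *filled*
  shapes carry a finite-size bias and measure ~1.8–1.9 rather than 2.
* **Arc lengths** (SLL, SH) are measured on the pixel path subsampled
  every 4 vertices, suppressing the up-to-8% staircase overestimate of
  raw 8-connected path length.
* **Standard deviations** are population SDs (divisor $N$); the schema
  carries SDSLL without a mean SLL, so the mean is emitted as an extra,
  clearly non-canonical `mean_SLL` column after the 45. The schema lists
  total leaf dry weight twice (LDW, TLDW); both columns are written and
  kept equal.
* **Stem volume** SV treats the stem as a cylinder of diameter SW = SPA/SH.
* Five traits (TDW, LDW, TLA, TLDW, SDW) are regression estimates, not
  measurements; they stay NA until a fitted model is supplied, and the
  provenance column in the schema says which is which.

## Biomass models

`stepwise_fit()` is forward-entry (partial-F p-to-enter 0.05) /
backward-removal (p-to-remove 0.10) ordinary least squares, deterministic
given the input: ties break by larger partial F, then alphabetically. The
default candidate list is TPA, TLPA, TLL, SPA, SV, SH, MPH. Selection
stops when the fit is numerically perfect (residual sum of squares below
$10^{-10}$ of total), so a noiseless linear target recovers its exact
coefficients and nothing more. $R^2$ is the squared Pearson correlation
between prediction and truth — this follows the convention of reporting
"squares of the correlation coefficients", and differs from
$1 - SSE/SST$ off the 1:1 line, which the tests document. MAPE excludes
zero-truth entries and reports how many were excluded. Negative biomass
predictions are clipped to zero with a warning count.

Two properties of forward selection are worth knowing: under a pure-noise
target the family-wise chance of any entry grows with the candidate list
(about $1 - 0.95^k$), and with correlated candidates a spurious collinear
predictor occasionally enters alongside the true ones, inflating their
coefficient variance. The validation suite measures both on simulated
trait tables drawn from a shared lognormal plant-size factor.

## The synthetic plant renderer

`generate_plant()` is the oracle that makes every stage testable without
field data. A plant is a vertical linearly-tapered stem (base 18–26 mm,
apex ~60% of base) with 4–7 alternately inserted leaves; each leaf midline
is a quadratic Bézier — insertion on the stem axis, apex at the chord
length along an upward-outward elevation direction, control point
displaced perpendicular to the chord by the curvature parameter — swept
with a sine width profile that stays attached at the stem and tapers to
the tip. Lower leaves are long and near-horizontal (elevation ~26°),
upper leaves shorter and steeper (~62°), stems 550–900 mm, blades 46–66 mm
wide and 150–380 mm long: a vegetative-stage maize habit. The top two
leaves insert together at the stem apex (fractions ~0.99 and 1.0),
emulating the whorl; this is also why the skeleton's endpoint count equals
leaf count + 1 — with a bare stem tip above the top leaf there would be an
extra endpoint. The default canvas is 656×492 px at 2 mm/px (a
downscaled portrait phone frame); these sizes keep a full 20-plant
validation under two minutes on one core while leaving stems ~10 px and
blades ~25 px wide, comfortably above the resolution where the skeleton
degrades.

Ground-truth leaf lengths and curvature come from the *continuous* Bézier
(numeric arc length at 600 samples); heights, widths and areas from the
rasterized truth mask. Raster-induced error is therefore part of what the
validation measures. `render_tilted()` applies the exact inverse of the
calibration homography, and `corrupt()` adds seeded sensor noise, colour
casts, brightness shifts and backdrop texture.

What the synthetic validation shows: the geometry inverts its own forward
model; the skeleton finds exactly one endpoint per organ; programmed
heights and lengths are recovered within a few percent (MPH exactly, SH
~1%, TLL ~1% mean over seeds 0–19). What it does not show: performance on
real canopies — overlapping neighbour plants, wind-deformed stems, specular
pots, soil clutter and true camera PSFs are all absent, and the classical
segmenter is a stand-in for a trained network on such scenes. The
published-protocol metrics (precision/recall/F1/IoU, MAPE, $R^2$) are
implemented precisely so that users can rerun the evaluation on their own
annotated data.

## Configuration, reproducibility, batch flow

All tunables live in one `pipeline_config()` (YAML round-trip, unknown
keys rejected): segmentation threshold override and kernel sizes, spur
floor, tangent window (15 px), single-route stem fraction (0.6), stepwise
thresholds, default field of view and scale. `analyze_images()` runs
calibrate → segment (or external mask) → skeletonize → decompose → traits,
appends one CSV row per image, writes QC organ-label composites, logs
per-stage timings, and preserves the partial CSV when an image fails.
`simulate_plants()` writes byte-identical fixture sets for a given seed.
A thin command-line wrapper (`inst/cli/phenomaize`) exposes `analyze`,
`simulate`, `fit-biomass`, `evaluate-seg` and `compare-skeletons`.

## Known limitations

* Leaves crossing each other or wrapping behind the stem create skeleton
  cycles; routes then shortcut and per-leaf attribution degrades. Severe
  overlap is out of scope, as is multi-plant separation.
* The insertion refinement assumes a locally quadratic blade midline and a
  near-straight stem; strongly kinked blades fall back to the tangent
  rule and lose a few percent of length.
* Lens distortion is not corrected here; apply a standard checkerboard
  calibration upstream if the optics need it.
* Tassel and cob structures are not modelled.
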