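---
title: "Measuring retinal vessel tortuosity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring retinal vessel tortuosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retort)
```

## The measurement problem

Retinal vessel tortuosity — how much a vessel bends and twists relative to a
straight course — is a candidate biomarker for diabetic retinopathy,
hypertensive disease and glaucoma. **retort** implements a length-based
definition: for a vessel traced from the optic disc (OD) to a terminal
endpoint,

$$T = \frac{L_{curve}}{L_{straight}},$$

where $L_{curve}$ is the length along the vessel centerline and
$L_{straight}$ the Euclidean (chord) distance between the two ends. A
perfectly straight vessel scores 1; twisting raises the score. The package
covers the full chain needed to compute $T$ from a colour fundus photograph:
intensity normalization and a resolution-standardizing resize policy,
ISODATA vessel segmentation on the LAB b channel, vesselness enhancement,
ground-truth-guided artery/vein separation, skeletonization, OD-anchored
breadth-first-search (BFS) path tracing, and the comparison statistics used
to contrast arteries against veins and healthy against diseased eyes.

Arteries and veins are kept separate throughout, because the two vessel
types differ systematically in wall structure and baseline geometry and
pooling them obscures exactly the contrast of clinical interest. The
separation relies on colour-coded annotation maps (red = artery, blue =
vein, green = pixels where the two cross); fully automatic artery/vein
classification is out of scope.

## Pipeline stages and their parameters

### Normalization and the resize policy

Raw 8-bit images are divided by 255. Images whose largest dimension exceeds
1,000 px are halved once (bilinear); the pixels-per-degree ratio
$ppd = H/\mathrm{FOV}$ is then recomputed and images still above 50 ppd are
halved again. The policy applies each trigger at most once per invocation —
a 3304×2336 image at 45° lands at 1652×1168 (≈26 ppd) and is left there,
which is the documented behaviour even though the result still exceeds the
size trigger. `resize_factor` accumulates the applied scale so OD
coordinates can be restored to the original resolution.

### Segmentation

The b (yellow–blue) channel of the CIE LAB transform separates vessels from
fundus background well; it is min–max normalized and thresholded with the
ISODATA intermeans rule — iterate
$T_{k+1} = \tfrac12\left(\mathrm{mean}(v<T_k)+\mathrm{mean}(v\ge T_k)\right)$
from the global mean until the update falls below $10^{-6}$ (cap 100
iterations; the intermeans rule is the standard one, the stopping schedule
is this package's choice). Whether vessels are bright or dark in the
normalized b channel
depends on the colour balance of the image; the `invert_b` flag (default
`FALSE`) selects the polarity. The synthetic phantoms render vessels dark in
b, so pipeline runs on phantoms set `invert_b = TRUE`.

Morphological cleanup removes 8-connected components below 20 px (the
cleanup size is our choice; the procedure prescribes cleanup without a
size). A multiscale Gaussian–Hessian vesselness filter (scales 1–3 px,
response threshold 0.15 on the min–max-normalized response) then adds
tube-like pixels that thresholding missed; enhancement is monotone — it can
only add foreground, never delete it. The trainable-filter enhancement
variant used in some segmentation pipelines is exposed only as a pluggable
`method` argument and is not implemented. Finally the artery/vein/overlap
masks derived from the annotation map are unioned in and a disc-shaped
closing restores continuity.

### Optic disc

The OD anchors tracing: start points live on its boundary band and its
interior is excluded from traversal. Detection runs CLAHE equalization, a
Gaussian blur (σ = 3 px, so that thin vessels stop producing edges), a
gradient-magnitude edge map at the 0.97 quantile, and a Hough circular
transform implemented as ring-kernel correlation. Scores are votes per
$\sqrt{\text{ring area}}$ — plain counts favour the largest ring,
plain means favour tiny rings on thick edge blobs — and candidates whose
interior is not brighter than the image average are rejected. The search
radius spans $[0.5, 2.5]\times$ the nominal radius $ppd \cdot 5^\circ/2$
(OD diameter ≈ 5° of visual angle). Because OD detection is the least
reproducible stage across datasets, a manually specified circle is
first-class and bypasses detection entirely.

### Artery/vein separation and skeletonization

Annotation colours are classified in HSV (all channels in $[0,1]$): red
(artery) at $H \le 0.1$ or $H \ge 0.9$ with $S > 0.4, V > 0.3$; blue (vein)
at $0.55 \le H \le 0.75$; green (crossing) at $0.2 \le H \le 0.45$ with
$S > 0.3$. The hue bands are disjoint, so the three masks are provably
disjoint per pixel.
Class masks are the intersection of the segmentation with (own colour ∪
overlap): crossing pixels enter *both* masks so that each class map stays
connected, then a disc(2) closing heals hairline gaps.

Each class map is reduced to a one-pixel centerline by iterative
two-subiteration parallel thinning run to a fixpoint. We use the Guo–Hall
subiteration conditions rather than Zhang–Suen ones: Zhang–Suen
progressively erodes two-pixel-wide diagonal ribbons, which truncated
oblique vessels by tens of pixels in our phantom experiments, while
Guo–Hall preserves them. The classical morphological-skeleton formula
(union of erosions minus their openings) describes what a skeleton is; the
thinning iteration is the executable definition, as tracing requires
spur-free 1-px paths. A final pruning pass removes residual 2×2 blocks by
deleting only pixels whose neighbours remain locally 8-connected; a 2×2
core where four diagonal arms meet at four distinct corners is irreducible
(deleting any pixel disconnects an arm) and is left in place — tube-shaped
masks do not produce it.

### Start points, endpoints and BFS tracing

Skeleton pixels at distance $d$ from the OD centre with
$r_{OD} < d \le r_{OD} + \delta$ are candidate starts; $\delta$ defaults to
5 px. The lower bound is strict (a pixel on or inside the disc is never a
start). Endpoints are skeleton pixels with exactly one foreground
8-neighbour; isolated pixels are discarded. An endpoint is traced only if
it lies outside the disc ($d_e > r_{OD}$), and endpoints that are
themselves candidate starts are treated as vessel origins, not terminals —
tracing them would produce degenerate zero-chord pairs.

For each remaining endpoint a BFS runs over the 8-connected skeleton graph
with the closed disc interior removed; reaching any start validates the
pair. BFS on a unit-weight graph returns a shortest path, so
$L_{curve}$ is well defined and reproducible; neighbour expansion follows a
fixed row-major order and, when several starts are reached at the same
depth, the smallest linear index wins, making results bit-identical across
runs. A consequence worth knowing: where two skeleton arms meet at a right
angle, the shortest path cuts the corner diagonally rather than passing
through the corner pixel.

### Arc length, chord length and the three arc modes

The stored per-vessel quantities are $L_{curve}$ (inclusive pixel count of
the BFS path) and $L_{straight} = \mathrm{round}\left(\sqrt{(x_e-x_s)^2 +
(y_e-y_s)^2}\right)$. Tortuosity supports three arc modes:

* **`pixel`** (default): $T = \text{pixel count} / \text{rounded chord}$.
  This is the classic integer bookkeeping of length-based tortuosity
  tables, and it admits values below 1: a straight diagonal path of $n$
  pixels has chord $\approx \sqrt2\,(n-1)$, so $T \to 1/\sqrt2 \approx
  0.707$. The pixel count of a shallow oblique curve also equals its
  column count, so small-amplitude undulations do not move this measure.
* **`geometric`**: the BFS path is subsampled every 5 pixels (always
  keeping the final pixel) and the polyline segment lengths are summed;
  the chord is used unrounded. Subsampling removes the digitization bias
  of a raw chain step-sum — summing 1 per axial and $\sqrt2$ per diagonal
  step overestimates smooth curves by ≈5.5% on average over orientations
  (up to 8.2% at 22.5°), which would exceed the 5% recovery tolerance we
  hold the pipeline to. The 5-px interval keeps the residual bias ≈0.3% on
  a radius-60 semicircle while staying exact on straight axial runs; paths
  whose curvature radius falls below ≈5 px are slightly underestimated.
  With the unrounded chord this mode guarantees $T \ge 1$ up to floating
  point (a polyline through the endpoints can never be shorter than the
  chord, whereas a rounded chord could exceed a straight line's true
  length by up to 0.5 px).
* **`chain`**: the raw 1/$\sqrt2$ step-sum, kept for reference and
  comparison; carries the digitization bias just described.

### Statistics

The unit of inference is the per-image mean tortuosity per vessel class;
with $n$ images, an artery-vs-vein comparison is a paired design with $n$
pairs. (Per-segment pooled means are also reported, but tests on pooled
segments would treat correlated segments within an eye as independent, and
a paired signed-rank test at segment level is impossible when the two
classes have different segment counts.) `compare_groups()` runs
Shapiro–Wilk on both samples and gates at $\alpha = 0.05$: if both pass,
the primary branch is parametric — Pearson $r$ with its two-sided $t$-test
$p$, single-predictor regression $R^2$ ($= r^2$), and Cohen's $d$ with the
pooled-SD formula and sign $\bar a - \bar b$ (artery − vein, hence negative
when veins are more tortuous); otherwise the nonparametric branch —
Spearman $r$, Mann–Whitney U on the full samples, Wilcoxon signed-rank on
the image-paired means. Every statistic the sample sizes permit is
computed; the gate only marks which set is primary. With per-image pairing
the effective sample size is the number of images, which is what the
correlation test sees: for example, $r = 0.5608$ over $n = 20$ pairs gives
a two-sided
$p = 2\,P\!\left(t_{18} < -r\sqrt{18}/\sqrt{1-r^2}\right) \approx 0.0101$.
No multiple-testing correction is applied.

## The synthetic phantom

`generate_phantom()` renders everything the pipeline consumes: a
fundus-like RGB image (bright textured background, brighter disc, dark
vessels), a binary vessel mask, a red/blue/green label map, the disc
circle, and an analytic truth table. Vessels are parametric curves — lines,
circular arcs, sinusoids, cubic Béziers — radiating from the disc band to
the periphery in jittered angular sectors, alternating artery/vein, 3 px
wide. Arc lengths come from closed forms (lines, arcs) or adaptive
quadrature at tolerance $10^{-8}$ (sinusoids, Béziers), so truth error is
negligible against the 5% recovery band used in testing.

Two generator choices deserve explanation:

* **Class-specific tortuosity targets.** Each vessel draws an analytic
  tortuosity target from its class distribution — arteries
  $1.11 \pm 0.05$, veins $1.21 \pm 0.07$, truncated to $[1.002, 1.45]$ —
  and the curve's displacement parameter is solved by root-finding to meet
  it. These magnitudes emulate healthy 45° fundus photographs, where veins
  run systematically more tortuous than arteries; a phantom population
  built this way lets the comparison machinery demonstrate the
  artery–vein contrast it exists to detect. Curve kinds are restricted by
  target (a high target cannot be met by a single shallow arc without a
  huge lateral bulge, so targets above 1.10 use oscillating kinds).
* **Inward extension of the tube.** Real vessels continue into the disc;
  phantom tubes are therefore extended a few pixels inward from the truth
  start (mask only — the truth chain is untouched). Thinning retracts
  rounded end caps by a couple of pixels, and without the extension a
  vessel whose start sits near the outer edge of the band could retract
  past it and lose its start point.

One artery/vein pair per phantom (configurable) is deliberately placed in
adjacent sectors with a sinusoid wide enough to cross, exercising the green
overlap labels and the both-masks inclusion rule. All other intersections
are avoided: vessels are rasterized in order and any unplanned collision
shrinks the offender's displacement by 0.7 and retries (deterministically),
because an unplanned same-class crossing would create skeleton junctions
and spurious endpoints that corrupt per-vessel truth matching.

`degrade()` deletes short runs and adds 1–3 px spurs at Poisson rates per
100 foreground pixels, reproducibly by seed, to stress the
continuity-restoration stage.

**What the phantoms do not emulate:** photorealistic texture, vessel
calibre variation and branching trees, pathology (neovascularization,
haemorrhages), annotation noise in the label maps, and OD appearance
variation. Passing phantom tests therefore demonstrates the geometric and
statistical machinery — segmentation robustness on real fundus photographs
must be judged on real data.

## Numerical and degenerate-case conventions

* Coordinates are 1-based (row, col) matrices internally — R's native
  indexing; every exported "(x, y)" string uses x = column, y = row.
* A constant b channel min–max-normalizes to all zeros; a constant grid is
  a "degenerate histogram" error in ISODATA.
* Bilinear interpolation for intensity images; nearest-neighbour for masks
  and label maps (preserves binarity and label colours).
* A zero chord (coincident start and end) flags the record invalid rather
  than producing an infinite ratio; untraceable pairs store a missing
  curve length.
* Tie-breaks in BFS are fixed (row-major neighbour order, smallest-index
  start), so every pipeline output is deterministic; the only randomness
  anywhere is the phantom generator's, and it is fully owned by the seed.

## Problem sizes used by the test-suite and the acceptance script

Unit and property tests run on 160–512 px phantoms with 6–20 vessels,
50 random-walk skeletons for the shortest-path oracle, and 1,000 random
rasterized curves for the tortuosity lower bounds. The acceptance script
processes eight 384 px, 14-vessel phantoms through the full pipeline
(including detection of the disc it could instead have been given), one
20-vessel phantom for geometric-mode recovery, and 200 random curves for
the bound checks. These sizes were chosen so the entire suite completes in
about a minute on a single core while still exercising every stage at
realistic vessel counts.

## Known limitations

* Artery/vein separation requires colour-coded ground-truth maps; images
  without them cannot be processed per class (automatic classification is
  explicitly future work).
* The pixel-count tortuosity is scale- and orientation-sensitive (values
  below 1 on near-diagonal straight vessels; insensitivity to sub-pixel
  undulation). Geometric mode exists precisely for metric fidelity, but
  the pixel mode remains the default because it reproduces the reference
  bookkeeping.
* One traced path per endpoint: vessels are measured OD-to-terminal, with
  no subdivision at bifurcations and no width measurement.
* OD detection assumes a bright disc of roughly 5° diameter; unusual
  acquisitions should use the manual override.
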