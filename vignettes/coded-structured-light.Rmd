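---
title: "One-shot coded structured light: pattern design, decoding and reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-shot coded structured light: pattern design, decoding and reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cslrecon` implements an active 3D reconstruction pipeline built around a
one-shot coded structured light (CSL) pattern: a single binary image of
white geometric symbols on a black background is projected onto a smooth
surface, one camera frame is captured, and every detected symbol is
identified with its position in the projected pattern by decoding its
spatial neighbourhood. Matched centroids are then triangulated against the
projector--camera geometry. Because a single frame suffices, the method
suits moving subjects; because the pattern is binary, it is insensitive to
surface colour. The package targets fusiform (spindle-shaped) subjects such
as farmed fish, whose low surface curvature justifies the central modelling
assumption described below, and ships a synthetic scene simulator that
stands in for real captures in all tests.

## The pattern code

The pattern is a `rows x cols` lattice (default 43 x 76) of symbols drawn
from a six-letter alphabet: rectangle, L, T, triangle, X, Pi. Each 3x3
window of the lattice -- a *subpattern* -- is flattened in a fixed row-major
order into a nine-symbol *codeword*. The defining property is that any two
codewords of the pattern differ in at least three positions (pairwise
Hamming distance >= 3). A decoder that accepts words within distance 0 or 1
of a known codeword can therefore correct one misclassified symbol per
codeword, and a word within distance 1 of one codeword can never be within
distance 1 of another.

No published construction is prescribed for filling the lattice, so the
package uses a seeded randomized greedy scan: cells are filled in raster
order, and a placement that completes a 3x3 window is accepted only if the
new codeword keeps distance >= 3 to every previously completed window.
Because eight of the nine symbols of a completing window are already fixed,
each prior word either blocks one candidate symbol (when it matches the
fixed eight in all but two positions) or blocks the cell entirely (fewer
than two mismatches); dead ends trigger bounded backtracking and, if the
budget is exhausted, a restart from a derived seed. In practice the default
43 x 76 grid generates in about one second and has never needed a restart
across the seeds we exercised; the exhaustive pairwise verification of all
3034 codewords (about 4.6 million pairs) is part of the test suite.

The row-major flattening order is a free choice: any fixed bijection
between window cells and codeword positions preserves Hamming distances,
so it only has to be shared between encoder and decoder.

### Symbol geometry

The six glyphs are drawn on a 20 x 20 px cell with 4 px strokes (the
triangle is filled, the rectangle is a slim 6 x 14 filled block). Their
exact shapes are a design parameter with one hard constraint, checked at
construction time: every pair of rasters must be at normalized SAD >= 0.7
(see below), the separability that makes minimum-dissimilarity
classification robust. A full-cell filled rectangle cannot meet this floor
-- any glyph contained in it would sit at dissimilarity `1 - |Y|/|X| <
0.7` -- which is why the rectangle is slim. The shipped set has a minimum
pairwise dissimilarity of 0.816.

## Binarization

Captured frames are converted to grayscale (ITU-R 601 luma) and binarized
with Sauvola's adaptive threshold, `t = m (1 + k (s/R - 1))`, computed from
the local mean `m` and standard deviation `s` over a square window.
Sauvola's formula is defined for dark foreground on light background; the
projected symbols are bright, so the threshold is evaluated on the
photometrically inverted image (a pixel is foreground when `pixel >=
max - (max - m)(1 + k (s/R - 1))`). Applying the textbook polarity
directly would label every flat dark region -- image borders, unlit
margins -- as foreground, because there `s` is small and `t < m`.

Defaults: `window = 31` px, `k = 0.2`, `R = 128`. The window must exceed
the symbol pitch (about 20 px in camera pixels at the default rig and
working distance) so that every local window mixes symbol and background
populations; 31 px satisfies this with margin. On a constant image the
inverted threshold sits above the local level everywhere and the output is
uniformly background -- the documented degenerate case.

Connected components are labelled with 8-connectivity (thin diagonal
strokes of the X must not fragment) and components under 50 px are
discarded as noise. The global Otsu threshold (exact discrete maximization
of between-class variance over the 8-bit histogram) is provided as the
baseline: under a 2x linear illumination ramp it provably mis-sizes or
loses symbols on the dark side while the adaptive threshold tracks the
local contrast, and the package asserts the resulting strict decode-rate
ordering on the simulator.

## Symbol classification

Each component is classified by exhaustive template matching over the
fundamental transformations only -- rotation and anisotropic scale. For
each class, 45 rotated variants (-22 to 22 degrees in 1-degree steps) are
precomputed, cropped to content; at match time each variant is resized to
the component's bounding box (templates are warped toward the component,
never the reverse) and scored with the normalized sum of absolute
differences

    SAD(X, Y) = sum |X_ij - Y_ij| / max(|X|, |Y|),

where `|X|` is the white-pixel count: 0 for identical rasters, 2 for
disjoint rasters of equal area. The component takes the class of the
global minimum over all 6 x 45 candidates; ties resolve to the lowest
class id, then the smallest rotation magnitude, purely for determinism.
Restricting the search to rotation and scale (rather than a full
projective warp) is the modelling assumption justified by fusiform
surfaces: within one symbol's extent the surface is nearly planar and
nearly fronto-parallel, so the residual projective distortion is small
against the 0.7 separability margin of the alphabet.

Rotation and resizing use nearest-neighbour resampling with a 0.5
threshold, keeping every intermediate raster binary and the whole
classifier deterministic. Scaled templates are cached per (class, angle,
bounding box) since near-planar scenes reuse a handful of box sizes.

## Subpattern topology

For every symbol with at least eight neighbours, the decoder must recover
*which* eight symbols form its 3x3 neighbourhood and in what arrangement,
using geometry alone:

1. the eight nearest components (Euclidean distance between reference
   points) are collected;
2. a chain visits them by repeatedly stepping to the nearest unvisited
   member, starting from the centre. On a regular lattice this chain closes
   the four overlapping 2x2 quads of the neighbourhood after 3, +2, +2 and
   +1 visits, each quad sharing the centre symbol;
3. corner roles are assigned at two levels -- among the four quad centroids
   and among the four members of each quad -- by greedy exclusion against
   the corners of their bounding box (repeatedly fixing the globally
   closest point--corner pair);
4. the 3x3 arrangement is then read off corner-wise. Every edge-middle
   symbol is determined twice (from two adjacent quads) and the centre four
   times; any disagreement, a coincident/collinear degeneracy, or a chain
   step longer than 1.8x the local pitch (median distance to the four
   nearest neighbours) invalidates the candidate rather than guessing.

Two design choices deserve comment. First, the topology stage uses
*bounding-box centres*, not foreground centroids, as reference points: the
centroid of a glyph sits up to ~5 px from its cell centre and differs per
class, which on a ~20 px pitch occasionally pulls a two-away symbol into
the eight-nearest set even on a perfect plane; bounding-box centres are
class-independent to ~2.5 px and keep the reference lattice regular. The
correspondence feature points remain the true foreground centroids on both
the pattern and image sides. Second, the 1.8x-pitch chain-break rule and
the greedy corner assignment are exact on the method's operating domain --
grids distorted by rotation within the classifier sweep, moderate
anisotropic scale, and centroid jitter up to ~5% of pitch -- where the
greedy assignment provably coincides with the exhaustive
minimum-total-distance bijection over all 24 candidate assignments (the
package tests this equivalence on 1000 such quadruples). On arbitrary
point quadruples the two can differ; such configurations do not arise from
2x2 symbol grids within the validity checks above.

## Decoding and error propagation

Each valid candidate is flattened and compared against the codeword book.
Distance-0 and unique distance-1 matches are accepted; a distance-1 match
identifies exactly one misclassified image symbol together with its true
class. That correction is applied to the symbol's label *globally*, which
can bring other codewords containing the symbol within decoding distance;
passes repeat until no new correction arises. Accepted codewords are never
revoked, so the accepted set grows monotonically and termination is
guaranteed. If two codewords propose different classes for the same symbol
in one pass, the decoder abstains and logs the conflict.

One behaviour is worth stating plainly: a codeword with *two*
misclassifications is usually rejected (its distance to every book word is
at least 2), but when both errors land on the differing positions of
another codeword at distance exactly 3 -- with precisely that word's
symbols -- the corrupted word sits at distance 1 from the alias and is
miscorrected to the wrong origin. This is the standard miscorrection mode
of any minimum-distance-3 code under two errors and is not detectable from
the word alone; empirically it affects about 2% of random double errors on
the default book. Downstream, positional consistency (a symbol decoded by
several codewords must map to a single grid position) and the triangulation
quality gate suppress most of the resulting outliers.

A symbol is decoded when it belongs to at least one accepted codeword, so
decoding a single codeword yields nine symbols and interior symbols enjoy
up to nine-fold redundancy; symbols near the object outline participate in
fewer codewords, which is why losses concentrate there.

## Triangulation and morphometrics

Correspondences pair the centroid of a symbol's cell in the rendered
pattern (equivalently, projector pixel coordinates) with the detected
component centroid in the camera frame. Both devices are pinhole models in
a camera-centred frame: focal length in pixels is `(width/2) /
tan(hfov/2)`, the projector sits at `(baseline, 0, 0)` and is toed in
towards the camera axis. Default geometry: 53.4 cm baseline, 3328 x 2496
camera at 78.7 degrees horizontal field of view, 1920 x 1080 projector at
42.5 degrees, subject at about 72 cm. The default convergence aims the
projector axis at the point of the camera axis at the working distance
(atan2(53.4, 72), about 36.6 degrees); smaller toe-in angles leave part of
the subject outside the projector frustum at this baseline, so the aiming
choice is the natural default and the angle remains configurable.

Each pair is triangulated as the midpoint of the common perpendicular
between the camera and projector rays; the segment length (skew distance)
is retained as a per-point quality metric and points with skew above 1 cm
or near-parallel rays are rejected. On noiseless synthetic input the
pipeline recovers depth to floating-point accuracy (~1e-13 cm); a 1 px
centroid error at 72 cm costs about `z^2 / (f b)` = 0.048 cm of depth,
which the tests verify against simulation.

Morphometrics are principal-axis extents: total length is the max-minus-min
projection of the cloud on the first eigenvector of its covariance, height
on the second. This matches the "total length" semantics of calliper
measurements; a 1st--99th percentile option exists for noisy clouds. Note
the extents measure the *decoded patch*, so they approach the true body
dimensions only as pattern coverage of the subject grows.

## The scene simulator

`render_scene()` replaces real captures. It inverse-renders each camera
pixel: back-project to the surface (fronto-parallel plane or an ellipsoid
stand-in for a fusiform body), reproject the hit into the projector, sample
the pattern raster, and shade foreground/background; projector-side
shadowing and camera-side occlusion are ray-cast exactly. It then applies,
in order, a multiplicative left-to-right illumination ramp, Gaussian blur,
and additive Gaussian noise scaled so that `10 log10(var(signal) /
var(noise))` hits the requested SNR (the SNR definition is pinned here
because reported capture SNRs come without one). Exact ground truth --
per-symbol correspondences with depth, per-pixel depth, interior flags --
comes from the same geometry, and a reprojection identity test holds it to
1e-3 px. All randomness flows from the scene seed; identical configurations
render bit-identically.

Default operating point: subject at 72 cm, SNR 14 dB (middle of the
13--16 dB band of the reference captures), blur sigma 1 px, shading 180
(lit symbol) over 45 (background). The shading models a capture with
ambient light: a pure dark-room model (roughly 230 over 25) gives a 9:1
contrast under which *any* global threshold lands in the empty histogram
gap and the adaptive-vs-global comparison becomes vacuous at moderate
illumination gradients; a 4:1 contrast reflects projector black lift plus
room light and lets the comparison behave as observed on real fish. The
default ellipsoid has semi-axes (15, 5.5, 2) cm -- a 30 cm x 11 cm
fusiform body -- with its front face at the working distance.

What the simulator does not model: fins, eyes and scale texture, specular
highlights, surface albedo variation, lens distortion, and underwater
refraction. Passing the suite therefore demonstrates the geometric and
coding pipeline under controlled noise, blur and illumination gradients,
not robustness to biological surface detail.

### Problem sizes used by the tests

The test suite runs the full 43 x 76 pattern for code-structure checks
(exhaustive distance verification, error-correction sampling), and scales
scenes down for end-to-end runs: a 12 x 16 pattern (192 symbols) for plane
scenes and binarization comparisons, and an 18 x 16 pattern for ellipsoid
scenes -- chosen so that, as with the full-frame pattern on a real subject,
the projection overflows the body height and silhouette-grazing symbols are
truncated rather than cleanly imaged. Depth-range acceptance on the
ellipsoid is judged against ground truth over *interior* symbols (those
whose full 3x3 neighbourhood is rendered), since boundary symbols cannot
belong to any complete subpattern and are unrecoverable by construction.

## Known limitations

- Double misclassifications can alias to a wrong codeword at distance 3
  (about 2% of random double errors); see the decoding section.
- Grid-position errors along the epipolar (horizontal) direction produce
  geometrically consistent but wrong depths that the skew gate cannot
  catch; they surface only at object silhouettes, where truncated symbols
  make whole-neighbourhood errors possible.
- Morphometric extents underestimate true body dimensions when pattern
  coverage is partial, and the first principal axis tracks the decoded
  patch, not necessarily the anatomical axis.
- The classifier's rotation sweep is hard-bounded at +-22 degrees; symbols
  rotated beyond that (steep surface slant at silhouettes) classify
  unreliably and are expected to be caught by the consistency checks.
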