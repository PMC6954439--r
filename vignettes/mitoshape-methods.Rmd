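---
title: "Quantifying mitochondrial network morphology with mitoshape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial network morphology with mitoshape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoshape)
```

## The measurement problem

Mitochondria in adherent cells form a mixed population of shapes: long
interconnected tubules (*filaments*), shorter tubules (*rods*), small
fragmented spheres (*puncta*) and enlarged quasi-spherical structures
(*swollen* mitochondria). The balance between these shapes reports on
fusion/fission activity and on mitochondrial stress, so a per-cell census
of the four classes is a useful phenotype. `mitoshape` computes that
census from calibrated 2D fluorescence images (e.g. MitoTracker staining,
confocal Z-stacks): it segments mitochondrial candidate objects, measures
six shape features per object, assigns each object to one of the four
classes with fixed sequential rules, and reports per-cell percentages and
per-group (cell line / clone) statistics.

All tunable parameters are physical quantities in micrometres, converted
to pixels through the image's pixel size. This makes one configuration
portable across magnifications, and it is why an image without a
resolvable pixel size is rejected rather than guessed at.

## Pipeline

For each image and each manually outlined cell:

1. **Z-projection.** Stacks are collapsed by per-pixel maximum. The
   projection statistic is not prescribed by the method we follow;
   maximum-intensity projection is the standard choice for thin bright
   structures and is the package default (`z_project`).
2. **Cell masking.** Intensities outside the cell's region are set to
   zero; objects are clipped at the cell boundary (`apply_cell_region`).
   Regions come from integer label masks or ImageJ ROI files.
3. **Background subtraction** (`subtract_background`): grayscale opening
   with a ball (spherical-cap) structuring function of radius 2.5 µm,
   subtracted from the image and clamped at zero. The ball's intensity
   aspect defaults to the image's dynamic range over one ball radius, so
   the background estimate follows illumination trends but rolls under
   anything narrower than the ball. The opening is exact (not the
   classic paraboloid approximation), anti-extensive and idempotent.
4. **Tube enhancement** (`enhance_tubes`): a Laplacian-of-Gaussian at
   smoothing scale 1 µm, negated so bright structures become maxima,
   clamped at zero, rescaled to [0, 1], then CLAHE with 2.5 µm tiles.
5. **Thresholding** (`yen_threshold`): Yen's maximum-correlation
   criterion on a 256-bin histogram of the in-cell pixels; foreground is
   strictly above the threshold.
6. **Segmentation** (`segment_objects`): 8-connected components;
   components smaller than `min_area_um2` (default 0.25 µm²) are
   excluded.
7. **Morphometry** (`measure_objects`): area A, perimeter P, aspect
   ratio AR, circularity C, solidity S, minimum Feret diameter MLE and
   skeleton extension E, plus the equivalent-circle radius
   r_eq = sqrt(A/π).
8. **Classification** (`classify_features`) and **reporting**
   (`summarize_cell`, `aggregate_cells`, `write_results`).

### Two interpretation choices in the preprocessing

Two details of step 4 deserve justification because they are genuinely
underdetermined:

*The LoG scale.* We interpret the 1 µm "smoothing scale" as the diameter
of the structure the filter is matched to. A LoG responds maximally to a
disc of radius r at σ = r/√2, so the Gaussian σ is scale/(2√2) ≈ 0.354 µm
— the radius scale of a mitochondrial tubule. The alternative reading
(σ = 1 µm directly) is internally inconsistent with the classifier it
feeds: a σ = 1 µm LoG blurs any sub-resolution spot into a blob of
apparent radius ≈ 0.7–1 µm after thresholding, which would make the
sub-0.6 µm punctum class unreachable for *any* threshold, yet puncta
below 0.6 µm are one of the four classes the method reports.

*Clamping the response.* Only the positive (bright-structure) half of the
negated LoG response is kept before rescaling. The negative lobes flank
*dark* structures; if they are retained, the flat background lands in the
middle of the [0, 1] scale, and after CLAHE the background sits next to
the segmentation threshold, turning background noise into spurious
objects.

### The small-object exclusion

The exclusion cutoff of the original analysis is not printed in the text
we follow. Our default, 0.25 µm², is the area of a diffraction-limited
spot for far-red emission at high numerical aperture (Airy radius
0.61·λ/NA ≈ 0.29 µm for λ ≈ 665 nm, NA 1.4): a segmented object smaller
than the point-spread function cannot be a resolved organelle and is
treated as noise. The cutoff is a config key (`min_area_um2`) and a CLI
flag.

## The six features and their discrete conventions

The continuous definitions (area; 4πA/P² circularity; convex-hull
solidity; best-fit-ellipse aspect ratio; minimum projection width;
longest shortest-path between skeleton endpoints) leave real freedom in
how they are estimated on a pixel grid. The package's conventions:

* **Perimeter** uses the Vossepoel–Smeulders weighted 8-chain around the
  outer boundary pixel centres (0.980 per axial step, 1.406 per
  diagonal, −0.091 per direction change) plus 4, the exact perimeter
  excess of a convex pixel footprint (the Minkowski sum of the centre
  polygon with the unit pixel square) over that polygon. This makes a
  w×h rectangle's perimeter essentially exact and keeps a 20-px-radius
  digital disc's circularity above 0.95. Holes are ignored. Circularity
  is clamped at 1 because discrete estimates can exceed it for very
  small objects; a single-pixel object has AR = C = S = 1 by convention.
* **Aspect ratio** comes from the second-moment ellipse of the binary
  pixel set (axis length 4·√eigenvalue); the minor axis is floored at
  one pixel so collinear pixel sets stay finite.
* **Solidity and MLE** use the convex hull of the pixel *corner* points
  (each pixel contributes its four corners), so a filled rectangle has
  solidity exactly 1, and MLE is the rotating-calipers minimum width of
  that hull — for each hull edge the farthest vertex distance, minimized
  over edges.
* **Extension E** thins the mask to a skeleton and takes the longest
  weighted shortest path (axial edge = pixel size, diagonal = √2 ×
  pixel size) between endpoints, i.e. skeleton pixels with exactly one
  8-neighbour. Objects without endpoints (closed loops, compact blobs)
  fall back to the longest shortest path over all skeleton pixel pairs,
  so a ring reports half its geodesic circumference.

The thinning is Zhang–Suen with *distance-transform anchors*: interior
ridge pixels of the Euclidean distance transform (8-neighbourhood maxima
with distance > 1) are never deleted, which keeps the skeleton on the
discrete medial axis. Plain thinning retracts the skeleton tip of a
rounded tube end by one to two pixels — a constant ≈ 0.15 µm bias that is
material for short rods. A second thinning pass, anchored only at the
endpoints of the first result, resolves the 2-pixel ribbons that ridge
plateaus can leave, without re-retracting the tips. On straight tubes of
2.5–12.5 µm the measured extension is within 1.2 % of the planted length.

## Classification rules

Rules are evaluated sequentially, first match wins, so the classes are
exhaustive and mutually exclusive:

1. **punctum** — round (C ≥ 0.8 and AR ≤ 2) and radius < 0.6 µm;
2. **swollen** — round, solidity ≥ 0.9 and radius ≥ 0.6 µm;
3. **filament** — extension E > 11 µm;
4. **rod** — everything else (the intermediate phenotype).

The 11 µm and 0.6 µm values are the published constants; the roundness
gates (C ≥ 0.8, AR ≤ 2) and the solidity surrogate for "compact in
intensity" (S ≥ 0.9) are this package's documented operationalization,
since the published per-class criteria sets are not available in the main
text. "Radius" is the equivalent-circle radius r_eq = √(A/π) by default;
MLE/2 is available as a config switch (`radius_feature: feret`).
Boundary ties go as written: strictly greater for the filament
extension, strictly smaller for the punctum radius.

Per-cell percentages are count-based (fraction of retained objects);
area-weighted percentages are written alongside because the denominator
convention is not prescribed. Group statistics are unweighted means (and
SDs) of per-cell percentages — cell-level, not object-pooled, averaging.
A cell with no retained objects has undefined (NA) percentages and is
excluded from group means with a message.

## The synthetic scene generator

`generate_scene` renders scenes with exact ground truth so the whole
pipeline can be validated without microscopy data. What it emulates:
bright, constant-width tubes along gently curved centrelines (filaments
and rods), small discs (puncta), larger discs (swollen) at 400 counts on
a 100-count background; signal-scaled shot-like noise
(gain·√intensity·N(0,1)) plus additive read noise (SD 2); a minimum
spacing of 1.2 µm between objects enforced by rejection sampling; pixel
size 0.065 µm (Nyquist-sampled high-NA confocal). Identical specs
(including the seed) produce bit-identical scenes, and generation leaves
the caller's RNG stream untouched.

Planted geometry respects the class thresholds with a guard margin
(validated at spec construction, default 10 %) and, beyond the bare
margin, stays clear of the boundaries by the pipeline's own measured
segmentation broadening (≈ +0.15 µm on small-disc radii at the default
threshold): filaments 12.5–18 µm, rods 2.5–9.5 µm, puncta 0.25–0.40 µm,
swollen 0.7–1.1 µm. The punctum range doubles as the biologically
realistic one — fragmented mitochondria of 0.5–0.8 µm diameter — and its
lower bound keeps planted objects above the small-object exclusion floor
so the generator's recoverability contract (a noise-free scene is
recovered perfectly, end to end) can hold.

Two subtleties of tube ground truth:

* Centrelines are piecewise circular arcs (three segments, |turn rate| ≤
  0.01 rad/px). White-noise headings would add pixel-scale jitter that
  the rendered tube's skeleton cannot follow, biasing length comparisons.
* The planted tube length is stored in the *discrete path metric the
  skeleton geodesic itself uses* (the octagonal grid distance,
  max + (√2−1)·min per displacement, summed over coarse centreline
  samples). The discrete metric overestimates Euclidean length by up to
  8 % at orientations near 22.5°, so a Euclidean ground truth could not
  agree with any skeleton measurement to 5 % at fixed edge weights;
  expressing both quantities in the same metric makes the renderer ↔
  morphometry consistency check meaningful. Across random scenes the
  planted and measured tube geodesics agree within 5 %.

What the generator does **not** emulate: the microscope point-spread
function (objects render at their geometric size; the pipeline's LoG is
the only blur), photobleaching, out-of-focus haze, 3D structure, or
touching/overlapping organelles. Passing recovery tests therefore shows
that segmentation, morphometry, classification and reporting are
internally consistent at realistic SNR and sampling — not that the
pipeline resolves the harder ambiguities of real micrographs (crossing
tubules, variable staining, projection artifacts).

## Validation summary

The test suite asserts, among other things:

* the rolling-ball opening equals a brute-force structuring-function
  opening and is idempotent;
* the Yen threshold equals exhaustive maximization of the criterion on
  random 8-bit images, and tracks affine intensity rescaling;
* minimum Feret agrees with a 0.25° rotation-sweep oracle within 1 % on
  random polyominoes, and never exceeds the maximum Feret;
* skeleton extension equals a Floyd–Warshall all-pairs oracle exactly on
  random pixel trees, and equals planted geodesics within 5 % on
  rendered tubes;
* sweeping straight tubes 5→15 µm (0.05 µm/px) switches rod→filament
  once, at 11 µm within one 0.1 µm step; sweeping discs 0.2→1.2 µm
  (0.02 µm/px) switches punctum→swollen once, at 0.6 µm within one
  0.02 µm step;
* a 640×640 px scene with a planted 30/30/30/10 class mix at default SNR
  is recovered within 5 percentage points per class through the full
  pipeline;
* identical configs and inputs reproduce byte-identical CSVs.

Problem sizes in the suite (384–640 px scenes, 25–40 planted objects,
50-case oracle batteries) were chosen so the whole suite exercises every
stage at realistic scale while remaining quick to run on one CPU.

## Known limitations

* 2D only; Z-projection superimposes structures from different planes,
  so dense 3D networks are under-segmented and the filament/rod balance
  on projected images should be interpreted with care.
* No watershed splitting: touching mitochondria become one object.
* Percentages are undefined (not zero) for cells with no retained
  objects; downstream code must handle the NA.
* The CLAHE clip limit (0.01 of the tile histogram) and the projection
  statistic are defaults of this package, not published values; both are
  exposed in the config.
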