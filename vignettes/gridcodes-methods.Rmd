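---
title: "Coordinate-encoding fiducial microgrids: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinate-encoding fiducial microgrids: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridcodes)
```

## The problem

Correlative and multimodal microscopy moves one sample between instruments
whose fields of view differ by orders of magnitude — widefield fluorescence
at a few millimetres, confocal at hundreds of micrometres, SEM at tens.
Relocating a particular cell after the sample has been carried through
staining, drying and coating steps is slow and error-prone, because the
substrate offers no absolute reference and deforms chemically and
mechanically along the way.

A coordinate-encoding fiducial microgrid solves this by fabricating, into
the substrate itself, a regular lattice of small markers each of which
*encodes its own grid coordinate* as machine- and human-readable geometry.
Any single marker seen in any field of view then fixes the absolute sample
position; two markers calibrate an instrument's stage to the grid; markers
shared between two images of different modalities are matched
correspondences for co-registration.

This package implements the complete desk-side toolchain: coding-scheme
geometry, photomask layout (GDSII), a synthetic camera model that stands in
for real micrographs, a classical machine-vision decoder, two-anchor stage
navigation with substrate-deformation metrics, and fiducial-driven image
registration.

## Coding schemes

All schemes are built from axis-aligned rectangles no smaller than the
minimum feature size $f$ (micrometres), the smallest dimension the
fabrication process resolves. Curved numerals are deliberately avoided:
rectilinear elements survive molding and pattern transfer and are easy for
thresholding-based machine vision.

* **Binary** (the default and most compact): a $(n{+}1) \times (n{+}1)$
  cell lattice of cell size $f$, default $n = 6$ bits per axis. The corner
  cell is the always-filled *align mark* — orientation reference and
  measurement origin. The bottom row holds the x bits, the left column the
  y bits, most significant bit adjacent to the align mark. Footprint
  $7f \times 7f$: seven times the minimum feature (6 bits + 1 align mark).
  Capacity $64 \times 64$ coordinates.
* **Ternary**: same L-layout; stroke thickness is the third level
  (empty / half-width $f/2$ / full cell), giving $729$ values per axis in
  the same footprint.
* **Decimal**: rectilinear seven-segment digits (stroke $f$, glyph
  $3f \times 5f$), x-digit row above y-digit row, with a full-height align
  bar. Most human-readable, largest footprint.
* **Planet** (postal two-of-five bar code): five bars per digit, two tall
  ($5f$) and three short ($2f$), weights 7-4-2-1-0 with 0 encoded as
  weight 11; one bottom-aligned bar row holding the x then y digit string
  between two full-height frame bars that act as align marks and
  measurement points.

Two conventions here are package choices, documented rather than copied
from any published mask set: the MSB-adjacent-to-align bit order (it makes
a printed coordinate read naturally off a micrograph), and the exact
L-arrangement of the two bit vectors. The planet scheme places both digit
strings in a single row because the design uses exactly two frame bars;
the consequence — a 180° reading ambiguity for that scheme — is one reason
image-plane detection is scoped to the chiral binary/ternary layouts
(decimal and planet symbols are still fully supported at the logical level
and by the rectified-crop reader `read_code_crop()`).

### Chirality, and where it fails

A binary code with at least one set bit in *each* arm cannot be confused
with any rotation of any other code: the L of filled cells breaks all
rotational symmetry. The subtle exception is a code with an all-zero arm:
a code with only y bits, rotated by $-90^\circ$, is geometrically identical
to the corresponding x-only code. The decoder therefore resolves
orientation *per scene*: codes with two non-empty arms vote for a
consensus orientation, and ambiguous (one-armed) codes are interpreted in
the consensus frame. An isolated one-armed code with no consensus
available is reported as undecodable rather than guessed.

## Layout and masks

The design rule is that at least one complete code must fall in the field
of view of the most constrained ("bottleneck") instrument. For a square
field of side $F$ and code footprint $c$, any pitch $S$ with
$S + c \le F$ guarantees this for every axis-aligned window;
`select_spacing()` returns the largest such $S$ on a quantization grid
(default 100 µm, because round pitches are preferred on masks). A 600 µm
confocal field with the 80 µm binary code gives the 500 µm pitch, and a
marker density of $(1000/S)^2 = 4$ codes per mm².

`generate_grid()` places code $(i, j)$ with its align-mark corner at
$(iS, jS)$; `write_gdsii()` emits a GDSII stream with a 1 nm database unit
and 1 µm user unit, one structure per code plus a top structure of
structure-references. The GDSII writer/reader is implemented in-package
(records HEADER/BGNLIB/UNITS/BGNSTR/BOUNDARY/SREF/…, excess-64 reals)
because no R package provides the format; round-trip tests confirm
nanometre-exact re-reading.

## The synthetic camera

`render()` maps code rectangles through an optional substrate-deformation
field and a stage-to-image similarity (pixel size, in-plane rotation,
translation), rasterises with area-weighted anti-aliasing (subpixel
supersampling), convolves with an isotropic Gaussian PSF, applies polarity
(`dark_features` emulating brightfield, `bright_features` darkfield or
secondary-electron SEM), and adds seeded Gaussian noise. Conventions: image
row axis is $-y$ physical; the centre pixel sees the `translation` point; a
stage-to-image rotation $\theta$ maps the physical $+x$ direction to pixel
direction $(\cos\theta, \sin\theta)$ in (col, row).

What the model emulates: pixel scale, orientation, defocus-like blur,
sensor noise, contrast polarity, and uniform/anisotropic/piecewise-affine
substrate deformation. What it does not: shot noise, illumination
gradients, charging artifacts, occluding cells, and z-defocus stacks —
passing the synthetic suite therefore demonstrates geometric and
radiometric robustness, not robustness to every real-world nuisance.
`ground_truth()` tabulates the exact projected align-corner positions of
codes fully inside the frame (with a small border margin, default 3 px) —
the oracle all decoder tests are scored against.

## The decoder

`detect_codes()` is a classical pipeline; every stage is ordinary image
processing, arranged so that each geometric quantity is anchored to an
observable that is invariant to the two dominant nuisances — Gaussian blur
and threshold-level dilation/erosion of the binary mask:

1. **Segmentation.** Light pre-smoothing, then a noise-adaptive threshold
   just above the background mode (median + $\max(4.5\,\hat\sigma_{MAD},
   0.15 \times$ amplitude$)$). A class-balancing (Otsu) cut is used only as
   a fallback: with sparse faint features it lands too high and fragments
   the heavily attenuated single-cell bits.
2. **Clustering.** Connected components are grouped into code candidates
   by single-linkage proximity at the code scale.
3. **Feature scale (pitch).** The scale in px/feature is estimated three
   ways and reconciled: (i) a blur-invariant flux/shape fit on isolated
   single-cell components (peak-to-flux ratio and half-peak area matched
   against a lookup table over feature size and PSF width — integrals and
   centroids are unaffected by symmetric blur); (ii) a lattice fit of
   component centres (half-integer cell positions) and start/end edge
   differences (integer positions, with the dilation bias cancelling in
   differences); (iii) inter-code anchor distances, which are integer
   multiples of the known spacing. Competing pitch candidates — the
   half-integer lattice admits exact aliases about 20 % away — are
   arbitrated by decoding under each and scoring the analytic
   blurred-template cross-correlation plus the spacing-consistency of the
   decoded indices.
4. **Orientation.** The minimum-area bounding rectangle of the cluster
   and the circular mean of pairwise component-centroid directions give
   the angle modulo 90°; all four quarter-turns are attempted and the
   chiral L decides (with scene consensus for one-armed codes).
5. **Reading.** Cell means (3×3 stencil per cell) are compared not to
   fixed thresholds but to the *predicted* means of the
   Gaussian-blurred template under each bit hypothesis, with gain and
   offset fitted per cluster — attenuation and inter-cell leakage are part
   of the model, not noise. The decoded pattern must also *explain* the
   cluster: pixels outside decoded-filled cells (coverage) reject aliased
   or misplaced fits, and a joint origin/pitch rescue fit is attempted
   before a cluster is abandoned.
6. **Position.** The align-mark corner is refined to sub-pixel precision
   by an iterated intensity-weighted centroid of the align cell.
7. **Consistency.** `neighbor_consistency_filter()` keeps the largest
   subset of detections consistent with one similarity between coordinate
   and pixel space (tolerance 0.25 × spacing).

Detections below `min_confidence` (margin-based, default 0.8) are dropped.
Clusters reaching the image border are never attempted: a truncated code
would read missing bits as zeros and decode confidently to the wrong
coordinate, and a false coordinate is worse than a missed one. The same
asymmetry — precision over recall — motivates several withholding rules
for detections that cannot be corroborated: a solitary detection must
carry a decisive template score, must not be one-armed (the
rotation-ambiguous class), and must have its align-corner hinterland — the
band where the align mark of a larger, partially visible parent code would
sit if our "align mark" were really one of its bits — visible in the frame
and empty. A code truncated through empty cells leaves a fragment
pixel-identical to a smaller complete code; only that hinterland check can
tell them apart.

## Navigation

`calibrate()` implements the two-point stage calibration a user performs at
the instrument: grid physical positions are $p_i = k_i S$, and for two
anchors the similarity is exact, with
$s = |\Delta q| / |\Delta p|$ (stage distance over grid distance) — the
substrate-deformation *scale factor* — and $\theta$ the angle between the
displacement vectors. More anchors give least squares with an RMS
residual; the affine model reports anisotropic factors $(s_x, s_y)$ as the
singular values of its linear part plus a shear angle; the
piecewise-affine model interpolates exactly through $\ge 4$ anchors over a
Delaunay triangulation (Bowyer–Watson, implemented in-package since no
triangulation library is available) with a global affine fallback outside
the hull.

Two anchors cannot distinguish a proper rotation from a mirrored view, so
reflection is an explicit flag rather than a fitted parameter;
`detect_reflection()` sets it automatically from three or more decoded
codes by comparing signed areas in coordinate and pixel space — possible
only because the L-layout is chiral. `stage_to_grid()` inverts the
mapping and rounds to the nearest lattice site, halves toward the lower
index.

## Registration

Because every fiducial carries its identity, correspondence between two
modalities is a dictionary lookup (`match_by_code()`), not a geometric
search. `estimate_transform()` fits moving→fixed pixels by least squares —
similarity by default (rotation + scale is what fiducial overlays need);
affine for anisotropic shrinkage. `warp_and_overlay()` resamples the
moving image bilinearly (bilinear warping is implemented in-package to keep
one row/col convention across the decoder and the warper) and composites at
a chosen transparency, 50 % by default; a tint mode produces the usual
fluorescence-on-SEM colour overlay. No intensity-based refinement is
applied: the method is purely fiducial.

## Numerical choices and degenerate inputs

* Spacing quantization default: 100 µm. Fill factor default 1; adjacent
  set bits merging visually is harmless because reading samples cell
  interiors.
* Pitch aliases are rejected rather than tolerated: candidate pitches
  implying more cells than the lattice holds, or component widths
  inconsistent with one shared dilation offset, are discarded.
* Degenerate calibrations fail loudly: coincident anchors, collinear
  anchors for affine fits, and non-invertible linear parts raise errors.
* Rounding ties in `stage_to_grid()` go toward the lower index.
* All randomness (noise, test scenes) is seeded; rendering is bitwise
  reproducible for a fixed seed.

## Test problem sizes

The test-suite scenes are sized for a single CPU: rendered fields are
384–512 px across, the decoder property suite uses 100 random scenes of a
binary grid with 10 µm features at a 180 µm pitch, pixel scale spanning
4–40 px per feature, rotations uniform over 0–360°, PSF width uniform up to
0.5 f and noise up to 5 % — the stress envelope for the decoder, far
beyond the near-diffraction-limited blur (a few percent of a 10 µm
feature) of a focused micrograph. Navigation and registration checks use
forward-synthesised transforms recovered to $10^{-9}$ and Monte-Carlo
noise studies with 1000 replicates.

## Known limitations

* Image-plane detection covers the binary and ternary L-layouts; decimal
  and planet codes decode from rectified crops only.
* The decoder assumes one uniform pixel scale per image (true of
  microscope frames) and grids whose spacing is at least about 2.5× the
  code footprint; denser grids can merge neighbouring clusters.
* Recall degrades once the PSF width passes roughly 0.4 f: a single-cell
  bit then retains only about a fifth of its contrast, and the ~20 %
  pitch aliases of the cell lattice become hard to refute from one image.
  The decoder prefers reporting nothing over guessing there, which keeps
  the wrong-coordinate rate at zero throughout the stress envelope at the
  cost of completeness at its extreme corner. Focused micrographs sit far
  from this regime.
* z (height) information, occlusion by overlying cells, and learned
  detectors are out of scope.
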