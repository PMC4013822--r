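---
title: "Measuring tooth enamel thickness from OCT volumes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring tooth enamel thickness from OCT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enameloct)
```

## The measurement problem

Fixed orthodontic appliances interact destructively with tooth enamel:
polishing, acid etching, adhesive application, bracket bonding and the final
clean-up each add or remove tens to hundreds of micrometres of material.
Optical coherence tomography images the enamel cross-section non-invasively:
a volume is a stack of `I` B-scans, each an `M x N` depth-by-lateral image,
with axial/lateral pixel sizes around 5 and 11.7 micrometres and roughly
47 micrometres between B-scans. `enameloct` turns such volumes into
per-stage enamel thickness maps, aligns the stages of a treatment series on
a common en-face grid, restricts them to the tooth area and reports
thickness statistics and pairwise stage differences.

The pipeline is fully automatic:

1. 3-D median pre-filtering (3 x 3 x 3).
2. Outer surface: a global Otsu threshold `p_r`; the boundary `L_ef(n,i)`
   is the first depth row whose intensity exceeds it.
3. Inner enamel boundary, per A-scan: the sub-surface intensity profile is
   a fast linear brightness decay through enamel followed by an
   approximately constant dentine plateau. The histogram mode `p_r2` marks
   the plateau level; `p_r3` adds one standard deviation of the plateau.
   The volume is binarized, median-filtered (3 x 3 x 3), closed in-plane
   (3 x 3 structuring element), hole-filled and labelled; per B-scan only
   the largest 8-connected component survives. The component's bottom edge
   is smoothed by a least-squares cubic in the column index.
4. Thickness: `L_d = L_in - L_en`, converted to micrometres by the axial
   pixel size (70 px at 5 um/px is 350 um).
5. Stage alignment: each stage's depth-summed, min-max-normalized C-scan
   projection is registered to the first stage by exhaustive search over
   integer shifts (±40 px per axis) and zoom (−20 % to 20 % in 10 % steps),
   minimising the mean absolute difference `J` with zero written outside
   the moving image and the full grid as denominator.
6. ROI: the reference projection is median-smoothed (31 x 31) and a greedy
   active contour shrinks a frame-inset polygon onto the tooth outline;
   statistics are computed inside the rasterized contour only.

## Boundary conventions and the p_r2/p_r3 decision

Rows and columns are 1-based. Boundaries are stored in an exclusive
convention: the outer boundary is the first enamel row, the inner boundary
the first row *below* the enamel, so their difference is the enamel row
count. Undefined columns are `NA`, never row 0. Micrometre conversion
happens only at the reporting boundary.

The single most consequential numerical choice is which threshold defines
the inner boundary. The dentine plateau is a roughly constant level with
speckle around it, and its histogram mode `p_r2` therefore *bisects* it:
binarizing at the mode leaves about half the plateau above threshold, and
after closing those voxels merge with the enamel component, dragging its
bottom edge tens of rows too deep. The working threshold has to lie between
`p_r2` and `p_r3` — a wrong choice shifts the boundary by up to about 70 px
(350 um at 5 um/px). `enameloct` resolves it as follows: the component
binarized at `p_r2` defines the object (its column span and the outer
boundary restriction), while the inner edge is read from the component
binarized at `p_r3`, one plateau standard deviation up, which cleanly
separates the decaying enamel tail from the plateau. Columns where the two
routes disagree by more than the 70-px limit are flagged and replaced by
the median of the five neighbouring columns. On noise-free data
`p_r3 = p_r2` and the two routes coincide, so exact-recovery behaviour is
unaffected. On the package's own speckled phantoms this choice brings the
relative thickness error from ~44 % (mode threshold alone) to ~1–4 %.

The plateau itself is located by a two-segment least-squares change point
that fits a *straight line* to the leading segment and a *constant* to the
trailing one, mirroring the decay-then-plateau A-scan shape. A
constant/constant change point misplaces the split midway down long decays
and inflates `p_r3` above the dimmest enamel rows, which measurably biased
thick stages; the line/constant model removes that bias.

Other conventions: argmax ties in the histogram mode take the smallest grey
level (favouring the darker plateau); Otsu ties (empty gaps between modes)
take the rounded midpoint of the tied range; negative thickness cells are
marked undefined rather than clipped, because zero is a meaningful
thickness; a cubic fit needs at least 4 defined columns, otherwise the raw
edge is kept and the B-scan flagged.

## Registration model

The moving projection is zoomed about the grid centre with
nearest-neighbour sampling (stride `1 + dz/100`; +10 % means the moving
image is 110 % of the reference scale and is shrunk to match), then
shifted. Out-of-range samples contribute `|ref − 0|` and the denominator
stays the full grid size. The exhaustive scan is zoom-outer, shift-inner;
exact ties are broken towards the smallest Euclidean norm of
`(dn, di, dz)` and then lexicographically. Nearest-neighbour interpolation
keeps every `J` comparison bit-reproducible. Rotation is not modelled: with
repeatable in-vitro attachment, rotational error stays below about one
degree.

A subtlety worth recording: the criterion's zero-fill makes a lost pixel
cost `|ref|` (about the image mean) while a *decorrelated* pixel costs only
the mean absolute difference of two independent image values, which is
smaller for any unimodal value distribution. When a planted transform
pushes a large part of the object out of the field of view, a wrong
zoom-with-smaller-shift candidate can therefore genuinely undercut the true
optimum. Recovery is guaranteed only when the whole object stays in view
for every transform in the search range, which is how the registration
phantom is laid out (below).

## The synthetic phantom world

No scanner data ships with the package; every test runs against a phantom
generator whose defaults state the emulated world once:

* geometry `884 x 512` per B-scan at `5 x 11.7` um/px, 47 um between
  B-scans (the acquisition geometry of the motivating setup); test volumes
  use fewer B-scans for speed, never different physics;
* a smooth, slightly asymmetric curved outer surface around row 120 (at
  the native depth), scaled proportionally for smaller test volumes;
* an enamel band whose brightness decays linearly from 220 at the surface
  to 110 at the inner boundary, over a constant dentine plateau of 80 and
  background of 10 — the decay-then-plateau A-scan shape described above.
  The absolute levels are free parameters (no intensity statistics of real
  Topcon volumes are available); only their ordering and the
  decay-into-plateau shape matter;
* an elliptical tooth footprint (semi-axes 45 % of each en-face half-extent)
  with thickness tapering from 730 um at the centre to 60 % of that at the
  rim;
* multiplicative Rayleigh-like speckle: voxel intensity is scaled by
  `1 + strength*(R − 1)` with `R` a unit-mean Rayleigh variate, clipped to
  `[0, 255]`; `strength = 0.15` is the stated "moderate" level and 0 turns
  noise off exactly;
* treatment stages differ by a per-stage thickness offset and a planted
  shift/zoom; the warp fills uncovered cells with *background*, not zero —
  a displaced acquisition images background there, and zero strips would
  corrupt the min–max normalization of the stage projection.

What a green test does establish: the implementation recovers exactly what
it should on piecewise-constant data, stays within the published 15 %
error bound under stated speckle, recovers planted transforms exactly when
the object stays in view, and reproduces the published stage-difference
arithmetic. What it does not establish: performance on real enamel (no
bracket shadowing, no depth-dependent attenuation, no refraction artefacts,
no real speckle statistics), nor agreement with the original
implementation's ROI, whose snake energy and schedule were never specified.

Dedicated test phantoms deviate from the defaults only where the property
under test demands it: registration phantoms add strong sinusoidal surface
texture (etched enamel is rough; without high-frequency content a
registration optimum is weakly identified) and use a footprint small enough
that all ±40 px / ±20 % transforms keep the tooth in view; the seven-stage
series phantom uses a constant in-footprint thickness so planted mean
differences are exact by construction.

## Active contour

The tooth outline on the smoothed reference projection is found by a greedy
snake: 64 vertices start on a rectangle inset a few pixels from the frame;
each vertex may move along its inward normal (towards the current centroid)
up to 20 px per sweep, and a move is accepted only if it increases the
contrast between the mean grey levels of the 6 x 6 patches just inside and
just outside the vertex. The sweep repeats until no vertex moves (or 100
sweeps). The polygon is rasterized even-odd, reduced to its largest
connected region and hole-filled. Movement is restricted to the normal
direction — a full box search lets vertices drift tangentially and bunch
up. The accepted-gain total is non-decreasing, so termination is
guaranteed. Against phantom footprints this recovers the tooth area with
Dice above 0.95; no claim is made about numerical agreement with the
original paper's (unspecified) contour mechanics.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `spacing_axial` | 5 um/px | depth pixel size; scales thickness values |
| `spacing_lateral` / `spacing_slice` | 11.7 um/px, 47 um | lateral/B-scan spacing (reporting only) |
| `h1`, `h2` | 3 x 3 x 3 | grey / binary volume median masks |
| `se` | 3 x 3 | in-plane closing element (speckle clusters are 2–3 px) |
| `h3` | 31 x 31 | projection median; shrink it for volumes with few B-scans |
| `shift_range` | 40 px | registration shift search half-range per axis |
| `zoom_levels` | −20..20 step 10 % | registration zoom grid |
| `limit_shift_px` | 70 px | p_r2/p_r3 disagreement limit (350 um) |
| `contour` | ±20 px, 6 x 6, 64 vertices | snake search range, patch, resolution |

Every constant lives in `pipeline_config()`; nothing is hard-coded
elsewhere, and reports echo the configuration used.

## Known limitations

* Single-tooth scenes only; dentine/pulp boundaries are out of scope.
* The proprietary `.fds`/`.fda` scanner format is not parsed; volumes enter
  as multi-page TIFF (a minimal baseline reader/writer is built in).
* Sub-pixel registration and rotation are not modelled.
* The expert-comparison error can only be computed against supplied
  annotation CSVs; the original expert study is not reproducible, so the
  packaged accuracy figure is measured against phantom ground truth
  instead.
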