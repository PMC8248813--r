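---
title: "Measuring ribbon synapses in 3D: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ribbon synapses in 3D: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ribbonmorph)
```

`ribbonmorph` quantifies afferent ribbon synapses of cochlear inner hair
cells (IHCs) from segmented, isotropic voxel volumes — label maps in which
each ribbon, presynaptic density (PD), postsynaptic density (PSD), and
cell carries an integer label. This vignette records the measurement
definitions, the synthetic-data generator, and the numerical and design
choices a maintainer or reviewer would want spelled out.

## Coordinate and unit conventions

Voxels are isotropic (default 7 nm, the acquisition resolution the package
is designed around). Physical coordinates are voxel centers,
`pos = (index − 0.5) · spacing` for R's 1-based indices, so a single voxel
is symmetric about its center. Axes are fixed: X is tonotopic, Y runs from
the habenular (basal, synaptic) pole toward the cuticular pole, Z from the
modiolar side (negative) toward the pillar side (positive). All internal
lengths are nm; reporting columns convert to µm², or 10⁶ nm³ where that is
the field's custom.

## Morphometry

**Volume** is the foreground voxel count times the voxel volume.

**Voxel-face surface area** counts foreground faces adjacent to background
under 6-connectivity. For a digitized smooth surface this overestimates
the smooth area by the staircase factor — the surface integral of
|n·x̂|+|n·ŷ|+|n·ẑ|, which equals 3/2 for a sphere. The measurement is kept
raw (it is the field's standard module output); the tests verify the 3/2
limit rather than "correcting" it.

**Feret axes.** For solid bodies (ribbons), the axis along a direction *u*
is the span of the foreground voxel centers lying within a capture radius
(√3/2 · spacing, half the voxel diagonal) of the line through the center
of gravity, plus one voxel for the end-voxel extents; the long axis
maximizes and the short axis minimizes this over sampled directions, and
the two are not forced to be orthogonal. Directions come from a nested
low-discrepancy sequence (Halton pairs mapped area-preservingly to the
sphere) expanded into whole orbits of the octahedral group — all 48 signed
axis permutations of each base direction. The orbit expansion makes
measurements *exactly* invariant under 90° lattice rotations of the mask,
and the nesting guarantees that increasing `n_directions` can only
lengthen the long axis and shorten the short axis (refinement
monotonicity); a plain Fibonacci lattice has neither property, which is
why it was not used. Ties between equal extreme directions are broken
lexicographically for determinism. The default of 2048 directions puts the
nearest sampled direction within ~4° of any axis, i.e. within ~2 voxels of
the true chord for structures up to ~800 nm; the closed-form oracle tests
(balls, boxes, ellipsoids) pin this down.

**Membrane densities are sheets, not solids.** Applied to a voxelized
2-voxel-thick sheet, the 3D minimal chord through the centroid returns the
slab *thickness* (~14 nm) as the short axis — which is not what an axis
summary of a PD or PSD means, and could never reproduce the 0.3–0.8 µm
in-plane short axes this field reports. `measure_all()` therefore measures
PDs and PSDs with in-plane Feret calipers: the sheet's principal plane is
fit by PCA of the voxel centers, and the long/short extents are taken over
directions within that plane through the center of gravity. For a flat
elliptical patch this recovers the ellipse diameters exactly (to one
voxel). The fully 3D chord and projection modes remain available in
`feret_axes()` for solid objects. The **ellipse-model area** is
π·(L/2)·(S/2) from those in-plane axes, reported in µm².

No tissue-shrinkage correction is applied anywhere; measurements are
reported in acquisition coordinates.

## The proximity descriptor

The package's central shape measure treats each synapse as a distribution:
from every face center on the **ribbon-facing surface of the PSD**, the
shortest Euclidean distance to the ribbon surface (the ribbon's
boundary-face centers; the union of surfaces for double-ribbon synapses).
Sorted and normalized, these distances form a per-synapse cumulative curve
(Cum. PDF) whose shape separates flat appositions from curved, wrapping
ones; the median and 15th-percentile distances summarize it for group
statistics.

Design points:

- *Ribbon-facing selection.* A PSD boundary face belongs to the
  ribbon-facing sheet when its outward normal has a positive dot product
  with the direction to the nearest ribbon-surface point. If that selects
  nothing (pathological curvature), a fallback keeps the faces on the
  ribbon side of the plane through the PSD centroid perpendicular to the
  centroid-to-centroid direction.
- *Distance engine.* Exact nearest-neighbor search over boundary-face
  centers, chunked to bound memory — not a grid distance transform, so
  distances are not quantized to the lattice. Face centers (rather than
  mesh vertices of a smoothed surface) are the surface representation;
  both the query and target surfaces are therefore quantized by up to
  √3/2 voxel. On a concentric ribbon/shell phantom with a true 100 nm gap
  this puts the median within one voxel of truth with an SD of about half
  a voxel; isolated corner faces can deviate ~2 voxels, which is the
  attainable precision of any face-center representation.
- *Quantiles* use linear interpolation between order statistics (type 7),
  the field's default.
- *Group mean curves* interpolate each synapse's cumulative curve onto a
  common grid (default 0–1050 nm in 7 nm steps, extended to the data) and
  average with one unit of weight per synapse, so large PSDs do not
  dominate.
- A profile of a structure against itself is rejected (overlapping masks
  error out) rather than returning zeros.

## The four geometric model synapses

`phantom_spec()` builds the reference shapes used to interpret real
curves: a 300 nm spherical ribbon whose edge sits 84 nm (12 voxels) from
the center of a PSD sheet with a 1400 nm projected diameter; the *disk*
(flat), *ring* (flat, 250 nm central hole), *hemisphere* (bowl), and
*donut* (central hole, curvature changing sign radially).

Two geometric readings deserve a note:

- *Hemisphere.* Three constraints must hold together: the 84 nm edge
  offset, the 1400 nm projection, and distances spanning a narrow range
  ("the ribbon sits inside the bowl"). With the PSD "center" read as the
  bowl's pole, the nearest distance would be 84 nm but the rim distance
  ~690 nm — wider than the disk, contradicting the narrow-range behavior.
  The package reads "center" as the centroid of the PSD sheet (for the
  flat models the same point as the sheet center): the bowl is a
  hemisphere of radius 700 nm (projection 1400 nm) and the ribbon sits on
  the symmetry axis 84 nm + ribbon radius from the shell centroid, toward
  the mouth — near the bowl's sphere center, hence distances confined to a
  ~140 nm band but not constant. The bowl radius is exposed as a
  parameter.
- *Donut.* The published description fixes the hole, the outer diameter,
  and the curvature sign (concave near the hole, convex peripherally) but
  no radii. The sheet is a surface of revolution whose radial profile
  enters the hole edge at a fixed downward angle, descends along a
  concave arc (`donut_inner_radius_nm`, default 300), and falls away
  convexly (`donut_outer_radius_nm`, default 600). Because the profile
  descends monotonically, every donut distance is at least the ring's
  distance at the same radius: the donut curve starts where the ring's
  does (the hole removes the shortest disk distances) and rises more
  slowly, sitting between the ring and the hemisphere at short distances —
  the qualitative ordering the models exist to span. Both radii are
  parameters, not constants.

PSD sheets are 2 voxels thick — the thinnest shell that stays closed under
6-connectivity.

## Synthetic scenes and what they do (and do not) emulate

`scene_spec()`/`make_scene()` build a small population of synapses on a
row of IHCs with known ground truth. The defaults are the study conditions
the package is tested against:

- 3 cells staggered along Z by ±3000 nm (neighboring IHC basolateral poles
  alternate), 38 synapses (16+16+6) in the immature-like profile or 32
  (16+8+8) in the mature-like profile; double-ribbon synapses at the
  observed fractions (3/38, 2/32).
- Ribbon volumes are log-normal. The mature-like profile programs the M–P
  gradient as a modiolar/pillar *step* in the median (4.87 vs
  2.38 × 10⁶ nm³; dispersion sdlog 0.45 from the printed SD/median
  ratio). A step — rather than a continuous ramp — makes the group medians
  equal the programmed parameters exactly and implies a Spearman ρ of
  about −0.5 against the M–P coordinate, matching the reported gradient
  strength. The immature-like profile uses one median (4.3 × 10⁶ nm³) on
  both sides, so its gradient is null.
- PSD/PD areas are log-normal (medians 0.58/0.75 µm² immature, 0.31/0.33
  mature) with log-scale correlation 0.9 across the cleft; axis ratios
  ~1.65 (immature) vs ~3.0 (mature).
- Vesicle pools: ribbon-associated counts are Poisson with mean
  1200 · (analytic ellipsoid surface in µm²) — calibrated so the median
  synapse carries ~120–130 vesicles, because smooth ellipsoids have less
  surface per volume than real amorphous ribbons — plus a
  membrane-associated pool (mean 53 immature / 30 mature per synapse) and
  distractor markers beyond both thresholds. Markers are points; pools
  are defined by center-to-surface distance with inclusive thresholds
  (80 nm ribbon, 20 nm PD), and are never deduplicated across pools (dual
  members are flagged).

Scenes are emitted at 14 nm spacing. A full multi-cell volume at 7 nm
would be tens of billions of voxels; at 14 nm the smallest ribbons still
rasterize with sub-3% volume error while a 3-cell scene fits in a single
in-memory array. The cell row is also spatially compacted (synapse
footprints keep their true sizes; empty space between structures is
reduced), and PD/PSD patches are placed flat (normal along Y) on a
collision-free slot grid — truncating the rare patch whose axes exceed the
slot. The geometric model synapses keep the native 7 nm.

Constructive truth: the truth table records both the analytic draw and the
voxel recount of every ribbon volume (they agree within voxelization
error), the anchor coordinates, frames, and group labels computed by the
same translation rules the mapping module uses, and per-pool marker counts
classified against the same voxel surfaces the counting module uses — so
recovery tests compare against exact constructed values, with markers kept
away from the threshold boundaries so a recount cannot flip them.

`make_scene(..., voxelize = FALSE)` emits the same truth, layout, and
markers without rasterizing. This light mode is used for statistical
calibrations across many seeds (the null-gradient rate at the immature
profile; the translated-vs-native attenuation property), where only
anchors and sizes matter and voxelization perturbs volumes by under 3%.
The voxelized path is exercised end-to-end on single seeds.

What the generator does **not** emulate: amorphous ribbon shapes (real
ribbons have ~2–3× the surface-to-volume of ellipsoids, so voxel-face
areas of scene ribbons sit below the reported 0.3–0.4 µm² range), curved
or obliquely oriented membrane densities, IHC cell bodies, segmentation
errors, and any EM gray-scale appearance. Passing recovery tests therefore
demonstrates that the measurement chain is correct on known geometry — not
that it is robust to segmentation noise.

## Position mapping

The synapse anchor is the centroid of the union of the synapse's ribbon
voxels (the structure every synapse has; the choice is documented and
swappable). Frames are pure translations, never rotations or scalings:

- *native*: Y shifted so the most habenular synapse is 0; Z shifted so the
  most modiolar and most pillar synapses are equidistant from 0.
- *translated*: the same two shifts applied per IHC, then pooled — a
  common cell-centric frame.

Groups: Z < 0 → modiolar, Z > 0 → pillar; Z exactly 0 is assigned pillar
*and flagged*, since the sign rule covers only strict inequalities. The
habenular/cuticular split at the midrange of Y is a reporting convenience;
the H–C axis is otherwise treated continuously. A cell whose synapses do
not span Z has an undefined cell frame: its rows are flagged, never
silently dropped. Gradients are Spearman's ρ of a metric against one
coordinate with the t-test p-value.

## Statistics

All values are reported as median ± SD (n−1). The battery is deliberately
nonparametric: a KS screen against a fitted normal (plain, not Lilliefors
— with estimated parameters it is conservative as a rejection device,
which is acceptable for a screen), two-tailed Wilcoxon rank-sum for group
contrasts, Spearman's ρ with p from t = ρ√((n−2)/(1−ρ²)), and the
**median-based** Hedge's g (difference of medians over pooled SD). The
median-based numerator is intentional — it is the definition that
reproduces the printed effect sizes for skewed morphometric data; the
conventional mean-based variant is available behind a flag.

Wilcoxon switches from the exact distribution to the tie-corrected normal
approximation (with continuity correction) at combined n > 25 or any ties;
the branch used is recorded in each result. The approximate branch's
type-I error at n = 15+15 is calibrated in the tests (0.05 ± 0.01 over
2000 null replicates). No multiple-testing correction is applied; all
p-values are raw, matching the reporting style the tables follow.

`group_table()` builds the reporting table: one row per metric × group
with n, median, SD, range (ribbons counted per ribbon, so double-ribbon
synapses contribute two rows), and Wilcoxon + g for each contrast; groups
with n < 2 are flagged rather than dropped, and contrasts against them are
skipped with a recorded reason.

The receptor-count helper multiplies a PSD area by a constant packing
density (default 900 AMPA-type receptors per µm²) — a stated downstream
interpretation, kept as a reporting column with the density configurable.

## Pipeline, determinism, problem sizes

`run_pipeline()` composes measure → map → proximity → pools → stats on a
file pair, a phantom list, or a scene spec, writes the report bundle
(morphometry, positions, per-synapse profiles, summary curves, pools,
group table, contrasts) plus a manifest (config, seed, package version),
and is a pure function of (input, config, seed): reruns are byte-identical
up to the manifest timestamp. Every stochastic step draws from the single
seed.

Problem sizes used by the shipped tests: phantoms at 7 nm (≈4–6 M voxel
grids, 30–95 k surface faces per model); one fully voxelized mature-like
scene (3 cells, 32 synapses, ≈2×10⁸ voxels) for end-to-end gradient
recovery; 100-seed light-mode batches for the statistical calibrations;
2000-replicate null calibration of the Wilcoxon path. These sizes were
chosen so the full suite represents every code path at full resolution
while remaining runnable on a laptop-class single core.

## Known limitations

- The in-plane sheet axes assume a locally planar density; a strongly
  cup-shaped PSD's long axis is measured in its principal plane, which can
  exceed the geodesic extent of the sheet.
- Face-center surface representation limits distance precision to about
  one voxel (see above); sub-voxel claims should not be made from these
  profiles.
- The scene generator's ellipsoid ribbons undercut real voxel-face surface
  areas; tests that need realistic area *values* (rather than rank
  structure) use the analytic truth instead.
- Wilcoxon p-values under heavy ties rely on the normal approximation;
  with tiny tied samples, exact conditional tests would differ.
- Single-IHC volumes make the translated and native views identical by
  construction; gradient comparisons between views require ≥ 2 cells.
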