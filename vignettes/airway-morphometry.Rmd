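---
title: "Airway-tree morphometry from binary masks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Airway-tree morphometry from binary masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwaymorph)
```

## The measurement problem

Automatic airway segmentation of chest CT tends to be *incomplete*: distal
branches are missed, and the branches that are found may include part of the
airway wall, so the lumen looks wider than it is. Whether a segmentation
improved after manual correction or model retraining is therefore judged on
aggregate morphometry: how many airway branches a segmentation contains, how
much total centerline length, and how wide the median lumen is — overall and
per bronchial generation. `airwaymorph` computes these quantities from a
binary mask alone, and ships a phantom generator so that every stage of the
computation can be validated against known ground truth without patient
data.

The pipeline is:

1. **Thinning** (`skeletonize`) — the mask is reduced to a one-voxel-wide
   centerline skeleton, turned into a graph whose nodes are skeleton voxels
   (physical mm coordinates) and whose edges join 26-adjacent voxels.
2. **Cycle removal** (`break_cycles`) — per component, a
   maximum-total-length spanning tree is kept. This both removes genuine
   loops (touching segmentations) and the edge triangles that 26-adjacency
   creates at diagonal steps, preferring the longer, straighter diagonal
   edges.
3. **Root detection** (`find_root`) — the trachea end is the most superior
   degree-1 node of the component with the largest mask voxel count; ties
   break to the lowest node id.
4. **Spur pruning** (`prune_spurs`) — terminal chains shorter than
   `min_spur_length_mm` (default 2 mm, about three voxels at CT spacing)
   are thinning artifacts, not airways, and are removed iteratively.
5. **Branch decomposition** (`decompose_branches`) — branches are maximal
   chains between the root, junction nodes (degree ≥ 3) and leaves.
   *Generation* counts bifurcation events on the path back to the trachea:
   the trachea is generation 0, the main bronchi generation 1. A junction
   of degree d spawns d − 1 daughters that all inherit parent + 1, so a
   voxel-level trifurcation increments once; junction nodes closer together
   than `junction_fuse_mm` (default 1.5 mm, about two voxel steps) are
   treated as a single smeared bifurcation for the same reason.
6. **Occlusion bridging** (`attach_disconnected`) — a mucous plug splits
   the air column; the distal part appears as a separate mask component.
   A component whose air column comes within `bridge_max_mm` (default 5 mm)
   of the main component is virtually bridged at the nearest pair of
   skeleton endpoints; generations continue across the bridge (a degree-1
   to degree-1 bridge is a continuation, not a bifurcation) and the bridge
   gap contributes no length. Unbridgeable components stay in the branch
   list with generation "unassigned".
7. **Measurement** (`measure_tree`) — branch length is the centerline arc
   length between bifurcations; lumen diameter is sampled every
   `interval_mm` (default 1 mm) of arc length as twice the trilinearly
   interpolated Euclidean distance to the background (the inscribed-sphere
   diameter) and averaged per branch, unweighted.
8. **Cohort statistics** (`summarize_segmentation`, `compare_paired`) —
   per-segmentation aggregates; paired variants are compared per subject
   with the exact Wilcoxon signed-rank test and Bonferroni correction,
   significance at adjusted p < 0.05.

## Numerical choices

**Thinning.** The skeleton is computed by distance-ordered homotopic
erosion: border voxels are deleted in increasing order of their exact
Euclidean distance to the background (ties broken by voxel index, so the
result is deterministic), subject to two constraints — a voxel is only
deleted if it is *simple* (deleting it changes neither the 26-connected
foreground topology nor the 6-connected background topology of its 3×3×3
neighbourhood, the Bertrand–Malandain characterization) and never if it is
a curve endpoint (a single foreground neighbour). Deleting cheapest-first
makes the surviving voxels track the medial ridge of the distance field, so
the skeleton is centered in the lumen. Directional (6-subiteration)
thinning was tried first and rejected: its sequential passes can peel a
short side branch entirely before an endpoint forms.

**Distance field.** The exact anisotropic Euclidean distance transform
(per-axis lower-envelope algorithm) gives each foreground voxel its
distance in mm to the nearest *background voxel center*. This definition is
exactly checkable against an all-pairs scan, and makes the inscribed-sphere
diameter biased high by up to about half a voxel — within the one-voxel
tolerance the validation targets use.

**Tip localization.** Thinning leaves roughly one lumen radius of
uncertainty at a free tube end: depending on deletion order it may freeze a
spike running into the rounded end, or stop short while the distance value
is still large. Measured branches therefore end at the outermost point —
walking along the chain and, if necessary, its straight continuation —
where the interpolated distance value still reaches the branch's median
caliber minus half a voxel (`refine_tips`). Beyond that point the lumen
profile collapses, which is the operational definition of "the branch ends
here". A consequence worth knowing: at a *flat* airway stump (an occlusion
face) this rule retracts the tip by about one radius, so fragment lengths
near occlusions are conservative; bridging is unaffected because it is
decided on the mask, not the skeleton.

**Bifurcation localization.** The skeleton junction node sits inside the
inflated parent–daughter union and can be a millimetre or two proximal or
distal of the anatomical carina. Since airway branches are locally
straight, the carina is re-estimated as the least-squares intersection of
the branch axes fitted just outside the junction ball (`refine_junctions`);
the fit excludes the region within one junction-ball radius of the node.
The relocation is rejected if it moves the point by more than 1.5 junction
radii (a sanity guard against pathological fits).

**Centerline smoothing.** Branch polylines are mildly smoothed with a
5-point moving average (endpoints fixed) before measuring. Raw voxel
chains overestimate the length of oblique branches by up to ~8%
(staircase effect), which is incompatible with recovering lengths to
within max(5%, one voxel diagonal); the smoothed chains stay inside the
lumen for any branch at least a voxel in radius. Set `smooth_window = 0`
to audit the raw chains.

**Signed-rank test.** Zero differences are dropped (Wilcoxon's
convention), tied absolute differences get average ranks, the statistic is
min(W+, W−). For effective n ≤ 25 the two-sided p is exact: doubling the
average ranks makes them integers, so the permutation distribution of W+
over all 2^n sign assignments is obtained by convolution and the lower
tail is doubled (the distribution is symmetric even under ties). Above
n = 25 a normal approximation with tie-corrected variance and no
continuity correction is used, matching the common scientific-software
default. Bonferroni m defaults to the number of non-baseline variants per
metric — comparisons are all made against the same baseline — and can be
overridden.

**Aggregate definitions.** The median luminal diameter of a segmentation
is the median over per-branch *mean* diameters: diameters are averaged
within a branch first, so long branches do not dominate the
per-segmentation value. `airway_count` and `total_length_mm` cover every
branch with an assigned generation (trachea-connected plus bridged);
unassigned (disconnected, unbridgeable) branches are tallied separately,
appear as an `"unassigned"` row of the per-generation table, and are
included in the `*_all` fields, so either reading of "total airway count"
is available. The trachea (generation 0) is counted; the per-generation
table makes that auditable.

**Probability maps.** Thresholding uses the inclusive convention: a voxel
exactly at the 0.5 cut-off is foreground. The convention is fixed and
documented rather than inferred.

## The phantom generator

`tree_spec()`/`generate_tree()` grow a recursive branching-tube tree with
known topology, generations, radii and lengths; `rasterize_tree()` renders
every branch as a capsule (cylinder with hemispherical caps: a voxel is
foreground iff its center lies within the branch radius of the centerline
segment), which is deliberately simple enough to verify voxel-by-voxel
against a brute-force point-in-capsule test.

Geometry defaults, chosen once to be anatomically proportioned and fully
resolvable at 0.7 mm isotropic spacing (the CT reconstruction increment the
package targets):

| parameter | default | why |
|---|---|---|
| `root_length_mm`, `root_radius_mm` | 20 mm, 4 mm | desk-scale trachea analogue, slender (L/r = 5) |
| `length_ratio`, `radius_ratio` | 0.72, 0.72 | homothetic branching: length stays ~5 lumen radii at every generation, as in real bronchi; stubby branches (free length below ~2 radii) are what thinning cannot resolve |
| `branch_angle_deg` | 35° | typical bronchial half-angle |
| `angle_jitter_deg` | 5° | randomness across seeds without risking branch collisions |
| `spacing_mm` | 0.7 mm isotropic | CT-like reconstruction increment |
| `min_radius_mm` | 1 mm | ~1.4 voxels; below ~2 voxels of radius thinning becomes unreliable |

Each junction tilts its daughters within the plane *perpendicular to the
parent's own branching plane* (propagated down the tree), the alternating
arrangement of real bifurcations. This structured construction — rather
than fully random azimuths — is what keeps non-adjacent branches well
separated (`branch_clearance` stays above ~4 mm at depth 4, versus
collisions with random azimuths); the jitter on tilt and azimuth supplies
the seed-to-seed variability.

`degradation_spec()`/`degrade_mask()` emulate the three contrasts of
interest: pruning whole distal subtrees (how an automatic model misses
continuations), isotropic radius dilation (over-inclusion of the airway
wall), and focal occlusion gaps with flat faces (mucous plugging; the
distal part is kept in the returned ground truth as a separate component).

**What the phantoms do not emulate:** CT intensities, noise and dose, the
airway wall as a structure, non-circular cross-sections, curved branches,
anatomical asymmetry (real airway trees are not balanced binary trees) and
neighbouring structures (vessels, parenchyma). Passing the recovery tests
therefore demonstrates that the *measurement machinery* is correct on
resolvable geometry; it does not certify segmentation accuracy on real
scans.

## Validation problem sizes

The test suite and acceptance checks run at sizes chosen to exercise every
code path at desk scale: topology/metric recovery uses ten seeded phantoms
of maximum generation 3 (15 branches each, radii 4 mm down to 1.49 mm, all
at least two voxels) at 0.7 mm spacing; the paired-cohort check uses 15
phantom subjects with a pruned variant (all generation-3 branches removed)
and a dilated variant (+0.5 mm radius); exactness of the signed-rank test
is checked against full 2^n enumeration on 100 random fixtures with n ≤ 12.
On these conditions the pipeline recovers branch counts, parent relations
and generations exactly, branch lengths within max(5%, one voxel diagonal)
and mean diameters within one voxel of twice the truth radius.

## Known limitations

- Branches thinner than about two voxels in radius may be shortened or
  missed by thinning — the same resolution limit that makes real small
  airways hard to segment. Phantom defaults keep radii above it.
- The diameter estimator is the inscribed-sphere reading of "lumen
  diameter". A perpendicular-cross-section equivalent diameter would differ
  for non-circular lumens; the choice is documented, not claimed to match
  any particular clinical tool.
- Diameter samples at shared junction endpoints are included in the branch
  mean; near a bifurcation the inscribed sphere spans the union, biasing
  branch means slightly upward (fractions of a voxel for branches several
  samples long).
- Lengths of branch fragments at occlusion faces are conservative by about
  one radius (see tip localization above).
- The DICOM support is a minimal Explicit-VR-Little-Endian
  secondary-capture-style slice series — a transport format that
  round-trips geometry exactly, not a conformant clinical archive.

## A worked phantom

```{r example, eval = FALSE}
spec <- tree_spec(seed = 1, max_generation = 3)
truth <- generate_tree(spec)
mask <- rasterize_tree(truth)
tree <- measure_airways(mask)
summary(tree)
compare_tree_to_truth(tree, truth)$topology_equal
```
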