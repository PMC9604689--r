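---
title: "Graph-based unsupervised brain segmentation: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based unsupervised brain segmentation: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gubs)
```

## The segmentation model

`gubs` treats skull stripping as a graph-partition problem with three
terminals. The preprocessed volume defines a 6-connected voxel adjacency
graph whose edge weights are absolute intensity differences, so low-weight
edges run inside homogeneous tissue and high-weight edges cross tissue
boundaries. Seed voxels known (by construction) to lie in the brain, in
non-brain head tissue, and in the background are each collapsed onto one
representative node; the minimum spanning tree of the collapsed graph then
contains exactly one path between any two representatives, and removing the
heaviest edge on the brain/non-brain path, followed by the heaviest edge on
the non-brain/background path, partitions the tree into the three classes.

The model's central assumption is that the heaviest intensity step along
the MST path between two region representatives is the anatomical boundary
between those regions. That holds when (a) each region is an intensity
plateau relative to the boundary contrasts, and (b) the seed sets actually
lie inside their regions. Almost all of the pipeline's machinery —
column-wise scaling, thresholding, the centroid-distance filter, the
zero-intensity check — exists to make (a) and (b) true on real heads.

Collapsing is done *before* the MST is built. This matters: collapsing
thousands of seed voxels into one node inserts zero-cost connectivity
between all of them, which anchors each region's plateau to its
representative and makes the two path cuts independent of where inside a
region the representative happens to sit.

## Parameters

| parameter | unit | default | role |
|---|---|---|---|
| `target_shape` | voxels | `NULL` (keep grid); profiles use 128³ | common working resolution |
| `threshold` | intensity (after scaling) | `NULL`; 0.32 (OASIS), 0.25 (IBSR) | zeroes dark voxels to disconnect brain from skull across thin dark interfaces |
| `min_object_size` | voxels | 64 | clears background speckle so the background is one clean region |
| `selection_line` | axis-0 index | none (heuristic 0.45·M with a warning) | surface points on the superior side of this line seed the brain |
| `delta1` | voxels | 15 (128-grid); 8 at 64³ | inward pull distance for brain seeds |
| `delta2` | voxels | 1; 3 for unthresholded data | inward pull distance for non-brain seeds |
| `distance_factor` | — | 0.75 | centroid-distance filter keeping pulled brain seeds away from the skull |
| `n_background` | points | 20 000; 5000 at 64³ | background seeds drawn without replacement |
| `axes` | — | `0` | axes for surface edge detection (see below) |
| `seed` | — | 1 | controls background sampling and representative choice |

Pull distances scale with the grid: the defaults above halve at a 64³
working size. The selection line is intentionally *not* automated — on real
data it is placed by visual inspection above the eyes/ears; the 0.45·M
default is a flagged heuristic starting point, not a validated procedure.

### Why `delta2` is the critical parameter

The dark interface (CSF/dura) that separates brain from skull is closer in
intensity to the brain than to the bright shell, so the heaviest edge on a
core-to-shell path is the interface/shell boundary — cutting there leaves
the interface attached to the brain. There are two ways to obtain a clean
brain boundary, and they correspond to the two parameter regimes shipped in
the profiles:

* **threshold regime** (`threshold` set, `delta2 = 1`): dark-interface
  voxels are zeroed; non-brain seeds stay on the bright tissue. Some zeroed
  interface voxels still side with the brain at the cut, which is why
  thresholded cohorts show slightly lower precision.
* **contrast regime** (no threshold, larger `delta2`): the `delta2` pull
  reaches *past* the bright shell into the dark interface, whose voxels are
  nonzero and therefore survive the zero-intensity check. They join the
  collapsed non-brain node, so the brain/non-brain path crosses only the
  brain/interface boundary, and the cut lands exactly there. This regime
  gives the cleanest recovery and is what the phantom tests use.

## Edge detection and pull geometry

Surface points are the ±1 forward differences of the hole-filled binary
head along a given axis. Each recorded point is the *foreground-side* voxel
of its transition, tagged with the detection axis and sign, so "pull
inward" is exactly `+sign · δ` along that axis for both transition
directions.

Detection defaults to axis 0 alone. With all three axes enabled, points
detected along an axis nearly tangent to the head surface move almost
parallel to the surface when pulled, ending *outside* the head yet close to
the centroid of the pulled cloud — the 0.75 filter cannot remove them, and
a single such stray, once collapsed into the brain node, connects the brain
representative to the background plateau at zero cost and ruins both cuts.
Restricting detection to the selection-line axis makes every pulled
candidate either land deep in the head or end up far from the centroid
laterally, where the 0.75 filter provably removes it.
`detect_edge_points()` still accepts any axis subset for analyses that need
full surface coverage.

## Numerical and contract choices

* **Scaling** is min–max per axis-0 column, matching the reshape-to-2D
  feature-scaling idiom; a column whose range is ≤ `1e-12` keeps divisor 1,
  so constant (all-background) columns map to 0 instead of amplifying
  noise.
* **Resize** uses trilinear interpolation (nearest-neighbour for labels);
  linear interpolation cannot overshoot, preserving the [0, 1] invariant.
  Mapping is pixel-centre aligned and an equal-shape resize is the
  identity.
* **Hole filling** is binary closing (3×3×3 element) plus interior-cavity
  filling (background components not reachable from the volume boundary),
  OR-ed with the input so foreground never shrinks.
* **Collapse** reduces the parallel edges it creates to their
  minimum-weight representative; only that edge can enter an MST, so the
  tree's total weight is unchanged (verified against a multigraph oracle in
  the tests).
* **MST determinism**: edges are put in canonical (weight, endpoint pair)
  order before the tree is computed, so re-runs are identical; ties beyond
  that are resolved by the deterministic C implementation in `igraph`.
* **Cut tie-break**: among equal-maximum path edges, the one nearest the
  first endpoint is removed. Any choice separates the endpoints; fixing one
  makes runs reproducible.
* **Seed-set contract**: the three sets must be pairwise disjoint and
  strictly smaller than the grid. Collisions are resolved with precedence
  brain > non-brain > background; background sampling is without
  replacement so every collapsed candidate is distinct.
* **The 0.75 filter is applied once**, not iterated: its purpose is to trim
  the stragglers of a single pull, and iterating it would progressively eat
  the legitimate seed cloud.
* **Node linearization** is R's native column-major order
  (`id = 1 + i + j·M + k·M·N`), documented and fixed so component labels
  reshape onto the volume with one `dim<-` assignment.
* **Thresholded voxels stay in the graph** as zero-intensity plateaus; the
  cuts, not a mask, decide their label.
* **No post-segmentation smoothing** is applied: the output is exactly the
  three MST components. Morphological cleanup of the mask is easy to add
  downstream but is not part of the model.

## The phantom: what it emulates, and what it does not

`generate_phantom()` builds concentric geometry — a medium-bright spherical
brain core (intensity 0.55), a dark thin gap (0.15, the CSF/dura analog), a
bright thin outer shell (0.9, scalp/skull analog) and exactly-zero
background — with voxel-exact 3-class ground truth. Defaults: 64³ grid,
core radius 0.8 of the half-extent (brains fill most of the skull), gap and
shell one voxel thick each (a few millimetres at this resolution). Optional
Gaussian noise (`noise_sigma`) perturbs tissue voxels and is clipped to
[0, 1]; the background stays exactly zero, both because the phantom's
contract is a zero background and because a real scanner's background noise
belongs to the scanner model, not to this geometry. An `ellipticity`
argument deforms the spheres for variety.

The phantom exercises every operator: binarization and hole filling see a
genuine enclosed cavity (the gap), edge detection sees a curved surface,
both pulls and the 0.75 filter act on real sphere geometry, and the two
cuts must find the brain/gap and shell/background contrasts. What it does
*not* emulate: anatomical shape, intensity inhomogeneity (bias fields),
partial-volume voxels, Rician background noise, or the open
neck/shoulders boundary of a real scan. Passing the phantom tests therefore
demonstrates that the machinery is correct, not that any particular
parameter set transfers to a given scanner protocol — on real data the
selection line and `delta2` still need per-cohort inspection.

Test and verification sizes were chosen to keep the full suite at roughly a
minute on one CPU: unit tests use 32³ phantoms and graphs of up to a dozen
nodes (where exhaustive spanning-tree enumeration is feasible as an
oracle); end-to-end recovery, determinism and seed-contract checks run at
64³ (≈ 2.6·10⁵ nodes, ≈ 7.7·10⁵ edges), with ten noise realisations at
σ = 0.02.

## Known limitations

* The selection line is manual by design; heads oriented unusually need the
  `direction` argument flipped.
* A single global `delta2` cannot follow a shell of strongly varying
  thickness; seeds then sample a mixture of shell and interface, and the
  brain/non-brain cut may leave part of the dark interface with the brain
  (lower precision, as on thresholded real cohorts).
* Regions are assumed 6-connected through their own plateau; pathologies
  that sever the brain into disconnected bright components would need
  multiple brain seeds per component and more than two cuts.
* The whole-volume graph is kept in memory; at 128³ this is ~6.3·10⁶ edges,
  comfortably within a laptop's RAM, but the approach is not designed for
  0.5 mm whole-head grids without downsampling.
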