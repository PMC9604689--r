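# gubs — graph-based unsupervised brain segmentation

`gubs` performs skull stripping (brain extraction) on 3D T1-weighted head MRI
volumes without any training data or atlas. It is aimed at neuroimaging
researchers who need a transparent, fully inspectable alternative to learned
or template-based brain extractors, and at method developers who want each
stage of a graph-based segmenter available as a standalone, testable
function.

## The method

A head volume `A(i,j,k)` of shape `M × N × L` is preprocessed (resized,
intensity-scaled per axis-0 column to [0, 1], cleared of small background
speckle, optionally thresholded) and represented as a **voxel adjacency
graph** `G = (V, E)`: one node per voxel, an edge between every 6-connected
pair (squared Euclidean distance 1), with edge weight

```
w(u, v) = |A(u) − A(v)|
```

Three mutually disjoint seed sets are sampled from the geometry of the head
surface, found as the ±1 forward differences of the hole-filled binary
volume:

* **TB** (brain): surface points above a user-set selection line, pulled
  inward by `δ1` voxels, then filtered by discarding points farther than
  0.75 × the maximum distance from the pulled-cloud centroid;
* **TNB** (non-brain): all surface points pulled inward by `δ2` voxels,
  dropping any that land on zero intensity;
* **TBG** (background): a uniform random sample (default 20 000) of the zero
  voxels outside the closed head surface.

Each seed set is **collapsed** onto a single representative node (edges
inside the set are discarded, edges touching it are re-homed, parallel edges
keep their minimum weight). On the collapsed graph the **minimum spanning
tree** is computed, and the tree is cut twice: the heaviest edge on the
unique path between the brain and non-brain representatives, then the
heaviest edge on the path between the non-brain and background
representatives. The three resulting components, mapped back through the
collapse, label every voxel as background (0), non-brain tissue (1) or
brain (2).

Results are scored with the six standard voxel-overlap measures
(`JI = TP/(TP+FP+FN)`, `DSC = 2TP/(2TP+FP+FN)`, sensitivity, specificity,
accuracy, precision).

## Worked example

The package ships a synthetic head-phantom generator (bright thin
scalp/skull shell, dark thin CSF-analog gap, medium-bright spherical brain
core, zero background) with voxel-exact ground truth, so the whole pipeline
can be exercised without downloading MRI data:

```r
library(gubs)
ph  <- generate_phantom(shape = c(64, 64, 64), noise_sigma = 0.02, seed = 1)
fit <- gubs(ph$volume, selection_line = 29, delta1 = 8, delta2 = 1,
            n_background = 5000, seed = 1)
print(fit)
summary(fit, truth = ph$labels)
```

```
Graph-based brain segmentation
  grid: 64x64x64 (262144 voxels)
  brain: 71680  non-brain: 16168  background: 174296 voxels
  seeds: 1664 TB / 4784 TNB / 5000 TBG; cut edge weights: 0.3201, 0.8816
Segmentation summary (64x64x64 grid)
background   nonbrain      brain
    174296      16168      71680
selection line 29, delta1 8, delta2 1, threshold none, seed 1
overlap with ground truth (brain class):
    jaccard        dice sensitivity specificity    accuracy   precision
     0.9810      0.9904      1.0000      0.9929      0.9948      0.9810
```

The two printed cut weights are the intensity contrasts the method severed:
the brain/interface boundary (0.32) and the head/background boundary (0.88)
— exactly the two transitions a correct segmentation must cut. A Dice of
0.99 with sensitivity 1.0 means the full brain core was recovered, with the
small false-positive excess coming from the dark interface voxels adjacent
to the brain.

For real data, `gubs_profile("oasis" | "ibsr" | "bw")` returns the
per-cohort parameter sets at the standard 128³ working grid (thresholds
0.32 / 0.25 / none, selection lines 60 / 65 / 35, `δ1 = 15`,
`δ2 = 1 / 1 / 3`), and `plot(fit)` shows intensity and label slices side by
side.

## Command line

```sh
inst/scripts/gubs phantom  --output head.nii.gz --labels-output truth.nii.gz
inst/scripts/gubs segment  --input head.nii.gz --output labels.nii.gz \
    --selection-line 29 --delta1 8 --delta2 1 --bg-samples 5000 --seed 7
inst/scripts/gubs evaluate --input labels.nii.gz --truth truth.nii.gz
```

`segment` writes a JSON provenance sidecar (all parameters, seed, package
version); re-running with the same seed reproduces the labels byte for
byte. A YAML file passed via `--config` supplies defaults; explicit flags
win.

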