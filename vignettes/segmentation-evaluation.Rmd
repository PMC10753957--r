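---
title: "Evaluating 3D instance segmentations with mitometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating 3D instance segmentations with mitometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitometrics)
```

## The problem

Volume electron microscopy of brain tissue resolves individual mitochondria
across thousands of serial sections, and automatic instance segmentation of
those volumes — one integer id per mitochondrion, 0 for background — is now
good enough that the interesting question is *how* a prediction fails, not
just how much. A single overlap score hides the difference between a decoder
that shatters long, beaded mitochondria ("mitochondria-on-a-string", MOAS)
into fragments and one that fuses neighboring organelles into a single
blob. `mitometrics` implements a metric panel designed to separate those
failure modes, together with the baseline watershed decoder that most
foreground + contour ("BC") segmentation networks rely on, and a synthetic
scene generator that can fabricate segmentations with *known* errors to
validate the whole pipeline.

Everything operates on two `label_volume` objects of identical shape, with
axes ordered (z, y, x) — the thick sectioning axis first — and a physical
voxel spacing in nm (the serial-section convention of 30 x 8 x 8 nm is the
default). All metrics flow from a single sparse overlap table: the voxel
count of every co-occurring (ground-truth id, prediction id) pair.

## The metric panel

**IoU and the overlap table.** For instances $A$ (ground truth) and $B$
(prediction), $\mathrm{IoU}(A,B) = |A \cap B| / |A \cup B|$. The table is
built in one linear pass over paired voxels; IoU is always derived from its
counts, never from re-rasterized masks, so every downstream metric shares
one source of truth.

**Matching accuracy.** Predictions and ground-truth instances are matched
one-to-one by the Hungarian algorithm, minimizing
$\sum_{i,j} C(i,j)\,X(i,j)$ with

$$C(i,j) = -\big[\mathrm{IoU}(g_j, p_i) \ge T\big] \;-\;
  \frac{\mathrm{IoU}(g_j, p_i)}{2N},$$

where $T = 0.75$ and $N = \min(\#\text{pred}, \#\text{gt})$. The second
term is read as a *division* by $2N$: only a term strictly smaller than
$1/2$ per pair keeps the indicator dominant, so the assignment first
maximizes the number of supra-threshold matches and uses IoU purely as a
tie-break among equal-indicator alternatives. Assigned pairs with IoU
$\ge T$ are true positives; precision $= TP/(TP+FP)$, recall
$= TP/(TP+FN)$, and the ranking metric accuracy $= TP/(TP+FP+FN)$. A $0/0$
ratio is reported as 0, which is what a per-group table shows when a group
has no instances on either side.

**AP-75.** Bottom-up decoders emit no confidence, so instance voxel count
stands in for it: predictions are ranked by size (ties by ascending id) and
matched greedily in rank order — each prediction takes the highest-IoU
still-unmatched ground-truth instance if IoU $\ge 0.75$. Precision is
interpolated as $p_{\mathrm{interp}}(r) = \max_{\tilde r \ge r} p(\tilde
r)$ and averaged at the eleven recall levels $0, 0.1, \ldots, 1$. The
greedy matcher is deliberately distinct from the Hungarian one — it is the
standard AP semantics — and the exact-area variant (`ap_allpoint()`) is
exposed for diagnostics only.

**Association taxonomy.** With $A$ the set of (prediction, ground truth)
pairs of positive overlap, $A(g)$ the predictions touching $g$ and
$A'(p)$ the ground-truth instances touching $p$, every ground-truth
instance is exactly one of: *one-to-one*, *over-segmentation* (split into
exclusive pieces), *under-segmentation* (merged exclusively with others;
each merged instance receives the label), *missing*, or *many-to-many*.
Predictions touching nothing are *background*. Non-background categories
are percentages of the ground-truth count — they always sum to 100 — while
background is a percentage of the prediction count.

**Cable length and size groups.** Instances are grouped as small (length
$\le 1\,\mu m$), medium, or large ($\ge 4\,\mu m$) by the length of their
skeleton. The skeleton is computed by sequential topological thinning on
the voxel grid (simple border points are peeled in six directional
subiterations; endpoints are preserved), the surviving voxels become a
26-connected graph with physically weighted edges, and the cable length is
the spanning-tree edge sum — the tree prevents double-counting in thick
junction clusters. Thinning runs on the grid and weights edges by spacing
afterwards, with no isotropic resampling: this is deterministic and
interpolation-free, and is the main free choice in the morphology module.
Its known cost is a small orientation sensitivity — a tube can lose about
one voxel per end depending on which axis it runs along — so cable length
is invariant under joint axis permutation only up to that end effect, and
the toy-scene tube lengths are chosen with comfortable margins to their
group boundaries. A legacy volume-based grouping is available but has no
default thresholds, since voxel cutoffs are dataset-specific.

**Splits and mergers.** Over-segmentation pairs form the split set $S$ and
under-segmentation pairs the merger set $M$; a many-to-many pair goes to
$S$ when the ground-truth fan-out dominates ($|A(g)| > |A'(p)|$), to $M$
when the merge dominates, and to $S$ on ties. The printed form of the
split-set definition attaches the opposite inequality, which would exclude
every pure over-segmentation pair from $S$; the package follows the
fan-out semantics, and `as_printed = TRUE` gives the literal reading for
comparison. Per-instance split/merger counts are summarized in 15
equal-width bins of ground-truth cable length ("evenly divided" is read as
linear, not logarithmic, bins).

## The baseline decoder

`decode()` implements the BC pipeline: seeds are connected components of
(foreground $\ge \theta_{seed}$) AND (contour $< \theta_{contour}$) — the
AND of a high foreground and a low contour is the only combination of the
two thresholded maps that yields distinct, non-touching seeds — then a
marker-controlled watershed floods the inverted foreground probabilities
from the seeds, confined to the mask foreground $\ge \theta_{fg}$, and
instances smaller than `min_voxels` are removed (strictly fewer than: an
instance of exactly the threshold survives). Two presets carry the
challenge post-processing settings: `"mitoem-h"` (0.7 / 0.6 / 0.6,
min 1024 voxels) and `"mitoem-r"` (0.85 / 0.6 / 0.8, min 1024).
Connectivity defaults to 26 (full 3D) and is configurable to 6. Watershed
plateau ties are broken by deterministic insertion order, so identical
inputs always produce identical labels. An optional per-x-slice (y, z)
median filter reproduces the 2D baseline's denoising step.

## The synthetic generator

The generator serves two purposes and deliberately nothing more.

First, `build_toy_scene()` reconstructs the published six-instance worked
example: 2 small, 3 medium and 1 large instance by cable length; one small
and two medium instances matched exactly; the remaining small + medium
pair covered by a single merged prediction; the large instance covered by
three disjoint pieces; plus five background false positives. The published
description fixes only the *outcome-determining* facts — the counts, which
IoUs clear 0.75, and the exclusive-overlap structure — not the geometry,
so the scene uses schematic axis-z tubes (3 x 3 voxel cross-section) whose
lengths (20/30/68/40/150 voxels) land safely inside their groups, and the
construction asserts post hoc that every planned relation holds. The
false-positive count is a free parameter: the published background
percentage and small-group precision depend on an unprinted FP count whose
printed values are not simultaneously satisfiable with integer counts, so
those cells are not targets of this reconstruction. The merged pair uses
comparable sizes (30 vs 40 voxel tubes) precisely so that neither
constituent reaches IoU 0.75 against the union.

Second, `random_scene()` + `error_plan()` + `inject_errors()` fabricate
arbitrary segmentations with known error content — $k$-way splits, $m$-way
merges, dropped instances, background false positives — under a fixed
seed. Because the planned categories are known exactly, the association
module can be tested for *parameter recovery*: a planned $k$-piece split
must come back as exactly $k$ split pieces, every time.

What the generator does **not** emulate: real EM texture, probability maps
from an actual network (rendered maps are clean indicators with 1-voxel
contour shells plus optional Gaussian noise), anisotropic boundary
uncertainty, or MOAS-like bead geometry. Passing tests therefore
demonstrate the correctness of the *metrics* and the *decoder mechanics*,
not segmentation performance on real tissue.

## Numerical choices and conventions

* Threshold boundaries are inclusive everywhere: IoU exactly $T$ counts as
  a match ("larger than" is implemented as $\ge$ for consistency and
  determinism; exact-boundary cases are measure-zero in practice), length
  exactly 1 um is small and exactly 4 um is large, probability exactly at
  a decoder threshold is included.
* Greedy AP ties between equal-IoU candidates go to the lowest
  ground-truth id; size ties in the confidence ranking go to the lowest
  prediction id.
* The Hungarian step is solved exactly (via `clue::solve_LSAP` on the
  shifted cost; shifting by a constant cannot change the optimizer of a
  padded square problem). Among multiple equal-cost optima the solver's
  deterministic order decides; a strict lexicographic preference over
  optima was considered and dropped, as selecting the lexicographically
  minimal optimum is a separate optimization problem and determinism is
  what reproducibility actually requires.
* Per-group false positives are binned by the *prediction's own* group
  (its mask's cable length) by default, because per-group precision
  requires a group for predictions that match nothing; binning by the
  best-overlapping ground-truth instance's group is available via
  `fp_by = "matched_gt"`.
* Per-group AP restricts both sides to the group before matching, which
  reproduces the known behavior that a small instance merged into a
  larger prediction is a small false negative.
* Degenerate inputs: empty predictions give recall 0 and 100% missing;
  empty groups report score 0 with an `empty` flag rather than NA; an
  all-equal length vector occupies a single histogram bin.
* Label I/O: HDF5 (dataset `"main"`, spacing as an attribute) round-trips
  integer grids bit-exactly; multi-page TIFF stores 16-bit labels (ids
  above 65535 require HDF5) with spacing in a JSON sidecar. Missing
  spacing metadata falls back to 30 x 8 x 8 nm with a warning.

## Problem sizes used in the test suite

The validation suite works at desk scale by design: oracle-equivalence
checks run 200 random scenes with at most 6 instances per side on
$8 \times 10 \times 10$ grids, where exhaustive assignment enumeration and
per-voxel double loops are feasible; parameter recovery runs 50 seeded
error plans on $24 \times 44 \times 44$ grids with 6–8 instances; the
decoder recovery test renders 10 ellipsoids of about 1700 voxels each.
These sizes exercise every code path (rectangular cost matrices, empty
groups, many-to-many tangles) while keeping the full suite under a
minute. Scoring itself scales linearly in voxels and has no interaction
between instances beyond the sparse table, so desk-scale validation
transfers directly to larger volumes.

## A worked run

```{r example, eval = FALSE}
scene <- build_toy_scene()
report <- evaluate(scene$gt, scene$pred)
report
write_report(report, "report.json")
```

## Known limitations

* No out-of-core or chunked processing: volumes must fit in memory
  (desk-scale by design; the full challenge test volumes do not apply
  here since their labels are private).
* The thinning-based cable length is a documented stand-in for the
  original (unpublished) skeletonization procedure; absolute lengths can
  differ by end effects of one voxel per tube end, though grouping is
  robust for instances away from the 1 um / 4 um boundaries.
* No mesh, NIfTI or OME-Zarr I/O; no boundary-distance or surface
  metrics; no multi-threshold mAP (the panel evaluates AP-75 only); no
  network inference — probability maps must come from elsewhere (or from
  the synthetic renderer).
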