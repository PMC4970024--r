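---
title: "Separating maize, weeds, and soil in depth-camera field scans: methods and design notes"
author: "weedvol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{weedvol methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weedvol)
```

## The problem

Site-specific weed management needs per-patch estimates of weed pressure.
Consumer depth cameras (time-of-flight RGB-D sensors) can reconstruct a
colored 3D mesh of a field plot in seconds, and plant volume extracted
from such a mesh is a good proxy for biomass. The difficulty is
separating three classes in one scan of a tilled seedbed:

* **maize**, 0.40–0.55 m tall at the treatment-relevant growth stage;
* **weeds** — grasses up to 0.20 m and broad-leaved weeds under 0.10 m;
* **soil**, whose tilled microrelief (a few cm) is on the same height
  scale as the smallest weeds.

`weedvol` implements the full analysis as a tested pipeline: isolated
point filtering, detection of the white 1 m × 1 m sampling frame,
cropping and splitting into four 0.5 m × 0.5 m quadrats, a *dual*
segmentation (height for the crop, color for the weeds), polyhedral
volume estimation, and the downstream statistics (correlation and
regression of volume against dry biomass and weed density, and canonical
discriminant classification of the weed community into monocots, dicots,
and mixtures).

Because no field scans are publicly deposited, the package ships a
synthetic scene generator that emulates the study design with exact
ground truth; every stage is validated against it.

## The pipeline, stage by stage

### Isolated-point filtering

Fused depth reconstructions contain isolated speckle points off the
surfaces. A point survives if it has at least `min_neighbors` (default
1) other points within `radius` (default 1 cm, the reconstruction grid
scale); the rule is applied to point clouds or, for meshed input, to the
vertex set (faces that lose a vertex are dropped). The operation is
idempotent and order-independent, and the fixed-radius search is exact
(hashed uniform grid, distances re-checked).

### Frame detection and quadrat geometry

The sampling frame is painted white, so its vertices are found by a
low-chroma rule: all channels ≥ 200 **and** channel spread ≤ 30 (both
configurable). A PCA plane is fitted to the white vertices; their
in-plane projection is enclosed in a minimum-area rotated rectangle
(rotating calipers over the convex hull), which is then shrunk inward by
the median point-to-boundary distance. For a painted band this recovers
the band *centerline* — the nominal 1 m square — rather than the outer
silhouette. Cropping keeps faces whose centroid falls inside that
square (frame faces themselves are excluded); quadrat splitting assigns
each face by the quadrant of its centroid in frame coordinates, with
half-open midlines so a centroid exactly on a midline goes to the
lower-index quadrat.

Two consequences of face-centroid assignment are worth stating. Total
face count and area are conserved exactly, which is the invariant the
downstream volume bookkeeping relies on. The price is that a quadrat's
*vertices* can overhang its rectangle by up to one face diameter; a
strict vertex-containment guarantee is incompatible with exact face
conservation, and we chose conservation.

### Dual segmentation

Maize is isolated **by height**: faces with any vertex above
`height_threshold` seed a region growth over edge-connected faces
(adjacency = shared undirected edge, the conservative reading of
"connected faces" that cannot leak through a single pinch vertex).
The default threshold of 0.30 m is the midpoint between the tallest
weeds (0.20 m) and the shortest maize (0.40 m). Growth is restricted to
vegetation-colored faces and never enters faces lying entirely below
`ground_clearance` (2 cm), so a flood fill cannot escape through the
soil where a stalk meets the ground.

The remainder is split **by color**: the excess-green index
ExG = 2G − R − B is strongly positive on green tissue and zero on both
achromatic soil and the white frame. A face is weed when at least 2 of
its 3 vertices exceed `exg_threshold` (default 20 on the 0–255 channel
scale; an Otsu auto-threshold on the quadrat's ExG histogram is
available). The face-level 2-of-3 vote keeps the partition well defined
across color gradients. Weed sets are monotone in the threshold by
construction.

### Volume by polyhedral mass properties

Volumes are computed with the divergence theorem: one sixth of the sum
of vertex-position determinants over triangles, after faces are
reoriented coherently (breadth-first propagation across shared edges)
and the global sign fixed per connected component. This requires a
watertight mesh, and canopy surfaces from a top-view sensor are not
watertight, so `close_to_ground()` seals boundary loops first:

* loops whose lowest vertex comes within `ground_attach` (5 cm) of the
  ground plane — where a canopy surface ends at the soil — are projected
  onto the plane and sealed with side walls and a base fan;
* all other loops (sensor dropouts, cuts through foliage at a quadrat
  border) are patched in place with a centroid fan.

The distinction matters: projecting an airborne loop to the ground would
add the entire prism beneath it. With in-place patching, the two closed
halves of a plant cut by a quadrat border sum to the whole plant's
volume exactly (the shared cut loop gets the same fan with opposite
orientation). Boundary loops are extracted by an edge walk that
tolerates non-manifold (even-degree) boundary vertices and pinches
figure-eight walks into simple loops.

Two documented alternatives exist: `prism_volume()` (projected area ×
mean height, a height-field fallback used automatically when a boundary
cannot be closed) and `voxel_volume()` (counting 5 mm voxel centers by
vertical ray parity), which serves only as an independent oracle in the
tests. The voxel grid is anchored to the absolute coordinate lattice so
the oracle does not depend on an object's bounding box. On thin-bladed
plants with centimeter-scale stalks, single-mesh voxel error is
dominated by cross-section lattice quantization (roughly one lattice
cell on a 1 cm-radius stalk, i.e. several percent of one plant); the
estimator is unbiased, so agreement is tested on the mean over plants
and per mesh against the 2 · voxel · surface-area bound.

Estimated canopy volumes systematically *over*-estimate plant tissue
volume (closure seals concavities); this mirrors the behavior of the
sensor methodology the pipeline models, and it is why the statistics
work with linear relationships between volume and biomass rather than
absolute agreement.

### Statistics

Pearson correlation (p from the t-transform with n − 2 df) and ordinary
least-squares regression relate estimated volumes to dry biomass and
weed density; six relationships are computed per study, and a constant
regressor (e.g. maize count in a uniformly planted stand) flags the
relationship as degenerate rather than producing a spurious coefficient.
No multiple-testing correction is applied — six planned comparisons
reported raw, as is conventional for this design.

Weed-class discrimination uses canonical discriminant analysis on
per-quadrat weed height features (maximum and 90th percentile; the mean
is computed but not used by default). The canonical axes solve the
generalized eigenproblem "between-group over pooled within-group
scatter" through the Cholesky factor of the within matrix; axes are
scaled to unit pooled within-group variance so nearest-centroid
classification in canonical space is the Mahalanobis rule with equal
priors. A singular within matrix — the (max, p90) pair is nearly
collinear in small field samples — is ridge-regularized with
10⁻⁸ × trace. Confusion matrices are row-normalized percentages; the
default evaluation is leave-one-out (refit without each sample), the
less optimistic choice, with resubstitution also reported.

## The synthetic field generator

`generate_scene()` builds a complete framed scene with exact ground
truth; `generate_study()` arranges 40 quadrats (10 frames × 4) with half
the quadrats on the maize row, and a fixed composition of 12 grass-only,
10 broadleaf-only, 10 mixed, and 8 weed-free quadrats shuffled over the
study — the explicit version of the study's loosely stated mix.

Key modeling choices, with reasons:

* **Geometry is parametric-procedural**, not botanically realistic:
  maize is a tapered stalk with 4–6 arching blades, grasses are tufts of
  thin erect blades, broad-leaved weeds are low rosettes. The pipeline
  consumes only height, color, connectivity, and volume, so this is the
  right level of detail. Every plant is a *closed* mesh whose enclosed
  volume is computed at build time, making ground truth exact by
  construction.
* **All surfaces are tessellated at `point_spacing`** (default 7 mm),
  emulating the uniform sampling of a fused depth reconstruction. In
  truth-only mode (`mesh = FALSE`, used for large statistical
  replicates) the same parametric plants are discretized at a coarser
  2 cm step; this changes stored volumes only by small tessellation
  differences and none of the statistical structure.
* **Soil microrelief** is a smooth random cosine field of ±2 cm — large
  enough that height alone cannot separate the lowest weeds from soil,
  which is precisely why the color stage exists.
* **Maize canopies stay inside the frame** (wide placement margins at
  the outer frame edges), mirroring the field protocol of laying the
  frame around the sampled plants and keeping per-plant truth well
  defined under face-centroid cropping. Plants may still overhang the
  *internal* quadrat midlines; cut parts are closed on both sides and
  their volumes add back exactly.
* **Sensor noise** (`add_sensor_noise()`) models fusion residue: a
  smooth random depth field of the requested sd (default 3 mm;
  low-frequency registration error, the dominant error of ICP-fused
  multi-frame scans) plus a 0.3 mm white residual, 1% isolated outliers
  injected at least 2 cm off the surface, and 0.2% face dropout. An
  i.i.d. per-vertex depth error of 3 mm would be physically wrong for
  fused output and would occasionally isolate genuine surface vertices
  from their whole neighborhood.
* **Biomass** is linear in volume with multiplicative noise:
  `biomass = a · volume · (1 + ε)`, ε ~ Normal(0, σ), with σ calibrated
  from the realized volume moments so the population volume–biomass
  correlation equals a requested `target_r`
  (σ² = Var(V)(1/r² − 1)/E[V²]; σ = 0 at r = 1). Dry-matter density
  factors default to 60 kg m⁻³ (maize) and 90 kg m⁻³ (weeds), the
  order of magnitude of dry matter per canopy volume for young plants.
  ε is left untruncated to keep the stated model exact; at the default
  correlations negative draws extreme enough to matter are rare.

What the generator does **not** emulate: radiometric physics (sunlight,
IR interference), leaf overlap occlusion from a single viewpoint,
species-level leaf morphology, or registration artifacts beyond the
smooth error field. Passing tests therefore demonstrate the internal
correctness and statistical behavior of the pipeline, not sensor-level
performance on real scans.

## Numerical choices and degenerate inputs

* Degenerate faces are removed below an area of 10⁻¹² m² (numerically
  zero at scene scale); `clean_mesh()` is idempotent.
* Component ids are ordered by descending face count with ties broken
  toward the lowest face index, so labelings are deterministic.
* PLY I/O supports ASCII and binary little-endian dialects with
  per-vertex `uchar` colors; binary coordinates are 32-bit floats
  (round trips are exact to 10⁻⁶ m). Output is byte-stable.
* Empty inputs: empty cloud → empty cloud; soil-only quadrat → empty
  maize and weed meshes and zero volumes; an empty weed mesh is an
  error for height features ("no weed vertices").
* Every stochastic routine takes a single integer seed and restores the
  caller's RNG state; a study, and the full pipeline report, reproduce
  byte-for-byte from one seed.

## Problem sizes used in validation

The shipped validation runs at desk scale, chosen to exercise every code
path while keeping the suite quick: 5 noiseless scenes (20 quadrats,
~140k faces each) for exact segmentation recovery; 2 noisy scenes for
the robustness checks; 200 truth-only study replicates (40 quadrats
each) for correlation recovery; 20 random convex polyhedra and 5 maize
plants for the volume oracles. The analysis drivers under `analysis/`
run the full 10-frame, 40-quadrat study.

## Known limitations

* Weed volume under default noise is less accurate than maize volume
  (small absolute volumes, so closure effects weigh more); relationships
  with biomass remain strong because the errors are roughly
  proportional.
* The mixture class is intrinsically confusable with pure grass on
  height features alone — the sample maximum of a mixed quadrat *is* a
  grass height. The confusion matrix reproduces exactly this structure;
  discriminating the two needs features beyond height.
* `prism_volume()` assumes a height-field surface; it exists as a
  documented fallback and is wrong for closed elevated canopies. The
  closure path makes its use rare, and the report records which method
  produced each number.
* Frame detection assumes one dominant planar white rectangle; two
  frames in view, or a heavily occluded band, are out of scope.
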