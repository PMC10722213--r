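# fkmeans

Automatic segmentation of left-atrial (LA) fibrosis from 3D
late-gadolinium-enhancement (LGE) MRI-like volumes, in R.

Fibrotic atrial wall retains contrast agent and shows irregular,
high-complexity texture. `fkmeans` quantifies that irregularity with the
differential box-counting fractal dimension (FD) and segments fibrosis in
two stages:

1. **Voronoi clipping** removes the anatomical structures that confound
   fibrosis estimates — mitral valve (MV), pulmonary veins (PVs) and
   appendage (LAA). The periatrial region is binarized after z-scoring
   within the LA, a per-slice distance map from the wall edge localizes
   candidate structures, Voronoi cells partition the region, and adjacent
   cells whose FD difference is at least 0.7 *and* whose skeleton
   tortuosity difference is at least 1.0 are truncated from the wall.
2. **Hierarchical fractal-penalized K-means++** clusters the clipped wall
   voxels in three levels (cluster ranges 2–30, 2–5, 2–3) under the
   distance

   d(x,c) = sqrt( ‖x−c‖² + β·(FD(x)−FD(c))² + γ·(FD(x)−mean FD(cᵢ))² )

   with β = 0.1, γ = 0.5. At each stage the fibrosis estimate is the
   cluster(s) of maximal mean FD; a level's sweep over k stops when the
   estimate's FD mean or variance jumps by τ₁ = 0.1 / τ₂ = 0.05.

The per-pixel FD is the least-squares slope of log Nr versus log(1/r)
over scales 2 < r < R (default R = 7), with
Nr = (R²/r²)·((Mr−mr)/r) + 1 and Mr, mr the window extrema.

A synthetic phantom generator (ellipsoidal blood pool, thin wall, helical
PV tubes, smooth MV/LAA bulges, a planted textured fibrosis patch) makes
every stage testable without patient data, and an evaluation module
provides Dice, precision, recall, ASSD, MSSD, Hausdorff distance, HD95
and ICC(2,1). 2D intensity K-means and 3D region growing are included as
baselines.

## Worked example

```r
library(fkmeans)

spec <- phantomSpec(seed = 1)          # 96 x 96 x 24 LA phantom
res  <- runFull(list(phantom = spec, seed = 1), "demo_run")
res$report
```

```
SegmentationReport: Dice 0.932  precision 0.944  recall 0.920
  ASSD 0.176  MSSD 1.414  HD 1.414  HD95 1.000 (physical units)
```

`runFull` generates the phantom, clips the anatomical structures, computes
the FD map, runs the three-level clustering and evaluates the result
against the planted fibrosis. Dice 0.93 means the recovered mask overlaps
93% (by the harmonic criterion) with the planted patch; the sub-voxel
average surface distance (ASSD 0.18, maximum 1.4 voxel widths) shows the
disagreement is confined to the patch rim. The per-(level, k) FD
statistics and stop reasons land in `res$history` and in the run
directory's `provenance.json`; the fibrosis and clipped-wall masks are
written as NIfTI next to them. The individual stages are available as
`generatePhantom()`, `fdMap()`, `clipPipeline()`, `segmentFibrosis()`,
`tortuosity()` and `evaluateSegmentation()`.

Volumes and masks read and write NIfTI (`.nii`, `.nii.gz`) and MetaImage
(`.mha`/`.mhd`); `inst/cli/fkmeans.R` wraps the same functions as a small
command line (`phantom`, `fdmap`, `clip`, `segment`, `evaluate`, `run`,
`sweep`).

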