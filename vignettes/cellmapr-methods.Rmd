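---
title: "Whole-brain cell mapping with cellmapr: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-brain cell mapping with cellmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Immunolabeling for immediate-early gene products such as c-Fos marks
recently active neurons. After tissue clearing and light-sheet fluorescence
microscopy, a whole mouse brain becomes a 3D image stack of hundreds of
gigavoxels in which each labeled nucleus is a small bright blob a few
micrometres across. Turning such a stack into per-brain-region cell counts
requires detecting every blob, discarding confounds (ventricle lumens
accumulate antibody and glow), assigning each detection to an anatomical
region of a reference atlas, and comparing groups of animals region by
region. cellmapr implements that pipeline at desk scale, together with a
synthetic cleared-brain generator so that every stage can be validated
against known ground truth without any microscope data.

# Conventions

All volumes are R arrays with `dim = c(Z, Y, X)` — the first index is the
z-plane, matching multi-page TIFF layout. Voxel indices are 1-based, as is
idiomatic in R; the physical center of voxel `i` along an axis with
spacing `s` µm is `(i - 0.5) * s`. Bounding boxes are half-open
(`z0` inclusive, `z1` exclusive). Affine transforms map physical
micrometre coordinates of the stack to micrometre coordinates of the
atlas; atlas label lookup floors the continuous coordinate, because region
labels are categorical and must not be interpolated.

# The synthetic cleared-brain generator

`generate_toy_atlas()` builds a hierarchical region ontology in the style
of the Allen structure graph: one root, a ventricle leaf and a
fiber-tract leaf at level 2, and a recursive rectangular partition of
anatomical areas down to the requested depth (at most the 11 levels a
real structure graph uses). `generate_scene()` then emulates the
properties of a cleared, immunolabeled, light-sheet-imaged brain that
matter to the pipeline:

* **Cells** are drawn per region by a homogeneous Poisson point process at
  a chosen density (cells/mm³), rejecting placements that would overlap an
  existing cell or the ventricle lumen, so the ground-truth label mask has
  exactly one connected component per cell. Each cell is a 3D Gaussian
  blob, isotropic in micrometres and rendered into the (possibly
  anisotropic) voxel grid; somata of c-Fos+ nuclei are compact and round,
  so a blob with a truncated-normal radius (default 7 ± 1.5 µm) is an
  adequate morphological model. The binary ground truth marks voxels
  within one radius of the center (always at least one voxel).
* **Background** combines a parenchyma level, an elevated level inside
  ventricles (their lumen accumulates label), a smooth low-order
  polynomial illumination field applied multiplicatively (light-sheet
  illumination is never flat), and heteroscedastic Gaussian noise whose
  variance grows with intensity, mimicking photon noise. The
  signal-to-noise ratio parameter is defined as peak cell amplitude over
  the noise standard deviation at background level.
* **Geometry**: the stack grid is the atlas grid refined by an integer
  per-axis factor, so the true stack-to-atlas map is known exactly (an
  identity in micrometre coordinates) and is stored with the scene.

What the generator deliberately does **not** model: stripe artifacts,
refraction, stitching seams, cell-density gradients within a region, and
non-spherical morphologies (e.g. microglial processes). Passing the
recovery benchmarks on synthetic scenes therefore demonstrates that the
pipeline's machinery is correct and well calibrated, not that the shipped
defaults transfer to any particular real acquisition — for real data the
model is meant to be retrained on annotated patches, exactly as the
training entry point supports.

Default study conditions used by the full-scale validation suite: a 24³
atlas at 20 µm refined ×8 to a 192³ stack at 2.5 µm, 3 500 cells/mm³
(≈ 380 cells per scene), SNR 4, illumination amplitude 0.2. Twenty 64³
patches are sampled *after* ventricle masking (the scene's ground-truth
lumen mask standing in for a manual mask) — training data prepared on
masked images teaches the network that masked-out regions and their sharp
edges are not cells — and split 16 train / 4 test, stratified by signal:
patches are ranked by foreground voxel count, divided at the median into
high- and low-signal strata, and the test set takes its proportional
share from each stratum.

# Ventricle masking

The pre-processing downsamples the stack to an isotropic working
resolution (default 25 µm) by anti-aliased box averaging, classifies each
voxel as ventricle or parenchyma, upsamples the binary mask back to stack
resolution, and zeroes the masked voxels. The classifier is a random
forest (100 trees) over per-voxel features computed at physical scales
of 25, 50 and 100 µm: Gaussian-smoothed intensity, gradient magnitude and
Laplacian of Gaussian. The feature family and scales are this package's
choice — pixel-classification tools leave them to the user — and are
recorded in a JSON sidecar next to the saved classifier so a mask is
reproducible from its inputs.

Mask upsampling interpolates bicubically within each z-plane (aliased
ventricle edges are an in-plane phenomenon at light-sheet anisotropy;
masking is applied plane-wise) and nearest across z, then binarizes at a
threshold of 0.5 (exposed). Masked voxels are set to 0 rather than NA so
the stack stays within its unsigned 16-bit contract.

# The segmentation network

The detector is a symmetric 3D encoder–decoder voxel classifier: two
3×3×3 convolutions with Mish activations per encoder level, 2× max
pooling between levels, nearest-neighbour upsampling plus skip
concatenation and two further convolutions per decoder level, and a 1×1×1
logit head. Channels start at `base_features` and double per level.
Training minimizes voxelwise binary cross-entropy; no model selection is
performed — the last epoch's checkpoint is kept.

Numerical engine: the network is implemented in compiled code
(single-precision im2col + BLAS GEMM convolutions with hand-derived
backpropagation). The test suite verifies the gradients against central
finite differences layer by layer. All stochastic pieces (weight
initialization, shuffling, flip/90°-rotation augmentation) draw from R's
RNG, so a seed fixes training bit-for-bit.

Choices the training recipe leaves open, and how they are set here:

* **Optimizer**: Adam with linear warmup over the first 5 % of steps and
  cosine decay to 10 % of the peak rate. This is a deliberate stand-in for
  the heavily-scheduled variance-rectifying optimizers popular in medical
  imaging; the acceptance surface of this package is synthetic-data
  recovery, not weight-level parity with any external training run.
* **Intensity normalization**: each volume is centered and scaled by a
  trimmed median/MAD estimate of its background distribution (zeros —
  padding and masked-out voxels — excluded; bright structures dropped by
  a 3.5-MAD trim; the ±3-MAD band maps to [0, 1]). Two properties drove
  this choice over simple percentile scaling. First, the upper tail must
  stay linear: labeled somata live in the top fraction of a percent of
  the histogram, and clipping them to the same value as the brightest
  noise erases the very contrast the detector needs. Second, the scale
  estimate must ignore bright non-cell structures: ventricle lumens
  occupy a few percent of a brain, enough to move a 99th percentile by
  tens of percent depending on whether masking is enabled, whereas the
  trimmed estimate is invariant to masking within about one percent —
  so masked and unmasked runs of one stack see the same intensity scale.
* **Head initialization**: the logit-head bias starts at −4, the logit of
  a ≈ 2 % foreground prior. With extremely imbalanced targets and plain
  BCE, a zero-initialized head spends a long plateau pushing the constant
  prediction down before it can begin detecting; starting at the sparse
  prior removes that plateau. This matters at the reduced epoch budgets
  used here (the original recipe trains 500 epochs and can afford the
  plateau).
* **Binarization threshold** 0.5; **sliding window** 64³–128³ with 0.25
  overlap and Gaussian blending (window-center predictions are trusted
  more than window borders); borders are reflect-padded and cropped back.

## Problem sizes of the validation benchmark

The recovery benchmark trains `depth = 3`, `base_features = 8` for
25 epochs (batch 4, lr 10⁻³) on 16 patches of 64³ voxels from the default
synthetic scene and requires instance F1 ≥ 0.85 and volumetric Dice ≥ 0.6
on 4 held-out patches. These sizes are the package's own desk-scale
calibration: with ~100 optimizer steps the task is learned with a
comfortable margin (measured F1 ≈ 0.92, Dice ≈ 0.85 at the shipped
seeds), and one training run completes in minutes on a single CPU core.

# Instance extraction

Connected components of the binarized probability map, with configurable
6/18/26-connectivity (default 26, the convention of the 3D
connected-components tools used in this field). Components are numbered
by first-voxel scan order, making labeling deterministic. The size filter
keeps volumes within inclusive user-defined bounds (defaults 4–5 000
voxels at the c-Fos acquisition scale) and is applied before atlas
mapping. Centroids are unweighted voxel centroids.

# Atlas mapping and registration

Cell centroids go voxel → micrometre → affine transform → atlas voxel
(floored) → region label. Out-of-atlas and background landings keep
region id 0 and are reported, never dropped. The per-cell table carries
coordinates in both spaces, the region id, acronym and ontology color;
the region table has one leaf region per row (zero-filled), with region
volumes measured from the atlas label grid itself — they are needed for
densities and no external source is assumed.

Registration is deliberately affine-only: a 12-parameter transform
(translation, log-scale, rotation, shear) maximizing normalized mutual
information over a seeded subsample of moving voxels, initialized from
image moments and refined by Nelder–Mead in two stages (translation +
scale first, then all 12 parameters). Deformable alignment is out of
scope; externally computed transforms can be imported from JSON and used
identically, which is also the interoperability path for point transports
computed by dedicated alignment tools.

# Region statistics

Densities are compared at a chosen structure level after aggregating each
leaf's count into its unique ancestor at that level (leaves shallower
than the level keep their own row; totals are conserved at every level).
Fiber tracts are excluded from testing — white matter does not carry the
neuronal-activity signal — but their cells still count toward per-sample
totals when the per-total normalization is chosen. Per region, a
two-sided unpaired t-test (Welch by default; pooled-variance Student
behind a flag) is followed by Benjamini–Hochberg adjustment at q = 0.1
applied within each level independently — the natural reading of
level-aware correction, since each level forms one family of tests; a
global-across-levels option exists. Note the published description of
this procedure conflates FDR and FWER terminology; what is controlled
here (and by the original implementation, which used standard BH
routines) is the false discovery rate. Log2 fold changes floor both group
means at half the smallest nonzero density in the matrix, so empty
regions stay finite while nonzero ratios are exact.

# Evaluation

Two tracks, scored globally: volumetric (voxelwise confusion) and
instance-level. A predicted cell overlapping any reference cell by ≥ 1
voxel is a true positive; a predicted cell with zero overlap is a false
positive; an undetected reference cell is a false negative. The rule is
asymmetric by construction — two predictions covering one reference cell
are both TPs, and TP + FN can exceed the reference count — and is kept
exactly as defined, because it is the definition under which the
published benchmark numbers were computed. Counts are summed across all
test patches before the Dice/sensitivity/precision formulas are applied
once (global scores, not means of per-patch scores; the instance F1 is
the instance Dice, equivalently the harmonic mean of precision and
sensitivity). Undefined metrics (zero denominators) surface as flagged
`NA` with a warning, never as silent zeros. An IoU-threshold matching
mode is intentionally absent from the default path: matching stricter
than 1-voxel overlap would change the metric the benchmark defines.

# Visualization

Image-space output paints each cell's voxels with its atlas region id and
ships a color lookup table, preserving the "threshold value = region id"
trick that makes the overlay explorable in standard viewers. Atlas-space
output is a per-voxel histogram of mapped centers, optionally normalized
per sample, Gaussian-smoothed (default σ = 2 atlas voxels = 100 µm at the
50 µm atlas scale; the kernel width is this package's choice) and
averaged within groups. 32-bit float TIFFs are written with values scaled
by 2⁻²⁴ — an exact exponent shift that keeps any float32 in the writer's
[0, 1] range losslessly; the readers undo it.

# Pipeline and degenerate inputs

`run_pipeline()` chains downsample → ventricle mask (optional) →
sliding-window inference → binarize → components → size filter →
register/import → map → tables → visualization, writing every
intermediate as TIFF/CSV/JSON plus a JSON run report. Stages whose
outputs exist are skipped on re-run, so intermediates are reusable by the
owning modules; two runs with one config and seed produce byte-identical
tables. Degenerate inputs are handled explicitly: all-constant images are
rejected by registration; single-class label sets are rejected by the
classifier; empty scenes/filters produce empty-but-well-formed tables;
out-of-bounds cells are counted as unassigned.

# Known limitations

* The synthetic generator's simplifications listed above; headline scores
  on synthetic scenes do not transfer to real stacks without retraining.
* Affine-only registration cannot absorb nonlinear clearing-induced
  deformation; use the transform import path with an external deformable
  aligner for real brains.
* The 1-voxel-overlap instance metric saturates when cells touch;
  watershed splitting of fused cells is out of scope by design.
* Training is CPU-bound single-precision; it is sized for desk-scale
  validation and fine-tuning, not for training on hundreds of 100³
  patches.
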